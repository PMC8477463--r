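#' Mono-exponential DWI signal model
#'
#' Predicts the diffusion-weighted signal S(b) = S(0) exp(-b * ADC) with ADC
#' expressed in 10^-6 mm^2/s and b in s/mm^2.
#'
#' @param s0 signal at b = 0 (a.u.), non-negative.
#' @param adc apparent diffusion coefficient in 10^-6 mm^2/s.
#' @param b diffusion sensitization in s/mm^2, non-negative.
#' @return predicted signal (vectorized over all arguments).
#' @export
predict_signal <- function(s0, adc, b) {
  if (any(b < 0)) stop("b must be non-negative")
  if (any(s0 < 0)) stop("s0 must be non-negative")
  s0 * exp(-b * adc * 1e-6)
}

#' Fit an ADC map from a multi-b DWI stack
#'
#' Per-voxel ordinary least squares of log-signal against b: the slope gives
#' the ADC, the intercept log S(0). Non-positive signals are floored at
#' `floor_eps` before the log; negative fitted ADCs are clamped to 0. Both
#' events are counted in the fit metadata.
#'
#' @param stack a [dwi_stack()].
#' @param b_subset optional subset of b-values to fit on (at least 2).
#' @param floor_eps floor applied to non-positive signals before the log
#'   (a.u.).
#' @param weighted if TRUE, weight each (b, log S) sample by S^2 — the
#'   first-order variance weighting for log-transformed data.
#' @return An `adc_map`: an [image_volume()] (modality "ADC", units
#'   10^-6 mm^2/s) with attributes `s0` (fitted S(0) array) and `fit_meta`
#'   (list: `b_used`, `n_floored`, `n_clamped`, `weighted`).
#' @export
fit_adc <- function(stack, b_subset = NULL, floor_eps = 1e-3,
                    weighted = FALSE) {
  stopifnot(inherits(stack, "dwi_stack"))
  b <- stack$b_values
  keep <- if (is.null(b_subset)) seq_along(b) else match(b_subset, b)
  if (anyNA(keep)) stop("b_subset contains b-values not in the stack")
  if (length(keep) < 2L) stop("at least 2 b-values are required for the fit")
  b_used <- b[keep]
  dims <- dim(stack$data)[1:3]
  nvox <- prod(dims)
  # voxels x b matrix of signals
  S <- matrix(stack$data[, , , keep, drop = FALSE], nrow = nvox)
  n_floored <- sum(S <= 0)
  S[S <= 0] <- floor_eps
  L <- log(S)
  if (!weighted) {
    # closed-form simple regression of log S on b, shared design
    bb <- b_used - mean(b_used)
    denom <- sum(bb^2)
    slope <- as.vector(L %*% bb) / denom        # d logS / d b  (negative)
    intercept <- rowMeans(L) - slope * mean(b_used)
  } else {
    W <- S^2
    sw <- rowSums(W)
    bw <- as.vector(W %*% b_used) / sw
    lw <- rowSums(W * L) / sw
    num <- as.vector((W * L) %*% b_used) - sw * bw * lw
    den <- as.vector(W %*% b_used^2) - sw * bw^2
    slope <- num / den
    intercept <- lw - slope * bw
  }
  adc <- -slope * 1e6                            # 10^-6 mm^2/s
  n_clamped <- sum(adc < 0)
  adc[adc < 0] <- 0
  vol <- image_volume(array(adc, dim = dims), spacing = stack$spacing,
                      modality = "ADC")
  attr(vol, "s0") <- array(exp(intercept), dim = dims)
  attr(vol, "fit_meta") <- list(b_used = b_used, n_floored = n_floored,
                                n_clamped = n_clamped, weighted = weighted)
  class(vol) <- c("adc_map", class(vol))
  vol
}
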