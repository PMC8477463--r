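#' First-order histogram statistics of a masked intensity sample
#'
#' Mean, sample SD (n-1 denominator), median, 5th and 95th percentiles
#' (linear interpolation between order statistics), skewness (Fisher-Pearson
#' with sample-size correction) and excess kurtosis (Fisher convention,
#' Gaussian -> 0, with sample-size correction). A zero-variance sample
#' returns skewness = kurtosis = 0 by convention.
#'
#' @param values numeric vector of in-mask intensities (at least one value).
#' @return named numeric vector: mean, std, median, p5, p95, skewness,
#'   kurtosis.
#' @export
first_order <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values)) stop("empty or NA sample")
  q <- unname(quantile(values, c(0.05, 0.5, 0.95), type = 7))
  s <- if (length(values) > 1L) sd(values) else 0
  if (s == 0) {
    sk <- 0; ku <- 0
  } else {
    n <- length(values)
    sk <- if (n >= 3L) e1071::skewness(values, type = 2) else NA_real_
    ku <- if (n >= 4L) e1071::kurtosis(values, type = 2) else NA_real_
  }
  c(mean = mean(values), std = s, median = q[2], p5 = q[1], p95 = q[3],
    skewness = sk, kurtosis = ku)
}

#' Lesion volume in millilitres
#'
#' @param mask a [lesion_mask()].
#' @return foreground voxel count times voxel volume (mm^3), divided by 1000.
#' @export
lesion_volume <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  sum(mask) * voxel_volume_mm3(mask) / 1000
}

#' Quantize in-mask intensities to integer gray levels
#'
#' Equal-width bins spanning the in-mask [min, max]; the maximum maps to the
#' top bin; a constant region maps entirely to level 0.
#'
#' @param volume an [image_volume()] or array.
#' @param mask a [lesion_mask()] or logical array on the same grid.
#' @param n_bins number of gray levels (>= 2).
#' @return integer array of levels 0..n_bins-1, NA outside the mask.
#' @export
quantize <- function(volume, mask, n_bins = 32) {
  if (n_bins < 2) stop("n_bins must be at least 2")
  v <- as.array(volume); m <- as.array(mask)
  if (!identical(dim(v), dim(m))) stop("volume and mask grids differ")
  lv <- array(NA_integer_, dim = dim(v))
  vals <- v[m]
  if (length(vals) == 0L) return(lv)
  rng <- range(vals)
  if (rng[2] == rng[1]) {
    lv[m] <- 0L
  } else {
    lev <- floor((vals - rng[1]) / (rng[2] - rng[1]) * n_bins)
    lev[lev >= n_bins] <- n_bins - 1L
    lv[m] <- as.integer(lev)
  }
  lv
}

#' The 13 unique 3D offset directions at distance 1
#'
#' One representative per +/- pair of the 26-neighborhood, the standard
#' direction set for a single aggregated 3D co-occurrence matrix.
#'
#' @return 13 x 3 integer matrix of (dx, dy, dz) offsets.
#' @export
offsets_3d <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), ]
  # keep one of each +/- pair: first nonzero component positive
  keep <- apply(g, 1, function(o) o[match(TRUE, o != 0)] > 0)
  unname(g[keep, , drop = FALSE])
}

#' Gray-level co-occurrence matrix
#'
#' Accumulates co-occurrence counts of quantized gray levels over the given
#' offsets; both voxels of a pair must lie inside the mask. With
#' `symmetric = TRUE` the transpose is added before normalization, so p(i, j)
#' sums to 1 over the directed-plus-reversed pairs.
#'
#' @param levels integer level array from [quantize()] (NA outside mask).
#' @param mask logical array; defaults to `!is.na(levels)`.
#' @param offsets integer matrix of (dx, dy, dz) offsets, one per row.
#' @param symmetric add the transpose before normalizing.
#' @param n_levels number of gray levels; defaults to `max(levels) + 1`.
#' @return A `glcm_matrix`: list with `p` (n_levels x n_levels probabilities),
#'   `diff_hist` (difference histogram p_{x-y}(k), k = 0..n_levels-1),
#'   `n_levels`, `offsets`, `symmetric`, `n_pairs`, and `valid` (FALSE when no
#'   co-occurring pair exists, e.g. a single-voxel mask).
#' @export
glcm <- function(levels, mask = NULL, offsets = offsets_3d(),
                 symmetric = TRUE, n_levels = NULL) {
  lv <- as.array(levels)
  if (is.null(mask)) mask <- !is.na(lv)
  m <- as.array(mask)
  offsets <- rbind(offsets)
  if (any(rowSums(abs(offsets)) == 0)) stop("offsets must be nonzero")
  if (is.null(n_levels)) n_levels <- max(lv[m], -1L) + 1L
  if (n_levels < 1L) stop("mask selects no voxels")
  d <- dim(lv)
  counts <- matrix(0, n_levels, n_levels)
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    src <- lapply(1:3, function(ax) {
      s <- seq_len(d[ax])
      s[s + o[ax] >= 1L & s + o[ax] <= d[ax]]
    })
    if (any(vapply(src, length, 1L) == 0L)) next
    dst <- lapply(1:3, function(ax) src[[ax]] + o[ax])
    a <- lv[src[[1]], src[[2]], src[[3]], drop = FALSE]
    b <- lv[dst[[1]], dst[[2]], dst[[3]], drop = FALSE]
    ok <- m[src[[1]], src[[2]], src[[3]], drop = FALSE] &
      m[dst[[1]], dst[[2]], dst[[3]], drop = FALSE]
    if (!any(ok)) next
    tab <- table(factor(a[ok], levels = 0:(n_levels - 1L)),
                 factor(b[ok], levels = 0:(n_levels - 1L)))
    counts <- counts + unclass(tab)
  }
  if (symmetric) counts <- counts + t(counts)
  total <- sum(counts)
  valid <- total > 0
  p <- if (valid) counts / total else counts
  k <- 0:(n_levels - 1L)
  dh <- numeric(n_levels)
  if (valid) {
    ii <- row(p) - 1L; jj <- col(p) - 1L
    dh <- as.vector(tapply(as.vector(p), abs(ii - jj), sum))
    dh <- c(dh, numeric(n_levels - length(dh)))
  }
  structure(list(p = unname(p), diff_hist = unname(dh), n_levels = n_levels,
                 offsets = offsets, symmetric = symmetric,
                 n_pairs = total / if (symmetric) 2 else 1, valid = valid),
            class = "glcm_matrix")
}

#' Haralick features of a co-occurrence matrix
#'
#' contrast = sum (i-j)^2 p(i,j); entropy = -sum p log p;
#' diff_entropy = -sum_k p_{x-y}(k) log p_{x-y}(k);
#' diff_variance = sum_k (k - mu_d)^2 p_{x-y}(k), the variance of the
#' difference histogram. 0 log 0 is taken as 0.
#'
#' @param P a `glcm_matrix` from [glcm()].
#' @param log_base "natural" (default) or "2".
#' @return named numeric vector: contrast, entropy, diff_variance,
#'   diff_entropy (all NA when `P$valid` is FALSE).
#' @export
glcm_features <- function(P, log_base = c("natural", "2")) {
  log_base <- match.arg(log_base)
  stopifnot(inherits(P, "glcm_matrix"))
  if (!P$valid)
    return(c(contrast = NA_real_, entropy = NA_real_,
             diff_variance = NA_real_, diff_entropy = NA_real_))
  if (abs(sum(P$p) - 1) > 1e-8) stop("co-occurrence matrix is not normalized")
  lg <- if (log_base == "natural") log else log2
  xlogx <- function(x) ifelse(x > 0, x * lg(x), 0)
  p <- P$p
  ii <- row(p) - 1L; jj <- col(p) - 1L
  contrast <- sum((ii - jj)^2 * p)
  entropy <- -sum(xlogx(p))
  k <- 0:(P$n_levels - 1L)
  dh <- P$diff_hist
  mu_d <- sum(k * dh)
  diff_variance <- sum((k - mu_d)^2 * dh)
  diff_entropy <- -sum(xlogx(dh))
  c(contrast = contrast, entropy = entropy,
    diff_variance = diff_variance, diff_entropy = diff_entropy)
}

#' Extract the 12 whole-lesion parameters from a masked volume
#'
#' Composes lesion volume, the seven first-order histogram statistics, and
#' the four co-occurrence texture features (contrast, entropy,
#' diff-variance, diff-entropy) computed on a quantized copy of the in-mask
#' intensities.
#'
#' @param volume an [image_volume()].
#' @param mask a [lesion_mask()] on the same grid.
#' @param n_bins gray levels for quantization (default 32).
#' @param offsets co-occurrence offsets (default [offsets_3d()]).
#' @param log_base entropy log base, "natural" or "2".
#' @param modality modality tag recorded in the output (defaults to the
#'   volume's).
#' @return one-row data.frame with columns modality, volume_ml, mean, std,
#'   median, p5, p95, skewness, kurtosis, contrast, entropy, diff_variance,
#'   diff_entropy, and an attribute `config` recording the extraction
#'   settings.
#' @export
extract_features <- function(volume, mask, n_bins = 32,
                             offsets = offsets_3d(),
                             log_base = c("natural", "2"),
                             modality = NULL) {
  log_base <- match.arg(log_base)
  if (!identical(dim(as.array(volume)), dim(as.array(mask))))
    stop("volume and mask grids differ")
  if (!any(mask)) stop("mask is empty")
  if (is.null(modality)) {
    modality <- attr(volume, "modality")
    if (is.null(modality)) modality <- "generic"
  }
  vals <- as.array(volume)[as.array(mask)]
  fo <- first_order(vals)
  lev <- quantize(volume, mask, n_bins = n_bins)
  g <- glcm(lev, mask = as.array(mask), offsets = offsets, symmetric = TRUE,
            n_levels = n_bins)
  tx <- glcm_features(g, log_base = log_base)
  out <- data.frame(modality = modality,
                    volume_ml = lesion_volume(mask),
                    t(fo), t(tx), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "config") <- list(n_bins = n_bins, offsets = offsets,
                              log_base = log_base, symmetric = TRUE)
  out
}
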