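#' Class-conditional feature calibration for the simulated cohort
#'
#' Per-feature means and standard deviations for the two diagnostic classes —
#' prostate cancer (PCa) and benign prostatic hyperplasia (BPH) — used as the
#' defaults of the cohort generator. The constants reproduce the whole-lesion
#' ADC (10^-6 mm^2/s) and T2W (arbitrary units) histogram/texture statistics
#' of a 3T biparametric prostate MRI cohort of 90 PCa and 112 BPH patients.
#' The "±" values are treated as between-patient SDs of per-lesion summaries.
#'
#' @return data.frame with columns `feature`, `pca_mean`, `pca_sd`,
#'   `bph_mean`, `bph_sd`.
#' @export
default_cohort_params <- function() {
  x <- rbind(
    c("ADC_p5",            557.661, 131.688,  795.973, 116.08),
    c("ADC_mean",          806.754, 131.268,  988.752, 106.763),
    c("ADC_median",        788.539, 140.309,  979.942, 111.27),
    c("ADC_std",           176.311,  48.874,  129.004,  45.47),
    c("ADC_diff_variance",   0.195,   0.032,    0.178,   0.04),
    c("ADC_diff_entropy",    0.757,   0.099,    0.707,   0.086),
    c("ADC_contrast",        0.628,   0.231,    0.488,   0.21),
    c("ADC_entropy",         1.748,   0.289,    1.605,   0.234),
    c("ADC_p95",          1123.756, 169.511, 1217.362, 142.675),
    c("ADC_skewness",        0.472,   0.597,    0.297,   0.575),
    c("ADC_kurtosis",        0.419,   1.212,    0.315,   1.311),
    c("T2W_kurtosis",        2.272,   2.179,    1.375,   1.598),
    c("T2W_skewness",        0.851,   0.558,    0.631,   0.413),
    c("T2W_p5",            171.594,  43.653,  193.165,  45.757),
    c("T2W_median",        259.822,  54.330,  278.165,  54.817),
    c("T2W_std",            68.67,   20.296,   61.937,  18.164),
    c("T2W_mean",          267.630,  56.500,  283.756,  55.486),
    c("T2W_entropy",         2.355,   0.291,    2.362,   0.279),
    c("T2W_diff_variance",   0.589,   0.178,    0.570,   0.162),
    c("T2W_p95",           391.011,  88.876,  393.134,  78.278),
    c("T2W_diff_entropy",    1.467,   0.158,    1.459,   0.157),
    c("T2W_contrast",        1.847,   0.689,    1.851,   0.665))
  data.frame(feature = x[, 1],
             pca_mean = as.numeric(x[, 2]), pca_sd = as.numeric(x[, 3]),
             bph_mean = as.numeric(x[, 4]), bph_sd = as.numeric(x[, 5]),
             stringsAsFactors = FALSE)
}

# Median lesion volumes (ml) of the two classes; used to size phantom lesions.
class_lesion_volume_ml <- c(PCa = 2.50, BPH = 1.05)

#' Ellipsoid semi-axes for a target volume
#'
#' @param volume_ml target lesion volume in ml.
#' @param axis_ratios relative semi-axis proportions (a:b:c).
#' @return numeric length-3 semi-axes in mm such that 4/3*pi*a*b*c equals the
#'   target volume.
#' @export
semi_axes_for_volume <- function(volume_ml, axis_ratios = c(1.25, 1, 0.8)) {
  if (volume_ml <= 0) stop("volume_ml must be positive")
  v_mm3 <- volume_ml * 1000
  r0 <- (3 * v_mm3 / (4 * pi * prod(axis_ratios)))^(1 / 3)
  r0 * axis_ratios
}

#' Phantom specification
#'
#' Describes one synthetic prostate-lesion acquisition: an ellipsoidal lesion
#' embedded in a homogeneous background, imaged as a multi-b DWI stack (via
#' the mono-exponential signal model with Rician noise) and a T2W volume.
#' Within-lesion heterogeneity comes from Gaussian-smoothed white noise scaled
#' to the requested mean/SD; the T2W field additionally passes through a
#' sinh-arcsinh transform to hit a target skewness.
#'
#' @param class_label "PCa" or "BPH"; picks class defaults for all
#'   unspecified intensity parameters.
#' @param grid_shape voxels per axis.
#' @param voxel_spacing mm per axis (default: the DWI grid of the emulated
#'   protocol, 224x280 mm FOV on a 120x150 matrix with 4 mm slices, i.e.
#'   1.867 x 1.867 x 4 mm).
#' @param lesion_volume_ml lesion volume in ml (default: class median).
#' @param lesion_shape ellipsoid semi-axes in mm (overrides
#'   `lesion_volume_ml`).
#' @param lesion_adc_mean,lesion_adc_sd within-lesion true-ADC mean/SD in
#'   10^-6 mm^2/s.
#' @param background_adc_mean background ADC in 10^-6 mm^2/s.
#' @param t2w_mean,t2w_sd,t2w_skew_target within-lesion T2W moments (a.u.).
#' @param background_t2w_mean background T2W intensity (a.u.).
#' @param s0_mean b=0 signal amplitude (a.u.).
#' @param noise_sigma Rician noise scale (a.u.); default gives SNR ~ 50 at
#'   b = 0.
#' @param texture_smoothing_fwhm Gaussian smoothing FWHM in mm for the
#'   within-lesion random fields.
#' @param b_values diffusion sensitizations in s/mm^2 (strictly increasing,
#'   starting at 0).
#' @param rng_seed integer seed; identical spec + seed gives bit-identical
#'   phantoms.
#' @return A validated `phantom_spec` list.
#' @export
phantom_spec <- function(class_label = c("PCa", "BPH"),
                         grid_shape = c(48, 48, 20),
                         voxel_spacing = c(224 / 120, 280 / 150, 4),
                         lesion_volume_ml = NULL,
                         lesion_shape = NULL,
                         lesion_adc_mean = NULL,
                         lesion_adc_sd = NULL,
                         background_adc_mean = 1400,
                         t2w_mean = NULL,
                         t2w_sd = NULL,
                         t2w_skew_target = NULL,
                         background_t2w_mean = 150,
                         s0_mean = 1000,
                         noise_sigma = 20,
                         texture_smoothing_fwhm = 3,
                         b_values = c(0, 500, 800, 1000, 1500, 2000),
                         rng_seed = 1L) {
  class_label <- match.arg(class_label)
  p <- default_cohort_params()
  pick <- function(feature) {
    if (class_label == "PCa") p$pca_mean[p$feature == feature]
    else p$bph_mean[p$feature == feature]
  }
  if (is.null(lesion_adc_mean)) lesion_adc_mean <- pick("ADC_mean")
  if (is.null(lesion_adc_sd)) lesion_adc_sd <- pick("ADC_std")
  if (is.null(t2w_mean)) t2w_mean <- pick("T2W_mean")
  if (is.null(t2w_sd)) t2w_sd <- pick("T2W_std")
  if (is.null(t2w_skew_target)) t2w_skew_target <- pick("T2W_skewness")
  if (is.null(lesion_volume_ml))
    lesion_volume_ml <- class_lesion_volume_ml[[class_label]]
  if (is.null(lesion_shape))
    lesion_shape <- semi_axes_for_volume(lesion_volume_ml)
  spec <- list(class_label = class_label,
               grid_shape = as.integer(grid_shape),
               voxel_spacing = as.numeric(voxel_spacing),
               lesion_shape = as.numeric(lesion_shape),
               lesion_adc_mean = lesion_adc_mean,
               lesion_adc_sd = lesion_adc_sd,
               background_adc_mean = background_adc_mean,
               t2w_mean = t2w_mean, t2w_sd = t2w_sd,
               t2w_skew_target = t2w_skew_target,
               background_t2w_mean = background_t2w_mean,
               s0_mean = s0_mean, noise_sigma = noise_sigma,
               texture_smoothing_fwhm = texture_smoothing_fwhm,
               b_values = as.numeric(b_values),
               rng_seed = as.integer(rng_seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (length(grid_shape) != 3L || any(grid_shape < 1))
      stop("grid_shape must be 3 positive integers")
    if (any(voxel_spacing <= 0)) stop("voxel_spacing must be positive")
    if (any(lesion_shape <= 0)) stop("lesion semi-axes must be positive")
    if (lesion_adc_sd < 0 || t2w_sd < 0 || noise_sigma < 0 ||
        texture_smoothing_fwhm < 0)
      stop("SDs, noise_sigma and smoothing FWHM must be non-negative")
    if (b_values[1] != 0) stop("b_values must start at 0")
    if (any(diff(b_values) <= 0)) stop("b_values must be strictly increasing")
    # lesion (centered) must fit inside the field of view
    fov_half <- grid_shape * voxel_spacing / 2
    if (any(lesion_shape >= fov_half))
      stop("lesion does not fit inside the grid")
  })
  invisible(spec)
}

# Separable 3D Gaussian smoothing; sigma in voxels per axis, kernel truncated
# at 3 sigma, renormalized at the borders.
smooth_gaussian <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- dnorm(seq(-half, half), sd = s)
    k <- k / sum(k)
    arr <- convolve_axis(arr, k, ax)
  }
  arr
}

# 1D convolution along one axis with border renormalization (zero padding
# divided by the in-bounds kernel mass).
convolve_axis <- function(arr, k, ax) {
  d <- dim(arr)
  half <- (length(k) - 1L) %/% 2L
  perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(arr, perm)
  n <- dim(a)[1]
  m <- matrix(a, nrow = n)
  out <- matrix(0, nrow = n, ncol = ncol(m))
  norm <- numeric(n)
  for (off in seq_along(k)) {
    sh <- off - half - 1L
    src <- seq_len(n) + sh
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + k[off] * m[src[ok], ]
    norm[ok] <- norm[ok] + k[off]
  }
  out <- out / norm
  a <- array(out, dim = dim(a))
  aperm(a, order(perm))
}

# sinh-arcsinh skewing: X = sinh(asinh(Z) + eps) for standard normal Z.
# Population skewness is monotone in eps; invert numerically for a target.
sas_transform <- function(z, eps) sinh(asinh(z) + eps)

sas_population_skewness <- function(eps) {
  mom <- function(k) {
    integrate(function(z) sas_transform(z, eps)^k * dnorm(z),
              -Inf, Inf, rel.tol = 1e-10)$value
  }
  m1 <- mom(1); m2 <- mom(2); m3 <- mom(3)
  v <- m2 - m1^2
  (m3 - 3 * m1 * v - m1^3) / v^1.5
}

sas_eps_for_skewness <- function(target) {
  if (abs(target) < 1e-12) return(0)
  if (abs(target) > 5) stop("skewness target out of supported range [-5, 5]")
  uniroot(function(e) sas_population_skewness(e) - target,
          interval = c(-1.6, 1.6), tol = 1e-8)$root
}

rician <- function(signal, sigma) {
  if (sigma == 0) return(signal)
  n <- length(signal)
  sqrt((signal + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
}

# Ellipsoid mask at the grid center, semi-axes in mm, voxel-center convention.
ellipsoid_mask <- function(grid_shape, spacing, semi_axes) {
  ctr <- grid_shape * spacing / 2
  xs <- ((seq_len(grid_shape[1]) - 0.5) * spacing[1] - ctr[1]) / semi_axes[1]
  ys <- ((seq_len(grid_shape[2]) - 0.5) * spacing[2] - ctr[2]) / semi_axes[2]
  zs <- ((seq_len(grid_shape[3]) - 0.5) * spacing[3] - ctr[3]) / semi_axes[3]
  r2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  r2 <= 1
}

# Smoothed white-noise field standardized over `mask` to mean 0, SD 1.
# Returns zeros when the in-mask field is degenerate.
textured_field <- function(grid_shape, sigma_vox, mask) {
  f <- smooth_gaussian(array(rnorm(prod(grid_shape)), dim = grid_shape),
                       sigma_vox)
  v <- f[mask]
  s <- sd(v)
  if (!is.finite(s) || s == 0) return(array(0, dim = grid_shape))
  (f - mean(v)) / s
}

#' Generate a synthetic multi-modal lesion phantom
#'
#' Builds the true ADC field (homogeneous background, textured lesion),
#' synthesizes the DWI stack via S(b) = S(0) exp(-b ADC) with Rician noise,
#' generates an analogous T2W volume with the requested skewness, and returns
#' the ground-truth lesion mask.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `dwi` (`dwi_stack`), `t2w` (`image_volume`),
#'   `mask` (`lesion_mask`, ground truth), `adc_true` (`image_volume`, the
#'   generating ADC field), and `class_label`.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  set.seed(spec$rng_seed)
  gs <- spec$grid_shape; sp <- spec$voxel_spacing
  sigma_vox <- (spec$texture_smoothing_fwhm / 2.35482) / sp
  msk <- ellipsoid_mask(gs, sp, spec$lesion_shape)
  if (!any(msk)) stop("lesion contains no voxels at this resolution")

  adc <- array(spec$background_adc_mean, dim = gs)
  z_adc <- textured_field(gs, sigma_vox, msk)
  adc[msk] <- spec$lesion_adc_mean + spec$lesion_adc_sd * z_adc[msk]
  adc[adc < 0] <- 0

  dwi_vols <- lapply(spec$b_values, function(b) {
    s <- spec$s0_mean * exp(-b * adc * 1e-6)
    array(rician(s, spec$noise_sigma), dim = gs)
  })

  z_t2 <- textured_field(gs, sigma_vox, msk)
  eps <- sas_eps_for_skewness(spec$t2w_skew_target)
  w <- sas_transform(z_t2, eps)
  wv <- w[msk]
  sw <- sd(wv)
  if (is.finite(sw) && sw > 0) w <- (w - mean(wv)) / sw else w[] <- 0
  t2 <- array(spec$background_t2w_mean, dim = gs)
  t2[msk] <- spec$t2w_mean + spec$t2w_sd * w[msk]
  t2 <- array(rician(t2, spec$noise_sigma), dim = gs)

  list(dwi = dwi_stack(dwi_vols, spec$b_values, spacing = sp),
       t2w = image_volume(t2, spacing = sp, modality = "T2W"),
       mask = lesion_mask(msk, spacing = sp),
       adc_true = image_volume(adc, spacing = sp, modality = "ADC"),
       class_label = spec$class_label)
}

#' Cohort specification
#'
#' A two-class simulated patient cohort. In fast mode each patient is a draw
#' of the 22 whole-lesion features from class-conditional normal
#' distributions; in image mode each patient gets a full phantom whose
#' lesion-level parameters are drawn from between-patient distributions.
#'
#' @param n_pca,n_bph class sizes (defaults 90 and 112, the emulated cohort).
#' @param params calibration data.frame as returned by
#'   [default_cohort_params()]; means/SDs are interpreted as between-patient.
#' @param template_pca,template_bph `phantom_spec`s used in image mode.
#' @param master_seed integer; per-patient seeds are derived deterministically
#'   from it.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_pca = 90, n_bph = 112,
                        params = default_cohort_params(),
                        template_pca = NULL, template_bph = NULL,
                        master_seed = 1L) {
  if (n_pca < 1 || n_bph < 1)
    stop("both classes need at least one patient")
  stopifnot(all(c("feature", "pca_mean", "pca_sd", "bph_mean", "bph_sd")
                %in% names(params)))
  if (any(params$pca_sd < 0) || any(params$bph_sd < 0))
    stop("between-patient SDs must be non-negative")
  structure(list(n_pca = as.integer(n_pca), n_bph = as.integer(n_bph),
                 params = params,
                 template_pca = template_pca, template_bph = template_bph,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

# Counter-based derivation of per-patient / per-stage seeds from a master
# seed; keeps results below 2^31 - 1.
derive_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) * 2654435761 + index * 40503 + 17) %%
               2147483647)
}

#' Generate a simulated two-class cohort
#'
#' @param cohort a [cohort_spec()].
#' @param mode "fast" draws per-patient feature vectors directly from the
#'   class-conditional distributions; "image" synthesizes a full phantom per
#'   patient (lesion-level ADC/T2W parameters drawn between patients).
#' @return fast mode: data.frame with `patient_id`, `label` and one column per
#'   feature. image mode: list of per-patient records, each with `patient_id`,
#'   `label`, `spec` and the [generate_phantom()] output.
#' @export
generate_cohort <- function(cohort, mode = c("fast", "image")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "cohort_spec"))
  n <- cohort$n_pca + cohort$n_bph
  labels <- rep(c("PCa", "BPH"), c(cohort$n_pca, cohort$n_bph))
  ids <- sprintf("P%03d", seq_len(n))
  p <- cohort$params
  if (mode == "fast") {
    rows <- lapply(seq_len(n), function(i) {
      set.seed(derive_seed(cohort$master_seed, i))
      mu <- if (labels[i] == "PCa") p$pca_mean else p$bph_mean
      sdv <- if (labels[i] == "PCa") p$pca_sd else p$bph_sd
      stats::setNames(rnorm(nrow(p), mu, sdv), p$feature)
    })
    out <- data.frame(patient_id = ids, label = labels,
                      do.call(rbind, rows), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    return(out)
  }
  pickp <- function(lab, feature, col) {
    v <- p[p$feature == feature, ]
    if (lab == "PCa") v[[paste0("pca_", col)]] else v[[paste0("bph_", col)]]
  }
  lapply(seq_len(n), function(i) {
    lab <- labels[i]
    seed_i <- derive_seed(cohort$master_seed, i)
    set.seed(seed_i)
    template <- if (lab == "PCa") cohort$template_pca else cohort$template_bph
    if (is.null(template)) template <- phantom_spec(class_label = lab)
    # between-patient draws of the lesion-level generating parameters
    template$lesion_adc_mean <- rnorm(1, pickp(lab, "ADC_mean", "mean"),
                                      pickp(lab, "ADC_mean", "sd"))
    template$lesion_adc_sd <- max(1, rnorm(1, pickp(lab, "ADC_std", "mean"),
                                           pickp(lab, "ADC_std", "sd")))
    template$t2w_mean <- rnorm(1, pickp(lab, "T2W_mean", "mean"),
                               pickp(lab, "T2W_mean", "sd"))
    template$t2w_sd <- max(1, rnorm(1, pickp(lab, "T2W_std", "mean"),
                                    pickp(lab, "T2W_std", "sd")))
    template$rng_seed <- derive_seed(seed_i, 1L)
    validate_phantom_spec(template)
    rec <- generate_phantom(template)
    c(list(patient_id = ids[i], label = lab, spec = template), rec)
  })
}
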