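#' Gaussian edge weights on the 6-connected lattice
#'
#' Rescales the volume intensities to [0, 1] over their full range and sets
#' the weight of every 6-neighbor edge (i, j) to exp(-beta * (g_i - g_j)^2),
#' the Gaussian intensity-difference functional of Grady-style random-walker
#' segmentation. A constant volume (zero range) skips the rescaling and gives
#' unit weights everywhere.
#'
#' @param volume an [image_volume()] or 3D array with finite values.
#' @param beta non-negative contrast sensitivity (dimensionless).
#' @return list with `edges` (2-column matrix of linear voxel indices),
#'   `weights` in (0, 1], and `dims`.
#' @export
edge_weights <- function(volume, beta) {
  if (beta < 0) stop("beta must be non-negative")
  v <- as.array(volume)
  if (any(!is.finite(v))) stop("volume must be finite")
  d <- dim(v)
  rng <- range(v)
  g <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else array(0, d)
  idx <- array(seq_len(prod(d)), dim = d)
  edges <- vector("list", 3)
  for (ax in 1:3) {
    if (d[ax] < 2) next
    lo <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    hi <- lo
    lo[[ax]] <- seq_len(d[ax] - 1L)
    hi[[ax]] <- 2:d[ax]
    from <- idx[lo[[1]], lo[[2]], lo[[3]]]
    to <- idx[hi[[1]], hi[[2]], hi[[3]]]
    edges[[ax]] <- cbind(as.vector(from), as.vector(to))
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges)) stop("grid has no edges")
  w <- exp(-beta * (g[edges[, 1]] - g[edges[, 2]])^2)
  list(edges = edges, weights = w, dims = d)
}

#' Random-walker foreground probability map
#'
#' Solves the combinatorial Dirichlet problem on the intensity-weighted
#' lattice graph: each unseeded voxel receives the probability that a random
#' walk started there reaches a foreground seed before a background seed,
#' which is the discrete harmonic function with the seed values (1 for
#' foreground, 0 for background) as boundary conditions. The sparse
#' symmetric positive-definite system is solved directly (Matrix package
#' sparse Cholesky).
#'
#' @param volume the guidance image (typically the b = 1500 s/mm^2 DWI
#'   volume).
#' @param seeds a [seed_labels()] object on the same grid.
#' @param beta contrast sensitivity of [edge_weights()].
#' @param tol maximum admissible residual of the linear solve.
#' @return A `probability_map`: numeric array in [0, 1] with attributes
#'   `residual`, `beta`, and `spacing`.
#' @export
random_walker <- function(volume, seeds, beta = 130, tol = 1e-8) {
  stopifnot(inherits(seeds, "seed_labels"))
  if (tol <= 0) stop("tol must be positive")
  d <- dim(as.array(volume))
  if (!identical(as.integer(d), seeds$grid_shape))
    stop("seeds and volume grids differ")
  ew <- edge_weights(volume, beta)
  n <- prod(d)
  seeded <- c(seeds$foreground, seeds$background)
  seed_val <- rep(c(1, 0), c(length(seeds$foreground),
                             length(seeds$background)))
  prob <- rep(NA_real_, n)
  prob[seeded] <- seed_val
  free <- which(is.na(prob))

  if (length(free) > 0L) {
    # graph components without any seed cannot be determined; flag with 0.5
    unreached <- integer(0)
    if (any(ew$weights == 0)) {
      comp <- lattice_components(n, ew$edges[ew$weights > 0, , drop = FALSE])
      seeded_comps <- unique(comp[seeded])
      unreached <- which(!(comp %in% seeded_comps))
      if (length(unreached) > 0L) {
        warning("graph component disconnected from all seeds; assigned 0.5")
        prob[unreached] <- 0.5
        free <- setdiff(free, unreached)
      }
    }
    if (length(free) > 0L) {
      W <- Matrix::sparseMatrix(i = ew$edges[, 1], j = ew$edges[, 2],
                                x = ew$weights, dims = c(n, n),
                                symmetric = TRUE)
      deg <- Matrix::rowSums(W)
      L <- Matrix::Diagonal(n, deg) - W
      Luu <- L[free, free, drop = FALSE]
      rhs <- -as.vector(L[free, seeded, drop = FALSE] %*% seed_val)
      x <- as.vector(Matrix::solve(Luu, rhs))
      resid <- max(abs(as.vector(Luu %*% x) - rhs))
      if (!is.finite(resid) || resid > tol)
        warning(sprintf("solver residual %.3g exceeds tol %.3g", resid, tol))
      prob[free] <- pmin(1, pmax(0, x))
      attr_res <- resid
    } else attr_res <- 0
  } else attr_res <- 0

  sp <- attr(volume, "spacing")
  structure(array(prob, dim = d),
            residual = attr_res, beta = beta,
            spacing = if (is.null(sp)) c(1, 1, 1) else sp,
            class = c("probability_map", "array"))
}

# Connected components over an undirected edge list; iterative label
# propagation (only used when some weights underflow to exactly 0).
lattice_components <- function(n, edges) {
  comp <- seq_len(n)
  if (nrow(edges) == 0L) return(comp)
  repeat {
    a <- pmin(comp[edges[, 1]], comp[edges[, 2]])
    changed <- FALSE
    for (col in 1:2) {
      upd <- a < comp[edges[, col]]
      if (any(upd)) {
        changed <- TRUE
        comp[edges[upd, col]] <- a[upd]
      }
    }
    comp <- comp[comp]   # path compression
    if (!changed) break
  }
  comp
}

#' Threshold a probability map into a lesion mask
#'
#' @param prob a `probability_map` from [random_walker()].
#' @param level decision threshold in (0, 1); voxels with probability >=
#'   `level` become foreground, so seeds always keep their own label.
#' @return A [lesion_mask()].
#' @export
threshold_mask <- function(prob, level = 0.5) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  sp <- attr(prob, "spacing")
  lesion_mask(array(prob >= level, dim = dim(prob)),
              spacing = if (is.null(sp)) c(1, 1, 1) else sp)
}

#' Propagate a lesion mask to another volume's grid
#'
#' Copies the mask when the grids are identical; otherwise resamples it by
#' nearest neighbor in world coordinates. Both grids are assumed to share the
#' field-of-view corner, with voxel centers at (index - 0.5) * spacing.
#'
#' @param mask a [lesion_mask()].
#' @param target an [image_volume()] defining the output grid.
#' @return A [lesion_mask()] on the target grid.
#' @export
propagate_mask <- function(mask, target) {
  stopifnot(inherits(mask, "lesion_mask"))
  sp_s <- attr(mask, "spacing")
  sp_t <- attr(target, "spacing")
  if (identical(dim(mask), dim(target)) && isTRUE(all.equal(sp_s, sp_t)))
    return(lesion_mask(array(mask, dim = dim(mask)), spacing = sp_s))
  d_t <- dim(target); d_s <- dim(mask)
  # nearest source voxel per axis for each target voxel center
  near <- lapply(1:3, function(ax) {
    world <- (seq_len(d_t[ax]) - 0.5) * sp_t[ax]
    # nearest center: round half up of world/spacing + 0.5
    src <- floor(world / sp_s[ax] + 1)
    as.integer(src)
  })
  inside <- lapply(1:3, function(ax) near[[ax]] >= 1L & near[[ax]] <= d_s[ax])
  if (!any(inside[[1]]) || !any(inside[[2]]) || !any(inside[[3]]))
    stop("target grid does not overlap the mask's field of view")
  out <- array(FALSE, dim = d_t)
  ii <- which(inside[[1]]); jj <- which(inside[[2]]); kk <- which(inside[[3]])
  out[ii, jj, kk] <-
    array(mask, dim = d_s)[near[[1]][ii], near[[2]][jj], near[[3]][kk]]
  lesion_mask(out, spacing = sp_t)
}

#' Segment a lesion from seeds
#'
#' Convenience wrapper: random walker + threshold.
#'
#' @inheritParams random_walker
#' @inheritParams threshold_mask
#' @return A [lesion_mask()].
#' @export
segment_lesion <- function(volume, seeds, beta = 130, tol = 1e-8,
                           level = 0.5) {
  threshold_mask(random_walker(volume, seeds, beta = beta, tol = tol),
                 level = level)
}
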