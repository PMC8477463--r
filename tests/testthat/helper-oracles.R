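# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from first principles, without calling the package
# implementations they check.

# AUC by explicit concordant-pair counting with half credit for ties,
# oriented so that the positive class scores high.
oracle_auc <- function(scores, is_pos) {
  pos <- scores[is_pos]
  neg <- scores[!is_pos]
  total <- 0
  for (x in pos) total <- total + sum(x > neg) + 0.5 * sum(x == neg)
  total / (length(pos) * length(neg))
}

# Random-walker probabilities by assembling the full dense graph Laplacian of
# the 6-connected lattice and solving with base::solve.
oracle_walker <- function(vol, fg_lin, bg_lin, beta) {
  v <- as.array(vol)
  d <- dim(v)
  n <- prod(d)
  rng <- range(v)
  g <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else array(0, d)
  W <- matrix(0, n, n)
  lin <- function(i, j, k) i + (j - 1) * d[1] + (k - 1) * d[1] * d[2]
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- lin(i, j, k)
    for (o in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
      ii <- i + o[1]; jj <- j + o[2]; kk <- k + o[3]
      if (ii <= d[1] && jj <= d[2] && kk <= d[3]) {
        b <- lin(ii, jj, kk)
        w <- exp(-beta * (g[a] - g[b])^2)
        W[a, b] <- w; W[b, a] <- w
      }
    }
  }
  L <- diag(rowSums(W)) - W
  seeded <- c(fg_lin, bg_lin)
  vals <- rep(c(1, 0), c(length(fg_lin), length(bg_lin)))
  free <- setdiff(seq_len(n), seeded)
  x <- rep(NA_real_, n)
  x[seeded] <- vals
  x[free] <- solve(L[free, free], -L[free, seeded, drop = FALSE] %*% vals)
  array(x, dim = d)
}

# GLCM probabilities by explicit enumeration of every voxel/offset pair.
oracle_glcm <- function(levels, mask, offsets, n_levels, symmetric = TRUE) {
  d <- dim(levels)
  counts <- matrix(0, n_levels, n_levels)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    for (r in seq_len(nrow(offsets))) {
      ii <- i + offsets[r, 1]; jj <- j + offsets[r, 2]; kk <- k + offsets[r, 3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3])
        next
      if (!mask[ii, jj, kk]) next
      a <- levels[i, j, k] + 1L; b <- levels[ii, jj, kk] + 1L
      counts[a, b] <- counts[a, b] + 1
    }
  }
  if (symmetric) counts <- counts + t(counts)
  counts / sum(counts)
}

# Percentile by direct linear interpolation between sorted order statistics
# (the type-7 rule, written out by hand).
oracle_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Rician corruption of a clean magnitude signal.
rician_noise <- function(signal, sigma) {
  sqrt((signal + rnorm(length(signal), 0, sigma))^2 +
         rnorm(length(signal), 0, sigma)^2)
}

# Small helper: fast-mode cohort AUC for one seeded replicate of the
# two-class normal model.
simulate_feature_auc <- function(n_pos, n_neg, mu_pos, sd_pos, mu_neg, sd_neg,
                                 seed) {
  set.seed(seed)
  scores <- c(rnorm(n_pos, mu_pos, sd_pos), rnorm(n_neg, mu_neg, sd_neg))
  labels <- rep(c("PCa", "BPH"), c(n_pos, n_neg))
  roc(scores, labels, positive = "PCa")$auc
}

# Strip class/attributes for plain-value array comparisons.
as_plain <- function(x) array(as.vector(x), dim(x))
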