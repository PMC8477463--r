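test_that("first-order statistics match their conventions", {
  fo <- first_order(c(5, 5, 5))
  expect_equal(unname(fo[c("mean", "std", "skewness", "kurtosis")]),
               c(5, 0, 0, 0))
  fo <- first_order(1:5)
  expect_equal(unname(fo[c("mean", "median", "skewness")]), c(3, 3, 0))
  fo <- first_order(1:100)
  expect_equal(unname(fo["p5"]), 5.95)
  expect_equal(unname(fo["p95"]), 95.05)
  expect_error(first_order(numeric(0)), "empty")
})

test_that("percentiles agree with a hand-rolled order-statistic oracle", {
  set.seed(41)
  for (rep in 1:10) {
    x <- rnorm(sample(5:200, 1))
    fo <- first_order(x)
    expect_equal(unname(fo["p5"]), oracle_percentile(x, 0.05))
    expect_equal(unname(fo["p95"]), oracle_percentile(x, 0.95))
    expect_equal(unname(fo["median"]), oracle_percentile(x, 0.5))
  }
})

test_that("lesion volume is count times voxel volume", {
  m <- array(FALSE, c(10, 10, 10)); m[1:10, 1:10, 1:10] <- TRUE
  expect_equal(lesion_volume(lesion_mask(m, spacing = c(1, 1, 1))), 1.0)
  expect_equal(lesion_volume(lesion_mask(array(FALSE, c(4, 4, 4)))), 0)
  # 625 voxels on the emulated DWI grid (1.867 x 1.867 x 4 mm)
  m2 <- array(FALSE, c(25, 25, 1)); m2[1:25, 1:25, 1] <- TRUE
  expect_equal(lesion_volume(lesion_mask(m2, spacing = c(1.867, 1.867, 4))),
               8.715, tolerance = 1e-3)
})

test_that("quantization uses equal-width bins with top-bin closure", {
  v <- array(c(0, 0.5, 1), c(3, 1, 1))
  m <- array(TRUE, c(3, 1, 1))
  expect_equal(as.vector(quantize(v, m, 4)), c(0L, 2L, 3L))
  expect_true(all(quantize(array(7, c(2, 2, 2)),
                           array(TRUE, c(2, 2, 2)), 8) == 0L))
  expect_error(quantize(v, m, 1), "at least 2")
  set.seed(42)
  u <- array(runif(1e5), c(100, 100, 10))
  lev <- quantize(u, array(TRUE, dim(u)), 32)
  chi <- chisq.test(tabulate(lev + 1L, 32))
  expect_gt(chi$p.value, 0.01)
})

test_that("co-occurrence matrices match hand enumeration", {
  lv <- array(c(0L, 0L, 1L, 1L), c(4, 1, 1))
  g <- glcm(lv, offsets = matrix(c(1, 0, 0), 1), symmetric = TRUE)
  expect_equal(g$p, matrix(c(2, 1, 1, 2) / 6, 2))
  expect_equal(g$diff_hist, c(4 / 6, 2 / 6))
  # checkerboard: all mass off-diagonal for a single-axis offset
  cb <- array(as.integer((outer(1:4, 1:4, "+") + 1) %% 2), c(4, 4, 1))
  gcb <- glcm(cb, offsets = matrix(c(1, 0, 0), 1))
  expect_equal(sum(diag(gcb$p)), 0)
  # constant region: all mass at p(0,0)
  gc <- glcm(array(0L, c(3, 3, 3)))
  expect_equal(gc$p[1, 1], 1)
  # single voxel: no valid pair
  one <- array(NA_integer_, c(3, 3, 3)); one[2, 2, 2] <- 0L
  g1 <- glcm(one, n_levels = 2)
  expect_false(g1$valid)
  expect_true(all(is.na(glcm_features(g1))))
})

test_that("GLCM agrees with brute-force pair enumeration on random masks", {
  set.seed(43)
  for (rep in 1:3) {
    d <- c(sample(4:8, 1), sample(4:8, 1), sample(4:8, 1))
    m <- array(runif(prod(d)) > 0.3, d)
    if (!any(m)) next
    v <- array(rnorm(prod(d)), d)
    lv <- quantize(v, m, 6)
    offs <- offsets_3d()[sample(13, 5), , drop = FALSE]
    got <- glcm(lv, mask = m, offsets = offs, n_levels = 6)
    want <- oracle_glcm(lv, m, offs, 6)
    expect_lt(max(abs(got$p - want)), 1e-12)
  }
})

test_that("Haralick features evaluate to their closed forms", {
  # uniform 2x2 matrix
  gu <- structure(list(p = matrix(0.25, 2, 2), diff_hist = c(0.5, 0.5),
                       n_levels = 2L, valid = TRUE), class = "glcm_matrix")
  f <- glcm_features(gu)
  expect_equal(unname(f), c(0.5, log(4), 0.25, log(2)))
  # diagonal matrix: no transitions
  gd <- structure(list(p = diag(2) / 2, diff_hist = c(1, 0),
                       n_levels = 2L, valid = TRUE), class = "glcm_matrix")
  f <- glcm_features(gd)
  expect_equal(unname(f[c("contrast", "diff_variance", "diff_entropy")]),
               c(0, 0, 0))
  # hand-enumerated example from above
  g <- glcm(array(c(0L, 0L, 1L, 1L), c(4, 1, 1)),
            offsets = matrix(c(1, 0, 0), 1))
  expect_equal(unname(glcm_features(g)["contrast"]), 1 / 3)
  # log base 2 option
  expect_equal(unname(glcm_features(gu, log_base = "2")["entropy"]), 2)
})

test_that("entropies respect their combinatorial upper bounds", {
  set.seed(44)
  d <- c(7, 7, 7)
  v <- array(rnorm(prod(d)), d)
  m <- array(TRUE, d)
  for (nb in c(4, 16, 32)) {
    g <- glcm(quantize(v, m, nb), mask = m, n_levels = nb)
    f <- glcm_features(g)
    expect_lte(f[["entropy"]], log(nb^2))
    expect_lte(f[["diff_entropy"]], log(nb))
  }
})

test_that("adding a constant shifts location features and nothing else", {
  set.seed(45)
  d <- c(8, 8, 6)
  v <- array(rnorm(prod(d), 900, 150), d)
  m <- array(runif(prod(d)) > 0.4, d)
  a <- extract_features(image_volume(v), lesion_mask(m))
  b <- extract_features(image_volume(v + 250), lesion_mask(m))
  for (col in c("mean", "median", "p5", "p95"))
    expect_equal(b[[col]], a[[col]] + 250)
  for (col in c("std", "skewness", "kurtosis", "contrast", "entropy",
                "diff_variance", "diff_entropy", "volume_ml"))
    expect_equal(b[[col]], a[[col]], tolerance = 1e-10)
})

test_that("feature extraction composes deterministically and handles edge cases", {
  d <- c(6, 6, 4)
  v <- image_volume(array(42, d), spacing = c(1, 1, 2), modality = "ADC")
  m <- lesion_mask(array(TRUE, d), spacing = c(1, 1, 2))
  f <- extract_features(v, m)
  expect_equal(f$mean, 42); expect_equal(f$median, 42)
  expect_equal(f$p5, 42); expect_equal(f$p95, 42)
  expect_equal(f$std, 0); expect_equal(f$contrast, 0)
  expect_equal(f$modality, "ADC")
  set.seed(46)
  v2 <- image_volume(array(rnorm(prod(d)), d))
  f1 <- extract_features(v2, m)
  f2 <- extract_features(v2, m)
  expect_identical(f1, f2)
  expect_error(extract_features(v2, lesion_mask(array(FALSE, d))), "empty")
})
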