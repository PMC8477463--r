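#' Two-group comparison
#'
#' Independent-samples t-test (Welch by default, pooled-variance optionally)
#' or Mann-Whitney U test, two-sided.
#'
#' @param values_a,values_b numeric samples.
#' @param test "t" or "mannwhitney".
#' @param var_equal pooled-variance t-test when TRUE (classic
#'   "independent-samples t-test" line); Welch when FALSE.
#' @return list with `statistic`, `p_value`, `method`, and `degenerate`
#'   (TRUE when both groups have zero variance).
#' @export
compare_groups <- function(values_a, values_b,
                           test = c("t", "mannwhitney"), var_equal = FALSE) {
  test <- match.arg(test)
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (test == "t") {
    if (length(a) < 2L || length(b) < 2L)
      stop("t-test needs at least 2 observations per group")
    if (sd(a) == 0 && sd(b) == 0) {
      same <- isTRUE(all.equal(mean(a), mean(b)))
      return(list(statistic = if (same) 0 else sign(mean(a) - mean(b)) * Inf,
                  p_value = if (same) 1 else 0,
                  method = "t", degenerate = TRUE))
    }
    ht <- t.test(a, b, var.equal = var_equal)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = if (var_equal) "t (pooled)" else "t (Welch)",
         degenerate = FALSE)
  } else {
    if (length(a) < 1L || length(b) < 1L)
      stop("Mann-Whitney needs at least 1 observation per group")
    ht <- suppressWarnings(wilcox.test(a, b))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "mannwhitney", degenerate = FALSE)
  }
}

# Placement (mid-rank) components of the DeLong variance: for each positive
# score, the fraction of negatives it beats (ties count 1/2), and vice versa.
delong_components <- function(pos, neg) {
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)),
                numeric(1))
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)),
                numeric(1))
  list(v10 = v10, v01 = v01)
}

#' ROC analysis of a continuous score
#'
#' AUC by the Mann-Whitney pair-counting estimator with half credit for
#' ties; 95% confidence interval and a test of AUC = 0.5 by the DeLong
#' variance estimator. With `direction = "auto"` the score is oriented so
#' that AUC >= 0.5 and the orientation is recorded as the cutoff inequality:
#' ">" when high scores indicate the positive class, "<=" when low scores do
#' (e.g. low ADC indicating cancer).
#'
#' @param scores numeric score per subject.
#' @param labels class label per subject; `positive` names the positive
#'   class.
#' @param positive the positive-class label (default "PCa").
#' @param direction "auto", ">" (positives high) or "<=" (positives low).
#' @param conf_level confidence level for the AUC interval.
#' @return A `roc_result` list: `auc`, `se`, `ci` (length 2), `p_vs_half`,
#'   `direction`, `n_pos`, `n_neg`, plus the oriented data for cutoff
#'   selection.
#' @export
roc <- function(scores, labels, positive = "PCa",
                direction = c("auto", ">", "<="), conf_level = 0.95) {
  direction <- match.arg(direction)
  scores <- as.numeric(scores)
  if (anyNA(scores)) stop("scores contain NA")
  is_pos <- labels == positive
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  auc_high <- (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (direction == "auto") direction <- if (auc_high >= 0.5) ">" else "<="
  oriented <- if (direction == ">") scores else -scores
  auc <- if (direction == ">") auc_high else 1 - auc_high
  dc <- delong_components(oriented[is_pos], oriented[!is_pos])
  s10 <- if (n1 > 1) var(dc$v10) else 0
  s01 <- if (n0 > 1) var(dc$v01) else 0
  se <- sqrt(s10 / n1 + s01 / n0)
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(0, auc - z * se), min(1, auc + z * se))
  p_vs_half <- if (se > 0) 2 * pnorm(-abs(auc - 0.5) / se) else
    as.numeric(auc == 0.5)
  structure(list(auc = auc, se = se, ci = ci, p_vs_half = p_vs_half,
                 direction = direction, n_pos = n1, n_neg = n0,
                 scores = scores, labels = labels, positive = positive),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f, %.3f), direction %s, p(=0.5) %.4g\n",
              x$auc, x$ci[1], x$ci[2], x$direction, x$p_vs_half))
  invisible(x)
}

#' Youden-optimal cutoff
#'
#' Scans the midpoints between adjacent distinct score values and returns the
#' cutoff maximizing the Youden index J = sensitivity + specificity - 1,
#' classifying with the ROC's inequality direction (positive when score >
#' cutoff, or score <= cutoff). Ties are broken toward higher sensitivity,
#' then toward the lower cutoff.
#'
#' @param roc_result a [roc()] result.
#' @return list: `cutoff`, `direction`, `sensitivity`, `specificity`,
#'   `youden_j`, `lr_pos`, `lr_neg`.
#' @export
youden_cutoff <- function(roc_result) {
  stopifnot(inherits(roc_result, "roc_result"))
  scores <- roc_result$scores
  is_pos <- roc_result$labels == roc_result$positive
  u <- sort(unique(scores))
  cand <- if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2 else u
  best <- NULL
  for (ct in cand) {
    pred_pos <- if (roc_result$direction == ">") scores > ct else scores <= ct
    sens <- sum(pred_pos & is_pos) / sum(is_pos)
    spec <- sum(!pred_pos & !is_pos) / sum(!is_pos)
    j <- sens + spec - 1
    if (is.null(best) || j > best$youden_j + 1e-12 ||
        (abs(j - best$youden_j) <= 1e-12 &&
         (sens > best$sensitivity + 1e-12 ||
          (abs(sens - best$sensitivity) <= 1e-12 && ct < best$cutoff)))) {
      best <- list(cutoff = ct, direction = roc_result$direction,
                   sensitivity = sens, specificity = spec, youden_j = j)
    }
  }
  lr <- likelihood_ratios(best$sensitivity, best$specificity)
  c(best, lr)
}

#' Positive and negative likelihood ratios
#'
#' +LR = sensitivity / (1 - specificity); -LR = (1 - sensitivity) /
#' specificity. Boundary cases return an infinite sentinel.
#'
#' @param sensitivity,specificity values in [0, 1].
#' @return list with `lr_pos` and `lr_neg`.
#' @export
likelihood_ratios <- function(sensitivity, specificity) {
  if (sensitivity < 0 || sensitivity > 1 || specificity < 0 || specificity > 1)
    stop("sensitivity and specificity must lie in [0, 1]")
  lr_pos <- if (specificity == 1) {
    if (sensitivity == 0) NaN else Inf
  } else sensitivity / (1 - specificity)
  lr_neg <- if (specificity == 0) {
    if (sensitivity == 1) NaN else Inf
  } else (1 - sensitivity) / specificity
  list(lr_pos = lr_pos, lr_neg = lr_neg)
}

#' Full diagnostic analysis of one score
#'
#' ROC with DeLong CI, Youden-optimal cutoff, and likelihood ratios in one
#' call.
#'
#' @inheritParams roc
#' @return A `roc_result` with added fields `cutoff`, `sensitivity`,
#'   `specificity`, `youden_j`, `lr_pos`, `lr_neg`.
#' @export
roc_analysis <- function(scores, labels, positive = "PCa",
                         direction = c("auto", ">", "<=")) {
  r <- roc(scores, labels, positive = positive,
           direction = match.arg(direction))
  y <- youden_cutoff(r)
  r[names(y)] <- y
  r
}

# Ridge-stabilized logistic log-likelihood fit; used when the ML fit
# separates completely.
ridge_logistic <- function(X, y, lambda = 1e-3) {
  Xd <- cbind(1, X)
  nll <- function(beta) {
    eta <- as.vector(Xd %*% beta)
    sum(log1p(exp(-(2 * y - 1) * eta))) + lambda * sum(beta[-1]^2) / 2
  }
  grad <- function(beta) {
    eta <- as.vector(Xd %*% beta)
    p <- plogis(eta)
    g <- as.vector(crossprod(Xd, p - y))
    g + c(0, lambda * beta[-1])
  }
  fit <- optim(numeric(ncol(Xd)), nll, grad, method = "BFGS",
               control = list(maxit = 500))
  beta <- fit$par
  list(coefficients = beta, fitted = plogis(as.vector(Xd %*% beta)))
}

#' Combine parameters with a logistic model
#'
#' Fits a two-class logistic regression by maximum likelihood on the
#' (optionally standardized) feature columns; the combined score is the
#' predicted probability of the positive class, so reported cutoffs live on
#' the 0-1 probability scale. Complete separation triggers a
#' ridge-stabilized fit with a warning.
#'
#' @param feature_matrix numeric matrix or data.frame, one column per
#'   feature; rows with missing values are dropped listwise (with their
#'   labels).
#' @param labels class labels.
#' @param positive positive-class label.
#' @param standardize center/scale features before the fit.
#' @return list: `score` (predicted probabilities), `coefficients`,
#'   `roc` (a [roc_analysis()] of the score, direction ">"), `n_used`.
#' @export
combine_parameters <- function(feature_matrix, labels, positive = "PCa",
                               standardize = TRUE) {
  X <- as.matrix(as.data.frame(feature_matrix))
  if (ncol(X) < 1L) stop("at least one feature column is required")
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  labels <- labels[keep]
  y <- as.integer(labels == positive)
  if (all(y == 1L) || all(y == 0L)) stop("both classes must be present")
  if (standardize) X <- scale(X)
  fit <- suppressWarnings(glm.fit(cbind(1, X), y,
                                  family = binomial()))
  separated <- !fit$converged || all(abs(y - fit$fitted.values) < 1e-6)
  if (separated) {
    warning("complete separation; using ridge-stabilized logistic fit")
    fit <- ridge_logistic(X, y)
    score <- fit$fitted
    coefs <- fit$coefficients
  } else {
    score <- fit$fitted.values
    coefs <- fit$coefficients
  }
  list(score = score,
       coefficients = coefs,
       roc = roc_analysis(score, labels, positive = positive,
                          direction = ">"),
       n_used = sum(keep))
}

#' Cohort-level comparison and ROC report
#'
#' For every feature column: class means +/- SD with a two-group p-value, and
#' a full ROC/Youden/likelihood-ratio row; optionally logistic combinations
#' of feature subsets.
#'
#' @param table data.frame with a `label` column and numeric feature
#'   columns (e.g. fast-mode [generate_cohort()] output).
#' @param features feature column names; defaults to every numeric column
#'   except `label`/`patient_id`.
#' @param positive positive-class label.
#' @param test group-comparison test, "t" or "mannwhitney".
#' @param var_equal pooled-variance t-test when TRUE.
#' @param combinations list of character vectors of feature names to combine
#'   via [combine_parameters()].
#' @return list of data.frames: `comparison` (feature, class means/SDs, p),
#'   `roc` (feature, auc, ci, p, cutoff, direction, sens/spec %, J, LRs).
#' @export
cohort_report <- function(table, features = NULL, positive = "PCa",
                          test = "t", var_equal = FALSE,
                          combinations = list()) {
  stopifnot("label" %in% names(table))
  labs <- unique(table$label)
  if (length(labs) != 2L) stop("label must have exactly two classes")
  if (!positive %in% labs) stop("positive class absent from table")
  if (is.null(features)) {
    numeric_cols <- vapply(table, is.numeric, logical(1))
    features <- setdiff(names(table)[numeric_cols], c("patient_id"))
  }
  missing_f <- setdiff(features, names(table))
  if (length(missing_f) > 0)
    stop("features absent from table: ", paste(missing_f, collapse = ", "))
  is_pos <- table$label == positive
  cmp <- do.call(rbind, lapply(features, function(f) {
    ok <- is.finite(table[[f]])
    a <- table[[f]][is_pos & ok]; b <- table[[f]][!is_pos & ok]
    ct <- if (length(a) >= 2 && length(b) >= 2)
      compare_groups(a, b, test = test, var_equal = var_equal)
    else list(statistic = NA_real_, p_value = NA_real_)
    data.frame(feature = f,
               pos_mean = mean(a), pos_sd = sd(a),
               neg_mean = mean(b), neg_sd = sd(b),
               statistic = ct$statistic, p_value = ct$p_value,
               stringsAsFactors = FALSE)
  }))
  roc_row <- function(name, ra) {
    data.frame(feature = name,
               auc = round(ra$auc, 3),
               ci_low = round(ra$ci[1], 3), ci_high = round(ra$ci[2], 3),
               p_vs_half = ra$p_vs_half,
               cutoff = ra$cutoff, direction = ra$direction,
               sensitivity_pct = round(100 * ra$sensitivity, 1),
               specificity_pct = round(100 * ra$specificity, 1),
               youden_j = round(ra$youden_j, 3),
               lr_pos = round(ra$lr_pos, 2), lr_neg = round(ra$lr_neg, 2),
               stringsAsFactors = FALSE)
  }
  rocs <- do.call(rbind, lapply(features, function(f) {
    ok <- is.finite(table[[f]])
    if (length(unique(table$label[ok])) < 2)
      return(data.frame(feature = f, auc = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_vs_half = NA_real_,
                        cutoff = NA_real_, direction = NA_character_,
                        sensitivity_pct = NA_real_, specificity_pct = NA_real_,
                        youden_j = NA_real_, lr_pos = NA_real_,
                        lr_neg = NA_real_, stringsAsFactors = FALSE))
    roc_row(f, roc_analysis(table[[f]][ok], table$label[ok],
                            positive = positive))
  }))
  for (cb in combinations) {
    comb <- combine_parameters(table[, cb, drop = FALSE], table$label,
                               positive = positive)
    rocs <- rbind(rocs, roc_row(paste(cb, collapse = " & "), comb$roc))
  }
  rownames(cmp) <- rownames(rocs) <- NULL
  list(comparison = cmp, roc = rocs)
}
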