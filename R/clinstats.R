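#' ADAb positivity rule
#'
#' A titer is called positive when it strictly exceeds three times the
#' assay detection limit (3.5 AU/ml by default, so the working threshold is
#' 10.5 AU/ml); the three-fold margin guards against false positives near
#' the detection limit.
#'
#' @param titer Titer(s) in AU/ml, >= 0.
#' @param detection_limit Assay detection limit, default 3.5 AU/ml.
#' @return Logical vector.
#' @export
adab_positive <- function(titer, detection_limit = 3.5) {
  titer > 3 * detection_limit
}

#' EULAR response classification
#'
#' Classifies treatment response from the DAS28 decrease
#' (delta = baseline - week 24) crossed with the attained week-24 DAS28:
#' good = delta > 1.2 and attained <= 3.2; poor = delta < 0.6, or attained
#' > 5.1 with delta <= 1.2; otherwise moderate. `mode = "caption_literal"`
#' instead calls poor whenever delta < 0.6 or attained > 5.1 regardless of
#' delta, an abbreviated rule sometimes seen in figure legends; the default
#' is the standard grid.
#'
#' @param das28_baseline,das28_week24 DAS28 scores in \[0, 10\]
#'   (vectorized).
#' @param mode `"standard"` (default) or `"caption_literal"`.
#' @return Factor with levels good, moderate, poor.
#' @export
eular_classify <- function(das28_baseline, das28_week24,
                           mode = c("standard", "caption_literal")) {
  mode <- match.arg(mode)
  b <- das28_baseline; w <- das28_week24
  if (anyNA(b) || anyNA(w)) stop("missing DAS28 score")
  if (any(b < 0 | b > 10 | w < 0 | w > 10))
    stop("DAS28 scores must lie in [0, 10]")
  delta <- b - w
  good <- delta > 1.2 & w <= 3.2
  poor <- if (mode == "standard")
    delta < 0.6 | (w > 5.1 & delta <= 1.2)
  else
    delta < 0.6 | w > 5.1
  cls <- ifelse(good, "good", ifelse(poor, "poor", "moderate"))
  factor(cls, levels = c("good", "moderate", "poor"))
}

#' Low disease activity
#' @param das28 DAS28 score(s).
#' @return Logical: DAS28 <= 3.2.
#' @export
low_disease_activity <- function(das28) das28 <= 3.2

#' Rank-based AUC
#'
#' Area under the ROC curve computed from mid-ranks: the probability that a
#' random positive outranks a random negative, counting ties as 1/2. AUC
#' below 0.5 is reported as-is, never flipped.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (logical, 0/1, or two-level factor; the
#'   second level / TRUE / 1 is the positive class).
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  pos <- as_binary(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) stop("labels must have exactly two levels")
    labels == levels(labels)[2]
  } else if (is.logical(labels)) {
    labels
  } else if (is.numeric(labels) && all(labels %in% c(0, 1))) {
    labels == 1
  } else stop("labels must be logical, 0/1, or a two-level factor")
}

#' Select proteins by AUC at both timepoints
#'
#' @param auc_baseline,auc_week24 Named numeric vectors of per-protein AUC
#'   covering the same proteins.
#' @param threshold Minimum AUC (inclusive) required at both timepoints,
#'   default 0.8.
#' @return Sorted character vector of protein ids.
#' @export
select_by_auc <- function(auc_baseline, auc_week24, threshold = 0.8) {
  if (!setequal(names(auc_baseline), names(auc_week24)))
    stop("the two AUC maps must cover the same proteins")
  common <- names(auc_baseline)
  sel <- auc_baseline[common] >= threshold &
    auc_week24[common] >= threshold
  sort(common[sel])
}

#' Mann-Whitney U test
#'
#' U is reported for the first group (`x`). For total sample sizes up to 12
#' the two-sided p-value is computed by exhaustive enumeration of all rank
#' assignments (valid under ties); for larger samples the normal
#' approximation with tie correction is used (no continuity correction).
#'
#' @param x,y Numeric samples, each non-empty.
#' @return List with `U` and `p.value`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n1 <- length(x); n0 <- length(y); N <- n1 + n0
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n0 / 2
  if (N <= 12) {
    idx <- utils::combn(N, n1)
    stats <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(stats - mu) >= abs(U - mu) - 1e-12)
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))$p.value
    if (is.nan(p)) p <- 1  # all observations tied
  }
  list(U = U, p.value = min(p, 1))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks. Undefined (NA, with a warning) when
#' either vector is constant.
#'
#' @param x,y Numeric vectors, length >= 3.
#' @return rho in \[-1, 1\] or NA.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("'x' and 'y' must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Probability-mass rule: the p-value sums hypergeometric probabilities of
#' all tables with the observed margins whose probability does not exceed
#' the observed table's. A zero margin yields p = 1 with a warning.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2) || any(table < 0) ||
      any(table != round(table)))
    stop("'table' must be a 2x2 matrix of non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("zero margin: Fisher exact p-value is 1")
    return(1)
  }
  stats::fisher.test(table)$p.value
}

#' Multivariate logistic regression with Wald inference
#'
#' Maximum-likelihood fit (iteratively reweighted least squares via
#' `glm`). Reports coefficients, odds ratios, Wald 95% confidence
#' intervals, and p-values. Complete or quasi-complete separation is
#' detected (fitted probabilities numerically 0/1 with diverging
#' coefficients) and flagged rather than returned as spurious estimates.
#'
#' @param X Design matrix or data frame of covariates (no intercept
#'   column; one is added).
#' @param y Binary outcome.
#' @return List: `coefficients` (data.frame term, estimate, std_error,
#'   odds_ratio, ci_low, ci_high, p_value), `separation` flag,
#'   `converged`, `fit` (the glm object).
#' @export
logistic_multivariate <- function(X, y) {
  X <- as.data.frame(X)
  pos <- as_binary(y)
  if (length(unique(pos)) < 2) stop("outcome must include both classes")
  if (nrow(X) <= ncol(X) + 1)
    stop("more coefficients than observations")
  mm <- stats::model.matrix(~ ., data = X)
  qrk <- qr(mm)
  if (qrk$rank < ncol(mm)) {
    bad <- colnames(mm)[qrk$pivot[(qrk$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(pos ~ ., data = X, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  # diverging slopes with fitted probabilities pinned at 0/1 indicate
  # (quasi-)complete separation, whether or not glm warned
  pinned <- any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8)
  separation <- (sep_warned || pinned) &&
    any(abs(stats::coef(fit)[-1]) > 15)
  z <- stats::qnorm(0.975)
  coefs <- data.frame(
    term = rownames(sm),
    estimate = sm[, 1],
    std_error = sm[, 2],
    odds_ratio = exp(sm[, 1]),
    ci_low = exp(sm[, 1] - z * sm[, 2]),
    ci_high = exp(sm[, 1] + z * sm[, 2]),
    p_value = sm[, 4],
    row.names = NULL
  )
  list(coefficients = coefs, separation = separation,
       converged = fit$converged, fit = fit)
}

#' Ward clustering orders for heat maps
#'
#' Agglomerative clustering with Ward linkage on Euclidean distances
#' (`ward.D2`), applied to samples (rows) and proteins (columns).
#'
#' @param m An `expr_matrix` or numeric matrix, samples in rows.
#' @return List: `sample_order`, `protein_order` (leaf orders),
#'   `sample_hclust`, `protein_hclust` (NULL when the margin has < 2
#'   entries).
#' @export
ward_order <- function(m) {
  v <- if (inherits(m, "expr_matrix")) unwrap(m) else as.matrix(m)
  cluster <- function(x, ids) {
    if (nrow(x) < 2)
      return(list(order = ids, hclust = NULL))
    hc <- stats::hclust(stats::dist(x), method = "ward.D2")
    list(order = ids[hc$order], hclust = hc)
  }
  s <- cluster(v, rownames(v))
  p <- cluster(t(v), colnames(v))
  list(sample_order = s$order, protein_order = p$order,
       sample_hclust = s$hclust, protein_hclust = p$hclust)
}

#' Grouped clinical summary table
#'
#' Summarizes clinical variables by group the way cohort tables are
#' reported: binary variables as n (percent) with Fisher exact p-values,
#' numeric variables as mean +/- SD or median (IQR) with Mann-Whitney
#' p-values.
#'
#' @param meta Data frame of per-subject records.
#' @param group Name of a two-level grouping column in `meta`.
#' @param binary_vars Character vector of logical/binary columns.
#' @param numeric_vars Character vector of numeric columns.
#' @param numeric_summary `"mean_sd"` (default) or `"median_iqr"`.
#' @return Data frame: variable, one summary column per group level,
#'   p_value.
#' @export
table1_summary <- function(meta, group, binary_vars = character(),
                           numeric_vars = character(),
                           numeric_summary = c("mean_sd", "median_iqr")) {
  numeric_summary <- match.arg(numeric_summary)
  g <- factor(meta[[group]])
  if (nlevels(g) != 2) stop("'group' must have exactly two levels")
  lv <- levels(g)
  rows <- list()
  for (v in binary_vars) {
    x <- as.logical(meta[[v]])
    n <- tapply(x, g, function(z) sum(z, na.rm = TRUE))
    tot <- tapply(x, g, function(z) sum(!is.na(z)))
    tab <- rbind(n, tot - n)
    p <- suppressWarnings(fisher_exact(tab))
    cells <- sprintf("%d (%.1f%%)", n, 100 * n / tot)
    rows[[v]] <- data.frame(variable = v, g1 = cells[1], g2 = cells[2],
                            p_value = p)
  }
  for (v in numeric_vars) {
    x <- meta[[v]]
    sp <- split(x, g)
    cells <- vapply(sp, function(z) {
      z <- z[!is.na(z)]
      if (numeric_summary == "mean_sd")
        sprintf("%.2f ± %.2f", mean(z), stats::sd(z))
      else
        sprintf("%.2f (%.2f-%.2f)", stats::median(z),
                stats::quantile(z, .25), stats::quantile(z, .75))
    }, character(1))
    p <- mann_whitney(sp[[1]][!is.na(sp[[1]])],
                      sp[[2]][!is.na(sp[[2]])])$p.value
    rows[[v]] <- data.frame(variable = v, g1 = cells[1], g2 = cells[2],
                            p_value = p)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  names(out)[2:3] <- lv
  rownames(out) <- NULL
  out
}
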