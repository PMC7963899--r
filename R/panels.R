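#' RFE / random-forest configuration
#'
#' Defaults mirror the study conditions: 300 resampling iterations with
#' five-fold cross-validation, random forests of 1,000 trees with
#' `mtry = floor(sqrt(p))` and Gini-impurity importance, 20% of features
#' dropped per elimination step.
#'
#' @param n_iterations Resampling iterations of the RFE search.
#' @param cv_folds Cross-validation folds used to score subset sizes.
#' @param resample `"bootstrap"` (stratified, with replacement; default) or
#'   `"subsample"` (stratified, `subsample_fraction` without replacement).
#' @param subsample_fraction Fraction kept under `resample = "subsample"`.
#' @param rf_trees Trees per forest.
#' @param rf_mtry Variables per split; `NULL` (default) means
#'   `floor(sqrt(p))`.
#' @param elimination_fraction Fraction of features dropped per RFE step
#'   (at least one feature is always dropped).
#' @param seed Integer seed; every random draw derives from it.
#' @return A list of class `rfe_config`.
#' @export
rfe_config <- function(n_iterations = 300, cv_folds = 5,
                       resample = c("bootstrap", "subsample"),
                       subsample_fraction = 0.8, rf_trees = 1000,
                       rf_mtry = NULL, elimination_fraction = 0.2,
                       seed = 1) {
  resample <- match.arg(resample)
  stopifnot(n_iterations >= 1, cv_folds >= 2, rf_trees >= 1,
            elimination_fraction > 0, elimination_fraction < 1,
            subsample_fraction > 0, subsample_fraction <= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 cv_folds = as.integer(cv_folds), resample = resample,
                 subsample_fraction = subsample_fraction,
                 rf_trees = as.integer(rf_trees), rf_mtry = rf_mtry,
                 elimination_fraction = elimination_fraction,
                 seed = as.integer(seed)),
            class = "rfe_config")
}

iter_seed <- function(seed, i, offset = 0L) {
  as.integer((as.numeric(seed) + offset + i * 1009) %%
               (.Machine$integer.max - 1)) + 1L
}

fit_rf <- function(x, y, cfg, seed, importance = "none") {
  mtry <- if (is.null(cfg$rf_mtry)) max(1L, floor(sqrt(ncol(x)))) else
    min(cfg$rf_mtry, ncol(x))
  ranger::ranger(x = x, y = y, num.trees = cfg$rf_trees, mtry = mtry,
                 importance = importance, num.threads = 1, seed = seed,
                 verbose = FALSE)
}

stratified_draw <- function(y, replace, fraction = 1) {
  unlist(lapply(split(seq_along(y), y), function(idx) {
    k <- if (replace) length(idx) else max(1L, floor(fraction * length(idx)))
    sample(idx, k, replace = replace)
  }), use.names = FALSE)
}

cv_accuracy <- function(x, y, cfg, seed) {
  folds <- integer(length(y))
  for (cl in split(seq_along(y), y))
    folds[cl] <- sample(rep_len(seq_len(cfg$cv_folds), length(cl)))
  correct <- 0L
  for (f in seq_len(cfg$cv_folds)) {
    test <- folds == f
    if (!any(test) || length(unique(y[!test])) < 2) next
    fit <- fit_rf(x[!test, , drop = FALSE], y[!test], cfg,
                  seed = iter_seed(seed, f, 7e6))
    pred <- stats::predict(fit, data = x[test, , drop = FALSE],
                           num.threads = 1)$predictions
    correct <- correct + sum(pred == y[test])
  }
  correct / length(y)
}

#' Recursive feature elimination over random-forest importance
#'
#' Repeats, for each of `cfg$n_iterations` stratified resamples of the
#' data: train a random forest, rank features by mean decrease in Gini
#' impurity, drop the lowest `elimination_fraction`, and repeat down to a
#' single feature, scoring every visited subset size by `cv_folds`-fold
#' cross-validated accuracy; the best-scoring subset of the iteration is
#' recorded. The aggregate per-feature importance is the mean elimination
#' rank across iterations (1 = eliminated last). Fully reproducible given
#' `cfg$seed`.
#'
#' @param X Feature matrix (samples in rows) or `expr_matrix`; typically
#'   batch-adjusted intensities.
#' @param y Binary class labels (e.g. ADAb status).
#' @param cfg An [rfe_config()].
#' @return List of class `rfe_result`: `importance` (data.frame feature,
#'   mean_rank, sorted ascending), `subsets` (per-iteration list with
#'   `features` and `cv_accuracy`), `config`.
#' @export
rfe_search <- function(X, y, cfg = rfe_config()) {
  x <- if (inherits(X, "expr_matrix")) unwrap(X) else as.matrix(X)
  if (is.null(colnames(x))) stop("'X' must have feature (column) names")
  if (ncol(x) < 2) stop("need at least two features")
  if (anyNA(x)) stop("'X' contains missing values")
  y <- factor(y)
  if (nlevels(y) != 2) stop("'y' must have exactly two classes")
  p <- ncol(x)
  ranks <- matrix(NA_real_, cfg$n_iterations, p,
                  dimnames = list(NULL, colnames(x)))
  subsets <- vector("list", cfg$n_iterations)

  for (i in seq_len(cfg$n_iterations)) {
    set.seed(iter_seed(cfg$seed, i))
    idx <- stratified_draw(y, replace = cfg$resample == "bootstrap",
                           fraction = cfg$subsample_fraction)
    xi <- x[idx, , drop = FALSE]
    yi <- y[idx]

    feats <- colnames(x)
    eliminated <- character(0)
    history <- list()
    repeat {
      acc <- cv_accuracy(xi[, feats, drop = FALSE], yi, cfg,
                         seed = iter_seed(cfg$seed, i, 3e6 + length(feats)))
      history[[length(history) + 1L]] <- list(features = feats,
                                              cv_accuracy = acc)
      if (length(feats) == 1L) break
      fit <- fit_rf(xi[, feats, drop = FALSE], yi, cfg,
                    seed = iter_seed(cfg$seed, i, 5e6 + length(feats)),
                    importance = "impurity")
      imp <- fit$variable.importance[feats]
      n_drop <- max(1L, floor(cfg$elimination_fraction * length(feats)))
      # drop lowest-importance features; deterministic tie-break by id
      ord <- order(imp, feats)
      drop <- feats[ord[seq_len(n_drop)]]
      eliminated <- c(eliminated, drop)
      feats <- setdiff(feats, drop)
    }
    eliminated <- c(eliminated, feats)  # final survivor, best rank
    ranks[i, eliminated] <- rev(seq_len(p))

    accs <- vapply(history, `[[`, numeric(1), "cv_accuracy")
    sizes <- lengths(lapply(history, `[[`, "features"))
    best <- which(accs == max(accs))
    best <- best[which.min(sizes[best])]  # tie: prefer the smaller panel
    subsets[[i]] <- history[[best]]
  }

  importance <- data.frame(feature = colnames(x),
                           mean_rank = colMeans(ranks), row.names = NULL)
  importance <- importance[order(importance$mean_rank,
                                 importance$feature), ]
  rownames(importance) <- NULL
  structure(list(importance = importance, subsets = subsets, config = cfg),
            class = "rfe_result")
}

#' Enumerate candidate panels from RFE iterations
#'
#' Distinct best subsets across RFE iterations, ranked by selection
#' frequency then mean cross-validated accuracy.
#'
#' @param subsets `subsets` element of an [rfe_search()] result (or the
#'   result itself).
#' @param top_k Number of panels to return (default 7).
#' @return Data frame: panel (id string), size, frequency,
#'   mean_cv_accuracy, with a `members` list column of protein ids.
#' @export
panel_enumerate <- function(subsets, top_k = 7) {
  if (inherits(subsets, "rfe_result")) subsets <- subsets$subsets
  if (!length(subsets)) stop("no iteration subsets supplied")
  keys <- vapply(subsets, function(s)
    paste(sort(s$features), collapse = "|"), character(1))
  accs <- vapply(subsets, `[[`, numeric(1), "cv_accuracy")
  agg <- lapply(split(seq_along(keys), keys), function(ii)
    data.frame(panel = keys[ii[1]],
               size = length(strsplit(keys[ii[1]], "|", fixed = TRUE)[[1]]),
               frequency = length(ii) / length(keys),
               mean_cv_accuracy = mean(accs[ii])))
  out <- do.call(rbind, agg)
  out <- out[order(-out$frequency, -out$mean_cv_accuracy, out$panel), ]
  out <- utils::head(out, top_k)
  out$members <- I(strsplit(out$panel, "|", fixed = TRUE))
  rownames(out) <- NULL
  out
}

#' Random-forest stability assessment of a biomarker panel
#'
#' Repeats, `n_iter` times, a stratified random train/test split (default
#' 70/30), fits a random forest on the panel features, and records the
#' test-set confusion matrix; sensitivity, specificity, accuracy, and
#' balanced accuracy distributions summarize stability.
#'
#' @param X Feature matrix (samples in rows) or `expr_matrix`.
#' @param y Binary class labels; the second factor level is the positive
#'   class.
#' @param panel Character vector of panel features (subset of
#'   `colnames(X)`).
#' @param n_iter Stability iterations, default 1000.
#' @param cfg An [rfe_config()] (supplies trees, mtry, seed).
#' @param train_fraction Fraction of each class used for training.
#' @return List of class `panel_result`: `panel`, per-iteration `metrics`
#'   data frame, `summary` (mean/sd/quantiles per metric), pooled
#'   `confusion` totals.
#' @export
rf_stability <- function(X, y, panel, n_iter = 1000, cfg = rfe_config(),
                         train_fraction = 0.7) {
  x <- if (inherits(X, "expr_matrix")) unwrap(X) else as.matrix(X)
  missing <- setdiff(panel, colnames(x))
  if (length(missing))
    stop("panel feature(s) not in X: ", paste(missing, collapse = ", "))
  y <- factor(y)
  if (nlevels(y) != 2) stop("'y' must have exactly two classes")
  pos <- levels(y)[2]
  x <- x[, panel, drop = FALSE]

  metrics <- matrix(NA_real_, n_iter, 4,
                    dimnames = list(NULL, c("sensitivity", "specificity",
                                            "accuracy",
                                            "balanced_accuracy")))
  totals <- c(tp = 0, fp = 0, tn = 0, fn = 0)
  for (i in seq_len(n_iter)) {
    set.seed(iter_seed(cfg$seed, i, 9e6))
    for (try in 1:10) {
      train <- unlist(lapply(split(seq_along(y), y), function(idx)
        sample(idx, max(1L, round(train_fraction * length(idx))))),
        use.names = FALSE)
      test <- setdiff(seq_along(y), train)
      if (length(unique(y[test])) == 2 && length(unique(y[train])) == 2)
        break
    }
    fit <- fit_rf(x[train, , drop = FALSE], y[train], cfg,
                  seed = iter_seed(cfg$seed, i, 11e6))
    pred <- stats::predict(fit, data = x[test, , drop = FALSE],
                           num.threads = 1)$predictions
    truth <- y[test]
    tp <- sum(pred == pos & truth == pos)
    fp <- sum(pred == pos & truth != pos)
    tn <- sum(pred != pos & truth != pos)
    fn <- sum(pred != pos & truth == pos)
    totals <- totals + c(tp = tp, fp = fp, tn = tn, fn = fn)
    metrics[i, ] <- unlist(confusion_metrics(tp, fp, tn, fn))
  }
  qs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  summary <- data.frame(
    metric = colnames(metrics),
    mean = colMeans(metrics),
    sd = apply(metrics, 2, stats::sd),
    t(apply(metrics, 2, stats::quantile, probs = qs)),
    row.names = NULL, check.names = FALSE
  )
  names(summary)[4:8] <- paste0("q", qs * 100)
  structure(list(panel = panel, metrics = as.data.frame(metrics),
                 summary = summary, confusion = totals, n_iter = n_iter,
                 train_fraction = train_fraction),
            class = "panel_result")
}

#' Confusion-matrix metrics
#'
#' @param tp,fp,tn,fn Non-negative counts; both class margins must be
#'   non-empty.
#' @return Named list: sensitivity, specificity, accuracy,
#'   balanced_accuracy.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (tp + fn == 0) stop("no positive cases (tp + fn = 0)")
  if (tn + fp == 0) stop("no negative cases (tn + fp = 0)")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  list(sensitivity = sens, specificity = spec,
       accuracy = (tp + tn) / sum(counts),
       balanced_accuracy = (sens + spec) / 2)
}
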