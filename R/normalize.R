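#' Quantile normalization across samples
#'
#' Forces every sample's intensity distribution onto the across-sample mean
#' of order statistics; ties within a sample receive the mean of the
#' reference values they span (mid-rank rule). The heavy lifting is done by
#' limma's quantile normalizer; this wrapper handles the samples-in-rows
#' orientation and provenance bookkeeping.
#'
#' @param m An `expr_matrix` (samples in rows).
#' @return An `expr_matrix` with provenance `"normalized"`.
#' @export
quantile_normalize <- function(m) {
  if (nrow(m) < 2) {
    warning("single-sample matrix: quantile normalization is the identity")
    return(expr_matrix(unwrap(m), "normalized"))
  }
  v <- t(limma::normalizeQuantiles(t(unwrap(m)), ties = TRUE))
  dimnames(v) <- dimnames(m)
  expr_matrix(v, "normalized")
}

#' Control-anchored intensity scaling
#'
#' Rescales each sample by the ratio of the grand mean of per-sample
#' Cy3-BSA control means to that sample's own control mean, equalizing
#' labelling efficiency across arrays.
#'
#' @param m An `expr_matrix`.
#' @param control_means Named numeric vector of per-sample control means
#'   (see [control_means()]); must cover every sample and be positive.
#' @return Rescaled `expr_matrix` (same provenance as input).
#' @export
control_anchor_scale <- function(m, control_means) {
  missing <- setdiff(rownames(m), names(control_means))
  if (length(missing))
    stop("no control mean for sample(s): ", paste(missing, collapse = ", "))
  cm <- control_means[rownames(m)]
  if (any(!is.finite(cm) | cm <= 0))
    stop("non-positive control mean for sample(s): ",
         paste(rownames(m)[!is.finite(cm) | cm <= 0], collapse = ", "))
  scale <- mean(cm) / cm
  v <- unwrap(m) * scale
  expr_matrix(v, provenance(m))
}

#' Composite normalization
#'
#' Control-anchored scaling first (correcting per-array labelling
#' efficiency), then quantile normalization (aligning distributions).
#'
#' @inheritParams control_anchor_scale
#' @return An `expr_matrix`, provenance `"normalized"`.
#' @export
composite_normalize <- function(m, control_means) {
  quantile_normalize(control_anchor_scale(m, control_means))
}

#' Fold change against a reference sample set
#'
#' Each value is divided by the per-protein mean over the reference samples
#' (by default the pooled healthy controls).
#'
#' @param m An `expr_matrix`.
#' @param reference_sample_ids Sample ids forming the reference; must be
#'   non-empty and present in `m`.
#' @return An `expr_matrix` with provenance `"fold_change"`.
#' @export
fold_change <- function(m, reference_sample_ids) {
  if (!length(reference_sample_ids))
    stop("reference sample set is empty")
  missing <- setdiff(reference_sample_ids, rownames(m))
  if (length(missing))
    stop("reference sample(s) not in matrix: ",
         paste(missing, collapse = ", "))
  ref <- unwrap(m)[reference_sample_ids, , drop = FALSE]
  ref_mean <- colMeans(ref)
  if (any(ref_mean <= 0))
    stop("non-positive reference mean for protein(s): ",
         paste(colnames(m)[ref_mean <= 0], collapse = ", "))
  v <- sweep(unwrap(m), 2, ref_mean, "/")
  expr_matrix(v, "fold_change")
}
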