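#' Penetrance screening statistics
#'
#' For every protein, a sample is "penetrant" when its fold change meets the
#' cutoff (default 2.0). Per protein the screen reports:
#' \describe{
#'   \item{pfc}{penetrance fold change: mean fold change over the penetrant
#'     test samples, 0 when no test sample is penetrant;}
#'   \item{pfreq_test}{percent of test-group samples penetrant;}
#'   \item{pfreq_ctrl}{percent of control-group samples penetrant.}
#' }
#' A protein is flagged as a biomarker when pfc >= `pfc_min`, pfreq_test >=
#' `pfreq_test_min`, and pfreq_ctrl strictly below `pfreq_ctrl_max`
#' (see [classify_biomarker()]).
#'
#' @param fc An `expr_matrix` with provenance `"fold_change"`.
#' @param test_ids,ctrl_ids Disjoint, non-empty sample-id sets.
#' @param fc_cutoff Penetrance fold-change cutoff, default 2.0.
#' @param pfc_min,pfreq_test_min,pfreq_ctrl_max Biomarker criteria
#'   (defaults 2.0, 20, 10; frequencies in percent).
#' @return Data frame: protein_id, pfc, pfreq_test, pfreq_ctrl,
#'   n_penetrant_test, is_biomarker.
#' @export
penetrance_stats <- function(fc, test_ids, ctrl_ids, fc_cutoff = 2.0,
                             pfc_min = 2.0, pfreq_test_min = 20,
                             pfreq_ctrl_max = 10) {
  if (!identical(provenance(fc), "fold_change"))
    stop("penetrance screening expects a fold-change matrix")
  if (!length(test_ids) || !length(ctrl_ids))
    stop("test and control sample sets must be non-empty")
  if (length(intersect(test_ids, ctrl_ids)))
    stop("test and control sample sets overlap: ",
         paste(intersect(test_ids, ctrl_ids), collapse = ", "))
  unknown <- setdiff(c(test_ids, ctrl_ids), rownames(fc))
  if (length(unknown))
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))

  v <- unwrap(fc)
  test <- v[test_ids, , drop = FALSE]
  ctrl <- v[ctrl_ids, , drop = FALSE]
  pen_test <- test >= fc_cutoff
  pen_ctrl <- ctrl >= fc_cutoff
  n_pen <- colSums(pen_test)
  pfc <- ifelse(n_pen > 0, colSums(test * pen_test) / pmax(n_pen, 1), 0)
  rec <- data.frame(
    protein_id = colnames(v),
    pfc = pfc,
    pfreq_test = 100 * n_pen / length(test_ids),
    pfreq_ctrl = 100 * colSums(pen_ctrl) / length(ctrl_ids),
    n_penetrant_test = as.integer(n_pen),
    row.names = NULL
  )
  rec$is_biomarker <- classify_biomarker(rec, pfc_min, pfreq_test_min,
                                         pfreq_ctrl_max)
  rec
}

#' Biomarker classification rule
#'
#' All three criteria must hold: pfc >= `pfc_min` (inclusive), pfreq_test >=
#' `pfreq_test_min` (inclusive), pfreq_ctrl < `pfreq_ctrl_max` (strict).
#'
#' @param records Data frame with columns pfc, pfreq_test, pfreq_ctrl
#'   (vectorized over rows).
#' @param pfc_min,pfreq_test_min,pfreq_ctrl_max Criterion thresholds.
#' @return Logical vector.
#' @export
classify_biomarker <- function(records, pfc_min = 2.0, pfreq_test_min = 20,
                               pfreq_ctrl_max = 10) {
  records$pfc >= pfc_min &
    records$pfreq_test >= pfreq_test_min &
    records$pfreq_ctrl < pfreq_ctrl_max
}

#' Top-k biomarkers by penetrance fold change
#'
#' Biomarker-flagged records sorted by pfc descending; ties broken by
#' pfreq_test descending, then protein id lexicographically, so runs are
#' reproducible.
#'
#' @param records Output of [penetrance_stats()].
#' @param k Number of records to return (default 20; fewer if fewer
#'   qualify).
#' @return The top-k rows of `records`.
#' @export
top_k_by_pfc <- function(records, k = 20) {
  if (k < 1) stop("'k' must be >= 1")
  hits <- records[records$is_biomarker, , drop = FALSE]
  ord <- order(-hits$pfc, -hits$pfreq_test, hits$protein_id)
  hits <- hits[ord, , drop = FALSE]
  utils::head(hits, k)
}

#' Overlap of two biomarker lists
#'
#' @param list_a,list_b Character vectors of protein ids (or data frames
#'   with a `protein_id` column).
#' @return Sorted character vector of shared protein ids.
#' @export
timepoint_overlap <- function(list_a, list_b) {
  ids <- function(x) if (is.data.frame(x)) x$protein_id else as.character(x)
  sort(intersect(ids(list_a), ids(list_b)))
}
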