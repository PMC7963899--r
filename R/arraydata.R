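#' Read a spot-level microarray table
#'
#' Canonical input is a long-format TSV/CSV with one row per physical spot
#' and columns `sample_id`, `protein_id`, `replicate`, `fg`, `bg`,
#' `spot_class` (values `protein`, `cy3_bsa_control`, `igg_dilution_control`).
#' A GenePix-style dialect (`"gpr"`) is accepted as a convenience: the
#' header block is skipped and `Name`, `F635 Median`, `B635 Median` are
#' mapped to `protein_id`, `fg`, `bg`; one file corresponds to one sample.
#'
#' @param path Path to the spot table.
#' @param dialect `"long"` (default) or `"gpr"`.
#' @param sample_id Sample identifier for the `"gpr"` dialect (defaults to
#'   the file name without extension).
#' @return A `data.frame` of spot records with the canonical columns.
#' @export
read_spot_table <- function(path, dialect = c("long", "gpr"),
                            sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("spot table not found: ", path)
  spots <- if (dialect == "long") read_spot_long(path) else
    read_spot_gpr(path, sample_id)
  validate_spots(spots)
  spots
}

read_spot_long <- function(path) {
  dt <- data.table::fread(path)
  required <- c("sample_id", "protein_id", "replicate", "fg", "bg",
                "spot_class")
  missing <- setdiff(required, names(dt))
  if (length(missing))
    stop("spot table schema error: missing column(s) ",
         paste(sQuote(missing), collapse = ", "), " in ", path)
  as.data.frame(dt[, required, with = FALSE])
}

read_spot_gpr <- function(path, sample_id) {
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  hdr <- grep("\\bName\\b", lines)
  hdr <- hdr[grepl("F635", lines[hdr])]
  if (!length(hdr))
    stop("spot table schema error: no GPR column header with ",
         "'Name' and 'F635 Median' found in ", path)
  dt <- data.table::fread(path, skip = hdr[1] - 1, sep = "\t")
  required <- c("Name", "F635 Median", "B635 Median")
  missing <- setdiff(required, names(dt))
  if (length(missing))
    stop("spot table schema error: missing column(s) ",
         paste(sQuote(missing), collapse = ", "), " in ", path)
  spots <- data.frame(
    sample_id  = sample_id,
    protein_id = as.character(dt$Name),
    fg         = as.numeric(dt[["F635 Median"]]),
    bg         = as.numeric(dt[["B635 Median"]])
  )
  spots$spot_class <- ifelse(
    grepl("cy3|bsa", spots$protein_id, ignore.case = TRUE),
    "cy3_bsa_control",
    ifelse(grepl("^igg", spots$protein_id, ignore.case = TRUE),
           "igg_dilution_control", "protein"))
  spots$replicate <- stats::ave(seq_len(nrow(spots)), spots$protein_id,
                                FUN = seq_along)
  spots[, c("sample_id", "protein_id", "replicate", "fg", "bg", "spot_class")]
}

validate_spots <- function(spots) {
  classes <- c("protein", "cy3_bsa_control", "igg_dilution_control")
  bad <- which(!spots$spot_class %in% classes)
  if (length(bad))
    stop("unknown spot_class at row ", bad[1], ": ",
         sQuote(spots$spot_class[bad[1]]))
  for (col in c("fg", "bg")) {
    v <- spots[[col]]
    if (anyNA(v) || any(!is.finite(v)))
      stop("non-finite ", col, " intensity at row ",
           which(is.na(v) | !is.finite(v))[1])
    if (any(v < 0))
      stop("negative ", col, " intensity at row ", which(v < 0)[1])
  }
  invisible(spots)
}

#' Net spot intensity
#'
#' Foreground minus background, floored at a small positive value so that
#' downstream logs and fold changes stay defined.
#'
#' @param fg,bg Non-negative foreground/background RFU (vectorized).
#' @param floor Positive lower bound, default 1 RFU.
#' @return `pmax(fg - bg, floor)`.
#' @export
net_intensity <- function(fg, bg, floor = 1) {
  if (!is.numeric(floor) || length(floor) != 1 || floor <= 0)
    stop("'floor' must be a single positive number")
  pmax(fg - bg, floor)
}

#' Collapse replicate spots into a per-sample, per-protein matrix
#'
#' Net intensities of the (typically quadruplicate) protein spots are
#' collapsed with a robust location estimate. Replicate sets whose
#' coefficient of variation exceeds `cv_flag_threshold` are flagged but
#' retained; flagging is advisory, not an exclusion.
#'
#' @param spots Spot records from [read_spot_table()].
#' @param method `"median"` (default, robust to one bad spot) or `"mean"`.
#' @param cv_flag_threshold CV above which a (sample, protein) replicate set
#'   is flagged; default 0.5.
#' @param floor Net-intensity floor passed to [net_intensity()].
#' @return List with `matrix` (an `expr_matrix`, provenance `"aggregated"`)
#'   and `qc` (data.frame: sample_id, protein_id, n_spots, cv, flagged).
#' @export
aggregate_replicates <- function(spots, method = c("median", "mean"),
                                 cv_flag_threshold = 0.5, floor = 1) {
  method <- match.arg(method)
  prot <- data.table::as.data.table(spots)[spot_class == "protein"]
  if (!nrow(prot)) stop("no protein-class spots to aggregate")
  prot[, net := net_intensity(fg, bg, floor)]
  fun <- if (method == "median") stats::median else mean
  agg <- prot[, .(
    value   = fun(net),
    n_spots = .N,
    cv      = if (.N > 1) stats::sd(net) / mean(net) else NA_real_
  ), by = .(sample_id, protein_id)]
  agg[, flagged := !is.na(cv) & cv > cv_flag_threshold]

  samples  <- sort(unique(agg$sample_id))
  proteins <- sort(unique(agg$protein_id))
  # completeness: every sample must carry every protein seen on the layout
  expected <- length(samples) * length(proteins)
  if (nrow(agg) < expected) {
    grid <- data.table::CJ(sample_id = samples, protein_id = proteins)
    miss <- grid[!agg, on = c("sample_id", "protein_id")]
    stop("missing protein spots for ", nrow(miss), " (sample, protein) ",
         "pair(s), e.g. ", miss$sample_id[1], " / ", miss$protein_id[1])
  }

  v <- matrix(NA_real_, length(samples), length(proteins),
              dimnames = list(samples, proteins))
  v[cbind(match(agg$sample_id, samples), match(agg$protein_id, proteins))] <-
    agg$value
  list(matrix = expr_matrix(v, "aggregated"),
       qc = as.data.frame(agg[, .(sample_id, protein_id, n_spots, cv,
                                  flagged)]))
}

#' Control-spot quality control per sample
#'
#' Cy3-BSA positive-control spots gauge labelling consistency (their CV
#' should be low); the IgG dilution series gauges binding capacity (net
#' intensity should increase monotonically with concentration, measured by
#' Spearman correlation between dilution level and net intensity). IgG
#' dilution levels are parsed from the trailing integer of the control's
#' protein id (e.g. `IgG_3`), higher = more concentrated.
#'
#' @param spots Spot records.
#' @param cy3_cv_max Maximum acceptable Cy3-BSA CV (default 0.3).
#' @param igg_cor_min Minimum acceptable IgG dilution correlation
#'   (default 0.8).
#' @param floor Net-intensity floor.
#' @return Data frame: sample_id, cy3_mean, cy3_cv, igg_rho, status
#'   (`"pass"`, `"fail"`, or `"uncheckable"` when a sample has no control
#'   spots).
#' @export
qc_controls <- function(spots, cy3_cv_max = 0.3, igg_cor_min = 0.8,
                        floor = 1) {
  dt <- data.table::as.data.table(spots)
  dt[, net := net_intensity(fg, bg, floor)]
  samples <- sort(unique(dt$sample_id))
  out <- lapply(samples, function(s) {
    cy3 <- dt[sample_id == s & spot_class == "cy3_bsa_control", net]
    igg <- dt[sample_id == s & spot_class == "igg_dilution_control"]
    cy3_mean <- if (length(cy3)) mean(cy3) else NA_real_
    cy3_cv <- if (length(cy3) > 1) stats::sd(cy3) / mean(cy3) else NA_real_
    igg_rho <- NA_real_
    if (nrow(igg) >= 2) {
      level <- suppressWarnings(
        as.numeric(sub(".*_(\\d+)$", "\\1", igg$protein_id)))
      if (!anyNA(level) && length(unique(level)) >= 2)
        igg_rho <- suppressWarnings(
          stats::cor(level, igg$net, method = "spearman"))
    }
    status <- if (!length(cy3) && !nrow(igg)) {
      "uncheckable"
    } else {
      fail <- (!is.na(cy3_cv) && cy3_cv > cy3_cv_max) ||
        (!is.na(igg_rho) && igg_rho < igg_cor_min)
      if (fail) "fail" else "pass"
    }
    data.frame(sample_id = s, cy3_mean = cy3_mean, cy3_cv = cy3_cv,
               igg_rho = igg_rho, status = status)
  })
  do.call(rbind, out)
}

#' Per-sample Cy3-BSA control means
#'
#' Convenience extractor feeding [control_anchor_scale()].
#'
#' @param spots Spot records.
#' @param floor Net-intensity floor.
#' @return Named numeric vector of Cy3-BSA mean net intensity per sample.
#' @export
control_means <- function(spots, floor = 1) {
  dt <- data.table::as.data.table(spots)[spot_class == "cy3_bsa_control"]
  if (!nrow(dt)) stop("no Cy3-BSA control spots found")
  dt[, net := net_intensity(fg, bg, floor)]
  agg <- dt[, .(m = mean(net)), by = sample_id]
  stats::setNames(agg$m, agg$sample_id)
}

#' Write spot records as canonical long-format TSV
#' @param spots Spot records.
#' @param path Output path.
#' @export
write_spot_table <- function(spots, path) {
  data.table::fwrite(spots, path, sep = "\t", quote = FALSE)
  invisible(path)
}
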