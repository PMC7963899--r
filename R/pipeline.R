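#' Pipeline configuration
#'
#' Declarative configuration for the full discovery pipeline, with the
#' study's screening thresholds pre-filled: penetrance fold-change cutoff
#' 2.0, penetrance frequency 20% (test) / 10% (control), top-20 ranking,
#' AUC 0.8 at both timepoints, RFE with 5-fold cross-validation, random
#' forests of 1,000 trees. All randomness derives from `seed`.
#'
#' @param outdir Run directory for stage artifacts.
#' @param input `NULL` (default) to simulate a cohort with `synth`, or a
#'   list with paths `spots` (long TSV) and `meta` (CSV).
#' @param synth A [synth_config()] used when `input` is `NULL`; its seed
#'   is replaced by `seed`.
#' @param seed Root seed, expanded per stage.
#' @param floor Net-intensity floor (RFU).
#' @param aggregate_method Replicate collapse, `"median"` or `"mean"`.
#' @param cv_flag_threshold Replicate-CV QC flag threshold.
#' @param exclude_qc_failures Drop samples failing control QC (default
#'   FALSE: warn and keep).
#' @param fc_cutoff,pfc_min,pfreq_test_min,pfreq_ctrl_max Penetrance
#'   screen parameters (see [penetrance_stats()]).
#' @param penetrance_control Group used for the low-penetrance criterion:
#'   `"adab_neg"` (default; the ADAb-negative patients at the same
#'   timepoint) or `"healthy"` (the pooled healthy controls — with only
#'   four of them the "< 10%" criterion degenerates to 0-of-4).
#' @param top_k Penetrance top-k per timepoint.
#' @param auc_threshold Per-antigen AUC filter threshold.
#' @param combat Apply batch adjustment when merging cohorts.
#' @param protect_class Protect ADAb status as a covariate during batch
#'   adjustment.
#' @param rfe An [rfe_config()]; its seed is replaced by `seed + 1000`.
#' @param stability_iterations Random-forest stability iterations for the
#'   top panel.
#' @param panel_top_k Number of candidate panels reported.
#' @param stages Stages to run, in order.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            input = NULL,
                            synth = synth_config(),
                            seed = 1,
                            floor = 1,
                            aggregate_method = "median",
                            cv_flag_threshold = 0.5,
                            exclude_qc_failures = FALSE,
                            fc_cutoff = 2.0, pfc_min = 2.0,
                            pfreq_test_min = 20, pfreq_ctrl_max = 10,
                            penetrance_control = c("adab_neg", "healthy"),
                            top_k = 20,
                            auc_threshold = 0.8,
                            combat = TRUE, protect_class = TRUE,
                            rfe = rfe_config(),
                            stability_iterations = 1000,
                            panel_top_k = 7,
                            stages = c("penetrance", "stats", "combat",
                                       "panels")) {
  cfg <- as.list(environment())
  cfg$penetrance_control <- match.arg(penetrance_control)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
    stop("config field 'seed' must be a single integer")
  for (f in c("fc_cutoff", "pfc_min"))
    if (cfg[[f]] < 0) stop("config field '", f, "' must be >= 0")
  for (f in c("pfreq_test_min", "pfreq_ctrl_max"))
    if (cfg[[f]] < 0 || cfg[[f]] > 100)
      stop("config field '", f, "' must lie in [0, 100]")
  if (cfg$auc_threshold < 0 || cfg$auc_threshold > 1)
    stop("config field 'auc_threshold' must lie in [0, 1]")
  if (cfg$top_k < 1) stop("config field 'top_k' must be >= 1")
  cfg$synth$seed <- as.integer(seed)
  cfg$rfe$seed <- as.integer(seed + 1000)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; nested
#' `synth:` and `rfe:` blocks are passed to [synth_config()] and
#' [rfe_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synth)) y$synth <- do.call(synth_config, y$synth)
  if (!is.null(y$rfe)) y$rfe <- do.call(rfe_config, y$rfe)
  unknown <- setdiff(names(y), names(formals(pipeline_config)))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, y)
}

#' Run the discovery pipeline
#'
#' Executes spot aggregation, composite normalization and fold change,
#' penetrance screening per timepoint, per-antigen AUC filtering and
#' clinical summaries, cohort merging with batch adjustment, and
#' RFE/random-forest panel selection, writing every stage artifact under
#' `cfg$outdir`. Re-running with the same configuration and inputs
#' reproduces the artifacts bit for bit.
#'
#' @param cfg A [pipeline_config()] or path to a YAML config.
#' @return (Invisibly) list of in-memory stage results and artifact paths.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list(config = cfg)

  # ---- input -------------------------------------------------------------
  if (is.null(cfg$input)) {
    sim <- generate_cohort(cfg$synth, dir = file.path(cfg$outdir, "synth"))
    spots <- sim$spots
    meta <- sim$meta
    res$manifest <- sim$manifest
  } else {
    if (!file.exists(cfg$input$spots))
      stop("missing input file: ", cfg$input$spots)
    if (!file.exists(cfg$input$meta))
      stop("missing input file: ", cfg$input$meta)
    spots <- read_spot_table(cfg$input$spots)
    meta <- as.data.frame(data.table::fread(cfg$input$meta))
  }

  # ---- arraydata ---------------------------------------------------------
  agg <- aggregate_replicates(spots, cfg$aggregate_method,
                              cfg$cv_flag_threshold, cfg$floor)
  ctrl_qc <- qc_controls(spots, floor = cfg$floor)
  failed <- ctrl_qc$sample_id[ctrl_qc$status == "fail"]
  m <- agg$matrix
  if (length(failed)) {
    if (cfg$exclude_qc_failures) {
      m <- expr_matrix(unwrap(m)[!rownames(m) %in% failed, , drop = FALSE],
                       "aggregated")
      meta <- meta[!meta$sample_id %in% failed, ]
    } else {
      warning("sample(s) failing control QC retained: ",
              paste(failed, collapse = ", "))
    }
  }
  write_expr_matrix(m, file.path(cfg$outdir, "matrix_aggregated.tsv"))
  data.table::fwrite(agg$qc[agg$qc$flagged, ],
                     file.path(cfg$outdir, "qc_flags.tsv"), sep = "\t")
  data.table::fwrite(ctrl_qc, file.path(cfg$outdir, "qc_controls.tsv"),
                     sep = "\t")
  res$matrix <- m
  res$qc <- list(spots = agg$qc, controls = ctrl_qc)

  # ---- normalize ---------------------------------------------------------
  cm <- control_means(spots, cfg$floor)[rownames(m)]
  norm <- composite_normalize(m, cm)
  hc_ids <- meta$sample_id[meta$group == "healthy_control"]
  fc <- fold_change(norm, hc_ids)
  write_expr_matrix(norm, file.path(cfg$outdir, "matrix_normalized.tsv"))
  write_expr_matrix(fc, file.path(cfg$outdir, "matrix_fold_change.tsv"))
  jsonlite::write_json(
    list(control_means = as.list(cm), reference_samples = hc_ids,
         floor = cfg$floor, aggregate_method = cfg$aggregate_method),
    file.path(cfg$outdir, "normalization_params.json"),
    auto_unbox = TRUE, digits = NA)
  res$normalized <- norm
  res$fc <- fc

  # ---- penetrance per timepoint (pilot cohort) ---------------------------
  pilot <- meta[meta$cohort == "cohort1" & meta$group != "healthy_control", ]
  timepoints <- intersect(c("baseline", "week24"), unique(pilot$timepoint))
  if ("penetrance" %in% cfg$stages) {
    res$penetrance <- list()
    for (tp in timepoints) {
      test_ids <- pilot$sample_id[pilot$timepoint == tp &
                                    pilot$group == "adab_pos"]
      ctrl_ids <- if (cfg$penetrance_control == "adab_neg")
        pilot$sample_id[pilot$timepoint == tp & pilot$group == "adab_neg"]
      else hc_ids
      rec <- penetrance_stats(fc, test_ids, ctrl_ids, cfg$fc_cutoff,
                              cfg$pfc_min, cfg$pfreq_test_min,
                              cfg$pfreq_ctrl_max)
      top <- top_k_by_pfc(rec, cfg$top_k)
      data.table::fwrite(rec, file.path(cfg$outdir,
                                        paste0("penetrance_", tp, ".tsv")),
                         sep = "\t")
      data.table::fwrite(top, file.path(cfg$outdir,
                                        paste0("top", cfg$top_k, "_", tp,
                                               ".tsv")), sep = "\t")
      res$penetrance[[tp]] <- list(records = rec, top = top)
    }
    if (length(timepoints) == 2) {
      res$overlap <- timepoint_overlap(res$penetrance$baseline$top,
                                       res$penetrance$week24$top)
      writeLines(res$overlap, file.path(cfg$outdir, "overlap.txt"))
    }
  }

  # ---- stats: per-antigen AUC + clinical table ---------------------------
  if ("stats" %in% cfg$stages) {
    auc <- list()
    for (tp in timepoints) {
      ids <- pilot$sample_id[pilot$timepoint == tp]
      labels <- pilot$group[pilot$timepoint == tp] == "adab_pos"
      v <- unwrap(norm)[ids, , drop = FALSE]
      auc[[tp]] <- apply(v, 2, auc_rank, labels = labels)
      data.table::fwrite(data.frame(protein_id = colnames(v),
                                    auc = auc[[tp]]),
                         file.path(cfg$outdir, paste0("auc_", tp, ".tsv")),
                         sep = "\t")
    }
    if (length(timepoints) == 2) {
      pool <- if (!is.null(res$overlap)) res$overlap else
        names(auc$baseline)
      sel <- select_by_auc(auc$baseline[pool], auc$week24[pool],
                           cfg$auc_threshold)
      writeLines(sel, file.path(cfg$outdir, "selected_markers.txt"))
      res$selected <- sel
    }
    res$auc <- auc

    patients <- meta[meta$group != "healthy_control", ]
    patients$poor_eular <- patients$eular == "poor"
    patients$lda <- low_disease_activity(patients$das28_week24)
    tab1 <- table1_summary(patients, "group",
                           binary_vars = c("poor_eular", "lda"),
                           numeric_vars = c("adab_titer", "drug_level",
                                            "das28_baseline",
                                            "das28_week24"))
    data.table::fwrite(tab1, file.path(cfg$outdir, "table1.tsv"),
                       sep = "\t")
    res$table1 <- tab1

    if (!is.null(res$penetrance)) {
      ids <- unique(unlist(lapply(res$penetrance,
                                  function(p) p$top$protein_id)))
      if (length(ids) >= 2) {
        ord <- ward_order(expr_matrix(
          unwrap(fc)[pilot$sample_id, ids, drop = FALSE], "fold_change"))
        jsonlite::write_json(ord[c("sample_order", "protein_order")],
                             file.path(cfg$outdir, "heatmap_order.json"),
                             auto_unbox = FALSE, digits = NA)
        res$heatmap <- ord
      }
    }
  }

  # ---- combat: merge cohorts on net intensities --------------------------
  merged_ids <- meta$sample_id[meta$group != "healthy_control" &
                                 meta$timepoint == "baseline"]
  merged_meta <- meta[match(merged_ids, meta$sample_id), ]
  merged <- expr_matrix(unwrap(m)[merged_ids, , drop = FALSE],
                        "aggregated")
  if ("combat" %in% cfg$stages && cfg$combat &&
      length(unique(merged_meta$batch)) >= 1) {
    cb <- combat_fit_adjust(
      merged, merged_meta$batch,
      covariates = if (cfg$protect_class)
        data.frame(group = merged_meta$group) else NULL)
    panel_input <- cb$adjusted
    write_expr_matrix(cb$adjusted, file.path(cfg$outdir,
                                             "matrix_combat.tsv"))
    if (!is.null(cb$model$gamma_star))
      jsonlite::write_json(
        list(hyperpriors = cb$model$hyperpriors,
             gamma_star = as.data.frame(cb$model$gamma_star),
             delta2_star = as.data.frame(cb$model$delta2_star),
             batch_sizes = cb$model$batch_sizes),
        file.path(cfg$outdir, "batch_model.json"), digits = NA)
    res$combat <- cb
  } else {
    panel_input <- merged
  }

  # ---- panels ------------------------------------------------------------
  if ("panels" %in% cfg$stages) {
    x <- log2(unwrap(panel_input))
    y <- factor(merged_meta$group, levels = c("adab_neg", "adab_pos"))
    rfe <- rfe_search(x, y, cfg$rfe)
    panels <- panel_enumerate(rfe, cfg$panel_top_k)
    # mirror the study: assess every candidate panel's stability by
    # iterated random forest and keep the most stable (highest mean
    # accuracy, ties to the smaller panel)
    stabs <- lapply(panels$members, function(p)
      rf_stability(x, y, p, n_iter = cfg$stability_iterations,
                   cfg = cfg$rfe))
    acc <- vapply(stabs, function(s)
      s$summary$mean[s$summary$metric == "accuracy"], numeric(1))
    panels$stability_accuracy <- acc
    best <- order(-acc, panels$size)[1]
    stab <- stabs[[best]]
    data.table::fwrite(rfe$importance,
                       file.path(cfg$outdir, "importance.tsv"), sep = "\t")
    data.table::fwrite(panels[, c("panel", "size", "frequency",
                                  "mean_cv_accuracy",
                                  "stability_accuracy")],
                       file.path(cfg$outdir, "panels.tsv"), sep = "\t")
    data.table::fwrite(cbind(iteration = seq_len(nrow(stab$metrics)),
                             stab$metrics),
                       file.path(cfg$outdir, "stability_metrics.tsv"),
                       sep = "\t")
    res$rfe <- rfe
    res$panels <- panels
    res$stability <- stab
  }

  # ---- summary -----------------------------------------------------------
  summary <- list(
    seed = cfg$seed,
    n_samples = nrow(meta),
    n_proteins = ncol(m),
    top20_baseline = if (!is.null(res$penetrance$baseline))
      res$penetrance$baseline$top$protein_id,
    top20_week24 = if (!is.null(res$penetrance$week24))
      res$penetrance$week24$top$protein_id,
    overlap = res$overlap,
    selected_markers = res$selected,
    top_panel = if (!is.null(res$stability)) res$stability$panel,
    stability = if (!is.null(res$stability))
      stats::setNames(as.list(res$stability$summary$mean),
                      res$stability$summary$metric)
  )
  jsonlite::write_json(summary[!vapply(summary, is.null, logical(1))],
                       file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  res$summary <- summary
  invisible(res)
}

#' Assemble a human-readable report from a completed run
#'
#' Renders the clinical summary, penetrance top-k tables, overlap list,
#' AUC filter result, panel table, and heat-map ordering from the stage
#' artifacts on disk; nothing is recomputed. Missing artifacts are listed
#' rather than silently skipped.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @param path Output file (default `report.md` inside `run_dir`).
#' @return (Invisibly) the report path.
#' @export
report_run <- function(run_dir, path = file.path(run_dir, "report.md")) {
  if (!dir.exists(run_dir)) stop("run directory not found: ", run_dir)
  lines <- c("# Autoantibody biomarker discovery report", "")
  missing <- character(0)
  add_table <- function(file, title) {
    fp <- file.path(run_dir, file)
    if (!file.exists(fp)) {
      missing <<- c(missing, file)
      return(invisible())
    }
    dt <- data.table::fread(fp)
    lines <<- c(lines, paste("##", title), "",
                paste(names(dt), collapse = " | "),
                paste(rep("---", ncol(dt)), collapse = " | "),
                apply(dt, 1, paste, collapse = " | "), "")
  }
  add_table("table1.tsv", "Clinical characteristics by ADAb status")
  for (f in list.files(run_dir, pattern = "^top\\d+_.*\\.tsv$"))
    add_table(f, paste("Penetrance screen:", sub("\\.tsv$", "", f)))
  ov <- file.path(run_dir, "overlap.txt")
  if (file.exists(ov))
    lines <- c(lines, "## Markers overlapping both timepoints", "",
               paste("-", readLines(ov)), "")
  sel <- file.path(run_dir, "selected_markers.txt")
  if (file.exists(sel))
    lines <- c(lines, "## Markers with AUC above threshold at both timepoints",
               "", paste("-", readLines(sel)), "")
  add_table("panels.tsv", "Candidate biomarker panels")
  sm <- file.path(run_dir, "summary.json")
  if (file.exists(sm)) {
    s <- jsonlite::read_json(sm)
    if (!is.null(s$top_panel))
      lines <- c(lines, "## Most stable panel", "",
                 paste("-", unlist(s$top_panel)), "")
    if (!is.null(s$stability))
      lines <- c(lines, "## Stability metrics (means)", "",
                 sprintf("- %s: %.3f", names(s$stability),
                         unlist(s$stability)), "")
  } else missing <- c(missing, "summary.json")
  hm <- file.path(run_dir, "heatmap_order.json")
  if (file.exists(hm)) {
    h <- jsonlite::read_json(hm)
    lines <- c(lines, "## Heat-map ordering (Ward / Euclidean)", "",
               paste("- samples:", paste(unlist(h$sample_order),
                                         collapse = ", ")),
               paste("- proteins:", paste(unlist(h$protein_order),
                                          collapse = ", ")), "")
  }
  if (length(missing))
    lines <- c(lines, "## Missing artifacts", "", paste("-", missing), "")
  writeLines(lines, path)
  invisible(path)
}
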