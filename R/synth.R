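#' Synthetic-cohort configuration
#'
#' Declares the study conditions the generator emulates: a pilot cohort of
#' 6 ADAb-positive / 6 ADAb-negative patients sampled at baseline and week
#' 24, a replication cohort of 24 / 26 patients, and 4 healthy controls;
#' arrays with quadruplicate protein spots plus Cy3-BSA and IgG-dilution
#' controls; a planted differential-autoantibody panel of 8 markers led by
#' a strong `TROVE2_like` marker; additive/multiplicative between-cohort
#' batch effects on the log2 scale; and clinical couplings in which ADAb
#' titers increase with the lead marker's fold change, drug trough levels
#' decay with titer, and DAS28 improvement decreases with titer.
#'
#' @param n_proteins Number of array proteins (planted markers included).
#' @param cohort1,cohort2 Lists with `n_pos`, `n_neg`, `timepoints`;
#'   `cohort2 = NULL` generates a single-cohort design.
#' @param n_healthy Healthy-control samples (fold-change reference).
#' @param planted_markers Data frame `protein_id`, `log2_effect`,
#'   `penetrance` (per-sample responder probability in ADAb-positive
#'   patients).
#' @param log2_mean_mu,log2_mean_sd Distribution of per-protein baseline
#'   means on the log2 RFU scale.
#' @param bio_sd Between-subject biological noise SD (log2).
#' @param n_replicates Protein spot replicates per sample (default 4).
#' @param replicate_cv Multiplicative replicate noise CV.
#' @param bg_mean,bg_cv Background intensity level and CV.
#' @param labelling_sd Per-sample labelling-efficiency SD (log2); shared by
#'   protein and control spots, so control anchoring can remove it.
#' @param batch_shift,batch_scale Named per-cohort additive shift and
#'   multiplicative noise scale on the log2 scale.
#' @param cy3_level,n_cy3_spots,cy3_cv Cy3-BSA control level, spot count,
#'   and spot CV.
#' @param igg_levels,igg_top IgG two-fold dilution series: number of levels
#'   and top-level net intensity.
#' @param titer_scale,titer_noise_sd ADAb titer (AU/ml) response to the
#'   lead marker's fold change.
#' @param drug_d0,drug_decay,drug_noise_sd Drug trough model: level
#'   `d0 * exp(-decay * titer)` with multiplicative log-normal noise.
#' @param das28_baseline_mean,das28_baseline_sd Baseline DAS28
#'   distribution.
#' @param delta_das28_max,delta_das28_slope,delta_das28_noise_sd DAS28
#'   improvement model `max - slope * log1p(titer)` plus noise.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 200,
                         cohort1 = list(n_pos = 6, n_neg = 6,
                                        timepoints = c("baseline", "week24")),
                         cohort2 = list(n_pos = 24, n_neg = 26,
                                        timepoints = "baseline"),
                         n_healthy = 4,
                         planted_markers = default_markers(),
                         log2_mean_mu = 7, log2_mean_sd = 1,
                         bio_sd = 0.5, n_replicates = 4,
                         replicate_cv = 0.1,
                         bg_mean = 60, bg_cv = 0.2,
                         labelling_sd = 0.3,
                         batch_shift = c(cohort1 = 0, cohort2 = 0.8),
                         batch_scale = c(cohort1 = 1, cohort2 = 1.3),
                         cy3_level = 1024, n_cy3_spots = 8, cy3_cv = 0.05,
                         igg_levels = 6, igg_top = 2000,
                         titer_scale = 40, titer_noise_sd = 3,
                         drug_d0 = 6.4, drug_decay = 0.08,
                         drug_noise_sd = 0.3,
                         das28_baseline_mean = 6.5, das28_baseline_sd = 0.8,
                         delta_das28_max = 4.2, delta_das28_slope = 0.9,
                         delta_das28_noise_sd = 0.5,
                         seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_proteins >= nrow(planted_markers), n_healthy >= 1,
            n_replicates >= 1,
            all(planted_markers$penetrance > 0),
            all(planted_markers$penetrance <= 1))
  class(cfg) <- "synth_config"
  cfg
}

#' Default planted-marker panel
#'
#' Eight markers: a strong lead (`TROVE2_like`, log2 effect 1.6,
#' penetrance 0.6) and seven moderate markers (log2 effect 1.0,
#' penetrance 0.4).
#' @return Data frame `protein_id`, `log2_effect`, `penetrance`.
#' @export
default_markers <- function() {
  data.frame(
    protein_id = c("TROVE2_like", sprintf("MARKER%02d", 2:8)),
    log2_effect = c(1.6, rep(1.0, 7)),
    penetrance = c(0.6, rep(0.4, 7))
  )
}

synth_subjects <- function(cfg) {
  mk <- function(cohort, spec, prefix) {
    if (is.null(spec)) return(NULL)
    n <- spec$n_pos + spec$n_neg
    data.frame(
      subject_id = sprintf("%sS%02d", prefix, seq_len(n)),
      cohort = cohort,
      group = rep(c("adab_pos", "adab_neg"), c(spec$n_pos, spec$n_neg)),
      stringsAsFactors = FALSE
    )
  }
  subj <- rbind(mk("cohort1", cfg$cohort1, "C1"),
                mk("cohort2", cfg$cohort2, "C2"),
                data.frame(subject_id = sprintf("HC%02d",
                                                seq_len(cfg$n_healthy)),
                           cohort = "cohort1", group = "healthy_control"))
  subj
}

#' Generate a synthetic microarray cohort
#'
#' Emits (1) a spot-level table with `n_replicates` protein spots per
#' protein plus Cy3-BSA and IgG-dilution control spots per sample, (2) a
#' sample-metadata table with cohort/batch/timepoint/group, ADAb titer,
#' drug trough level, and DAS28 pair, and (3) a ground-truth manifest
#' naming the planted markers, their per-subject responder indicators, and
#' the batch parameters — sufficient to score recall and precision of
#' every discovery stage. Fully deterministic given `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @param dir Optional output directory; when given, `spots.tsv`,
#'   `meta.csv`, and `manifest.json` are written there.
#' @return (Invisibly when writing) list with `spots`, `meta`, `manifest`,
#'   and `paths`.
#' @export
generate_cohort <- function(cfg = synth_config(), dir = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)

  markers <- cfg$planted_markers
  proteins <- c(markers$protein_id,
                sprintf("PROT%04d", seq_len(cfg$n_proteins -
                                              nrow(markers))))
  mu <- stats::rnorm(cfg$n_proteins, cfg$log2_mean_mu, cfg$log2_mean_sd)
  names(mu) <- proteins

  subj <- synth_subjects(cfg)
  # persistent per-subject responder indicators for each planted marker
  resp <- matrix(0L, nrow(subj), nrow(markers),
                 dimnames = list(subj$subject_id, markers$protein_id))
  pos <- subj$group == "adab_pos"
  for (k in seq_len(nrow(markers)))
    resp[pos, k] <- stats::rbinom(sum(pos), 1, markers$penetrance[k])

  # one sample per subject per timepoint of its cohort
  tp_of <- function(cohort) {
    if (cohort == "cohort1" || is.null(cfg$cohort2)) cfg$cohort1$timepoints
    else cfg$cohort2$timepoints
  }
  samples <- do.call(rbind, lapply(seq_len(nrow(subj)), function(i) {
    tps <- if (subj$group[i] == "healthy_control") "baseline" else
      tp_of(subj$cohort[i])
    data.frame(sample_id = paste0(subj$subject_id[i], "_",
                                  ifelse(tps == "baseline", "BL", "W24")),
               subject_id = subj$subject_id[i], cohort = subj$cohort[i],
               batch = subj$cohort[i], timepoint = tps,
               group = subj$group[i])
  }))
  ns <- nrow(samples)

  # latent log2 signal: protein mean + planted effect + batch location +
  # batch-scaled biological noise + per-sample labelling efficiency
  shift <- cfg$batch_shift[samples$cohort]
  scale <- cfg$batch_scale[samples$cohort]
  eff <- matrix(0, ns, cfg$n_proteins, dimnames = list(samples$sample_id,
                                                       proteins))
  for (k in seq_len(nrow(markers)))
    eff[, markers$protein_id[k]] <-
      markers$log2_effect[k] * resp[samples$subject_id, k]
  e_s <- stats::rnorm(ns, 0, cfg$labelling_sd)
  noise <- matrix(stats::rnorm(ns * cfg$n_proteins, 0, cfg$bio_sd), ns)
  lsig <- sweep(eff + noise * scale, 2, mu, "+") + shift + e_s

  spots <- synth_spots(cfg, samples, lsig, e_s)

  # clinical couplings (titer from the lead marker's realized fold change)
  lead <- markers$protein_id[1]
  titer <- rep(NA_real_, ns)
  is_pos <- samples$group == "adab_pos"
  is_neg <- samples$group == "adab_neg"
  # subject-level titers, identical across a subject's timepoints
  u_pos <- unique(samples$subject_id[is_pos])
  t_pos <- 10.5 + cfg$titer_scale *
    (2^(markers$log2_effect[1] * resp[u_pos, lead]) - 1) +
    abs(stats::rnorm(length(u_pos), 0, cfg$titer_noise_sd)) + 0.1
  u_neg <- unique(samples$subject_id[is_neg])
  t_neg <- stats::runif(length(u_neg), 0, 8)
  titer[is_pos] <- t_pos[match(samples$subject_id[is_pos], u_pos)]
  titer[is_neg] <- t_neg[match(samples$subject_id[is_neg], u_neg)]

  clin <- generate_clinical(cfg, samples$group, titer,
                            subject_id = samples$subject_id)
  meta <- cbind(samples, adab_titer = titer, clin)

  manifest <- list(
    seed = cfg$seed,
    planted_markers = markers,
    lead_marker = lead,
    batch_shift = as.list(cfg$batch_shift),
    batch_scale = as.list(cfg$batch_scale),
    responders = cbind(subject_id = rownames(resp),
                       as.data.frame(resp)),
    n_samples = ns,
    n_proteins = cfg$n_proteins,
    n_replicates = cfg$n_replicates,
    healthy_controls = samples$sample_id[samples$group ==
                                           "healthy_control"]
  )

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(spots = file.path(dir, "spots.tsv"),
                  meta = file.path(dir, "meta.csv"),
                  manifest = file.path(dir, "manifest.json"))
    write_spot_table(spots, paths$spots)
    data.table::fwrite(meta, paths$meta)
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, dataframe = "columns")
  }
  out <- list(spots = spots, meta = meta, manifest = manifest,
              paths = paths)
  if (is.null(dir)) out else invisible(out)
}

synth_spots <- function(cfg, samples, lsig, e_s) {
  ns <- nrow(samples)
  np <- ncol(lsig)
  nr <- cfg$n_replicates
  sdlog_rep <- sqrt(log(1 + cfg$replicate_cv^2))
  sdlog_bg <- sqrt(log(1 + cfg$bg_cv^2))

  # protein spots, replicate-major within (sample, protein)
  n_ps <- ns * np * nr
  signal <- rep(as.vector(2^t(lsig)), each = nr) *
    stats::rlnorm(n_ps, -sdlog_rep^2 / 2, sdlog_rep)
  bg <- stats::rlnorm(n_ps, log(cfg$bg_mean) - sdlog_bg^2 / 2, sdlog_bg)
  prot <- data.frame(
    sample_id = rep(samples$sample_id, each = np * nr),
    protein_id = rep(rep(colnames(lsig), each = nr), times = ns),
    replicate = rep(seq_len(nr), times = ns * np),
    fg = signal + bg,
    bg = bg,
    spot_class = "protein"
  )

  # Cy3-BSA positive-control spots carry the labelling efficiency
  n_cy <- ns * cfg$n_cy3_spots
  cy_sd <- sqrt(log(1 + cfg$cy3_cv^2))
  cy_sig <- rep(cfg$cy3_level * 2^e_s, each = cfg$n_cy3_spots) *
    stats::rlnorm(n_cy, -cy_sd^2 / 2, cy_sd)
  cy_bg <- stats::rlnorm(n_cy, log(cfg$bg_mean) - sdlog_bg^2 / 2, sdlog_bg)
  cy3 <- data.frame(
    sample_id = rep(samples$sample_id, each = cfg$n_cy3_spots),
    protein_id = "CY3_BSA",
    replicate = rep(seq_len(cfg$n_cy3_spots), times = ns),
    fg = cy_sig + cy_bg,
    bg = cy_bg,
    spot_class = "cy3_bsa_control"
  )

  # IgG two-fold dilution series (level igg_levels = most concentrated)
  lv <- seq_len(cfg$igg_levels)
  conc <- cfg$igg_top / 2^(cfg$igg_levels - lv)
  n_ig <- ns * cfg$igg_levels
  ig_sig <- rep(2^e_s, each = cfg$igg_levels) * rep(conc, times = ns) *
    stats::rlnorm(n_ig, -sdlog_rep^2 / 2, sdlog_rep)
  ig_bg <- stats::rlnorm(n_ig, log(cfg$bg_mean) - sdlog_bg^2 / 2, sdlog_bg)
  igg <- data.frame(
    sample_id = rep(samples$sample_id, each = cfg$igg_levels),
    protein_id = sprintf("IGG_%d", rep(lv, times = ns)),
    replicate = 1L,
    fg = ig_sig + ig_bg,
    bg = ig_bg,
    spot_class = "igg_dilution_control"
  )

  rbind(prot, cy3, igg)
}

#' Generate clinical outcomes from ADAb titers
#'
#' Drug trough levels decay exponentially with titer; the week-24 DAS28
#' improvement decreases with `log1p(titer)`, which induces EULAR labels
#' with a higher poor-response rate among ADAb-positive patients. Healthy
#' controls receive no clinical values.
#'
#' @param cfg A [synth_config()].
#' @param group Per-sample group labels (`adab_pos`, `adab_neg`,
#'   `healthy_control`).
#' @param titer Per-sample ADAb titers (AU/ml; NA for healthy controls).
#' @param subject_id Optional subject ids; when supplied, outcomes are
#'   drawn once per subject and repeated across that subject's samples.
#' @return Data frame: drug_level, das28_baseline, das28_week24,
#'   delta_das28, eular.
#' @export
generate_clinical <- function(cfg, group, titer, subject_id = NULL) {
  if (is.null(subject_id)) subject_id <- as.character(seq_along(group))
  patient <- group != "healthy_control"
  u <- unique(subject_id[patient])
  ut <- titer[match(u, subject_id)]

  drug_u <- cfg$drug_d0 * exp(-cfg$drug_decay * ut) *
    2^stats::rnorm(length(u), 0, cfg$drug_noise_sd)
  b_u <- pmin(pmax(stats::rnorm(length(u), cfg$das28_baseline_mean,
                                cfg$das28_baseline_sd), 2), 9.5)
  delta_u <- cfg$delta_das28_max -
    cfg$delta_das28_slope * log1p(ut) +
    stats::rnorm(length(u), 0, cfg$delta_das28_noise_sd)
  w_u <- pmin(pmax(b_u - delta_u, 0), 10)

  idx <- match(subject_id, u)
  out <- data.frame(drug_level = drug_u[idx],
                    das28_baseline = b_u[idx],
                    das28_week24 = w_u[idx])
  out$delta_das28 <- out$das28_baseline - out$das28_week24
  out$eular <- NA_character_
  ok <- patient & !is.na(out$das28_baseline)
  out$eular[ok] <- as.character(
    eular_classify(out$das28_baseline[ok], out$das28_week24[ok]))
  out
}
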