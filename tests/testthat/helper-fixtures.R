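# shared fixtures, built in code

# plain numeric matrix from an expr_matrix
unwrap_values <- function(m) {
  x <- unclass(m)
  attr(x, "provenance") <- NULL
  x
}

# minimal long-format spot data.frame
toy_spots <- function(values, sample_id = "s1", protein_id = "p1",
                      bg = 0, spot_class = "protein") {
  data.frame(sample_id = sample_id, protein_id = protein_id,
             replicate = seq_along(values), fg = values + bg, bg = bg,
             spot_class = spot_class)
}

# an expr_matrix from a plain matrix with auto names
toy_matrix <- function(v, provenance = "aggregated") {
  if (is.null(rownames(v))) rownames(v) <- paste0("s", seq_len(nrow(v)))
  if (is.null(colnames(v))) colnames(v) <- paste0("p", seq_len(ncol(v)))
  expr_matrix(v, provenance)
}

# the parameter-recovery study conditions: 25 vs 25 patients at two
# timepoints, 8 planted markers at fold change 3 with 50% penetrance,
# 200 noise proteins
recovery_config <- function(seed) {
  synth_config(
    n_proteins = 208,
    cohort1 = list(n_pos = 25, n_neg = 25,
                   timepoints = c("baseline", "week24")),
    cohort2 = NULL,
    planted_markers = data.frame(
      protein_id = c("TROVE2_like", sprintf("MARKER%02d", 2:8)),
      log2_effect = log2(3), penetrance = 0.5),
    seed = seed)
}

# run generator -> aggregation -> composite normalization -> fold change
# against the healthy controls; returns fc matrix + metadata + manifest
recovery_fc <- function(seed) {
  sim <- generate_cohort(recovery_config(seed))
  agg <- aggregate_replicates(sim$spots)
  fc <- fold_change(
    composite_normalize(agg$matrix, control_means(sim$spots)),
    sim$meta$sample_id[sim$meta$group == "healthy_control"])
  list(fc = fc, meta = sim$meta, manifest = sim$manifest)
}

# penetrance screen at one timepoint of a recovery cohort
recovery_screen <- function(run, tp) {
  meta <- run$meta
  penetrance_stats(
    run$fc,
    meta$sample_id[meta$group == "adab_pos" & meta$timepoint == tp],
    meta$sample_id[meta$group == "adab_neg" & meta$timepoint == tp])
}

# batch-effect simulation matching the adjustment model: class effect in
# the design, batch shift added, batch scale multiplying only the noise
batch_sim <- function(seed, n_per = 20, p = 200, shift = 2, scale = 1.5,
                      n_signal = 20, effect = 1) {
  set.seed(seed)
  n_signal <- min(n_signal, p)
  n <- 2 * n_per
  batch <- rep(c("b1", "b2"), each = n_per)
  cls <- factor(rep(rep(c("a", "b"), each = n_per / 2), 2))
  mu <- stats::rnorm(p, 7, 1)
  eff <- c(rep(effect, n_signal), rep(0, p - n_signal))
  L <- vapply(seq_len(p), function(j) {
    eps <- stats::rnorm(n, 0, 0.5) * ifelse(batch == "b2", scale, 1)
    mu[j] + eff[j] * (cls == "b") + ifelse(batch == "b2", shift, 0) + eps
  }, numeric(n))
  dimnames(L) <- list(paste0("s", seq_len(n)), paste0("f", seq_len(p)))
  list(L = L, batch = batch, cls = cls, signal = seq_len(n_signal))
}
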