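small_cfg <- function(seed = 1, ...) {
  synth_config(n_proteins = 30,
               cohort1 = list(n_pos = 4, n_neg = 4,
                              timepoints = c("baseline", "week24")),
               cohort2 = list(n_pos = 5, n_neg = 5,
                              timepoints = "baseline"),
               n_healthy = 2, seed = seed, ...)
}

test_that("generation is byte-identical given the same config and seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_cohort(small_cfg(5), dir = d1)
  generate_cohort(small_cfg(5), dir = d2)
  for (f in c("spots.tsv", "meta.csv", "manifest.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  d3 <- withr::local_tempdir()
  generate_cohort(small_cfg(6), dir = d3)
  expect_false(identical(readLines(file.path(d1, "spots.tsv")),
                         readLines(file.path(d3, "spots.tsv"))))
})

test_that("spot counts, positivity, and control layout match the config", {
  sim <- generate_cohort(small_cfg())
  ns <- nrow(sim$meta)
  expect_equal(ns, 4 * 2 + 4 * 2 + 10 + 2)
  prot <- sim$spots[sim$spots$spot_class == "protein", ]
  expect_equal(nrow(prot), ns * 30 * 4)
  expect_true(all(sim$spots$fg > 0 & sim$spots$bg > 0))
  # every sample carries both control types
  for (cls in c("cy3_bsa_control", "igg_dilution_control"))
    expect_setequal(unique(sim$spots$sample_id[sim$spots$spot_class ==
                                                 cls]),
                    sim$meta$sample_id)
})

test_that("group labels and titers are mutually consistent", {
  sim <- generate_cohort(small_cfg(2))
  meta <- sim$meta
  neg <- meta[meta$group == "adab_neg", ]
  expect_true(all(!adab_positive(neg$adab_titer)))
  pos <- meta[meta$group == "adab_pos", ]
  expect_true(all(adab_positive(pos$adab_titer)))
  hc <- meta[meta$group == "healthy_control", ]
  expect_true(all(is.na(hc$adab_titer)))
  expect_true(all(is.na(hc$das28_baseline)))
  # titers constant within subject across timepoints
  split_t <- split(pos$adab_titer, pos$subject_id)
  expect_true(all(vapply(split_t, function(t) length(unique(t)) == 1,
                         logical(1))))
})

test_that("clinical couplings reproduce the study's sign structure", {
  sim <- generate_cohort(synth_config(seed = 1))
  pat <- sim$meta[sim$meta$group != "healthy_control" &
                    sim$meta$timepoint == "baseline", ]
  expect_lte(spearman(pat$adab_titer, pat$drug_level), -0.4)
  expect_lt(spearman(pat$adab_titer, pat$delta_das28), 0)
  poor <- tapply(pat$eular == "poor", pat$group, mean)
  expect_gt(poor[["adab_pos"]], poor[["adab_neg"]])
})

test_that("the realized lead-marker fold change matches the planted effect", {
  sim <- generate_cohort(synth_config(seed = 1))
  agg <- aggregate_replicates(sim$spots)
  fc <- fold_change(
    composite_normalize(agg$matrix, control_means(sim$spots)),
    sim$meta$sample_id[sim$meta$group == "healthy_control"])
  resp <- sim$manifest$responders
  lead <- sim$manifest$lead_marker
  responders <- rownames(resp)[resp[[lead]] == 1]
  ids <- sim$meta$sample_id[sim$meta$subject_id %in% responders]
  realized <- mean(log2(unwrap_values(fc)[ids, lead]))
  expect_lt(abs(realized - 1.6), 0.3)
})

test_that("an effect-free configuration is calibrated under the null", {
  n_tests <- 0L; n_rej <- 0L
  poor_pos <- poor_neg <- 0L
  for (s in 1:20) {
    cfg <- synth_config(
      n_proteins = 100,
      cohort1 = list(n_pos = 12, n_neg = 13, timepoints = "baseline"),
      cohort2 = NULL, n_healthy = 2,
      planted_markers = data.frame(protein_id = "NULLMARK",
                                   log2_effect = 0, penetrance = 0.5),
      delta_das28_slope = 0, seed = 400 + s)
    sim <- generate_cohort(cfg)
    x <- log2(unwrap_values(aggregate_replicates(sim$spots)$matrix))
    meta <- sim$meta
    pos <- meta$sample_id[meta$group == "adab_pos"]
    neg <- meta$sample_id[meta$group == "adab_neg"]
    for (j in seq_len(ncol(x))) {
      p <- mann_whitney(x[pos, j], x[neg, j])$p.value
      n_tests <- n_tests + 1L
      n_rej <- n_rej + (p < 0.05)
    }
    poor_pos <- poor_pos + sum(meta$eular[meta$group == "adab_pos"] ==
                                 "poor")
    poor_neg <- poor_neg + sum(meta$eular[meta$group == "adab_neg"] ==
                                 "poor")
  }
  rate <- n_rej / n_tests
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.08)
  # EULAR poor rates match between groups when response is decoupled
  expect_lt(abs(poor_pos / (20 * 12) - poor_neg / (20 * 13)), 0.1)
})

test_that("marker ids must be a subset of the protein registry", {
  expect_error(synth_config(n_proteins = 4), "n_proteins")
  expect_error(synth_config(planted_markers = data.frame(
    protein_id = "X", log2_effect = 1, penetrance = 0)), "penetrance")
})
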