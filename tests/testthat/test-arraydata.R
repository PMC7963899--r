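test_that("long-format spot tables round-trip exactly", {
  spots <- data.frame(
    sample_id = c("s1", "s1", "s2"),
    protein_id = c("p1", "p1", "p1"),
    replicate = c(1L, 2L, 1L),
    fg = c(500, 510.5, 300),
    bg = c(100, 99.5, 80),
    spot_class = "protein"
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spot_table(spots, path)
  back <- read_spot_table(path)
  expect_equal(nrow(back), 3L)
  for (col in names(spots)) expect_equal(back[[col]], spots[[col]])
})

test_that("schema and validation errors name the offending column/row", {
  spots <- toy_spots(c(10, 20))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spot_table(spots[, setdiff(names(spots), "fg")], path)
  expect_error(read_spot_table(path), "missing column.*fg")

  bad <- toy_spots(c(10, 20))
  bad$bg[2] <- -5
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_spot_table(bad, path2)
  expect_error(read_spot_table(path2), "negative bg.*row 2")
})

test_that("GPR-like dialect maps Name/F635/B635 and classifies controls", {
  path <- withr::local_tempfile(fileext = ".gpr")
  writeLines(c(
    "ATF\t1.0", "2\t4",
    "\"Type=GenePix Results 3\"", "\"Wavelengths=635\"",
    paste("\"Block\"", "\"Name\"", "\"F635 Median\"", "\"B635 Median\"",
          sep = "\t"),
    "1\tP1\t500\t100",
    "1\tP1\t480\t95",
    "1\tCy3-BSA\t2000\t100",
    "1\tIgG_2\t800\t90"
  ), path)
  spots <- read_spot_table(path, dialect = "gpr", sample_id = "arrayA")
  expect_equal(nrow(spots), 4L)
  expect_equal(unique(spots$sample_id), "arrayA")
  expect_equal(spots$fg[1], 500)
  expect_equal(spots$replicate[spots$protein_id == "P1"], c(1, 2))
  expect_equal(spots$spot_class,
               c("protein", "protein", "cy3_bsa_control",
                 "igg_dilution_control"))
})

test_that("net intensity subtracts background and floors at a positive value", {
  expect_equal(net_intensity(500, 100, 1), 400)
  expect_equal(net_intensity(50, 80, 1), 1)
  expect_equal(net_intensity(200, 200, 1), 1)
  expect_error(net_intensity(10, 5, 0), "positive")
})

test_that("replicate aggregation is robust, flags high-CV sets, keeps values", {
  spots <- rbind(toy_spots(c(10, 12, 11, 100), protein_id = "noisy"),
                 toy_spots(c(5, 5, 5, 5), protein_id = "flat"),
                 toy_spots(7, protein_id = "single"))
  out <- aggregate_replicates(spots, method = "median",
                              cv_flag_threshold = 0.5)
  m <- out$matrix
  expect_equal(m["s1", "noisy"], 11.5)
  expect_equal(m["s1", "flat"], 5)
  expect_equal(m["s1", "single"], 7)
  qc <- out$qc
  expect_true(qc$flagged[qc$protein_id == "noisy"])
  # hand CV of {10,12,11,100}: sd/mean = 44.53.../33.25 > 0.5
  expect_gt(qc$cv[qc$protein_id == "noisy"], 0.5)
  expect_false(qc$flagged[qc$protein_id == "flat"])
  expect_false(qc$flagged[qc$protein_id == "single"])  # CV undefined, n=1
})

test_that("median aggregation is invariant to spot order", {
  set.seed(4)
  spots <- do.call(rbind, lapply(c("a", "b", "c"), function(p)
    toy_spots(stats::runif(4, 10, 1000), protein_id = p)))
  ref <- aggregate_replicates(spots)$matrix
  for (i in 1:5) {
    perm <- spots[sample(nrow(spots)), ]
    expect_equal(aggregate_replicates(perm)$matrix, ref)
  }
})

test_that("aggregation reports missing (sample, protein) pairs", {
  spots <- rbind(toy_spots(c(10, 11), sample_id = "s1", protein_id = "p1"),
                 toy_spots(c(10, 11), sample_id = "s1", protein_id = "p2"),
                 toy_spots(c(9, 12), sample_id = "s2", protein_id = "p1"))
  expect_error(aggregate_replicates(spots), "s2 / p2")
})

test_that("control QC scores Cy3-BSA consistency and IgG dilution monotonicity", {
  igg <- data.frame(sample_id = "s1", protein_id = sprintf("IGG_%d", 1:5),
                    replicate = 1L, fg = c(100, 200, 400, 800, 1600),
                    bg = 0, spot_class = "igg_dilution_control")
  cy3 <- toy_spots(c(100, 100, 100), protein_id = "CY3_BSA",
                   spot_class = "cy3_bsa_control")
  qc <- qc_controls(rbind(igg, cy3))
  expect_equal(qc$igg_rho, 1)
  expect_equal(qc$cy3_cv, 0)
  expect_equal(qc$status, "pass")

  set.seed(7)
  igg$fg <- sample(igg$fg)
  qc2 <- qc_controls(rbind(igg, cy3))
  expect_lt(abs(qc2$igg_rho), 0.9)
  expect_equal(qc2$status, "fail")

  bare <- toy_spots(c(10, 11), sample_id = "s9")
  expect_equal(qc_controls(bare)$status, "uncheckable")
})

test_that("generated cohorts produce complete, non-negative matrices", {
  cfg <- synth_config(n_proteins = 20,
                      cohort1 = list(n_pos = 3, n_neg = 3,
                                     timepoints = "baseline"),
                      cohort2 = NULL, n_healthy = 2, seed = 1)
  sim <- generate_cohort(cfg)
  n_samples <- nrow(sim$meta)
  expect_equal(n_samples, 8L)
  prot <- sim$spots[sim$spots$spot_class == "protein", ]
  expect_equal(nrow(prot), n_samples * 20 * 4)
  m <- aggregate_replicates(sim$spots)$matrix
  expect_equal(dim(m), c(n_samples, 20L))
  expect_equal(rownames(m), sort(sim$meta$sample_id))
  expect_true(all(m > 0))
})
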