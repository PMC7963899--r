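test_that("ADAb positivity is strict at three times the detection limit", {
  expect_true(adab_positive(10.6))
  expect_false(adab_positive(10.5))
  expect_false(adab_positive(0))
  expect_true(adab_positive(7, detection_limit = 2))   # threshold 6
})

test_that("EULAR classification matches the response grid", {
  expect_equal(as.character(eular_classify(6.0, 3.0)), "good")
  expect_equal(as.character(eular_classify(6.0, 5.6)), "poor")
  expect_equal(as.character(eular_classify(5.5, 4.5)), "moderate")
  # standard grid: large decrease but attained > 5.1 is moderate;
  # the caption-literal mode calls it poor
  expect_equal(as.character(eular_classify(8.0, 5.5)), "moderate")
  expect_equal(as.character(eular_classify(8.0, 5.5,
                                           mode = "caption_literal")),
               "poor")
  expect_error(eular_classify(NA, 3), "missing")
  expect_error(eular_classify(11, 3), "0, 10")
})

test_that("EULAR classification is total over the score grid", {
  grid <- expand.grid(b = seq(0, 10, by = 0.5), w = seq(0, 10, by = 0.5))
  for (mode in c("standard", "caption_literal")) {
    cls <- eular_classify(grid$b, grid$w, mode = mode)
    expect_false(anyNA(cls))
    expect_true(all(cls %in% c("good", "moderate", "poor")))
  }
})

test_that("rank AUC equals brute-force pair counting", {
  expect_equal(auc_rank(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_rank(rep(2, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_equal(auc_rank(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)

  pair_auc <- function(s, l) {  # independent oracle
    pos <- s[l == 1]; neg <- s[l == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  set.seed(31)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    l <- c(0, 1, stats::rbinom(n - 2, 1, 0.5))
    s <- sample(1:8, n, replace = TRUE)  # heavy ties
    expect_equal(auc_rank(s, l), pair_auc(s, l))
  }
  expect_error(auc_rank(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(32)
  s <- stats::rnorm(40)
  l <- stats::rbinom(40, 1, 0.5); l[1:2] <- c(0, 1)
  a <- auc_rank(s, l)
  expect_equal(auc_rank(exp(s), l), a)
  expect_equal(auc_rank(rank(s), l), a)
  expect_equal(auc_rank(s^3, l), a)
})

test_that("AUC filter requires the threshold at both timepoints", {
  b <- c(p1 = 0.85, p2 = 0.85, p3 = 0.95)
  w <- c(p1 = 0.81, p2 = 0.79, p3 = 0.80)
  expect_equal(select_by_auc(b, w), c("p1", "p3"))
  expect_error(select_by_auc(b, w[1:2]), "same proteins")
})

test_that("Mann-Whitney U is oriented to the first group with exact small-N p", {
  sep <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p.value, 1)

  # independent enumeration oracle over all C(6,3) assignments
  x <- c(1, 3, 5); y <- c(2, 4, 6)
  r <- rank(c(x, y))
  stats <- apply(utils::combn(6, 3), 2,
                 function(idx) sum(r[idx]) - 6)
  obs <- sum(r[1:3]) - 6
  p_oracle <- mean(abs(stats - 4.5) >= abs(obs - 4.5))
  expect_equal(mann_whitney(x, y)$p.value, p_oracle)

  # U links to AUC: U = AUC * n1 * n0 (positives = second group)
  set.seed(33)
  for (i in 1:20) {
    a <- stats::rnorm(7); b <- stats::rnorm(9)
    U <- mann_whitney(a, b)$U
    auc <- auc_rank(c(a, b), rep(c(1, 0), c(7, 9)))
    expect_equal(U, auc * 63)
  }
})

test_that("exact and approximate Mann-Whitney p agree with wilcox.test", {
  set.seed(34)
  x <- stats::rnorm(20); y <- stats::rnorm(25, 0.5)
  expect_equal(mann_whitney(x, y)$p.value,
               stats::wilcox.test(x, y, exact = FALSE,
                                  correct = FALSE)$p.value)
  # tie-free small samples: exact enumeration equals wilcox.test exact p
  for (i in 1:10) {
    x <- stats::rnorm(5); y <- stats::rnorm(6, 0.8)
    expect_equal(mann_whitney(x, y)$p.value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("Spearman correlation handles monotone, reversed, and tied data", {
  expect_equal(spearman(1:5, c(2, 4, 6, 8, 10)), 1)
  expect_equal(spearman(1:5, -(1:5)), -1)
  expect_equal(spearman(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_warning(r <- spearman(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(r))
})

test_that("Fisher exact test reproduces the probability-mass rule", {
  expect_equal(fisher_exact(matrix(1, 2, 2)), 1.0)
  expect_lt(fisher_exact(matrix(c(9, 2, 5, 44), 2)), 0.001)
  expect_warning(p0 <- fisher_exact(matrix(c(0, 0, 3, 4), 2)),
                 "zero margin")
  expect_equal(p0, 1)
  expect_error(fisher_exact(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("logistic regression recovers the 2x2 cross-product odds ratio", {
  x <- rep(c(1, 1, 0, 0), c(20, 10, 5, 25))
  y <- rep(c(1, 0, 1, 0), c(20, 10, 5, 25))
  fit <- logistic_multivariate(data.frame(exposure = x), y)
  or <- fit$coefficients$odds_ratio[fit$coefficients$term == "exposure"]
  expect_equal(or, 10.0, tolerance = 1e-6)
  expect_false(fit$separation)
  expect_true(fit$converged)
})

test_that("separation and collinearity are flagged, not returned as estimates", {
  y <- rep(c(0, 1), each = 15)
  fit <- logistic_multivariate(data.frame(z = y), y)
  expect_true(fit$separation)
  X <- data.frame(a = stats::rnorm(30), b = 0)
  X$b <- 2 * X$a
  expect_error(logistic_multivariate(X, y), "collinear.*b")
})

test_that("logistic Wald p-values hold their size under the null", {
  set.seed(3)
  rej <- 0L
  for (i in 1:500) {
    y <- stats::rbinom(200, 1, 0.5)
    X <- data.frame(x = stats::rnorm(200))
    fit <- logistic_multivariate(X, y)
    p <- fit$coefficients$p_value[fit$coefficients$term == "x"]
    rej <- rej + (p < 0.05)
  }
  expect_gte(rej / 500, 0.02)
  expect_lte(rej / 500, 0.09)
})

test_that("Ward/Euclidean clustering splits separated groups and orders leaves", {
  set.seed(5)
  blob <- rbind(matrix(stats::rnorm(40, 0, 0.3), 8),
                matrix(stats::rnorm(40, 6, 0.3), 8))
  rownames(blob) <- paste0("s", 1:16)
  colnames(blob) <- paste0("f", 1:5)
  ord <- ward_order(blob)
  groups <- stats::cutree(ord$sample_hclust, 2)
  expect_equal(length(unique(groups[1:8])), 1L)
  expect_equal(length(unique(groups[9:16])), 1L)
  expect_true(groups[1] != groups[9])

  twin <- toy_matrix(rbind(c(1, 2), c(1, 2), c(9, 9)))
  hc <- ward_order(twin)$sample_hclust
  expect_equal(min(hc$height), 0)

  single <- toy_matrix(matrix(1:3, 1))
  expect_equal(ward_order(single)$sample_order, "s1")
  expect_null(ward_order(single)$sample_hclust)
})

test_that("grouped clinical summaries report rates and between-group tests", {
  meta <- data.frame(
    group = rep(c("adab_pos", "adab_neg"), c(14, 46)),
    ro60 = c(rep(TRUE, 9), rep(FALSE, 5), rep(TRUE, 2), rep(FALSE, 44)),
    das28 = c(stats::rnorm(14, 6.7, 0.8), stats::rnorm(46, 6.4, 0.8))
  )
  tab <- table1_summary(meta, "group", binary_vars = "ro60",
                        numeric_vars = "das28")
  row <- tab[tab$variable == "ro60", ]
  expect_match(row$adab_pos, "9 \\(64.3%\\)")
  expect_match(row$adab_neg, "2 \\(4.3%\\)")
  expect_lt(row$p_value, 0.001)
  expect_equal(nrow(tab), 2L)
})

test_that("a planted binary group difference is detected reliably", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    meta <- data.frame(
      group = rep(c("adab_pos", "adab_neg"), c(14, 46)),
      marker = c(stats::rbinom(14, 1, 0.65) == 1,
                 stats::rbinom(46, 1, 0.05) == 1)
    )
    tab <- table1_summary(meta, "group", binary_vars = "marker")
    hits <- hits + (tab$p_value[1] < 0.05)
  }
  expect_gte(hits, 90L)
})
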