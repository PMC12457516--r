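test_that("normality gate routes by Shapiro-Wilk and flags degenerate samples", {
  set.seed(101)
  parametric <- sum(vapply(1:100, function(i) {
    normality_gate(list(rnorm(500)))$route == "parametric"
  }, logical(1)))
  expect_gte(parametric, 90L)

  nonpar <- sum(vapply(1:100, function(i) {
    normality_gate(list(rexp(100)))$route == "nonparametric"
  }, logical(1)))
  expect_gte(nonpar, 99L)

  g <- normality_gate(list(c(2, 2, 2)))
  expect_equal(g$route, "nonparametric")
  expect_true(g$tests$degenerate[1])
})

test_that("Kruskal-Wallis matches the rank-sum oracle and handles degeneracy", {
  r <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(r$statistic, oracle_kw_H(list(c(1, 2), c(3, 4), c(5, 6))),
               tolerance = 1e-12)
  expect_equal(r$df, 2)
  # eta^2 = (H - k + 1)/(N - k)
  expect_equal(r$effect, (r$statistic - 2) / 3, tolerance = 1e-12)

  same <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0, tolerance = 1e-12)

  const <- kruskal_wallis(list(c(2, 2), c(2, 2)))
  expect_equal(const$statistic, 0)
  expect_equal(const$p, 1)
})

test_that("two-group Kruskal-Wallis equals the squared Mann-Whitney normal z", {
  x <- c(1.2, 3.4, 2.2, 8.1)
  y <- c(4.4, 0.7, 9.9, 6.1, 5.5)
  H <- kruskal_wallis(list(x, y))$statistic
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  u1 <- oracle_u1(x, y)
  z <- (u1 - n1 * n2 / 2) / sqrt(n1 * n2 * (N + 1) / 12)  # no ties, no cc
  expect_equal(H, z^2, tolerance = 1e-9)
})

test_that("Dunn post hoc matches its oracle and adjusts as stated", {
  g <- list(a = c(1, 5, 9), b = c(1, 5, 9), c = c(20, 25, 30))
  d <- dunn_posthoc(g, adjust = "bonferroni")
  ab <- d[d$group1 == "a" & d$group2 == "b", ]
  expect_equal(ab$z, 0, tolerance = 1e-12)
  expect_equal(ab$p, 1, tolerance = 1e-12)
  for (i in seq_len(nrow(d))) {
    expect_equal(d$z[i], oracle_dunn_z(g, match(d$group1[i], names(g)),
                                       match(d$group2[i], names(g))),
                 tolerance = 1e-12)
  }
  expect_equal(d$p_adjust, pmin(1, d$p * 3))

  # fully separated groups: the largest-gap pair has the largest |z|
  g2 <- list(lo = c(1, 2, 3), mid = c(10, 11, 12), hi = c(20, 21, 22))
  d2 <- dunn_posthoc(g2, adjust = "fdr-BH")
  worst <- which.max(abs(d2$z))
  expect_equal(sort(c(d2$group1[worst], d2$group2[worst])), c("hi", "lo"))

  # Bonferroni multiplies by the number of pairs, capped at 1
  g6 <- split(seq(1, 60), rep(1:6, each = 10))
  d6 <- dunn_posthoc(g6, adjust = "bonferroni")
  expect_equal(nrow(d6), 15L)
  expect_equal(d6$p_adjust, pmin(1, d6$p * 15))
})

test_that("Benjamini-Hochberg follows the step-up rule and preserves order", {
  expect_equal(benjamini_hochberg(0.037), 0.037)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(13)
  p <- runif(50)
  bh <- benjamini_hochberg(p)
  bonf <- pmin(1, p * 50)
  expect_true(all(bonf >= bh - 1e-12))
  expect_true(all(bh >= p - 1e-12))
  shuf <- sample(50)
  expect_equal(benjamini_hochberg(p[shuf]), bh[shuf])
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("per-region count tests pick the right branch and control FDR", {
  # identical outlier columns in both groups -> no association
  x <- matrix(rep(c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0), 3), ncol = 3)
  out <- make_outlier_matrix(cbind(rbind(x, x)),
                             diagnosis = rep(c("A", "B"), each = 10))
  r <- region_count_tests(out, c("A", "B"), "all")
  expect_true(all(r$p > 0.99))

  # complete separation with small expected counts -> exact branch with the
  # hypergeometric two-corner p
  x2 <- matrix(0L, 14, 1)
  x2[1:7, 1] <- 1L
  out2 <- make_outlier_matrix(x2, diagnosis = rep(c("A", "B"), each = 7))
  r2 <- region_count_tests(out2, c("A", "B"), "all")
  expect_equal(r2$test, "fisher-exact")
  expect_equal(r2$p, 2 / choose(14, 7), tolerance = 1e-12)

  # zero outlier margin -> flagged, p = 1
  out3 <- make_outlier_matrix(matrix(0L, 10, 2),
                              diagnosis = rep(c("A", "B"), each = 5))
  r3 <- region_count_tests(out3, c("A", "B"), "all")
  expect_true(all(r3$flag == "zero-margin"))
  expect_true(all(r3$p == 1))

  # null simulation: BH-significant count stays within the FDR budget
  set.seed(17)
  rejections <- vapply(1:100, function(i) {
    m <- matrix(rbinom(40 * 60, 1, 0.15), nrow = 40)
    o <- make_outlier_matrix(m, diagnosis = rep(c("A", "B"), each = 20),
                             regions = toy_region_set(60))
    sum(region_count_tests(o, c("A", "B"), "all")$p_adjust < 0.05)
  }, numeric(1))
  expect_lte(mean(rejections), 0.05 * 60)
})

test_that("chi-square contingency matches hand-computed O/E sums", {
  # perfectly proportional table -> 0
  expect_equal(chi_square_contingency(rbind(c(10, 20), c(20, 40)))$statistic,
               0, tolerance = 1e-12)
  # hand O/E: margins 30/30 x 30/30, all E = 15, chi2 = 4 * 25/15 = 20/3
  r <- chi_square_contingency(rbind(c(20, 10), c(10, 20)))
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(r$df, 1)
  expect_error(chi_square_contingency(rbind(c(0, 0), c(1, 2))), "margin")
  expect_error(chi_square_contingency(rbind(c(1.5, 2), c(1, 2))), "integer")
})

test_that("one-way ANOVA: raw and summary paths agree; two-group F = t^2", {
  set.seed(19)
  g <- list(rnorm(12, 0), rnorm(15, 0.5), rnorm(9, 1))
  raw <- anova_oneway(g)
  summ <- anova_oneway_summary(lengths(g), vapply(g, mean, 1),
                               vapply(g, sd, 1))
  expect_equal(raw$statistic, summ$statistic, tolerance = 1e-10)
  expect_equal(raw$p, summ$p, tolerance = 1e-10)

  eq <- anova_oneway(list(c(1, 2, 3), c(3, 1, 2)))
  expect_equal(eq$statistic, 0, tolerance = 1e-12)

  x <- rnorm(10); y <- rnorm(12, 0.8)
  F2 <- anova_oneway(list(x, y))$statistic
  t2 <- unname(t.test(x, y, var.equal = TRUE)$statistic)^2
  expect_equal(F2, t2, tolerance = 1e-9)

  inf <- anova_oneway_summary(c(5, 5), c(0, 1), c(0, 0))
  expect_equal(inf$note, "infinite-F")
})

test_that("Welch t with Cohen's d behaves at its limits", {
  x <- c(1, 2, 3, 4, 5)
  r0 <- welch_t(x, x + 0)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$effect, 0, tolerance = 1e-12)
  expect_true(r0$effect_ci[1] < 0 && r0$effect_ci[2] > 0)

  # equal variances: Welch df approaches n1 + n2 - 2
  set.seed(23)
  x1 <- scale(rnorm(40))[, 1]; y1 <- scale(rnorm(40))[, 1] + 1
  expect_equal(welch_t(x1, y1)$df, 78, tolerance = 1e-6)

  x2 <- rnorm(1000); y2 <- rnorm(1000) - 1
  d <- welch_t(x2, y2)$effect
  expect_lt(abs(d - 1), 0.1)
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
})

test_that("Mann-Whitney U and rank-biserial follow the stated conventions", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), exact = TRUE)
  expect_equal(r$statistic, 0)
  expect_equal(r$effect, -1)      # complete dominance of the second sample
  expect_equal(r$p, oracle_mwu_exact_p(c(1, 2, 3), c(4, 5, 6)),
               tolerance = 1e-12)

  same <- mann_whitney_u(c(1, 2, 3), c(3, 1, 2))
  expect_equal(same$effect, 0, tolerance = 1e-12)

  tied <- mann_whitney_u(c(5, 5), c(5, 5, 5))
  expect_equal(tied$p, 1)
  expect_equal(tied$effect, 0)

  # normal-approximation p equals the tie- and continuity-corrected oracle
  x <- c(3, 1, 4, 1, 5); y <- c(9, 2, 6, 5, 3, 5)
  got <- mann_whitney_u(x, y)
  expect_equal(got$p,
               suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE)$p.value))
})

test_that("severity stratification implements both modes and the scale map", {
  subj <- data.frame(subject_id = paste0("s", 1:5),
                     diagnosis = c("PSP", "CBS", "bvFTD", "svPPA", "nfvPPA"),
                     severity = c(0, 0.5, 1, 2, NA))
  def <- severity_stratify(subj)
  expect_equal(def$stratum, c("excluded", "mild", "severe", "severe", "excluded"))
  expect_equal(def$reason[c(1, 5)], c("score 0 in default mode", "missing score"))
  expect_equal(def$scale[1:3], c("CDR", "CDR", "CDR-plus-NACC-FTLD"))

  mz <- severity_stratify(subj, mode = "merge-zero")
  expect_equal(mz$stratum, c("<=0.5", "<=0.5", "severe", "severe", "excluded"))

  expect_error(severity_stratify(transform(subj, diagnosis = "ALS")),
               "unknown group")
})

test_that("severity comparisons sign severe-worse as negative and skip degenerate strata", {
  set.seed(29)
  metrics <- data.frame(
    subject_id = paste0("s", 1:40),
    diagnosis = rep(c("PSP", "CBS"), each = 20),
    severity = rep(c(0.5, 2), 20),
    tOC_cortical = NA_real_)
  # severe subjects have systematically higher counts
  metrics$tOC_cortical <- ifelse(metrics$severity >= 1,
                                 rpois(40, 30), rpois(40, 5))
  strat <- severity_stratify(metrics[, c("subject_id", "diagnosis", "severity")])
  cmp <- severity_comparisons(metrics, strat, "tOC_cortical")
  expect_setequal(names(cmp), c("PSP", "CBS"))
  for (r in cmp) expect_lt(r$effect, 0)   # mild first => severe worse negative

  # all severe -> not estimable
  allsev <- metrics[metrics$severity >= 1, ]
  strat2 <- severity_stratify(allsev[, c("subject_id", "diagnosis", "severity")])
  cmp2 <- severity_comparisons(allsev, strat2, "tOC_cortical")
  expect_length(cmp2, 0)
  expect_setequal(attr(cmp2, "skipped"), c("PSP", "CBS"))
})
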