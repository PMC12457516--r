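# Shared fixtures and independent oracles for the test suite.

new_subject_table <- normdev:::new_subject_table

# Build a deviation_table directly from a z matrix (subjects x regions).
make_deviation_table <- function(z, diagnosis = "CN", severity = NA_real_,
                                 regions = NULL) {
  n <- nrow(z)
  if (is.null(regions)) {
    regions <- toy_region_set(ncol(z))
  }
  colnames(z) <- regions$name
  meta <- data.frame(subject_id = sprintf("s%03d", seq_len(n)),
                     age = 65, sex = 0L, site = "t",
                     diagnosis = rep_len(diagnosis, n),
                     severity = rep_len(severity, n),
                     stringsAsFactors = FALSE)
  rownames(z) <- meta$subject_id
  structure(list(z = z, meta = meta, regions = regions),
            class = "deviation_table")
}

# Build an outlier_matrix directly from a binary matrix.
make_outlier_matrix <- function(x, diagnosis = "CN", severity = NA_real_,
                                regions = NULL, tau = -1.96) {
  dev <- make_deviation_table(matrix(0, nrow(x), ncol(x)),
                              diagnosis = diagnosis, severity = severity,
                              regions = regions)
  structure(list(x = matrix(as.integer(x), nrow(x), ncol(x),
                            dimnames = list(dev$meta$subject_id,
                                            dev$regions$name)),
                 tau = tau, two_sided = FALSE,
                 meta = dev$meta, regions = dev$regions),
            class = "outlier_matrix")
}

# Average ranks computed from first principles (count of smaller values plus
# half the ties), independent of base::rank.
oracle_ranks <- function(x) {
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))
}

# Kruskal-Wallis H from the rank-sum formula with the tie correction, using
# oracle_ranks; independent of stats::kruskal.test.
oracle_kw_H <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  r <- oracle_ranks(x)
  idx <- rep(seq_along(groups), lengths(groups))
  H <- 12 / (N * (N + 1)) *
    sum(vapply(seq_along(groups), function(i) {
      ni <- sum(idx == i)
      ni * (mean(r[idx == i]) - (N + 1) / 2)^2
    }, numeric(1)))
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C == 0) return(0)
  H / C
}

# Dunn pairwise z for groups i, j from the pooled oracle ranking.
oracle_dunn_z <- function(groups, i, j) {
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  r <- oracle_ranks(x)
  idx <- rep(seq_along(groups), lengths(groups))
  ties <- table(x)
  v <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  se <- sqrt(v * (1 / sum(idx == i) + 1 / sum(idx == j)))
  (mean(r[idx == i]) - mean(r[idx == j])) / se
}

# Mann-Whitney U1 (wins of x, ties half) by direct pair counting, plus the
# exact two-sided p from full enumeration of all labelings of the pooled
# sample (no-ties definition used by the exact distribution).
oracle_u1 <- function(x, y) {
  sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

oracle_mwu_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(ix) oracle_u1(pooled[ix], pooled[-ix]))
  u1 <- oracle_u1(x, y)
  pl <- mean(us <= u1)
  pu <- mean(us >= u1)
  min(1, 2 * min(pl, pu))
}

# One shared normative fit on a toy reference, reused across tests that only
# need *some* correctly fitted model (built lazily, once per test run).
.fixture_env <- new.env()

fixture_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    regs <- toy_region_set(5)
    cfg <- cohort_config(n_per_site = c(a = 400, b = 400),
                         site_offset = c(a = 0.05, b = -0.05), seed = 11)
    ref <- generate_reference_cohort(cfg, regs)
    .fixture_env$regs <- regs
    .fixture_env$fit <- fit_normative(ref, model_spec())
  }
  list(params = .fixture_env$fit, regions = .fixture_env$regs)
}
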