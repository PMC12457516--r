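#' Uniform record for a statistical test
#'
#' Every test in the battery returns a `stat_result` so results can be bound
#' into one tidy table: method tag, statistic, degrees of freedom (NA for
#' exact tests), raw and adjusted p, adjustment method, an effect size with
#' optional 95% CI, and group sizes.
#'
#' @param method method tag, e.g. `"kruskal-wallis"`.
#' @param statistic test statistic value.
#' @param df degrees of freedom (may be length 2, e.g. ANOVA), or NA.
#' @param p raw p value.
#' @param effect effect-size value (or NA).
#' @param effect_name name of the effect size (`"eta2"`, `"cohen_d"`,
#'   `"rank_biserial"`, ...).
#' @param effect_ci optional length-2 CI for the effect.
#' @param n integer vector of group sizes.
#' @param p_adjust adjusted p (defaults to raw p).
#' @param adjust_method `"none"`, `"bonferroni"` or `"fdr-BH"`.
#' @param note free-text diagnostic flag.
#' @return A `stat_result` object.
#' @export
stat_result <- function(method, statistic, df = NA_real_, p,
                        effect = NA_real_, effect_name = NA_character_,
                        effect_ci = c(NA_real_, NA_real_),
                        n = integer(0), p_adjust = p,
                        adjust_method = "none", note = NA_character_) {
  if (is.finite(p) && (p < 0 || p > 1)) stop("p outside [0, 1]")
  structure(list(method = method, statistic = unname(statistic),
                 df = unname(df), p = unname(p), p_adjust = unname(p_adjust),
                 adjust_method = adjust_method, effect = unname(effect),
                 effect_name = effect_name, effect_ci = unname(effect_ci),
                 n = unname(n), note = note),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  df_str <- if (all(is.na(x$df))) "" else paste0("(", paste(round(x$df, 2), collapse = ", "), ")")
  cat(sprintf("%s%s = %.4g, p = %.4g%s", x$method, df_str, x$statistic, x$p,
              if (!is.na(x$effect)) sprintf(", %s = %.3f", x$effect_name, x$effect) else ""),
      "\n")
  invisible(x)
}

#' @export
as.data.frame.stat_result <- function(x, ...) {
  data.frame(method = x$method, statistic = x$statistic,
             df1 = x$df[1], df2 = if (length(x$df) > 1) x$df[2] else NA_real_,
             p = x$p, p_adjust = x$p_adjust, adjust_method = x$adjust_method,
             effect = x$effect, effect_name = x$effect_name,
             effect_ci_low = x$effect_ci[1], effect_ci_high = x$effect_ci[2],
             n = paste(x$n, collapse = "/"), note = x$note,
             signif = sig_markers(x$p_adjust),
             stringsAsFactors = FALSE)
}

#' Bind stat results into a tidy table
#'
#' @param results list of `stat_result` objects (optionally named; names
#'   become a `label` column).
#' @return Data frame, one row per result.
#' @export
stat_table <- function(results) {
  rows <- lapply(results, as.data.frame)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(names(results))) out <- cbind(label = names(results), out)
  out
}

#' Significance markers at 0.05 / 0.01 / 0.001 / 0.0001
#'
#' @param p vector of p values.
#' @return Character vector of `""`, `"*"`, `"**"`, `"***"`, `"****"`.
#' @export
sig_markers <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", ""), right = TRUE) |> as.character()
}

#' Route samples to a parametric or nonparametric comparison
#'
#' Shapiro-Wilk per group at `alpha`; any rejection (or any degenerate,
#' constant sample) routes the comparison to the nonparametric branch. Every
#' W and p is recorded.
#'
#' @param samples list of numeric vectors (each n >= 3 for the test itself).
#' @param alpha normality test level, default 0.05.
#' @return List with `route` (`"parametric"` / `"nonparametric"`) and `tests`
#'   (data frame of per-group W, p, degenerate flag).
#' @export
normality_gate <- function(samples, alpha = 0.05) {
  if (!length(samples)) stop("no samples")
  recs <- lapply(seq_along(samples), function(i) {
    x <- samples[[i]]
    if (length(unique(x)) == 1L) {
      return(data.frame(group = i, n = length(x), W = NA_real_, p = NA_real_,
                        degenerate = TRUE))
    }
    sw <- stats::shapiro.test(x)
    data.frame(group = i, n = length(x), W = unname(sw$statistic),
               p = sw$p.value, degenerate = FALSE)
  })
  tests <- do.call(rbind, recs)
  if (!is.null(names(samples))) tests$group <- names(samples)
  reject <- any(tests$degenerate) || any(tests$p < alpha, na.rm = TRUE)
  list(route = if (reject) "nonparametric" else "parametric", tests = tests)
}

stack_groups <- function(groups) {
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  list(x = unlist(groups, use.names = FALSE),
       g = factor(rep(names(groups), lengths(groups)), levels = names(groups)))
}

#' Kruskal-Wallis H test with rank eta-squared
#'
#' H with average-rank tie correction (via [stats::kruskal.test()]), df =
#' k - 1, chi-square reference p, and the rank epsilon-free eta-squared
#' estimator `(H - k + 1) / (N - k)`, floored at 0. All-identical values give
#' H = 0, p = 1.
#'
#' @param groups list of numeric vectors, >= 2 groups, total n >= 3.
#' @return A `stat_result` (`effect_name = "eta2"`).
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups")
  s <- stack_groups(groups)
  k <- length(groups); N <- length(s$x)
  if (N < 3L) stop("need total n >= 3")
  if (length(unique(s$x)) == 1L) {
    return(stat_result("kruskal-wallis", statistic = 0, df = k - 1, p = 1,
                       effect = 0, effect_name = "eta2", n = lengths(groups),
                       note = "all values identical"))
  }
  kt <- stats::kruskal.test(s$x, s$g)
  H <- unname(kt$statistic)
  eta2 <- max(0, (H - k + 1) / (N - k))
  stat_result("kruskal-wallis", statistic = H, df = k - 1, p = kt$p.value,
              effect = eta2, effect_name = "eta2", n = lengths(groups))
}

#' Dunn's post hoc test on the pooled ranking
#'
#' For every pair of groups, `z = (mean-rank difference) / SE` with the
#' tie-corrected standard error on the pooled ranking, two-sided normal p,
#' adjusted across all k(k-1)/2 pairs by Bonferroni or Benjamini-Hochberg.
#'
#' @param groups named list of numeric vectors.
#' @param adjust `"bonferroni"` or `"fdr-BH"`.
#' @return Data frame with one row per pair: `group1`, `group2`, `z`, `p`,
#'   `p_adjust`, plus the adjustment method.
#' @export
dunn_posthoc <- function(groups, adjust = c("bonferroni", "fdr-BH")) {
  adjust <- match.arg(adjust)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  keep <- lengths(groups) > 0L
  skipped <- names(groups)[!keep]
  groups <- groups[keep]
  if (length(groups) < 2L) stop("need >= 2 non-empty groups")
  s <- stack_groups(groups)
  N <- length(s$x)
  r <- rank(s$x)
  mean_ranks <- tapply(r, s$g, mean)
  ns <- tapply(r, s$g, length)
  ties <- table(s$x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  base_var <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(names(groups), 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    if (base_var <= 0) return(c(z = 0, p = 1))   # every value tied
    se <- sqrt(base_var * (1 / ns[[i]] + 1 / ns[[j]]))
    z <- (mean_ranks[[i]] - mean_ranks[[j]]) / se
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = res["z", ], p = res["p", ],
                    stringsAsFactors = FALSE)
  out$p_adjust <- if (adjust == "bonferroni") {
    pmin(1, out$p * nrow(out))
  } else benjamini_hochberg(out$p)
  out$adjust_method <- adjust
  attr(out, "skipped") <- skipped
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Step-up adjustment with monotone enforcement; the input order is
#' preserved in the output.
#'
#' @param pvals vector of p values in [0, 1].
#' @return Adjusted p values, same order as the input.
#' @export
benjamini_hochberg <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Per-region outlier-count comparisons between two groups
#'
#' For every region of the selected kind, forms the 2x2 table (group x
#' outlier status) and applies the Pearson chi-square test when all expected
#' counts are >= 5, otherwise Fisher's exact test; raw p values are
#' BH-adjusted across the regions of that kind. Regions where neither group
#' has any outliers (zero outlier margin) are recorded with p = 1 and a
#' zero-margin flag.
#'
#' @param out an `outlier_matrix`.
#' @param groups character vector of exactly two diagnosis labels.
#' @param kind region kind.
#' @return Data frame, one row per region: counts, test used, statistic, raw
#'   and BH-adjusted p, flag.
#' @export
region_count_tests <- function(out, groups, kind = c("cortical", "subcortical", "all")) {
  stopifnot(inherits(out, "outlier_matrix"), length(groups) == 2L)
  kind <- match.arg(kind)
  ix1 <- group_rows(out, groups[1]); ix2 <- group_rows(out, groups[2])
  cols <- kind_columns(out, kind)
  rows <- lapply(cols, function(r) {
    a <- sum(out$x[ix1, r]); b <- length(ix1) - a
    c_ <- sum(out$x[ix2, r]); d <- length(ix2) - c_
    tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE)
    if (a + c_ == 0L || b + d == 0L) {
      return(data.frame(region = r, n1_out = a, n1 = length(ix1),
                        n2_out = c_, n2 = length(ix2), test = "none",
                        statistic = NA_real_, p = 1,
                        flag = "zero-margin", stringsAsFactors = FALSE))
    }
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (all(expected >= 5)) {
      ct <- stats::chisq.test(tab, correct = FALSE)
      data.frame(region = r, n1_out = a, n1 = length(ix1),
                 n2_out = c_, n2 = length(ix2), test = "chi-square",
                 statistic = unname(ct$statistic), p = min(1, ct$p.value),
                 flag = NA_character_, stringsAsFactors = FALSE)
    } else {
      # fisher.test can return 1 + eps in degenerate tables; clamp
      ft <- stats::fisher.test(tab)
      data.frame(region = r, n1_out = a, n1 = length(ix1),
                 n2_out = c_, n2 = length(ix2), test = "fisher-exact",
                 statistic = NA_real_, p = min(1, ft$p.value),
                 flag = NA_character_, stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, rows)
  res$p_adjust <- benjamini_hochberg(res$p)
  res$adjust_method <- "fdr-BH"
  res
}

#' Pearson chi-square test of an r x c contingency table
#'
#' No continuity correction by default (matching the r x c case).
#'
#' @param table matrix of nonnegative integer counts with positive margins.
#' @param correct apply Yates continuity correction (2x2 only).
#' @return A `stat_result`.
#' @export
chi_square_contingency <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be nonnegative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row/column margin")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  stat_result("chi-square", statistic = unname(ct$statistic),
              df = unname(ct$parameter), p = ct$p.value,
              n = colSums(table))
}

#' One-way ANOVA from raw data
#'
#' Classical equal-variance one-way ANOVA; also reports eta-squared
#' (SSB / SST).
#'
#' @param groups list of numeric vectors.
#' @return A `stat_result` with `df = c(k - 1, N - k)`.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups")
  s <- stack_groups(groups)
  fit <- stats::oneway.test(s$x ~ s$g, var.equal = TRUE)
  gm <- mean(s$x)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, numeric(1)) - gm)^2)
  sst <- sum((s$x - gm)^2)
  stat_result("anova-oneway", statistic = unname(fit$statistic),
              df = unname(fit$parameter), p = fit$p.value,
              effect = if (sst > 0) ssb / sst else 0, effect_name = "eta2",
              n = lengths(groups))
}

#' One-way ANOVA from group summary statistics
#'
#' Computes F = MSB / MSW from per-group (n, mean, sd): SSB = sum n_i (m_i -
#' grand mean)^2, SSW = sum (n_i - 1) s_i^2. Agrees with [anova_oneway()] to
#' numerical precision when the summaries come from the same data. Useful for
#' published demographic tables where only summaries are printed.
#'
#' @param ns,means,sds per-group sizes (>= 2), means, sds (>= 0).
#' @return A `stat_result` with `df = c(k - 1, N - k)`.
#' @export
anova_oneway_summary <- function(ns, means, sds) {
  stopifnot(length(ns) == length(means), length(ns) == length(sds))
  if (any(ns < 2)) stop("summary ANOVA needs all n >= 2")
  if (any(sds < 0)) stop("sds must be >= 0")
  k <- length(ns); N <- sum(ns)
  gm <- sum(ns * means) / N
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((ns - 1) * sds^2)
  df1 <- k - 1; df2 <- N - k
  if (ssw == 0 && ssb > 0) {
    return(stat_result("anova-oneway-summary", statistic = Inf,
                       df = c(df1, df2), p = 0, n = ns, note = "infinite-F"))
  }
  F <- (ssb / df1) / (ssw / df2)
  stat_result("anova-oneway-summary", statistic = F, df = c(df1, df2),
              p = stats::pf(F, df1, df2, lower.tail = FALSE),
              effect = if (ssb + ssw > 0) ssb / (ssb + ssw) else 0,
              effect_name = "eta2", n = ns)
}

#' Welch two-sample t test with Cohen's d
#'
#' Welch statistic with Satterthwaite df; Cohen's d on the pooled sd, with a
#' 95% CI by noncentral-t inversion (normal-approximation fallback is
#' recorded in the note field).
#'
#' @param x,y numeric vectors, each n >= 2.
#' @return A `stat_result` (`effect_name = "cohen_d"`).
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("both samples need n >= 2")
  if (stats::var(x) == 0 && stats::var(y) == 0) stop("zero variance in both samples")
  tt <- stats::t.test(x, y)   # Welch by default
  n1 <- length(x); n2 <- length(y)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2))
  d <- if (sp > 0) (mean(x) - mean(y)) / sp else 0
  ci <- cohen_d_ci(d, n1, n2)
  stat_result("welch-t", statistic = unname(tt$statistic),
              df = unname(tt$parameter), p = tt$p.value,
              effect = d, effect_name = "cohen_d", effect_ci = ci$ci,
              n = c(n1, n2), note = ci$note)
}

# 95% CI for Cohen's d by inverting the noncentral t distribution of the
# pooled-variance t statistic; falls back to the normal-approximation CI if
# the inversion fails numerically.
cohen_d_ci <- function(d, n1, n2, level = 0.95) {
  scale <- sqrt(1 / n1 + 1 / n2)
  tstat <- d / scale
  df <- n1 + n2 - 2
  alpha <- (1 - level) / 2
  lim <- max(10, abs(tstat) + 10) * 2
  # pt() warns about reduced precision deep in the noncentral tail; the
  # residual error there is far below the CI's own resolution
  f_lo <- function(ncp) suppressWarnings(stats::pt(tstat, df, ncp)) - (1 - alpha)
  f_hi <- function(ncp) suppressWarnings(stats::pt(tstat, df, ncp)) - alpha
  lo <- tryCatch(stats::uniroot(f_lo, c(-lim, lim))$root, error = function(e) NA)
  hi <- tryCatch(stats::uniroot(f_hi, c(-lim, lim))$root, error = function(e) NA)
  if (is.na(lo) || is.na(hi)) {
    se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2 - 2)))
    return(list(ci = d + c(-1, 1) * stats::qnorm(1 - alpha) * se,
                note = "normal-approximation CI"))
  }
  list(ci = c(lo, hi) * scale, note = NA_character_)
}

#' Mann-Whitney U test with rank-biserial correlation
#'
#' Normal-approximation p with tie-corrected variance and 0.5 continuity
#' correction (via [stats::wilcox.test()]); optionally the exact p for small
#' untied samples. Reports `U = min(U1, U2)` as the statistic and the
#' rank-biserial correlation `r = 2 U1 / (n1 n2) - 1`, where `U1` counts wins
#' of the first sample: complete dominance of the second sample yields
#' `r = -1`.
#'
#' @param x,y numeric vectors (n >= 1 each).
#' @param exact use the exact distribution (untied samples only).
#' @return A `stat_result` (`effect_name = "rank_biserial"`); the `note`
#'   field carries `U1`.
#' @export
mann_whitney_u <- function(x, y, exact = FALSE) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both samples need n >= 1")
  if (length(unique(c(x, y))) == 1L) {
    return(stat_result("mann-whitney-u", statistic = n1 * n2 / 2, df = NA,
                       p = 1, effect = 0, effect_name = "rank_biserial",
                       n = c(n1, n2), note = "all values tied"))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact))
  u1 <- unname(wt$statistic)      # wins of x over y (ties counted 1/2)
  u <- min(u1, n1 * n2 - u1)
  r <- 2 * u1 / (n1 * n2) - 1
  stat_result("mann-whitney-u", statistic = u, df = NA, p = wt$p.value,
              effect = r, effect_name = "rank_biserial", n = c(n1, n2),
              note = sprintf("U1=%g%s", u1, if (exact) ";exact" else ""))
}

#' Stratify clinical subjects by disease severity
#'
#' Splits each diagnostic group into a very-mild and a clearly-symptomatic
#' subgroup using the global score of the severity scale appropriate to the
#' group (CDR for PSP/CBS, CDR plus NACC-FTLD for the FTD variants, by
#' default). Default mode: score 0.5 is mild, >= 1 is severe, 0 or missing is
#' excluded with a recorded reason. Merge-zero mode pools scores 0 and 0.5
#' into one "<=0.5" subgroup (missing scores stay excluded).
#'
#' @param subjects data frame with `subject_id`, `diagnosis` and `severity`
#'   columns (global scores in {0, 0.5, 1, 1.5, 2, 3} or NA).
#' @param mode `"default"` or `"merge-zero"`.
#' @param scale_map named character vector mapping diagnosis to scale label.
#' @return A data frame (`subject_id`, `diagnosis`, `scale`, `severity`,
#'   `stratum`, `reason`); `stratum` is `"mild"`/`"<=0.5"`, `"severe"` or
#'   `"excluded"`.
#' @export
severity_stratify <- function(subjects,
                              mode = c("default", "merge-zero"),
                              scale_map = c(PSP = "CDR", CBS = "CDR",
                                            bvFTD = "CDR-plus-NACC-FTLD",
                                            svPPA = "CDR-plus-NACC-FTLD",
                                            nfvPPA = "CDR-plus-NACC-FTLD")) {
  mode <- match.arg(mode)
  need <- c("subject_id", "diagnosis", "severity")
  miss <- setdiff(need, names(subjects))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  unknown <- setdiff(unique(subjects$diagnosis), names(scale_map))
  if (length(unknown)) {
    stop("unknown group label(s) for severity scale map: ",
         paste(unknown, collapse = ", "))
  }
  sev <- subjects$severity
  mild_lab <- if (mode == "merge-zero") "<=0.5" else "mild"
  stratum <- rep("excluded", length(sev))
  reason <- rep(NA_character_, length(sev))
  reason[is.na(sev)] <- "missing score"
  stratum[!is.na(sev) & sev >= 1] <- "severe"
  stratum[!is.na(sev) & sev == 0.5] <- mild_lab
  if (mode == "merge-zero") {
    stratum[!is.na(sev) & sev == 0] <- mild_lab
  } else {
    reason[!is.na(sev) & sev == 0] <- "score 0 in default mode"
  }
  data.frame(subject_id = subjects$subject_id,
             diagnosis = subjects$diagnosis,
             scale = unname(scale_map[subjects$diagnosis]),
             severity = sev, stratum = stratum, reason = reason,
             stringsAsFactors = FALSE)
}

#' Mild-versus-severe comparison of a heterogeneity marker within groups
#'
#' For each diagnostic group with both severity strata present (n >= 2 in
#' each, n >= 3 for the normality gate), compares the marker between the
#' mild and severe subgroups: Welch t if both strata pass the Shapiro-Wilk
#' gate, otherwise Mann-Whitney U. The mild stratum is the first argument, so
#' "severe worse" gives a negative rank-biserial r (or negative t).
#'
#' @param metrics data frame from [heterogeneity_summary()].
#' @param strat data frame from [severity_stratify()].
#' @param marker column of `metrics` to compare.
#' @return Named list of `stat_result`s (one per estimable group); groups
#'   without both strata are reported as not estimable in the `skipped`
#'   attribute.
#' @export
severity_comparisons <- function(metrics, strat, marker = "tOC_cortical") {
  if (!marker %in% names(metrics)) stop("no such marker column: ", marker)
  m <- merge(metrics, strat[, c("subject_id", "stratum")], by = "subject_id")
  out <- list()
  skipped <- character(0)
  mild_lab <- setdiff(unique(m$stratum), c("severe", "excluded"))
  for (g in unique(m$diagnosis)) {
    mg <- m[m$diagnosis == g & m$stratum != "excluded", ]
    x <- mg[[marker]][mg$stratum %in% mild_lab]
    y <- mg[[marker]][mg$stratum == "severe"]
    if (length(x) < 2L || length(y) < 2L) {
      skipped <- c(skipped, g)
      next
    }
    route <- if (length(x) >= 3L && length(y) >= 3L) {
      normality_gate(list(x, y))$route
    } else "nonparametric"
    out[[g]] <- if (route == "parametric") welch_t(x, y) else mann_whitney_u(x, y)
  }
  attr(out, "skipped") <- skipped
  out
}
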