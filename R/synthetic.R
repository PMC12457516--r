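#' Deterministic child seeds for pipeline stages
#'
#' One global seed is expanded into per-stage seeds so that each stage
#' (reference generation, clinical generation, control split, ...) is
#' individually reproducible and stages stay decoupled: changing how many
#' random draws one stage consumes does not perturb the next.
#'
#' The scheme hashes the stage label into an integer and mixes it with the
#' parent seed by modular multiplication; results always lie in
#' [1, 2^31 - 2] so they are valid R integer seeds.
#'
#' @param seed parent integer seed.
#' @param stage character stage label.
#' @return An integer seed, a deterministic function of (seed, stage).
#' @examples
#' child_seed(1, "reference") != child_seed(1, "clinical")
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647   # 2^31 - 1, prime
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% m
  s <- (abs(as.numeric(seed)) %% m)
  as.integer(((s * 48271) %% m + h * 16807) %% (m - 1) + 1)
}

# sinh-arcsinh transform of a standard normal draw: skew eps, tail delta.
# eps = 0, delta = 1 recovers the standard normal exactly.
shash_sample <- function(n, eps = 0, delta = 1) {
  sinh((asinh(stats::rnorm(n)) + eps) / delta)
}

#' Configuration of a synthetic multi-site morphometry cohort
#'
#' Describes the generating model for healthy-control-like data:
#' per site, `value = site_offset + site_scale * (growth(age) + sex_effect *
#' sex + noise)`, with a quadratic growth curve in decades of age and
#' optionally skewed (sinh-arcsinh) noise. All randomness derives from `seed`
#' via [child_seed()].
#'
#' @param n_per_site named integer vector: subjects per site; names are the
#'   site labels.
#' @param age_range length-2 numeric, years; ages are drawn uniformly.
#' @param sex_ratio proportion of subjects coded `sex = 1`.
#' @param coefs optional data frame with columns `region`, `intercept`,
#'   `age_lin`, `age_quad` (per decade and decade squared, centred at 65
#'   years), `sex_effect`, `noise_sd`; defaults are filled per region kind by
#'   [default_growth_coefs()].
#' @param site_offset,site_scale named numeric vectors per site (additive
#'   offset in measure units; multiplicative scale, > 0). Default 0 / 1.
#' @param noise_sd scalar override of the per-region noise sd (measure units,
#'   > 0); `NULL` keeps the per-region values in `coefs`.
#' @param skew,tail sinh-arcsinh noise shape; `skew = 0`, `tail = 1` is
#'   Gaussian.
#' @param seed integer master seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_site = c(siteA = 100, siteB = 100),
                          age_range = c(46, 83),
                          sex_ratio = 0.5,
                          coefs = NULL,
                          site_offset = NULL,
                          site_scale = NULL,
                          noise_sd = NULL,
                          skew = 0,
                          tail = 1,
                          seed = 1L) {
  if (is.null(names(n_per_site)) || any(!nzchar(names(n_per_site)))) {
    stop("n_per_site must be a named vector (names = site labels)")
  }
  if (any(n_per_site <= 0)) stop("configuration error: non-positive subject count")
  if (length(age_range) != 2L || diff(range(age_range)) <= 0) {
    stop("configuration error: degenerate age range")
  }
  sites <- names(n_per_site)
  if (is.null(site_offset)) site_offset <- stats::setNames(rep(0, length(sites)), sites)
  if (is.null(site_scale)) site_scale <- stats::setNames(rep(1, length(sites)), sites)
  if (any(site_scale <= 0)) stop("configuration error: site scales must be > 0")
  if (!is.null(noise_sd) && noise_sd <= 0) {
    stop("configuration error: noise sd must be > 0")
  }
  if (tail <= 0) stop("configuration error: tail parameter must be > 0")
  structure(list(n_per_site = n_per_site, age_range = as.numeric(age_range),
                 sex_ratio = sex_ratio, coefs = coefs,
                 site_offset = site_offset[sites], site_scale = site_scale[sites],
                 noise_sd = noise_sd, skew = skew, tail = tail,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default per-region growth-curve coefficients
#'
#' Deterministic, region-indexed defaults on scales typical of FreeSurfer
#' output: cortical thickness around 2.5 mm thinning with age, subcortical
#' volumes around a few thousand mm^3 shrinking with age. Age enters in
#' decades centred at 65 years.
#'
#' @param regions a `region_set`.
#' @return Data frame with columns `region`, `intercept`, `age_lin`,
#'   `age_quad`, `sex_effect`, `noise_sd`.
#' @export
default_growth_coefs <- function(regions) {
  assert_region_set(regions)
  cortical <- regions$kind == "cortical-thickness"
  i <- seq_len(nrow(regions))
  data.frame(
    region = regions$name,
    intercept = ifelse(cortical, 2.5 + 0.002 * (i %% 7), 4000 + 40 * (i %% 11)),
    age_lin = ifelse(cortical, -0.04, -60),
    age_quad = ifelse(cortical, -0.004, -5),
    sex_effect = ifelse(cortical, 0.05, 150),
    noise_sd = ifelse(cortical, 0.15, 350),
    stringsAsFactors = FALSE
  )
}

resolve_coefs <- function(config, regions) {
  coefs <- config$coefs
  if (is.null(coefs)) coefs <- default_growth_coefs(regions)
  missing <- setdiff(regions$name, coefs$region)
  if (length(missing)) {
    stop("no growth coefficients for regions: ", paste(missing, collapse = ", "))
  }
  coefs <- coefs[match(regions$name, coefs$region), , drop = FALSE]
  if (!is.null(config$noise_sd)) coefs$noise_sd <- config$noise_sd
  coefs
}

growth_mean <- function(coefs, age, sex) {
  dec <- (age - 65) / 10
  # rows of coefs x subjects -> subjects x regions
  outer(dec, coefs$age_lin) + outer(dec^2, coefs$age_quad) +
    outer(sex, coefs$sex_effect) +
    matrix(coefs$intercept, nrow = length(age), ncol = nrow(coefs), byrow = TRUE)
}

new_subject_table <- function(df, regions) {
  attr(df, "regions") <- regions
  class(df) <- c("subject_table", "data.frame")
  df
}

#' @export
print.subject_table <- function(x, ...) {
  regions <- attr(x, "regions")
  cat("Subject feature table: ", nrow(x), " subjects x ", nrow(regions),
      " regions; sites: ", paste(unique(x$site), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Generate a healthy reference cohort
#'
#' Draws a multi-site healthy cohort from the generating model in
#' [cohort_config()]: uniform ages, Bernoulli sex, and per region
#' `site_offset + site_scale * (growth(age) + sex_effect * sex + noise)`.
#' Reproducible: the same config (including its seed) always yields the same
#' table.
#'
#' @param config a `cohort_config`.
#' @param regions a `region_set`.
#' @param diagnosis diagnosis label stamped on every row.
#' @param stage stage label used to derive the child seed; vary it to obtain
#'   independent cohorts from one config.
#' @return A `subject_table`: data frame with columns `subject_id`, `age`,
#'   `sex`, `site`, `diagnosis`, `severity` (NA for healthy rows) and one
#'   column per region.
#' @export
generate_reference_cohort <- function(config, regions,
                                      diagnosis = "CN",
                                      stage = "reference") {
  stopifnot(inherits(config, "cohort_config"))
  assert_region_set(regions)
  if (length(config$n_per_site) < 1L) stop("configuration error: no sites")
  coefs <- resolve_coefs(config, regions)
  set.seed(child_seed(config$seed, stage))

  n <- sum(config$n_per_site)
  site <- rep(names(config$n_per_site), times = config$n_per_site)
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  sex <- stats::rbinom(n, 1L, config$sex_ratio)
  mu <- growth_mean(coefs, age, sex)
  eps <- matrix(shash_sample(n * nrow(regions), config$skew, config$tail),
                nrow = n) *
    matrix(coefs$noise_sd, nrow = n, ncol = nrow(regions), byrow = TRUE)
  off <- config$site_offset[site]
  scl <- config$site_scale[site]
  values <- off + scl * (mu + eps)
  colnames(values) <- regions$name

  df <- data.frame(subject_id = sprintf("%s_%s_%04d", diagnosis, stage, seq_len(n)),
                   age = age, sex = sex, site = site,
                   diagnosis = diagnosis, severity = NA_real_,
                   stringsAsFactors = FALSE)
  new_subject_table(cbind(df, as.data.frame(values, check.names = FALSE)), regions)
}

#' Atrophy signature of a clinical group
#'
#' Defines how a diagnostic group deviates from the healthy generating model:
#' a set of signature regions, a mean atrophy depth (in units of the healthy
#' residual sd, negative), a per-subject probability that each signature
#' region is involved (the heterogeneity dial: 1 = perfectly homogeneous
#' group), a rate of off-signature involvement, a categorical severity
#' distribution over the clinical dementia rating global scores
#' {0, 0.5, 1, 1.5, 2, 3}, and a multiplier scaling depth for severity >= 1.
#'
#' @param label diagnosis label.
#' @param regions character vector of signature region names.
#' @param n_subjects subjects in the group.
#' @param depth mean atrophy depth, units of healthy residual sd; must be
#'   <= 0.
#' @param involvement_prob probability each signature region is involved in a
#'   given subject.
#' @param off_rate probability a non-signature region is involved.
#' @param severity_probs named numeric vector of probabilities over severity
#'   scores; names among "0", "0.5", "1", "1.5", "2", "3".
#' @param severity_multiplier factor (>= 1) scaling depth when severity >= 1.
#' @return A `group_signature` list.
#' @export
group_signature <- function(label, regions, n_subjects,
                            depth = -3,
                            involvement_prob = 0.8,
                            off_rate = 0.02,
                            severity_probs = c("0.5" = 0.5, "1" = 0.3, "2" = 0.2),
                            severity_multiplier = 1.5) {
  if (depth > 0) stop("atrophy depth must be <= 0 (sd units)")
  if (involvement_prob < 0 || involvement_prob > 1) {
    stop("involvement probability must be in [0, 1]")
  }
  if (severity_multiplier < 1) stop("severity multiplier must be >= 1")
  lev <- c("0", "0.5", "1", "1.5", "2", "3")
  if (!all(names(severity_probs) %in% lev)) {
    stop("severity_probs names must be among ", paste(lev, collapse = ", "))
  }
  structure(list(label = label, regions = regions, n_subjects = n_subjects,
                 depth = depth, involvement_prob = involvement_prob,
                 off_rate = off_rate,
                 severity_probs = severity_probs / sum(severity_probs),
                 severity_multiplier = severity_multiplier),
            class = "group_signature")
}

#' Generate clinical cohorts with group-specific atrophy signatures
#'
#' Each group's subjects start as healthy-control draws from the same
#' generating model, then each signature region is independently atrophied
#' with the group's involvement probability (and each non-signature region
#' with the off-signature rate). The atrophy added to an involved region is
#' `depth * noise_sd * site_scale`, multiplied by the severity multiplier
#' when the subject's severity score is >= 1. Diagnosis and severity columns
#' are populated.
#'
#' @param config a `cohort_config`; sites for clinical subjects are assigned
#'   round-robin over the config's sites.
#' @param signatures list of [group_signature()] objects.
#' @param regions a `region_set`.
#' @param stage stage label for seed derivation.
#' @return A `subject_table` stacking all groups.
#' @export
generate_clinical_cohort <- function(config, signatures, regions,
                                     stage = "clinical") {
  stopifnot(inherits(config, "cohort_config"))
  assert_region_set(regions)
  if (inherits(signatures, "group_signature")) signatures <- list(signatures)
  coefs <- resolve_coefs(config, regions)
  sites <- names(config$n_per_site)

  out <- vector("list", length(signatures))
  for (g in seq_along(signatures)) {
    sig <- signatures[[g]]
    unknown <- setdiff(sig$regions, regions$name)
    if (length(unknown)) {
      stop("unknown region in signature '", sig$label, "': ",
           paste(unknown, collapse = ", "))
    }
    set.seed(child_seed(config$seed, paste(stage, sig$label, sep = ":")))
    n <- sig$n_subjects
    site <- sites[((seq_len(n) - 1L) %% length(sites)) + 1L]
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    sex <- stats::rbinom(n, 1L, config$sex_ratio)
    mu <- growth_mean(coefs, age, sex)
    eps <- matrix(shash_sample(n * nrow(regions), config$skew, config$tail),
                  nrow = n) *
      matrix(coefs$noise_sd, nrow = n, ncol = nrow(regions), byrow = TRUE)

    severity <- as.numeric(sample(names(sig$severity_probs), n, replace = TRUE,
                                  prob = sig$severity_probs))
    is_sig <- regions$name %in% sig$regions
    p_mat <- matrix(ifelse(is_sig, sig$involvement_prob, sig$off_rate),
                    nrow = n, ncol = nrow(regions), byrow = TRUE)
    involved <- matrix(stats::rbinom(n * nrow(regions), 1L, as.vector(t(p_mat))),
                       nrow = n, byrow = TRUE)
    mult <- ifelse(severity >= 1, sig$severity_multiplier, 1)
    atrophy <- involved * (sig$depth * mult) *
      matrix(coefs$noise_sd, nrow = n, ncol = nrow(regions), byrow = TRUE)

    off <- config$site_offset[site]
    scl <- config$site_scale[site]
    values <- off + scl * (mu + eps + atrophy)
    colnames(values) <- regions$name
    df <- data.frame(
      subject_id = sprintf("%s_%04d", sig$label, seq_len(n)),
      age = age, sex = sex, site = site,
      diagnosis = sig$label, severity = severity,
      stringsAsFactors = FALSE)
    out[[g]] <- cbind(df, as.data.frame(values, check.names = FALSE))
  }
  new_subject_table(do.call(rbind, out), regions)
}

#' Split controls into adaptation and test sets
#'
#' Random disjoint partition used for transfer adaptation: `round(fraction *
#' n)` subjects go to the adaptation set, the rest to the test set. The same
#' seed always yields the same membership.
#'
#' @param controls a `subject_table`.
#' @param fraction adaptation fraction, in (0, 1); default 0.8.
#' @param seed integer seed.
#' @return A list with `subject_table` elements `adaptation` and `test`.
#' @export
split_adaptation_test <- function(controls, fraction = 0.8, seed = 1L) {
  n <- nrow(controls)
  if (n < 2L) stop("need at least 2 controls to split")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  k <- round(fraction * n)
  if (k < 1L || k >= n) {
    stop("fraction ", fraction, " yields an empty split for n = ", n)
  }
  set.seed(child_seed(seed, "adaptation-split"))
  idx <- sample.int(n, k)
  regions <- attr(controls, "regions")
  list(adaptation = new_subject_table(controls[sort(idx), , drop = FALSE], regions),
       test = new_subject_table(controls[setdiff(seq_len(n), idx), , drop = FALSE],
                                regions))
}

#' Values matrix of a subject table
#'
#' @param x a `subject_table`.
#' @param kind restrict to one region kind (`"all"`, `"cortical"`,
#'   `"subcortical"`).
#' @return Numeric matrix, subjects x regions, subject IDs as row names.
#' @export
feature_matrix <- function(x, kind = "all") {
  regions <- attr(x, "regions")
  cols <- region_names_of_kind(regions, kind)
  m <- as.matrix(x[, cols, drop = FALSE])
  rownames(m) <- x$subject_id
  m
}

covariate_columns <- function() {
  c("subject_id", "age", "sex", "site", "diagnosis", "severity")
}
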