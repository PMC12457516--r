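#' Normative model specification
#'
#' Describes the per-region normative regression: an age basis (cubic
#' B-spline with interior knots at reference age quantiles, or a raw
#' polynomial), sex and site as further covariates, an optional
#' sinh-arcsinh warp lifting the Gaussian residual assumption, and a
#' homoscedastic or per-site residual scale.
#'
#' @param basis `"bspline"` (default) or `"poly"`.
#' @param n_knots interior knots for the B-spline basis (placed at the
#'   corresponding reference age quantiles); default 3 at quantiles
#'   0.25/0.5/0.75.
#' @param degree polynomial degree when `basis = "poly"`.
#' @param warp `"none"` (Gaussian residuals, closed-form fit) or
#'   `"sinh-arcsinh"` (skew/tail parameters estimated by maximum likelihood).
#' @param variance `"per-site"` (default) or `"pooled"` residual scale.
#' @param tol optimizer tolerance for the heteroscedastic / warped fits.
#' @param maxit maximum optimizer iterations.
#' @return A `model_spec` list.
#' @export
model_spec <- function(basis = c("bspline", "poly"),
                       n_knots = 3L, degree = 2L,
                       warp = c("none", "sinh-arcsinh"),
                       variance = c("per-site", "pooled"),
                       tol = 1e-8, maxit = 500L) {
  basis <- match.arg(basis)
  warp <- match.arg(warp)
  variance <- match.arg(variance)
  if (n_knots < 0L) stop("n_knots must be >= 0")
  if (tol <= 0) stop("tolerance must be > 0")
  structure(list(basis = basis, n_knots = n_knots, degree = degree,
                 warp = warp, variance = variance, tol = tol,
                 maxit = as.integer(maxit)),
            class = "model_spec")
}

check_covariates <- function(x) {
  need <- c("age", "sex", "site")
  miss <- need[!need %in% names(x)]
  if (length(miss)) stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  invisible(x)
}

# Age basis settings learned from the reference sample.
age_basis_info <- function(spec, age) {
  if (spec$basis == "bspline") {
    knots <- if (spec$n_knots > 0L) {
      unname(stats::quantile(age, probs = seq_len(spec$n_knots) / (spec$n_knots + 1L)))
    } else numeric(0)
    list(type = "bspline", knots = knots, boundary = range(age))
  } else {
    list(type = "poly", degree = spec$degree, center = mean(age), scale = stats::sd(age))
  }
}

age_basis_matrix <- function(info, age) {
  if (info$type == "bspline") {
    # clamp so held-out ages slightly outside the reference range do not
    # extrapolate the spline
    a <- pmin(pmax(age, info$boundary[1]), info$boundary[2])
    b <- splines::bs(a, knots = info$knots, Boundary.knots = info$boundary,
                     degree = 3L, intercept = FALSE)
    colnames(b) <- paste0("age_bs", seq_len(ncol(b)))
    unclass(b)[, , drop = FALSE]
  } else {
    a <- (age - info$center) / info$scale
    b <- outer(a, seq_len(info$degree), `^`)
    colnames(b) <- paste0("age_poly", seq_len(info$degree))
    b
  }
}

# Sum-to-zero site encoding: the intercept is the across-site average, so a
# site unseen at fit time (all columns zero) is predicted at the reference
# average, and the adaptation shift absorbs the true offset.
site_design <- function(site, levels) {
  s <- length(levels)
  if (s < 2L) return(matrix(numeric(0), nrow = length(site), ncol = 0))
  m <- matrix(0, nrow = length(site), ncol = s - 1L,
              dimnames = list(NULL, paste0("site_", levels[-s])))
  for (j in seq_len(s - 1L)) {
    m[site == levels[j], j] <- 1
    m[site == levels[s], j] <- -1
  }
  m
}

build_design <- function(meta, info, site_levels) {
  cbind(`(Intercept)` = 1,
        age_basis_matrix(info, meta$age),
        sex = meta$sex,
        site_design(meta$site, site_levels))
}

# Warped-normal log-likelihood. t = standardized residual; with the
# sinh-arcsinh warp the latent standard-normal score is
# z = sinh(delta * asinh(t) - eps); eps = 0, delta = 1 is the identity.
shash_z <- function(t, eps, delta) sinh(delta * asinh(t) - eps)

warped_loglik <- function(y, mu, sigma, eps, delta) {
  t <- (y - mu) / sigma
  z <- shash_z(t, eps, delta)
  sum(stats::dnorm(z, log = TRUE) + log(delta) + 0.5 * log1p(z^2) -
        0.5 * log1p(t^2) - log(sigma))
}

gaussian_loglik <- function(y, mu, sigma) {
  sum(stats::dnorm(y, mean = mu, sd = sigma, log = TRUE))
}

# Heteroscedastic Gaussian ML per region: alternate weighted least squares
# for the mean coefficients with per-site ML scale updates. Each half-step
# maximizes the likelihood in one block, so the recorded trace is monotone.
fit_region_gaussian <- function(y, X, site, site_levels, variance, tol, maxit) {
  per_site <- variance == "per-site" && length(site_levels) > 1L
  groups <- if (per_site) split(seq_along(y), factor(site, levels = site_levels))
            else list(all = seq_along(y))
  beta <- qr.coef(qr(X), y)
  trace <- numeric(0)
  sigma <- NULL
  for (it in seq_len(max(2L, min(maxit, 50L)))) {
    res <- y - drop(X %*% beta)
    sigma <- vapply(groups, function(ix) sqrt(mean(res[ix]^2)), numeric(1))
    sigma[sigma < 1e-12] <- 1e-12
    sig_vec <- if (per_site) sigma[site] else rep(sigma[[1]], length(y))
    ll <- gaussian_loglik(y, drop(X %*% beta), sig_vec)
    trace <- c(trace, ll)
    if (it > 1L && abs(trace[it] - trace[it - 1L]) < tol * (abs(ll) + 1)) break
    w <- 1 / sig_vec^2
    beta <- qr.coef(qr(X * sqrt(w)), y * sqrt(w))
  }
  if (per_site) names(sigma) <- site_levels
  list(beta = beta, sigma = sigma, per_site = per_site, loglik_trace = trace,
       loglik = trace[length(trace)], warp = c(eps = 0, delta = 1),
       converged = TRUE)
}

fit_region_warped <- function(y, X, site, site_levels, variance, tol, maxit) {
  g <- fit_region_gaussian(y, X, site, site_levels, variance, tol, maxit)
  p <- ncol(X)
  ns <- length(g$sigma)
  theta0 <- c(g$beta, log(g$sigma), 0, 0)   # beta, log sigma, eps, log delta
  sig_of <- function(lsig) {
    s <- exp(lsig)
    if (g$per_site) s[match(site, site_levels)] else rep(s, length(y))
  }
  negll <- function(theta) {
    beta <- theta[seq_len(p)]
    sig <- sig_of(theta[p + seq_len(ns)])
    eps <- theta[p + ns + 1L]
    delta <- exp(theta[p + ns + 2L])
    -warped_loglik(y, drop(X %*% beta), sig, eps, delta)
  }
  opt <- stats::optim(theta0, negll, method = "BFGS",
                      control = list(maxit = maxit, reltol = tol))
  ll0 <- -negll(theta0)
  ll1 <- -opt$value
  # keep the better of the Gaussian start and the warped optimum so the
  # likelihood trace is non-decreasing even on a failed line search
  if (ll1 < ll0) {
    opt$par <- theta0
    ll1 <- ll0
  }
  beta <- opt$par[seq_len(p)]
  names(beta) <- colnames(X)
  sigma <- exp(opt$par[p + seq_len(ns)])
  names(sigma) <- names(g$sigma)
  list(beta = beta, sigma = sigma, per_site = g$per_site,
       loglik_trace = c(g$loglik_trace, ll1), loglik = ll1,
       warp = c(eps = opt$par[p + ns + 1L], delta = exp(opt$par[p + ns + 2L])),
       converged = opt$convergence == 0)
}

#' Fit per-region normative models on a healthy reference cohort
#'
#' For every region, estimates by maximum likelihood a mean function (age
#' basis + sex + sum-to-zero site offsets), a residual scale (per site or
#' pooled), and — when the spec enables the sinh-arcsinh warp — skew and
#' tail parameters of the residual distribution. The recorded log-likelihood
#' trace is non-decreasing; refitting the same data gives identical
#' estimates (the fit consumes no random numbers).
#'
#' @param reference a `subject_table` of healthy reference subjects.
#' @param spec a [model_spec()].
#' @return A `normative_params` object.
#' @export
fit_normative <- function(reference, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  check_covariates(reference)
  regions <- attr(reference, "regions")
  assert_region_set(regions)
  site_levels <- sort(unique(reference$site))
  info <- age_basis_info(spec, reference$age)
  X <- build_design(reference, info, site_levels)
  if (nrow(X) < ncol(X) + length(site_levels) + 2L) {
    stop("reference too small: need at least ", ncol(X) + length(site_levels) + 2L,
         " subjects for ", ncol(X), " design columns")
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ", paste(bad, collapse = ", "))
  }
  Y <- feature_matrix(reference)
  fits <- vector("list", nrow(regions))
  names(fits) <- regions$name
  warn_regions <- character(0)
  for (r in regions$name) {
    f <- if (spec$warp == "none") {
      fit_region_gaussian(Y[, r], X, reference$site, site_levels,
                          spec$variance, spec$tol, spec$maxit)
    } else {
      fit_region_warped(Y[, r], X, reference$site, site_levels,
                        spec$variance, spec$tol, spec$maxit)
    }
    names(f$beta) <- colnames(X)
    f$n <- nrow(X)
    if (!f$converged) warn_regions <- c(warn_regions, r)
    fits[[r]] <- f
  }
  if (length(warn_regions)) {
    warning("optimizer did not converge for region(s): ",
            paste(warn_regions, collapse = ", "))
  }
  structure(list(spec = spec, regions = regions, site_levels = site_levels,
                 age_basis = info, coef_names = colnames(X), fits = fits),
            class = "normative_params")
}

#' @export
print.normative_params <- function(x, ...) {
  cat("Normative model: ", length(x$fits), " regions, ",
      length(x$site_levels), " reference sites, warp = ", x$spec$warp,
      ", variance = ", x$spec$variance, "\n", sep = "")
  invisible(x)
}

# Predicted mean and residual scale for arbitrary subjects; unseen sites get
# the reference-average offset and the across-site average scale.
predict_normative <- function(params, meta) {
  check_covariates(meta)
  X <- build_design(meta, params$age_basis, params$site_levels)
  list(X = X, mu = function(region) drop(X %*% params$fits[[region]]$beta),
       sigma = function(region) {
         f <- params$fits[[region]]
         if (!f$per_site) return(rep(unname(f$sigma[[1]]), nrow(meta)))
         s <- unname(f$sigma[match(meta$site, params$site_levels)])
         s[is.na(s)] <- mean(f$sigma)
         s
       })
}

#' Recalibrate a reference normative model to a target cohort
#'
#' Transfer adaptation: for every region, the adaptation subjects' residuals
#' under the reference mean function (with unseen-site offsets marginalized
#' to the reference average) yield a target shift (their location, in
#' measure units) and scale (their spread relative to the reference residual
#' scale), so that adaptation-set z-scores have location ~ 0 and spread ~ 1
#' after recalibration. Robust estimators (median / normalized MAD) are the
#' default because adaptation sets are typically small.
#'
#' @param params a `normative_params` fit.
#' @param adaptation a `subject_table` of local healthy controls (>= 2).
#' @param estimator `"robust"` (median / 1.4826 MAD) or `"moment"`
#'   (mean / sd).
#' @return An `adapted_params` object.
#' @export
adapt_to_site <- function(params, adaptation, estimator = c("robust", "moment")) {
  stopifnot(inherits(params, "normative_params"))
  estimator <- match.arg(estimator)
  if (nrow(adaptation) < 2L) stop("need >= 2 adaptation subjects (scale undefined)")
  check_covariates(adaptation)
  pred <- predict_normative(params, adaptation)
  Y <- feature_matrix(adaptation)
  miss <- setdiff(colnames(Y), names(params$fits))
  if (length(miss)) stop("region(s) absent from model: ", paste(miss, collapse = ", "))
  adapt <- lapply(colnames(Y), function(r) {
    res <- Y[, r] - pred$mu(r)
    sig <- pred$sigma(r)
    if (estimator == "robust") {
      shift <- stats::median(res)
      scale <- stats::mad((res - shift) / sig, center = 0)
    } else {
      shift <- mean(res)
      scale <- stats::sd((res - shift) / sig)
    }
    if (!is.finite(scale) || scale <= 0) {
      stop("degenerate adaptation spread for region ", r)
    }
    list(shift = shift, scale = scale, n = nrow(adaptation))
  })
  names(adapt) <- colnames(Y)
  structure(c(unclass(params), list(adaptation = adapt, estimator = estimator)),
            class = c("adapted_params", "normative_params"))
}

#' @export
print.adapted_params <- function(x, ...) {
  NextMethod()
  cat("Adapted on n = ", x$adaptation[[1]]$n, " controls (",
      x$estimator, " estimators)\n", sep = "")
  invisible(x)
}

#' Deviation z-scores of test subjects under an adapted normative model
#'
#' For each subject and region, `z` standardizes the residual against the
#' adapted model: subtract the predicted mean and the adaptation shift,
#' divide by (reference residual scale x adaptation scale); with the
#' sinh-arcsinh warp enabled, `z` is the latent standard-normal score of the
#' warped residual. Row metadata (diagnosis, severity, age, sex, site) is
#' carried along.
#'
#' @param adapted an `adapted_params` object.
#' @param test a `subject_table`.
#' @return A `deviation_table`: list with `z` (subjects x regions matrix),
#'   `meta` (covariate data frame) and `regions`.
#' @export
compute_zscores <- function(adapted, test) {
  if (!inherits(adapted, "adapted_params")) {
    stop("expected adapted_params; run adapt_to_site() first")
  }
  check_covariates(test)
  Y <- feature_matrix(test)
  miss <- setdiff(colnames(Y), names(adapted$fits))
  if (length(miss)) stop("region(s) absent from model: ", paste(miss, collapse = ", "))
  pred <- predict_normative(adapted, test)
  z <- matrix(NA_real_, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  for (r in colnames(Y)) {
    a <- adapted$adaptation[[r]]
    f <- adapted$fits[[r]]
    t_std <- (Y[, r] - pred$mu(r) - a$shift) / (pred$sigma(r) * a$scale)
    z[, r] <- if (adapted$spec$warp == "none") t_std
              else shash_z(t_std, f$warp[["eps"]], f$warp[["delta"]])
  }
  meta <- as.data.frame(test)[, covariate_columns(), drop = FALSE]
  rownames(meta) <- NULL
  structure(list(z = z, meta = meta, regions = attr(test, "regions")),
            class = "deviation_table")
}

#' @export
print.deviation_table <- function(x, ...) {
  cat("Deviation table: ", nrow(x$z), " subjects x ", ncol(x$z),
      " regions; groups: ", paste(unique(x$meta$diagnosis), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
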