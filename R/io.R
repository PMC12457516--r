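#' Read a FreeSurfer-style stats table
#'
#' Parses the tab-separated dialect emitted by FreeSurfer's
#' `aparcstats2table` / `asegstats2table`: a header row of region names and
#' one row per subject, first column the subject ID. Region names are
#' validated against a region set when one is supplied (hemisphere prefixes
#' preserved, case-sensitive) and the returned columns follow the region
#' set's order.
#'
#' @param path path to the TSV file.
#' @param regions optional `region_set` to validate and order against; with
#'   `NULL`, all non-ID columns are accepted as cortical-thickness regions in
#'   file order.
#' @return A data frame fragment: `subject_id` plus one numeric column per
#'   region, with a `units` attribute (`"mm"` for thickness, `"mm^3"` for
#'   volumes, per region) and the `region_set` as attribute `regions`.
#' @export
read_freesurfer_table <- function(path, regions = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expected a subject-ID column plus region columns")
  names(raw)[1] <- "subject_id"
  raw$subject_id <- as.character(raw$subject_id)
  if (anyDuplicated(raw$subject_id)) {
    stop("duplicate subject ID(s): ",
         paste(unique(raw$subject_id[duplicated(raw$subject_id)]), collapse = ", "))
  }
  found <- names(raw)[-1]
  if (is.null(regions)) {
    regions <- region_set(found, kind = "cortical-thickness", hemisphere = "midline")
  } else {
    assert_region_set(regions)
    unknown <- setdiff(found, regions$name)
    if (length(unknown)) {
      stop("unknown region name(s): ", paste(unknown, collapse = ", "))
    }
    regions <- regions[regions$name %in% found, , drop = FALSE]
    class(regions) <- c("region_set", "data.frame")
  }
  for (r in regions$name) {
    v <- raw[[r]]
    num <- suppressWarnings(as.numeric(v))
    if (anyNA(num) && !all(is.na(v))) {
      i <- which(is.na(num) & !is.na(v))[1]
      stop("non-numeric cell at subject ", raw$subject_id[i], ", region ", r,
           ": '", v[i], "'")
    }
    raw[[r]] <- num
  }
  out <- raw[, c("subject_id", regions$name), drop = FALSE]
  attr(out, "units") <- stats::setNames(
    ifelse(regions$kind == "cortical-thickness", "mm", "mm^3"), regions$name)
  attr(out, "regions") <- regions
  out
}

#' Write a feature table in FreeSurfer stats-table dialect
#'
#' @param x a `subject_table` or a fragment from [read_freesurfer_table()].
#' @param path output TSV path.
#' @param kind restrict to one region kind.
#' @return `path`, invisibly.
#' @export
write_freesurfer_table <- function(x, path, kind = "all") {
  regions <- attr(x, "regions")
  cols <- if (is.null(regions)) setdiff(names(x), covariate_columns())
          else region_names_of_kind(regions, kind)
  df <- data.frame(subject_id = x$subject_id, check.names = FALSE)
  df[cols] <- as.data.frame(x)[cols]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge a covariate table into a feature table
#'
#' Inner join on `subject_id`, with a report of unmatched IDs on both sides
#' attached as attribute `join_report` (and logged as a message). Conflicting
#' duplicate covariate rows are an error.
#'
#' @param features feature fragment (from [read_freesurfer_table()] or a
#'   `subject_table`).
#' @param covariates data frame or CSV path with `subject_id` plus covariate
#'   columns (age, sex, site, diagnosis, severity, ...).
#' @return A `subject_table` with the canonical covariate columns first.
#' @export
merge_covariates <- function(features, covariates) {
  if (is.character(covariates)) {
    covariates <- utils::read.csv(covariates, stringsAsFactors = FALSE)
  }
  if (!"subject_id" %in% names(covariates)) {
    names(covariates)[1] <- "subject_id"
  }
  covariates$subject_id <- as.character(covariates$subject_id)
  if (anyDuplicated(covariates$subject_id)) {
    dup <- unique(covariates$subject_id[duplicated(covariates$subject_id)])
    stop("conflicting duplicate covariate rows for: ", paste(dup, collapse = ", "))
  }
  unmatched_feat <- setdiff(features$subject_id, covariates$subject_id)
  unmatched_cov <- setdiff(covariates$subject_id, features$subject_id)
  merged <- merge(covariates, as.data.frame(features), by = "subject_id",
                  sort = FALSE)
  if (nrow(merged) == 0L) stop("zero subject-ID overlap between tables")
  if (length(unmatched_feat) || length(unmatched_cov)) {
    message("unmatched subjects dropped - features: ",
            paste(unmatched_feat, collapse = ", "), "; covariates: ",
            paste(unmatched_cov, collapse = ", "))
  }
  if (!"diagnosis" %in% names(merged)) merged$diagnosis <- NA_character_
  if (!"severity" %in% names(merged)) merged$severity <- NA_real_
  regions <- attr(features, "regions")
  merged <- merged[, c(covariate_columns(),
                       setdiff(names(merged), covariate_columns()))]
  out <- new_subject_table(merged, regions)
  attr(out, "join_report") <- list(unmatched_features = unmatched_feat,
                                   unmatched_covariates = unmatched_cov)
  out
}

#' Long/wide views of a subject table
#'
#' The long CSV layout (`subject_id, age, sex, site, diagnosis, severity,
#' region, value`) is the canonical interchange format; wide tables are
#' views of it.
#'
#' @param x a `subject_table`.
#' @return `as_long_table()`: long data frame. `as_wide_table()` (on a long
#'   data frame plus its `region_set`): a `subject_table`.
#' @export
as_long_table <- function(x) {
  regions <- attr(x, "regions")
  vals <- feature_matrix(x)
  meta <- as.data.frame(x)[, covariate_columns(), drop = FALSE]
  out <- meta[rep(seq_len(nrow(meta)), times = ncol(vals)), , drop = FALSE]
  out$region <- rep(colnames(vals), each = nrow(vals))
  out$value <- as.vector(vals)
  rownames(out) <- NULL
  out
}

#' @rdname as_long_table
#' @param long long-format data frame.
#' @param regions the `region_set` governing column order.
#' @export
as_wide_table <- function(long, regions) {
  assert_region_set(regions)
  miss <- setdiff(regions$name, unique(long$region))
  if (length(miss)) stop("long table lacks region(s): ", paste(miss, collapse = ", "))
  meta <- long[!duplicated(long$subject_id), covariate_columns(), drop = FALSE]
  m <- matrix(NA_real_, nrow(meta), nrow(regions),
              dimnames = list(meta$subject_id, regions$name))
  m[cbind(match(long$subject_id, meta$subject_id),
          match(long$region, regions$name))] <- long$value
  rownames(meta) <- NULL
  new_subject_table(cbind(meta, as.data.frame(m, check.names = FALSE)), regions)
}

#' Serialize normative (or adapted) parameters to versioned JSON
#'
#' @param params a `normative_params` or `adapted_params` object.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
params_to_json <- function(params, path) {
  doc <- list(
    format = "normdev-params", version = 1L,
    adapted = inherits(params, "adapted_params"),
    spec = unclass(params$spec),
    site_levels = params$site_levels,
    age_basis = params$age_basis,
    coef_names = params$coef_names,
    regions = as.data.frame(params$regions),
    fits = lapply(params$fits, function(f) {
      list(beta = as.list(f$beta), sigma = as.list(f$sigma),
           per_site = f$per_site, warp = as.list(f$warp),
           loglik = f$loglik, loglik_trace = f$loglik_trace,
           n = f$n, converged = f$converged)
    })
  )
  if (doc$adapted) {
    doc$estimator <- params$estimator
    doc$adaptation <- params$adaptation
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname params_to_json
#' @export
params_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  if (!identical(doc$format, "normdev-params")) stop("not a normdev params file")
  regions <- doc$regions
  class(regions) <- c("region_set", "data.frame")
  fits <- lapply(doc$fits, function(f) {
    list(beta = unlist(f$beta), sigma = unlist(f$sigma),
         per_site = f$per_site, warp = unlist(f$warp),
         loglik_trace = f$loglik_trace, loglik = f$loglik,
         n = f$n, converged = f$converged)
  })
  spec <- doc$spec
  class(spec) <- "model_spec"
  ab <- doc$age_basis
  out <- list(spec = spec, regions = regions, site_levels = doc$site_levels,
              age_basis = ab, coef_names = doc$coef_names, fits = fits)
  if (isTRUE(doc$adapted)) {
    out$adaptation <- lapply(doc$adaptation, function(a) {
      list(shift = a$shift, scale = a$scale, n = a$n)
    })
    out$estimator <- doc$estimator
    class(out) <- c("adapted_params", "normative_params")
  } else {
    class(out) <- "normative_params"
  }
  out
}

#' Write / read a deviation table as wide CSV
#'
#' Covariate columns first, then one z-score column per region.
#'
#' @param dev a `deviation_table`.
#' @param path CSV path.
#' @return `path` (write) or a `deviation_table` (read).
#' @export
write_deviation_csv <- function(dev, path) {
  stopifnot(inherits(dev, "deviation_table"))
  df <- cbind(dev$meta, as.data.frame(dev$z, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_deviation_csv
#' @param regions the `region_set` of the z columns.
#' @export
read_deviation_csv <- function(path, regions) {
  assert_region_set(regions)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(regions$name, names(df))
  if (length(miss)) stop("deviation CSV lacks region(s): ", paste(miss, collapse = ", "))
  z <- as.matrix(df[, regions$name, drop = FALSE])
  rownames(z) <- df$subject_id
  structure(list(z = z, meta = df[, covariate_columns(), drop = FALSE],
                 regions = regions),
            class = "deviation_table")
}
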