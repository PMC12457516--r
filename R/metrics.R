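#' Binarize deviation z-scores into an outlier matrix
#'
#' An outlier is a region whose deviation z-score falls strictly below the
#' threshold (default -1.96, the 2.5th percentile of the standard normal),
#' i.e. marked atrophy relative to the normative expectation. `z == tau`
#' exactly is not an outlier. By default only negative deviations count;
#' `two_sided = TRUE` additionally flags `z > |tau|`.
#'
#' @param dev a `deviation_table`.
#' @param tau z threshold, finite; default -1.96.
#' @param two_sided also flag positive deviations beyond `|tau|`.
#' @return An `outlier_matrix`: list with binary `x` (subjects x regions),
#'   `tau`, `two_sided`, `meta`, `regions`.
#' @export
binarize_outliers <- function(dev, tau = -1.96, two_sided = FALSE) {
  stopifnot(inherits(dev, "deviation_table"))
  if (!is.finite(tau)) stop("tau must be finite")
  bad <- which(!is.finite(dev$z), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-finite z-score at subject ", rownames(dev$z)[bad[1, 1]],
         ", region ", colnames(dev$z)[bad[1, 2]])
  }
  x <- (dev$z < tau) * 1L
  if (two_sided) x <- pmax(x, (dev$z > abs(tau)) * 1L)
  structure(list(x = x, tau = tau, two_sided = two_sided,
                 meta = dev$meta, regions = dev$regions),
            class = "outlier_matrix")
}

#' @export
print.outlier_matrix <- function(x, ...) {
  cat("Outlier matrix: ", nrow(x$x), " subjects x ", ncol(x$x),
      " regions; tau = ", x$tau,
      if (x$two_sided) " (two-sided)" else " (atrophy only)", "\n", sep = "")
  invisible(x)
}

kind_columns <- function(out, kind) {
  cols <- region_names_of_kind(out$regions, kind)
  cols <- intersect(cols, colnames(out$x))
  if (!length(cols)) stop("no regions of kind '", kind, "' in the matrix")
  cols
}

group_rows <- function(out, group) {
  ix <- which(out$meta$diagnosis == group)
  if (!length(ix)) stop("empty group: ", group)
  ix
}

#' Total outlier count (tOC) per subject
#'
#' Row sum of the binary outlier matrix over one region kind; ranges 0..148
#' for the default cortical set and 0..19 for the default subcortical set.
#' Cortical and subcortical counts are never pooled.
#'
#' @param out an `outlier_matrix`.
#' @param kind `"cortical"` or `"subcortical"` (or `"all"` for non-atlas
#'   simulations).
#' @return Named integer vector, one count per subject.
#' @export
total_outlier_count <- function(out, kind = c("cortical", "subcortical", "all")) {
  stopifnot(inherits(out, "outlier_matrix"))
  kind <- match.arg(kind)
  cols <- kind_columns(out, kind)
  toc <- as.integer(rowSums(out$x[, cols, drop = FALSE]))
  names(toc) <- out$meta$subject_id
  toc
}

#' Pairwise Hamming distances within a diagnostic group
#'
#' `d(i, j)` counts the regions at which two subjects' binary outlier
#' vectors differ — the within-group dissimilarity metric. Computed within
#' one region kind only. Uses the identity
#' `d(i, j) = tOC_i + tOC_j - 2 * (shared outlier regions)`.
#'
#' @param out an `outlier_matrix`.
#' @param group diagnosis label; the group must have >= 2 subjects.
#' @param kind region kind as in [total_outlier_count()].
#' @return Symmetric integer matrix with zero diagonal, subject IDs as
#'   dimnames.
#' @export
hamming_matrix <- function(out, group, kind = c("cortical", "subcortical", "all")) {
  stopifnot(inherits(out, "outlier_matrix"))
  kind <- match.arg(kind)
  ix <- group_rows(out, group)
  if (length(ix) < 2L) stop("group '", group, "' has a single subject; no pairs")
  m <- out$x[ix, kind_columns(out, kind), drop = FALSE]
  toc <- rowSums(m)
  shared <- m %*% t(m)
  d <- outer(toc, toc, `+`) - 2 * shared
  storage.mode(d) <- "integer"
  dimnames(d) <- list(out$meta$subject_id[ix], out$meta$subject_id[ix])
  d
}

#' Per-subject median Hamming distance to same-group peers
#'
#' Each subject's heterogeneity score is the median of its Hamming distances
#' to every other subject of the same group (self excluded; even counts use
#' the midpoint convention).
#'
#' @param dists a pairwise distance matrix from [hamming_matrix()].
#' @return Named numeric vector of per-subject medians.
#' @export
median_hamming_per_subject <- function(dists) {
  if (!is.matrix(dists) || nrow(dists) != ncol(dists)) {
    stop("expected a square distance matrix")
  }
  if (nrow(dists) < 2L) stop("singleton group; no pairs")
  vapply(seq_len(nrow(dists)),
         function(i) stats::median(dists[i, -i]), numeric(1)) |>
    stats::setNames(rownames(dists))
}

#' Per-region outlier proportions within a group
#'
#' Fraction of group members flagged as outliers in each region; the basis of
#' the group-level proportion maps.
#'
#' @param out an `outlier_matrix`.
#' @param group diagnosis label (>= 1 subject).
#' @param kind region kind.
#' @return Data frame with columns `region`, `proportion`, `n_outliers`, `n`.
#' @export
outlier_proportions <- function(out, group, kind = c("cortical", "subcortical", "all")) {
  stopifnot(inherits(out, "outlier_matrix"))
  kind <- match.arg(kind)
  ix <- group_rows(out, group)
  m <- out$x[ix, kind_columns(out, kind), drop = FALSE]
  data.frame(region = colnames(m),
             proportion = unname(colMeans(m)),
             n_outliers = unname(colSums(m)),
             n = length(ix),
             stringsAsFactors = FALSE)
}

#' Per-subject heterogeneity summary across all groups
#'
#' Convenience table combining the individual markers: cortical and
#' subcortical tOC and, for subjects whose group has at least two members,
#' the per-subject median Hamming distance to same-group peers. With
#' `pooled = TRUE` the per-group pooled set of pairwise distances is returned
#' instead (long format), for the alternative reading of group-level
#' Hamming-distance comparisons.
#'
#' @param out an `outlier_matrix`.
#' @param pooled return pooled pairwise distances per group instead of
#'   per-subject medians.
#' @return With `pooled = FALSE` (default): data frame with one row per
#'   subject (`subject_id`, `diagnosis`, `severity`, `tOC_cortical`,
#'   `tOC_subcortical`, `medianHamming_cortical`, `medianHamming_subcortical`).
#'   With `pooled = TRUE`: data frame of pairwise distances (`diagnosis`,
#'   `kind`, `i`, `j`, `distance`).
#' @export
heterogeneity_summary <- function(out, pooled = FALSE) {
  stopifnot(inherits(out, "outlier_matrix"))
  kinds <- intersect(c("cortical", "subcortical"),
                     c("cortical", "subcortical")[c(
                       any(out$regions$kind == "cortical-thickness"),
                       any(out$regions$kind == "subcortical-volume"))])
  if (!length(kinds)) kinds <- "all"
  groups <- unique(out$meta$diagnosis)
  if (pooled) {
    rows <- list()
    for (g in groups) {
      if (sum(out$meta$diagnosis == g) < 2L) next
      for (k in kinds) {
        d <- hamming_matrix(out, g, k)
        ut <- which(upper.tri(d), arr.ind = TRUE)
        rows[[paste(g, k)]] <- data.frame(
          diagnosis = g, kind = k,
          i = rownames(d)[ut[, 1]], j = colnames(d)[ut[, 2]],
          distance = d[ut], stringsAsFactors = FALSE)
      }
    }
    return(do.call(rbind, c(rows, list(make.row.names = FALSE))))
  }
  res <- out$meta[, c("subject_id", "diagnosis", "severity"), drop = FALSE]
  for (k in kinds) {
    res[[paste0("tOC_", k)]] <- unname(total_outlier_count(out, k))
    med <- rep(NA_real_, nrow(res))
    for (g in groups) {
      ix <- which(out$meta$diagnosis == g)
      if (length(ix) < 2L) next
      med[ix] <- unname(median_hamming_per_subject(hamming_matrix(out, g, k)))
    }
    res[[paste0("medianHamming_", k)]] <- med
  }
  rownames(res) <- NULL
  res
}
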