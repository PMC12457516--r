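#' Pipeline configuration
#'
#' Everything [run_pipeline()] needs: the input cohorts (in-memory tables, or
#' file paths to FreeSurfer-style tables plus a covariate CSV, or a synthetic
#' simulation block), the model spec, the outlier threshold, the adaptation
#' split, severity handling, adjustment methods, and the output directory.
#'
#' @param reference,target either `subject_table`s, or lists
#'   `list(features = <tsv path(s)>, covariates = <csv path>)`; ignored when
#'   `simulate` is given.
#' @param simulate optional list of arguments to [simulate_study_cohort()]
#'   (e.g. `list(seed = 1)`); replaces `reference`/`target`.
#' @param regions `region_set` used to validate file inputs.
#' @param model a [model_spec()].
#' @param tau outlier threshold (must be < 0 in the default one-sided mode).
#' @param two_sided flag positive deviations too.
#' @param adaptation_fraction fraction of local controls used for transfer
#'   adaptation.
#' @param seed master seed for the split (and the simulation, if any).
#' @param control_label diagnosis label of healthy controls.
#' @param scale_map group-to-severity-scale map for [severity_stratify()].
#' @param dunn_adjust adjustment for Dunn post hocs.
#' @param out_dir output directory (created); `NULL` for no files.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(reference = NULL, target = NULL, simulate = NULL,
                            regions = default_region_set(),
                            model = model_spec(),
                            tau = -1.96, two_sided = FALSE,
                            adaptation_fraction = 0.8,
                            seed = 1L,
                            control_label = "CN",
                            scale_map = c(PSP = "CDR", CBS = "CDR",
                                          bvFTD = "CDR-plus-NACC-FTLD",
                                          svPPA = "CDR-plus-NACC-FTLD",
                                          nfvPPA = "CDR-plus-NACC-FTLD"),
                            dunn_adjust = "bonferroni",
                            out_dir = NULL) {
  if (!two_sided && tau >= 0) stop("tau must be < 0 in one-sided mode")
  if (is.null(simulate) && (is.null(reference) || is.null(target))) {
    stop("provide reference and target inputs, or a simulate block")
  }
  structure(list(reference = reference, target = target, simulate = simulate,
                 regions = regions, model = model, tau = tau,
                 two_sided = two_sided,
                 adaptation_fraction = adaptation_fraction,
                 seed = as.integer(seed), control_label = control_label,
                 scale_map = scale_map, dunn_adjust = dunn_adjust,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' File-based front end for [pipeline_config()]: top-level keys mirror its
#' arguments; `reference`/`target` are `features`/`covariates` path blocks,
#' `model` is a [model_spec()] argument block, `simulate` a
#' [simulate_study_cohort()] argument block.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  model <- do.call(model_spec, if (is.null(y$model)) list() else y$model)
  args <- y[setdiff(names(y), "model")]
  if (!is.null(args$scale_map)) args$scale_map <- unlist(args$scale_map)
  do.call(pipeline_config, c(args, list(model = model)))
}

resolve_input <- function(input, regions, what) {
  if (inherits(input, "subject_table")) return(input)
  if (!is.list(input) || is.null(input$features) || is.null(input$covariates)) {
    stop(what, " input must be a subject_table or list(features=, covariates=)")
  }
  frags <- lapply(input$features, read_freesurfer_table, regions = regions)
  feats <- frags[[1]]
  for (f in frags[-1]) {
    if (!identical(f$subject_id, feats$subject_id)) {
      stop("feature tables for ", what, " disagree on subjects")
    }
    reg2 <- rbind(attr(feats, "regions"), attr(f, "regions"))
    class(reg2) <- c("region_set", "data.frame")
    feats <- cbind(feats, f[, -1, drop = FALSE])
    attr(feats, "regions") <- reg2
  }
  merge_covariates(feats, input$covariates)
}

write_stage <- function(obj, path, writer) {
  writer(obj, path)
  path
}

#' Run the full deviation-analysis pipeline
#'
#' Executes split -> fit -> adapt -> z-score -> binarize -> tOC / Hamming /
#' proportions -> group statistics -> severity statistics on the configured
#' cohorts, writes every module output plus a run manifest to the output
#' directory (when one is set), and returns all results in memory. The whole
#' bundle is a pure function of (inputs, config, seed): rerunning with the
#' same configuration gives identical files and checksums.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the fitted objects, result tables, and the
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings_log <- character(0)
  note <- function(...) {
    warnings_log <<- c(warnings_log, paste0(...))
  }
  stage <- "inputs"
  result <- tryCatch({
    if (!is.null(config$simulate)) {
      sim <- do.call(simulate_study_cohort,
                     c(config$simulate,
                       if (is.null(config$simulate$seed)) list(seed = config$seed)))
      reference <- sim$reference
      controls <- sim$controls
      clinical <- sim$clinical
      regions <- sim$regions
      config$control_label <- "CN"
    } else {
      reference <- resolve_input(config$reference, config$regions, "reference")
      target <- resolve_input(config$target, config$regions, "target")
      jr <- attr(target, "join_report")
      if (!is.null(jr)) {
        for (s in jr$unmatched_features) note("excluded (failed join, no covariates): ", s)
        for (s in jr$unmatched_covariates) note("excluded (failed join, no features): ", s)
      }
      is_ctl <- target$diagnosis == config$control_label
      controls <- new_subject_table(target[is_ctl, , drop = FALSE],
                                    attr(target, "regions"))
      clinical <- new_subject_table(target[!is_ctl, , drop = FALSE],
                                    attr(target, "regions"))
      regions <- attr(target, "regions")
    }

    stage <- "split"
    sp <- split_adaptation_test(controls, config$adaptation_fraction, config$seed)

    stage <- "fit"
    params <- fit_normative(reference, config$model)

    stage <- "adapt"
    adapted <- adapt_to_site(params, sp$adaptation)

    stage <- "zscore"
    test <- bind_subject_tables(sp$test, clinical)
    dev <- compute_zscores(adapted, test)

    stage <- "metrics"
    out <- binarize_outliers(dev, tau = config$tau, two_sided = config$two_sided)
    metrics <- heterogeneity_summary(out)
    groups <- unique(out$meta$diagnosis)
    clin_groups <- setdiff(groups, config$control_label)
    kinds <- intersect(c("cortical", "subcortical"),
                       sub("^tOC_", "", grep("^tOC_", names(metrics), value = TRUE)))
    proportions <- list()
    for (g in groups) for (k in kinds) {
      proportions[[paste(g, k, sep = ".")]] <-
        cbind(group = g, kind = k, outlier_proportions(out, g, k))
    }
    proportions <- do.call(rbind, c(proportions, list(make.row.names = FALSE)))

    stage <- "group-stats"
    group_stats <- list()
    dunn <- list()
    for (k in kinds) for (mk in paste0(c("tOC_", "medianHamming_"), k)) {
      by_group <- split(metrics[[mk]][!is.na(metrics[[mk]])],
                        metrics$diagnosis[!is.na(metrics[[mk]])])
      by_group <- by_group[lengths(by_group) > 0]
      if (length(by_group) >= 2) {
        group_stats[[mk]] <- kruskal_wallis(by_group)
        dunn[[mk]] <- cbind(marker = mk,
                            dunn_posthoc(by_group, config$dunn_adjust))
      }
    }
    dunn <- do.call(rbind, c(dunn, list(make.row.names = FALSE)))
    region_tests <- list()
    for (g in clin_groups) for (k in kinds) {
      if (sum(out$meta$diagnosis == g) < 2) next
      region_tests[[paste(g, k, sep = ".")]] <-
        cbind(group = g, kind = k,
              region_count_tests(out, c(g, config$control_label), k))
    }
    region_tests <- do.call(rbind, c(region_tests, list(make.row.names = FALSE)))

    stage <- "severity-stats"
    clin_meta <- out$meta[out$meta$diagnosis %in% names(config$scale_map), ,
                          drop = FALSE]
    strat <- severity_stratify(clin_meta, scale_map = config$scale_map)
    for (i in which(strat$stratum == "excluded")) {
      note("excluded from severity analysis (", strat$reason[i], "): ",
           strat$subject_id[i])
    }
    severity_stats <- list()
    for (mk in intersect(names(metrics),
                         as.vector(outer(c("tOC_", "medianHamming_"), kinds,
                                         paste0)))) {
      cmp <- severity_comparisons(metrics, strat, mk)
      for (g in attr(cmp, "skipped")) {
        note("severity comparison not estimable for ", g, " on ", mk)
      }
      if (length(cmp)) {
        severity_stats[[mk]] <- cbind(marker = mk, stat_table(cmp))
      }
    }
    severity_stats <- do.call(rbind, c(severity_stats, list(make.row.names = FALSE)))

    list(params = params, adapted = adapted, deviations = dev, outliers = out,
         metrics = metrics, proportions = proportions,
         group_stats = group_stats, dunn = dunn, region_tests = region_tests,
         severity_strata = strat, severity_stats = severity_stats,
         split = sp, regions = regions)
  }, error = function(e) {
    if (!is.null(config$out_dir) && dir.exists(config$out_dir)) {
      unlink(list.files(config$out_dir, full.names = TRUE))
    }
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  files <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    files <- c(
      write_stage(result$params, p("normative_params.json"), params_to_json),
      write_stage(result$adapted, p("adapted_params.json"), params_to_json),
      write_stage(result$deviations, p("deviations.csv"), write_deviation_csv))
    utils::write.csv(result$metrics, p("subject_metrics.csv"), row.names = FALSE)
    utils::write.csv(result$proportions, p("outlier_proportions.csv"),
                     row.names = FALSE)
    if (length(result$group_stats)) {
      utils::write.csv(stat_table(result$group_stats), p("group_stats.csv"),
                       row.names = FALSE)
    }
    if (!is.null(result$dunn)) {
      utils::write.csv(result$dunn, p("dunn_posthoc.csv"), row.names = FALSE)
    }
    if (!is.null(result$region_tests)) {
      utils::write.csv(result$region_tests, p("region_tests.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(result$severity_strata, p("severity_strata.csv"),
                     row.names = FALSE)
    if (!is.null(result$severity_stats)) {
      utils::write.csv(result$severity_stats, p("severity_stats.csv"),
                       row.names = FALSE)
    }
    files <- c(files, p(c("subject_metrics.csv", "outlier_proportions.csv",
                          "group_stats.csv", "dunn_posthoc.csv",
                          "region_tests.csv", "severity_strata.csv",
                          "severity_stats.csv")))
    files <- files[file.exists(files)]
  }

  # hash the analytic settings only (input objects and output paths excluded)
  cfg_desc <- utils::capture.output(utils::str(
    config[setdiff(names(config), c("reference", "target", "out_dir"))]))
  manifest <- list(
    package = "normdev",
    version = as.character(utils::packageVersion("normdev")),
    config_hash = digest_string(paste(cfg_desc, collapse = "\n")),
    seed = config$seed,
    stage_counts = list(
      reference = result$params$fits[[1]]$n,
      adaptation = result$adapted$adaptation[[1]]$n,
      test = nrow(result$deviations$z),
      regions = ncol(result$deviations$z)),
    exclusions = warnings_log,
    files = if (length(files)) {
      data.frame(file = basename(files),
                 md5 = unname(tools::md5sum(files)),
                 stringsAsFactors = FALSE)
    } else data.frame(file = character(0), md5 = character(0))
  )
  if (!is.null(config$out_dir)) {
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result$manifest <- manifest
  invisible(result)
}

# md5 of a string via a temp file (tools::md5sum is file-based)
digest_string <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}
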