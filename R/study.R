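#' Default atrophy signatures of the five FTLD clinical groups
#'
#' Desk-scale emulation of the variant-specific patterns reported for
#' frontotemporal lobar degeneration cohorts, on the default 148 + 19 region
#' set. Group sizes follow the published testing cohort (bvFTD 22, nfvPPA 14,
#' svPPA 21, CBS 43, PSP 45):
#' \itemize{
#'   \item bvFTD — bilateral frontal/anterior-cingulate signature, low
#'     involvement probability (the most heterogeneous group), deep atrophy.
#'   \item svPPA — focal left anterior-temporal signature including amygdala
#'     and hippocampus, high involvement probability (homogeneous, severe).
#'   \item nfvPPA — left inferior-frontal/precentral signature, mid
#'     involvement.
#'   \item CBS — asymmetric peri-rolandic/parietal signature, low involvement
#'     (heterogeneous), moderate depth.
#'   \item PSP — predominantly subcortical signature (brainstem, pallidum,
#'     thalamus, ventral diencephalon) plus medial frontal cortex.
#' }
#'
#' @return Named list of [group_signature()] objects.
#' @export
study_signatures <- function() {
  list(
    bvFTD = group_signature(
      "bvFTD",
      regions = c(paste0("lh_", c("G_front_middle", "G_front_sup",
                                  "G_front_inf-Orbital", "G_orbital",
                                  "G_and_S_cingul-Ant", "G_rectus",
                                  "G_insular_short", "S_orbital-H_Shaped")),
                  paste0("rh_", c("G_front_middle", "G_front_sup",
                                  "G_front_inf-Orbital", "G_orbital",
                                  "G_and_S_cingul-Ant", "G_rectus",
                                  "G_insular_short", "S_orbital-H_Shaped")),
                  "Left-Accumbens-area", "Right-Accumbens-area"),
      n_subjects = 22, depth = -3.5, involvement_prob = 0.45, off_rate = 0.03,
      severity_probs = c("0.5" = 0.15, "1" = 0.45, "1.5" = 0.15, "2" = 0.25)),
    svPPA = group_signature(
      "svPPA",
      regions = c(paste0("lh_", c("Pole_temporal", "G_temporal_inf",
                                  "G_temporal_middle", "G_oc-temp_med-Parahip",
                                  "G_temp_sup-Lateral", "S_temporal_inf",
                                  "G_oc-temp_lat-fusifor")),
                  "rh_Pole_temporal",
                  "Left-Amygdala", "Left-Hippocampus", "Left-Accumbens-area",
                  "Right-Amygdala"),
      n_subjects = 21, depth = -4.5, involvement_prob = 0.9, off_rate = 0.02,
      severity_probs = c("0.5" = 0.35, "1" = 0.4, "1.5" = 0.1, "2" = 0.15)),
    nfvPPA = group_signature(
      "nfvPPA",
      regions = c(paste0("lh_", c("G_front_inf-Opercular", "G_front_inf-Triangul",
                                  "G_front_inf-Orbital", "S_precentral-inf-part",
                                  "G_precentral", "S_circular_insula_ant"))),
      n_subjects = 14, depth = -3, involvement_prob = 0.65, off_rate = 0.02,
      severity_probs = c("0.5" = 0.3, "1" = 0.55, "1.5" = 0.15)),
    CBS = group_signature(
      "CBS",
      regions = c(paste0("lh_", c("G_precentral", "G_postcentral",
                                  "G_parietal_sup", "S_central",
                                  "G_and_S_paracentral")),
                  paste0("rh_", c("G_precentral", "G_postcentral",
                                  "G_parietal_sup", "S_central")),
                  "Left-Putamen", "Right-Putamen"),
      n_subjects = 43, depth = -2.5, involvement_prob = 0.45, off_rate = 0.03,
      severity_probs = c("0" = 0.15, "0.5" = 0.45, "1" = 0.25, "2" = 0.15)),
    PSP = group_signature(
      "PSP",
      regions = c("Brain-Stem", "Left-Pallidum", "Right-Pallidum",
                  "Left-Thalamus-Proper", "Right-Thalamus-Proper",
                  "Left-VentralDC", "Right-VentralDC",
                  "Left-Cerebellum-Cortex", "Right-Cerebellum-Cortex",
                  "lh_G_front_sup", "rh_G_front_sup",
                  "lh_G_and_S_cingul-Mid-Ant", "rh_G_and_S_cingul-Mid-Ant"),
      n_subjects = 45, depth = -3, involvement_prob = 0.7, off_rate = 0.03,
      severity_probs = c("0" = 0.1, "0.5" = 0.45, "1" = 0.3, "2" = 0.15))
  )
}

#' Simulate the full multi-site study structure
#'
#' One call producing the three cohorts the pipeline consumes, with the data
#' structure the analysis assumes: a large multi-site healthy reference set
#' (distinct sites and site effects), a local control set from held-out
#' target sites (to be split 80/20 into adaptation and test), and the five
#' clinical groups from the same target sites with group-specific signatures
#' from [study_signatures()].
#'
#' @param seed master seed.
#' @param n_reference_per_site reference subjects per reference site.
#' @param reference_sites number of reference sites.
#' @param n_controls local healthy controls on the target sites.
#' @param regions region set; default the full 148 + 19 atlas set.
#' @param signatures list of [group_signature()]s; default [study_signatures()].
#' @return List with `subject_table`s `reference`, `controls`, `clinical`,
#'   plus the `regions` and the two `cohort_config`s used.
#' @export
simulate_study_cohort <- function(seed = 1L,
                                  n_reference_per_site = 250,
                                  reference_sites = 4,
                                  n_controls = 63,
                                  regions = default_region_set(),
                                  signatures = study_signatures()) {
  ref_sites <- stats::setNames(rep(n_reference_per_site, reference_sites),
                               paste0("ref", seq_len(reference_sites)))
  # deterministic mild site effects so multi-site structure is real
  ref_offsets <- stats::setNames(
    0.05 * ((seq_len(reference_sites) - (reference_sites + 1) / 2)),
    names(ref_sites))
  ref_config <- cohort_config(
    n_per_site = ref_sites, site_offset = ref_offsets,
    site_scale = stats::setNames(1 + 0.05 * (seq_len(reference_sites) %% 2),
                                 names(ref_sites)),
    seed = child_seed(seed, "study-reference"))
  reference <- generate_reference_cohort(ref_config, regions)

  tgt_sites <- c(target1 = ceiling(n_controls / 2),
                 target2 = floor(n_controls / 2))
  tgt_config <- cohort_config(
    n_per_site = tgt_sites,
    site_offset = c(target1 = 0.08, target2 = -0.04),
    site_scale = c(target1 = 1.1, target2 = 0.95),
    seed = child_seed(seed, "study-target"))
  controls <- generate_reference_cohort(tgt_config, regions, stage = "controls")
  clinical <- generate_clinical_cohort(tgt_config, signatures, regions)

  list(reference = reference, controls = controls, clinical = clinical,
       regions = regions, reference_config = ref_config,
       target_config = tgt_config)
}

#' Stack subject tables that share a region set
#'
#' @param ... `subject_table`s with identical region sets.
#' @return A `subject_table`.
#' @export
bind_subject_tables <- function(...) {
  tabs <- list(...)
  regions <- attr(tabs[[1]], "regions")
  for (t in tabs[-1]) {
    if (!identical(attr(t, "regions")$name, regions$name)) {
      stop("region sets differ between tables")
    }
  }
  new_subject_table(do.call(rbind, lapply(tabs, as.data.frame)), regions)
}
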