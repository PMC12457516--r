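#' Region sets for cortical thickness and subcortical volume analyses
#'
#' A region set is an ordered table of region identifiers with, per region,
#' the measure kind (`"cortical-thickness"` or `"subcortical-volume"`) and a
#' hemisphere tag (`"left"`, `"right"` or `"midline"`). Region order is stable
#' and is inherited by every table derived from the set (feature tables,
#' deviation tables, outlier matrices), so column order never has to be
#' re-negotiated downstream.
#'
#' @param name character vector of unique region identifiers.
#' @param kind per-region measure kind, recycled if length 1; one of
#'   `"cortical-thickness"`, `"subcortical-volume"`.
#' @param hemisphere per-region tag, recycled if length 1; one of `"left"`,
#'   `"right"`, `"midline"`.
#' @return A `region_set`: a data frame with columns `name`, `kind`,
#'   `hemisphere`.
#' @examples
#' region_set(c("lh_A", "rh_A"), "cortical-thickness", c("left", "right"))
#' @export
region_set <- function(name, kind, hemisphere) {
  name <- as.character(name)
  if (anyDuplicated(name) > 0L) {
    stop("region names must be unique; duplicated: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  kind <- rep_len(match.arg(kind, c("cortical-thickness", "subcortical-volume"),
                            several.ok = TRUE), length(name))
  hemisphere <- rep_len(match.arg(hemisphere, c("left", "right", "midline"),
                                  several.ok = TRUE), length(name))
  out <- data.frame(name = name, kind = kind, hemisphere = hemisphere,
                    stringsAsFactors = FALSE)
  class(out) <- c("region_set", "data.frame")
  out
}

# The 74 Destrieux (aparc.a2009s) parcel labels of one hemisphere, in
# FreeSurfer's canonical order.
destrieux_base_labels <- function() {
  c("G_and_S_frontomargin", "G_and_S_occipital_inf", "G_and_S_paracentral",
    "G_and_S_subcentral", "G_and_S_transv_frontopol", "G_and_S_cingul-Ant",
    "G_and_S_cingul-Mid-Ant", "G_and_S_cingul-Mid-Post",
    "G_cingul-Post-dorsal", "G_cingul-Post-ventral", "G_cuneus",
    "G_front_inf-Opercular", "G_front_inf-Orbital", "G_front_inf-Triangul",
    "G_front_middle", "G_front_sup", "G_Ins_lg_and_S_cent_ins",
    "G_insular_short", "G_occipital_middle", "G_occipital_sup",
    "G_oc-temp_lat-fusifor", "G_oc-temp_med-Lingual", "G_oc-temp_med-Parahip",
    "G_orbital", "G_pariet_inf-Angular", "G_pariet_inf-Supramar",
    "G_parietal_sup", "G_postcentral", "G_precentral", "G_precuneus",
    "G_rectus", "G_subcallosal", "G_temp_sup-G_T_transv",
    "G_temp_sup-Lateral", "G_temp_sup-Plan_polar", "G_temp_sup-Plan_tempo",
    "G_temporal_inf", "G_temporal_middle", "Lat_Fis-ant-Horizont",
    "Lat_Fis-ant-Vertical", "Lat_Fis-post", "Pole_occipital",
    "Pole_temporal", "S_calcarine", "S_central", "S_cingul-Marginalis",
    "S_circular_insula_ant", "S_circular_insula_inf", "S_circular_insula_sup",
    "S_collat_transv_ant", "S_collat_transv_post", "S_front_inf",
    "S_front_middle", "S_front_sup", "S_interm_prim-Jensen",
    "S_intrapariet_and_P_trans", "S_oc_middle_and_Lunatus",
    "S_oc_sup_and_transversal", "S_occipital_ant", "S_oc-temp_lat",
    "S_oc-temp_med_and_Lingual", "S_orbital_lateral", "S_orbital_med-olfact",
    "S_orbital-H_Shaped", "S_parieto_occipital", "S_pericallosal",
    "S_postcentral", "S_precentral-inf-part", "S_precentral-sup-part",
    "S_suborbital", "S_subparietal", "S_temporal_inf", "S_temporal_sup",
    "S_temporal_transverse")
}

#' Default Destrieux cortical-thickness region set (148 regions)
#'
#' The 74 Destrieux atlas parcels per hemisphere, prefixed `lh_` / `rh_` as in
#' FreeSurfer's `aparcstats2table --parc aparc.a2009s` output.
#'
#' @return A `region_set` of 148 cortical-thickness regions (74 left followed
#'   by 74 right).
#' @export
destrieux_regions <- function() {
  base <- destrieux_base_labels()
  region_set(c(paste0("lh_", base), paste0("rh_", base)),
             kind = "cortical-thickness",
             hemisphere = rep(c("left", "right"), each = length(base)))
}

#' Default subcortical volume region set (19 regions)
#'
#' Nine bilateral structures (cerebellar cortex, thalamus, caudate, putamen,
#' pallidum, hippocampus, amygdala, accumbens, ventral diencephalon) plus the
#' brainstem, named as in FreeSurfer's `asegstats2table` output.
#'
#' @return A `region_set` of 19 subcortical-volume regions.
#' @export
aseg_regions <- function() {
  bilateral <- c("Cerebellum-Cortex", "Thalamus-Proper", "Caudate", "Putamen",
                 "Pallidum", "Hippocampus", "Amygdala", "Accumbens-area",
                 "VentralDC")
  region_set(c(paste0("Left-", bilateral), paste0("Right-", bilateral),
               "Brain-Stem"),
             kind = "subcortical-volume",
             hemisphere = c(rep("left", 9L), rep("right", 9L), "midline"))
}

#' Default full region set: 148 cortical + 19 subcortical regions
#'
#' @return A `region_set` of 167 regions, cortical first.
#' @export
default_region_set <- function() {
  out <- rbind(destrieux_regions(), aseg_regions())
  class(out) <- c("region_set", "data.frame")
  out
}

#' Generic labelled region set for simulations
#'
#' Convenience constructor of `n` regions named `region_01`, ... used by
#' desk-scale simulations where atlas names are irrelevant.
#'
#' @param n number of regions.
#' @param kind measure kind for all regions.
#' @return A `region_set` of `n` regions.
#' @export
toy_region_set <- function(n, kind = "cortical-thickness") {
  region_set(sprintf("region_%02d", seq_len(n)), kind = kind,
             hemisphere = "midline")
}

#' @export
print.region_set <- function(x, ...) {
  cat("Region set: ", nrow(x), " regions (",
      sum(x$kind == "cortical-thickness"), " cortical-thickness, ",
      sum(x$kind == "subcortical-volume"), " subcortical-volume)\n", sep = "")
  invisible(x)
}

region_names_of_kind <- function(regions, kind = c("cortical", "subcortical", "all")) {
  kind <- match.arg(kind)
  if (kind == "all") return(regions$name)
  want <- if (kind == "cortical") "cortical-thickness" else "subcortical-volume"
  regions$name[regions$kind == want]
}

assert_region_set <- function(regions) {
  if (!inherits(regions, "region_set")) {
    stop("expected a region_set; see region_set()")
  }
  invisible(regions)
}
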