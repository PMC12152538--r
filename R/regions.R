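#' Default 52-region parcellation
#'
#' Bilateral (left+right merged) region names covering subcortical grey
#' matter, cortical parcels, cerebellum cortex and white matter, brain stem,
#' ventricles and extracerebral CSF, in the style of a whole-brain
#' segmentation merged across hemispheres. The exact composition of any
#' given segmentation pipeline differs in detail; the list is a default and
#' every function accepting volumes takes region names from the data.
#'
#' @return Character vector of 52 region names.
#' @export
default_region_names <- function() {
  c(
    # subcortical grey matter
    "thalamus", "caudate", "putamen", "pallidum", "hippocampus", "amygdala",
    "accumbens area", "ventral DC",
    # white matter, cerebellum, brain stem
    "cerebral white matter", "cerebellum white matter", "cerebellum cortex",
    "brain stem",
    # ventricles and CSF spaces
    "lateral ventricle", "inferior lateral ventricle", "third ventricle",
    "fourth ventricle", "extracerebral CSF", "choroid plexus",
    # cortical parcels (bilateral)
    "superior frontal", "rostral middle frontal", "caudal middle frontal",
    "pars opercularis", "pars triangularis", "pars orbitalis",
    "lateral orbitofrontal", "medial orbitofrontal", "frontal pole",
    "precentral", "paracentral", "postcentral",
    "superior parietal", "inferior parietal", "supramarginal", "precuneus",
    "cuneus", "pericalcarine", "lateral occipital", "lingual",
    "fusiform", "inferior temporal", "middle temporal", "superior temporal",
    "transverse temporal", "temporal pole", "banks superior temporal sulcus",
    "entorhinal", "parahippocampal",
    "insula", "rostral anterior cingulate", "caudal anterior cingulate",
    "posterior cingulate", "isthmus cingulate"
  )
}

#' Region category (lobe/structure class) for each default region
#'
#' Used as the default block structure of the synthetic generator's
#' covariance model and for display grouping.
#'
#' @param regions Character vector of region names
#'   (default [default_region_names()]).
#' @return Named character vector mapping region -> category.
#' @export
region_categories <- function(regions = default_region_names()) {
  cat_map <- c(
    "thalamus" = "subcortical", "caudate" = "subcortical",
    "putamen" = "subcortical", "pallidum" = "subcortical",
    "hippocampus" = "subcortical", "amygdala" = "subcortical",
    "accumbens area" = "subcortical", "ventral DC" = "subcortical",
    "cerebral white matter" = "white matter",
    "cerebellum white matter" = "cerebellum",
    "cerebellum cortex" = "cerebellum",
    "brain stem" = "brain stem",
    "lateral ventricle" = "ventricle-CSF",
    "inferior lateral ventricle" = "ventricle-CSF",
    "third ventricle" = "ventricle-CSF", "fourth ventricle" = "ventricle-CSF",
    "extracerebral CSF" = "ventricle-CSF", "choroid plexus" = "ventricle-CSF",
    "superior frontal" = "frontal", "rostral middle frontal" = "frontal",
    "caudal middle frontal" = "frontal", "pars opercularis" = "frontal",
    "pars triangularis" = "frontal", "pars orbitalis" = "frontal",
    "lateral orbitofrontal" = "frontal", "medial orbitofrontal" = "frontal",
    "frontal pole" = "frontal", "precentral" = "frontal",
    "paracentral" = "frontal", "postcentral" = "parietal",
    "superior parietal" = "parietal", "inferior parietal" = "parietal",
    "supramarginal" = "parietal", "precuneus" = "parietal",
    "cuneus" = "occipital", "pericalcarine" = "occipital",
    "lateral occipital" = "occipital", "lingual" = "occipital",
    "fusiform" = "temporal", "inferior temporal" = "temporal",
    "middle temporal" = "temporal", "superior temporal" = "temporal",
    "transverse temporal" = "temporal", "temporal pole" = "temporal",
    "banks superior temporal sulcus" = "temporal",
    "entorhinal" = "temporal", "parahippocampal" = "temporal",
    "insula" = "cingulate-insula",
    "rostral anterior cingulate" = "cingulate-insula",
    "caudal anterior cingulate" = "cingulate-insula",
    "posterior cingulate" = "cingulate-insula",
    "isthmus cingulate" = "cingulate-insula"
  )
  out <- cat_map[regions]
  out[is.na(out)] <- "other"
  names(out) <- regions
  out
}

#' Subcortical regions used for the image QC gate
#'
#' @param regions Character vector of region names.
#' @return Character vector: regions whose category is "subcortical".
#' @export
subcortical_regions <- function(regions = default_region_names()) {
  regions[region_categories(regions) == "subcortical"]
}

# plausible baseline raw volumes (mm^3) per category; only the relative
# scale matters downstream because volumes are divided by ICV
.base_volume_for <- function(regions) {
  base_by_cat <- c(
    "subcortical" = 8000, "white matter" = 450000, "cerebellum" = 70000,
    "brain stem" = 22000, "ventricle-CSF" = 15000, "frontal" = 20000,
    "parietal" = 18000, "occipital" = 12000, "temporal" = 14000,
    "cingulate-insula" = 9000, "other" = 10000
  )
  unname(base_by_cat[region_categories(regions)])
}
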