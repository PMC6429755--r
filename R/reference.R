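#' Sensorimotor regions of interest
#'
#' The somatosensory-network region panel used throughout the package:
#' primary/secondary somatosensory and motor cortices, insular subdivisions,
#' basal ganglia, and thalamus, with their Destrieux / Harvard-Oxford
#' abbreviations. Centrality features are labelled `X_Y_Z` where `X` is the
#' metric (`S` degree strength, `B` betweenness, `E` eigenvector), `Y` the
#' laterality (`L`/`R`), and `Z` one of these abbreviations.
#'
#' @return A tibble with columns `region_group`, `description`, `abbreviation`.
#' @export
#' @examples
#' roi_table()
roi_table <- function() {
  tibble::tribble(
    ~region_group, ~description, ~abbreviation,
    "Primary somatosensory cortex (S1)", "Postcentral gyrus", "PosCG",
    "Primary somatosensory cortex (S1)", "Postcentral sulcus", "PosCS",
    "Primary somatosensory cortex (S1)", "Central sulcus", "CS",
    "Secondary somatosensory cortex (S2)", "Subcentral gyrus (central operculum) and sulcus", "SbCG_S",
    "Primary motor cortex (M1)", "Precentral gyrus", "PRCG",
    "Primary motor cortex (M1)", "Inferior part of the precentral sulcus", "InfPrCS",
    "Primary motor cortex (M1)", "Superior part of the precentral sulcus", "SupPrCs",
    "Supplementary motor area (M2/SMA)", "Superior frontal gyrus", "SupFG",
    "Supplementary motor area (M2/SMA)", "Superior frontal sulcus", "SupFS",
    "Anterior/middle insula (a/mINS)", "Superior segment of the circular sulcus of the insula", "SupCirInS",
    "Middle/posterior insula (m/pINS)", "Long insular gyrus and central sulcus of the insula", "LoInG_CInS",
    "Middle/posterior insula (m/pINS)", "Inferior segment of the circular sulcus of the insula", "InfCirInS",
    "Posterior insula (pINS)", "Posterior ramus of the lateral sulcus", "PosLS",
    "Basal ganglia", "Putamen", "Pu",
    "Basal ganglia", "Caudate nucleus", "CaN",
    "Basal ganglia", "Nucleus accumbens", "NAcc",
    "Basal ganglia", "Globus pallidus", "Pal",
    "Thalamus", "Thalamus", "Tha"
  )
}

#' Clostridiales genus panel
#'
#' The serotonin-modulating genus panel from the families Ruminococcaceae and
#' Lachnospiraceae (order Clostridiales) used for the microbe block.
#'
#' @return A tibble with columns `family` and `genus`.
#' @export
#' @examples
#' genus_panel()
genus_panel <- function() {
  tibble::tribble(
    ~family, ~genus,
    "Ruminococcaceae", "Clostridium IV",
    "Ruminococcaceae", "Faecalibacterium",
    "Ruminococcaceae", "Oscillibacter",
    "Lachnospiraceae", "Clostridium XIVa",
    "Lachnospiraceae", "Clostridium XIVb",
    "Lachnospiraceae", "Blautia",
    "Lachnospiraceae", "Coprococcus",
    "Lachnospiraceae", "Roseburia",
    "Lachnospiraceae", "Lachnospiracea incertae sedis"
  )
}

#' Reference GI sensorimotor phenotype summaries
#'
#' Group-level means and standard deviations of the gastrointestinal
#' sensorimotor phenotype battery (rectal barostat thresholds and intensity
#' ratings, symptom severity score, nutrient + lactulose challenge AUCs, and
#' oroanal transit time) for healthy controls (n = 21) and IBS patients
#' (n = 65). These summaries parameterise the default phenotype block of
#' [simulation_config()] and are the inputs to the Table-2-style group
#' comparison in [cohort_report()].
#'
#' @return A tibble with columns `variable`, `unit`, `mean_hc`, `sd_hc`,
#'   `mean_ibs`, `sd_ibs`, `n_hc`, `n_ibs`.
#' @export
#' @examples
#' phenotype_reference()
phenotype_reference <- function() {
  out <- tibble::tribble(
    ~variable, ~unit, ~mean_hc, ~sd_hc, ~mean_ibs, ~sd_ibs,
    "Rectal discomfort threshold", "mmHg", 24.4, 7.1, 21.2, 7.8,
    "Rectal pain threshold", "mmHg", 30.5, 10.3, 27.4, 8.8,
    "First rectal sensation", "mmHg", 10.3, 5.1, 9.9, 5.9,
    "IBS-SSS", "score", 26, 31.3, 280, 100,
    "Rectal discomfort intensity", "VAS mm", 49.8, 22.1, 68.7, 25.7,
    "Rectal pain intensity", "VAS mm", 25.4, 31.33, 40.4, 31.5,
    "Lactulose challenge - pain", "AUC", 60.7, 166.4, 1139.4, 1243.07,
    "Lactulose challenge - discomfort", "AUC", 212.5, 227.9, 1911.1, 1062.2,
    "OATT", "days", 1.5, 0.7, 1.6, 1.2
  )
  out$n_hc <- 21L
  out$n_ibs <- 65L
  out
}

#' Compose and parse centrality feature labels
#'
#' Brain features are labelled `X_Y_Z`: metric (`S`, `B`, `E`), laterality
#' (`L`, `R`, or absent for midline structures), region abbreviation.
#'
#' @param metric One of `"S"` (degree strength), `"B"` (betweenness),
#'   `"E"` (eigenvector).
#' @param laterality `"L"`, `"R"`, or `NA` for midline regions.
#' @param region Region abbreviation (see [roi_table()]).
#' @return `centrality_label()`: a character vector of labels.
#' @export
#' @examples
#' centrality_label("S", "L", "Pu")
#' parse_centrality_label("B_R_CaN")
centrality_label <- function(metric, laterality, region) {
  metric <- as.character(metric)
  bad <- !metric %in% c("S", "B", "E")
  if (any(bad)) {
    abort(paste0("unknown centrality metric: ", paste(unique(metric[bad]), collapse = ", ")))
  }
  ifelse(is.na(laterality) | laterality == "",
    paste(metric, region, sep = "_"),
    paste(metric, laterality, region, sep = "_")
  )
}

#' @rdname centrality_label
#' @param label Character vector of `X_Y_Z` labels.
#' @return `parse_centrality_label()`: a tibble with columns `label`,
#'   `metric`, `laterality`, `region`.
#' @export
parse_centrality_label <- function(label) {
  parts <- strsplit(label, "_", fixed = TRUE)
  rows <- lapply(seq_along(label), function(i) {
    p <- parts[[i]]
    if (length(p) < 2L || !p[1] %in% c("S", "B", "E")) {
      abort(paste0("not an X_Y_Z centrality label: '", label[i], "'"))
    }
    if (length(p) >= 3L && p[2] %in% c("L", "R")) {
      tibble(label = label[i], metric = p[1], laterality = p[2],
             region = paste(p[-(1:2)], collapse = "_"))
    } else {
      tibble(label = label[i], metric = p[1], laterality = NA_character_,
             region = paste(p[-1], collapse = "_"))
    }
  })
  list_rbind(rows)
}

#' Default brain feature labels
#'
#' All three centrality metrics, left and right, for a set of region
#' abbreviations (default: the basal ganglia, thalamus, and primary/secondary
#' somatosensory regions of [roi_table()]).
#'
#' @param regions Character vector of region abbreviations.
#' @param metrics Subset of `c("S", "B", "E")`.
#' @return Character vector of `X_Y_Z` labels.
#' @export
default_brain_features <- function(regions = c("Pu", "CaN", "NAcc", "Tha", "PosCG", "SbCG_S"),
                                   metrics = c("S", "B", "E")) {
  grid <- expand.grid(region = regions, laterality = c("L", "R"), metric = metrics,
                      stringsAsFactors = FALSE)
  centrality_label(grid$metric, grid$laterality, grid$region)
}
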