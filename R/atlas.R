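#' Atlas specification
#'
#' An atlas specification lists the parcellation regions used as network
#' nodes together with the reference labels used for SUVR normalization.
#' Analysis regions (`is_reference = FALSE`) define the columns of every
#' [suvr_table()] and the nodes of every group network; reference regions
#' (typically the cerebellar labels) are only used to form the per-subject
#' reference mean when converting raw SUV to SUVR.
#'
#' @param id integer region labels (as found in a label volume); unique.
#' @param name character region names.
#' @param center numeric matrix with one row per region and columns x, y, z
#'   (mm); used only for node-file export.
#' @param is_reference logical flag per region; `TRUE` marks reference
#'   (e.g. cerebellar) labels excluded from analysis.
#'
#' @return An object of class `atlas_spec`: a data frame with columns
#'   `id`, `name`, `x`, `y`, `z`, `is_reference` and an `n_analysis`
#'   attribute giving the number of analysis regions.
#' @seealso [atlas_aal90()]
#' @export
atlas_spec <- function(id, name, center = NULL, is_reference = FALSE) {
  id <- as.integer(id)
  if (anyDuplicated(id)) stop("atlas region ids must be unique")
  n <- length(id)
  if (length(name) != n) stop("id and name lengths differ")
  if (is.null(center)) center <- matrix(0, n, 3)
  center <- matrix(as.numeric(center), ncol = 3)
  if (nrow(center) != n) stop("center must have one row per region")
  is_reference <- rep_len(as.logical(is_reference), n)
  out <- data.frame(
    id = id, name = as.character(name),
    x = center[, 1], y = center[, 2], z = center[, 3],
    is_reference = is_reference,
    stringsAsFactors = FALSE
  )
  attr(out, "n_analysis") <- sum(!is_reference)
  class(out) <- c("atlas_spec", "data.frame")
  out
}

#' @export
print.atlas_spec <- function(x, ...) {
  cat(sprintf("atlas_spec: %d analysis regions, %d reference labels\n",
              n_analysis(x), sum(x$is_reference)))
  invisible(x)
}

#' Number of analysis regions in an atlas
#' @param atlas an [atlas_spec()].
#' @return Integer count of non-reference regions.
#' @export
n_analysis <- function(atlas) sum(!atlas$is_reference)

#' Analysis-region subset of an atlas
#' @param atlas an [atlas_spec()].
#' @return The rows of `atlas` with `is_reference = FALSE`.
#' @export
analysis_regions <- function(atlas) atlas[!atlas$is_reference, , drop = FALSE]

# Standard AAL-90 cerebral region labels, in conventional order
# (odd = left, even = right).
aal90_names <- function() {
  base <- c(
    "Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
    "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri",
    "Frontal_Inf_Orb", "Rolandic_Oper", "Supp_Motor_Area", "Olfactory",
    "Frontal_Sup_Medial", "Frontal_Med_Orb", "Rectus", "Insula",
    "Cingulum_Ant", "Cingulum_Mid", "Cingulum_Post", "Hippocampus",
    "ParaHippocampal", "Amygdala", "Calcarine", "Cuneus", "Lingual",
    "Occipital_Sup", "Occipital_Mid", "Occipital_Inf", "Fusiform",
    "Postcentral", "Parietal_Sup", "Parietal_Inf", "SupraMarginal",
    "Angular", "Precuneus", "Paracentral_Lobule", "Caudate", "Putamen",
    "Pallidum", "Thalamus", "Heschl", "Temporal_Sup", "Temporal_Pole_Sup",
    "Temporal_Mid", "Temporal_Pole_Mid", "Temporal_Inf"
  )
  as.vector(rbind(paste0(base, "_L"), paste0(base, "_R")))
}

cerebellum_names <- function() {
  lobes <- c("Crus1", "Crus2", "3", "4_5", "6", "7b", "8", "9", "10")
  hemi <- as.vector(rbind(paste0("Cerebelum_", lobes, "_L"),
                          paste0("Cerebelum_", lobes, "_R")))
  vermis <- paste0("Vermis_", c("1_2", "3", "4_5", "6", "7", "8", "9", "10"))
  c(hemi, vermis)
}

#' AAL-style 90-region atlas with cerebellar reference labels
#'
#' Builds the default atlas: the 90 AAL cerebral regions (labels 1-90) as
#' analysis regions plus the 26 cerebellar/vermis labels (91-116) flagged
#' as the reference set. Node center coordinates are a synthetic schematic
#' layout (left regions at negative x, ordered along y) suitable only for
#' node-file export and toy label volumes; they are not MNI centroids.
#'
#' @return An [atlas_spec()] with 116 rows, 90 of them analysis regions.
#' @export
atlas_aal90 <- function() {
  nm <- c(aal90_names(), cerebellum_names())
  n <- length(nm)
  side <- ifelse(grepl("_L$", nm), -1, ifelse(grepl("_R$", nm), 1, 0))
  ord <- ceiling(seq_len(n) / 2)
  center <- cbind(
    x = side * 40,
    y = 80 - 160 * (ord - 1) / max(ord - 1),
    z = ifelse(seq_len(n) <= 90, 20, -40)
  )
  atlas_spec(seq_len(n), nm, center, is_reference = seq_len(n) > 90)
}

#' Blood biochemical indicator panel
#'
#' The 28 routinely collected blood biochemistry indicators used in the
#' biomarker screens, in a fixed order. The synthetic generator draws
#' its biomarker columns from this panel by default.
#'
#' @return Character vector of 28 indicator names.
#' @export
biomarker_panel <- function() {
  c("sodium", "potassium", "chloride", "calcium", "urea", "creatinine",
    "uric_acid", "fasting_glucose", "total_protein", "albumin", "globulin",
    "alt", "ast", "total_bilirubin", "direct_bilirubin",
    "indirect_bilirubin", "alkaline_phosphatase", "cholinesterase",
    "bun_creatinine_ratio", "triglycerides", "total_cholesterol",
    "hdl_cholesterol", "ldl_cholesterol", "apolipoprotein_a1",
    "apolipoprotein_b", "apolipoprotein_e", "free_fatty_acids",
    "total_bile_acids")
}
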