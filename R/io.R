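#' Read a subject metadata / biomarker table
#'
#' Reads a delimited text file with one row per subject. Required columns:
#' `subject_id`, `group`, `age`, `sex`; `bmi` and any biomarker columns are
#' optional. Missing biomarker cells (empty or `NA`) are preserved as `NA`,
#' never imputed. Sex is recoded to numeric male = 1 / female = 0 through
#' `sex_map` (case-insensitive); already-numeric 0/1 columns pass through.
#'
#' @param path file path (CSV by default; TSV autodetected from extension).
#' @param sep field separator; `NULL` to infer from the file extension.
#' @param sex_map named numeric vector mapping sex strings to 0/1.
#' @return A data frame with columns `subject_id` (character), `group`
#'   (character), `age`, `sex` (0/1), optional `bmi`, and one numeric
#'   column per biomarker. A header-only file yields zero rows (with a
#'   warning).
#' @export
read_subject_table <- function(path, sep = NULL,
                               sex_map = c(male = 1, m = 1, "1" = 1,
                                           female = 0, f = 0, "0" = 0)) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           na.strings = c("", "NA"),
                           check.names = FALSE)
  req <- c("subject_id", "group", "age", "sex")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0) {
    stop("missing required columns: ", paste(miss, collapse = ", "))
  }
  if (nrow(raw) == 0) {
    warning("subject table has a header but no data rows")
    raw$subject_id <- character(0)
    return(raw)
  }
  raw$subject_id <- as.character(raw$subject_id)
  dup <- unique(raw$subject_id[duplicated(raw$subject_id)])
  if (length(dup) > 0) {
    stop("duplicate subject_id: ", paste(dup, collapse = ", "))
  }
  sx <- raw$sex
  if (!is.numeric(sx)) {
    key <- tolower(trimws(as.character(sx)))
    mapped <- unname(sex_map[key])
    bad <- which(is.na(mapped) & !is.na(key))
    if (length(bad) > 0) {
      stop(sprintf("unmappable sex value '%s' in row %d (subject %s)",
                   sx[bad[1]], bad[1], raw$subject_id[bad[1]]))
    }
    raw$sex <- mapped
  } else if (!all(raw$sex %in% c(0, 1, NA))) {
    stop("numeric sex column must be coded 0/1")
  }
  if (any(!is.na(raw$age) & raw$age <= 0)) stop("age must be positive")
  if ("bmi" %in% names(raw) && any(!is.na(raw$bmi) & raw$bmi <= 0)) {
    stop("bmi must be positive when present")
  }
  raw$group <- as.character(raw$group)
  raw
}

#' Names of biomarker columns in a subject table
#'
#' Everything that is not subject metadata (`subject_id`, `group`, `age`,
#' `sex`, `bmi`) is treated as a biomarker column.
#'
#' @param subjects a subject data frame as from [read_subject_table()].
#' @return Character vector of biomarker column names.
#' @export
biomarker_columns <- function(subjects) {
  setdiff(names(subjects), c("subject_id", "group", "age", "sex", "bmi"))
}

#' Write a BrainNet Viewer .node file
#'
#' Plain-text node file: one row per analysis region, six whitespace-
#' separated columns `x y z color size label`, in atlas order. By
#' convention the color column carries a group-difference direction
#' (+1/-1/0) and the size column a magnitude (e.g. |t|).
#'
#' @param atlas an [atlas_spec()]; only analysis regions are written.
#' @param colors numeric scalar per analysis region.
#' @param sizes numeric scalar per analysis region.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_brainnet_node <- function(atlas, colors, sizes, path) {
  reg <- analysis_regions(atlas)
  n <- nrow(reg)
  if (length(colors) != n || length(sizes) != n) {
    stop(sprintf("need %d colors and sizes, got %d and %d",
                 n, length(colors), length(sizes)))
  }
  lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%s",
                   formatC(reg$x, format = "g", digits = 6),
                   formatC(reg$y, format = "g", digits = 6),
                   formatC(reg$z, format = "g", digits = 6),
                   formatC(colors, format = "g", digits = 6),
                   formatC(sizes, format = "g", digits = 6),
                   reg$name)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BrainNet Viewer .node file
#'
#' @param path node file path.
#' @return Data frame with columns `x`, `y`, `z`, `color`, `size`, `label`.
#' @export
read_brainnet_node <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      color = numeric(0), size = numeric(0),
                      label = character(0)))
  }
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  names(tab) <- c("x", "y", "z", "color", "size", "label")
  tab
}

#' Write a BrainNet Viewer .edge file
#'
#' Square symmetric matrix written as n rows of n whitespace-separated
#' numbers with a zero diagonal, at six significant digits.
#'
#' @param mat square symmetric numeric matrix (NAs written as 0).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_brainnet_edge <- function(mat, path) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("edge matrix must be square")
  m2 <- mat
  m2[is.na(m2)] <- 0
  if (!isSymmetric(unname(m2), tol = 1e-8)) {
    stop("edge matrix must be symmetric")
  }
  diag(m2) <- 0
  lines <- apply(m2, 1, function(row) {
    paste(formatC(row, format = "g", digits = 6), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read a BrainNet Viewer .edge file
#'
#' @param path edge file path.
#' @return Square numeric matrix.
#' @export
read_brainnet_edge <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) stop("edge file is not square")
  m
}

#' Extract per-region means from an image volume and a label volume
#'
#' Computes, for each atlas region, the mean of the image voxels whose
#' label equals the region id. Non-finite image voxels (e.g. NaN padding
#' outside the brain in spatially normalized PET volumes) are ignored.
#' Inputs may be NIfTI file paths (read via RNifti) or plain arrays.
#'
#' @param image numeric 3-D array or NIfTI path: the PET (SUV/SUVR) volume.
#' @param labels integer 3-D array or NIfTI path: the atlas label volume,
#'   0 = background, sharing the image grid.
#' @param atlas an [atlas_spec()]; all regions (analysis + reference) are
#'   extracted.
#' @return Data frame with columns `id`, `name`, `mean`, `n_voxels`.
#' @export
extract_roi_means <- function(image, labels, atlas) {
  if (is.character(image)) image <- RNifti::readNifti(image)
  if (is.character(labels)) labels <- RNifti::readNifti(labels)
  image <- unclass(image)
  labels <- unclass(labels)
  if (!identical(dim(image), dim(labels))) {
    stop(sprintf("image grid %s does not match label grid %s",
                 paste(dim(image), collapse = "x"),
                 paste(dim(labels), collapse = "x")))
  }
  lab <- as.integer(round(labels))
  if (any(lab < 0)) stop("labels must be non-negative integers")
  img <- as.numeric(image)
  ok <- is.finite(img)
  # one pass over all voxels: per-label sums and counts of finite voxels
  keep <- ok & lab > 0
  sums <- vapply(split(img[keep], lab[keep]), sum, numeric(1))
  cnts <- vapply(split(img[keep], lab[keep]), length, integer(1))
  out <- data.frame(id = atlas$id, name = atlas$name,
                    mean = NA_real_, n_voxels = 0L,
                    stringsAsFactors = FALSE)
  key <- as.character(atlas$id)
  hit <- key %in% names(cnts)
  if (any(!hit)) {
    stop("region(s) with zero voxels: ",
         paste(atlas$name[!hit], collapse = ", "))
  }
  out$n_voxels <- as.integer(cnts[key])
  out$mean <- as.numeric(sums[key]) / out$n_voxels
  out
}

#' Per-subject reference mean from ROI extraction results
#'
#' Aggregates the reference (cerebellar) labels into one scalar per
#' subject, voxel-count weighted when counts are available.
#'
#' @param roi_list list of data frames as returned by
#'   [extract_roi_means()], one per subject.
#' @param atlas an [atlas_spec()].
#' @param weighted use voxel-count weighting (default `TRUE`).
#' @return Numeric vector of reference means, one per subject.
#' @export
reference_means <- function(roi_list, atlas, weighted = TRUE) {
  ref_ids <- atlas$id[atlas$is_reference]
  if (length(ref_ids) == 0) stop("atlas has no reference regions")
  vapply(roi_list, function(tab) {
    sub <- tab[tab$id %in% ref_ids, , drop = FALSE]
    w <- if (weighted && all(sub$n_voxels > 0)) sub$n_voxels else
      rep(1, nrow(sub))
    sum(sub$mean * w) / sum(w)
  }, numeric(1))
}

#' Write a SUVR table to delimited text
#'
#' One row per subject: a `subject_id` column followed by one numeric
#' column per analysis region (atlas order).
#'
#' @param tab a [suvr_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_suvr_table <- function(tab, path) {
  df <- data.frame(subject_id = tab$subject_ids, tab$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a SUVR table from delimited text
#'
#' @param path CSV path as written by [write_suvr_table()].
#' @param atlas an [atlas_spec()] whose analysis regions match the file's
#'   value columns (by name when named, else by position).
#' @param kind the kind tag to attach (default `"suvr"`).
#' @return A [suvr_table()].
#' @export
read_suvr_table <- function(path, atlas, kind = "suvr") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df)) stop("missing subject_id column")
  ids <- as.character(df$subject_id)
  vals <- as.matrix(df[, setdiff(names(df), "subject_id"), drop = FALSE])
  reg <- analysis_regions(atlas)
  if (!is.null(colnames(vals)) && all(reg$name %in% colnames(vals))) {
    vals <- vals[, reg$name, drop = FALSE]
  } else if (ncol(vals) != nrow(reg)) {
    stop("value columns do not match atlas analysis regions")
  }
  suvr_table(vals, atlas, subject_ids = ids, kind = kind)
}
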