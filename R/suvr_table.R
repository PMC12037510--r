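#' Subjects-by-regions SUVR table
#'
#' Container tying a numeric subjects x regions matrix to an atlas.
#' Columns are the atlas analysis regions, in atlas order. The `kind` tag
#' tracks where the values are in the processing chain: raw region-mean
#' SUV (`"raw_suv"`), reference-normalized SUVR (`"suvr"`), or
#' age/sex-corrected SUVR (`"corrected_suvr"`).
#'
#' @param values numeric matrix, one row per subject, one column per
#'   analysis region (atlas order). For `raw_suv` and `suvr` kinds all
#'   values must be finite and positive.
#' @param atlas an [atlas_spec()].
#' @param subject_ids character vector of row identifiers; defaults to the
#'   rownames of `values`.
#' @param kind one of `"raw_suv"`, `"suvr"`, `"corrected_suvr"`.
#'
#' @return An object of class `suvr_table` with elements `values`,
#'   `atlas`, `subject_ids`, `kind`.
#' @export
suvr_table <- function(values, atlas,
                       subject_ids = rownames(values),
                       kind = c("suvr", "raw_suv", "corrected_suvr")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (ncol(values) != n_analysis(atlas)) {
    stop(sprintf("values has %d columns but atlas has %d analysis regions",
                 ncol(values), n_analysis(atlas)))
  }
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(nrow(values)))
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids")
  if (length(subject_ids) != nrow(values)) {
    stop("subject_ids length does not match number of rows")
  }
  if (kind %in% c("raw_suv", "suvr")) {
    if (!all(is.finite(values)) || any(values <= 0)) {
      stop(sprintf("%s values must be finite and positive", kind))
    }
  }
  dimnames(values) <- list(subject_ids, analysis_regions(atlas)$name)
  structure(
    list(values = values, atlas = atlas,
         subject_ids = subject_ids, kind = kind),
    class = "suvr_table"
  )
}

#' @export
print.suvr_table <- function(x, ...) {
  cat(sprintf("suvr_table [%s]: %d subjects x %d regions\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.suvr_table <- function(x) dim(x$values)

#' Subset a SUVR table by subject
#'
#' @param tab a [suvr_table()].
#' @param subjects character subject ids or logical/integer row index.
#' @return A `suvr_table` restricted to the selected subjects.
#' @export
subset_subjects <- function(tab, subjects) {
  if (is.character(subjects)) {
    idx <- match(subjects, tab$subject_ids)
    if (anyNA(idx)) {
      stop("unknown subject ids: ",
           paste(subjects[is.na(idx)], collapse = ", "))
    }
  } else {
    idx <- subjects
  }
  suvr_table(tab$values[idx, , drop = FALSE], tab$atlas,
             subject_ids = tab$subject_ids[idx], kind = tab$kind)
}

same_atlas <- function(a, b) {
  identical(a$atlas$id, b$atlas$id) && identical(a$atlas$name, b$atlas$name)
}
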