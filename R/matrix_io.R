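#' Read a subject-by-vertex matrix
#'
#' Reads a rectangular TSV whose first column is `subject_id` (optionally
#' followed by a `timepoint` column when the accompanying cohort is
#' longitudinal) and whose remaining columns are per-vertex values. Rows are
#' reordered to match the cohort row order so that row `i` of the returned
#' matrix corresponds to cohort row `i`.
#'
#' @param path Path to a TSV file.
#' @param cohort The cohort `data.frame` the matrix accompanies.
#' @return A numeric matrix, `nrow(cohort)` x V, with row names equal to the
#'   cohort row keys.
#' @export
read_subject_matrix <- function(path, cohort) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"subject_id" %in% names(df)) {
    stop("matrix format error: first column must be 'subject_id'")
  }
  has_tp <- "timepoint" %in% names(df)
  value_cols <- setdiff(names(df), c("subject_id", "timepoint"))
  mat <- as.matrix(df[, value_cols, drop = FALSE])
  if (!is.numeric(mat)) {
    stop("matrix format error: non-numeric vertex values")
  }
  file_key <- if (has_tp) paste(df$subject_id, df$timepoint, sep = "\r")
              else as.character(df$subject_id)
  cohort_key <- if (has_tp) paste(cohort$subject_id, cohort$timepoint, sep = "\r")
                else as.character(cohort$subject_id)
  unknown <- setdiff(file_key, cohort_key)
  if (length(unknown) > 0L) {
    stop("matrix integrity error: id(s) absent from cohort: ",
         paste(gsub("\r", ":", unknown), collapse = ", "))
  }
  idx <- match(cohort_key, file_key)
  if (anyNA(idx)) {
    stop("matrix integrity error: cohort row(s) missing from matrix: ",
         paste(gsub("\r", ":", cohort_key[is.na(idx)]), collapse = ", "))
  }
  out <- mat[idx, , drop = FALSE]
  rownames(out) <- gsub("\r", ":", cohort_key)
  out
}

#' Write a subject-by-vertex matrix
#'
#' @param mat Numeric matrix (subjects x vertices).
#' @param cohort Cohort `data.frame` whose rows match `mat` rows.
#' @param path Output path (TSV).
#' @export
write_subject_matrix <- function(mat, cohort, path) {
  stopifnot(nrow(mat) == nrow(cohort))
  if (any(rowSums(!is.finite(mat)) == ncol(mat))) {
    stop("matrix value error: all-NaN row")
  }
  lead <- data.frame(subject_id = cohort$subject_id,
                     stringsAsFactors = FALSE)
  if (any(cohort$timepoint != "single")) lead$timepoint <- cohort$timepoint
  df <- cbind(lead, as.data.frame(mat))
  if (is.null(colnames(mat))) {
    names(df)[(ncol(lead) + 1L):ncol(df)] <- paste0("v", seq_len(ncol(mat)))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a vertex map
#'
#' One value per line, preceded by a header line naming the surface template
#' the map is aligned to. `NA` values (masked vertices) are written as `NA`;
#' `NaN`/`Inf` are rejected.
#'
#' @param values Numeric vector of per-vertex values.
#' @param path Output path.
#' @param template_id Identifier of the common surface template.
#' @export
write_vertex_map <- function(values, path, template_id = "synthetic-sphere") {
  bad <- is.nan(values) | is.infinite(values)
  if (any(bad)) {
    stop("vertex map value error: non-finite unmasked values")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(template_id, con)
  writeLines(format(values, digits = 17, trim = TRUE, scientific = FALSE),
             con)
  invisible(path)
}

#' Read a vertex map written by [write_vertex_map()]
#'
#' @param path Path to the file.
#' @return Numeric vector with attribute `template_id`.
#' @export
read_vertex_map <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("vertex map format error: empty map")
  body <- lines[-1L]
  values <- suppressWarnings(as.numeric(body))
  if (any(is.na(values) & body != "NA")) {
    stop("vertex map format error: non-numeric value")
  }
  attr(values, "template_id") <- lines[1L]
  values
}
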