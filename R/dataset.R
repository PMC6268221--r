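#' Build a spectrum-record table
#'
#' The package's central container is an ordinary tibble with one row per
#' compound: `id`, an optional `structure` string (see [format_structure()]),
#' a `shifts` list-column of raw 13C chemical shifts in ppm (1-23 values,
#' any order), and the nine label columns of [task_names()]. Labels are
#' derived from the structure whenever one is given.
#'
#' @param id Character vector of compound identifiers (unique).
#' @param shifts List of numeric vectors, ppm values in (0, 230), at most 23
#'   per compound.
#' @param structure Optional character vector of structure strings.
#' @return A tibble of class `glyco_records`.
#' @examples
#' glycan_records("x1", shifts = list(c(96.7, 103.2, 61.6, 75.0)),
#'                structure = "b-D-Glcp-(1->4)-a-D-Glcp")
#' @export
glycan_records <- function(id, shifts, structure = NULL) {
  stopifnot(length(id) == length(shifts))
  out <- tibble(id = as.character(id),
                structure = if (is.null(structure)) NA_character_ else as.character(structure),
                shifts = as.list(shifts))
  if (!is.null(structure)) {
    labs <- purrr::map_dfr(structure, function(s) {
      labels_from_structure(parse_structure(s))
    })
    out <- dplyr::bind_cols(out, labs)
  } else {
    for (t in task_names()) out[[t]] <- NA_character_
  }
  validate_records(out)
}

validate_records <- function(records) {
  stopifnot(is.data.frame(records), all(c("id", "shifts") %in% names(records)))
  bad <- vapply(records$shifts, function(x) {
    length(x) < 1 || length(x) > 23 || anyNA(x) || any(x <= 0 | x >= 230)
  }, logical(1))
  if (any(bad)) {
    abort(paste0("invalid shift lists (need 1-23 values in (0,230) ppm) for: ",
                 paste(records$id[bad], collapse = ", ")),
          class = "glyco_validation_error")
  }
  if (anyDuplicated(records$id)) {
    abort("record ids must be unique", class = "glyco_validation_error")
  }
  class(records) <- unique(c("glyco_records", class(records)))
  records
}

#' Read and write spectrum-record tables
#'
#' Datasets are plain TSV or CSV (chosen by file extension, or forced with
#' `format`) with columns `id`, `structure`, `shifts` (semicolon-separated
#' ppm values, written at 6 decimals) and optionally the nine label columns.
#' On read, labels are recomputed from the structure when one is present; if
#' stored labels disagree with the recomputed ones the read fails, naming the
#' offending records.
#'
#' @param path File path (`.tsv` or `.csv`).
#' @param format `"tsv"` or `"csv"`; default inferred from the extension.
#' @param records A `glyco_records` tibble (see [glycan_records()]).
#' @return `read_dataset()` returns a `glyco_records` tibble;
#'   `write_dataset()` returns `path` invisibly.
#' @export
read_dataset <- function(path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  reader <- if (format == "csv") readr::read_csv else readr::read_tsv
  raw <- reader(path, show_col_types = FALSE, progress = FALSE,
                col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("id", "shifts") %in% names(raw))) {
    abort("dataset must have 'id' and 'shifts' columns",
          class = "glyco_format_error")
  }
  out <- tibble(
    id = raw$id,
    structure = if ("structure" %in% names(raw)) raw$structure else NA_character_,
    shifts = lapply(strsplit(raw$shifts, ";", fixed = TRUE), as.numeric)
  )
  have_struct <- !is.na(out$structure) & nzchar(out$structure)
  derived <- matrix(NA_character_, nrow(out), length(task_names()),
                    dimnames = list(NULL, task_names()))
  if (any(have_struct)) {
    derived[have_struct, ] <- t(vapply(out$structure[have_struct], function(s) {
      unlist(labels_from_structure(parse_structure(s)))
    }, character(length(task_names()))))
  }
  stored_cols <- intersect(task_names(), names(raw))
  for (t in task_names()) {
    stored <- if (t %in% stored_cols) raw[[t]] else NA_character_
    out[[t]] <- ifelse(is.na(derived[, t]), stored, derived[, t])
    mism <- !is.na(derived[, t]) & !is.na(stored) & derived[, t] != stored
    if (any(mism)) {
      abort(paste0("stored ", t, " labels disagree with structures for: ",
                   paste(out$id[mism], collapse = ", ")),
            class = "glyco_validation_error")
    }
  }
  validate_records(out)
}

#' @rdname read_dataset
#' @export
write_dataset <- function(records, path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  records <- validate_records(records)
  flat <- dplyr::mutate(
    as_tibble(records),
    shifts = vapply(.data$shifts,
                    function(x) paste(sprintf("%.6f", x), collapse = ";"),
                    character(1))
  )
  flat <- flat[, intersect(c("id", "structure", "shifts", task_names()), names(flat))]
  if (format == "csv") readr::write_csv(flat, path, progress = FALSE)
  else readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
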