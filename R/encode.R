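#' Encode raw shifts as the fixed-length 23-descriptor vector
#'
#' The learners all consume a compound as its unassigned 13C chemical shifts
#' sorted in ascending order and padded at the front with zeros to length 23.
#' Descriptor `C(j)` is the j-th entry of that vector (1-based), so the top
#' of the vector is anchored to the highest-ppm carbons: `C23` is always the
#' maximum observed shift (the carbonyl carbon for N-acetylated compounds,
#' otherwise typically an anomeric carbon), and for compounds with fewer than
#' 23 carbons the leading descriptors are 0.
#'
#' @param shifts_ppm Numeric vector of 1-23 chemical shifts in ppm, each in
#'   (0, 230), in any order.
#' @return A named numeric vector of length 23 (`C1` ... `C23`),
#'   non-decreasing.
#' @examples
#' encode_shifts(c(103.2, 61.6, 75.0))
#' @export
encode_shifts <- function(shifts_ppm) {
  shifts_ppm <- as.numeric(shifts_ppm)
  if (length(shifts_ppm) > 23) {
    abort(sprintf("got %d shifts; the descriptor holds at most 23",
                  length(shifts_ppm)), class = "glyco_capacity_error")
  }
  if (length(shifts_ppm) < 1 || anyNA(shifts_ppm) ||
      any(shifts_ppm <= 0 | shifts_ppm >= 230)) {
    abort("shifts must be 1-23 finite ppm values in (0, 230)",
          class = "glyco_validation_error")
  }
  out <- c(numeric(23 - length(shifts_ppm)), sort(shifts_ppm))
  names(out) <- paste0("C", 1:23)
  out
}

#' Descriptor matrix for a record table
#'
#' Applies [encode_shifts()] row-wise and stacks the results.
#'
#' @param records A `glyco_records` tibble (or any data frame with `id` and a
#'   `shifts` list-column).
#' @return A numeric matrix with one row per record (rownames = ids) and 23
#'   columns `C1` ... `C23`.
#' @export
descriptor_matrix <- function(records) {
  stopifnot(is.data.frame(records), all(c("id", "shifts") %in% names(records)))
  if (nrow(records) == 0) {
    return(matrix(numeric(0), 0, 23, dimnames = list(NULL, paste0("C", 1:23))))
  }
  rows <- lapply(seq_len(nrow(records)), function(i) {
    tryCatch(encode_shifts(records$shifts[[i]]), error = function(e) {
      abort(paste0("record '", records$id[i], "': ", conditionMessage(e)),
            class = class(e)[1])
    })
  })
  X <- do.call(rbind, rows)
  rownames(X) <- records$id
  X
}
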