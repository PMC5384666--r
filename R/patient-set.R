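#' Patient sets
#'
#' The saved result of a cohort query: an ordered, duplicate-free set of
#' patient identifiers with a provenance label.
#'
#' @param patients Integer vector of patient ids (deduplicated, sorted).
#' @param set_id Identifier; defaults to a content hash.
#' @param provenance Free-text label (e.g. a query digest).
#' @return A `patient_set` object.
#' @export
patient_set <- function(patients, set_id = NULL, provenance = "") {
  patients <- sort(unique(as.integer(patients)))
  structure(
    list(
      set_id = set_id %||% paste0("ps_", substr(rlang::hash(patients), 1, 10)),
      patients = patients,
      provenance = provenance
    ),
    class = "patient_set"
  )
}

#' @export
print.patient_set <- function(x, ...) {
  cat("<patient_set ", x$set_id, "> n=", length(x$patients), sep = "")
  if (nzchar(x$provenance)) cat("  (", x$provenance, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
format.patient_set <- function(x, ...) paste0(x$set_id, " [n=", length(x$patients), "]")

#' @rdname patient_set
#' @param x A `patient_set`.
#' @param ... Unused.
#' @export
tidy.patient_set <- function(x, ...) {
  tibble::tibble(set_id = x$set_id, patient_num = x$patients)
}

#' Patient-set IO
#'
#' JSON form `{"set_id", "provenance", "patients": [...]}`; TSV form has a
#' single `patient_num` column.
#'
#' @param ps A [patient_set()].
#' @param path File path (`.json` or `.tsv` chosen by extension).
#' @return `write_patient_set()` the path invisibly; `read_patient_set()`
#'   a `patient_set`.
#' @export
write_patient_set <- function(ps, path) {
  stopifnot(inherits(ps, "patient_set"))
  if (grepl("\\.tsv$", path)) {
    readr::write_tsv(tibble::tibble(patient_num = ps$patients), path)
  } else {
    jsonlite::write_json(
      list(set_id = ps$set_id, provenance = ps$provenance,
           patients = ps$patients),
      path, auto_unbox = TRUE
    )
  }
  invisible(path)
}

#' @rdname write_patient_set
#' @export
read_patient_set <- function(path) {
  if (grepl("\\.tsv$", path)) {
    tbl <- readr::read_tsv(path, show_col_types = FALSE)
    patient_set(tbl$patient_num)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    patient_set(obj$patients, set_id = obj$set_id,
                provenance = obj$provenance %||% "")
  }
}
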