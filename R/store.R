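#' Create an empty observation-fact store
#'
#' The store is the star-schema warehouse at the centre of the package: a
#' patient dimension, an encounter dimension (one encounter per genomic input
#' file per patient), and an observation-fact table in modified
#' entity-attribute-value form. Each fact row carries a concept code, an
#' optional modifier code (the sentinel `"@"` means "no modifier"), and an
#' instance number that ties the rows of one observed variant together into
#' an n-tuple.
#'
#' The store is an environment, so registration and insertion mutate it in
#' place; all accessors return plain tibbles.
#'
#' @return A `fact_store` object.
#' @seealso [insert_facts()], [register_patient()], [facts_for_instance()],
#'   [audit_store()]
#' @export
#' @examples
#' st <- fact_store()
#' p <- register_patient(st, "SAMP001", c(population = "CEU"))
#' e <- register_encounter(st, p, "exome.vcf")
fact_store <- function() {
  st <- new.env(parent = emptyenv())
  st$patients <- tibble::tibble(patient_num = integer(), source_id = character())
  st$patient_attrs <- tibble::tibble(
    patient_num = integer(), key = character(), value = character()
  )
  st$encounters <- tibble::tibble(
    encounter_num = integer(), patient_num = integer(), source_file = character()
  )
  st$facts <- empty_facts()
  st$ontology <- NULL
  class(st) <- "fact_store"
  st
}

empty_facts <- function() {
  tibble::tibble(
    patient_num = integer(), encounter_num = integer(), instance_num = integer(),
    concept_cd = character(), modifier_cd = character(),
    valtype = character(), nval = double(), tval = character()
  )
}

FACT_COLS <- c(
  "patient_num", "encounter_num", "instance_num",
  "concept_cd", "modifier_cd", "valtype", "nval", "tval"
)

#' @export
print.fact_store <- function(x, ...) {
  cat(
    "<fact_store> ", nrow(x$patients), " patients, ",
    nrow(x$encounters), " encounters, ", nrow(x$facts), " facts\n",
    sep = ""
  )
  invisible(x)
}

#' Register patients and encounters
#'
#' Identifiers are dense positive integers assigned in registration order,
#' so reloading the same inputs in the same order reproduces the same ids.
#' Both functions are vectorised.
#'
#' @param store A [fact_store()].
#' @param source_id Character vector of external sample / subject ids.
#' @param attributes Optional patient attributes: a named character vector
#'   (applied to every patient) or a data frame with one row per `source_id`
#'   (e.g. a `population` column).
#' @return Integer vector of assigned `patient_num`s.
#' @export
register_patient <- function(store, source_id, attributes = NULL) {
  stopifnot(inherits(store, "fact_store"))
  source_id <- as.character(source_id)
  if (anyDuplicated(source_id) > 0 || any(source_id %in% store$patients$source_id)) {
    dup <- unique(c(
      source_id[duplicated(source_id)],
      intersect(source_id, store$patients$source_id)
    ))
    vf_abort("duplicate_source", paste0(
      "source_id already registered: ", paste(dup, collapse = ", ")
    ))
  }
  ids <- nrow(store$patients) + seq_along(source_id)
  store$patients <- dplyr::bind_rows(
    store$patients,
    tibble::tibble(patient_num = as.integer(ids), source_id = source_id)
  )
  if (!is.null(attributes)) {
    attrs <- if (is.data.frame(attributes)) {
      stopifnot(nrow(attributes) == length(source_id))
      tidyr::pivot_longer(
        dplyr::mutate(
          as_tibble(lapply(attributes, as.character)),
          patient_num = as.integer(ids)
        ),
        -"patient_num", names_to = "key", values_to = "value"
      )
    } else {
      tidyr::expand_grid(
        patient_num = as.integer(ids),
        tibble::tibble(key = names(attributes), value = unname(attributes))
      )
    }
    store$patient_attrs <- dplyr::bind_rows(
      store$patient_attrs, dplyr::filter(attrs, !is.na(.data$value))
    )
  }
  as.integer(ids)
}

#' @rdname register_patient
#' @param patient_num Integer vector of registered patient ids.
#' @param source_file The genomic (or phenotype) input file this encounter
#'   represents; one encounter per (patient, file).
#' @return `register_encounter()`: integer vector of assigned `encounter_num`s.
#' @export
register_encounter <- function(store, patient_num, source_file) {
  stopifnot(inherits(store, "fact_store"))
  patient_num <- as.integer(patient_num)
  unknown <- setdiff(patient_num, store$patients$patient_num)
  if (length(unknown) > 0) {
    vf_abort("unknown_patient", paste0(
      "patient_num not registered: ", paste(unknown, collapse = ", ")
    ))
  }
  ids <- nrow(store$encounters) + seq_along(patient_num)
  store$encounters <- dplyr::bind_rows(
    store$encounters,
    tibble::tibble(
      encounter_num = as.integer(ids), patient_num = patient_num,
      source_file = rep_len(as.character(source_file), length(patient_num))
    )
  )
  as.integer(ids)
}

# Coerce a user-supplied fact data frame to canonical column types, filling
# defaults for absent optional columns.
as_fact_tbl <- function(facts) {
  facts <- as_tibble(facts)
  if (!"modifier_cd" %in% names(facts)) facts$modifier_cd <- "@"
  if (!"valtype" %in% names(facts)) facts$valtype <- "NONE"
  if (!"nval" %in% names(facts)) facts$nval <- NA_real_
  if (!"tval" %in% names(facts)) facts$tval <- ""
  missing <- setdiff(FACT_COLS, names(facts))
  if (length(missing) > 0) {
    vf_abort("invalid_fact", paste0(
      "fact table lacks columns: ", paste(missing, collapse = ", ")
    ))
  }
  dplyr::mutate(
    facts[FACT_COLS],
    patient_num = as.integer(.data$patient_num),
    encounter_num = as.integer(.data$encounter_num),
    instance_num = as.integer(.data$instance_num),
    concept_cd = as.character(.data$concept_cd),
    modifier_cd = as.character(.data$modifier_cd),
    valtype = as.character(.data$valtype),
    nval = as.double(.data$nval),
    tval = dplyr::coalesce(as.character(.data$tval), "")
  )
}

#' Insert observation facts
#'
#' Validates and appends fact rows. The uniqueness key is
#' `(patient_num, encounter_num, instance_num, concept_cd, modifier_cd)`;
#' a collision (within the batch or with stored rows) is rejected as a
#' whole. All referenced patients and encounters must be registered first.
#'
#' @param store A [fact_store()].
#' @param facts Data frame of fact rows. Optional columns `modifier_cd`
#'   (default `"@"`), `valtype` (default `"NONE"`), `nval`, `tval` are
#'   filled with defaults. `valtype` must be one of `NONE`, `NUMERIC`
#'   (requires `nval`), `TEXT` (requires non-empty `tval`).
#' @return Number of rows inserted (invisibly mutates `store`).
#' @export
insert_facts <- function(store, facts) {
  stopifnot(inherits(store, "fact_store"))
  if (NROW(facts) == 0) return(0L)
  facts <- as_fact_tbl(facts)

  if (!all(facts$valtype %in% c("NONE", "NUMERIC", "TEXT"))) {
    vf_abort("invalid_fact", "valtype must be NONE, NUMERIC or TEXT")
  }
  bad_num <- facts$valtype == "NUMERIC" & is.na(facts$nval)
  bad_txt <- facts$valtype == "TEXT" & (is.na(facts$tval) | facts$tval == "")
  if (any(bad_num) || any(bad_txt)) {
    vf_abort("invalid_fact",
      "NUMERIC facts require nval; TEXT facts require a non-empty tval")
  }

  unknown_p <- setdiff(facts$patient_num, store$patients$patient_num)
  if (length(unknown_p) > 0) {
    vf_abort("unknown_patient", paste0(
      "facts reference unregistered patient_num: ",
      paste(sort(unknown_p), collapse = ", ")
    ))
  }
  bad_enc <- dplyr::anti_join(
    dplyr::distinct(facts, .data$patient_num, .data$encounter_num),
    store$encounters, by = c("patient_num", "encounter_num")
  )
  if (nrow(bad_enc) > 0) {
    vf_abort("unknown_patient", paste0(
      "facts reference unregistered (patient, encounter): ",
      paste(paste0(bad_enc$patient_num, "/", bad_enc$encounter_num), collapse = ", ")
    ))
  }

  key <- with(facts, paste(patient_num, encounter_num, instance_num,
                           concept_cd, modifier_cd, sep = "\r"))
  old_key <- with(store$facts, paste(patient_num, encounter_num, instance_num,
                                     concept_cd, modifier_cd, sep = "\r"))
  dup <- key[duplicated(key) | key %in% old_key]
  if (length(dup) > 0) {
    vf_abort("duplicate_fact", paste0(
      "duplicate fact key(s): ",
      paste(utils::head(gsub("\r", "|", unique(dup)), 5), collapse = "; ")
    ))
  }

  store$facts <- dplyr::bind_rows(store$facts, facts)
  nrow(facts)
}

#' Retrieve the n-tuple of one observational instance
#'
#' Returns all fact rows sharing `(patient_num, encounter_num,
#' instance_num)` — the rows describing one observed variant — with the
#' base row (modifier `"@"`) first, then modifiers in stable
#' `(concept_cd, modifier_cd)` order. An absent key yields an empty tibble.
#'
#' @inheritParams insert_facts
#' @param patient_num,encounter_num,instance_num The instance key.
#' @return Tibble of fact rows.
#' @export
facts_for_instance <- function(store, patient_num, encounter_num, instance_num) {
  stopifnot(inherits(store, "fact_store"))
  dplyr::arrange(
    dplyr::filter(
      store$facts,
      .data$patient_num == !!as.integer(patient_num),
      .data$encounter_num == !!as.integer(encounter_num),
      .data$instance_num == !!as.integer(instance_num)
    ),
    .data$modifier_cd != "@", .data$concept_cd, .data$modifier_cd
  )
}

#' Store accessors
#'
#' @inheritParams insert_facts
#' @return Tibbles of, respectively, all facts, the patient dimension
#'   (with attributes pivoted wide), and the encounter dimension.
#' @export
store_facts <- function(store) {
  stopifnot(inherits(store, "fact_store"))
  store$facts
}

#' @rdname store_facts
#' @export
store_patients <- function(store) {
  stopifnot(inherits(store, "fact_store"))
  out <- store$patients
  if (nrow(store$patient_attrs) > 0) {
    out <- dplyr::left_join(
      out,
      tidyr::pivot_wider(store$patient_attrs,
        names_from = "key", values_from = "value"),
      by = "patient_num"
    )
  }
  out
}

#' @rdname store_facts
#' @export
store_encounters <- function(store) {
  stopifnot(inherits(store, "fact_store"))
  store$encounters
}

#' Audit store invariants
#'
#' Scans the whole store for violations of the fact-table contract:
#' duplicate uniqueness keys, value/valtype mismatches, modifier rows with
#' no base (`"@"`) sibling in their instance, and facts referencing
#' unregistered patients or encounters. A clean store returns a
#' zero-row tibble.
#'
#' @inheritParams insert_facts
#' @return Tibble with columns `check`, `key`, `detail`, one row per
#'   violation.
#' @export
audit_store <- function(store) {
  stopifnot(inherits(store, "fact_store"))
  f <- store$facts
  out <- list()

  key <- with(f, paste(patient_num, encounter_num, instance_num,
                       concept_cd, modifier_cd, sep = "|"))
  if (anyDuplicated(key) > 0) {
    out$dup <- tibble::tibble(
      check = "unique_key", key = unique(key[duplicated(key)]),
      detail = "duplicate uniqueness key"
    )
  }

  bad_val <- f$valtype == "NUMERIC" & is.na(f$nval) |
    f$valtype == "TEXT" & (is.na(f$tval) | f$tval == "") |
    !f$valtype %in% c("NONE", "NUMERIC", "TEXT")
  if (any(bad_val)) {
    out$val <- tibble::tibble(
      check = "valtype", key = key[bad_val], detail = "value/valtype mismatch"
    )
  }

  mods <- dplyr::filter(f, .data$modifier_cd != "@")
  bases <- dplyr::distinct(
    dplyr::filter(f, .data$modifier_cd == "@"),
    .data$patient_num, .data$encounter_num, .data$instance_num
  )
  orphans <- dplyr::anti_join(
    mods, bases, by = c("patient_num", "encounter_num", "instance_num")
  )
  if (nrow(orphans) > 0) {
    out$orph <- tibble::tibble(
      check = "modifier_sibling",
      key = with(orphans, paste(patient_num, encounter_num, instance_num,
                                concept_cd, modifier_cd, sep = "|")),
      detail = "modifier row without a base '@' sibling in its instance"
    )
  }

  bad_ref <- dplyr::anti_join(
    dplyr::distinct(f, .data$patient_num, .data$encounter_num),
    store$encounters, by = c("patient_num", "encounter_num")
  )
  if (nrow(bad_ref) > 0) {
    out$ref <- tibble::tibble(
      check = "dimension_ref",
      key = with(bad_ref, paste(patient_num, encounter_num, sep = "|")),
      detail = "fact references unregistered (patient, encounter)"
    )
  }

  if (length(out) == 0) {
    tibble::tibble(check = character(), key = character(), detail = character())
  } else {
    dplyr::bind_rows(out)
  }
}

#' Persist and reload a store
#'
#' Writes the dimensions and the fact table as tab-delimited text under
#' `dir` (`patients.tsv`, `patient_attrs.tsv`, `encounters.tsv`,
#' `facts.tsv`). The fact export uses the fixed 8-column header
#' `patient_num, encounter_num, instance_num, concept_cd, modifier_cd,
#' valtype, nval, tval`.
#'
#' @inheritParams insert_facts
#' @param dir Directory to write to / read from (created if needed).
#' @return `write_store()` the directory path invisibly; `read_store()` a
#'   reconstructed [fact_store()].
#' @export
write_store <- function(store, dir) {
  stopifnot(inherits(store, "fact_store"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(store$patients, file.path(dir, "patients.tsv"))
  readr::write_tsv(store$patient_attrs, file.path(dir, "patient_attrs.tsv"))
  readr::write_tsv(store$encounters, file.path(dir, "encounters.tsv"))
  readr::write_tsv(store$facts[FACT_COLS], file.path(dir, "facts.tsv"))
  invisible(dir)
}

#' @rdname write_store
#' @export
read_store <- function(dir) {
  st <- fact_store()
  st$patients <- readr::read_tsv(
    file.path(dir, "patients.tsv"), show_col_types = FALSE,
    col_types = readr::cols(patient_num = "i", source_id = "c")
  )
  st$patient_attrs <- readr::read_tsv(
    file.path(dir, "patient_attrs.tsv"), show_col_types = FALSE,
    col_types = readr::cols(patient_num = "i", key = "c", value = "c")
  )
  st$encounters <- readr::read_tsv(
    file.path(dir, "encounters.tsv"), show_col_types = FALSE,
    col_types = readr::cols(encounter_num = "i", patient_num = "i", source_file = "c")
  )
  st$facts <- as_fact_tbl(readr::read_tsv(
    file.path(dir, "facts.tsv"), show_col_types = FALSE,
    col_types = readr::cols(
      patient_num = "i", encounter_num = "i", instance_num = "i",
      concept_cd = "c", modifier_cd = "c", valtype = "c",
      nval = "d", tval = "c"
    ), na = "NA"
  ))
  st$facts$tval[is.na(st$facts$tval)] <- ""
  st
}
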