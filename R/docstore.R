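# NoSQL-style backend: one JSON document per patient-variant, precomputed
# per-field views (sorted value -> doc_id indexes), and progressive
# filter chains seeded with a phenotype-derived patient set.

DOC_CORE <- c("doc_id", "patient_num", "chrom", "pos", "ref", "alt",
              "genotype", "gene", "func_class", "rs_id",
              "polyphen_hdiv_score", "polyphen_hdiv_pred")

#' Build per-patient-variant documents
#'
#' One document per (carrier sample, variant record): a flat record of the
#' variant coordinates, the carrier's genotype, and the annotation fields,
#' with any extra annotation columns collected into `extras`. The document
#' id is `patient:chrom:pos:ref:alt`.
#'
#' @param records Tibble from [read_annotated_variants()].
#' @param sample_map Tibble `(sample_id, patient_num)` (an
#'   `encounter_num` column, if present, is ignored here).
#' @return Tibble of documents; `extras` is a list-column of named
#'   character vectors.
#' @export
build_documents <- function(records, sample_map) {
  gl <- genotypes_long(records)
  carriers <- dplyr::filter(gl, gt_is_carrier(.data$gt))
  unknown <- setdiff(carriers$sample_id, sample_map$sample_id)
  if (length(unknown) > 0) {
    vf_abort("unknown_sample", paste0(
      "samples not in sample_map: ", paste(unknown, collapse = ", ")))
  }
  if (nrow(carriers) == 0) {
    return(tibble::tibble(
      doc_id = character(), patient_num = integer(), chrom = character(),
      pos = integer(), ref = character(), alt = character(),
      genotype = character(), gene = character(), func_class = character(),
      rs_id = character(), polyphen_hdiv_score = double(),
      polyphen_hdiv_pred = character(), extras = list()
    ))
  }
  extra_cols <- setdiff(names(records), c(ANNOTATION_COLS, "genotypes"))
  rec <- dplyr::mutate(records,
    id = paste0("varfact:", variant_key(.data$chrom, .data$pos,
                                        .data$ref, .data$alt)))
  if (anyDuplicated(rec$id) > 0) {
    vf_abort("duplicate_document", paste0(
      "duplicate (chrom, pos, ref, alt) record(s): ",
      paste(utils::head(unique(rec$id[duplicated(rec$id)]), 5),
            collapse = ", ")))
  }
  docs <- dplyr::inner_join(carriers, rec, by = "id")
  docs <- dplyr::inner_join(docs, sample_map[, c("sample_id", "patient_num")],
                            by = "sample_id")
  out <- tibble::tibble(
    doc_id = paste(docs$patient_num,
                   variant_key(docs$chrom, docs$pos, docs$ref, docs$alt),
                   sep = ":"),
    patient_num = as.integer(docs$patient_num),
    chrom = docs$chrom, pos = docs$pos, ref = docs$ref, alt = docs$alt,
    genotype = docs$gt, gene = docs$gene, func_class = docs$func_class,
    rs_id = docs$rs_id,
    polyphen_hdiv_score = docs$polyphen_hdiv_score,
    polyphen_hdiv_pred = docs$polyphen_hdiv_pred,
    extras = if (length(extra_cols) > 0) {
      lapply(seq_len(nrow(docs)), function(i) {
        v <- vapply(extra_cols, function(cc) as.character(docs[[cc]][i]), "")
        v[!is.na(v)]
      })
    } else {
      rep(list(setNames(character(0), character(0))), nrow(docs))
    }
  )
  if (anyDuplicated(out$doc_id) > 0) {
    vf_abort("duplicate_document", paste0(
      "duplicate (patient, variant) document(s): ",
      paste(utils::head(unique(out$doc_id[duplicated(out$doc_id)]), 5),
            collapse = ", ")))
  }
  out
}

#' Build precomputed field views
#'
#' A view is a sorted value-to-document index over one field, computed at
#' load time in the manner of document-database map views: lookups and
#' range scans at query time touch only the index. Only declared fields
#' can be filtered on later (strict mode) — anticipating the genotype
#' query at view-build time is an explicit part of this backend's
#' contract.
#'
#' @param docs Document tibble from [build_documents()].
#' @param fields Character vector of document fields to index.
#' @return A `variant_docstore`: list with `docs` and `views` (one sorted
#'   `(value, doc_id)` tibble per field, covering exactly the documents
#'   that have the field).
#' @export
build_views <- function(docs, fields = c("gene", "func_class", "rs_id",
                                         "polyphen_hdiv_score")) {
  views <- lapply(setNames(fields, fields), function(f) {
    if (!f %in% names(docs)) {
      return(tibble::tibble(value = character(0), doc_id = character(0)))
    }
    idx <- tibble::tibble(value = docs[[f]], doc_id = docs$doc_id)
    dplyr::arrange(idx[!is.na(idx$value), ], .data$value, .data$doc_id)
  })
  structure(list(docs = docs, views = views), class = "variant_docstore")
}

#' @export
print.variant_docstore <- function(x, ...) {
  cat("<variant_docstore> ", nrow(x$docs), " documents, views on: ",
      paste(names(x$views), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Filter blocks
#'
#' One block is a constraint on a single document attribute, the unit the
#' progressive filter workflow chains together.
#'
#' @param field Document field name (must be indexed in strict mode).
#' @param op One of `EQ, IN, LT, LE, GT, GE, EXISTS`.
#' @param operands Operand vector (`EXISTS` takes none).
#' @return A `filter_block`.
#' @export
filter_block <- function(field, op = c("EQ", "IN", "LT", "LE", "GT", "GE",
                                       "EXISTS"), operands = NULL) {
  op <- match.arg(op)
  arity_ok <- switch(op,
    EXISTS = length(operands) == 0,
    IN = length(operands) >= 1,
    length(operands) == 1
  )
  if (!arity_ok) {
    vf_abort("bad_params", paste0("operator ", op, " has wrong operand arity"))
  }
  structure(list(field = field, op = op, operands = operands),
            class = "filter_block")
}

# doc_ids satisfying one block, via the precomputed view.
query_view <- function(ds, block, strict = TRUE) {
  stopifnot(inherits(ds, "variant_docstore"))
  if (!block$field %in% names(ds$views)) {
    if (strict) {
      vf_abort("unindexed_field", paste0(
        "field '", block$field, "' was not declared at build_views() time; ",
        "indexed fields: ", paste(names(ds$views), collapse = ", ")))
    }
    v <- tibble::tibble(value = ds$docs[[block$field]], doc_id = ds$docs$doc_id)
    v <- v[!is.na(v$value), ]
  } else {
    v <- ds$views[[block$field]]
  }
  if (nrow(v) == 0) return(character(0))
  keep <- switch(block$op,
    EXISTS = rep(TRUE, nrow(v)),
    EQ = v$value %in% block$operands[[1]],
    IN = v$value %in% unlist(block$operands),
    LT = as.double(v$value) < as.double(block$operands[[1]]),
    LE = as.double(v$value) <= as.double(block$operands[[1]]),
    GT = as.double(v$value) > as.double(block$operands[[1]]),
    GE = as.double(v$value) >= as.double(block$operands[[1]])
  )
  v$doc_id[keep]
}

#' Progressive patient-set filtering over documents
#'
#' Applies the blocks sequentially, starting from a phenotype-derived
#' patient set: after block k the surviving patients are those among the
#' survivors of block k-1 owning at least one document that satisfies
#' blocks 1..k simultaneously. The per-document conjunction mirrors the
#' star store's same-instance semantics: a single variant must meet all
#' genomic constraints. The result table lists the qualifying
#' (patient, document) pairs.
#'
#' @param initial A [patient_set()] (may be empty).
#' @param blocks List of [filter_block()]s; an empty chain is the
#'   identity on the patient set.
#' @param ds A `variant_docstore` from [build_views()].
#' @param strict If `TRUE`, filtering on an unindexed field is an error.
#' @return List with `patients` (a [patient_set()]) and `result_table`
#'   (tibble `patient_num, doc_id, gene, func_class, rs_id`).
#' @export
filter_chain <- function(initial, blocks, ds, strict = TRUE) {
  stopifnot(inherits(initial, "patient_set"), inherits(ds, "variant_docstore"))
  if (inherits(blocks, "filter_block")) blocks <- list(blocks)
  surviving_docs <- ds$docs$doc_id[ds$docs$patient_num %in% initial$patients]
  survivors <- initial$patients
  for (b in blocks) {
    hit <- query_view(ds, b, strict = strict)
    surviving_docs <- intersect(surviving_docs, hit)
    owner <- ds$docs$patient_num[match(surviving_docs, ds$docs$doc_id)]
    survivors <- intersect(survivors, unique(owner))
    # documents owned by eliminated patients can no longer qualify
    surviving_docs <- surviving_docs[owner %in% survivors]
  }
  tbl <- ds$docs[match(surviving_docs, ds$docs$doc_id),
                 c("patient_num", "doc_id", "gene", "func_class", "rs_id")]
  tbl <- dplyr::arrange(tbl, .data$patient_num, .data$doc_id)
  list(
    patients = patient_set(survivors, provenance = "filter_chain"),
    result_table = tbl
  )
}

#' Answer a Common-Task use case through the document backend
#'
#' Reproduces the split workflow: the phenotype part of the use case runs
#' as a panel query against the star store (yielding the initial patient
#' set), and the genomic part runs as a block filter chain over the
#' documents. Block vocabularies are expanded through the ontology's
#' effect synonym table so ANNOVAR-style class strings in documents match.
#'
#' @inheritParams evaluate_use_case
#' @param ds A `variant_docstore`.
#' @return As [filter_chain()].
#' @export
docstore_use_case <- function(store, ds, case_id, params = list(), onto = NULL) {
  onto <- onto %||% store_ontology(store)
  m <- onto$mapping
  t <- params$ratio_threshold %||% 0
  phen_col <- params$phenotype %||% names(m$phenotype_paths)[1]
  ratio_item <- panel_item(m$phenotype_paths[[phen_col]], "BASE", "LT", t)

  synonyms_of <- function(term) {
    code <- map_effect(onto, term)
    m$effect_synonyms[[code]]
  }

  phen_panels <- switch(as.character(case_id),
    "1" = , "2" = list(panel(ratio_item)),
    "3" = {
      pop <- params$population %||%
        vf_abort("bad_params", "params$population is required for case 3")
      if (!pop %in% names(m$population_codes)) {
        vf_abort("bad_params", paste0("unknown population: ", pop))
      }
      list(panel(ratio_item),
           panel(panel_item(path_for_code(onto, m$population_codes[[pop]]),
                            "BASE")))
    },
    "4" = NULL,
    vf_abort("bad_params", "case_id must be 1, 2, 3 or 4")
  )
  initial <- if (is.null(phen_panels)) {
    patient_set(store$patients$patient_num, provenance = "all patients")
  } else {
    evaluate_query(store, query_definition(phen_panels,
                                           name = "phenotype seed"), onto)
  }

  genomic_case <- if (case_id == 3) params$base_case %||% 1 else case_id
  blocks <- switch(as.character(genomic_case),
    "1" = list(
      filter_block("gene", "EQ", params$gene %||%
                     vf_abort("bad_params", "params$gene is required")),
      filter_block("func_class", "IN",
                   c(synonyms_of("missense_variant"),
                     synonyms_of("stop_gained")))
    ),
    "2" = list(
      filter_block("gene", "EQ", params$gene %||%
                     vf_abort("bad_params", "params$gene is required")),
      filter_block("func_class", "IN", synonyms_of("missense_variant")),
      filter_block("polyphen_hdiv_score", "GE",
                   params$polyphen_threshold %||% 0.957)
    ),
    "4" = {
      rs <- params$rs_list
      if (is.null(rs) || length(rs) == 0) {
        vf_abort("bad_params", "params$rs_list is required for case 4")
      }
      list(filter_block("rs_id", "IN", rs))
    }
  )
  filter_chain(initial, blocks, ds)
}

#' Document dump / load as JSON Lines
#'
#' @param ds A `variant_docstore`.
#' @param path File path (`.jsonl`).
#' @param fields Fields to re-index on load.
#' @return `write_docstore()` the path invisibly; `read_docstore()` a
#'   `variant_docstore`.
#' @export
write_docstore <- function(ds, path) {
  stopifnot(inherits(ds, "variant_docstore"))
  docs <- ds$docs
  lines <- vapply(seq_len(nrow(docs)), function(i) {
    rec <- as.list(docs[i, setdiff(names(docs), "extras")])
    rec <- rec[!vapply(rec, function(v) is.na(v) || identical(v, ""), TRUE)]
    ex <- docs$extras[[i]]
    if (length(ex) > 0) rec$extras <- as.list(ex)
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_docstore
#' @export
read_docstore <- function(path, fields = c("gene", "func_class", "rs_id",
                                           "polyphen_hdiv_score")) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- purrr::map(lines, function(l) {
    obj <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    ex <- obj$extras
    obj$extras <- NULL
    core <- setNames(
      lapply(DOC_CORE, function(f) obj[[f]] %||% NA),
      DOC_CORE
    )
    out <- as_tibble(core)
    out$extras <- list(if (is.null(ex)) {
      setNames(character(0), character(0))
    } else {
      unlist(ex)
    })
    out
  })
  docs <- dplyr::bind_rows(rows)
  docs <- dplyr::mutate(docs,
    patient_num = as.integer(.data$patient_num), pos = as.integer(.data$pos),
    polyphen_hdiv_score = as.double(.data$polyphen_hdiv_score),
    dplyr::across(c("doc_id", "chrom", "ref", "alt", "genotype", "gene",
                    "func_class", "rs_id", "polyphen_hdiv_pred"), as.character)
  )
  build_views(docs, fields)
}
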