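# Panel-based cohort queries: items are ORed within a panel, panels are
# ANDed across the query; a panel may be an exclusion (patient-level NOT),
# and panels sharing an instance_group must be satisfied by the same
# observational instance (the same fact n-tuple, i.e. the same patient
# variant).

NUMERIC_OPS <- c("LT", "LE", "GT", "GE", "BETWEEN")
ALL_OPS <- c(NUMERIC_OPS, "EQ", "IN")

#' Build query components
#'
#' `panel_item()` describes one draggable concept: a concept path (expanded
#' to its whole subtree), whether it matches base facts or modifier rows,
#' and an optional value constraint. `panel()` groups items (logical OR)
#' and may be an exclusion or belong to a same-instance group.
#' `query_definition()` assembles panels (logical AND).
#'
#' @param path Concept path, e.g. `"\\Phenotype\\ProteinLevels\\..."`.
#' @param target `"BASE"` (match `concept_cd` of rows with modifier `"@"`)
#'   or `"MODIFIER"` (match `modifier_cd`).
#' @param op Optional value operator: `LT, LE, GT, GE, EQ, BETWEEN, IN`.
#' @param operands Operand vector; `BETWEEN` needs 2, `IN` at least 1,
#'   other ops exactly 1.
#' @return `panel_item`, `panel`, `query_definition` objects respectively.
#' @export
panel_item <- function(path, target = c("BASE", "MODIFIER"),
                       op = NULL, operands = NULL) {
  target <- match.arg(target)
  if (!is.null(op)) {
    op <- match.arg(op, ALL_OPS)
    arity_ok <- switch(op,
      BETWEEN = length(operands) == 2,
      IN = length(operands) >= 1,
      length(operands) == 1
    )
    if (!arity_ok) {
      vf_abort("bad_params", paste0("operator ", op, " has wrong operand arity"))
    }
  } else if (!is.null(operands)) {
    vf_abort("bad_params", "operands given without an operator")
  }
  structure(
    list(path = norm_path(path), target = target, op = op, operands = operands),
    class = "panel_item"
  )
}

#' @rdname panel_item
#' @param ... For `panel()`: `panel_item`s (or a single list of them).
#' @param exclude Exclusion panel: qualifying patients must have no
#'   matching fact at all.
#' @param instance_group Optional label; panels sharing a label must be
#'   satisfied by one common (patient, encounter, instance) key.
#' @export
panel <- function(..., exclude = FALSE, instance_group = NULL) {
  items <- list(...)
  if (length(items) == 1 && is.list(items[[1]]) &&
      !inherits(items[[1]], "panel_item")) {
    items <- items[[1]]
  }
  if (length(items) == 0 || !all(vapply(items, inherits, TRUE, "panel_item"))) {
    vf_abort("bad_params", "a panel needs at least one panel_item")
  }
  structure(
    list(items = items, exclude = isTRUE(exclude),
         instance_group = instance_group),
    class = "panel"
  )
}

#' @rdname panel_item
#' @param panels List of `panel`s.
#' @param name Query name.
#' @export
query_definition <- function(panels, name = "query") {
  if (inherits(panels, "panel")) panels <- list(panels)
  if (length(panels) == 0 || !all(vapply(panels, inherits, TRUE, "panel"))) {
    vf_abort("bad_params", "a query needs at least one panel")
  }
  groups <- vapply(panels, function(p) p$instance_group %||% NA_character_, "")
  tab <- table(groups[!is.na(groups)])
  if (any(tab < 2)) {
    vf_abort("bad_params",
      "every instance_group label must be shared by at least 2 panels")
  }
  if (any(!is.na(groups) & vapply(panels, function(p) p$exclude, TRUE))) {
    vf_abort("bad_params", "an exclude panel may not carry an instance_group")
  }
  structure(list(panels = panels, name = name), class = "query_definition")
}

#' @export
print.query_definition <- function(x, ...) {
  cat("<query_definition '", x$name, "'> ", length(x$panels), " panel(s)\n",
      sep = "")
  invisible(x)
}

# Value predicate on matched fact rows. FLAG facts (valtype NONE) are
# matched unconditionally; numeric operators act on nval, EQ/IN on tval for
# TEXT facts and on nval for NUMERIC facts (exact comparison).
apply_value_op <- function(f, op, operands) {
  if (is.null(op)) return(f)
  keep <- f$valtype == "NONE"
  num <- f$valtype == "NUMERIC"
  txt <- f$valtype == "TEXT"
  x <- suppressWarnings(as.double(operands))
  keep[num] <- switch(op,
    LT = f$nval[num] < x[1], LE = f$nval[num] <= x[1],
    GT = f$nval[num] > x[1], GE = f$nval[num] >= x[1],
    EQ = f$nval[num] == x[1],
    BETWEEN = f$nval[num] >= min(x) & f$nval[num] <= max(x),
    IN = f$nval[num] %in% x
  )
  if (op %in% c("EQ", "IN")) {
    keep[txt] <- f$tval[txt] %in% as.character(operands)
  }
  f[keep, ]
}

#' Row-level item matching
#'
#' Returns the (patient, encounter, instance) keys of facts matched by one
#' panel item: concept-subtree membership (on `concept_cd` for BASE items,
#' on `modifier_cd` for MODIFIER items) plus the optional value constraint.
#'
#' @inheritParams insert_facts
#' @param item A [panel_item()].
#' @param onto Ontology; defaults to the one attached to the store.
#' @return Tibble `(patient_num, encounter_num, instance_num)`, distinct.
#' @export
match_facts <- function(store, item, onto = NULL) {
  onto <- onto %||% store_ontology(store)
  codes <- resolve_subtree(onto, item$path)
  nodes <- dplyr::filter(onto$tree, .data$concept_cd %in% codes)
  if (!is.null(item$op) && item$op %in% NUMERIC_OPS &&
      any(nodes$value_kind == "TEXT")) {
    vf_abort("type_mismatch", paste0(
      "numeric operator ", item$op, " on TEXT concept under ", item$path))
  }
  f <- store$facts
  f <- if (item$target == "BASE") {
    dplyr::filter(f, .data$modifier_cd == "@", .data$concept_cd %in% codes)
  } else {
    dplyr::filter(f, .data$modifier_cd %in% codes)
  }
  f <- apply_value_op(f, item$op, item$operands)
  dplyr::distinct(f, .data$patient_num, .data$encounter_num, .data$instance_num)
}

#' Evaluate a panel query
#'
#' A patient qualifies iff (a) for every instance group there is at least
#' one (patient, encounter, instance) key matched by every panel of the
#' group — the same-n-tuple join that keeps gene and function constraints
#' on the same variant; (b) every ungrouped, non-excluded panel matches at
#' least one of the patient's facts; and (c) every exclusion panel matches
#' none.
#'
#' @inheritParams match_facts
#' @param query A [query_definition()].
#' @return A [patient_set()], ordered by `patient_num`.
#' @export
evaluate_query <- function(store, query, onto = NULL) {
  stopifnot(inherits(query, "query_definition"))
  onto <- onto %||% store_ontology(store)

  panel_keys <- purrr::map(query$panels, function(p) {
    dplyr::distinct(dplyr::bind_rows(
      purrr::map(p$items, function(it) match_facts(store, it, onto))
    ))
  })
  groups <- vapply(query$panels,
                   function(p) p$instance_group %||% NA_character_, "")
  excl <- vapply(query$panels, function(p) p$exclude, TRUE)

  ok <- store$patients$patient_num
  for (g in unique(stats::na.omit(groups))) {
    ks <- panel_keys[which(!is.na(groups) & groups == g)]
    joint <- purrr::reduce(ks, function(a, b) {
      dplyr::semi_join(a, b, by = c("patient_num", "encounter_num", "instance_num"))
    })
    ok <- intersect(ok, unique(joint$patient_num))
  }
  for (i in which(is.na(groups) & !excl)) {
    ok <- intersect(ok, unique(panel_keys[[i]]$patient_num))
  }
  for (i in which(excl)) {
    ok <- setdiff(ok, unique(panel_keys[[i]]$patient_num))
  }
  patient_set(ok, provenance = query$name)
}

#' Reference interpreter for panel queries
#'
#' A deliberately naive per-patient evaluator that loops over each
#' patient's fact rows and checks the query definition literally. It
#' shares no evaluation code with [evaluate_query()] and exists as an
#' independent cross-check.
#'
#' @inheritParams evaluate_query
#' @return A [patient_set()].
#' @export
evaluate_reference <- function(store, query, onto = NULL) {
  stopifnot(inherits(query, "query_definition"))
  onto <- onto %||% store_ontology(store)

  # Subtree codes are looked up once per item; everything else is a literal
  # per-patient, per-row check.
  item_codes <- lapply(query$panels, function(p) {
    lapply(p$items, function(it) resolve_subtree(onto, it$path))
  })

  item_hits_row <- function(it, codes, concept_cd, modifier_cd, valtype,
                            nval, tval) {
    in_tree <- if (it$target == "BASE") {
      modifier_cd == "@" && concept_cd %in% codes
    } else {
      modifier_cd %in% codes
    }
    if (!in_tree) return(FALSE)
    if (is.null(it$op)) return(TRUE)
    if (valtype == "NONE") return(TRUE)
    if (valtype == "NUMERIC") {
      x <- suppressWarnings(as.double(it$operands))
      return(switch(it$op,
        LT = nval < x[1], LE = nval <= x[1],
        GT = nval > x[1], GE = nval >= x[1],
        EQ = nval == x[1],
        BETWEEN = nval >= min(x) && nval <= max(x),
        IN = nval %in% x))
    }
    if (it$op %in% c("EQ", "IN")) {
      return(tval %in% as.character(it$operands))
    }
    FALSE
  }

  groups <- vapply(query$panels,
                   function(p) p$instance_group %||% NA_character_, "")
  qualifies <- logical(0)
  for (pn in store$patients$patient_num) {
    pf <- store$facts[store$facts$patient_num == pn, ]
    panel_key_sets <- lapply(seq_along(query$panels), function(pi) {
      p <- query$panels[[pi]]
      keys <- character(0)
      for (r in seq_len(nrow(pf))) {
        hit <- FALSE
        for (ii in seq_along(p$items)) {
          if (item_hits_row(p$items[[ii]], item_codes[[pi]][[ii]],
                            pf$concept_cd[r], pf$modifier_cd[r],
                            pf$valtype[r], pf$nval[r], pf$tval[r])) {
            hit <- TRUE
            break
          }
        }
        if (hit) keys <- c(keys, paste(pf$encounter_num[r], pf$instance_num[r]))
      }
      unique(keys)
    })
    good <- TRUE
    for (g in unique(stats::na.omit(groups))) {
      shared <- Reduce(intersect, panel_key_sets[which(!is.na(groups) & groups == g)])
      if (length(shared) == 0) good <- FALSE
    }
    for (i in seq_along(query$panels)) {
      if (!is.na(groups[i])) next
      n_keys <- length(panel_key_sets[[i]])
      if (query$panels[[i]]$exclude) {
        if (n_keys > 0) good <- FALSE
      } else if (n_keys == 0) good <- FALSE
    }
    qualifies[as.character(pn)] <- good
  }
  patient_set(as.integer(names(qualifies)[qualifies]),
              provenance = paste0(query$name, " (reference)"))
}

# Path lookup helpers used by the use-case builders.
path_for_code <- function(onto, code) {
  hit <- onto$tree$path[onto$tree$concept_cd == code]
  if (length(hit) == 0) vf_abort("unknown_path", paste0("no node with code ", code))
  hit[[1]]
}

effect_path <- function(onto, term) {
  code <- map_effect(onto, term)
  path_for_code(onto, code)
}

#' Build the query definition for a Common-Task use case
#'
#' Case 1: protein ratio below a threshold AND, in the same observational
#' instance, a missense-or-nonsense function modifier with the gene-symbol
#' modifier equal to the target gene. Case 2: as case 1 but missense only,
#' with a PolyPhen-2 HDIV score at or above the damaging threshold in the
#' same instance. Case 3: case 1 or 2 further restricted to one
#' population. Case 4: carriers of any RS id on a supplied panel list
#' (e.g. a hypertrophic-cardiomyopathy panel), over all patients.
#'
#' @inheritParams match_facts
#' @param case_id 1, 2, 3 or 4.
#' @param params List: `gene` (cases 1-3), `ratio_threshold` (default 0),
#'   `phenotype` (phenotype column, default the first configured),
#'   `polyphen_threshold` (default 0.957, the published HDIV
#'   probably-damaging cut-off), `population` (case 3), `base_case`
#'   (case 3; 1 or 2, default 1), `rs_list` (case 4).
#' @return `use_case_query()` a [query_definition()];
#'   `evaluate_use_case()` a [patient_set()].
#' @export
use_case_query <- function(onto, case_id, params = list()) {
  if (!case_id %in% 1:4) vf_abort("bad_params", "case_id must be 1, 2, 3 or 4")
  m <- onto$mapping
  t <- params$ratio_threshold %||% 0
  phen_col <- params$phenotype %||% names(m$phenotype_paths)[1]
  if (!phen_col %in% names(m$phenotype_paths)) {
    vf_abort("bad_params", paste0("unknown phenotype column: ", phen_col))
  }
  ratio_path <- m$phenotype_paths[[phen_col]]
  gene_path <- m$annotation_paths[["gene"]]
  pp_path <- m$annotation_paths[["polyphen_hdiv"]]
  rs_path <- m$annotation_paths[["rs_number"]]

  need_gene <- function() {
    params$gene %||% vf_abort("bad_params", "params$gene is required")
  }

  build_base <- function(which_case) {
    g <- need_gene()
    fn_items <- if (which_case == 1) {
      list(panel_item(effect_path(onto, "missense_variant"), "MODIFIER"),
           panel_item(effect_path(onto, "stop_gained"), "MODIFIER"))
    } else {
      list(panel_item(effect_path(onto, "missense_variant"), "MODIFIER"))
    }
    panels <- list(
      panel(panel_item(ratio_path, "BASE", "LT", t)),
      panel(fn_items, instance_group = "variant"),
      panel(panel_item(gene_path, "MODIFIER", "EQ", g),
            instance_group = "variant")
    )
    if (which_case == 2) {
      p <- params$polyphen_threshold %||% 0.957
      panels <- c(panels, list(
        panel(panel_item(pp_path, "MODIFIER", "GE", p),
              instance_group = "variant")
      ))
    }
    panels
  }

  panels <- switch(as.character(case_id),
    "1" = build_base(1),
    "2" = build_base(2),
    "3" = {
      pop <- params$population %||%
        vf_abort("bad_params", "params$population is required for case 3")
      if (!pop %in% names(m$population_codes)) {
        vf_abort("bad_params", paste0("unknown population: ", pop))
      }
      pop_code <- m$population_codes[[pop]]
      c(build_base(params$base_case %||% 1),
        list(panel(panel_item(path_for_code(onto, pop_code), "BASE"))))
    },
    "4" = {
      rs <- params$rs_list
      if (is.null(rs) || length(rs) == 0) {
        vf_abort("bad_params", "params$rs_list is required for case 4")
      }
      list(panel(panel_item(rs_path, "MODIFIER", "IN", rs)))
    }
  )
  query_definition(panels, name = paste0("use_case_", case_id))
}

#' @rdname use_case_query
#' @export
evaluate_use_case <- function(store, case_id, params = list(), onto = NULL) {
  onto <- onto %||% store_ontology(store)
  evaluate_query(store, use_case_query(onto, case_id, params), onto)
}

#' Query JSON dialect
#'
#' `{"name", "panels": [{"items": [{"path", "target", "op", "operands"}],
#' "exclude", "instance_group"}]}`.
#'
#' @param query A [query_definition()].
#' @param path File path.
#' @return `write_query()` the path invisibly; `read_query()` a
#'   `query_definition`.
#' @export
write_query <- function(query, path) {
  stopifnot(inherits(query, "query_definition"))
  obj <- list(
    name = query$name,
    panels = purrr::map(query$panels, function(p) {
      out <- list(
        items = purrr::map(p$items, function(it) {
          o <- list(path = it$path, target = it$target)
          if (!is.null(it$op)) {
            o$op <- it$op
            o$operands <- as.list(it$operands)
          }
          o
        }),
        exclude = p$exclude
      )
      if (!is.null(p$instance_group)) out$instance_group <- p$instance_group
      out
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_query
#' @export
read_query <- function(path) {
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) vf_abort("bad_params", paste0("malformed query JSON: ",
                                                      conditionMessage(e)))
  )
  if (is.null(obj$panels)) vf_abort("bad_params", "query JSON lacks 'panels'")
  panels <- purrr::map(obj$panels, function(p) {
    items <- purrr::map(p$items, function(it) {
      panel_item(it$path, it$target %||% "BASE", it$op,
                 if (!is.null(it$operands)) unlist(it$operands))
    })
    panel(items, exclude = isTRUE(p$exclude),
          instance_group = p$instance_group)
  })
  query_definition(panels, name = obj$name %||% "query")
}
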