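# Concept tree construction and lookups. Paths follow the i2b2 convention:
# backslash-separated from the root, with a trailing separator, e.g.
# "\Genomics\VariantType\SNV\".

SEP <- "\\"

norm_path <- function(path) {
  path <- gsub("/", SEP, as.character(path), fixed = TRUE)
  no_lead <- !startsWith(path, SEP)
  path[no_lead] <- paste0(SEP, path[no_lead])
  no_trail <- !endsWith(path, SEP)
  path[no_trail] <- paste0(path[no_trail], SEP)
  path
}

parent_path <- function(path) {
  comps <- strsplit(sub("^\\\\", "", sub("\\\\$", "", path)), SEP, fixed = TRUE)
  vapply(comps, function(cc) {
    if (length(cc) <= 1) SEP
    else paste0(SEP, paste(cc[-length(cc)], collapse = SEP), SEP)
  }, character(1))
}

folder_code <- function(path) {
  core <- toupper(sub("^\\\\", "", sub("\\\\$", "", path)))
  core <- gsub("[^A-Z0-9\\\\]+", "_", core)
  paste0("FLD:", gsub("\\\\", ":", core))
}

#' Path to the packaged default concept-mapping configuration
#' @return File path of the YAML shipped with the package.
#' @export
default_ontology_config <- function() {
  system.file("extdata", "ontology.yaml", package = "varfact", mustWork = TRUE)
}

node_tbl <- function(path, concept_cd, name, node_kind, value_kind) {
  tibble::tibble(
    path = norm_path(path), concept_cd = concept_cd, name = name,
    node_kind = node_kind, value_kind = value_kind
  )
}

#' Load the concept tree and Sequence Ontology mapping
#'
#' Builds the hierarchical concept tree from a YAML mapping configuration:
#' variant types become genomic concepts under `\Genomics\VariantType\`,
#' variant effects and sequence features become modifier nodes (they qualify
#' a base variant fact within its n-tuple), the annotation value modifiers
#' (gene symbol, dbSNP RS, PolyPhen-2 HDIV) live under
#' `\Genomics\Annotations\`, and the phenotype augmentation adds numeric
#' protein-level concepts plus CEU/CHB/YRI population leaves. Intermediate
#' folder nodes are created automatically.
#'
#' @param config Path to a YAML mapping configuration; defaults to the
#'   packaged curated mapping ([default_ontology_config()]).
#' @return An `so_ontology` object: list with `tree` (tibble of
#'   `path, concept_cd, name, node_kind, value_kind`), `mapping` (the
#'   effect/type/feature synonym maps and modifier slots), and `digest`.
#' @export
#' @examples
#' onto <- load_ontology()
#' resolve_subtree(onto, "\\Phenotype\\Population\\")
load_ontology <- function(config = default_ontology_config()) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config

  need <- function(section) cfg[[section]] %||% list()
  vt <- need("variant_types"); eff <- need("effects"); feat <- need("features")
  ann <- need("annotation_modifiers"); phen <- need("phenotype_numeric")
  pops <- need("populations"); extra <- need("extra_nodes")

  leaf <- function(entries, root, kind, vkind) {
    if (length(entries) == 0) return(NULL)
    node_tbl(
      path = paste0(root, vapply(entries, `[[`, "", "name"), SEP),
      concept_cd = vapply(entries, `[[`, "", "code"),
      name = vapply(entries, `[[`, "", "name"),
      node_kind = kind, value_kind = vkind
    )
  }

  nodes <- dplyr::bind_rows(
    leaf(vt, "\\Genomics\\VariantType\\", "CONCEPT", "FLAG"),
    leaf(eff, "\\Genomics\\VariantEffect\\", "MODIFIER", "FLAG"),
    leaf(feat, "\\Genomics\\Feature\\", "MODIFIER", "FLAG"),
    if (length(ann) > 0) node_tbl(
      path = paste0("\\Genomics\\Annotations\\",
                    vapply(ann, `[[`, "", "name"), SEP),
      concept_cd = vapply(ann, `[[`, "", "code"),
      name = vapply(ann, `[[`, "", "name"),
      node_kind = "MODIFIER",
      value_kind = vapply(ann, function(a) a$value_kind %||% "TEXT", "")
    ),
    if (length(phen) > 0) node_tbl(
      path = paste0("\\Phenotype\\ProteinLevels\\",
                    vapply(phen, `[[`, "", "name"), SEP),
      concept_cd = vapply(phen, `[[`, "", "code"),
      name = vapply(phen, `[[`, "", "name"),
      node_kind = "CONCEPT", value_kind = "NUMERIC"
    ),
    leaf(pops, "\\Phenotype\\Population\\", "CONCEPT", "FLAG"),
    if (length(extra) > 0) {
      ex <- node_tbl(
        path = vapply(extra, `[[`, "", "path"),
        concept_cd = vapply(extra, `[[`, "", "code"),
        name = vapply(extra, function(e) e$name %||% basename(gsub("\\\\", "/", e$path)), ""),
        node_kind = vapply(extra, function(e) e$node_kind %||% "CONCEPT", ""),
        value_kind = vapply(extra, function(e) e$value_kind %||% "FLAG", "")
      )
      declared_parent <- vapply(
        extra, function(e) if (is.null(e$parent)) NA_character_ else norm_path(e$parent),
        character(1)
      )
      if (any(!is.na(declared_parent) & declared_parent == ex$path)) {
        vf_abort("cyclic_path", "extra node declares itself as its own parent")
      }
      ex
    }
  )

  # Auto-create ancestor folders; a parent chain must strictly shorten and
  # terminate at the root, otherwise the path set is cyclic/malformed.
  all_paths <- unique(nodes$path)
  folders <- character(0)
  for (p in all_paths) {
    cur <- parent_path(p)
    steps <- 0L
    while (cur != SEP) {
      if (nchar(cur) >= nchar(p) || steps > 50L) {
        vf_abort("cyclic_path", paste0("path does not reduce to the root: ", p))
      }
      folders <- c(folders, cur)
      p <- cur
      cur <- parent_path(cur)
      steps <- steps + 1L
    }
  }
  folders <- setdiff(unique(folders), nodes$path)
  if (length(folders) > 0) {
    nodes <- dplyr::bind_rows(
      node_tbl(
        path = folders, concept_cd = folder_code(folders),
        name = basename(gsub("\\\\", "/", folders)),
        node_kind = "CONCEPT", value_kind = "FLAG"
      ),
      nodes
    )
  }
  nodes <- dplyr::arrange(nodes, .data$path)

  dup_path <- nodes$path[duplicated(nodes$path)]
  if (length(dup_path) > 0) {
    vf_abort("duplicate_code", paste0(
      "duplicate concept path(s): ", paste(unique(dup_path), collapse = ", ")))
  }
  dup_cd <- dplyr::filter(
    dplyr::add_count(nodes, .data$node_kind, .data$concept_cd), .data$n > 1)
  if (nrow(dup_cd) > 0) {
    vf_abort("duplicate_code", paste0(
      "concept_cd not unique within node_kind: ",
      paste(unique(dup_cd$concept_cd), collapse = ", ")))
  }

  syn_map <- function(entries) {
    if (length(entries) == 0) return(setNames(character(0), character(0)))
    pairs <- purrr::map(entries, function(e) {
      keys <- tolower(c(e$name, unlist(e$synonyms %||% character(0))))
      setNames(rep(e$code, length(keys)), keys)
    })
    m <- unlist(pairs)
    if (anyDuplicated(names(m)) > 0) {
      vf_abort("duplicate_code", "effect/type synonym maps must be injective on keys")
    }
    m
  }

  mapping <- list(
    variant_type_map = syn_map(vt),
    effect_map = syn_map(eff),
    feature_map = syn_map(feat),
    effect_names = setNames(vapply(eff, `[[`, "", "name"),
                            vapply(eff, `[[`, "", "code")),
    # original-case synonym spellings, for matching raw annotation strings
    effect_synonyms = setNames(
      lapply(eff, function(e) unique(c(e$name, unlist(e$synonyms %||% character(0))))),
      vapply(eff, `[[`, "", "code")),
    type_names = setNames(vapply(vt, `[[`, "", "name"),
                          vapply(vt, `[[`, "", "code")),
    feature_names = setNames(vapply(feat, `[[`, "", "name"),
                             vapply(feat, `[[`, "", "code")),
    annotation_codes = setNames(vapply(ann, `[[`, "", "code"),
                                vapply(ann, `[[`, "", "slot")),
    annotation_paths = setNames(
      paste0("\\Genomics\\Annotations\\", vapply(ann, `[[`, "", "name"), SEP),
      vapply(ann, `[[`, "", "slot")),
    phenotype_numeric = setNames(vapply(phen, `[[`, "", "code"),
                                 vapply(phen, `[[`, "", "column")),
    phenotype_paths = setNames(
      paste0("\\Phenotype\\ProteinLevels\\", vapply(phen, `[[`, "", "name"), SEP),
      vapply(phen, `[[`, "", "column")),
    population_codes = setNames(vapply(pops, `[[`, "", "code"),
                                vapply(pops, `[[`, "", "name")),
    modifier_slots = c("feature", "function", "gene", "rs_number", "polyphen_hdiv")
  )

  structure(
    list(tree = nodes, mapping = mapping, digest = rlang::hash(nodes)),
    class = "so_ontology"
  )
}

#' @export
print.so_ontology <- function(x, ...) {
  cat("<so_ontology> ", nrow(x$tree), " concept nodes (digest ",
      substr(x$digest, 1, 8), ")\n", sep = "")
  invisible(x)
}

#' Resolve a concept path to the codes of its subtree
#'
#' Returns the concept code of the node at `path` and of all its
#' descendants, in depth-first (path-sorted) order. This is the hierarchical
#' expansion used when a query item names an inner node such as
#' `\Genomics\VariantEffect\`.
#'
#' @param onto An `so_ontology` from [load_ontology()].
#' @param path Concept path (leading/trailing backslash optional).
#' @return Character vector of concept codes.
#' @export
resolve_subtree <- function(onto, path) {
  stopifnot(inherits(onto, "so_ontology"))
  path <- norm_path(path)
  sub <- dplyr::filter(onto$tree, startsWith(.data$path, !!path))
  if (!path %in% onto$tree$path && path != SEP) {
    vf_abort("unknown_path", paste0("no such concept path: ", path))
  }
  if (path == SEP) sub <- onto$tree
  dplyr::arrange(sub, .data$path)$concept_cd
}

# Shared lookup over a synonym map with a descriptive failure.
map_via <- function(m, key, what) {
  key_lc <- tolower(trimws(as.character(key)))
  hit <- unname(m[key_lc])
  if (any(is.na(hit))) {
    vf_abort("unmapped_effect", paste0(
      "unmapped ", what, ": ",
      paste(unique(key[is.na(hit)]), collapse = ", "),
      " (known: ", paste(sort(unique(names(m))), collapse = ", "), ")"
    ))
  }
  hit
}

#' Map annotation vocabulary onto Sequence Ontology codes
#'
#' Case-insensitive lookups through the packaged synonym tables: ANNOVAR
#' style function classes (e.g. `"nonsynonymous SNV"`, `"stopgain"`) map to
#' variant-effect accessions, variant type names (`"SNV"`, `"insertion"`,
#' `"deletion"`) to type accessions, and feature labels (`"exonic"`) to
#' feature accessions. Unknown inputs fail loudly, listing the known
#' vocabulary, rather than silently dropping facts.
#'
#' @inheritParams resolve_subtree
#' @param function_class,type_name,feature Character vectors to map.
#' @return Character vector of concept codes (vectorised).
#' @export
map_effect <- function(onto, function_class) {
  map_via(onto$mapping$effect_map, function_class, "function class")
}

#' @rdname map_effect
#' @export
map_variant_type <- function(onto, type_name) {
  map_via(onto$mapping$variant_type_map, type_name, "variant type")
}

#' @rdname map_effect
#' @export
map_feature <- function(onto, feature) {
  map_via(onto$mapping$feature_map, feature, "feature")
}

#' Export the concept tree as 3-column TSV
#'
#' @inheritParams resolve_subtree
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_ontology_tsv <- function(onto, path) {
  stopifnot(inherits(onto, "so_ontology"))
  readr::write_tsv(
    dplyr::select(onto$tree, "path", code = "concept_cd", kind = "node_kind"),
    path
  )
  invisible(path)
}

# Attach / fetch the ontology used by a store (query evaluation needs it).
#' Attach an ontology to a store
#' @inheritParams insert_facts
#' @inheritParams resolve_subtree
#' @return The store, invisibly.
#' @export
set_ontology <- function(store, onto) {
  stopifnot(inherits(store, "fact_store"), inherits(onto, "so_ontology"))
  store$ontology <- onto
  invisible(store)
}

store_ontology <- function(store) {
  store$ontology %||% vf_abort("invalid_fact", "store has no attached ontology")
}
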