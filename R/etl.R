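# ETL: annotated VCF -> GVF-like intermediate -> observation-fact n-tuples.
# One encounter per genomic input file; each patient-variant becomes a base
# fact (variant-type concept) plus modifier facts sharing its instance
# number (the "six-tuple" when all annotations are present).

ANNOTATION_COLS <- c(
  "chrom", "pos", "ref", "alt", "gene", "feature", "func_class",
  "rs_id", "polyphen_hdiv_score", "polyphen_hdiv_pred"
)

#' Read a VCF and join per-variant annotations
#'
#' Parses a (multi-sample) VCF 4.x, splits multi-allelic lines into one
#' record per alternate allele, drops variants with no called non-reference
#' genotype, and joins a tab-delimited per-variant annotation table
#' (ANNOVAR-like columns) on `(chrom, pos, ref, alt)` with `chr`-prefix
#' normalisation. Annotation columns beyond the documented set are carried
#' through unchanged (they end up in document `extras`).
#'
#' The annotation table header must contain `chrom, pos, ref, alt, gene,
#' feature, func_class` and may contain `rs_id`, `polyphen_hdiv_score`,
#' `polyphen_hdiv_pred`.
#'
#' @param vcf_path Path to a VCF file.
#' @param annotation_path Path to the annotation TSV.
#' @param strict If `TRUE` (default) a VCF variant absent from the
#'   annotation table is an error; otherwise it is skipped with a warning
#'   and recorded in the `"skipped"` attribute of the result.
#' @return Tibble with one row per (variant, alt allele): columns
#'   `chrom, pos, ref, alt`, the annotation columns, any extra annotation
#'   columns, and a `genotypes` list-column of named genotype strings
#'   (recoded against the single alt allele: `0/0`, `0/1`, `1/1`, `./.`).
#'   Attribute `"samples"` holds the VCF sample names.
#' @export
read_annotated_variants <- function(vcf_path, annotation_path, strict = TRUE) {
  ann <- readr::read_tsv(annotation_path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  missing_cols <- setdiff(c("chrom", "pos", "ref", "alt", "gene", "feature",
                            "func_class"), names(ann))
  if (length(missing_cols) > 0) {
    vf_abort("missing_annotation", paste0(
      "annotation table lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  ann <- dplyr::mutate(ann,
    chrom = normalize_chrom(.data$chrom),
    pos = as.integer(.data$pos),
    rs_id = if ("rs_id" %in% names(ann)) {
      dplyr::na_if(dplyr::na_if(.data$rs_id, ""), ".")
    } else NA_character_,
    polyphen_hdiv_score = if ("polyphen_hdiv_score" %in% names(ann)) {
      suppressWarnings(as.double(dplyr::na_if(.data$polyphen_hdiv_score, ".")))
    } else NA_real_,
    polyphen_hdiv_pred = if ("polyphen_hdiv_pred" %in% names(ann)) {
      dplyr::na_if(dplyr::na_if(.data$polyphen_hdiv_pred, ""), ".")
    } else NA_character_
  )

  raw <- parse_vcf(vcf_path)
  rec <- raw$records
  if (nrow(rec) == 0) {
    out <- dplyr::mutate(ann[0, ], genotypes = list())[
      , c(ANNOTATION_COLS, setdiff(names(ann), ANNOTATION_COLS), "genotypes")]
    attr(out, "samples") <- raw$samples
    attr(out, "skipped") <- tibble::tibble(key = character(), reason = character())
    return(out)
  }

  joined <- dplyr::left_join(rec, ann, by = c("chrom", "pos", "ref", "alt"))
  unmatched <- is.na(joined$gene) & is.na(joined$func_class)
  skipped <- tibble::tibble(
    key = variant_key(joined$chrom, joined$pos, joined$ref, joined$alt)[unmatched],
    reason = "missing annotation"
  )
  if (any(unmatched)) {
    if (strict) {
      vf_abort("missing_annotation", paste0(
        "VCF variant(s) absent from annotation table: ",
        paste(utils::head(skipped$key, 5), collapse = ", ")))
    }
    rlang::warn(paste0("skipping ", sum(unmatched),
                       " variant(s) with no annotation row"))
    joined <- joined[!unmatched, ]
  }
  out <- joined[, c(ANNOTATION_COLS, setdiff(names(ann), ANNOTATION_COLS),
                    "genotypes")]
  attr(out, "samples") <- raw$samples
  attr(out, "skipped") <- skipped
  out
}

# Low-level VCF ingestion via vcfR, with multi-allelic splitting and
# per-alt genotype recoding.
parse_vcf <- function(vcf_path) {
  lines <- readLines(vcf_path, n = -1L)
  header <- grep("^#CHROM", lines, value = TRUE)
  if (length(header) != 1) vf_abort("malformed_vcf", "no #CHROM header line")
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  samples <- if (length(cols) > 9) cols[10:length(cols)] else character(0)
  n_body <- sum(!startsWith(lines, "#"))
  empty <- tibble::tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    genotypes = list()
  )
  if (n_body == 0) return(list(records = empty, samples = samples))

  vcf <- tryCatch(
    vcfR::read.vcfR(vcf_path, verbose = FALSE),
    error = function(e) vf_abort("malformed_vcf", conditionMessage(e))
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt_full <- as.character(fix[, "ALT"])
  ref <- as.character(fix[, "REF"])
  if (any(grepl("[^ACGTN]", ref)) ||
      any(grepl("[^ACGTN,]", alt_full)) || any(alt_full == "")) {
    vf_abort("malformed_vcf", "REF/ALT must be non-empty over ACGTN (no symbolic alleles)")
  }

  gtm <- if (length(samples) > 0) {
    m <- vcfR::extract.gt(vcf, element = "GT")
    matrix(as.character(m), nrow = nrow(fix), dimnames = list(NULL, colnames(m)))
  } else {
    matrix(character(0), nrow = nrow(fix), ncol = 0)
  }

  alts <- strsplit(alt_full, ",", fixed = TRUE)
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    gt_i <- if (ncol(gtm) > 0) gtm[i, ] else character(0)
    alleles <- strsplit(ifelse(is.na(gt_i), ".", gt_i), "[/|]")
    for (k in seq_along(alts[[i]])) {
      cnt <- vapply(alleles, function(a) {
        sum(suppressWarnings(as.integer(a)) == k, na.rm = TRUE)
      }, integer(1))
      called <- vapply(alleles, function(a) {
        any(!is.na(suppressWarnings(as.integer(a))))
      }, logical(1))
      if (!any(cnt > 0)) next  # no non-reference call for this alt
      gt_new <- dplyr::case_when(
        !called ~ "./.", cnt == 0 ~ "0/0", cnt == 1 ~ "0/1", TRUE ~ "1/1"
      )
      rows[[length(rows) + 1]] <- tibble::tibble(
        chrom = normalize_chrom(fix[i, "CHROM"]),
        pos = as.integer(fix[i, "POS"]),
        ref = ref[i], alt = alts[[i]][k],
        genotypes = list(setNames(gt_new, samples))
      )
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  list(
    records = if (length(rows) > 0) dplyr::bind_rows(rows) else empty,
    samples = samples
  )
}

#' Convert variant records to the GVF-like intermediate
#'
#' Classifies each record by REF/ALT length (equal length 1: SNV; longer
#' ALT: insertion; longer REF: deletion) and emits one 9-column GFF3-style
#' row per variant with Sequence Ontology term names. VCF anchor bases are
#' stripped: a deletion of the bases after the anchor spans
#' `pos+1 .. pos+len(ref)-1` with `Reference_seq` excluding the anchor; an
#' insertion spans `pos+1 .. pos` (zero length) with `Variant_seq`
#' excluding the anchor. Complex substitutions cannot be typed and are
#' routed to the `"skipped"` attribute.
#'
#' @param records Tibble from [read_annotated_variants()].
#' @param onto An `so_ontology`; supplies canonical effect/feature term
#'   names for the `Variant_effect` attribute.
#' @return Tibble of GVF rows: `seqid, source, so_type, start, end, score,
#'   strand, phase, id, variant_seq, reference_seq, effect, feature, gene,
#'   dbxref, polyphen_hdiv`; attribute `"skipped"` is a (key, reason)
#'   tibble.
#' @export
to_gvf <- function(records, onto = load_ontology()) {
  rl <- nchar(records$ref); al <- nchar(records$alt)
  so_type <- dplyr::case_when(
    rl == 1 & al == 1 ~ "SNV",
    al > rl ~ "insertion",
    rl > al ~ "deletion",
    TRUE ~ NA_character_
  )
  skipped <- tibble::tibble(
    key = variant_key(records$chrom, records$pos, records$ref,
                      records$alt)[is.na(so_type)],
    reason = "untypable variant (complex substitution)"
  )
  keep <- !is.na(so_type)
  r <- records[keep, ]; so_type <- so_type[keep]
  rl <- rl[keep]; al <- al[keep]

  eff_code <- map_effect(onto, r$func_class)
  feat_code <- map_feature(onto, r$feature)
  out <- tibble::tibble(
    seqid = r$chrom,
    source = "varfact",
    so_type = so_type,
    start = dplyr::if_else(so_type == "SNV", r$pos, r$pos + 1L),
    end = dplyr::case_when(
      so_type == "SNV" ~ r$pos,
      so_type == "deletion" ~ r$pos + rl - 1L,
      TRUE ~ r$pos  # insertion: zero-length interval
    ),
    score = ".", strand = ".", phase = ".",
    id = paste0("varfact:", variant_key(r$chrom, r$pos, r$ref, r$alt)),
    variant_seq = dplyr::case_when(
      so_type == "SNV" ~ r$alt,
      so_type == "insertion" ~ substring(r$alt, 2),
      TRUE ~ "-"
    ),
    reference_seq = dplyr::case_when(
      so_type == "SNV" ~ r$ref,
      so_type == "deletion" ~ substring(r$ref, 2),
      TRUE ~ "-"
    ),
    effect = unname(onto$mapping$effect_names[eff_code]),
    feature = unname(onto$mapping$feature_names[feat_code]),
    gene = r$gene,
    dbxref = dplyr::if_else(is.na(r$rs_id), NA_character_,
                            paste0("dbSNP:", r$rs_id)),
    polyphen_hdiv = r$polyphen_hdiv_score
  )
  attr(out, "skipped") <- skipped
  out
}

#' Write / read the GVF dialect
#'
#' Nine tab-delimited columns on a GFF3 skeleton (`score`, `strand`,
#' `phase` as `"."`), with the attributes column holding `ID`,
#' `Variant_seq`, `Reference_seq`, `Variant_effect` (effect term, index 0,
#' feature term, gene symbol, space-separated), optional `Dbxref`
#' (`dbSNP:rs...`) and optional `polyphen_hdiv`. `read_gvf()` inverts
#' `write_gvf()` exactly.
#'
#' @param gvf Tibble from [to_gvf()].
#' @param path File path.
#' @return `write_gvf()` the path invisibly; `read_gvf()` the tibble.
#' @export
write_gvf <- function(gvf, path) {
  attrs <- paste0(
    "ID=", gvf$id,
    ";Variant_seq=", gvf$variant_seq,
    ";Reference_seq=", gvf$reference_seq,
    ";Variant_effect=", gvf$effect, " 0 ", gvf$feature, " ", gvf$gene,
    ifelse(is.na(gvf$dbxref), "", paste0(";Dbxref=", gvf$dbxref)),
    ifelse(is.na(gvf$polyphen_hdiv), "",
           paste0(";polyphen_hdiv=", format(gvf$polyphen_hdiv, trim = TRUE)))
  )
  lines <- paste(gvf$seqid, gvf$source, gvf$so_type, gvf$start, gvf$end,
                 gvf$score, gvf$strand, gvf$phase, attrs, sep = "\t")
  writeLines(c("##gvf-version 1.10", lines), path)
  invisible(path)
}

#' @rdname write_gvf
#' @export
read_gvf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(to_gvf(tibble::tibble(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), gene = character(), feature = character(),
      func_class = character(), rs_id = character(),
      polyphen_hdiv_score = double()
    )))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 9)) {
    vf_abort("malformed_vcf", "GVF lines must have exactly 9 columns")
  }
  m <- do.call(rbind, parts)
  att <- function(a, key) {
    hit <- regmatches(a, regexpr(paste0("(^|;)", key, "=[^;]*"), a))
    out <- rep(NA_character_, length(a))
    found <- lengths(regmatches(a, gregexpr(paste0("(^|;)", key, "="), a))) > 0
    out[found] <- sub(paste0("^;?", key, "="), "", hit)
    out
  }
  a <- m[, 9]
  ve <- strsplit(att(a, "Variant_effect"), " ", fixed = TRUE)
  tibble::tibble(
    seqid = m[, 1], source = m[, 2], so_type = m[, 3],
    start = as.integer(m[, 4]), end = as.integer(m[, 5]),
    score = m[, 6], strand = m[, 7], phase = m[, 8],
    id = att(a, "ID"),
    variant_seq = att(a, "Variant_seq"),
    reference_seq = att(a, "Reference_seq"),
    effect = vapply(ve, `[`, "", 1),
    feature = vapply(ve, `[`, "", 3),
    gene = vapply(ve, function(x) paste(x[-(1:3)], collapse = " "), ""),
    dbxref = att(a, "Dbxref"),
    polyphen_hdiv = as.double(att(a, "polyphen_hdiv"))
  )
}

#' Expand GVF records and genotypes into fact n-tuples
#'
#' For every (patient, variant) pair in which the patient carries at least
#' one alternate allele, emits one base fact (concept = the variant-type
#' accession, modifier `"@"`) and modifier facts sharing its instance
#' number: sequence feature, variant-effect function, gene symbol (TEXT),
#' dbSNP RS (TEXT, only when present) and PolyPhen-2 HDIV score (NUMERIC,
#' only when present) — six rows per fully annotated variant. Instance
#' numbers are allocated sequentially per encounter in input order.
#'
#' @param gvf Tibble from [to_gvf()] / [read_gvf()].
#' @param genotypes Long tibble `(id, sample_id, gt)` where `id` matches
#'   the GVF `ID` attribute; see [genotypes_long()].
#' @param sample_map Tibble `(sample_id, patient_num, encounter_num)`.
#' @param onto An `so_ontology`.
#' @param start_instance First instance number to allocate per encounter.
#' @return Tibble of fact rows ready for [insert_facts()].
#' @export
gvf_to_facts <- function(gvf, genotypes, sample_map, onto, start_instance = 1L) {
  carriers <- dplyr::filter(genotypes, gt_is_carrier(.data$gt))
  unknown <- setdiff(carriers$sample_id, sample_map$sample_id)
  if (length(unknown) > 0) {
    vf_abort("unknown_sample", paste0(
      "samples not in sample_map: ", paste(unknown, collapse = ", ")))
  }
  gvf <- dplyr::mutate(gvf, .gvf_order = dplyr::row_number())
  hits <- dplyr::inner_join(carriers, gvf, by = "id")
  hits <- dplyr::inner_join(hits, sample_map, by = "sample_id")
  if (nrow(hits) == 0) return(empty_facts())

  hits <- dplyr::mutate(
    dplyr::group_by(
      dplyr::arrange(hits, .data$encounter_num, .data$.gvf_order),
      .data$encounter_num
    ),
    instance_num = as.integer(start_instance - 1L + dplyr::row_number())
  )
  hits <- dplyr::ungroup(hits)

  base_of <- function(h) {
    tibble::tibble(
      patient_num = h$patient_num, encounter_num = h$encounter_num,
      instance_num = h$instance_num
    )
  }
  type_code <- map_variant_type(onto, hits$so_type)
  eff_code <- map_effect(onto, hits$effect)
  feat_code <- map_feature(onto, hits$feature)
  ann_cd <- onto$mapping$annotation_codes

  facts <- dplyr::bind_rows(
    dplyr::mutate(base_of(hits), concept_cd = type_code, modifier_cd = "@",
                  valtype = "NONE", nval = NA_real_, tval = ""),
    dplyr::mutate(base_of(hits), concept_cd = type_code, modifier_cd = feat_code,
                  valtype = "NONE", nval = NA_real_, tval = ""),
    dplyr::mutate(base_of(hits), concept_cd = type_code, modifier_cd = eff_code,
                  valtype = "NONE", nval = NA_real_, tval = ""),
    dplyr::mutate(base_of(hits), concept_cd = type_code,
                  modifier_cd = unname(ann_cd["gene"]),
                  valtype = "TEXT", nval = NA_real_, tval = hits$gene),
    dplyr::mutate(base_of(hits)[!is.na(hits$dbxref), ],
                  concept_cd = type_code[!is.na(hits$dbxref)],
                  modifier_cd = unname(ann_cd["rs_number"]),
                  valtype = "TEXT", nval = NA_real_,
                  tval = sub("^dbSNP:", "", hits$dbxref[!is.na(hits$dbxref)])),
    dplyr::mutate(base_of(hits)[!is.na(hits$polyphen_hdiv), ],
                  concept_cd = type_code[!is.na(hits$polyphen_hdiv)],
                  modifier_cd = unname(ann_cd["polyphen_hdiv"]),
                  valtype = "NUMERIC",
                  nval = hits$polyphen_hdiv[!is.na(hits$polyphen_hdiv)],
                  tval = "E")
  )
  dplyr::arrange(facts, .data$encounter_num, .data$instance_num,
                 .data$modifier_cd != "@", .data$modifier_cd)
}

#' Unnest the genotypes list-column to long form
#'
#' @param records Tibble from [read_annotated_variants()].
#' @return Tibble `(id, sample_id, gt)` keyed like the GVF `ID` attribute.
#' @export
genotypes_long <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(id = character(), sample_id = character(),
                          gt = character()))
  }
  tibble::tibble(
    id = rep(paste0("varfact:", variant_key(records$chrom, records$pos,
                                            records$ref, records$alt)),
             lengths(records$genotypes)),
    sample_id = unlist(lapply(records$genotypes, names), use.names = FALSE),
    gt = unlist(records$genotypes, use.names = FALSE)
  )
}

#' Load phenotype facts
#'
#' One NUMERIC fact per patient per non-missing phenotype column (tval
#' `"E"`) and one FLAG fact at the patient's population leaf, all under a
#' dedicated phenotype encounter per patient. Patients are matched by
#' `source_id` and must already be registered.
#'
#' @inheritParams insert_facts
#' @param phenotypes Path to a CSV with columns `source_id, population`
#'   plus one column per numeric phenotype (e.g. `hladqb1_log_ratio`), or
#'   an equivalent data frame.
#' @param onto An `so_ontology`.
#' @return Number of facts inserted.
#' @export
load_phenotypes <- function(store, phenotypes, onto) {
  tbl <- if (is.character(phenotypes)) {
    readr::read_csv(phenotypes, show_col_types = FALSE)
  } else {
    as_tibble(phenotypes)
  }
  src_label <- if (is.character(phenotypes)) phenotypes else "phenotypes"
  if (nrow(tbl) == 0) return(0L)

  pop_codes <- onto$mapping$population_codes
  bad_pop <- setdiff(stats::na.omit(unique(tbl$population)), names(pop_codes))
  if (length(bad_pop) > 0) {
    vf_abort("unknown_population", paste0(
      "population(s) not in the ontology: ", paste(bad_pop, collapse = ", "),
      " (known: ", paste(names(pop_codes), collapse = ", "), ")"))
  }

  pts <- dplyr::inner_join(tbl, store$patients, by = "source_id")
  unknown <- setdiff(tbl$source_id, pts$source_id)
  if (length(unknown) > 0) {
    vf_abort("unknown_sample", paste0(
      "phenotype rows for unregistered source_id: ",
      paste(unknown, collapse = ", ")))
  }
  enc <- register_encounter(store, pts$patient_num, src_label)
  pts$encounter_num <- enc

  num_cols <- intersect(names(onto$mapping$phenotype_numeric), names(pts))
  fact_list <- list()
  for (col in num_cols) {
    has <- !is.na(pts[[col]])
    fact_list[[col]] <- tibble::tibble(
      patient_num = pts$patient_num[has],
      encounter_num = pts$encounter_num[has],
      concept_cd = unname(onto$mapping$phenotype_numeric[col]),
      modifier_cd = "@", valtype = "NUMERIC",
      nval = as.double(pts[[col]][has]), tval = "E"
    )
  }
  has_pop <- !is.na(pts$population)
  fact_list$pop <- tibble::tibble(
    patient_num = pts$patient_num[has_pop],
    encounter_num = pts$encounter_num[has_pop],
    concept_cd = unname(pop_codes[pts$population[has_pop]]),
    modifier_cd = "@", valtype = "NONE", nval = NA_real_, tval = ""
  )
  facts <- dplyr::bind_rows(fact_list)
  if (nrow(facts) == 0) return(0L)
  facts <- dplyr::mutate(
    dplyr::group_by(facts, .data$encounter_num),
    instance_num = dplyr::row_number()
  )
  insert_facts(store, dplyr::ungroup(facts))
}

#' Load a full cohort into a store
#'
#' Convenience pipeline: registers patients from the phenotype table (in
#' file order, so identifiers are reproducible), loads phenotype facts,
#' then runs the variant ETL (VCF + annotation join, GVF conversion, fact
#' expansion) with one encounter per patient for the VCF file.
#'
#' @inheritParams insert_facts
#' @inheritParams read_annotated_variants
#' @param phenotype_path Phenotype CSV path.
#' @param onto An `so_ontology` (attached to the store for querying).
#' @return List with counts: `patients`, `phenotype_facts`,
#'   `variant_facts`, `variants`, and the `sample_map` tibble.
#' @export
load_cohort <- function(store, vcf_path, annotation_path, phenotype_path,
                        onto = load_ontology(), strict = TRUE) {
  phen <- readr::read_csv(phenotype_path, show_col_types = FALSE,
                          col_types = readr::cols(source_id = "c",
                                                  population = "c",
                                                  .default = "d"))
  set_ontology(store, onto)
  pnum <- if (nrow(phen) > 0) {
    register_patient(store, phen$source_id,
                     attributes = phen[, "population", drop = FALSE])
  } else integer(0)
  n_phen <- load_phenotypes(store, phen, onto)

  records <- read_annotated_variants(vcf_path, annotation_path, strict = strict)
  samples <- attr(records, "samples")
  unknown <- setdiff(samples, phen$source_id)
  if (length(unknown) > 0) {
    vf_abort("unknown_sample", paste0(
      "VCF samples without phenotype rows: ", paste(unknown, collapse = ", ")))
  }
  sample_map <- tibble::tibble(
    sample_id = samples,
    patient_num = store$patients$patient_num[
      match(samples, store$patients$source_id)]
  )
  sample_map$encounter_num <- if (nrow(sample_map) > 0) {
    register_encounter(store, sample_map$patient_num, vcf_path)
  } else integer(0)

  gvf <- to_gvf(records, onto)
  facts <- gvf_to_facts(gvf, genotypes_long(records), sample_map, onto)
  n_var <- insert_facts(store, facts)
  list(
    patients = length(pnum), phenotype_facts = n_phen,
    variant_facts = n_var, variants = nrow(records),
    sample_map = sample_map,
    skipped = dplyr::bind_rows(attr(records, "skipped"), attr(gvf, "skipped"))
  )
}

#' Annotation-volume arithmetic
#'
#' The size of a per-variant annotation matrix: unique variants times
#' annotation characteristics per variant. Useful for sizing loads before
#' fact expansion (fact counts then grow with carrier replication, not
#' with this product).
#'
#' @param n_variants Number of unique variants.
#' @param n_characteristics Annotation characteristics per variant.
#' @return Tibble with `n_variants`, `n_characteristics`,
#'   `total_annotations`.
#' @export
annotation_volume <- function(n_variants, n_characteristics) {
  tibble::tibble(
    n_variants = as.double(n_variants),
    n_characteristics = as.double(n_characteristics),
    total_annotations = as.double(n_variants) * as.double(n_characteristics)
  )
}
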