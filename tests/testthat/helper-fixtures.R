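# Shared fixtures, all built in code at test time.

test_onto <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- load_ontology()
    cached
  }
})

# Codes used repeatedly in fixtures.
SNV_CD <- "SO:0001483"
MISSENSE_CD <- "SO:0001583"
STOPGAIN_CD <- "SO:0001587"
SYNONYMOUS_CD <- "SO:0001819"
EXON_CD <- "SO:0000147"
RATIO_CD <- "PHN:HLADQB1_RATIO"
RATIO_PATH <- "\\Phenotype\\ProteinLevels\\HLA-DQB1 log protein ratio\\"
GENE_PATH <- "\\Genomics\\Annotations\\Gene symbol\\"
RS_PATH <- "\\Genomics\\Annotations\\dbSNP RS\\"
PPH_PATH <- "\\Genomics\\Annotations\\PolyPhen-2 HDIV score\\"
MISSENSE_PATH <- "\\Genomics\\VariantEffect\\missense_variant\\"
STOPGAIN_PATH <- "\\Genomics\\VariantEffect\\stop_gained\\"

# Fact rows of one variant n-tuple (base + feature + function + gene and,
# optionally, RS and PolyPhen modifiers).
variant_tuple <- function(p, e, i, func_cd, gene, rs = NULL, pph = NULL) {
  rows <- tibble::tibble(
    patient_num = p, encounter_num = e, instance_num = i,
    concept_cd = SNV_CD,
    modifier_cd = c("@", EXON_CD, func_cd, "MOD:GENE"),
    valtype = c("NONE", "NONE", "NONE", "TEXT"),
    nval = NA_real_, tval = c("", "", "", gene)
  )
  if (!is.null(rs)) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      patient_num = p, encounter_num = e, instance_num = i,
      concept_cd = SNV_CD, modifier_cd = "MOD:RS",
      valtype = "TEXT", nval = NA_real_, tval = rs
    ))
  }
  if (!is.null(pph)) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      patient_num = p, encounter_num = e, instance_num = i,
      concept_cd = SNV_CD, modifier_cd = "MOD:PPH_HDIV",
      valtype = "NUMERIC", nval = pph, tval = "E"
    ))
  }
  rows
}

ratio_fact <- function(p, e, i, value) {
  tibble::tibble(
    patient_num = p, encounter_num = e, instance_num = i,
    concept_cd = RATIO_CD, modifier_cd = "@",
    valtype = "NUMERIC", nval = value, tval = "E"
  )
}

pop_fact <- function(p, e, i, pop) {
  tibble::tibble(
    patient_num = p, encounter_num = e, instance_num = i,
    concept_cd = paste0("DEM:POP:", pop), modifier_cd = "@",
    valtype = "NONE", nval = NA_real_, tval = ""
  )
}

# Three-patient fixture: P1 ratio -0.4 + missense on HLA-DQB1; P2 ratio
# -0.2 + synonymous on HLA-DQB1; P3 ratio +0.3 + missense on HLA-DQB1.
# `p2_other_gene_missense` adds a missense tuple on OTHER_GENE to P2 to
# demonstrate cross-variant leakage without the same-instance join.
toy_store <- function(p2_other_gene_missense = FALSE) {
  st <- fact_store()
  set_ontology(st, test_onto())
  p <- register_patient(st, c("P1", "P2", "P3"),
                        attributes = data.frame(
                          population = c("CEU", "YRI", "CEU")))
  phen_enc <- register_encounter(st, p, "phenotypes")
  vcf_enc <- register_encounter(st, p, "cohort.vcf")
  insert_facts(st, dplyr::bind_rows(
    ratio_fact(p[1], phen_enc[1], 1, -0.4),
    ratio_fact(p[2], phen_enc[2], 1, -0.2),
    ratio_fact(p[3], phen_enc[3], 1, 0.3),
    pop_fact(p[1], phen_enc[1], 2, "CEU"),
    pop_fact(p[2], phen_enc[2], 2, "YRI"),
    pop_fact(p[3], phen_enc[3], 2, "CEU"),
    variant_tuple(p[1], vcf_enc[1], 1, MISSENSE_CD, "HLA-DQB1",
                  rs = "rs111", pph = 0.98),
    variant_tuple(p[2], vcf_enc[2], 1, SYNONYMOUS_CD, "HLA-DQB1",
                  rs = "rs222"),
    variant_tuple(p[3], vcf_enc[3], 1, MISSENSE_CD, "HLA-DQB1",
                  rs = "rs333", pph = 0.99),
    if (p2_other_gene_missense) {
      variant_tuple(p[2], vcf_enc[2], 2, MISSENSE_CD, "OTHER_GENE")
    }
  ))
  st
}

# The use-case-1 query over the toy fixture (ratio < 0 AND same-instance
# missense/stop-gained + gene = HLA-DQB1), optionally without the
# same-instance join.
toy_uc1_query <- function(grouped = TRUE) {
  g <- if (grouped) "variant" else NULL
  query_definition(list(
    panel(panel_item(RATIO_PATH, "BASE", "LT", 0)),
    panel(list(panel_item(MISSENSE_PATH, "MODIFIER"),
               panel_item(STOPGAIN_PATH, "MODIFIER")),
          instance_group = g),
    panel(panel_item(GENE_PATH, "MODIFIER", "EQ", "HLA-DQB1"),
          instance_group = g)
  ), name = "uc1")
}

# Small annotated-VCF fixture written to disk; returns the paths.
write_tiny_vcf <- function(dir, samples = c("S1", "S2"),
                           lines = list(
                             c("1", "100", "rs1", "A", "G", "0/1", "0/0")
                           )) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf <- file.path(dir, "tiny.vcf")
  body <- vapply(lines, function(l) {
    paste(c(l[1:5], ".", "PASS", ".", "GT", l[-(1:5)]), collapse = "\t")
  }, "")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body
  ), vcf)
  vcf
}

write_tiny_annotation <- function(dir, rows) {
  path <- file.path(dir, "tiny_ann.tsv")
  hdr <- c("chrom", "pos", "ref", "alt", "gene", "feature", "func_class",
           "rs_id", "polyphen_hdiv_score", "polyphen_hdiv_pred")
  writeLines(c(
    paste(hdr, collapse = "\t"),
    vapply(rows, paste, "", collapse = "\t")
  ), path)
  path
}

# Small cohort spec for property tests (kept at desk scale).
mini_spec <- function(seed, n = 15, bg = 25) {
  cohort_spec(n_patients = n, n_background_variants = bg, seed = seed)
}

# Map a patient_set back to source ids for comparison with ground truth.
to_source_ids <- function(st, ps) {
  src <- store_patients(st)
  sort(src$source_id[match(ps$patients, src$patient_num)])
}

# Generate + load one cohort end to end; returns store, docstore, truth.
load_generated_cohort <- function(spec, dir = tempfile("cohort")) {
  res <- generate_cohort(spec, dir)
  st <- fact_store()
  counts <- load_cohort(st, res$vcf_path, res$annotation_path,
                        res$phenotype_path, test_onto())
  records <- read_annotated_variants(res$vcf_path, res$annotation_path)
  ds <- build_views(build_documents(records, counts$sample_map))
  list(store = st, docstore = ds, truth = res$truth, res = res,
       counts = counts, records = records)
}

# A random panel query over the concepts the generator emits, for
# engine-vs-reference equivalence sweeps.
random_query <- function(onto, rng_genes = sprintf("GENE%03d", 1:60)) {
  rand_item <- function() {
    kind <- sample(c("ratio", "pop", "effect", "gene", "pph", "type"), 1)
    switch(kind,
      ratio = {
        op <- sample(c("LT", "GT", "BETWEEN"), 1)
        ops <- if (op == "BETWEEN") sort(round(runif(2, -1, 1), 2))
               else round(runif(1, -1, 1), 2)
        panel_item(RATIO_PATH, "BASE", op, ops)
      },
      pop = panel_item(paste0("\\Phenotype\\Population\\",
                              sample(c("CEU", "CHB", "YRI"), 1), "\\"),
                       "BASE"),
      effect = panel_item(sample(c(MISSENSE_PATH, STOPGAIN_PATH,
                                   "\\Genomics\\VariantEffect\\"), 1),
                          "MODIFIER"),
      gene = {
        ops <- sample(c("HLA-DQB1", rng_genes), sample(1:3, 1))
        panel_item(GENE_PATH, "MODIFIER",
                   if (length(ops) == 1) sample(c("EQ", "IN"), 1) else "IN",
                   ops)
      },
      pph = panel_item(PPH_PATH, "MODIFIER",
                       sample(c("GE", "LT"), 1), round(runif(1), 2)),
      type = panel_item("\\Genomics\\VariantType\\", "BASE")
    )
  }
  n_panels <- sample(1:3, 1)
  grouped <- n_panels >= 2 && runif(1) < 0.4
  panels <- lapply(seq_len(n_panels), function(i) {
    items <- lapply(seq_len(sample(1:2, 1)), function(j) rand_item())
    panel(items,
          exclude = !grouped && i == n_panels && runif(1) < 0.3,
          instance_group = if (grouped && i <= 2) "g" else NULL)
  })
  query_definition(panels, name = "random")
}
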