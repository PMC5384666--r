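ann_row <- function(chrom, pos, ref, alt, gene = "GENE1",
                    func = "nonsynonymous SNV", rs = "rs1",
                    pph = "0.900", pred = "P") {
  c(chrom, pos, ref, alt, gene, "exonic", func, rs, pph, pred)
}

test_that("VCF reading joins annotations and recodes genotypes per alt", {
  dir <- withr::local_tempdir()
  vcf <- write_tiny_vcf(dir, samples = c("S1", "S2"), lines = list(
    c("1", "100", "rs1", "A", "G", "0/1", "0/0"),
    c("1", "200", ".", "C", "G,T", "1/2", "0/2"),
    c("1", "300", ".", "T", "A", "0/0", "0/0")   # no carrier: dropped
  ))
  ann <- write_tiny_annotation(dir, list(
    ann_row("1", "100", "A", "G"),
    ann_row("1", "200", "C", "G", func = "stopgain", rs = "."),
    ann_row("1", "200", "C", "T", func = "synonymous SNV", pph = ".", pred = "."),
    ann_row("1", "300", "T", "A")
  ))
  rec <- read_annotated_variants(vcf, ann)
  expect_equal(nrow(rec), 3L)  # one SNV + the biallelic line split in two
  expect_equal(rec$genotypes[[1]], c(S1 = "0/1", S2 = "0/0"))
  # the 1/2 genotype carries one copy of each alt
  two <- rec[rec$pos == 200, ]
  expect_equal(two$alt, c("G", "T"))
  expect_equal(two$genotypes[[1]], c(S1 = "0/1", S2 = "0/0"))
  expect_equal(two$genotypes[[2]], c(S1 = "0/1", S2 = "0/1"))
  expect_true(is.na(two$rs_id[1]))
  expect_equal(rec$polyphen_hdiv_score[1], 0.9)
})

test_that("annotation misses fail in strict mode and skip in lenient mode", {
  dir <- withr::local_tempdir()
  vcf <- write_tiny_vcf(dir, samples = "S1", lines = list(
    c("1", "100", ".", "A", "G", "0/1"),
    c("1", "200", ".", "C", "T", "1/1")
  ))
  ann <- write_tiny_annotation(dir, list(ann_row("1", "100", "A", "G")))
  expect_error(read_annotated_variants(vcf, ann),
               class = "varfact_missing_annotation")
  expect_warning(
    rec <- read_annotated_variants(vcf, ann, strict = FALSE),
    "skipping"
  )
  expect_equal(nrow(rec), 1L)
  expect_equal(attr(rec, "skipped")$key, "1:200:C:T")
})

test_that("chr prefixes are normalised at the join", {
  dir <- withr::local_tempdir()
  vcf <- write_tiny_vcf(dir, samples = "S1", lines = list(
    c("chr1", "100", ".", "A", "G", "0/1")
  ))
  ann <- write_tiny_annotation(dir, list(ann_row("1", "100", "A", "G")))
  rec <- read_annotated_variants(vcf, ann)
  expect_equal(rec$chrom, "1")
})

test_that("to_gvf applies the anchor-stripping coordinate dialect", {
  onto <- test_onto()
  mk <- function(ref, alt, func = "nonsynonymous SNV") tibble::tibble(
    chrom = "1", pos = 100L, ref = ref, alt = alt, gene = "GENE1",
    feature = "exonic", func_class = func, rs_id = "rs9",
    polyphen_hdiv_score = 0.8, polyphen_hdiv_pred = "P",
    genotypes = list(c(S1 = "0/1"))
  )
  snv <- to_gvf(mk("A", "G"), onto)
  expect_equal(snv[c("so_type", "start", "end", "variant_seq",
                     "reference_seq")],
               tibble::tibble(so_type = "SNV", start = 100L, end = 100L,
                              variant_seq = "G", reference_seq = "A"),
               ignore_attr = TRUE)
  expect_equal(snv$effect, "missense_variant")

  del <- to_gvf(mk("AT", "A", func = "frameshift deletion"), onto)
  expect_equal(del[c("so_type", "start", "end", "reference_seq")],
               tibble::tibble(so_type = "deletion", start = 101L, end = 101L,
                              reference_seq = "T"),
               ignore_attr = TRUE)

  ins <- to_gvf(mk("A", "AG", func = "frameshift insertion"), onto)
  expect_equal(ins[c("so_type", "start", "end", "variant_seq")],
               tibble::tibble(so_type = "insertion", start = 101L, end = 100L,
                              variant_seq = "G"),
               ignore_attr = TRUE)

  cplx <- to_gvf(mk("AT", "GC"), onto)  # complex substitution: skipped
  expect_equal(nrow(cplx), 0L)
  expect_equal(attr(cplx, "skipped")$key, "1:100:AT:GC")
})

test_that("the GVF dialect round-trips through its serialization", {
  onto <- test_onto()
  rec <- tibble::tibble(
    chrom = c("1", "2", "X"), pos = c(100L, 250L, 999L),
    ref = c("A", "CTT", "G"), alt = c("G", "C", "GAA"),
    gene = c("GENE1", "GENE2", "HLA-DQB1"), feature = "exonic",
    func_class = c("nonsynonymous SNV", "frameshift deletion", "stopgain"),
    rs_id = c("rs1", NA, "rs3"),
    polyphen_hdiv_score = c(0.95, NA, NA),
    polyphen_hdiv_pred = c("D", NA, NA),
    genotypes = list(c(S1 = "0/1"), c(S1 = "1/1"), c(S1 = "0/1"))
  )
  gvf <- to_gvf(rec, onto)
  path <- withr::local_tempfile(fileext = ".gvf")
  write_gvf(gvf, path)
  lines <- readLines(path)
  expect_true(all(lengths(strsplit(lines[-1], "\t")) == 9))
  back <- read_gvf(path)
  expect_equal(back, gvf, ignore_attr = TRUE)
})

test_that("fact expansion emits the six-tuple and omits absent annotations", {
  onto <- test_onto()
  dir <- withr::local_tempdir()
  vcf <- write_tiny_vcf(dir, samples = c("S1", "S2", "S3", "S4", "S5"),
    lines = list(
      c("6", "100", "rs1", "A", "G", "0/1", "0/0", "1/1", "0/1", "0/0"),
      c("6", "200", ".", "C", "T", "0/1", "0/0", "0/0", "0/0", "0/0")
    ))
  ann <- write_tiny_annotation(dir, list(
    ann_row("6", "100", "A", "G", gene = "HLA-DQB1", pph = "0.990", pred = "D"),
    ann_row("6", "200", "C", "T", rs = ".", pph = ".", pred = ".")
  ))
  rec <- read_annotated_variants(vcf, ann)
  smap <- tibble::tibble(sample_id = paste0("S", 1:5),
                         patient_num = 1:5, encounter_num = 1:5)
  facts <- gvf_to_facts(to_gvf(rec, onto), genotypes_long(rec), smap, onto)

  # variant 1: 3 carriers (S1, S3, S4) x 6 rows; variant 2: 1 carrier x 4 rows
  expect_equal(nrow(facts), 3 * 6 + 1 * 4)
  expect_setequal(unique(facts$patient_num), c(1L, 3L, 4L))
  v1 <- dplyr::filter(facts, patient_num == 1, instance_num == 1)
  expect_equal(nrow(v1), 6L)
  expect_setequal(v1$modifier_cd,
                  c("@", EXON_CD, MISSENSE_CD, "MOD:GENE", "MOD:RS",
                    "MOD:PPH_HDIV"))
  expect_equal(v1$tval[v1$modifier_cd == "MOD:GENE"], "HLA-DQB1")
  expect_equal(v1$tval[v1$modifier_cd == "MOD:RS"], "rs1")
  expect_equal(v1$nval[v1$modifier_cd == "MOD:PPH_HDIV"], 0.99)

  v2 <- dplyr::filter(facts, patient_num == 1, instance_num == 2)
  expect_equal(nrow(v2), 4L)
  expect_error(
    gvf_to_facts(to_gvf(rec, onto),
                 tibble::tibble(id = genotypes_long(rec)$id[1],
                                sample_id = "GHOST", gt = "0/1"),
                 smap, onto),
    class = "varfact_unknown_sample"
  )
})

test_that("total fact volume matches the carrier-wise closed form", {
  # Sum over (patient, variant) carriers of 4 + rs_present + pph_present,
  # recomputed by brute force from the generator's raw tables.
  fixture <- load_generated_cohort(mini_spec(seed = 11))
  rec <- fixture$records
  gl <- genotypes_long(rec)
  carriers <- gl[grepl("1", gl$gt), ]
  per_variant <- 4L + (!is.na(rec$rs_id)) + (!is.na(rec$polyphen_hdiv_score))
  names(per_variant) <- paste0("varfact:",
    varfact:::variant_key(rec$chrom, rec$pos, rec$ref, rec$alt))
  want <- sum(per_variant[carriers$id])
  vf <- dplyr::filter(store_facts(fixture$store),
                      startsWith(concept_cd, "SO:"))
  expect_equal(nrow(vf), want)
})

test_that("fact counts grow exactly linearly in carrier count", {
  onto <- test_onto()
  dir <- withr::local_tempdir()
  counts <- vapply(1:5, function(k) {
    gts <- c(rep("0/1", k), rep("0/0", 5 - k))
    vcf <- write_tiny_vcf(file.path(dir, k), samples = paste0("S", 1:5),
                          lines = list(c("1", "100", "rs1", "A", "G", gts)))
    ann <- write_tiny_annotation(file.path(dir, k),
                                 list(ann_row("1", "100", "A", "G")))
    rec <- read_annotated_variants(vcf, ann)
    smap <- tibble::tibble(sample_id = paste0("S", 1:5),
                           patient_num = 1:5, encounter_num = 1:5)
    nrow(gvf_to_facts(to_gvf(rec, onto), genotypes_long(rec), smap, onto))
  }, integer(1))
  expect_equal(counts, 6L * (1:5))
})

test_that("phenotype loading emits numeric + population facts", {
  onto <- test_onto()
  st <- fact_store()
  register_patient(st, c("A", "B", "C"))
  tbl <- tibble::tibble(
    source_id = c("A", "B", "C"),
    population = c("YRI", "CEU", "CHB"),
    hladqb1_log_ratio = c(-0.4, NA, 0.2)
  )
  n <- load_phenotypes(st, tbl, onto)
  expect_equal(n, 5L)  # 2 ratios + 3 population flags
  a_facts <- dplyr::filter(store_facts(st), patient_num == 1)
  expect_equal(nrow(a_facts), 2L)
  b_facts <- dplyr::filter(store_facts(st), patient_num == 2)
  expect_equal(b_facts$concept_cd, "DEM:POP:CEU")

  bad <- tbl
  bad$population[1] <- "ABC"
  st2 <- fact_store()
  register_patient(st2, c("A", "B", "C"))
  expect_error(load_phenotypes(st2, bad, onto),
               class = "varfact_unknown_population")
})
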