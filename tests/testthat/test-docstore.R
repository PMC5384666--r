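toy_records <- function() {
  tibble::tibble(
    chrom = c("6", "6"), pos = c(100L, 200L), ref = c("A", "C"),
    alt = c("G", "T"), gene = c("HLA-DQB1", "GENE2"), feature = "exonic",
    func_class = c("nonsynonymous SNV", "synonymous SNV"),
    rs_id = c("rs1", NA), polyphen_hdiv_score = c(0.98, NA),
    polyphen_hdiv_pred = c("D", NA),
    genotypes = list(
      c(S1 = "0/1", S2 = "0/0", S3 = "1/1", S4 = "0/1", S5 = "0/0"),
      c(S1 = "0/0", S2 = "0/1", S3 = "0/0", S4 = "0/0", S5 = "0/0")
    )
  )
}

toy_smap <- tibble::tibble(sample_id = paste0("S", 1:5), patient_num = 1:5)

test_that("one document per carrier sample per variant", {
  docs <- build_documents(toy_records(), toy_smap)
  expect_equal(nrow(docs), 4L)  # 3 carriers + 1 carrier
  expect_setequal(docs$patient_num[docs$gene == "HLA-DQB1"], c(1L, 3L, 4L))
  expect_equal(docs$doc_id[1], "1:6:100:A:G")
  expect_equal(anyDuplicated(docs$doc_id), 0L)

  none <- toy_records()
  none$genotypes <- list(setNames(rep("0/0", 5), paste0("S", 1:5)),
                         setNames(rep("0/0", 5), paste0("S", 1:5)))
  expect_equal(nrow(build_documents(none, toy_smap)), 0L)

  dup <- dplyr::bind_rows(toy_records(), toy_records()[1, ])
  expect_error(build_documents(dup, toy_smap),
               class = "varfact_duplicate_document")
  expect_error(
    build_documents(toy_records(), toy_smap[1:2, ]),
    class = "varfact_unknown_sample"
  )
})

test_that("views agree with a linear scan for every operator", {
  fixture <- load_generated_cohort(mini_spec(seed = 51))
  ds <- fixture$docstore
  docs <- ds$docs
  scan <- function(field, op, operands) {
    v <- docs[[field]]
    keep <- switch(op,
      EQ = !is.na(v) & v %in% operands,
      IN = !is.na(v) & v %in% operands,
      LT = !is.na(v) & as.double(v) < operands,
      GE = !is.na(v) & as.double(v) >= operands,
      EXISTS = !is.na(v)
    )
    sort(docs$doc_id[keep])
  }
  via_view <- function(field, op, operands = NULL) {
    fc <- filter_chain(patient_set(unique(docs$patient_num)),
                       list(filter_block(field, op, operands)), ds)
    sort(fc$result_table$doc_id)
  }
  expect_equal(via_view("gene", "EQ", "HLA-DQB1"), scan("gene", "EQ", "HLA-DQB1"))
  expect_equal(via_view("func_class", "IN", c("stopgain", "synonymous SNV")),
               scan("func_class", "IN", c("stopgain", "synonymous SNV")))
  expect_equal(via_view("polyphen_hdiv_score", "LT", 0.5),
               scan("polyphen_hdiv_score", "LT", 0.5))
  expect_equal(via_view("polyphen_hdiv_score", "GE", 0.957),
               scan("polyphen_hdiv_score", "GE", 0.957))
  expect_equal(via_view("rs_id", "EXISTS"), scan("rs_id", "EXISTS"))
})

test_that("filter chains are progressive, conjunctive, and order-invariant", {
  docs <- build_documents(toy_records(), toy_smap)
  ds <- build_views(docs)
  seed <- patient_set(c(1L, 2L))  # the ratio<0 patients of the toy fixture

  out <- filter_chain(seed, list(
    filter_block("gene", "EQ", "HLA-DQB1"),
    filter_block("func_class", "IN", c("nonsynonymous SNV", "stopgain"))
  ), ds)
  expect_equal(out$patients$patients, 1L)  # must equal use-case 1 on the toy
  expect_equal(out$result_table$doc_id, "1:6:100:A:G")

  # empty initial set dominates
  empty <- filter_chain(patient_set(integer(0)),
                        list(filter_block("gene", "EXISTS")), ds)
  expect_equal(empty$patients$patients, integer(0))
  expect_equal(nrow(empty$result_table), 0L)

  # empty chain is the identity, with all the seed's documents listed
  id <- filter_chain(patient_set(1:5), list(), ds)
  expect_equal(id$patients$patients, 1:5)
  expect_equal(sort(id$result_table$doc_id), sort(docs$doc_id))

  # permuting blocks never changes the final patient set
  fixture <- load_generated_cohort(mini_spec(seed = 52))
  blocks <- list(
    filter_block("gene", "EQ", "HLA-DQB1"),
    filter_block("func_class", "IN", c("nonsynonymous SNV")),
    filter_block("polyphen_hdiv_score", "GE", 0.5)
  )
  all_p <- patient_set(unique(fixture$docstore$docs$patient_num))
  base <- filter_chain(all_p, blocks, fixture$docstore)$patients$patients
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(
      filter_chain(all_p, blocks[perm], fixture$docstore)$patients$patients,
      base
    )
  }
})

test_that("undeclared fields fail loudly in strict mode", {
  docs <- build_documents(toy_records(), toy_smap)
  ds <- build_views(docs, fields = "gene")
  expect_error(
    filter_chain(patient_set(1:5),
                 list(filter_block("func_class", "EQ", "stopgain")), ds),
    class = "varfact_unindexed_field"
  )
  # lenient mode falls back to a scan
  out <- filter_chain(patient_set(1:5),
                      list(filter_block("func_class", "EQ", "stopgain")),
                      ds, strict = FALSE)
  expect_equal(out$patients$patients, integer(0))
})

test_that("documents round-trip through JSON Lines", {
  rec <- toy_records()
  rec$extra_anno <- c("depth=30", "depth=12")  # pass-through column
  docs <- build_documents(rec, toy_smap)
  ds <- build_views(docs)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_docstore(ds, path)
  ds2 <- read_docstore(path)
  d1 <- dplyr::arrange(ds$docs, doc_id)
  d2 <- dplyr::arrange(ds2$docs, doc_id)
  expect_equal(d2[varfact:::DOC_CORE], d1[varfact:::DOC_CORE])
  expect_equal(d2$extras[[1]], d1$extras[[1]])
})

test_that("docstore use cases agree with the star-schema engine", {
  fixture <- load_generated_cohort(mini_spec(seed = 53, n = 30, bg = 40))
  st <- fixture$store
  ds <- fixture$docstore
  spec_rs <- sprintf("rsSYN9%05d", 1:5)
  cases <- list(
    list(id = 1, params = list(gene = "HLA-DQB1")),
    list(id = 2, params = list(gene = "HLA-DQB1")),
    list(id = 3, params = list(gene = "HLA-DQB1", population = "YRI")),
    list(id = 4, params = list(rs_list = spec_rs))
  )
  for (cs in cases) {
    eng <- evaluate_use_case(st, cs$id, cs$params)
    doc <- docstore_use_case(st, ds, cs$id, cs$params)
    expect_equal(doc$patients$patients, eng$patients)
  }
})
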