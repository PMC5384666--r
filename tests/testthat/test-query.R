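test_that("match_facts honours subtrees, value ops, and value kinds", {
  st <- toy_store()
  lt0 <- match_facts(st, panel_item(RATIO_PATH, "BASE", "LT", 0))
  expect_setequal(lt0$patient_num, c(1L, 2L))

  ceu <- match_facts(st,
    panel_item("\\Phenotype\\Population\\CEU\\", "BASE"))
  expect_setequal(ceu$patient_num, c(1L, 3L))

  expect_error(
    match_facts(st, panel_item(GENE_PATH, "MODIFIER", "LT", 1)),
    class = "varfact_type_mismatch"
  )
  expect_error(
    match_facts(st, panel_item("\\Nope\\", "BASE")),
    class = "varfact_unknown_path"
  )
})

test_that("the same-instance join separates per-variant constraints", {
  # P2 has a missense on OTHER_GENE and a synonymous on HLA-DQB1; only the
  # same-instance join keeps those constraints on one variant.
  st <- toy_store(p2_other_gene_missense = TRUE)
  grouped <- evaluate_query(st, toy_uc1_query(grouped = TRUE))
  expect_equal(grouped$patients, 1L)
  leaky <- evaluate_query(st, toy_uc1_query(grouped = FALSE))
  expect_equal(leaky$patients, c(1L, 2L))
})

test_that("exclusion panels are patient-level NOT", {
  st <- toy_store()
  q <- query_definition(list(
    panel(panel_item(RATIO_PATH, "BASE", "LT", 1)),
    panel(panel_item("\\Phenotype\\Population\\", "BASE"), exclude = TRUE)
  ))
  expect_equal(evaluate_query(st, q)$patients, integer(0))

  # exclusion duality: evaluate(P + exclude(X)) == evaluate(P) - evaluate(X)
  qx <- query_definition(list(
    panel(panel_item(RATIO_PATH, "BASE", "LT", 0)),
    panel(panel_item("\\Phenotype\\Population\\YRI\\", "BASE"),
          exclude = TRUE)
  ))
  base <- evaluate_query(st, query_definition(list(
    panel(panel_item(RATIO_PATH, "BASE", "LT", 0)))))
  yri <- evaluate_query(st, query_definition(list(
    panel(panel_item("\\Phenotype\\Population\\YRI\\", "BASE")))))
  expect_equal(evaluate_query(st, qx)$patients,
               setdiff(base$patients, yri$patients))
})

test_that("query composition is monotone", {
  fixture <- load_generated_cohort(mini_spec(seed = 21))
  st <- fixture$store
  q1 <- query_definition(list(
    panel(panel_item(MISSENSE_PATH, "MODIFIER"))))
  q2 <- query_definition(list(
    panel(panel_item(MISSENSE_PATH, "MODIFIER")),
    panel(panel_item(RATIO_PATH, "BASE", "LT", 0))))
  # adding a non-excluded panel never enlarges the set
  expect_true(all(evaluate_query(st, q2)$patients %in%
                    evaluate_query(st, q1)$patients))
  # adding an item to a panel never shrinks it
  q3 <- query_definition(list(
    panel(list(panel_item(MISSENSE_PATH, "MODIFIER"),
               panel_item(STOPGAIN_PATH, "MODIFIER")))))
  expect_true(all(evaluate_query(st, q1)$patients %in%
                    evaluate_query(st, q3)$patients))
})

test_that("query invariants are validated at construction", {
  expect_error(panel_item(RATIO_PATH, "BASE", "BETWEEN", 1),
               class = "varfact_bad_params")
  expect_error(panel(), class = "varfact_bad_params")
  it <- panel_item(RATIO_PATH, "BASE")
  expect_error(query_definition(list(panel(it, instance_group = "g"))),
               class = "varfact_bad_params")
  expect_error(
    query_definition(list(
      panel(it, instance_group = "g", exclude = TRUE),
      panel(it, instance_group = "g"))),
    class = "varfact_bad_params"
  )
})

test_that("use-case wrappers behave at their boundaries", {
  st <- toy_store()
  # an RS list matching nothing yields the empty set
  ps <- evaluate_use_case(st, 4, list(rs_list = c("rs999", "rs998")))
  expect_equal(ps$patients, integer(0))
  # a matching RS list finds the carriers regardless of phenotype
  ps <- evaluate_use_case(st, 4, list(rs_list = "rs333"))
  expect_equal(ps$patients, 3L)
  # case 3 is a restriction of case 1
  uc1 <- evaluate_use_case(st, 1, list(gene = "HLA-DQB1"))
  uc3 <- evaluate_use_case(st, 3, list(gene = "HLA-DQB1",
                                       population = "YRI"))
  expect_true(all(uc3$patients %in% uc1$patients))
  expect_error(evaluate_use_case(st, 1, list()),
               class = "varfact_bad_params")
  expect_error(evaluate_use_case(st, 5, list()),
               class = "varfact_bad_params")
})

test_that("case 2 at threshold zero equals the missense-only case 1", {
  for (seed in c(31, 32)) {
    fixture <- load_generated_cohort(mini_spec(seed = seed))
    st <- fixture$store
    uc2_p0 <- evaluate_use_case(st, 2, list(gene = "HLA-DQB1",
                                            polyphen_threshold = 0))
    # brute force from the raw tables: lower-mode carriers of any scored
    # target-gene missense variant
    ann <- fixture$res$tables$annotations
    gt <- fixture$res$tables$genotypes
    ph <- fixture$res$tables$phenotypes
    vids <- ann$vid[ann$gene == "HLA-DQB1" &
                      ann$func_class == "nonsynonymous SNV" &
                      !is.na(ann$polyphen_hdiv_score)]
    carriers <- unique(gt$source_id[gt$vid %in% vids & gt$alt_count > 0])
    low <- ph$source_id[ph$hladqb1_log_ratio < 0]
    expect_equal(to_source_ids(st, uc2_p0), sort(intersect(low, carriers)))
  }
})

test_that("evaluate_query matches the naive reference interpreter", {
  n_pairs <- 0
  for (seed in c(41, 42)) {
    fixture <- load_generated_cohort(mini_spec(seed = seed, n = 12, bg = 15))
    st <- fixture$store
    set.seed(seed * 7)
    for (i in 1:15) {
      q <- random_query(test_onto())
      fast <- evaluate_query(st, q)
      slow <- evaluate_reference(st, q)
      expect_equal(fast$patients, slow$patients)
      n_pairs <- n_pairs + 1
    }
  }
  expect_gte(n_pairs, 30)
})

test_that("query and patient-set serializations round-trip", {
  q <- toy_uc1_query()
  qp <- withr::local_tempfile(fileext = ".json")
  write_query(q, qp)
  q2 <- read_query(qp)
  st <- toy_store()
  expect_equal(evaluate_query(st, q2)$patients,
               evaluate_query(st, q)$patients)

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(read_query(bad), class = "varfact_bad_params")

  ps <- evaluate_query(st, q)
  for (ext in c(".json", ".tsv")) {
    f <- withr::local_tempfile(fileext = ext)
    write_patient_set(ps, f)
    expect_equal(read_patient_set(f)$patients, ps$patients)
  }
})
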