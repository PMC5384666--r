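test_that("subset counts report cardinalities and overlap", {
  s1 <- patient_set(1L, set_id = "low")
  s2 <- patient_set(c(2L, 3L), set_id = "high")
  out <- subset_counts(s1, s2)
  expect_equal(out$n, c(1L, 2L))
  expect_false(attr(out, "overlap"))

  expect_warning(
    out2 <- subset_counts(patient_set(1:3), patient_set(2:4)),
    "overlap"
  )
  expect_true(attr(out2, "overlap"))

  empty <- subset_counts(patient_set(integer(0)), patient_set(integer(0)))
  expect_equal(empty$n, c(0L, 0L))
})

test_that("the Pearson statistic matches its closed form on a 2x2 table", {
  # n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)) for [[20,10],[10,20]] = 20/3
  ht <- chisq_homogeneity(matrix(c(20, 10, 10, 20), nrow = 2, byrow = TRUE))
  expect_equal(round(unname(ht$statistic), 4), 6.6667)
  expect_equal(unname(ht$parameter), 1)
})

breakdown_fixture <- function(pop_by_patient) {
  st <- fact_store()
  set_ontology(st, test_onto())
  n <- length(pop_by_patient)
  p <- register_patient(st, sprintf("S%02d", seq_len(n)))
  e <- register_encounter(st, p, "phenotypes")
  insert_facts(st, dplyr::bind_rows(
    lapply(seq_len(n), function(i) pop_fact(p[i], e[i], 1L, pop_by_patient[i]))
  ))
  st
}

test_that("categorical breakdown builds the contingency table and test", {
  # identical distributions: statistic 0, p 1
  st <- breakdown_fixture(rep(c("CEU", "YRI"), 10))
  s1 <- patient_set(1:10)
  s2 <- patient_set(11:20)
  rep0 <- categorical_breakdown(st, s1, s2, "\\Phenotype\\Population\\")
  expect_equal(rep0$statistic, 0)
  expect_equal(rep0$p_value, 1)

  # a distinct distribution moves the statistic off zero; df = (r-1)(c-1)
  st2 <- breakdown_fixture(c(rep("CEU", 12), rep("YRI", 3),
                             rep("CEU", 3), rep("YRI", 12)))
  repx <- categorical_breakdown(st2, patient_set(1:15), patient_set(16:30),
                                "\\Phenotype\\Population\\",
                                labels = c("low", "high"))
  expect_equal(unname(rowSums(repx$table)), c(15, 15))
  expect_equal(repx$df, 1)
  expect_gt(repx$statistic, 0)
  # invariance under swapping the subsets and permuting categories
  swap <- categorical_breakdown(st2, patient_set(16:30), patient_set(1:15),
                                "\\Phenotype\\Population\\")
  expect_equal(swap$statistic, repx$statistic)
  expect_equal(chisq_homogeneity(repx$table[, 2:1])$statistic,
               chisq_homogeneity(repx$table)$statistic)

  # one subset empty -> degenerate margin
  expect_error(
    categorical_breakdown(st2, patient_set(integer(0)), patient_set(1:15),
                          "\\Phenotype\\Population\\"),
    class = "varfact_degenerate_table"
  )

  # patients without a category fact are excluded and counted
  rep_excl <- categorical_breakdown(st2, patient_set(c(1:15, 999L)),
                                    patient_set(16:30),
                                    "\\Phenotype\\Population\\")
  expect_equal(rep_excl$n_excluded, 1L)
})

numeric_fixture <- function(values1, values2) {
  st <- fact_store()
  set_ontology(st, test_onto())
  n <- length(values1) + length(values2)
  p <- register_patient(st, sprintf("S%02d", seq_len(n)))
  e <- register_encounter(st, p, "phenotypes")
  vals <- c(values1, values2)
  insert_facts(st, dplyr::bind_rows(
    lapply(seq_len(n), function(i) ratio_fact(p[i], e[i], 1L, vals[i]))
  ))
  list(store = st,
       s1 = patient_set(seq_along(values1)),
       s2 = patient_set(length(values1) + seq_along(values2)))
}

test_that("numeric comparison runs Welch's t with degeneracy guards", {
  fx <- numeric_fixture(c(1, 2, 3, 4), c(1, 2, 3, 4))
  rep0 <- numeric_comparison(fx$store, fx$s1, fx$s2, RATIO_PATH)
  expect_equal(rep0$statistic, 0)
  expect_equal(rep0$p_value, 1)
  expect_equal(rep0$test_name, "t_welch")

  fx2 <- numeric_fixture(c(-0.5, -0.3, -0.4), c(0.4, 0.5, 0.6, 0.3))
  repx <- numeric_comparison(fx2$store, fx2$s1, fx2$s2, RATIO_PATH)
  want <- t.test(c(-0.5, -0.3, -0.4), c(0.4, 0.5, 0.6, 0.3))
  expect_equal(repx$statistic, unname(want$statistic))
  expect_equal(repx$df, unname(want$parameter))
  expect_equal(repx$p_value, want$p.value)

  fx3 <- numeric_fixture(0.5, c(1, 2, 3))
  expect_error(numeric_comparison(fx3$store, fx3$s1, fx3$s2, RATIO_PATH),
               class = "varfact_insufficient_data")

  # zero within-group variance with differing means: p -> 0 flag
  fx4 <- numeric_fixture(c(0, 0, 0, 0), c(1, 1, 1, 1))
  rep4 <- numeric_comparison(fx4$store, fx4$s1, fx4$s2, RATIO_PATH)
  expect_true(rep4$degenerate)
  expect_equal(rep4$test_name, "degenerate_variance")
  expect_equal(rep4$p_value, 0)
  expect_true(is.infinite(rep4$statistic))
})

test_that("null-simulated type-I error sits at the nominal level", {
  set.seed(2026)
  n_rep <- 2000
  p <- c(0.3, 0.4, 0.3)
  pvals <- vapply(seq_len(n_rep), function(i) {
    m <- t(cbind(rmultinom(1, 200, p), rmultinom(1, 200, p)))
    chisq_homogeneity(m)$p.value
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("reports expose tidy/glance/autoplot surfaces", {
  st <- breakdown_fixture(c(rep("CEU", 8), rep("YRI", 4),
                            rep("CEU", 4), rep("YRI", 8)))
  rep <- categorical_breakdown(st, patient_set(1:12), patient_set(13:24),
                               "\\Phenotype\\Population\\",
                               labels = c("low", "high"))
  td <- tidy(rep)
  expect_equal(names(td), c("subset", "category", "count"))
  expect_equal(sum(td$count), 24)
  gl <- glance(rep)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("statistic", "df", "p_value") %in% names(gl)))
  expect_s3_class(autoplot(rep), "ggplot")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_breakdown_tsv(rep, path)
  expect_equal(nrow(readr::read_tsv(path, show_col_types = FALSE)), 4)
})
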