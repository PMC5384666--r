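# Subset comparison layer: counts, categorical breakdown with Pearson
# chi-square (no continuity correction), numeric comparison with the Welch
# two-sample t-test. Both test variants are the modern defaults; the
# classical alternatives are switchable.

#' Subset cardinalities
#'
#' @param subset1,subset2 Two [patient_set()]s (typically disjoint; an
#'   overlap is flagged, not rejected).
#' @return Tibble with one row per subset (`label`, `n`); attribute
#'   `"overlap"` is `TRUE` if the subsets intersect.
#' @export
subset_counts <- function(subset1, subset2) {
  stopifnot(inherits(subset1, "patient_set"), inherits(subset2, "patient_set"))
  out <- tibble::tibble(
    label = c(subset1$set_id, subset2$set_id),
    n = c(length(subset1$patients), length(subset2$patients))
  )
  overlap <- length(intersect(subset1$patients, subset2$patients)) > 0
  if (overlap) rlang::warn("subsets overlap")
  attr(out, "overlap") <- overlap
  out
}

#' Pearson chi-square test of homogeneity
#'
#' Thin wrapper over [stats::chisq.test()] with the package's defaults
#' (no Yates continuity correction); exposed so the same statistic can be
#' checked on bare contingency matrices.
#'
#' @param m Contingency matrix (rows = subsets, columns = categories).
#' @param correct Apply the continuity correction (default `FALSE`).
#' @return `htest` object.
#' @export
chisq_homogeneity <- function(m, correct = FALSE) {
  suppressWarnings(stats::chisq.test(m, correct = correct))
}

new_subset_report <- function(...) {
  structure(list(...), class = "subset_report")
}

#' @export
print.subset_report <- function(x, ...) {
  cat("<subset_report: ", x$test_name, ">\n", sep = "")
  cat("  counts: ", paste(x$labels, x$counts, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$table)) {
    print(x$table)
  }
  cat("  statistic = ", format(x$statistic), ", df = ", format(x$df),
      ", p = ", format(x$p_value), "\n", sep = "")
  if (x$n_excluded > 0) {
    cat("  (", x$n_excluded, " patient(s) without the variable excluded)\n",
        sep = "")
  }
  invisible(x)
}

#' Categorical breakdown of two subsets
#'
#' Cross-tabulates the two subsets against the FLAG leaves under a
#' category node (e.g. the population folder) and runs a Pearson
#' chi-square test of homogeneity with `df = (r-1)(c-1)`. Patients with no
#' fact under the category are excluded listwise and counted in the
#' report. Categories observed in neither subset are dropped before
#' testing; a subset with no categorised patients makes the statistic
#' undefined and is rejected.
#'
#' @inheritParams insert_facts
#' @param subset1,subset2 Two [patient_set()]s.
#' @param category_path Concept path whose children are the category
#'   leaves (e.g. `"\\Phenotype\\Population\\"`).
#' @param labels Length-2 character vector naming the subsets.
#' @param correct Continuity correction (default `FALSE`).
#' @param onto Ontology; defaults to the store's.
#' @return A `subset_report` with the contingency `table`, `statistic`,
#'   `df`, `p_value`; see [tidy.subset_report()] / [glance.subset_report()].
#' @export
categorical_breakdown <- function(store, subset1, subset2, category_path,
                                  labels = c("subset1", "subset2"),
                                  correct = FALSE, onto = NULL) {
  onto <- onto %||% store_ontology(store)
  category_path <- norm_path(category_path)
  leaves <- dplyr::filter(
    onto$tree,
    startsWith(.data$path, category_path), .data$path != category_path
  )
  if (nrow(leaves) == 0) {
    vf_abort("unknown_path", paste0("no category leaves under ", category_path))
  }
  pf <- dplyr::filter(store$facts, .data$concept_cd %in% leaves$concept_cd,
                      .data$modifier_cd == "@")
  cat_of <- setNames(leaves$name, leaves$concept_cd)
  patient_cat <- dplyr::distinct(
    dplyr::mutate(pf, category = unname(cat_of[.data$concept_cd])),
    .data$patient_num, .data$category
  )

  count_row <- function(ps) {
    hits <- patient_cat[patient_cat$patient_num %in% ps$patients, ]
    list(
      counts = table(factor(hits$category, levels = sort(unique(leaves$name)))),
      n_excluded = length(setdiff(ps$patients, hits$patient_num))
    )
  }
  r1 <- count_row(subset1); r2 <- count_row(subset2)
  m <- rbind(as.integer(r1$counts), as.integer(r2$counts))
  dimnames(m) <- list(labels, names(r1$counts))
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (any(rowSums(m) == 0) || ncol(m) < 2) {
    vf_abort("degenerate_table",
      "a margin of the contingency table is all zero; statistic undefined")
  }
  ht <- chisq_homogeneity(m, correct = correct)
  new_subset_report(
    counts = c(length(subset1$patients), length(subset2$patients)),
    labels = labels, table = m,
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value,
    test_name = if (correct) "chisq_yates" else "chisq_pearson",
    n_excluded = r1$n_excluded + r2$n_excluded,
    degenerate = FALSE
  )
}

#' Numeric comparison of two subsets
#'
#' Compares the values of a NUMERIC concept between the two subsets with
#' the Welch two-sample t-test (Welch-Satterthwaite df, two-sided p);
#' `pooled = TRUE` switches to the classical equal-variance test. Patients
#' without a value are excluded listwise; each subset must retain at least
#' two. When both groups are (numerically) constant the t statistic is
#' undefined: equal means are reported as `statistic 0, p 1`, unequal
#' means as a degenerate-variance report with `p -> 0`.
#'
#' @inheritParams categorical_breakdown
#' @param concept_path Path of a NUMERIC concept.
#' @param pooled Use the pooled-variance t-test instead of Welch.
#' @return A `subset_report`.
#' @export
numeric_comparison <- function(store, subset1, subset2, concept_path,
                               labels = c("subset1", "subset2"),
                               pooled = FALSE, onto = NULL) {
  onto <- onto %||% store_ontology(store)
  codes <- resolve_subtree(onto, concept_path)
  vals <- dplyr::filter(store$facts, .data$concept_cd %in% codes,
                        .data$modifier_cd == "@", .data$valtype == "NUMERIC")
  vals <- dplyr::summarise(dplyr::group_by(vals, .data$patient_num),
                           value = mean(.data$nval), .groups = "drop")
  v1 <- vals$value[vals$patient_num %in% subset1$patients]
  v2 <- vals$value[vals$patient_num %in% subset2$patients]
  if (length(v1) < 2 || length(v2) < 2) {
    vf_abort("insufficient_data",
      "each subset needs at least 2 patients with a value")
  }
  n_excl <- (length(subset1$patients) - length(v1)) +
    (length(subset2$patients) - length(v2))
  test_name <- if (pooled) "t_pooled" else "t_welch"

  if (stats::sd(v1) == 0 && stats::sd(v2) == 0) {
    same <- isTRUE(all.equal(mean(v1), mean(v2)))
    return(new_subset_report(
      counts = c(length(subset1$patients), length(subset2$patients)),
      labels = labels, table = NULL,
      statistic = if (same) 0 else Inf * sign(mean(v1) - mean(v2)),
      df = NA_real_, p_value = if (same) 1 else 0,
      test_name = if (same) test_name else "degenerate_variance",
      n_excluded = n_excl, degenerate = !same
    ))
  }
  ht <- stats::t.test(v1, v2, var.equal = pooled)
  new_subset_report(
    counts = c(length(subset1$patients), length(subset2$patients)),
    labels = labels, table = NULL,
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value, test_name = test_name,
    n_excluded = n_excl, degenerate = FALSE
  )
}

#' Tidy subset reports
#'
#' `tidy()` returns the per-cell breakdown (for categorical reports: one
#' row per subset x category, bar-chart ready; for numeric reports the
#' subset sizes); `glance()` returns the one-row test summary.
#'
#' @param x A `subset_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.subset_report <- function(x, ...) {
  if (!is.null(x$table)) {
    as_tibble(as.data.frame(as.table(x$table), responseName = "count",
                            stringsAsFactors = FALSE),
              .name_repair = ~ c("subset", "category", "count"))
  } else {
    tibble::tibble(subset = x$labels, n = x$counts)
  }
}

#' @rdname tidy.subset_report
#' @export
glance.subset_report <- function(x, ...) {
  tibble::tibble(
    test = x$test_name, statistic = x$statistic, df = x$df,
    p_value = x$p_value, n1 = x$counts[1], n2 = x$counts[2],
    n_excluded = x$n_excluded, degenerate = x$degenerate
  )
}

#' Bar chart of a categorical breakdown
#'
#' Patient counts per category, dodged by subset — the chart the subset
#' comparison workflow produces for, e.g., population breakdowns.
#'
#' @param object A `subset_report` from [categorical_breakdown()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subset_report <- function(object, ...) {
  if (is.null(object$table)) {
    vf_abort("bad_params", "autoplot is defined for categorical reports")
  }
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$count,
                                   fill = .data$subset)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = NULL, y = "patients",
      subtitle = sprintf("%s: statistic = %.3f, df = %s, p = %.3g",
                         object$test_name, object$statistic,
                         format(object$df), object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Export a breakdown as bar-chart-ready TSV
#'
#' @param report A categorical `subset_report`.
#' @param path Output TSV path (columns `subset, category, count`).
#' @return The path, invisibly.
#' @export
write_breakdown_tsv <- function(report, path) {
  readr::write_tsv(tidy(report), path)
  invisible(path)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
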