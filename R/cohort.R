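# Synthetic Common-Task cohort generator: a multi-sample VCF, an
# ANNOVAR-like per-variant annotation TSV, and a phenotype CSV with a
# bimodal log protein ratio, plus an independent brute-force oracle that
# answers the four use cases by literal iteration over the raw tables.

#' Specify a synthetic cohort
#'
#' Defaults define the study conditions: 55 patients across CEU/CHB/YRI, a
#' two-component Gaussian mixture for the HLA-DQB1 log protein ratio, with
#' the lower mode enriched for damaging variants in the target gene, a
#' small synthetic hypertrophic-cardiomyopathy RS panel, and a background
#' of exonic variants across other genes. All distributional parameters
#' are generator choices; RS ids are synthetic (`rsSYN...`) so no real
#' dbSNP claim is implied.
#'
#' @param n_patients Cohort size (default 55).
#' @param population_weights Named sampling weights for CEU/CHB/YRI.
#' @param phenotype_mix List `means` (lower, upper), `sds`, `weight`
#'   (probability of the lower mode).
#' @param target_gene Gene symbol for use cases 1-3.
#' @param carrier_rates Named probabilities: `missense_lower_mode`,
#'   `missense_upper_mode` (per-mode probability of carrying a target-gene
#'   missense variant), `nonsense`, `synonymous` (mode-independent).
#' @param polyphen_beta_params List `damaging`, `benign`: Beta shape pairs
#'   for HDIV scores of damaging vs benign missense variants.
#' @param hcm_rs_list Character vector of panel RS ids.
#' @param hcm_carrier_freq Per-patient carrier probability for each panel
#'   RS id.
#' @param n_background_variants Number of background exonic variants.
#' @param seed Mandatory integer seed; outputs are byte-identical for an
#'   identical spec.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 55,
                        population_weights = c(CEU = 1, CHB = 1, YRI = 1) / 3,
                        phenotype_mix = list(means = c(-0.5, 0.5),
                                             sds = c(0.2, 0.2),
                                             weight = 0.5),
                        target_gene = "HLA-DQB1",
                        carrier_rates = c(missense_lower_mode = 0.6,
                                          missense_upper_mode = 0.15,
                                          nonsense = 0.1,
                                          synonymous = 0.3),
                        polyphen_beta_params = list(damaging = c(12, 1.5),
                                                    benign = c(1.5, 8)),
                        hcm_rs_list = sprintf("rsSYN9%05d", 1:5),
                        hcm_carrier_freq = 0.1,
                        n_background_variants = 120,
                        seed = NULL) {
  if (is.null(seed)) vf_abort("invalid_spec", "a seed is mandatory")
  if (n_patients < 0 || n_background_variants < 0) {
    vf_abort("invalid_spec", "sizes must be non-negative")
  }
  probs <- c(population_weights, carrier_rates, phenotype_mix$weight,
             hcm_carrier_freq)
  if (any(probs < 0 | probs > 1) ||
      abs(sum(population_weights) - 1) > 1e-8) {
    vf_abort("invalid_spec",
      "probabilities must lie in [0,1] and population weights sum to 1")
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      population_weights = population_weights,
      phenotype_mix = phenotype_mix,
      target_gene = target_gene,
      carrier_rates = carrier_rates,
      polyphen_beta_params = polyphen_beta_params,
      hcm_rs_list = hcm_rs_list,
      hcm_carrier_freq = hcm_carrier_freq,
      n_background_variants = as.integer(n_background_variants),
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# The target-gene variant panel: a handful of distinct coding variants a
# carrier is assigned to. Positions are synthetic coordinates on 6p21.
target_gene_variants <- function(spec) {
  tibble::tibble(
    chrom = "6",
    pos = 32660000L + c(11L, 23L, 37L, 52L, 68L, 81L),
    ref = c("A", "G", "C", "G", "T", "C"),
    alt = c("G", "A", "T", "T", "C", "G"),
    gene = spec$target_gene,
    feature = "exonic",
    func_class = c("nonsynonymous SNV", "nonsynonymous SNV",
                   "nonsynonymous SNV", "stopgain",
                   "synonymous SNV", "synonymous SNV"),
    role = c("missense_damaging", "missense_damaging", "missense_benign",
             "nonsense", "synonymous", "synonymous")
  )
}

hcm_gene_panel <- c("MYH7", "MYBPC3", "TNNT2", "TNNI3", "TPM1")

#' Generate a synthetic cohort
#'
#' Writes `cohort.vcf` (VCF 4.2, multi-sample, GT only),
#' `annotations.tsv`, `phenotypes.csv` and `truth.json` under `dir`, and
#' returns the paths together with the raw tables and the brute-force
#' ground truth. Identical spec (including seed) reproduces byte-identical
#' files.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if needed).
#' @param truth_params Parameters passed to [oracle_use_cases()] (gene,
#'   thresholds, rs list default to the spec's).
#' @return List: `vcf_path`, `annotation_path`, `phenotype_path`,
#'   `truth_path`, `truth` (a `ground_truth`), and the raw `tables`
#'   (`annotations`, `genotypes`, `phenotypes`).
#' @export
generate_cohort <- function(spec, dir, truth_params = list()) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  n <- spec$n_patients
  samples <- sprintf("SAMP%03d", seq_len(n))

  ## phenotypes -------------------------------------------------------------
  pops <- names(spec$population_weights)
  population <- if (n > 0) {
    sample(pops, n, replace = TRUE, prob = spec$population_weights)
  } else character(0)
  lower_mode <- runif(n) < spec$phenotype_mix$weight
  ratio <- round(rnorm(
    n,
    mean = ifelse(lower_mode, spec$phenotype_mix$means[1],
                  spec$phenotype_mix$means[2]),
    sd = ifelse(lower_mode, spec$phenotype_mix$sds[1],
                spec$phenotype_mix$sds[2])
  ), 4)
  phen <- tibble::tibble(
    source_id = samples, population = population,
    hladqb1_log_ratio = ratio
  )

  ## variant panel ----------------------------------------------------------
  tg <- target_gene_variants(spec)
  bp <- spec$polyphen_beta_params
  tg$polyphen_hdiv_score <- NA_real_
  is_mis <- startsWith(tg$role, "missense")
  dmg <- tg$role == "missense_damaging"
  tg$polyphen_hdiv_score[dmg] <-
    round(0.957 + rbeta(sum(dmg), bp$damaging[1], bp$damaging[2]) * 0.043, 3)
  ben <- tg$role == "missense_benign"
  tg$polyphen_hdiv_score[ben] <-
    round(rbeta(sum(ben), bp$benign[1], bp$benign[2]) * 0.45, 3)
  tg$rs_id <- sprintf("rsSYN1%05d", seq_len(nrow(tg)))

  n_hcm <- length(spec$hcm_rs_list)
  hcm <- if (n_hcm > 0) tibble::tibble(
    chrom = c("14", "11", "1", "19", "15")[((seq_len(n_hcm) - 1) %% 5) + 1],
    pos = 23412000L + 100L * seq_len(n_hcm),
    ref = rep(c("G", "C", "A", "T"), length.out = n_hcm),
    alt = rep(c("A", "T", "G", "C"), length.out = n_hcm),
    gene = hcm_gene_panel[((seq_len(n_hcm) - 1) %% 5) + 1],
    feature = "exonic",
    func_class = "nonsynonymous SNV",
    role = "hcm_panel",
    polyphen_hdiv_score = round(runif(n_hcm, 0.5, 0.99), 3),
    rs_id = spec$hcm_rs_list
  ) else NULL

  nb <- spec$n_background_variants
  bg <- if (nb > 0) {
    bg_chrom <- as.character(sample(1:22, nb, replace = TRUE))
    bg_class <- sample(
      c("nonsynonymous SNV", "synonymous SNV", "stopgain"),
      nb, replace = TRUE, prob = c(0.5, 0.4, 0.1)
    )
    bases <- c("A", "C", "G", "T")
    bg_ref <- sample(bases, nb, replace = TRUE)
    bg_alt <- vapply(bg_ref, function(b) sample(setdiff(bases, b), 1), "")
    tibble::tibble(
      chrom = bg_chrom,
      pos = sample.int(5e7, nb, replace = TRUE) + 1e6L,
      ref = bg_ref, alt = unname(bg_alt),
      gene = sprintf("GENE%03d", sample.int(60, nb, replace = TRUE)),
      feature = "exonic",
      func_class = bg_class,
      role = "background",
      polyphen_hdiv_score = ifelse(
        bg_class == "nonsynonymous SNV", round(runif(nb), 3), NA_real_),
      rs_id = ifelse(runif(nb) < 0.8, sprintf("rsSYN0%05d", seq_len(nb)),
                     NA_character_)
    )
  } else NULL

  ann <- dplyr::bind_rows(tg, hcm, bg)
  ann <- ann[!duplicated(ann[, c("chrom", "pos", "ref", "alt")]), ]
  ann <- dplyr::mutate(ann,
    polyphen_hdiv_pred = dplyr::case_when(
      is.na(.data$polyphen_hdiv_score) ~ NA_character_,
      .data$polyphen_hdiv_score >= 0.957 ~ "D",
      .data$polyphen_hdiv_score >= 0.453 ~ "P",
      TRUE ~ "B"
    )
  )
  ord <- order(suppressWarnings(as.integer(ann$chrom)), ann$pos, ann$alt)
  ann <- ann[ord, ]
  ann$vid <- seq_len(nrow(ann))

  ## genotypes --------------------------------------------------------------
  cr <- spec$carrier_rates
  gmat <- matrix(0L, nrow = nrow(ann), ncol = n)  # alt allele counts
  zygosity <- function(k) ifelse(runif(k) < 0.1, 2L, 1L)
  assign_carriers <- function(role_rows, carrier) {
    k <- sum(carrier)
    if (length(role_rows) == 0 || k == 0) return(invisible())
    rows <- role_rows[sample.int(length(role_rows), k, replace = TRUE)]
    z <- zygosity(k)
    cols <- which(carrier)
    for (t in seq_len(k)) gmat[rows[t], cols[t]] <<- z[t]
  }
  if (n > 0) {
    mis_rows <- ann$vid[ann$role %in% c("missense_damaging", "missense_benign")]
    p_mis <- ifelse(lower_mode, cr["missense_lower_mode"],
                    cr["missense_upper_mode"])
    assign_carriers(mis_rows, runif(n) < p_mis)
    assign_carriers(ann$vid[ann$role == "nonsense"], runif(n) < cr["nonsense"])
    assign_carriers(ann$vid[ann$role == "synonymous"],
                    runif(n) < cr["synonymous"])
    for (i in ann$vid[ann$role == "hcm_panel"]) {
      carrier <- runif(n) < spec$hcm_carrier_freq
      gmat[i, carrier] <- zygosity(sum(carrier))
    }
    bg_rows <- ann$vid[ann$role == "background"]
    if (length(bg_rows) > 0) {
      af <- runif(length(bg_rows), 0.05, 0.4)
      gmat[bg_rows, ] <- vapply(seq_len(n), function(j) {
        rbinom(length(bg_rows), 2L, af)
      }, integer(length(bg_rows)))
    }
  }
  gt_chr <- matrix(c("0/0", "0/1", "1/1")[gmat + 1L], nrow = nrow(ann))

  genotypes <- tibble::tibble(
    vid = rep(ann$vid, times = n),
    source_id = rep(samples, each = nrow(ann)),
    alt_count = as.vector(gmat)
  )

  ## write files ------------------------------------------------------------
  vcf_path <- file.path(dir, "cohort.vcf")
  annotation_path <- file.path(dir, "annotations.tsv")
  phenotype_path <- file.path(dir, "phenotypes.csv")
  truth_path <- file.path(dir, "truth.json")

  keep <- rowSums(gmat) > 0  # VCF carries only observed variants
  vcf_header <- c(
    "##fileformat=VCFv4.2",
    "##source=varfact-synthetic-cohort",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- if (any(keep)) {
    paste(
      ann$chrom[keep], ann$pos[keep],
      ifelse(is.na(ann$rs_id[keep]), ".", ann$rs_id[keep]),
      ann$ref[keep], ann$alt[keep], ".", "PASS", ".", "GT",
      apply(gt_chr[keep, , drop = FALSE], 1, paste, collapse = "\t"),
      sep = "\t"
    )
  } else character(0)
  if (n == 0) {
    body <- character(0)
    vcf_header[4] <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                             "FILTER", "INFO"), collapse = "\t")
  }
  writeLines(c(vcf_header, body), vcf_path)

  ann_out <- dplyr::mutate(
    ann[keep, c("chrom", "pos", "ref", "alt", "gene", "feature", "func_class",
                "rs_id", "polyphen_hdiv_score", "polyphen_hdiv_pred")],
    rs_id = ifelse(is.na(.data$rs_id), ".", .data$rs_id),
    polyphen_hdiv_score = ifelse(is.na(.data$polyphen_hdiv_score), ".",
                                 sprintf("%.3f", .data$polyphen_hdiv_score)),
    polyphen_hdiv_pred = ifelse(is.na(.data$polyphen_hdiv_pred), ".",
                                .data$polyphen_hdiv_pred)
  )
  readr::write_tsv(ann_out, annotation_path)
  readr::write_csv(
    dplyr::mutate(phen,
                  hladqb1_log_ratio = sprintf("%.4f", .data$hladqb1_log_ratio)),
    phenotype_path
  )

  tables <- list(annotations = ann, genotypes = genotypes, phenotypes = phen)
  truth <- rlang::exec(oracle_use_cases, tables = tables,
                       !!!utils::modifyList(
                         list(gene = spec$target_gene,
                              rs_list = spec$hcm_rs_list),
                         truth_params))
  jsonlite::write_json(
    purrr::map(truth$sets, identity), truth_path, auto_unbox = FALSE
  )
  list(
    vcf_path = vcf_path, annotation_path = annotation_path,
    phenotype_path = phenotype_path, truth_path = truth_path,
    truth = truth, tables = tables
  )
}

#' Brute-force use-case oracle
#'
#' Answers the four Common-Task use cases by literal set comprehension
#' over the raw generated tables — no ontology, no store, no views — the
#' role the original validation scripts played. Derived exclusively from
#' the generator's tables, never from the engines under test.
#'
#' @param tables List with `annotations` (per-variant, including `role`
#'   column-free fields `gene`, `func_class`, `rs_id`,
#'   `polyphen_hdiv_score`, `vid`), `genotypes` (long `vid, source_id,
#'   alt_count`), `phenotypes` (`source_id, population,
#'   hladqb1_log_ratio`).
#' @param gene Target gene symbol.
#' @param ratio_threshold Lower-mode cut-off (default 0).
#' @param polyphen_threshold Probably-damaging HDIV cut-off (default
#'   0.957).
#' @param rs_list Panel RS ids for use case 4.
#' @param missense_classes,nonsense_classes Annotation vocabulary counted
#'   as missense / nonsense.
#' @return A `ground_truth`: list with `sets` (named list `uc1`..`uc4b`
#'   of source-id vectors; 3a/3b are the YRI and CEU restrictions of case
#'   1) and the `params` used.
#' @export
oracle_use_cases <- function(tables, gene, ratio_threshold = 0,
                             polyphen_threshold = 0.957,
                             rs_list = character(0),
                             missense_classes = c("nonsynonymous SNV",
                                                  "missense_variant"),
                             nonsense_classes = c("stopgain", "stop_gained")) {
  ann <- tables$annotations
  gt <- tables$genotypes
  ph <- tables$phenotypes

  carriers_of <- function(vids) {
    unique(gt$source_id[gt$vid %in% vids & gt$alt_count > 0])
  }
  low <- ph$source_id[!is.na(ph$hladqb1_log_ratio) &
                        ph$hladqb1_log_ratio < ratio_threshold]

  uc1_vars <- ann$vid[ann$gene == gene &
                        ann$func_class %in% c(missense_classes,
                                              nonsense_classes)]
  uc1 <- intersect(low, carriers_of(uc1_vars))

  uc2_vars <- ann$vid[ann$gene == gene &
                        ann$func_class %in% missense_classes &
                        !is.na(ann$polyphen_hdiv_score) &
                        ann$polyphen_hdiv_score >= polyphen_threshold]
  uc2 <- intersect(low, carriers_of(uc2_vars))

  pop_of <- setNames(ph$population, ph$source_id)
  uc3a <- uc1[pop_of[uc1] == "YRI"]
  uc3b <- uc1[pop_of[uc1] == "CEU"]

  uc4_vars <- ann$vid[!is.na(ann$rs_id) & ann$rs_id %in% rs_list]
  uc4 <- carriers_of(uc4_vars)

  structure(
    list(
      sets = list(uc1 = sort(uc1), uc2 = sort(uc2), uc3a = sort(uc3a),
                  uc3b = sort(uc3b), uc4 = sort(uc4)),
      params = list(gene = gene, ratio_threshold = ratio_threshold,
                    polyphen_threshold = polyphen_threshold,
                    rs_list = rs_list)
    ),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ",
      paste(names(x$sets), lengths(x$sets), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Phenotype mixture plot for a generated cohort
#'
#' Histogram of the log protein ratio coloured by population; the two
#' modes of the mixture are what the lower-mode use cases threshold on.
#'
#' @param cohort Result of [generate_cohort()].
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_cohort_phenotypes <- function(cohort, bins = 20) {
  ph <- cohort$tables$phenotypes
  ggplot2::ggplot(ph, ggplot2::aes(x = .data$hladqb1_log_ratio,
                                   fill = .data$population)) +
    ggplot2::geom_histogram(bins = bins, colour = "grey30") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "log protein ratio", y = "patients") +
    ggplot2::theme_minimal()
}
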