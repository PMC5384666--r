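#' @keywords internal
"_PACKAGE"

#' @import rlang
#' @importFrom dplyr filter mutate select arrange group_by ungroup summarise
#'   left_join inner_join anti_join semi_join bind_rows distinct pull n rename
#'   row_number across all_of first slice
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_int map_lgl map_dbl pmap imap keep
#' @importFrom stats rnorm runif rbinom rbeta setNames chisq.test t.test
#'   rmultinom
#' @importFrom utils head
NULL

# Condition helper: every user-facing failure carries a varfact_* class so
# callers (and the CLI) can branch on it.
vf_abort <- function(class, message, ...) {
  rlang::abort(message, class = c(paste0("varfact_", class), "varfact_error"), ...)
}

#' Normalise chromosome names
#'
#' Strips a leading `"chr"` prefix so that `"chr1"` and `"1"` join as the
#' same contig.
#'
#' @param chrom Character vector of chromosome names.
#' @return Character vector without the `chr` prefix.
#' @export
normalize_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom))
}

# Variant key used for joins and document ids.
variant_key <- function(chrom, pos, ref, alt) {
  paste(normalize_chrom(chrom), pos, ref, alt, sep = ":")
}

# A genotype string carries the alt allele iff any allele index is >= 1.
gt_is_carrier <- function(gt) {
  !is.na(gt) & vapply(
    strsplit(as.character(gt), "[/|]"),
    function(a) any(suppressWarnings(as.integer(a)) >= 1L, na.rm = TRUE),
    logical(1)
  )
}

`%||%` <- rlang::`%||%`
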