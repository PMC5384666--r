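---
title: "Methods: representing and querying genotype-phenotype data as observation facts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: representing and querying genotype-phenotype data as observation facts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varfact)
library(dplyr)
```

## The representation model

varfact stores every observation about a patient — a lab value, a
population label, an observed sequence variant — as rows of a single
star-schema fact table in modified entity–attribute–value form. A fact row
carries a patient id, an encounter id, a concept code, a modifier code
(the i2b2 sentinel `"@"` meaning "no modifier"), an instance number, and a
typed value (`NONE`, `NUMERIC` with `nval`, or `TEXT` with `tval`; numeric
facts set the comparison flag `tval = "E"`).

The instance number is what makes variant data representable at all: the
several rows describing one observed variant share an instance number
within their encounter and so form an *n-tuple*. For an exome-style
workload with gene, function, RS and PolyPhen annotations, each observed
patient variant becomes at least a **six-tuple**:

1. a base fact whose concept is the variant type (an SNV, insertion or
   deletion accession from the Sequence Ontology), modifier `"@"`;
2. a feature modifier (e.g. *exon*);
3. a function modifier (e.g. *missense_variant*, *stop_gained*);
4. a gene-symbol modifier (TEXT value);
5. a dbSNP RS modifier (TEXT value, present only when the variant has an
   RS id);
6. a PolyPhen-2 HDIV modifier (NUMERIC score in [0, 1], present only when
   scored).

One encounter represents one genomic input file for one patient, so
instance numbers only need to be unique within a file load; they are
allocated sequentially in input order, which keeps identifiers
reproducible across reloads. Patient and encounter ids are dense integers
assigned in registration order for the same reason.

The concept dimension is a tree in i2b2 path notation
(`\Genomics\VariantType\SNV\`). Variant types are *concepts*; variant
effects and features are *modifier* nodes, because they qualify a base
variant observation rather than stand alone. The packaged mapping
(`inst/extdata/ontology.yaml`) carries a curated subset of Sequence
Ontology accessions plus an explicit synonym table from ANNOVAR-style
vocabulary (`"nonsynonymous SNV"`, `"stopgain"`, ...) to SO terms. The
file is config-replaceable: nothing in the toolkit depends on the
specific accessions, only on the maps being injective. Unmapped classes
fail loudly (`UnmappedEffect`) rather than silently dropping facts — in a
warehouse, silent data loss is the worst failure mode.

## The ETL and its GVF dialect

The load path is VCF → annotated records → GVF-like intermediate → fact
stream. VCF parsing is delegated to `vcfR`; multi-allelic lines are split
into one record per alternate allele with genotypes recoded against that
allele, and only variants with at least one called non-reference genotype
survive (a variant nobody carries is not an observation about anyone).
The annotation join is strict on `(chrom, pos, ref, alt)` with
`chr`-prefix normalisation; in lenient mode unmatched variants go to a
skip report instead.

The GVF intermediate is a 9-column GFF3 skeleton whose types are SO term
names. VCF anchor bases are stripped, because GVF describes the changed
sequence only:

* SNV: `start = end = pos`;
* deletion: `start = pos + 1`, `end = pos + len(ref) - 1`,
  `Reference_seq` without the anchor;
* insertion: `start = pos + 1`, `end = pos` (zero-length interval),
  `Variant_seq` without the anchor.

Complex substitutions (`AT→GC`) have no single SO type in this dialect
and are routed to the skip report rather than guessed. Per-sample
genotypes travel alongside the GVF records, not inside their attributes:
GVF describes variants, and which patient carries one is the fact
table's business. Zygosity is deliberately not stored as a fact —
carrier status (≥ 1 alternate allele) is what every supported query
needs; recording it as an extra modifier would be a one-line extension
of the expansion table.

Fact expansion replicates variant-level annotation once per carrier, so
total fact volume is exactly `sum over carriers of
(4 + has_rs + has_polyphen)` and grows linearly in carrier count. The
test suite asserts this identity against a brute-force recount, and
`annotation_volume()` exposes the simpler pre-expansion arithmetic
(unique variants × characteristics per variant).

## Panel query semantics

A query is a list of panels; items within a panel are ORed, panels are
ANDed. Three refinements matter:

* **Same-instance groups.** Panels sharing an `instance_group` must be
  satisfied by one `(patient, encounter, instance)` key — i.e. by the
  same variant n-tuple. Without this join, "missense" and "in gene X"
  could be satisfied by two different variants; the toy fixture in the
  test suite demonstrates the leakage. Joining on the full instance key
  (not merely the patient) is the load-bearing design decision of the
  whole representation.
* **Exclusions are patient-level.** An exclude panel removes any patient
  with *any* matching fact (the i2b2 default), not instance-level
  non-matches. Exclude panels therefore cannot join instance groups.
* **Value constraints** apply on `nval` for numeric facts (exact decimal
  comparison, `BETWEEN` inclusive) and on `tval` for text facts; flag
  facts match unconditionally. A numeric operator aimed at a TEXT concept
  is a `TypeMismatch` error, not an empty result.

The "probably damaging" PolyPhen-2 cut-off defaults to 0.957, the
published HDIV threshold for the top category, and is a parameter
everywhere it appears. The protein-ratio threshold likewise defaults to 0
(the boundary between the two modes of the log-ratio mixture) and is a
parameter, since reasonable deployments may draw the line elsewhere.

`evaluate_reference()` is a second, deliberately naive interpreter (per
patient, per fact row, literal) kept free of the vectorised evaluation
code; the suite checks both agree on hundreds of random (cohort, query)
pairs.

## The document backend

The same records can be loaded as one flat JSON document per
(patient, variant), with precomputed per-field **views** — sorted
value-to-document indexes built at load time, in the manner of document
databases where query-time work happens only against indexes. Filtering
on a field that was not declared when the views were built is an
`UnindexedField` error in strict mode; this reproduces, honestly, the
operational property that the genotype query must be anticipated at
upload time. Lenient mode falls back to a scan.

A filter chain starts from a phenotype-derived patient set (produced by
the panel engine) and applies blocks sequentially; after block *k* the
survivors are the patients owning at least one document satisfying blocks
1..*k* *simultaneously*. This per-document conjunction mirrors the star
store's same-instance semantics — a single variant must meet all genomic
constraints — and makes block order irrelevant to the final patient set,
which the suite asserts. The alternative (per-patient conjunction, where
different blocks may be satisfied by different variants) would diverge
from the panel engine on exactly the cases the instance join exists for.

## Subset statistics

The comparison layer takes two patient sets and a concept. Categorical
breakdowns cross-tabulate FLAG leaves under a category node and run a
Pearson chi-square test of homogeneity **without** continuity correction;
numeric comparisons run the **Welch** two-sample t-test. Both are the
modern defaults; Yates correction and the pooled-variance t are available
behind flags since the classical variants are defensible. Patients
missing the category or value are excluded listwise and counted in the
report. Degenerate inputs are reported, not fudged: an all-zero margin
raises `DegenerateTable`; two constant groups with equal means give
statistic 0 and p 1, with differing means a flagged degenerate-variance
report with p → 0. A 2000-replicate null simulation (both subsets drawn
from one multinomial, 200 patients per subset, three categories) keeps
the empirical type-I error within 0.05 ± 0.02.

## The synthetic cohort generator

The generator emulates the shape of a small multi-population exome cohort
with a cellular phenotype; its defaults are fixed study conditions, not
tuning knobs:

| parameter | default | why |
|---|---|---|
| patients | 55 | the reference cohort size for desk-scale validation |
| population weights | CEU/CHB/YRI equal | no reason to prefer one label |
| log-ratio mixture | N(−0.5, 0.2) / N(+0.5, 0.2), weight 0.5 | clearly bimodal with a natural boundary at 0 |
| target-gene missense carrier rate | 0.6 lower mode / 0.15 upper | the lower mode should be visibly enriched, not exclusive |
| nonsense / synonymous rates | 0.1 / 0.3 | rare truncating, common silent |
| PolyPhen scores | damaging ≥ 0.957 via scaled Beta(12, 1.5); benign Beta(1.5, 8) × 0.45 | damaging variants must clear the published threshold, benign ones must not |
| HCM panel | 5 synthetic RS ids at carrier frequency 0.1 | "previously implicated, surprisingly prevalent" panel behaviour |
| background variants | 120 | enough cross-gene noise to catch leakage bugs at interactive test speed |

RS identifiers are synthetic (`rsSYN...`) so no real dbSNP claim is
implied; a user's own panel RS ids are accepted verbatim. Scores and
ratios are rounded (3 and 4 decimals) before writing so that files are
byte-stable and the values read back equal the values the ground truth
was computed from.

What the generator does *not* emulate: linkage disequilibrium, realistic
site-frequency spectra, indel-rich regions, multi-allelic complexity
beyond what the splitter handles, or exome scale (it supports large
`n_background_variants`, but the defaults are desk-scale). Passing tests
therefore demonstrate the *semantics* of the three integration paths —
that fact n-tuples, panel queries, document chains and the brute-force
oracle agree — not performance or robustness on production exomes.

`oracle_use_cases()` answers the four benchmark use cases by literal set
comprehension over the raw generated tables, with no ontology, store or
views involved; it is the reimplementation of the role shell-script
validation plays in practice, and the three-way agreement check
(panel engine ≡ document chain ≡ oracle on 50 seeded cohorts, all four
use cases) is the package's headline property.

## Numerical and engineering choices

* The store is an environment-backed object holding tibbles, persisted as
  plain TSV; the semantics (uniqueness key, modifier/instance audit,
  dense ids) are the contract, not the storage engine.
* All randomness flows from a single mandatory seed; generation is
  byte-identical given an identical spec.
* Numeric query comparison is exact (no epsilon): values are rounded once
  at generation/serialisation, so equality is well-defined.
* Ties and orderings are made deterministic everywhere results surface:
  patient sets sort by `patient_num`, subtree resolution by path,
  n-tuples base-row-first then `(concept_cd, modifier_cd)`.
* Problem sizes in the shipped checks: 50 × 55-patient cohorts for the
  agreement sweep, 10 × 12-patient cohorts × 20 random queries for the
  interpreter equivalence, 2000 replicates for the chi-square null —
  sizes chosen to exercise every code path many times while keeping the
  default test run interactive.

## Known limitations

* Carrier-status-only genotype facts: homozygous and heterozygous
  carriers are indistinguishable in queries (by design, see above).
* The panel engine evaluates in memory; it is a semantics reference, not
  a scale demonstration. Nothing here addresses concurrent loads or
  server deployment.
* The chi-square layer inherits the usual small-expected-count caveats of
  the Pearson statistic; it reports, but does not switch to, exact tests.
* Phenotype support is one numeric concept per column plus one
  categorical (population) axis; richer phenotype ontologies would need
  only config, but richer *temporal* semantics (dates, visit windows)
  are out of scope entirely.

## A worked example

```{r example}
onto <- load_ontology()
spec <- cohort_spec(seed = 7)
cohort <- generate_cohort(spec, tempfile("cohort"))

st <- fact_store()
counts <- load_cohort(st, cohort$vcf_path, cohort$annotation_path,
                      cohort$phenotype_path, onto)
counts[c("patients", "phenotype_facts", "variant_facts")]

uc1 <- evaluate_use_case(st, 1, list(gene = "HLA-DQB1"))
uc1

# the document route answers the same question from the same seed set
records <- read_annotated_variants(cohort$vcf_path, cohort$annotation_path)
ds <- build_views(build_documents(records, counts$sample_map))
docstore_use_case(st, ds, 1, list(gene = "HLA-DQB1"))$patients

# and the brute-force oracle agrees
cohort$truth$sets$uc1
```

```{r breakdown, fig.width = 5, fig.height = 3}
low <- evaluate_query(st, query_definition(list(panel(panel_item(
  "\\Phenotype\\ProteinLevels\\HLA-DQB1 log protein ratio\\",
  "BASE", "LT", 0)))))
high <- evaluate_query(st, query_definition(list(panel(panel_item(
  "\\Phenotype\\ProteinLevels\\HLA-DQB1 log protein ratio\\",
  "BASE", "GE", 0)))))
rep <- categorical_breakdown(st, low, high, "\\Phenotype\\Population\\",
                             labels = c("lower mode", "upper mode"))
glance(rep)
autoplot(rep)
```
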