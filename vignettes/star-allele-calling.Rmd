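---
title: "Star-allele calling from phased genotypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Star-allele calling from phased genotypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(starcallr)
library(dplyr)
```

## The problem

Pharmacogenes are reported clinically as *star alleles*: named haplotypes
defined by sets of variants that must co-occur on the same parental
chromosome. An individual's unordered pair of star alleles (the *diplotype*)
maps to a metabolizer phenotype — poor, intermediate, normal, rapid,
ultrarapid, or gene-specific categories such as dose or response phenotypes —
which in turn drives dosing guidance. Biobanks and clinical cohorts hold
phased, imputed genotype data (arrays or sequencing) that can be translated
into such reports at scale, but the translation has many sharp edges:
definition tables contain redundant and unvalidated alleles, array platforms
miss defining variants, imputation is imperfect, and CYP2D6 carries
whole-gene deletions and duplications that variant-level data cannot see.

`starcallr` implements that translation end to end: curated definition
tables, a phased-VCF reader with an imputation-probability filter, a
haplotype-to-allele match ladder, copy-number integration, diplotype-to-
phenotype mapping, and cohort-level frequency and impact statistics, plus a
seed-deterministic synthetic-cohort generator with ground truth so the whole
pipeline is testable without access to restricted cohort data.

## Definition tables and curation

A definition table is a per-gene matrix: one row per star allele, one column
per defining variant (GRCh37 coordinates, forward strand), cells stating the
required state (`ref`, `alt`, or blank = not required). The reference allele
(`*1` by convention) is the row with no requirements and normal function.
The package defines its own documented TSV dialect rather than parsing any
particular registry export, whose formatting varies by download date; the
dialect captures the same content (see `parse_definition_table()`).

Raw tables are deliberately over-complete, so calling against them produces
ambiguity (several alleles matching one haplotype) and no-matches (observed
variant combinations matching no allele). Curation directives encode the
manual pruning that fixes this, as data rather than code:

* `drop_allele` — remove unknown-function alleles and redundant proxies;
* `merge_alleles` — collapse suballeles (e.g. `*9A`/`*9B` into `*9`). The
  merged allele keeps the **shared core** of the source definitions (their
  intersection), after checking that no variant is required in opposite
  states. The intersection, not the union, is kept so the merged allele
  matches wherever any source matched — exactly the behaviour wanted when
  suballeles differ only by proxy variants;
* `drop_variant_from_allele` — keep a single tag variant when an allele's
  defining variants are in complete LD (the package does not compute LD; the
  reduction arrives as a directive);
* `drop_structural_for_platform` — remove deletion/duplication alleles on
  platforms that cannot support copy-number detection.

Unused variants are pruned after curation, so platform typability reports
(`typability_report()`) reflect the curated panel. A directive naming an
absent target is an error under `strict = TRUE` (the default, to catch
typos); with `strict = FALSE` applied directives become no-ops, which makes
curation idempotent.

## Genotype handling

`read_phased_vcf()` reads GT fields (first field = haplotype A), decomposes
multi-allelic records into biallelic site records, maps `./.` to missing, and
reads per-genotype provenance (genotyped vs imputed) from a configurable
FORMAT tag plus the best-genotype posterior probability from `GP`. Two
contracts matter downstream:

* **Probability filter** (`apply_probability_filter()`): imputed genotypes
  with best-genotype probability *strictly below* 0.90 (configurable) are set
  to missing; directly genotyped calls are exempt whatever their annotation.
* **Source preference** (`merge_sources()`): where a (sample, variant) key is
  both genotyped and imputed, the genotyped call wins.

The two operations commute, which the test suite asserts property-style.
Projection onto a table (`build_sample_haplotypes()`) yields state vectors
over exactly the table's variants, with untyped positions missing on both
haplotypes. Unphased heterozygotes are tolerated only when a sample has at
most one among the table's variants (phase is then irrelevant); otherwise
haplotype assignment would be arbitrary, and the package raises an error
rather than guessing — the pipeline assumes phased input.

## The match ladder

For each haplotype, every non-structural allele is tested for the presence of
all of its defining states. Two semantics decisions are load-bearing:

* **Missing never satisfies a requirement.** Requirements are met only by
  observed states. A companion *compatible set* (no observed contradiction;
  missing tolerated) is computed and reported with ambiguous calls so that
  missingness-driven ambiguity stays visible — but a compatible-only allele
  is never called positively. This prevents silent false positives while
  still surfacing the ambiguity structure of incomplete data.
* **The reference allele matches iff no alternate state is observed.** A
  reference call made while table variants are missing carries an explicit
  wild-type disclaimer flag: wild-type status is only asserted at the
  interrogated sites, and an uninterrogated site may always harbour
  undiscovered loss of function.

Resolution then runs a priority ladder:

1. **Nonfunctional first.** Only `no_function` alleles are tested; any full
   match resolves the haplotype there. Several nonfunctional matches are
   tie-broken by largest definition, then label (the tie-break is a package
   decision — documented, deterministic, and configurable in principle;
   genuinely simultaneous nonfunctional matches are rare and function-
   equivalent). A flag (`nonfunctional_semantics = "compatible"`) lets pass 1
   use no-contradiction semantics instead; the default is full-match, the
   conservative reading.
2. **Remaining alleles.** One match → `single`. Multiple matches whose
   definitions are pairwise disjoint and jointly explain every observed
   alternate state → `composite`: two named alleles on the same physical
   haplotype, reported with a `+`-joined label and the most severe member's
   function class (severity order: no function > decreased > normal >
   increased). Otherwise, if exactly one match has decreased function and the
   rest are normal, the decreased allele overrides. Anything left is
   `ambiguous` (candidates retained); no candidates with at least one
   observed alternate state is `no_match`.

The composite branch is checked **before** the decreased-function override.
The ordering matters: a haplotype genuinely carrying a decreased-function
allele and a normal allele at disjoint positions is a composite observation,
not an ambiguity for the override to settle; running the override first would
make such composites unreportable. The override exists for overlapping
definitions, where the composite condition cannot hold.

Calling is deterministic: identical inputs give identical calls, and the
cohort-level caller resolves each distinct haplotype pattern once.

## Copy-number integration

Whole-gene deletions and duplications arrive as per-sample calls (discovery
is out of scope). For a **deletion**, one haplotype label is replaced by the
deletion allele (`*5` for CYP2D6-style genes): the reference-labelled
haplotype when present — a deleted copy carries no observed alternate states,
so it presents as reference — otherwise the lower-severity label, with the
record flagged, since imputed data can be inconsistent with the CNV call.
For a **duplication**, the first label of the priority order `*2 > *1 > *4`
(reflecting previously reported European duplication frequencies, and
configurable) present in the pair gains the `xN` suffix; if neither is
present, the higher-severity label gains it and the record is flagged.
Copy numbers above 3 are duplications with the extra copies unannotated,
matching star-nomenclature convention. Multiallelic CNV records beyond
deletion/duplication are passed through flagged. Requesting CNV integration
on a platform without copy-number support is a configuration error.

## Phenotypes

All possible diplotypes are constructed as the unordered Cartesian product of
each haplotype's possibilities (resolved label, or candidate set when
ambiguous). Keys are normalised by a documented collation — numeric star
order, then suffix — so `*1/*2` and `*2/*1` are byte-identical. Lookup in the
diplotype-to-phenotype map is *determinate* only when every candidate
diplotype is mapped and all agree; this reproduces the useful behaviour that
ambiguity among same-function alleles does not block phenotype prediction.
Composite (`*2+*3`) and duplicated (`*2xN`) labels require explicit map
entries; anything else is indeterminate, never guessed. High-risk flagging is
set-membership against the gene's declared normal labels; indeterminate calls
yield `NA`, not a boolean, and never count as at-risk in cohort fractions.

## Cohort statistics

Frequencies are tallied per gene over haplotypes (alleles, statuses) and
samples (diplotypes, phenotypes), each category normalised to 1. Printed
percentages round half away from zero (`round_half_out()`), matching the
worked figures the package reproduces (e.g. 307 of 356 variants → 86%; 1073
of 32,369 deletion carriers → 3.31%).

The one-proportion z-test uses `z = (p̂ − p0)/√(p0(1−p0)/n)` with the
two-sided tail evaluated in log space (`pnorm(log.p = TRUE)`), so comparisons
at biobank scale — |z| near 27 gives p-values around 10⁻¹⁵⁴ — retain their
magnitude as `log10_p` instead of underflowing; `p.adjust`-style corrections
are deliberately not applied (raw p-values are reported, documented).
Reference population frequencies are user-supplied inputs, not bundled.
Drug-consumption impact multiplies population exposure (DDD/1000
inhabitants/day, a WHO unit) by the high-risk fraction; portfolio impact sums
per-drug products.

## The synthetic-cohort generator

`simulate_cohort()` emulates every input the pipeline consumes, with ground
truth: per-gene definition tables, phased VCF with per-genotype origin and GP
annotations, CNV calls, and complete phenotype maps. Design choices:

* **Haplotype independence.** Labels are drawn per haplotype from the allele
  frequency vector (Hardy–Weinberg); real LD structure and population
  stratification are not modelled — a documented limitation. Passing
  recovery tests therefore demonstrates correctness of the calling logic
  under the stated missingness/imputation conditions, not robustness to real
  LD pathologies.
* **Default conditions.** The three-gene default spec
  (`default_simulation_spec()`) mirrors the observed study conditions: a
  CYP2D6-like gene with deletion and duplication carrier rates of 3.31% and
  0.79%; a dose-style gene whose two single-variant alleles co-occur on one
  haplotype at a per-haplotype rate of 0.0806, so 15.5% of individuals carry
  the composite; and a metabolizer gene with nonfunctional, decreased and
  increased alleles at frequencies typical of European cohorts.
* **GP noise.** Imputed-site probabilities are drawn from a mixture: 95%
  uniform on [0.90, 1.0] (imputation of common pharmacogene variants is
  near-perfect) and 5% uniform on [0.50, 0.90), exercising the strict filter.
* **Simulated tables** give each named allele its own disjoint defining
  variants, so synthetic alleles are separable and composable; the
  overlapping-definition pathologies that curation removes in real tables are
  constructed explicitly in the test fixtures instead.
* **Deletions** present as an all-reference haplotype in the VCF with the
  deletion label recorded in truth, consistent with the integration rule.
* **Determinism.** One seed governs every draw; identical specs produce
  byte-identical VCF, CNV and truth files.
* **Phenotype maps** are generated from an activity-score emulation
  (no function 0, decreased 0.5, normal 1, increased 1.5; `xN` doubles;
  composites take the most severe member; pair sums map to the metabolizer
  scale). This yields complete, internally consistent maps of the right
  shape; it is not a clinical map.

## Worked example

```{r example}
spec <- default_simulation_spec(n_samples = 300, seed = 2026)
sim <- simulate_cohort(spec)
res <- call_pgx_cohort(sim$vcf, sim$tables, sim$maps, cnv = sim$cnv)
summary <- summarize_cohort(res$haplotypes, res$phenotypes)
glance(summary)
tidy(summary) |> filter(category == "status") |> head()
```

Against the generator's truth, a fully typed cohort recovers diplotypes and
phenotypes exactly:

```{r recovery}
called <- res$haplotypes |>
  group_by(sample, gene) |>
  summarise(dip = diplotype_key(resolved_label[haplotype == "A"],
                                resolved_label[haplotype == "B"]),
            .groups = "drop") |>
  inner_join(sim$truth, by = c("sample", "gene"))
mean(called$dip == called$diplotype)
```

## Problem sizes and numerical checks

The shipped test suite validates candidate matching against an exhaustive
per-allele oracle on 10,000 randomised (table, haplotype) instances (tables
up to 12 variants and 20 alleles), enumerates every ladder branch exhaustively
for two-allele tables, and runs end-to-end recovery on simulated cohorts of
10,000 individuals (plus a 3,000-individual cohort at 5% missingness, where
reference-defaulted calls must carry the wild-type disclaimer and no
non-reference single call may contradict the truth). Tail probabilities are
checked against 60-digit reference values down to |z| = 30 at 10⁻¹² relative
log error. These sizes keep the full suite within a couple of minutes on one
core while leaving the binomial noise on simulated rates well below the
tolerances asserted.

## Known limitations

* No activity-score arithmetic beyond function classes; gene-specific scoring
  systems need explicit phenotype-map entries.
* No phasing, imputation, liftover, strand-flipping, or reference-FASTA
  validation; mismatched ref/alt is a data error, not repaired.
* CNV discovery, hybrid tandem alleles, and HLA typing are out of scope; CNV
  calls and HLA tallies enter as inputs.
* The wild-type disclaimer is a flag, not a probability: the package does not
  model the residual risk of undiscovered variation on reference calls.
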