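#' Enumerate all possible diplotypes from a pair of haplotype calls
#'
#' Takes the Cartesian product of each haplotype's possibilities — its
#' resolved label for `single`/`composite` calls, its candidate set for
#' `ambiguous` calls — and deduplicates as unordered pairs. If either
#' haplotype is `no_match` the set is empty (no diplotype can be
#' constructed).
#'
#' @param calls Two-row haplotype-call tibble for one sample and gene (from
#'   [call_sample_gene()] or a two-row slice of [call_gene_cohort()]).
#' @return Tibble `gene`, `allele1`, `allele2`, `diplotype` (canonical
#'   unordered key); zero rows with a `reason` attribute when either
#'   haplotype had no match.
#' @export
enumerate_diplotypes <- function(calls) {
  stopifnot(nrow(calls) == 2)
  gene <- calls$gene[[1]]
  opts <- lapply(seq_len(2), function(i) {
    st <- calls$status[[i]]
    if (st %in% c("single", "composite")) calls$resolved_label[[i]]
    else if (st == "ambiguous") calls$candidates[[i]]
    else character(0)
  })
  if (any(lengths(opts) == 0)) {
    out <- tibble(gene = character(0), allele1 = character(0),
                  allele2 = character(0), diplotype = character(0))
    attr(out, "reason") <- "no_match haplotype"
    return(out)
  }
  grid <- tidyr::expand_grid(a = opts[[1]], b = opts[[2]])
  grid |>
    mutate(gene = gene, diplotype = diplotype_key(.data$a, .data$b)) |>
    distinct(.data$gene, .data$diplotype, .keep_all = TRUE) |>
    mutate(allele1 = map_chr(strsplit(.data$diplotype, "/", fixed = TRUE),
                             1),
           allele2 = map_chr(strsplit(.data$diplotype, "/", fixed = TRUE),
                             2)) |>
    select("gene", "allele1", "allele2", "diplotype")
}

#' Read a diplotype-to-phenotype mapping table
#'
#' @param file TSV with columns `gene`, `allele1`, `allele2`, `phenotype`.
#'   Pairs are unordered; keys are normalised on read.
#' @return Tibble `gene`, `diplotype` (canonical key), `phenotype`.
#' @export
read_phenotype_map <- function(file) {
  d <- readr::read_tsv(file, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  need <- c("gene", "allele1", "allele2", "phenotype")
  if (!all(need %in% names(d))) {
    abort("format error: phenotype map needs gene/allele1/allele2/phenotype")
  }
  phenotype_map(d)
}

#' Normalise a diplotype-to-phenotype map
#'
#' @param entries Tibble/data frame with `gene`, `allele1`, `allele2`,
#'   `phenotype`.
#' @return Tibble `gene`, `diplotype`, `phenotype` with unordered-unique keys.
#' @export
phenotype_map <- function(entries) {
  entries <- as_tibble(entries)
  out <- entries |>
    mutate(diplotype = diplotype_key(.data$allele1, .data$allele2)) |>
    select("gene", "diplotype", "phenotype")
  dup <- duplicated(out[c("gene", "diplotype")])
  if (any(dup)) {
    clash <- out |>
      group_by(.data$gene, .data$diplotype) |>
      summarise(n = dplyr::n_distinct(.data$phenotype), .groups = "drop")
    if (any(clash$n > 1)) {
      abort("format error: conflicting phenotypes for one unordered diplotype")
    }
    out <- out[!dup, ]
  }
  out
}

#' Resolve a phenotype from candidate diplotypes
#'
#' Looks every candidate diplotype up in the mapping table. If all are found
#' and they agree, the call is `determinate` with that phenotype (ambiguity
#' between same-function alleles therefore does not block phenotype
#' prediction). A missing map entry or disagreeing phenotypes yields
#' `indeterminate`, with the candidate set retained.
#'
#' @param diplotypes Tibble from [enumerate_diplotypes()].
#' @param map Phenotype map ([phenotype_map()] / [read_phenotype_map()]).
#' @return One-row tibble: `gene`, `phenotype`, `status`
#'   (`determinate`/`indeterminate`), list-column `candidate_diplotypes`.
#' @export
resolve_phenotype <- function(diplotypes, map) {
  if (nrow(diplotypes) == 0) {
    abort("precondition error: empty diplotype set")
  }
  gene <- diplotypes$gene[[1]]
  hits <- diplotypes |>
    left_join(map[map$gene == gene, c("diplotype", "phenotype")],
              by = "diplotype")
  phen <- unique(hits$phenotype)
  if (!anyNA(hits$phenotype) && length(phen) == 1) {
    tibble(gene = gene, phenotype = phen, status = "determinate",
           candidate_diplotypes = list(diplotypes$diplotype))
  } else {
    tibble(gene = gene, phenotype = NA_character_, status = "indeterminate",
           candidate_diplotypes = list(diplotypes$diplotype))
  }
}

#' Flag a phenotype call as high-risk
#'
#' A determinate phenotype outside the gene's normal category flags the
#' individual as requiring nonstandard dosing for drugs linked to that gene.
#' Indeterminate calls return `NA` (undefined risk), never a boolean.
#'
#' @param phenotype Character vector of phenotype labels (may be `NA`).
#' @param status Matching vector of `determinate`/`indeterminate`.
#' @param normal_labels Character vector of the gene's normal-phenotype
#'   labels.
#' @return Logical vector (`NA` where indeterminate).
#' @export
flag_high_risk <- function(phenotype, status, normal_labels) {
  if_else(status == "determinate", !phenotype %in% normal_labels,
          NA)
}

#' Phenotype a whole cohort for one gene
#'
#' Enumerates diplotypes and resolves phenotypes per sample from cohort
#' haplotype calls; samples with a `no_match` haplotype get status
#' `no_diplotype`.
#'
#' @param calls Haplotype-call tibble from [call_gene_cohort()] (optionally
#'   CNV-adjusted).
#' @param map Phenotype map.
#' @param normal_labels Normal-phenotype labels for the gene (default
#'   `"Normal metabolizer"`).
#' @return Tibble `sample`, `gene`, `diplotype` (canonical key of the unique
#'   diplotype, `NA` if several or none), `phenotype`, `status`, `high_risk`.
#' @export
phenotype_gene_cohort <- function(calls, map,
                                  normal_labels = "Normal metabolizer") {
  gene <- calls$gene[[1]]
  # identical pairs of haplotype calls resolve identically: memoize on the
  # pair's option-set signature
  opt_str <- ifelse(
    calls$status %in% c("single", "composite"), calls$resolved_label,
    ifelse(calls$status == "ambiguous",
           map_chr(calls$candidates, paste, collapse = "|"), ""))
  by_sample <- split(seq_len(nrow(calls)), calls$sample)
  sigs <- vapply(split(opt_str, calls$sample), function(o) {
    paste(sort(o), collapse = " // ")
  }, character(1))
  uniq <- !duplicated(sigs)
  resolved <- lapply(by_sample[uniq], function(idx) {
    two <- calls[idx, ]
    dips <- enumerate_diplotypes(two)
    if (nrow(dips) == 0) {
      return(tibble(gene = gene, diplotype = NA_character_,
                    phenotype = NA_character_, status = "no_diplotype",
                    high_risk = NA))
    }
    ph <- resolve_phenotype(dips, map)
    tibble(gene = gene,
           diplotype = if (nrow(dips) == 1) dips$diplotype else NA_character_,
           phenotype = ph$phenotype, status = ph$status,
           high_risk = flag_high_risk(ph$phenotype, ph$status, normal_labels))
  })
  names(resolved) <- sigs[uniq]
  list_rbind(resolved[sigs]) |>
    mutate(sample = names(by_sample), .before = 1) |>
    arrange(.data$sample)
}
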