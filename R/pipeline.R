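#' Run the full star-allele pipeline on a cohort VCF
#'
#' End-to-end convenience wrapper: reads the phased VCF (optionally merging a
#' separate imputed VCF with genotyped-call preference), applies the
#' imputation-probability filter, projects each gene's definition table,
#' resolves both haplotypes of every sample through the priority ladder,
#' integrates copy-number calls where provided, and maps diplotypes to
#' phenotypes.
#'
#' @param vcf Path to the phased VCF (genotyped + imputed, or genotyped only).
#' @param tables Named list of [allele_table()]s (curation already applied).
#' @param maps Named list (or one stacked tibble) of phenotype maps.
#' @param imputed_vcf Optional second VCF of imputed genotypes; merged with
#'   [merge_sources()] (genotyped calls win).
#' @param cnv Optional CNV tibble or TSV path ([read_cnv_calls()]).
#' @param profile Optional [platform_profile()] (checked for CNV support when
#'   `cnv` is given).
#' @param gp_threshold Imputation probability threshold (default 0.90).
#' @param normal_labels Per-gene normal phenotype labels: a character vector
#'   applied to every gene, or a named list.
#' @param priority Duplication priority order.
#' @param deletion_label,reference_label Structural labels.
#' @param ... Passed to [resolve_call()].
#' @return List with `haplotypes` (stacked haplotype calls) and `phenotypes`
#'   (stacked per-sample phenotype calls).
#' @export
call_pgx_cohort <- function(vcf, tables, maps, imputed_vcf = NULL, cnv = NULL,
                            profile = NULL, gp_threshold = 0.90,
                            normal_labels = "Normal metabolizer",
                            priority = c("*2", "*1", "*4"),
                            deletion_label = "*5", reference_label = "*1",
                            ...) {
  gt <- read_phased_vcf(vcf)
  if (!is.null(imputed_vcf)) {
    imp <- read_phased_vcf(imputed_vcf)
    imp$origin <- "imputed"
    gt <- merge_sources(gt[gt$origin == "genotyped", ], imp)
  }
  gt <- apply_probability_filter(gt, gp_threshold)
  if (is.character(cnv)) cnv <- read_cnv_calls(cnv)
  if (is.data.frame(maps)) {
    maps <- split(maps, maps$gene)
  }
  hap_calls <- list(); phen_calls <- list()
  for (gname in names(tables)) {
    tbl <- tables[[gname]]
    chaps <- cohort_haplotypes(gt, tbl)
    calls <- call_gene_cohort(chaps, tbl, ...)
    if (!is.null(cnv) && any(cnv$gene == gname)) {
      calls <- integrate_cnv_calls(calls, cnv[cnv$gene == gname, ],
                                   profile = profile, priority = priority,
                                   deletion_label = deletion_label,
                                   reference_label = reference_label)
    }
    nl <- if (is.list(normal_labels)) {
      normal_labels[[gname]] %||% "Normal metabolizer"
    } else normal_labels
    map <- maps[[gname]]
    if (is.null(map)) {
      abort(paste0("configuration error: no phenotype map for ", gname))
    }
    hap_calls[[gname]] <- calls
    phen_calls[[gname]] <- phenotype_gene_cohort(calls, map,
                                                 normal_labels = nl)
  }
  list(haplotypes = list_rbind(hap_calls),
       phenotypes = list_rbind(phen_calls))
}
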