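#' Read phased genotypes from a VCF
#'
#' Reads a multi-sample VCF (via \pkg{vcfR}) into a long tibble of per-sample,
#' per-site genotypes: one row per sample and biallelic site record.
#' Multi-allelic records are decomposed into one biallelic record per ALT
#' allele (a call of a different ALT counts as `ref` for the decomposed
#' record). `./.` becomes `(missing, missing)`. Unphased heterozygotes are
#' kept with `phased = FALSE`; downstream projection decides whether that is
#' an error.
#'
#' The provenance of each genotype (directly genotyped vs imputed) is read
#' from a per-genotype FORMAT tag (default `OR`, values starting with `I` =
#' imputed, otherwise genotyped); absent the tag, every call defaults to
#' `genotyped`. The best-genotype posterior probability is read from the `GP`
#' FORMAT tag (maximum over the comma-separated genotype probabilities, or a
#' single number).
#'
#' @param file Path to a VCF (plain or bgzipped).
#' @param region Optional `"contig:from-to"` string restricting records.
#' @param samples Optional character vector of sample ids to keep.
#' @param origin_tag FORMAT tag carrying per-genotype origin (default `"OR"`).
#' @param gp_tag FORMAT tag carrying genotype probabilities (default `"GP"`).
#' @return Tibble with columns `sample`, `contig`, `pos`, `ref`, `alt`,
#'   `rsid`, `variant_id`, `allele_a`, `allele_b` (each `ref`/`alt`/`missing`),
#'   `phased`, `origin`, `gp`.
#' @export
read_phased_vcf <- function(file, region = NULL, samples = NULL,
                            origin_tag = "OR", gp_tag = "GP") {
  vcf <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCFs drop to a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) abort("parse error: VCF has no records")
  gt_mat <- vcfR::extract.gt(vcf, element = "GT")
  format_field <- unlist(strsplit(vcf@gt[1, "FORMAT"], ":", fixed = TRUE))
  or_mat <- if (origin_tag %in% format_field) {
    vcfR::extract.gt(vcf, element = origin_tag)
  } else NULL
  gp_mat <- if (gp_tag %in% format_field) {
    vcfR::extract.gt(vcf, element = gp_tag)
  } else NULL
  sample_ids <- colnames(gt_mat)
  if (!is.null(samples)) {
    keep <- sample_ids %in% samples
    gt_mat <- gt_mat[, keep, drop = FALSE]
    if (!is.null(or_mat)) or_mat <- or_mat[, keep, drop = FALSE]
    if (!is.null(gp_mat)) gp_mat <- gp_mat[, keep, drop = FALSE]
    sample_ids <- colnames(gt_mat)
  }
  pos <- as.integer(fix$POS)
  keep_rec <- rep(TRUE, nrow(fix))
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4) abort("parse error: region must be contig:from-to")
    keep_rec <- fix$CHROM == m[[2]] & pos >= as.integer(m[[3]]) &
      pos <= as.integer(m[[4]])
  }
  rows <- list()
  for (i in which(keep_rec)) {
    alts <- strsplit(fix$ALT[[i]], ",", fixed = TRUE)[[1]]
    gts <- gt_mat[i, ]
    gts[is.na(gts)] <- "./."
    phased <- grepl("|", gts, fixed = TRUE)
    parts <- strsplit(gts, "[|/]")
    bad <- vapply(parts, length, integer(1)) != 2
    bad[!bad] <- vapply(parts[!bad], function(p) {
      !all(p %in% c(".", as.character(0:length(alts))))
    }, logical(1))
    if (any(bad)) {
      abort(paste0("parse error: malformed GT at ", fix$CHROM[[i]], ":",
                   pos[[i]], " (", gts[which(bad)[1]], ")"))
    }
    a1 <- unname(vapply(parts, `[[`, character(1), 1))
    a2 <- unname(vapply(parts, `[[`, character(1), 2))
    origin <- if (is.null(or_mat)) rep("genotyped", length(gts)) else {
      unname(if_else(startsWith(toupper(or_mat[i, ]), "I"),
                     "imputed", "genotyped", missing = "genotyped"))
    }
    gp <- if (is.null(gp_mat)) rep(NA_real_, length(gts)) else {
      unname(vapply(strsplit(gp_mat[i, ], ",", fixed = TRUE), function(g) {
        if (length(g) == 0 || all(g == ".") || all(is.na(g))) NA_real_
        else max(suppressWarnings(as.numeric(g)), na.rm = TRUE)
      }, numeric(1)))
    }
    for (j in seq_along(alts)) {
      state <- function(a) {
        if_else(a == ".", "missing", if_else(a == as.character(j),
                                             "alt", "ref"))
      }
      rows[[length(rows) + 1]] <- tibble(
        sample = sample_ids,
        contig = fix$CHROM[[i]], pos = pos[[i]],
        ref = fix$REF[[i]], alt = alts[[j]],
        rsid = if_else(fix$ID[[i]] %in% c(".", NA), NA_character_,
                       fix$ID[[i]]),
        allele_a = state(a1), allele_b = state(a2),
        phased = phased | a1 == a2 | a1 == "." | a2 == ".",
        origin = origin, gp = gp)
    }
  }
  out <- list_rbind(rows)
  out |>
    mutate(variant_id = variant_id(.data$contig, .data$pos, .data$ref,
                                   .data$alt)) |>
    select("sample", "contig", "pos", "ref", "alt", "rsid", "variant_id",
           "allele_a", "allele_b", "phased", "origin", "gp")
}

#' Filter low-confidence imputed genotypes
#'
#' Imputed genotypes whose best-genotype probability falls below the
#' threshold are set to missing on both haplotypes ("filtered out"); the
#' threshold is strict, so a probability exactly at the threshold is kept.
#' Directly genotyped records are never touched, whatever their `gp`.
#'
#' @param genotypes Genotype tibble from [read_phased_vcf()].
#' @param threshold Probability in `(0, 1]`; default `0.90`.
#' @return The tibble with filtered rows set to `missing`/`missing`.
#' @export
apply_probability_filter <- function(genotypes, threshold = 0.90) {
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  if (threshold <= 0 || threshold > 1) {
    abort("precondition error: threshold must be in (0, 1]")
  }
  imputed <- genotypes$origin == "imputed"
  if (any(imputed & is.na(genotypes$gp))) {
    abort("data error: imputed genotype without a genotype probability")
  }
  drop <- imputed & genotypes$gp < threshold
  genotypes |>
    mutate(allele_a = if_else(drop, "missing", .data$allele_a),
           allele_b = if_else(drop, "missing", .data$allele_b),
           phased = if_else(drop, TRUE, .data$phased))
}

#' Merge genotyped and imputed genotype sources
#'
#' Where a (sample, variant) key is covered by both sources the directly
#' genotyped call is preferred; otherwise the union of the two sources is
#' kept.
#'
#' @param genotyped,imputed Genotype tibbles keyed by `(sample, variant_id)`.
#' @return Merged genotype tibble.
#' @export
merge_sources <- function(genotyped, imputed) {
  key <- function(g) paste(g$sample, g$variant_id)
  for (nm in c("genotyped", "imputed")) {
    g <- if (nm == "genotyped") genotyped else imputed
    if (anyDuplicated(key(g))) {
      abort(paste0("data error: duplicate (sample, variant) keys in ",
                   nm, " source"))
    }
  }
  bind_rows(genotyped, imputed[!key(imputed) %in% key(genotyped), ])
}

#' Project one sample's genotypes onto a definition table
#'
#' Builds the pair of phased haplotype state vectors over exactly the table's
#' variants. Variants with no genotype record (or filtered ones) are
#' `missing` on both haplotypes. The first GT field maps to haplotype A. An
#' unphased heterozygote is tolerated only when it is the sample's sole
#' heterozygous site among the table's variants (phase is then irrelevant);
#' more than one is an ambiguity error, since haplotype assignment would be
#' arbitrary.
#'
#' @param genotypes Genotype tibble (filtered and merged).
#' @param tbl An [allele_table()].
#' @param sample Sample id to project.
#' @return Tibble `variant_id`, `hapA`, `hapB` with one row per table
#'   variant, in table order.
#' @export
build_sample_haplotypes <- function(genotypes, tbl, sample) {
  stopifnot(inherits(tbl, "allele_table"))
  g <- genotypes[genotypes$sample == sample &
                   genotypes$variant_id %in% tbl$variants$variant_id, ]
  het <- g$allele_a != g$allele_b & g$allele_a != "missing" &
    g$allele_b != "missing"
  if (sum(!g$phased & het) > 1) {
    abort(paste0("ambiguity error: sample ", sample, " has ",
                 sum(!g$phased & het),
                 " unphased heterozygous sites among table variants"))
  }
  idx <- match(tbl$variants$variant_id, g$variant_id)
  tibble(
    variant_id = tbl$variants$variant_id,
    hapA = if_else(is.na(idx), "missing", g$allele_a[idx]),
    hapB = if_else(is.na(idx), "missing", g$allele_b[idx]))
}

#' Project a whole cohort onto a definition table
#'
#' Vectorised form of [build_sample_haplotypes()] for all samples at once.
#'
#' @inheritParams build_sample_haplotypes
#' @param samples Optional sample ids (default: all samples present).
#' @return Tibble `sample`, `variant_id`, `hapA`, `hapB`.
#' @export
cohort_haplotypes <- function(genotypes, tbl, samples = NULL) {
  stopifnot(inherits(tbl, "allele_table"))
  samples <- samples %||% unique(genotypes$sample)
  g <- genotypes[genotypes$variant_id %in% tbl$variants$variant_id &
                   genotypes$sample %in% samples, ]
  het <- g$allele_a != g$allele_b & g$allele_a != "missing" &
    g$allele_b != "missing"
  viol <- table(g$sample[!g$phased & het])
  viol <- names(viol)[viol > 1]
  if (length(viol) > 0) {
    abort(paste0("ambiguity error: unphased heterozygous sites at >1 table ",
                 "variant for sample(s): ",
                 paste(head(viol, 5), collapse = ", ")))
  }
  grid <- tidyr::expand_grid(sample = samples,
                             variant_id = tbl$variants$variant_id)
  grid |>
    left_join(g[c("sample", "variant_id", "allele_a", "allele_b")],
              by = c("sample", "variant_id")) |>
    mutate(hapA = if_else(is.na(.data$allele_a), "missing", .data$allele_a),
           hapB = if_else(is.na(.data$allele_b), "missing", .data$allele_b)) |>
    select("sample", "variant_id", "hapA", "hapB")
}
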