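# Shared fixtures: hand-built tables, random-table generator and the
# independent brute-force matching oracle.

# five variants on one contig, reused across fixtures
fix_variants <- function(n = 5) {
  tibble::tibble(
    contig = "1",
    pos = 1000L + 10L * seq_len(n),
    ref = rep(c("A", "C", "G", "T", "A"), length.out = n),
    alt = rep(c("G", "T", "A", "C", "T"), length.out = n),
    rsid = sprintf("rs%d", seq_len(n)))
}

fix_vids <- function(n = 5) {
  v <- fix_variants(n)
  paste(v$contig, v$pos, v$ref, v$alt, sep = ":")
}

# ladder fixture covering every resolve_call branch:
#   *2 no_function {v1}; *3 normal {v2}; *4 decreased {v2,v3};
#   *5 normal {v4}; *9 normal {v2,v5}
ladder_table <- function() {
  vids <- fix_vids(5)
  allele_table(
    gene = "LADDER",
    variants = fix_variants(5),
    alleles = tibble::tibble(
      label = c("*1", "*2", "*3", "*4", "*5", "*9"),
      function_class = c("normal", "no_function", "normal", "decreased",
                         "normal", "normal"),
      structural = "none"),
    requirements = tibble::tibble(
      label = c("*2", "*3", "*4", "*4", "*5", "*9", "*9"),
      variant_id = vids[c(1, 2, 2, 3, 4, 2, 5)],
      state = "alt"))
}

# named haplotype over a table's variants; `alt`/`missing` name variant ids
make_hap <- function(tbl, alt = character(), missing = character()) {
  hap <- stats::setNames(rep("ref", nrow(tbl$variants)),
                         tbl$variants$variant_id)
  hap[alt] <- "alt"
  hap[missing] <- "missing"
  hap
}

# random valid table, allowing overlapping definitions and ref-requirements
random_table <- function(n_variants, n_alleles, gene = "RND") {
  v <- tibble::tibble(
    contig = "7",
    pos = 500L + 7L * seq_len(n_variants),
    ref = sample(c("A", "C", "G", "T"), n_variants, replace = TRUE))
  v$alt <- vapply(v$ref, function(r) {
    sample(setdiff(c("A", "C", "G", "T"), r), 1)
  }, character(1))
  v$rsid <- NA_character_
  vids <- paste(v$contig, v$pos, v$ref, v$alt, sep = ":")
  # cap at the number of distinct definitions (subsets of size <= 3 with at
  # least one alt-required state) so the rejection loop always terminates
  kmax <- min(3, n_variants)
  feasible <- sum(vapply(seq_len(kmax), function(k) {
    choose(n_variants, k) * (2^k - 1)
  }, numeric(1)))
  n_alleles <- min(n_alleles, feasible)
  defs <- list(); sigs <- character(0)
  while (length(defs) < n_alleles) {
    k <- sample(seq_len(min(3, n_variants)), 1)
    pick <- sample(vids, k)
    st <- sample(c("alt", "alt", "ref"), k, replace = TRUE)
    if (!any(st == "alt")) st[1] <- "alt"
    sig <- paste(sort(paste(pick, st)), collapse = ";")
    if (sig %in% sigs) next
    sigs <- c(sigs, sig)
    defs[[length(defs) + 1]] <- tibble::tibble(
      label = paste0("*", length(defs) + 2), variant_id = pick, state = st)
  }
  allele_table(
    gene = gene, variants = v,
    alleles = tibble::tibble(
      label = c("*1", paste0("*", seq_len(n_alleles) + 1)),
      function_class = c("normal",
                         sample(c("no_function", "decreased", "normal",
                                  "increased"), n_alleles, replace = TRUE)),
      structural = "none"),
    requirements = dplyr::bind_rows(defs))
}

random_hap <- function(tbl, p_missing = 0.15) {
  stats::setNames(
    sample(c("ref", "alt", "missing"), nrow(tbl$variants), replace = TRUE,
           prob = c(1 - 0.35 - p_missing, 0.35, p_missing)),
    tbl$variants$variant_id)
}

# Independent oracle: tests every allele definition one by one with plain
# loops over the requirement rows; reference = no observed alternate state.
# `reqs_by_label` (plain per-allele requirement lists) can be precomputed
# once per table when sweeping many haplotypes.
oracle_reqs <- function(tbl) {
  r <- as.data.frame(tbl$requirements)
  lapply(stats::setNames(nm = tbl$alleles$label), function(lab) {
    r[r$label == lab, , drop = FALSE]
  })
}

oracle_matches <- function(hap, tbl, reqs_by_label = NULL) {
  if (is.null(reqs_by_label)) reqs_by_label <- oracle_reqs(tbl)
  out <- character(0)
  for (i in seq_len(nrow(tbl$alleles))) {
    lab <- tbl$alleles$label[[i]]
    if (tbl$alleles$structural[[i]] != "none") next
    if (lab == tbl$reference_label) {
      ok <- TRUE
      for (v in names(hap)) if (hap[[v]] == "alt") ok <- FALSE
    } else {
      rr <- reqs_by_label[[lab]]
      ok <- nrow(rr) > 0
      for (j in seq_len(nrow(rr))) {
        if (hap[[rr$variant_id[[j]]]] != rr$state[[j]]) ok <- FALSE
      }
    }
    if (ok) out <- c(out, lab)
  }
  sort(out)
}

# minimal phased VCF writer for IO fixtures (independent of the simulator)
write_test_vcf <- function(path, records, samples) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=OR,Number=1,Type=String,Description=\"origin\">",
    "##FORMAT=<ID=GP,Number=1,Type=Float,Description=\"GP\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    vapply(records, function(r) paste(r, collapse = "\t"), character(1)))
  writeLines(lines, path)
  path
}
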