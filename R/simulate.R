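#' Simulate a star-allele definition table
#'
#' Generates a valid synthetic definition table: a reference allele plus
#' `n_alleles` named alleles, each defined by its own disjoint set of
#' alt-required variants (disjoint definitions keep synthetic alleles
#' separable and composable on one haplotype — the ambiguity that curation
#' exists to remove in real tables is constructed explicitly in tests
#' instead). Optionally adds structural deletion (`*5`-style) and duplication
#' rows.
#'
#' @param gene Gene symbol for the synthetic table.
#' @param n_alleles Number of non-reference, non-structural alleles (>= 1).
#' @param variants_per_allele Integer vector (recycled) of defining variants
#'   per allele; at least one allele gets more than one variant whenever any
#'   entry exceeds 1.
#' @param function_classes Character vector (recycled) of function classes
#'   for the alleles; the default cycles
#'   `no_function, normal, decreased, normal, increased` so at least one
#'   nonfunctional allele is always present.
#' @param n_variants Optional cap on available distinct variants; a spec
#'   needing more distinct defining variants than this is infeasible and
#'   errors.
#' @param include_structural Add a `*5` whole-gene deletion row
#'   (`no_function`) and a duplication placeholder row.
#' @param seed Integer seed; the same seed yields an identical table.
#' @param contig,base_pos Coordinates for the synthetic variants.
#' @return A validated [allele_table()].
#' @export
simulate_table <- function(gene, n_alleles, variants_per_allele = 1,
                           function_classes = NULL, n_variants = NULL,
                           include_structural = FALSE, seed = 1,
                           contig = "10", base_pos = 94000000L) {
  if (n_alleles < 1) abort("spec error: need >= 1 non-reference allele")
  vpa <- rep_len(as.integer(variants_per_allele), n_alleles)
  if (any(vpa < 1)) abort("spec error: each allele needs >= 1 variant")
  total <- sum(vpa)
  if (!is.null(n_variants) && n_variants < total) {
    abort(paste0("spec error: infeasible spec — needs ", total,
                 " distinct defining variants but only ", n_variants,
                 " are available"))
  }
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, total, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  variants <- tibble(
    contig = contig,
    pos = base_pos + cumsum(sample(50:500, total, replace = TRUE)),
    ref = ref, alt = unname(alt),
    rsid = sprintf("rs%07d", sample(1e6, total)))
  # *5 is reserved for the whole-gene deletion when structural rows are added
  nums <- if (include_structural) {
    setdiff(seq_len(n_alleles + 2L) + 1L, 5L)[seq_len(n_alleles)]
  } else seq_len(n_alleles) + 1L
  labels <- paste0("*", nums)
  fns <- rep_len(function_classes %||%
                   c("no_function", "normal", "decreased", "normal",
                     "increased"),
                 n_alleles)
  vids <- variant_id(variants$contig, variants$pos, variants$ref,
                     variants$alt)
  slice_end <- cumsum(vpa)
  slice_start <- slice_end - vpa + 1L
  requirements <- list_rbind(purrr::map(seq_len(n_alleles), function(i) {
    tibble(label = labels[[i]],
           variant_id = vids[slice_start[[i]]:slice_end[[i]]],
           state = "alt")
  }))
  alleles <- bind_rows(
    tibble(label = "*1", function_class = "normal", structural = "none"),
    tibble(label = labels, function_class = fns, structural = "none"))
  if (include_structural) {
    alleles <- bind_rows(
      alleles,
      tibble(label = "*5", function_class = "no_function",
             structural = "deletion"),
      tibble(label = paste0(labels[[1]], "xN"),
             function_class = "increased", structural = "duplication"))
  }
  allele_table(gene = gene, variants = variants, alleles = alleles,
               requirements = requirements, reference_label = "*1")
}

activity_score <- function(fn) {
  c(no_function = 0, decreased = 0.5, normal = 1, increased = 1.5,
    unknown = NA_real_)[fn]
}

label_activity <- function(label, tbl, deletion_label = "*5") {
  if (label == deletion_label) return(0)
  xn <- grepl("xN$", label)
  base <- sub("xN$", "", label)
  if (grepl("+", base, fixed = TRUE)) {
    members <- strsplit(base, "+", fixed = TRUE)[[1]]
    fn <- most_severe_function(
      tbl$alleles$function_class[match(members, tbl$alleles$label)])
  } else {
    fn <- tbl$alleles$function_class[match(base, tbl$alleles$label)]
  }
  a <- unname(activity_score(fn))
  if (xn) 2 * a else a
}

phenotype_of_activity <- function(s) {
  if (s <= 0) "Poor metabolizer"
  else if (s < 2) "Intermediate metabolizer"
  else if (s == 2) "Normal metabolizer"
  else if (s <= 2.5) "Rapid metabolizer"
  else "Ultrarapid metabolizer"
}

#' Generate a complete diplotype-to-phenotype map for a synthetic table
#'
#' Builds a deterministic metabolizer-scale map over every unordered pair of
#' labels the simulator can emit: the table's non-structural alleles, the
#' supplied composite labels, the deletion label and `xN`-suffixed labels.
#' Each label gets an activity score from its function class (`no_function`
#' 0, `decreased` 0.5, `normal` 1, `increased` 1.5; deletion 0; `xN` doubles;
#' a composite takes its most severe member), and the diplotype sum maps to
#' the poor/intermediate/normal/rapid/ultrarapid scale. This emulates the
#' shape of real diplotype-to-phenotype tables; it is not a clinical map.
#'
#' @param tbl An [allele_table()].
#' @param composite_labels Extra `"*a+*b"` labels to cover.
#' @param include_xn,include_deletion Cover `xN`/deletion labels.
#' @param deletion_label Deletion allele label (default `"*5"`).
#' @return Tibble `gene`, `diplotype`, `phenotype` (a [phenotype_map()]).
#' @export
simulate_phenotype_map <- function(tbl, composite_labels = character(),
                                   include_xn = TRUE,
                                   include_deletion = TRUE,
                                   deletion_label = "*5") {
  base <- tbl$alleles$label[tbl$alleles$structural == "none"]
  universe <- c(base, composite_labels)
  if (include_xn) universe <- c(universe, paste0(base, "xN"))
  if (include_deletion) universe <- c(universe, deletion_label)
  universe <- unique(universe)
  pairs <- tidyr::expand_grid(allele1 = universe, allele2 = universe) |>
    mutate(diplotype = diplotype_key(.data$allele1, .data$allele2)) |>
    distinct(.data$diplotype, .keep_all = TRUE)
  act <- vapply(universe, label_activity, numeric(1), tbl = tbl,
                deletion_label = deletion_label)
  pairs |>
    mutate(gene = tbl$gene,
           phenotype = vapply(act[.data$allele1] + act[.data$allele2],
                              phenotype_of_activity, character(1))) |>
    select("gene", "diplotype", "phenotype")
}

#' Specify a synthetic cohort simulation
#'
#' Bundles everything [simulate_cohort()] needs: per-gene tables, haplotype
#' label frequencies, composite and copy-number event rates, the platform
#' profile (which variants are directly typable and whether CNVs are
#' supported), per-site missingness, and the genotype-probability mixture for
#' imputed sites. The same spec and seed always produce byte-identical
#' outputs.
#'
#' @param genes List of per-gene specs, each a list with `table` (an
#'   [allele_table()]), `freqs` (named haplotype-label frequencies over the
#'   table's non-structural alleles, summing to 1), and optional
#'   `composite_rate` (probability a haplotype carries two compatible named
#'   alleles), `cnv_del_rate`, `cnv_dup_rate` (per-individual event rates).
#' @param n_samples Number of individuals.
#' @param seed Integer seed.
#' @param platform A [platform_profile()]; untypable variants are emitted as
#'   imputed genotypes (with GP draws) when `impute_untyped` is `TRUE`, else
#'   omitted from the VCF.
#' @param missingness Per-genotype probability of a `./.` call.
#' @param impute_untyped Emit untypable variants as imputed records.
#' @param gp_high_mass Probability an imputed genotype's GP lands in
#'   `gp_high_range` (default 0.95, mirroring near-perfect imputation of
#'   common pharmacogene variants); the rest land in `gp_low_range` and are
#'   removed by the default 0.90 filter.
#' @param gp_high_range,gp_low_range GP mixture component ranges.
#' @return A `simulation_spec` object.
#' @export
simulation_spec <- function(genes, n_samples = 1000, seed = 1,
                            platform = platform_profile("GS", "all", TRUE),
                            missingness = 0, impute_untyped = TRUE,
                            gp_high_mass = 0.95,
                            gp_high_range = c(0.90, 1.0),
                            gp_low_range = c(0.50, 0.90)) {
  stopifnot(inherits(platform, "platform_profile"))
  if (missingness < 0 || missingness > 1) {
    abort("spec error: missingness must be in [0, 1]")
  }
  genes <- lapply(genes, function(g) {
    stopifnot(inherits(g$table, "allele_table"))
    g$composite_rate <- g$composite_rate %||% 0
    g$cnv_del_rate <- g$cnv_del_rate %||% 0
    g$cnv_dup_rate <- g$cnv_dup_rate %||% 0
    ns <- g$table$alleles$label[g$table$alleles$structural == "none"]
    if (!setequal(names(g$freqs), ns)) {
      abort("spec error: freqs must be named over the non-structural labels")
    }
    if (abs(sum(g$freqs) - 1) > 1e-8) {
      abort("spec error: per-gene frequencies must sum to 1")
    }
    rates <- c(g$composite_rate, g$cnv_del_rate, g$cnv_dup_rate)
    if (any(rates < 0 | rates > 1) || g$cnv_del_rate + g$cnv_dup_rate > 1) {
      abort("spec error: rates must be probabilities")
    }
    g
  })
  names(genes) <- vapply(genes, function(g) g$table$gene, character(1))
  structure(list(genes = genes, n_samples = as.integer(n_samples),
                 seed = as.integer(seed), platform = platform,
                 missingness = missingness,
                 impute_untyped = isTRUE(impute_untyped),
                 gp_high_mass = gp_high_mass,
                 gp_high_range = gp_high_range, gp_low_range = gp_low_range),
            class = "simulation_spec")
}

# composite-eligible alleles: named (non-reference), non-structural,
# not nonfunctional (a nonfunctional member would be swallowed by the
# nonfunctional-first pass and the composite would be unrecoverable)
composite_pairs <- function(tbl) {
  a <- tbl$alleles
  elig <- a$label[a$structural == "none" & a$label != tbl$reference_label &
                    a$function_class != "no_function"]
  if (length(elig) < 2) return(NULL)
  utils::combn(sort_star_labels(elig), 2)
}

composite_label <- function(a, b) {
  paste(sort_star_labels(c(a, b)), collapse = "+")
}

# duplication rule mirrored independently of integrate_cnv(): first priority
# label present gains xN, else the more severe function class does
truth_duplicate <- function(labels, tbl, priority, deletion_label) {
  for (p in priority) {
    if (p %in% labels) {
      i <- which(labels == p)[1]
      labels[i] <- paste0(labels[i], "xN")
      return(labels)
    }
  }
  act <- vapply(labels, label_activity, numeric(1), tbl = tbl,
                deletion_label = deletion_label)
  i <- which.min(act)
  labels[i] <- paste0(labels[i], "xN")
  labels
}

#' Simulate a phased cohort with ground truth
#'
#' Draws each individual's two haplotype labels independently from the
#' per-gene allele frequencies (Hardy–Weinberg, no linkage between genes),
#' optionally places two compatible named alleles on one haplotype
#' (composite events), draws whole-gene deletion/duplication events for genes
#' with CNV rates, and writes a phased VCF, a CNV call file, and a truth
#' sidecar. On the VCF side, platform-typable variants are emitted as
#' directly genotyped; untypable ones as imputed with genotype-probability
#' draws (or omitted); random per-genotype missingness is applied last. A
#' deleted gene copy presents as an all-reference haplotype in the VCF, with
#' the deletion allele label recorded in the truth.
#'
#' @param spec A [simulation_spec()].
#' @param dir Output directory (created if needed); defaults to a session
#'   temporary directory.
#' @param priority Duplication priority order (default `c("*2","*1","*4")`).
#' @param deletion_label Deletion allele label (default `"*5"`).
#' @return List: `vcf` (path), `cnv` (tibble + `cnv_file` path), `truth`
#'   (tibble + `truth_file` path), `tables`, `maps` (per-gene phenotype
#'   maps), and `spec`.
#' @export
simulate_cohort <- function(spec, dir = NULL,
                            priority = c("*2", "*1", "*4"),
                            deletion_label = "*5") {
  stopifnot(inherits(spec, "simulation_spec"))
  dir <- dir %||% file.path(tempdir(), paste0("starcall_sim_", spec$seed))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  n <- spec$n_samples
  samples <- sprintf("S%05d", seq_len(n))
  truth <- list(); cnv <- list(); var_rows <- list(); maps <- list()
  gene_states <- list()
  for (gname in names(spec$genes)) {
    g <- spec$genes[[gname]]
    tbl <- g$table
    freqs <- g$freqs
    lab_a <- sample(names(freqs), n, replace = TRUE, prob = freqs)
    lab_b <- sample(names(freqs), n, replace = TRUE, prob = freqs)
    pairs <- composite_pairs(tbl)
    comp_labels <- character(0)
    if (g$composite_rate > 0) {
      if (is.null(pairs)) {
        abort("spec error: composite_rate > 0 needs >= 2 named functional alleles")
      }
      comp_labels <- apply(pairs, 2, function(p) composite_label(p[1], p[2]))
      for (side in c("a", "b")) {
        hit <- runif(n) < g$composite_rate
        pick <- comp_labels[sample.int(length(comp_labels), n,
                                       replace = TRUE)]
        if (side == "a") lab_a[hit] <- pick[hit] else lab_b[hit] <- pick[hit]
      }
    }
    # CNV events per individual
    p_del <- g$cnv_del_rate; p_dup <- g$cnv_dup_rate
    event <- if (p_del + p_dup > 0) {
      sample(c("deletion", "duplication", "normal"), n, replace = TRUE,
             prob = c(p_del, p_dup, 1 - p_del - p_dup))
    } else rep("normal", n)
    # a deleted copy carries no variants: it presents as reference in the VCF
    del <- event == "deletion"
    lab_b[del] <- tbl$reference_label
    truth_a <- lab_a; truth_b <- lab_b
    truth_b[del] <- deletion_label
    dup <- which(event == "duplication")
    for (i in dup) {
      adj <- truth_duplicate(c(truth_a[[i]], truth_b[[i]]), tbl, priority,
                             deletion_label)
      truth_a[[i]] <- adj[[1]]; truth_b[[i]] <- adj[[2]]
    }
    maps[[gname]] <- simulate_phenotype_map(
      tbl, composite_labels = comp_labels,
      include_xn = p_dup > 0, include_deletion = TRUE,
      deletion_label = deletion_label)
    dip <- diplotype_key(truth_a, truth_b)
    phen <- maps[[gname]]$phenotype[match(dip, maps[[gname]]$diplotype)]
    truth[[gname]] <- tibble(sample = samples, gene = gname,
                             hap_a = truth_a, hap_b = truth_b,
                             diplotype = dip, phenotype = phen,
                             cnv_event = event)
    if (p_del + p_dup > 0) {
      cnv[[gname]] <- tibble(sample = samples, gene = gname, event = event,
                             copy_number = dplyr::case_when(
                               event == "deletion" ~ 1L,
                               event == "duplication" ~ 3L,
                               TRUE ~ 2L))
    }
    # haplotype label -> alt-state variant set
    alt_of <- function(lab) {
      members <- strsplit(lab, "+", fixed = TRUE)[[1]]
      unique(unlist(lapply(members, required_alt_variants, tbl = tbl)))
    }
    label_universe <- unique(c(lab_a, lab_b))
    alt_sets <- lapply(setNames(label_universe, label_universe), alt_of)
    vids <- tbl$variants$variant_id
    stateA <- matrix("ref", nrow = length(vids), ncol = n,
                     dimnames = list(vids, samples))
    stateB <- stateA
    for (lab in label_universe) {
      av <- alt_sets[[lab]]
      if (length(av) > 0) {
        stateA[av, lab_a == lab] <- "alt"
        stateB[av, lab_b == lab] <- "alt"
      }
    }
    gene_states[[gname]] <- list(tbl = tbl, A = stateA, B = stateB)
  }
  truth <- list_rbind(truth)
  cnv <- if (length(cnv) > 0) list_rbind(cnv) else
    tibble(sample = character(0), gene = character(0), event = character(0),
           copy_number = integer(0))
  # ---- emit the VCF ----
  all_vars <- list_rbind(lapply(gene_states,
                                function(gs) gs$tbl$variants))
  ord <- order(all_vars$contig, all_vars$pos)
  all_vars <- all_vars[ord, ]
  typable <- is_typable(spec$platform, all_vars$variant_id)
  keep <- typable | spec$impute_untyped
  lines <- c("##fileformat=VCFv4.2",
             "##source=starcallr simulate_cohort",
             paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                    "Description=\"Phased genotype\">"),
             paste0("##FORMAT=<ID=OR,Number=1,Type=String,Description=",
                    "\"Call origin: G=genotyped, I=imputed\">"),
             paste0("##FORMAT=<ID=GP,Number=1,Type=Float,Description=",
                    "\"Best-genotype posterior probability\">"),
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  gene_of_variant <- rep(names(gene_states),
                         vapply(gene_states,
                                function(gs) nrow(gs$tbl$variants),
                                integer(1)))[ord]
  for (k in which(keep)) {
    v <- all_vars[k, ]
    gs <- gene_states[[gene_of_variant[[k]]]]
    a <- gs$A[v$variant_id, ]; b <- gs$B[v$variant_id, ]
    gt <- paste0(ifelse(a == "alt", "1", "0"), "|",
                 ifelse(b == "alt", "1", "0"))
    if (spec$missingness > 0) {
      gt[runif(n) < spec$missingness] <- ".|."
    }
    if (typable[[k]]) {
      cells <- paste0(gt, ":G:.")
    } else {
      hi <- runif(n) < spec$gp_high_mass
      gp <- ifelse(hi,
                   runif(n, spec$gp_high_range[1], spec$gp_high_range[2]),
                   runif(n, spec$gp_low_range[1], spec$gp_low_range[2]))
      cells <- paste0(gt, ":I:", sprintf("%.4f", gp))
    }
    lines <- c(lines, paste(c(v$contig, v$pos,
                              if (is.na(v$rsid)) "." else v$rsid,
                              v$ref, v$alt, ".", "PASS", ".", "GT:OR:GP",
                              cells), collapse = "\t"))
  }
  vcf_path <- file.path(dir, "cohort.vcf")
  writeLines(lines, vcf_path)
  cnv_path <- file.path(dir, "cnv.tsv")
  readr::write_tsv(cnv, cnv_path, progress = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  readr::write_tsv(truth, truth_path, progress = FALSE)
  tdir <- file.path(dir, "tables")
  dir.create(tdir, showWarnings = FALSE)
  for (gname in names(spec$genes)) {
    write_definition_table(spec$genes[[gname]]$table,
                           file.path(tdir, paste0(gname, ".tsv")))
  }
  list(vcf = vcf_path, cnv = cnv, cnv_file = cnv_path,
       truth = truth, truth_file = truth_path,
       tables = lapply(spec$genes, function(g) g$table), maps = maps,
       spec = spec)
}

#' Default synthetic study conditions
#'
#' A three-gene cohort emulating the structure of the real inputs: a
#' metabolizer gene with nonfunctional, decreased and increased alleles; a
#' warfarin-dose-style gene where two single-variant alleles co-occur on one
#' physical haplotype such that 15.5% of individuals carry the composite (the
#' per-sample rate observed for CYP4F2 *2+*3); and a CYP2D6-like gene with
#' whole-gene deletion and
#' duplication carrier rates of 3.31% and 0.79% (the observed CYP2D6 CNV
#' carrier percentages).
#'
#' @param n_samples Number of individuals (default 1000).
#' @param seed Integer seed.
#' @param platform Platform profile (default genome-sequencing-like).
#' @param missingness Per-genotype missing rate (default 0).
#' @param ... Passed through to [simulation_spec()].
#' @return A [simulation_spec()].
#' @export
default_simulation_spec <- function(n_samples = 1000, seed = 1,
                                    platform = platform_profile("GS", "all",
                                                                TRUE),
                                    missingness = 0, ...) {
  t1 <- simulate_table("CYP2C19S", n_alleles = 4,
                       variants_per_allele = c(1, 2, 1, 1),
                       function_classes = c("no_function", "decreased",
                                            "normal", "increased"),
                       seed = seed + 101L, contig = "10")
  t2 <- simulate_table("CYP4F2S", n_alleles = 2, variants_per_allele = 1,
                       function_classes = c("decreased", "normal"),
                       seed = seed + 202L, contig = "19",
                       base_pos = 15990000L)
  t3 <- simulate_table("CYP2D6S", n_alleles = 3,
                       variants_per_allele = c(1, 1, 2),
                       function_classes = c("decreased", "no_function",
                                            "normal"),
                       include_structural = TRUE, seed = seed + 303L,
                       contig = "22", base_pos = 42522500L)
  simulation_spec(
    genes = list(
      list(table = t1,
           freqs = c("*1" = 0.60, "*2" = 0.15, "*3" = 0.08, "*4" = 0.05,
                     "*5" = 0.12)),
      list(table = t2,
           # per-haplotype rate 0.0806 puts the two named alleles on the same
           # physical haplotype for 15.5% of individuals
           # (1 - (1 - 0.0806)^2 = 0.155)
           freqs = c("*1" = 0.55, "*2" = 0.30, "*3" = 0.15),
           composite_rate = 0.0806),
      list(table = t3,
           freqs = c("*1" = 0.70, "*2" = 0.15, "*3" = 0.05, "*4" = 0.10),
           cnv_del_rate = 0.0331, cnv_dup_rate = 0.0079)),
    n_samples = n_samples, seed = seed, platform = platform,
    missingness = missingness, ...)
}
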