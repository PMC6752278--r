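#' Star alleles fully matched by a haplotype
#'
#' Tests each star allele of the table, one by one, for the presence of all
#' of its defining variant states on the haplotype. A requirement is
#' satisfied only by the observed state — a missing genotype never satisfies
#' it. The reference allele matches if and only if no alternate state is
#' observed at any table variant. Structural (deletion/duplication) alleles
#' never match by variant states; they are assigned only through copy-number
#' integration.
#'
#' @param hap Named character vector `variant_id -> ref/alt/missing` whose
#'   names equal the table's variants.
#' @param tbl An [allele_table()].
#' @return Character vector of matching allele labels (star collation order).
#' @seealso [resolve_call()] for the full priority ladder.
#' @export
candidate_matches <- function(hap, tbl) {
  check_hap(hap, tbl)
  matchable <- tbl$alleles$label[tbl$alleles$structural == "none" &
                                   tbl$alleles$label != tbl$reference_label]
  r <- tbl$requirements
  # one vectorised pass over all requirement rows, then all() per allele
  sat <- hap[r$variant_id] == r$state
  ok_by_label <- tapply(sat, r$label, all)
  hits <- matchable[matchable %in% names(ok_by_label)[ok_by_label]]
  if (!any(hap == "alt")) hits <- c(hits, tbl$reference_label)
  sort_star_labels(unname(hits))
}

#' Star alleles compatible with a haplotype
#'
#' Like [candidate_matches()] but under no-contradiction semantics: a
#' requirement is also counted as satisfiable when the site is missing. The
#' compatible set is reported alongside ambiguous calls so that
#' missingness-driven ambiguity is visible, and is never used to *make* a
#' positive call.
#'
#' @inheritParams candidate_matches
#' @return Character vector of compatible allele labels.
#' @export
compatible_matches <- function(hap, tbl) {
  check_hap(hap, tbl)
  matchable <- tbl$alleles$label[tbl$alleles$structural == "none" &
                                   tbl$alleles$label != tbl$reference_label]
  r <- tbl$requirements
  obs <- hap[r$variant_id]
  sat <- obs == r$state | obs == "missing"
  ok_by_label <- tapply(sat, r$label, all)
  hits <- matchable[matchable %in% names(ok_by_label)[ok_by_label]]
  if (!any(hap == "alt")) hits <- c(hits, tbl$reference_label)
  sort_star_labels(unname(hits))
}

check_hap <- function(hap, tbl) {
  if (!setequal(names(hap), tbl$variants$variant_id)) {
    abort("precondition error: haplotype keys must equal the table's variants")
  }
  if (!all(hap %in% c("ref", "alt", "missing"))) {
    abort("precondition error: haplotype states must be ref/alt/missing")
  }
  invisible(TRUE)
}

required_alt_variants <- function(tbl, label) {
  rr <- tbl$requirements[tbl$requirements$label == label &
                           tbl$requirements$state == "alt", ]
  rr$variant_id
}

call_row <- function(gene, status, resolved_label, resolved_function,
                     candidates, compatible, unexplained, disclaimer) {
  tibble(gene = gene, status = status,
         resolved_label = resolved_label,
         resolved_function = resolved_function,
         candidates = list(candidates), compatible = list(compatible),
         unexplained_variants = list(unexplained),
         wildtype_disclaimer = disclaimer)
}

#' Resolve a haplotype to a star-allele call via the priority ladder
#'
#' Implements the match-priority ladder:
#'
#' 1. **Nonfunctional first.** Only alleles of class `no_function` are
#'    tested; any full match resolves the haplotype there (several matches
#'    are tie-broken by largest definition, then label), letting
#'    nonfunctional alleles override all others.
#' 2. **Remaining alleles.** A single remaining match resolves as `single`.
#'    Multiple matches whose definitions are pairwise disjoint and together
#'    explain every observed alternate state resolve as a `composite` call
#'    (`"*2+*3"`-style label; function = most severe member) — two named
#'    alleles detected on the same physical haplotype. Otherwise, if exactly
#'    one match has decreased function and the rest are normal, the
#'    decreased-function allele overrides. Anything else is `ambiguous`, with
#'    the candidate set retained. No match at all with at least one observed
#'    alternate state is `no_match` (an all-reference haplotype always
#'    matches the reference allele, so `no_match` with no alternate states
#'    cannot occur).
#'
#' A reference (`*1`-style) call made while one or more table variants are
#' missing carries `wildtype_disclaimer = TRUE`: wild-type status is only
#' asserted at the interrogated sites.
#'
#' @inheritParams candidate_matches
#' @param nonfunctional_semantics `"full"` (default) requires all defining
#'   states of a nonfunctional allele to be observed in pass 1;
#'   `"compatible"` lets missing sites satisfy pass-1 requirements.
#' @return One-row tibble: `gene`, `status` (`single`, `composite`,
#'   `ambiguous`, `no_match`), `resolved_label`, `resolved_function`,
#'   list-columns `candidates`, `compatible`, `unexplained_variants`, and
#'   `wildtype_disclaimer`.
#' @export
resolve_call <- function(hap, tbl,
                         nonfunctional_semantics = c("full", "compatible")) {
  nonfunctional_semantics <- match.arg(nonfunctional_semantics)
  check_hap(hap, tbl)
  gene <- tbl$gene
  observed_alt <- names(hap)[hap == "alt"]
  any_missing <- any(hap == "missing")
  cands <- candidate_matches(hap, tbl)
  compat <- compatible_matches(hap, tbl)
  nf <- tbl$alleles$label[tbl$alleles$function_class == "no_function" &
                            tbl$alleles$structural == "none"]
  pass1 <- if (nonfunctional_semantics == "full") intersect(cands, nf)
           else intersect(compat, nf)
  unexplained_by <- function(labels) {
    covered <- unique(unlist(lapply(labels, required_alt_variants,
                                    tbl = tbl)))
    setdiff(observed_alt, covered)
  }
  if (length(pass1) > 0) {
    n_req <- vapply(pass1, function(l) {
      sum(tbl$requirements$label == l)
    }, integer(1))
    pick <- pass1[order(-n_req, pass1)][[1]]
    return(call_row(gene, "single", pick, "no_function", cands, compat,
                    unexplained_by(pick), FALSE))
  }
  cands2 <- setdiff(cands, nf)
  if (length(cands2) == 0) {
    # reference matches whenever no alternate state is observed, so landing
    # here implies at least one unexplained alternate state
    return(call_row(gene, "no_match", NA_character_, NA_character_,
                    character(0), compat, observed_alt, FALSE))
  }
  fn_of <- function(labels) {
    tbl$alleles$function_class[match(labels, tbl$alleles$label)]
  }
  if (length(cands2) == 1) {
    lab <- cands2
    return(call_row(gene, "single", lab, fn_of(lab), cands, compat,
                    unexplained_by(lab),
                    lab == tbl$reference_label && any_missing))
  }
  # composite: pairwise-disjoint definitions that jointly explain every
  # observed alternate state (checked before the decreased-function override
  # so that e.g. a decreased + normal pair on one haplotype is reported as
  # the composite it is)
  members <- setdiff(cands2, tbl$reference_label)
  if (length(members) >= 2) {
    req_vids <- lapply(members, function(l) {
      tbl$requirements$variant_id[tbl$requirements$label == l]
    })
    all_vids <- unlist(req_vids)
    disjoint <- !anyDuplicated(all_vids)
    alt_union <- unique(unlist(lapply(members, required_alt_variants,
                                      tbl = tbl)))
    if (disjoint && setequal(alt_union, observed_alt) &&
        length(members) == length(cands2)) {
      lab <- paste(sort_star_labels(members), collapse = "+")
      return(call_row(gene, "composite", lab,
                      most_severe_function(fn_of(members)), cands, compat,
                      character(0), FALSE))
    }
  }
  fns <- fn_of(cands2)
  if (sum(fns == "decreased") == 1 && all(fns %in% c("decreased", "normal"))) {
    lab <- cands2[fns == "decreased"]
    return(call_row(gene, "single", lab, "decreased", cands, compat,
                    unexplained_by(lab), FALSE))
  }
  call_row(gene, "ambiguous", NA_character_, NA_character_, cands, compat,
           unexplained_by(cands), FALSE)
}

#' Call both haplotypes of a sample for one gene
#'
#' @param haps Tibble from [build_sample_haplotypes()] (`variant_id`, `hapA`,
#'   `hapB`).
#' @param tbl An [allele_table()].
#' @param ... Passed to [resolve_call()].
#' @return Two-row tibble (haplotypes `A` and `B`) of [resolve_call()]
#'   results with a `haplotype` column.
#' @export
call_sample_gene <- function(haps, tbl, ...) {
  a <- setNames(haps$hapA, haps$variant_id)
  b <- setNames(haps$hapB, haps$variant_id)
  bind_rows(
    mutate(resolve_call(a, tbl, ...), haplotype = "A"),
    mutate(resolve_call(b, tbl, ...), haplotype = "B")) |>
    select("gene", "haplotype", dplyr::everything())
}

#' Call every haplotype of a cohort for one gene
#'
#' Resolves each distinct haplotype state pattern once and maps results back
#' to samples, so cohorts of tens of thousands of samples resolve in seconds.
#'
#' @param chaps Tibble from [cohort_haplotypes()] (`sample`, `variant_id`,
#'   `hapA`, `hapB`).
#' @param tbl An [allele_table()].
#' @param ... Passed to [resolve_call()].
#' @return Tibble with one row per sample and haplotype: `sample`, `gene`,
#'   `haplotype`, `status`, `resolved_label`, `resolved_function`,
#'   list-columns `candidates`/`compatible`/`unexplained_variants`, and
#'   `wildtype_disclaimer`.
#' @export
call_gene_cohort <- function(chaps, tbl, ...) {
  vids <- tbl$variants$variant_id
  wide <- chaps |>
    arrange(.data$sample, match(.data$variant_id, vids))
  samples <- unique(wide$sample)
  n_v <- length(vids)
  if (nrow(wide) != length(samples) * n_v) {
    abort("precondition error: cohort haplotypes must cover samples x variants")
  }
  sigA <- vapply(split(wide$hapA, rep(seq_along(samples), each = n_v)),
                 paste, character(1), collapse = ",")
  sigB <- vapply(split(wide$hapB, rep(seq_along(samples), each = n_v)),
                 paste, character(1), collapse = ",")
  sigs <- unique(c(sigA, sigB))
  resolved <- lapply(sigs, function(s) {
    hap <- setNames(strsplit(s, ",", fixed = TRUE)[[1]], vids)
    resolve_call(hap, tbl, ...)
  })
  names(resolved) <- sigs
  per_hap <- function(sig, hap_name) {
    list_rbind(resolved[sig]) |>
      mutate(sample = samples, haplotype = hap_name)
  }
  bind_rows(per_hap(sigA, "A"), per_hap(sigB, "B")) |>
    arrange(.data$sample, .data$haplotype) |>
    select("sample", "gene", "haplotype", dplyr::everything())
}

#' Flatten haplotype calls for TSV export
#'
#' Collapses the list-columns of a haplotype-call tibble into comma-joined
#' strings (`sample, gene, haplotype, status, resolved_label, candidates,
#' function, unexplained_variants`).
#'
#' @param calls Haplotype-call tibble from [call_gene_cohort()].
#' @return Plain tibble of character/logical columns.
#' @export
flatten_haplotype_calls <- function(calls) {
  calls |>
    mutate(candidates = map_chr(.data$candidates, paste, collapse = ","),
           compatible = map_chr(.data$compatible, paste, collapse = ","),
           unexplained_variants = map_chr(.data$unexplained_variants, paste,
                                          collapse = ",")) |>
    rename(`function` = "resolved_function")
}
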