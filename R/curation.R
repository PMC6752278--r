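#' Read curation directives from TSV
#'
#' Curation directives encode the manual pruning applied to raw allele
#' definition tables before calling: dropping alleles with unknown function
#' or redundant proxies, merging suballeles into one named allele, dropping a
#' redundant defining variant from an allele (e.g. keeping a single tag
#' variant for an allele whose two defining variants are in complete LD), and
#' removing structural alleles on platforms without copy-number support.
#'
#' Columns: `gene`, `action` (`drop_allele`, `merge_alleles`,
#' `drop_variant_from_allele`, `drop_structural_for_platform`), `targets`
#' (comma-separated labels; for `drop_variant_from_allele`, the allele label
#' followed by variant ids), `merged_label` (for `merge_alleles`), `reason`.
#'
#' @param file TSV path, connection or literal text.
#' @return Tibble of directives.
#' @export
read_curation_directives <- function(file) {
  d <- readr::read_tsv(file, col_types = readr::cols(.default = "c"),
                       progress = FALSE, na = character())
  need <- c("gene", "action", "targets")
  if (!all(need %in% names(d))) {
    abort("curation error: directive file needs gene/action/targets columns")
  }
  if (!"merged_label" %in% names(d)) d$merged_label <- ""
  if (!"reason" %in% names(d)) d$reason <- ""
  as_tibble(d)
}

split_targets <- function(targets) {
  trimws(strsplit(targets, ",", fixed = TRUE)[[1]])
}

curation_error <- function(directive, msg) {
  abort(paste0("curation error in directive [", directive$action, " ",
               directive$targets, "]: ", msg))
}

apply_one_directive <- function(tbl, d, profile, strict) {
  labels <- tbl$alleles$label
  targets <- split_targets(d$targets)
  if (d$action == "drop_allele") {
    missing <- setdiff(targets, labels)
    if (length(missing) > 0 && strict) {
      curation_error(d, paste("unknown allele", paste(missing, collapse = ",")))
    }
    hit <- intersect(targets, labels)
    if (any(hit == tbl$reference_label)) {
      curation_error(d, "cannot drop the reference allele")
    }
    tbl$alleles <- tbl$alleles[!labels %in% hit, ]
    tbl$requirements <- tbl$requirements[!tbl$requirements$label %in% hit, ]
  } else if (d$action == "merge_alleles") {
    if (is.na(d$merged_label) || d$merged_label == "") {
      curation_error(d, "merge_alleles needs merged_label")
    }
    present <- intersect(targets, labels)
    if (length(present) < length(targets) && strict &&
        !(length(present) == 0 && d$merged_label %in% labels)) {
      curation_error(d, "merge source label not in table")
    }
    if (length(present) == 0) return(tbl)  # already merged
    reqs <- purrr::map(present, ~allele_requirements(tbl, .x))
    # union-compatibility: no variant at which sources demand opposite states
    all_vids <- unique(unlist(lapply(reqs, names)))
    for (vid in all_vids) {
      states <- unique(unlist(lapply(reqs, function(r) r[vid])))
      states <- states[!is.na(states)]
      if (length(states) > 1) {
        curation_error(d, paste("conflicting required states at", vid))
      }
    }
    # the merged allele keeps the shared core so it matches wherever any
    # source matched
    core_vids <- Reduce(intersect, lapply(reqs, names))
    if (length(core_vids) == 0) {
      curation_error(d, "merge sources share no defining variant")
    }
    fn <- most_severe_function(
      tbl$alleles$function_class[labels %in% present])
    tbl$alleles <- tbl$alleles[!labels %in% present, ]
    tbl$requirements <- tbl$requirements[!tbl$requirements$label %in% present, ]
    tbl$alleles <- bind_rows(tbl$alleles,
                             tibble(label = d$merged_label,
                                    function_class = fn, structural = "none"))
    tbl$requirements <- bind_rows(
      tbl$requirements,
      tibble(label = d$merged_label, variant_id = core_vids,
             state = unname(reqs[[1]][core_vids])))
  } else if (d$action == "drop_variant_from_allele") {
    lab <- targets[[1]]; vids <- targets[-1]
    if (!lab %in% labels) {
      if (strict) curation_error(d, paste("unknown allele", lab))
      return(tbl)
    }
    known <- vids %in% tbl$variants$variant_id
    if (any(!known) && strict) {
      curation_error(d, paste("unknown variant",
                              paste(vids[!known], collapse = ",")))
    }
    drop <- tbl$requirements$label == lab & tbl$requirements$variant_id %in% vids
    tbl$requirements <- tbl$requirements[!drop, ]
  } else if (d$action == "drop_structural_for_platform") {
    if (is.null(profile)) {
      curation_error(d, "drop_structural_for_platform needs a platform profile")
    }
    if (!profile$supports_cnv) {
      hit <- labels[tbl$alleles$structural != "none"]
      if (length(targets) > 0 && !identical(targets, "")) {
        hit <- intersect(hit, targets)
      }
      tbl$alleles <- tbl$alleles[!tbl$alleles$label %in% hit, ]
    }
  } else {
    curation_error(d, "unknown action")
  }
  tbl
}

#' Apply curation directives to a definition table
#'
#' Applies directives in order (see [read_curation_directives()] for the
#' actions), then prunes variants no longer required by any surviving allele
#' and re-validates the table. `drop_structural_for_platform` removes
#' structural (deletion/duplication) alleles only when the supplied platform
#' profile lacks copy-number support.
#'
#' @param tbl An [allele_table()].
#' @param directives Tibble of directives (rows for other genes are ignored).
#' @param profile Optional [platform_profile()]; required by
#'   `drop_structural_for_platform` directives.
#' @param strict If `TRUE` (default), a directive naming a target absent from
#'   the table is an error; with `FALSE` such directives are skipped, which
#'   makes curation idempotent (re-applying an applied directive list is a
#'   no-op).
#' @return A curated, validated `allele_table`.
#' @examples
#' txt <- paste("gene\tlabel\tfunction\tstructural\t1:10:A:G\t1:20:C:T",
#'   "DPYD\t*1\tnormal\tnone\t\t",
#'   "DPYD\t*9A\tnormal\tnone\talt\t",
#'   "DPYD\t*9B\tnormal\tnone\talt\talt", sep = "\n")
#' tbl <- parse_definition_table(txt)
#' d <- tibble::tibble(gene = "DPYD", action = "merge_alleles",
#'   targets = "*9A,*9B", merged_label = "*9", reason = "suballeles")
#' apply_curation(tbl, d)
#' @export
apply_curation <- function(tbl, directives, profile = NULL, strict = TRUE) {
  stopifnot(inherits(tbl, "allele_table"))
  directives <- as_tibble(directives)
  if (nrow(directives) > 0 && "gene" %in% names(directives)) {
    directives <- directives[directives$gene == tbl$gene, ]
  }
  n_applied <- nrow(directives)
  for (i in seq_len(n_applied)) {
    tbl <- apply_one_directive(tbl, directives[i, ], profile, strict)
  }
  if (n_applied > 0) {
    # prune variants no surviving allele requires
    used <- unique(tbl$requirements$variant_id)
    tbl$variants <- tbl$variants[tbl$variants$variant_id %in% used, ]
  }
  validate_allele_table(tbl)
  tbl
}
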