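#' Read per-sample copy-number calls
#'
#' @param file TSV with columns `sample`, `gene`, `event`
#'   (`deletion`/`duplication`/`normal`) and optional `copy_number`.
#' @return Validated tibble of CNV records.
#' @export
read_cnv_calls <- function(file) {
  d <- readr::read_tsv(file, col_types = readr::cols(
    sample = "c", gene = "c", event = "c", copy_number = "i"),
    progress = FALSE)
  validate_cnv_records(d)
}

#' Validate copy-number records
#'
#' Checks event vocabulary and, where a copy number is given, its consistency
#' with the event (deletion implies at most 1 copy, duplication at least 3).
#' Copy numbers above 3 are still duplications (the extra copies are not
#' annotated on the `xN` label).
#'
#' @param records Tibble with `sample`, `gene`, `event`, optional
#'   `copy_number`.
#' @return The tibble, invisibly validated.
#' @export
validate_cnv_records <- function(records) {
  records <- as_tibble(records)
  if (!"copy_number" %in% names(records)) records$copy_number <- NA_integer_
  if (!all(records$event %in% c("deletion", "duplication", "normal"))) {
    abort("data error: CNV event must be deletion/duplication/normal")
  }
  cn <- records$copy_number
  bad <- (records$event == "deletion" & !is.na(cn) & cn > 1) |
    (records$event == "duplication" & !is.na(cn) & cn < 3) |
    (!is.na(cn) & cn < 0)
  if (any(bad)) {
    abort("data error: copy_number inconsistent with CNV event")
  }
  records
}

#' Adjust a diplotype's labels for a whole-gene deletion or duplication
#'
#' For a **deletion**, one haplotype label is replaced by the deletion allele
#' (`*5` for CYP2D6): the reference-labelled haplotype when present (a
#' deleted gene copy carries no observed alternate states, so it presents as
#' reference), otherwise the lower-severity label, flagged (imputed data can
#' be inconsistent with the CNV call). For a **duplication**, the first label
#' of `priority` present in the pair gains the `xN` suffix — the duplication
#' order reflects previously reported European duplication frequencies; if
#' neither priority label is present, the higher-severity label gains `xN`
#' and the record is flagged. `normal` events change nothing.
#'
#' @param labels Character vector of the two haplotype labels.
#' @param functions Character vector of the two labels' function classes.
#' @param event `"deletion"`, `"duplication"` or `"normal"`.
#' @param priority Ordered labels assumed to be duplicated first (default
#'   `c("*2", "*1", "*4")`).
#' @param deletion_label Label of the whole-gene deletion allele (default
#'   `"*5"`).
#' @param reference_label Reference label (default `"*1"`).
#' @return List with `labels` (adjusted pair, same order) and `flagged`
#'   (logical: the documented fallback rule had to be used).
#' @examples
#' integrate_cnv(c("*2", "*4"), c("decreased", "no_function"), "duplication")
#' @export
integrate_cnv <- function(labels, functions, event,
                          priority = c("*2", "*1", "*4"),
                          deletion_label = "*5", reference_label = "*1") {
  stopifnot(length(labels) == 2, length(functions) == 2)
  if (!event %in% c("deletion", "duplication", "normal")) {
    abort("data error: CNV event must be deletion/duplication/normal")
  }
  if (event == "normal") {
    return(list(labels = labels, flagged = FALSE))
  }
  sev <- function_severity(functions)
  if (event == "deletion") {
    is_ref <- labels == reference_label
    if (any(is_ref)) {
      i <- which(is_ref)[length(which(is_ref))]  # prefer the second of two
      labels[i] <- deletion_label
      return(list(labels = labels, flagged = FALSE))
    }
    i <- which.min(sev)
    labels[i] <- deletion_label
    return(list(labels = labels, flagged = TRUE))
  }
  # duplication
  for (p in priority) {
    if (p %in% labels) {
      i <- which(labels == p)[1]
      labels[i] <- paste0(labels[i], "xN")
      return(list(labels = labels, flagged = FALSE))
    }
  }
  i <- which.max(sev)
  labels[i] <- paste0(labels[i], "xN")
  list(labels = labels, flagged = TRUE)
}

#' Integrate copy-number calls into cohort haplotype calls
#'
#' Applies [integrate_cnv()] to each sample with a non-`normal` CNV record
#' for the table's gene. Only samples whose two haplotype calls are both
#' resolved (`single` or `composite`) are adjusted; others are flagged and
#' passed through unchanged. Requesting CNV integration on a platform that
#' cannot support copy-number detection is a configuration error.
#'
#' @param calls Haplotype-call tibble from [call_gene_cohort()].
#' @param cnv Tibble of CNV records ([read_cnv_calls()]).
#' @param profile Optional [platform_profile()]; if given, `supports_cnv`
#'   must be `TRUE`.
#' @inheritParams integrate_cnv
#' @return `calls` with adjusted `resolved_label`s and an added `cnv_flagged`
#'   logical column.
#' @export
integrate_cnv_calls <- function(calls, cnv, profile = NULL,
                                priority = c("*2", "*1", "*4"),
                                deletion_label = "*5",
                                reference_label = "*1") {
  if (!is.null(profile) && !profile$supports_cnv) {
    abort(paste0("configuration error: platform ", profile$name,
                 " does not support copy-number detection"))
  }
  cnv <- validate_cnv_records(cnv)
  calls$cnv_flagged <- FALSE
  cnv <- cnv[cnv$gene %in% calls$gene & cnv$event != "normal", ]
  for (i in seq_len(nrow(cnv))) {
    rec <- cnv[i, ]
    idx <- which(calls$sample == rec$sample & calls$gene == rec$gene)
    if (length(idx) != 2) next
    idx <- idx[order(calls$haplotype[idx])]
    if (!all(calls$status[idx] %in% c("single", "composite"))) {
      calls$cnv_flagged[idx] <- TRUE
      next
    }
    adj <- integrate_cnv(calls$resolved_label[idx],
                         calls$resolved_function[idx], rec$event,
                         priority = priority,
                         deletion_label = deletion_label,
                         reference_label = reference_label)
    changed <- calls$resolved_label[idx] != adj$labels
    calls$resolved_label[idx] <- adj$labels
    calls$resolved_function[idx[changed & adj$labels == deletion_label]] <-
      "no_function"
    calls$cnv_flagged[idx] <- adj$flagged
  }
  calls
}
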