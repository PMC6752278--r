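#' Construct a star-allele definition table
#'
#' The in-memory form of a gene's allele definition table: the variants that
#' define its star alleles, the alleles themselves with their function class
#' and structural status, and the required variant states per allele. The
#' reference allele (conventionally `*1`) is the row with no required states
#' and normal function; structural deletion alleles (e.g. CYP2D6 `*5`) also
#' carry no SNV requirements and are only ever assigned through copy-number
#' integration, never by haplotype matching.
#'
#' @param gene Gene symbol.
#' @param variants Tibble with columns `contig`, `pos`, `ref`, `alt` and
#'   optionally `rsid`; one row per defining variant (GRCh37 coordinates,
#'   1-based).
#' @param alleles Tibble with columns `label`, `function_class`
#'   (`no_function`, `decreased`, `normal`, `increased`, `unknown`) and
#'   `structural` (`none`, `deletion`, `duplication`).
#' @param requirements Tibble with columns `label`, `variant_id`, `state`
#'   (`ref` or `alt`): the variant states an allele requires.
#' @param reference_label Label of the reference allele (default `"*1"`).
#' @return An `allele_table` object (validated).
#' @seealso [parse_definition_table()], [apply_curation()]
#' @export
allele_table <- function(gene, variants, alleles, requirements,
                         reference_label = "*1") {
  variants <- as_tibble(variants)
  if (!"rsid" %in% names(variants)) variants$rsid <- NA_character_
  variants <- variants |>
    mutate(pos = as.integer(.data$pos),
           variant_id = variant_id(.data$contig, .data$pos, .data$ref,
                                   .data$alt)) |>
    select("variant_id", "contig", "pos", "ref", "alt", "rsid")
  alleles <- as_tibble(alleles)
  if (!"structural" %in% names(alleles)) alleles$structural <- "none"
  requirements <- as_tibble(requirements)
  if (nrow(requirements) == 0) {
    requirements <- tibble(label = character(), variant_id = character(),
                           state = character())
  }
  tbl <- structure(
    list(gene = gene, reference_label = reference_label,
         variants = variants,
         alleles = alleles[c("label", "function_class", "structural")],
         requirements = requirements[c("label", "variant_id", "state")]),
    class = "allele_table")
  validate_allele_table(tbl)
  tbl
}

#' Validate an allele definition table
#'
#' Checks every structural invariant: positive 1-based positions, non-empty
#' distinct ref/alt, unique variants, unique allele labels, requirements that
#' point at table variants with states in `{ref, alt}`, exactly one reference
#' allele with no requirements and normal function, empty requirements for
#' deletion alleles, and no two non-structural alleles sharing an identical
#' definition.
#'
#' @param tbl An `allele_table`.
#' @return `tbl`, invisibly; aborts with a format error otherwise.
#' @export
validate_allele_table <- function(tbl) {
  stopifnot(inherits(tbl, "allele_table"))
  v <- tbl$variants; a <- tbl$alleles; r <- tbl$requirements
  if (any(v$pos < 1)) abort("format error: variant pos must be >= 1")
  if (any(v$ref == "" | v$alt == "" | is.na(v$ref) | is.na(v$alt))) {
    abort("format error: ref and alt must be non-empty")
  }
  if (any(v$ref == v$alt)) abort("format error: ref == alt in a variant")
  if (anyDuplicated(v$variant_id)) {
    abort("format error: duplicate variant (contig,pos,ref,alt)")
  }
  if (anyDuplicated(a$label)) {
    abort(paste0("format error: duplicate allele labels in ", tbl$gene))
  }
  function_severity(a$function_class)  # errors on unknown class names
  if (!all(a$structural %in% c("none", "deletion", "duplication"))) {
    abort("format error: structural must be none/deletion/duplication")
  }
  if (!all(r$state %in% c("ref", "alt"))) {
    abort("format error: required state must name 'ref' or 'alt'")
  }
  if (!all(r$variant_id %in% v$variant_id)) {
    abort("format error: requirement references a variant not in the table")
  }
  if (!all(r$label %in% a$label)) {
    abort("format error: requirement references an unknown allele label")
  }
  if (anyDuplicated(r[c("label", "variant_id")])) {
    abort("format error: duplicate requirement for one allele and variant")
  }
  if (sum(a$label == tbl$reference_label) != 1) {
    abort(paste0("format error: no reference row ('", tbl$reference_label,
                 "') in ", tbl$gene))
  }
  ref_req <- r$label == tbl$reference_label
  if (any(ref_req)) {
    abort("format error: reference allele must have no required states")
  }
  ref_row <- a[a$label == tbl$reference_label, ]
  if (ref_row$function_class != "normal" || ref_row$structural != "none") {
    abort("format error: reference allele must be normal function, non-structural")
  }
  del <- a$label[a$structural == "deletion"]
  if (any(r$label %in% del)) {
    abort("format error: deletion alleles must have empty required states")
  }
  # non-structural alleles other than the reference need >= 1 requirement and
  # pairwise-distinct definitions
  ns <- a$label[a$structural == "none" & a$label != tbl$reference_label]
  sig <- vapply(ns, function(lab) {
    rr <- r[r$label == lab, ]
    if (nrow(rr) == 0) {
      abort(paste0("format error: non-reference allele ", lab,
                   " has no required states"))
    }
    paste(sort(paste(rr$variant_id, rr$state)), collapse = ";")
  }, character(1))
  if (anyDuplicated(sig)) {
    abort("format error: two non-structural alleles share one definition")
  }
  invisible(tbl)
}

#' @exportS3Method base::print
print.allele_table <- function(x, ...) {
  cat("<allele_table> ", x$gene, ": ", nrow(x$alleles), " alleles, ",
      nrow(x$variants), " variants (reference ", x$reference_label, ")\n",
      sep = "")
  invisible(x)
}

is_variant_header <- function(h) {
  grepl("^[^:[:space:]]+:[0-9]+:[A-Za-z]+:[A-Za-z]+(:[^:[:space:]]+)?$", h)
}

parse_variant_header <- function(h) {
  parts <- strsplit(h, ":", fixed = TRUE)[[1]]
  tibble(contig = parts[[1]], pos = as.integer(parts[[2]]),
         ref = parts[[3]], alt = parts[[4]],
         rsid = if (length(parts) >= 5) parts[[5]] else NA_character_)
}

#' Parse an allele definition table from TSV
#'
#' Reads the package's documented tab-separated dialect: fixed columns
#' `gene`, `label`, `function`, `structural`, then one column per defining
#' variant headed `contig:pos:ref:alt[:rsid]`, with cell values `ref`, `alt`
#' or blank (blank = state not required by that allele). One row per star
#' allele; the reference allele is the non-structural row with no required
#' states.
#'
#' @param file Path to a TSV file, a connection, or a literal string of TSV
#'   text (anything [readr::read_tsv()] accepts).
#' @param gene Optional gene symbol; if supplied, rows are restricted to it
#'   (one file may hold several genes). If `NULL` the file must contain a
#'   single gene.
#' @return A validated [allele_table()].
#' @examples
#' txt <- paste(
#'   "gene\tlabel\tfunction\tstructural\t10:94781859:G:A:rs4244285",
#'   "CYP2C19\t*1\tnormal\tnone\t",
#'   "CYP2C19\t*2\tno_function\tnone\talt",
#'   sep = "\n")
#' parse_definition_table(txt)
#' @export
parse_definition_table <- function(file, gene = NULL) {
  raw <- readr::read_tsv(file, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = character())
  fixed <- c("gene", "label", "function", "structural")
  if (!all(fixed %in% names(raw))) {
    abort("format error: definition table needs gene/label/function/structural columns")
  }
  vcols <- setdiff(names(raw), fixed)
  if (!all(is_variant_header(vcols))) {
    bad <- vcols[!is_variant_header(vcols)]
    abort(paste0("format error: bad variant column header: ",
                 paste(bad, collapse = ", ")))
  }
  if (!is.null(gene)) raw <- raw[raw$gene == gene, ]
  genes <- unique(raw$gene)
  if (length(genes) != 1) {
    abort("format error: expected exactly one gene (pass `gene=` to select)")
  }
  variants <- purrr::map(vcols, parse_variant_header) |> list_rbind()
  states <- raw[vcols]
  bad_state <- !as.matrix(states) %in% c("", "ref", "alt")
  if (any(bad_state)) {
    abort("format error: required state must name 'ref' or 'alt'")
  }
  vids <- variant_id(variants$contig, variants$pos, variants$ref, variants$alt)
  requirements <- purrr::imap(states, function(col, j) {
    keep <- col != ""
    tibble(label = raw$label[keep],
           variant_id = vids[[match(j, vcols)]],
           state = col[keep])
  }) |> list_rbind()
  n_req <- vapply(raw$label,
                  function(l) sum(requirements$label == l), integer(1))
  ref_rows <- raw$structural == "none" & n_req == 0
  if (sum(ref_rows) == 0) abort("format error: no reference row")
  if (sum(ref_rows) > 1) {
    abort("format error: several non-structural rows have no required states")
  }
  allele_table(
    gene = genes,
    variants = variants,
    alleles = tibble(label = raw$label,
                     function_class = raw[["function"]],
                     structural = raw$structural),
    requirements = requirements,
    reference_label = raw$label[ref_rows])
}

#' Write an allele definition table to TSV
#'
#' Inverse of [parse_definition_table()]: emits the package's TSV dialect so
#' a write/parse round trip reproduces an equal table.
#'
#' @param tbl An `allele_table`.
#' @param file Path to write to.
#' @return `file`, invisibly.
#' @export
write_definition_table <- function(tbl, file) {
  stopifnot(inherits(tbl, "allele_table"))
  v <- tbl$variants
  headers <- ifelse(is.na(v$rsid), v$variant_id,
                    paste(v$variant_id, v$rsid, sep = ":"))
  cells <- matrix("", nrow = nrow(tbl$alleles), ncol = nrow(v),
                  dimnames = list(NULL, v$variant_id))
  for (i in seq_len(nrow(tbl$requirements))) {
    r <- tbl$requirements[i, ]
    cells[match(r$label, tbl$alleles$label), r$variant_id] <- r$state
  }
  out <- cbind(
    data.frame(gene = tbl$gene, label = tbl$alleles$label,
               `function` = tbl$alleles$function_class,
               structural = tbl$alleles$structural, check.names = FALSE),
    as.data.frame(cells, check.names = FALSE))
  names(out)[-(1:4)] <- headers
  readr::write_tsv(out, file, progress = FALSE)
  invisible(file)
}

#' Requirements of one allele as a named state vector
#' @param tbl An `allele_table`.
#' @param label Allele label.
#' @return Named character vector `variant_id -> state`.
#' @keywords internal
allele_requirements <- function(tbl, label) {
  rr <- tbl$requirements[tbl$requirements$label == label, ]
  setNames(rr$state, rr$variant_id)
}
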