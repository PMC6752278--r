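#' Define a genotyping platform profile
#'
#' A platform profile declares which defining variants a platform can
#' interrogate directly and whether it supports gene-level copy-number
#' detection. A genome-sequencing-like profile types everything
#' (`typable = "all"`); array and exome profiles carry an explicit list of
#' typable variants, and arrays with sparse coverage of CYP2D6 (or exome
#' capture) cannot support CNV calling.
#'
#' @param name Platform name (e.g. `"GS"`, `"ES"`, `"GSA"`, `"OMNI"`).
#' @param typable `"all"`, or a character vector of typable variant ids
#'   (`contig:pos:ref:alt`).
#' @param supports_cnv Logical; whether whole-gene deletions/duplications are
#'   detectable on this platform.
#' @return A `platform_profile` object.
#' @examples
#' platform_profile("GS", "all", supports_cnv = TRUE)
#' @export
platform_profile <- function(name, typable = "all", supports_cnv = TRUE) {
  if (!identical(typable, "all") && !is.character(typable)) {
    abort("typable must be \"all\" or a character vector of variant ids")
  }
  structure(list(name = name, typable = typable,
                 supports_cnv = isTRUE(supports_cnv)),
            class = "platform_profile")
}

#' @exportS3Method base::print
print.platform_profile <- function(x, ...) {
  cov <- if (identical(x$typable, "all")) "all variants"
         else paste(length(x$typable), "variants")
  cat("<platform_profile> ", x$name, ": types ", cov, ", CNV ",
      if (x$supports_cnv) "supported" else "unsupported", "\n", sep = "")
  invisible(x)
}

#' Is a variant typable on a platform?
#' @param profile A `platform_profile`.
#' @param vids Character vector of variant ids.
#' @return Logical vector.
#' @export
is_typable <- function(profile, vids) {
  stopifnot(inherits(profile, "platform_profile"))
  if (identical(profile$typable, "all")) rep(TRUE, length(vids))
  else vids %in% profile$typable
}

#' Platform typability report
#'
#' Counts how many of a table's defining variants a platform could directly
#' genotype, with the percentage rounded half away from zero to the integer —
#' the figure reported when comparing platforms' coverage of allele
#' definition tables.
#'
#' @param variants Tibble of variants with a `variant_id` column (as in an
#'   `allele_table`), or a character vector of variant ids.
#' @param profile A [platform_profile()].
#' @return One-row tibble: `platform`, `n_typable`, `n_total`, `percent`.
#' @examples
#' vids <- sprintf("1:%d:A:G", 1:4)
#' typability_report(vids, platform_profile("GS", "all"))
#' @export
typability_report <- function(variants, profile) {
  vids <- if (is.character(variants)) variants else variants$variant_id
  if (length(vids) == 0) abort("precondition error: empty variant list")
  k <- sum(is_typable(profile, vids))
  tibble(platform = profile$name, n_typable = k, n_total = length(vids),
         percent = round_half_out(100 * k / length(vids), 0))
}
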