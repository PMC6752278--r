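#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves rounded away from zero, the
#' convention used for all printed percentages in this package (base R's
#' `round()` rounds half to even). A tiny snap-to-grid guards against
#' binary-representation noise such as `100 * 307 / 356` landing a hair below
#' the half.
#'
#' @param x Numeric vector.
#' @param digits Integer number of decimal places (default 0).
#' @return Numeric vector of the same length.
#' @examples
#' round_half_out(2.5)   # 3, not 2
#' round_half_out(-2.5)  # -3
#' @export
round_half_out <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1, digits >= 0)
  u <- round(abs(x) * 10^digits, 9)
  sign(x) * floor(u + 0.5) / 10^digits
}

# Severity ranking of allele function classes: a composite or override call
# takes the most severe class present. Higher = more severe.
FUNCTION_CLASSES <- c("no_function", "decreased", "normal", "increased",
                      "unknown")

#' Severity rank of allele function classes
#'
#' @param fn Character vector of function classes
#'   (`no_function`, `decreased`, `normal`, `increased`, `unknown`).
#' @return Integer severity ranks; `no_function` is highest (4), `unknown`
#'   lowest (0).
#' @export
function_severity <- function(fn) {
  ranks <- c(no_function = 4L, decreased = 3L, normal = 2L, increased = 1L,
             unknown = 0L)
  bad <- setdiff(unique(fn), names(ranks))
  if (length(bad) > 0) {
    abort(paste0("unknown function class: ", paste(bad, collapse = ", ")))
  }
  unname(ranks[fn])
}

#' Most severe function class among several
#' @param fn Character vector of function classes.
#' @return Single function class string.
#' @export
most_severe_function <- function(fn) {
  fn[which.max(function_severity(fn))]
}

# Collation key for star labels: numeric star order, then suffix, so that
# "*1/*2" and "*2/*1" normalise to the same diplotype key. Composite labels
# ("*2+*3") sort by their first member, suffixed labels ("*2xN") after the
# bare label.
star_sort_key <- function(labels) {
  num <- suppressWarnings(as.numeric(sub("^\\*?([0-9]+).*$", "\\1", labels)))
  num[is.na(num)] <- Inf
  suffix <- sub("^\\*?[0-9]*", "", labels)
  order(num, suffix, labels)
}

#' Sort star-allele labels in star collation order
#'
#' Numeric star order first (`*2` before `*10`), then suffix, so ordering is
#' stable and human-natural.
#'
#' @param labels Character vector of star labels.
#' @return Sorted character vector.
#' @export
sort_star_labels <- function(labels) {
  labels[star_sort_key(labels)]
}

#' Canonical unordered diplotype key
#'
#' Normalises an allele pair into a single `a/b` string that is invariant
#' under haplotype order (`*1/*2` and `*2/*1` yield the identical key).
#'
#' @param a,b Character vectors of star labels (recycled pairwise).
#' @return Character vector of `a/b` keys.
#' @examples
#' diplotype_key("*2", "*1")  # "*1/*2"
#' @export
diplotype_key <- function(a, b) {
  stopifnot(length(a) == length(b))
  vapply(seq_along(a), function(i) {
    paste(sort_star_labels(c(a[[i]], b[[i]])), collapse = "/")
  }, character(1))
}

variant_id <- function(contig, pos, ref, alt) {
  paste(contig, pos, ref, alt, sep = ":")
}
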