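#' Plot cohort star-allele frequencies
#'
#' Stacked-bar view of resolved allele frequencies per gene, the standard way
#' cohort star-allele spectra are displayed; labels below `min_freq` are
#' pooled into "Other" for legibility.
#'
#' @param summary A `starcall_summary` (from [summarize_cohort()]) or its
#'   `allele_freqs` tibble.
#' @param min_freq Frequencies below this are pooled as `"Other"`
#'   (default 0.02).
#' @return A ggplot object.
#' @export
plot_allele_frequencies <- function(summary, min_freq = 0.02) {
  freqs <- if (inherits(summary, "starcall_summary")) summary$allele_freqs
           else as_tibble(summary)
  dat <- freqs |>
    mutate(label = if_else(.data$freq < min_freq, "Other", .data$label)) |>
    group_by(.data$gene, .data$label) |>
    summarise(freq = sum(.data$freq), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$gene, y = .data$freq,
                                    fill = .data$label)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%g%%",
                                                             100 * x)) +
    ggplot2::labs(x = NULL, y = "Haplotype frequency",
                  fill = "Star allele") +
    ggplot2::theme_minimal()
}

#' Plot cohort phenotype frequencies
#'
#' @inheritParams plot_allele_frequencies
#' @return A ggplot object.
#' @export
plot_phenotype_frequencies <- function(summary, min_freq = 0.02) {
  freqs <- if (inherits(summary, "starcall_summary")) summary$phenotype_freqs
           else as_tibble(summary)
  dat <- freqs |>
    mutate(phenotype = if_else(.data$freq < min_freq, "Other",
                               .data$phenotype)) |>
    group_by(.data$gene, .data$phenotype) |>
    summarise(freq = sum(.data$freq), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$gene, y = .data$freq,
                                    fill = .data$phenotype)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%g%%",
                                                             100 * x)) +
    ggplot2::labs(x = NULL, y = "Individuals", fill = "Phenotype") +
    ggplot2::theme_minimal()
}

#' Autoplot a cohort summary
#'
#' @param object A `starcall_summary`.
#' @param type `"alleles"` (default) or `"phenotypes"`.
#' @param ... Passed to the plot function.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.starcall_summary <- function(object,
                                      type = c("alleles", "phenotypes"),
                                      ...) {
  type <- match.arg(type)
  if (type == "alleles") plot_allele_frequencies(object, ...)
  else plot_phenotype_frequencies(object, ...)
}

#' @export
ggplot2::autoplot
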