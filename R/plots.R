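#' @importFrom ggplot2 ggplot aes geom_point geom_col geom_line geom_abline
#'   geom_hline labs facet_wrap theme_minimal autoplot scale_fill_brewer
NULL

#' Scatter plot of paired 5' UTR lengths
#'
#' @param pairs tibble from [build_utr_pairs()].
#' @return A ggplot.
#' @export
plot_utr_lengths <- function(pairs) {
  ggplot(pairs, aes(x = .data$len_a, y = .data$len_b)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_point(alpha = 0.6) +
    labs(x = "5' UTR length, species A (nt)",
         y = "5' UTR length, species B (nt)",
         title = "Paired 5' UTR lengths from conserved promoters") +
    theme_minimal()
}

#' Plot the conservation profile around translation starts
#'
#' @param profile tibble from [conservation_profile()].
#' @return A ggplot.
#' @export
plot_conservation_profile <- function(profile) {
  ggplot(profile, aes(x = .data$offset, y = .data$frac_identical)) +
    geom_line() +
    geom_hline(yintercept = 0.25, linetype = "dotted", colour = "grey60") +
    labs(x = "offset from translation start (nt)", y = "fraction identical",
         title = "Sequence conservation around orthologous translation starts") +
    theme_minimal()
}

#' Plot base preference around the TSS
#'
#' @param object a `dinuc_pref` from [dinucleotide_preference()].
#' @param ... unused.
#' @return A ggplot.
#' @export
plot_dinucleotide_preference <- function(object, ...) {
  ggplot(tidy(object), aes(x = factor(.data$offset), y = .data$fraction,
                           fill = .data$base)) +
    geom_col() +
    scale_fill_brewer(palette = "Set1") +
    labs(x = "offset from TSS (+1 = TSS base)", y = "base fraction",
         title = "Dinucleotide preference at the TSS") +
    theme_minimal()
}

#' @rdname plot_dinucleotide_preference
#' @method autoplot dinuc_pref
#' @export
autoplot.dinuc_pref <- function(object, ...) plot_dinucleotide_preference(object, ...)

#' Bar plot of promoter conservation categories per species
#'
#' @param summary tibble from [summarize_categories()].
#' @return A ggplot.
#' @export
plot_category_summary <- function(summary) {
  ggplot(summary, aes(x = .data$category, y = .data$n, fill = .data$category)) +
    geom_col(show.legend = FALSE) +
    facet_wrap(~ .data$species) +
    scale_fill_brewer(palette = "Set2") +
    labs(x = NULL, y = "TSSs",
         title = "Promoter conservation categories") +
    theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
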