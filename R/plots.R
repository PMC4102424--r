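#' Plot stratified mutability estimates
#'
#' Mutability (mean squared repeat-number difference) against repeat
#' number, one line per stratum, with bootstrap percentile ribbons,
#' faceted by motif size. The y axis is logarithmic, since interruption
#' effects span orders of magnitude.
#'
#' @param object An `ims_mutability` tibble from [stratified_mutability()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ims_mutability <- function(object, ...) {
  d <- tidy(object) %>% filter(.data$mu > 0 | .data$ci_high > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$repeat_number, y = .data$mu,
                                  colour = .data$stratum,
                                  fill = .data$stratum)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~motif_size, scales = "free",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "repeat number", y = "mutability (units²)",
                  colour = "stratum", fill = "stratum") +
    ggplot2::theme_minimal()
}

#' Plot a binned heterozygosity distribution
#'
#' @param het A tibble from [het_distribution()].
#' @return A ggplot.
#' @export
plot_het_distribution <- function(het) {
  ggplot2::ggplot(het, ggplot2::aes(x = .data$bin_lo + diff(c(0, het$bin_hi[1])) / 2,
                                    y = .data$freq)) +
    ggplot2::geom_col(width = het$bin_hi[1] - het$bin_lo[1],
                      fill = "steelblue") +
    ggplot2::labs(x = "heterozygosity (2pq)", y = "frequency") +
    ggplot2::theme_minimal()
}

#' Plot population-sharing counts of interruption calls
#'
#' @param sharing A tibble from [sharing_partition()].
#' @return A ggplot.
#' @export
plot_sharing <- function(sharing) {
  d <- sharing %>% arrange(.data$n_populations, .data$populations) %>%
    mutate(populations = factor(.data$populations,
                                levels = unique(.data$populations)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$populations, y = .data$n,
                                  fill = .data$sharing_class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "population subset", y = "distinct interruptions",
                  fill = "sharing") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a polymerase error-class profile
#'
#' Per-class corrected error frequencies of one reaction.
#'
#' @param object An `ims_polsum` from [pol_error_summary()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ims_polsum <- function(object, ...) {
  d <- tidy(object) %>% filter(.data$n_detectable > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$ef)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = NULL, y = "error frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
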