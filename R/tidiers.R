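#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a bootstrap KS test
#'
#' @param x An `ims_ks` object from [ks_boot()].
#' @param ... Unused.
#' @return A one-row tibble with `statistic`, `p.value`, `iterations`,
#'   `n_a`, `n_b`.
#' @export
tidy.ims_ks <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p.value,
         iterations = x$iterations, n_a = x$n_a, n_b = x$n_b)
}

#' @rdname tidy.ims_ks
#' @export
glance.ims_ks <- function(x, ...) tidy(x)

#' Tidy an F_ST result
#'
#' @param x An `ims_fst` object from [fst()].
#' @param ... Unused.
#' @return A one-row tibble with `h_s`, `h_t`, `fst`.
#' @export
tidy.ims_fst <- function(x, ...) tibble(h_s = x$h_s, h_t = x$h_t, fst = x$fst)

#' Tidy a polymerase error summary
#'
#' `tidy()` returns the per-class error-frequency table; `glance()` the
#' one-row reaction summary.
#'
#' @param x An `ims_polsum` object from [pol_error_summary()].
#' @param ... Unused.
#' @export
tidy.ims_polsum <- function(x, ...) x$class_ef

#' @rdname tidy.ims_polsum
#' @export
glance.ims_polsum <- function(x, ...) {
  tibble(observed_mf = x$observed_mf, background_mf = x$background_mf,
         outside_mf = x$outside_mf, pol_ef = x$pol_ef,
         pol_ef_est = x$pol_ef_est, n_records = x$n_records,
         n_events = x$n_events,
         multi_interruption_fraction =
           x$spectrum$multi_interruption_fraction)
}

#' Tidy a stratified mutability table
#'
#' The object is already a tibble; `tidy()` strips the class so it can be
#' manipulated freely, `glance()` summarises bin counts.
#'
#' @param x An `ims_mutability` object from [stratified_mutability()].
#' @param ... Unused.
#' @export
tidy.ims_mutability <- function(x, ...) {
  class(x) <- setdiff(class(x), "ims_mutability")
  as_tibble(x)
}

#' @rdname tidy.ims_mutability
#' @export
glance.ims_mutability <- function(x, ...) {
  tibble(n_bins = nrow(x), n_loci = sum(x$n_loci),
         n_low_confidence = sum(x$low_confidence))
}
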