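#' Detection threshold presets
#'
#' Two named threshold regimes are shipped. The `"primate"` preset requires
#' seeds of at least 9, 5, 4 and 3 units for mono-, di-, tri- and
#' tetranucleotide motifs respectively and imposes no upper length limit; it
#' is the regime for comparative (two-genome) mutability work. The
#' `"population"` preset restricts loci to the base-pair length windows
#' 8--10, 10--18, 12--24 and 16--28 bp -- the lower bounds are the mutability
#' thresholds and the upper bounds the lengths up to which short-read indel
#' calls are reliable -- and is the regime for interruption calling from
#' population variant sets.
#'
#' The minimum-unit comparison is inclusive (a seed of exactly the threshold
#' number of units is kept). Note the two presets are deliberately kept
#' verbatim rather than reconciled: the population tetranucleotide lower
#' bound (16 bp = 4 units) is stricter than the primate 3-unit threshold.
#'
#' @param preset `"primate"` or `"population"`.
#' @param min_units Optional integer vector of length 4 overriding the
#'   per-motif-size minimum seed units (mono, di, tri, tetra).
#' @param len_window Optional 4x2 matrix of locus length windows in bp
#'   (rows = motif size 1-4, columns = lower/upper bound), or `NULL` for no
#'   window.
#' @return An object of class `ims_thresholds`: a list with elements
#'   `preset`, `min_units` (length-4 integer) and `len_window`.
#' @examples
#' threshold_config("primate")
#' threshold_config("population")$len_window
#' @export
threshold_config <- function(preset = c("primate", "population"),
                             min_units = NULL, len_window = NULL) {
  preset <- match.arg(preset)
  if (preset == "primate") {
    mu <- c(9L, 5L, 4L, 3L)
    lw <- NULL
  } else {
    lw <- matrix(c(8L, 10L, 10L, 18L, 12L, 24L, 16L, 28L),
                 nrow = 4, byrow = TRUE,
                 dimnames = list(paste0("motif", 1:4), c("lo", "hi")))
    ## minimum seed units implied by the lower bp bounds
    mu <- as.integer(ceiling(lw[, "lo"] / 1:4))
  }
  if (!is.null(min_units)) {
    stopifnot(length(min_units) == 4, all(min_units >= 1))
    mu <- as.integer(min_units)
  }
  if (!is.null(len_window)) {
    stopifnot(is.matrix(len_window), nrow(len_window) == 4,
              ncol(len_window) == 2, all(len_window[, 1] <= len_window[, 2]))
    lw <- len_window
  }
  structure(list(preset = preset, min_units = mu, len_window = lw),
            class = "ims_thresholds")
}

#' @export
print.ims_thresholds <- function(x, ...) {
  cat("<ims_thresholds> preset:", x$preset, "\n")
  cat("  min units (mono-tetra):", paste(x$min_units, collapse = "/"), "\n")
  if (!is.null(x$len_window)) {
    cat("  length windows (bp):",
        paste(apply(x$len_window, 1, paste, collapse = "-"), collapse = ", "),
        "\n")
  }
  invisible(x)
}

check_thresholds <- function(cfg) {
  if (!inherits(cfg, "ims_thresholds"))
    abort("`cfg` must be created by threshold_config()")
  cfg
}

#' Filter a locus table to a preset's length windows
#'
#' @param loci Locus tibble from [scan_microsatellites()].
#' @param cfg An `ims_thresholds` object. If it has no length window the
#'   input is returned unchanged.
#' @return The filtered tibble.
#' @export
filter_locus_window <- function(loci, cfg) {
  check_thresholds(cfg)
  if (is.null(cfg$len_window)) return(loci)
  lw <- cfg$len_window
  keep <- with(loci, {
    len <- end - start
    lo <- lw[motif_size, "lo"]
    hi <- lw[motif_size, "hi"]
    len >= lo & len <= hi
  })
  loci[keep, , drop = FALSE]
}
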