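#' Expected heterozygosity of a biallelic locus
#'
#' `H = 2pq` with `q = 1 - p`; maximal (0.5) at `p = 0.5`.
#'
#' @param p Variant allele frequency, in `[0, 1]` (vectorized).
#' @return Numeric vector of heterozygosities in `[0, 0.5]`.
#' @examples
#' heterozygosity(c(0, 0.1, 0.5))
#' @export
heterozygosity <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    abort("allele frequencies must lie in [0, 1]")
  2 * p * (1 - p)
}

#' Fixation index from per-population allele frequencies
#'
#' `H_S` is the unweighted mean of the within-population heterozygosities
#' `2 p_i q_i`; the total-population frequency `P` is the unweighted mean of
#' the `p_i`; `H_T = 2 P Q`; and `F_ST = (H_T - H_S) / H_T`. When `H_T = 0`
#' (no variation anywhere) `fst` is undefined and reported as `NA`.
#'
#' @param p Numeric vector of variant allele frequencies, one per
#'   population (at least 2).
#' @return A one-row tibble of class `ims_fst` with `h_s`, `h_t`, `fst`.
#' @examples
#' fst(c(0.1, 0.2, 0.3, 0.4))  # fst = 1/15
#' @export
fst <- function(p) {
  if (length(p) < 2) abort("F_ST needs allele frequencies for >= 2 populations")
  h_i <- heterozygosity(p)
  h_s <- mean(h_i)
  P <- mean(p)
  h_t <- 2 * P * (1 - P)
  out <- tibble(h_s = h_s, h_t = h_t,
                fst = if (h_t > 0) (h_t - h_s) / h_t else NA_real_)
  class(out) <- c("ims_fst", class(out))
  out
}

#' Per-locus F_ST over a table of population frequencies
#'
#' @param df Tibble with one row per locus and one `af_<POP>` frequency
#'   column per population.
#' @param af_cols Columns holding the frequencies; default: every column
#'   matching `^af_`.
#' @return `df` with `h_s`, `h_t`, `fst` appended (rows where `h_t = 0`
#'   carry `fst = NA`, never dropped).
#' @export
fst_by_locus <- function(df, af_cols = NULL) {
  if (is.null(af_cols)) af_cols <- grep("^af_", names(df), value = TRUE)
  if (length(af_cols) < 2) abort("need >= 2 population frequency columns")
  P <- as.matrix(df[, af_cols])
  h_s <- rowMeans(2 * P * (1 - P))
  pbar <- rowMeans(P)
  h_t <- 2 * pbar * (1 - pbar)
  df %>% mutate(h_s = h_s, h_t = h_t,
                fst = ifelse(h_t > 0, (h_t - h_s) / h_t, NA_real_))
}

#' Binned heterozygosity distribution
#'
#' Bins heterozygosities into left-closed, right-open bins of width
#' `bin_width` over `[0, 0.5]` (the last bin is closed so `H = 0.5` is
#' counted); frequencies sum to 1.
#'
#' @param h Numeric vector of heterozygosities in `[0, 0.5]` (nonempty).
#' @param bin_width Bin width; the default 0.02 gives 25 bins.
#' @return A tibble with `bin_lo`, `bin_hi`, `count`, `freq`.
#' @export
het_distribution <- function(h, bin_width = 0.02) {
  if (length(h) == 0) abort("empty heterozygosity vector")
  if (any(is.na(h)) || any(h < 0 | h > 0.5))
    abort("heterozygosity must lie in [0, 0.5] (2pq of a biallelic locus)")
  breaks <- seq(0, 0.5, by = bin_width)
  idx <- pmin(findInterval(h, breaks, rightmost.closed = TRUE),
              length(breaks) - 1L)
  cnt <- tabulate(idx, nbins = length(breaks) - 1L)
  tibble(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
         count = cnt, freq = cnt / sum(cnt))
}

#' Two-sample bootstrap Kolmogorov-Smirnov test
#'
#' Computes the two-sample KS statistic `D = max |ECDF_a - ECDF_b|` and a
#' bootstrap p-value: the pooled sample is resampled with replacement into
#' groups of the original sizes `iterations` times, and `p` is the fraction
#' of bootstrap statistics at least as large as the observed one (`>=`
#' comparison, so ties -- the reason a bootstrap is needed for discrete
#' data -- are handled without the asymptotic distribution).
#'
#' @param sample_a,sample_b Nonempty numeric vectors.
#' @param iterations Bootstrap iterations (default 10000).
#' @param rng_seed Optional integer seed (RNG state restored afterwards).
#' @return An object of class `ims_ks`: list with `statistic`, `p.value`,
#'   `iterations`, `n_a`, `n_b`. `tidy()`/`glance()` methods are provided.
#' @export
ks_boot <- function(sample_a, sample_b, iterations = 10000, rng_seed = NULL) {
  if (length(sample_a) == 0 || length(sample_b) == 0)
    abort("both samples must be nonempty")
  na <- length(sample_a); nb <- length(sample_b)
  d_obs <- ks_stat(sample_a, sample_b)
  pool <- c(sample_a, sample_b)
  n <- na + nb
  p <- with_seed(rng_seed, {
    hits <- 0L
    chunk <- 2000L
    done <- 0L
    while (done < iterations) {
      b <- min(chunk, iterations - done)
      draws <- matrix(pool[sample.int(n, n * b, replace = TRUE)], n, b)
      dstar <- vapply(seq_len(b), function(j) {
        ks_stat(draws[seq_len(na), j], draws[na + seq_len(nb), j])
      }, numeric(1))
      hits <- hits + sum(dstar >= d_obs - 1e-12)
      done <- done + b
    }
    hits / iterations
  })
  structure(list(statistic = d_obs, p.value = p, iterations = iterations,
                 n_a = na, n_b = nb),
            class = "ims_ks")
}

## two-sample KS statistic, tie-safe
ks_stat <- function(a, b) {
  na <- length(a); nb <- length(b)
  x <- c(a, b)
  o <- order(x)
  z <- cumsum(ifelse(o <= na, 1 / na, -1 / nb))
  ## at tied values only the last cumulative step counts
  xs <- x[o]
  keep <- c(xs[-1] != xs[-length(xs)], TRUE)
  max(abs(z[keep]))
}

#' @export
print.ims_ks <- function(x, ...) {
  cat("Two-sample bootstrap Kolmogorov-Smirnov test\n")
  cat(sprintf("D = %.4g, bootstrap p = %.4g (%d iterations; n = %d, %d)\n",
              x$statistic, x$p.value, x$iterations, x$n_a, x$n_b))
  invisible(x)
}

#' Linkage disequilibrium r-squared between two phased binary haplotype
#' vectors
#'
#' `r2 = (p_AB - p_A p_B)^2 / (p_A q_A p_B q_B)`, computed from the
#' haplotype frequencies of the 2x2 table; equal to the squared Pearson
#' correlation of the two 0/1 vectors. Returns `NA` when either vector is
#' monomorphic.
#'
#' @param hap_a,hap_b Equal-length 0/1 vectors (one entry per phased
#'   haplotype).
#' @return A number in `[0, 1]`, or `NA`.
#' @export
ld_r2 <- function(hap_a, hap_b) {
  stopifnot(length(hap_a) == length(hap_b))
  if (!all(hap_a %in% 0:1) || !all(hap_b %in% 0:1))
    abort("haplotype vectors must be binary 0/1")
  pa <- mean(hap_a); pb <- mean(hap_b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
  pab <- mean(hap_a == 1 & hap_b == 1)
  (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' Best-LD SNP partner for an indel within a window
#'
#' Scans population-matched SNPs within `window` bp on each side of the
#' indel (1 Mb total by default) and returns the SNP with the maximum
#' haplotype `r2`; ties are broken by distance to the indel, then by lower
#' coordinate. Perfect LD is flagged when `r2` is within `1e-12` of 1.
#' Monomorphic SNPs are unusable and skipped.
#'
#' @param indel_hap 0/1 vector of the indel's phased haplotypes.
#' @param indel_pos 1-based position of the indel.
#' @param snp_haps Matrix of 0/1 SNP haplotypes, one column per SNP, rows
#'   aligned with `indel_hap`.
#' @param snp_pos Positions of the SNP columns.
#' @param window Half-window in bp (default 5e5, i.e. a 1-Mb window).
#' @return A one-row tibble with `snp` (column index or name), `pos`, `r2`,
#'   `perfect_ld`; or a zero-row tibble when no usable SNP is in the
#'   window.
#' @export
max_ld_partner <- function(indel_hap, indel_pos, snp_haps, snp_pos,
                           window = 5e5) {
  stopifnot(is.matrix(snp_haps), ncol(snp_haps) == length(snp_pos))
  nm <- colnames(snp_haps)
  if (is.null(nm)) nm <- as.character(seq_len(ncol(snp_haps)))
  in_win <- which(abs(snp_pos - indel_pos) <= window)
  empty <- tibble(snp = character(), pos = numeric(), r2 = numeric(),
                  perfect_ld = logical())
  if (length(in_win) == 0) return(empty)
  r2 <- vapply(in_win, function(j) ld_r2(indel_hap, snp_haps[, j]),
               numeric(1))
  usable <- !is.na(r2)
  if (!any(usable)) return(empty)
  in_win <- in_win[usable]; r2 <- r2[usable]
  best <- r2 >= max(r2) - 1e-12
  cand <- in_win[best]; cr2 <- r2[best]
  dist <- abs(snp_pos[cand] - indel_pos)
  o <- order(dist, snp_pos[cand])
  pick <- o[1]
  tibble(snp = nm[cand[pick]], pos = snp_pos[cand[pick]], r2 = cr2[pick],
         perfect_ld = abs(cr2[pick] - 1) <= 1e-12)
}
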