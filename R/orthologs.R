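#' Filter orthologous microsatellite pairs
#'
#' Applies, in order, the eight quality and comparability filters used to
#' clean orthologous locus sets before mutability estimation. A pair
#' survives only if it passes all eight; the rejection log counts the
#' *first* failing filter for each rejected pair.
#'
#' The filters, with the columns they read:
#' 1. proximity: `distance_to_nearest_locus_bp` >= 25;
#' 2. base quality: `min_flank_phred` >= 20;
#' 3. flank complexity: `flank_low_complexity` is `FALSE` (computed with
#'    [is_low_complexity()] from `flank_a`/`flank_b` when the logical column
#'    is absent);
#' 4. flank identity: `flank_identity` >= 0.85;
#' 5. motif: `motif_a == motif_b`;
#' 6. interruption count: `n_interruptions_a` and `n_interruptions_b` both
#'    <= 2;
#' 7. interrupting bases: `interruption_bases_a == interruption_bases_b`;
#' 8. interruption context (the repeat bases immediately flanking each
#'    interruption): `interruption_context_a == interruption_context_b`.
#'
#' @param pairs A tibble of ortholog pairs, one row per locus, with the
#'   columns listed above plus `repeat_number_a`/`repeat_number_b`.
#' @return A list with `kept` (the surviving rows) and `rejection_log`
#'   (tibble with `filter`, `name`, `n_rejected`).
#' @export
filter_orthologs <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  if (!("flank_low_complexity" %in% names(pairs))) {
    need_col(pairs, c("flank_a", "flank_b"), "flank complexity (filter 3)")
    pairs$flank_low_complexity <-
      is_low_complexity(pairs$flank_a) | is_low_complexity(pairs$flank_b)
  }
  specs <- list(
    list(name = "proximity", cols = "distance_to_nearest_locus_bp",
         fail = function(d) d$distance_to_nearest_locus_bp < 25),
    list(name = "base_quality", cols = "min_flank_phred",
         fail = function(d) d$min_flank_phred < 20),
    list(name = "low_complexity_flank", cols = "flank_low_complexity",
         fail = function(d) d$flank_low_complexity),
    list(name = "flank_identity", cols = "flank_identity",
         fail = function(d) d$flank_identity < 0.85),
    list(name = "motif_mismatch", cols = c("motif_a", "motif_b"),
         fail = function(d) d$motif_a != d$motif_b),
    list(name = "too_many_interruptions",
         cols = c("n_interruptions_a", "n_interruptions_b"),
         fail = function(d) d$n_interruptions_a > 2 | d$n_interruptions_b > 2),
    list(name = "interruption_base_mismatch",
         cols = c("interruption_bases_a", "interruption_bases_b"),
         fail = function(d) d$interruption_bases_a != d$interruption_bases_b),
    list(name = "interruption_context_mismatch",
         cols = c("interruption_context_a", "interruption_context_b"),
         fail = function(d) d$interruption_context_a != d$interruption_context_b)
  )
  first_fail <- rep(NA_integer_, nrow(pairs))
  for (i in seq_along(specs)) {
    need_col(pairs, specs[[i]]$cols, paste0(specs[[i]]$name, " (filter ", i, ")"))
    f <- specs[[i]]$fail(pairs)
    if (anyNA(f))
      abort(paste0("missing values in columns for filter ", i, " (",
                   specs[[i]]$name, ")"))
    first_fail[is.na(first_fail) & f] <- i
  }
  log <- tibble(
    filter = seq_along(specs),
    name = vapply(specs, `[[`, character(1), "name"),
    n_rejected = vapply(seq_along(specs),
                        function(i) sum(first_fail == i, na.rm = TRUE),
                        integer(1))
  )
  list(kept = pairs[is.na(first_fail), , drop = FALSE], rejection_log = log)
}

need_col <- function(d, cols, what) {
  miss <- setdiff(cols, names(d))
  if (length(miss))
    abort(paste0("missing column(s) ", paste0("`", miss, "`", collapse = ", "),
                 " required by filter: ", what))
}

#' Is a flank sequence low-complexity?
#'
#' A conventional proxy: the sequence contains a mono- or dinucleotide run
#' of at least `run_bp` bases, or its base-composition Shannon entropy falls
#' below `entropy_cutoff` bits.
#'
#' @param seq Character vector of DNA strings.
#' @param run_bp Minimum run length in bp that flags the flank.
#' @param entropy_cutoff Entropy cutoff in bits (max 2 for DNA).
#' @return Logical vector.
#' @export
is_low_complexity <- function(seq, run_bp = 8, entropy_cutoff = 1.0) {
  vapply(toupper(seq), function(s) {
    n <- nchar(s)
    if (n == 0) return(FALSE)
    for (b in c("A", "C", "G", "T"))
      if (grepl(strrep(b, run_bp), s, fixed = TRUE)) return(TRUE)
    ch <- strsplit(s, "")[[1]]
    if (n >= run_bp) {
      for (m in 1:2) {
        idx <- seq_len(n - m)
        eq <- ch[idx] == ch[idx + m]
        r <- rle(eq)
        if (any(r$values & r$lengths + m >= run_bp)) return(TRUE)
      }
    }
    p <- table(factor(ch, levels = c("A", "C", "G", "T"))) / n
    p <- p[p > 0]
    ent <- -sum(p * log2(p))
    ent < entropy_cutoff
  }, logical(1), USE.NAMES = FALSE)
}

#' Microsatellite mutability between two genomes
#'
#' Mutability is the mean squared difference in repeat number between the
#' two orthologous alleles of each locus, in squared repeat units. Loci that
#' have not changed contribute 0; a one-unit change contributes 1.
#'
#' @param pairs Ortholog pair tibble with `repeat_number_a` and
#'   `repeat_number_b`.
#' @return A single non-negative number.
#' @examples
#' mutability(tibble::tibble(repeat_number_a = c(10, 10),
#'                           repeat_number_b = c(12, 10)))  # 2
#' @export
mutability <- function(pairs) {
  need_col(pairs, c("repeat_number_a", "repeat_number_b"), "mutability")
  if (nrow(pairs) == 0) abort("cannot compute mutability of an empty pair set")
  mean((pairs$repeat_number_a - pairs$repeat_number_b)^2)
}

#' Bootstrap percentile interval for mutability
#'
#' Resamples loci (pairs) with replacement `B` times and returns the 2.5th
#' and 97.5th percentiles of the bootstrap mutability distribution.
#'
#' @inheritParams mutability
#' @param B Number of bootstrap resamples.
#' @param rng_seed Optional integer seed; when given, the RNG state is
#'   restored afterwards so the call is reproducible and side-effect free.
#' @param probs Percentiles to report.
#' @return Named numeric vector `c(ci_low, ci_high)`.
#' @export
bootstrap_ci <- function(pairs, B = 1000, rng_seed = NULL,
                         probs = c(0.025, 0.975)) {
  stopifnot(B >= 1)
  if (nrow(pairs) == 0) abort("cannot bootstrap an empty pair set")
  d2 <- (pairs$repeat_number_a - pairs$repeat_number_b)^2
  mu_star <- with_seed(rng_seed, boot_means(d2, B))
  q <- unname(quantile(mu_star, probs, type = 7))
  c(ci_low = q[1], ci_high = q[2])
}

#' Mutability stratified by repeat number and interruption features
#'
#' Bins pairs by motif size and by the repeat number of species A (the
#' "reference" slot; binning by species B is available via `by`), and within
#' each bin estimates mutability separately per stratum:
#'
#' * `"interruptions"`: number of interruptions (0, 1, 2) shared by the pair;
#' * `"position"`: perfect loci vs singly-interrupted loci whose interruption
#'   midpoint falls in the middle or fringe 25% of the locus
#'   ([interruption_position_class()]);
#' * `"identity"`: the interrupting base(s) of singly-interrupted loci.
#'
#' Motif sizes are never pooled. Bins with fewer than `min_loci` pairs are
#' reported but flagged `low_confidence`.
#'
#' @inheritParams bootstrap_ci
#' @param strata One of `"interruptions"`, `"position"`, `"identity"`.
#' @param by Which species' repeat number drives binning, `"a"` or `"b"`.
#' @param min_loci Flag bins with fewer loci than this as low-confidence.
#' @return A tibble of class `ims_mutability`: one row per nonempty
#'   (motif_size, repeat_number, stratum) bin with `mu`, `ci_low`,
#'   `ci_high`, `n_loci`, `low_confidence`.
#' @export
stratified_mutability <- function(pairs,
                                  strata = c("interruptions", "position",
                                             "identity"),
                                  B = 1000, rng_seed = NULL, by = c("a", "b"),
                                  min_loci = 20) {
  strata <- match.arg(strata)
  by <- match.arg(by)
  need_col(pairs, c("motif_size", "repeat_number_a", "repeat_number_b",
                    "n_interruptions_a"), "stratified mutability")
  rn <- if (by == "a") pairs$repeat_number_a else pairs$repeat_number_b
  stratum <- switch(
    strata,
    interruptions = as.character(pairs$n_interruptions_a),
    position = {
      need_col(pairs, c("interruption_spec_a", "length_a"), "position strata")
      vapply(seq_len(nrow(pairs)), function(i) {
        if (pairs$n_interruptions_a[i] == 0) return("perfect")
        if (pairs$n_interruptions_a[i] > 1) return("multiple")
        p <- parse_interruption_spec(pairs$interruption_spec_a[i])
        interruption_position_class(p$offset, p$length, pairs$length_a[i])
      }, character(1))
    },
    identity = {
      need_col(pairs, "interruption_bases_a", "identity strata")
      ifelse(pairs$n_interruptions_a == 0, "perfect",
             pairs$interruption_bases_a)
    }
  )
  grp <- tibble(motif_size = pairs$motif_size, repeat_number = rn,
                stratum = stratum,
                d_a = pairs$repeat_number_a, d_b = pairs$repeat_number_b)
  res <- grp %>%
    group_by(.data$motif_size, .data$repeat_number, .data$stratum) %>%
    group_modify(function(d, key) {
      sub <- tibble(repeat_number_a = d$d_a, repeat_number_b = d$d_b)
      ci <- bootstrap_ci(sub, B = B, rng_seed = rng_seed)
      tibble(mu = mutability(sub), ci_low = ci[["ci_low"]],
             ci_high = ci[["ci_high"]], n_loci = nrow(d))
    }) %>%
    ungroup() %>%
    mutate(low_confidence = .data$n_loci < min_loci)
  class(res) <- c("ims_mutability", class(res))
  attr(res, "strata") <- strata
  res
}

#' Bootstrap interval for a mutability fold-change
#'
#' Estimates the ratio of the mutabilities of two cohorts (typically
#' perfect over interrupted loci) with a percentile bootstrap: both
#' cohorts are resampled independently `B` times and the 2.5th/97.5th
#' percentiles of the ratio distribution are reported. Resamples where the
#' denominator cohort shows no change yield infinite ratios, which land in
#' the upper tail and widen the interval honestly.
#'
#' @param pairs_num,pairs_den Ortholog pair tibbles (numerator and
#'   denominator cohorts).
#' @inheritParams bootstrap_ci
#' @return Named numeric `c(ratio, ci_low, ci_high)`.
#' @export
mutability_ratio_ci <- function(pairs_num, pairs_den, B = 1000,
                                rng_seed = NULL, probs = c(0.025, 0.975)) {
  d2n <- (pairs_num$repeat_number_a - pairs_num$repeat_number_b)^2
  d2d <- (pairs_den$repeat_number_a - pairs_den$repeat_number_b)^2
  if (length(d2n) == 0 || length(d2d) == 0)
    abort("both cohorts must be nonempty")
  ratio <- mean(d2n) / mean(d2d)
  rat_star <- with_seed(rng_seed, boot_means(d2n, B) / boot_means(d2d, B))
  q <- unname(quantile(rat_star, probs, type = 7, na.rm = TRUE))
  c(ratio = ratio, ci_low = q[1], ci_high = q[2])
}

## bootstrap distribution of the sample mean; resampling n values with
## replacement is a multinomial draw over the distinct observed values,
## which keeps large cohorts cheap
boot_means <- function(x, B) {
  n <- length(x)
  vals <- sort(unique(x))
  if (length(vals) == 1) return(rep(vals, B))
  w <- tabulate(match(x, vals), nbins = length(vals)) / n
  counts <- stats::rmultinom(B, n, w)
  as.vector(crossprod(vals, counts)) / n
}

## run code with a temporary, restorable RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
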