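#' Generate a synthetic genome with planted microsatellite loci
#'
#' Builds one or more contigs containing planted perfect, interrupted and
#' (optionally) compound microsatellite loci, separated by non-repetitive
#' flanks of at least 30 bp so detection is unambiguous, and returns the
#' ground truth alongside. Flanks are drawn by rejection sampling: a flank
#' is redrawn until it contains no tandem structure that could seed or
#' extend a locus, and the bases abutting each planted locus are
#' constrained so they cannot continue its repeat phase. Interruption bases
#' are likewise constrained to break periodicity against both flanking
#' repeat tracts, so the planted annotation *is* the textual-definition
#' truth, not a re-run of the scanner.
#'
#' @param spec Tibble describing the loci to plant, one row per locus
#'   class: `motif`, `units` (repeat number), `n` (how many),
#'   `n_interruptions` (0, 1 or 2). For interrupted classes the
#'   interruption(s) are placed near the positions given by
#'   `int_offset_frac` (list-column of fractions of the locus length;
#'   defaults to central placement) with lengths `int_len` (defaults to 1).
#' @param n_compound Number of planted compound pairs (two abutting seeds
#'   of different motifs), each expected to be discarded by the scanner.
#' @param rng_seed Integer seed (required: truth must be reproducible).
#' @param flank_len Flank length between loci in bp (>= 30).
#' @param seqname Contig name.
#' @return A list with `sequences` (named character vector, one contig)
#'   and `truth` (tibble with `seqnames`, `start`, `end`, `motif`,
#'   `status`, `n_interruptions`, `interruption_spec`, `repeat_number`),
#'   plus `manifest` (the call parameters).
#' @export
gen_genome <- function(spec = default_genome_spec(), n_compound = 0,
                       rng_seed = 1, flank_len = 35, seqname = "chr1") {
  stopifnot(flank_len >= 30)
  need_col(spec, c("motif", "units", "n", "n_interruptions"), "genome spec")
  with_seed(rng_seed, {
    pieces <- list()
    truth <- list()
    cursor <- 0L
    prev <- NULL       # previous locus piece: list(seq, motif)

    sep_flank <- function(next_seq = NULL, next_motif = NULL) {
      repeat {
        fl <- make_flank(flank_len)
        if (is.null(fl)) next
        if (!is.null(prev))
          fl <- fix_boundary(fl, prev$seq, prev$motif, side = "right")
        if (!is.null(next_seq))
          fl <- fix_boundary(fl, next_seq, next_motif, side = "left")
        if (flank_ok(fl)) return(fl)
      }
    }

    rows <- spec[rep(seq_len(nrow(spec)), spec$n), , drop = FALSE]
    if (nrow(rows) > 1)
      rows <- rows[sample.int(nrow(rows)), , drop = FALSE]

    emit <- function(locus_seq, motif, status, n_int, spec_str, rep_num) {
      fl <- sep_flank(locus_seq, motif)
      pieces[[length(pieces) + 1L]] <<- fl
      cursor <<- cursor + nchar(fl)
      s0 <- cursor
      pieces[[length(pieces) + 1L]] <<- locus_seq
      cursor <<- cursor + nchar(locus_seq)
      prev <<- list(seq = locus_seq, motif = motif)
      truth[[length(truth) + 1L]] <<- tibble(
        seqnames = seqname, start = s0, end = cursor, motif = motif,
        status = status, n_interruptions = n_int,
        interruption_spec = spec_str, repeat_number = rep_num)
    }

    if (nrow(rows) > 0) for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      if (r$n_interruptions == 0) {
        emit(strrep(r$motif, r$units), r$motif, "perfect", 0L, "", r$units)
      } else {
        fr <- if ("int_offset_frac" %in% names(r) &&
                  length(r$int_offset_frac[[1]]))
          r$int_offset_frac[[1]]
        else seq_len(r$n_interruptions) / (r$n_interruptions + 1)
        il <- if ("int_len" %in% names(r) && length(r$int_len[[1]]))
          r$int_len[[1]] else rep(1L, r$n_interruptions)
        built <- build_interrupted(r$motif, r$units, fr, il)
        emit(built$seq, r$motif, "interrupted", r$n_interruptions,
             built$spec, r$units)
      }
    }
    if (n_compound > 0) for (i in seq_len(n_compound)) {
      a <- strrep("A", 10)
      b <- strrep("GT", 6)
      fl <- sep_flank(a, "A")
      pieces[[length(pieces) + 1L]] <- fl
      cursor <- cursor + nchar(fl)
      s0 <- cursor
      pieces[[length(pieces) + 1L]] <- paste0(a, b)
      prev <- list(seq = b, motif = "GT")
      truth[[length(truth) + 1L]] <- tibble(
        seqnames = seqname, start = s0, end = s0 + 10L, motif = "A",
        status = "compound-discarded", n_interruptions = 0L,
        interruption_spec = "", repeat_number = 10)
      truth[[length(truth) + 1L]] <- tibble(
        seqnames = seqname, start = s0 + 10L, end = s0 + 22L, motif = "GT",
        status = "compound-discarded", n_interruptions = 0L,
        interruption_spec = "", repeat_number = 6)
      cursor <- cursor + 22L
    }
    pieces[[length(pieces) + 1L]] <- sep_flank()
    seqs <- setNames(paste(unlist(pieces), collapse = ""), seqname)
    truth_tbl <- dplyr::bind_rows(truth)
    if (nrow(truth_tbl) == 0) {
      truth_tbl <- tibble(seqnames = character(), start = integer(),
                          end = integer(), motif = character(),
                          status = character(), n_interruptions = integer(),
                          interruption_spec = character(),
                          repeat_number = numeric())
    }
    list(sequences = seqs, truth = truth_tbl,
         manifest = list(rng_seed = rng_seed, flank_len = flank_len,
                         n_compound = n_compound))
  })
}

## build a repeat-free flank base by base: each added base is forbidden
## from completing two units of any 1-4 bp motif; NULL on a dead end
## (caller retries)
make_flank <- function(len) {
  s <- character(len)
  for (i in seq_len(len)) {
    excl <- character(0)
    if (i >= 2) excl <- c(excl, s[i - 1])                       # mono
    if (i >= 4 && s[i - 1] == s[i - 3]) excl <- c(excl, s[i - 2])   # di
    if (i >= 6 && s[i - 1] == s[i - 4] && s[i - 2] == s[i - 5])
      excl <- c(excl, s[i - 3])                                 # tri
    if (i >= 8 && s[i - 1] == s[i - 5] && s[i - 2] == s[i - 6] &&
        s[i - 3] == s[i - 7])
      excl <- c(excl, s[i - 4])                                 # tetra
    cand <- setdiff(c("A", "C", "G", "T"), excl)
    if (length(cand) == 0) return(NULL)
    s[i] <- if (length(cand) == 1) cand else sample(cand, 1)
  }
  paste(s, collapse = "")
}

#' @rdname gen_genome
#' @export
default_genome_spec <- function() {
  ## interrupted classes keep their first tract at/above the seed
  ## threshold (an iMS needs one perfect stretch beyond threshold to be
  ## detectable at all)
  tibble(
    motif = c("A", "AC", "AAG", "AATC", "A", "AC"),
    units = c(10L, 7L, 5L, 5L, 12L, 8L),
    n = c(4L, 4L, 3L, 3L, 3L, 3L),
    n_interruptions = c(0L, 0L, 0L, 0L, 1L, 1L),
    int_offset_frac = list(numeric(0), numeric(0), numeric(0), numeric(0),
                           0.75, 0.75)
  )
}

## no run of >= 2 units of any 1-4 bp motif anywhere in a flank (so flanks
## can never seed or extend); checked with direct periodicity scans
flank_ok <- function(fl) {
  ch <- strsplit(fl, "")[[1]]
  n <- length(ch)
  for (m in 1:4) {
    if (n <= m) next
    idx <- seq_len(n - m)
    eq <- ch[idx] == ch[idx + m]
    r <- rle(eq)
    ## a periodic region of length >= 2m means >= 2 complete units
    if (any(r$values & r$lengths >= m)) return(FALSE)
  }
  TRUE
}

## ensure the flank's boundary base does not equal the phase-continuing base
fix_boundary <- function(fl, locus_seq, motif, side) {
  m <- nchar(motif)
  if (side == "left") {
    bad <- substr(locus_seq, m, m)   # base that would extend phase leftwards
    cur <- substr(fl, nchar(fl), nchar(fl))
    if (cur == bad) {
      repl <- setdiff(c("A", "C", "G", "T"), c(bad, substr(fl, nchar(fl) - 1, nchar(fl) - 1)))[1]
      substr(fl, nchar(fl), nchar(fl)) <- repl
    }
  } else {
    bad <- substr(locus_seq, nchar(locus_seq) - m + 1L, nchar(locus_seq) - m + 1L)
    cur <- substr(fl, 1L, 1L)
    if (cur == bad) {
      repl <- setdiff(c("A", "C", "G", "T"), c(bad, substr(fl, 2L, 2L)))[1]
      substr(fl, 1L, 1L) <- repl
    }
  }
  fl
}

## assemble an interrupted locus [motif]_u1 INT [motif]_u2 ... with every
## interruption base breaking periodicity in both directions
build_interrupted <- function(motif, units, offset_frac, int_len) {
  m <- nchar(motif)
  k <- length(offset_frac)
  stopifnot(length(int_len) == k, all(int_len >= 1), all(int_len <= m))
  total_len <- units * m + sum(int_len)
  ## split units into k+1 tracts, each >= 2 units, at the requested fracs
  cuts <- sort(pmin(pmax(round(offset_frac * units), 2), units - 2))
  tract_units <- diff(c(0, cuts, units))
  if (any(tract_units < 2))
    abort("interruption placement leaves a tract of < 2 units")
  parts <- character(0)
  spec_entries <- character(0)
  off <- 0L
  for (j in seq_len(k + 1)) {
    parts <- c(parts, strrep(motif, tract_units[j]))
    off <- off + tract_units[j] * m
    if (j <= k) {
      ib <- make_interruption(motif, int_len[j])
      parts <- c(parts, ib)
      spec_entries <- c(spec_entries, paste0(off, ":", ib))
      off <- off + int_len[j]
    }
  }
  list(seq = paste(parts, collapse = ""),
       spec = paste(spec_entries, collapse = ";"))
}

## an interruption string whose every base differs from the phase base on
## both sides (cannot merge into either tract)
make_interruption <- function(motif, len) {
  m <- nchar(motif)
  mb <- strsplit(motif, "")[[1]]
  vapply(seq_len(len), function(j) {
    ## base expected by left-tract phase at this slot, and by right tract
    left_exp <- mb[(j - 1L) %% m + 1L]
    right_exp <- mb[(j - 1L + (m - len)) %% m + 1L]
    sample(setdiff(c("A", "C", "G", "T"), c(left_exp, right_exp)), 1)
  }, character(1)) %>% paste(collapse = "")
}

#' Generate orthologous pairs under interruption-dependent slippage
#'
#' Simulates `n` perfect and `n` interrupted loci evolving independently
#' along two lineages for `g` generations under a symmetric stepwise
#' (+/- 1 unit) slippage model. Perfect loci step with probability `r` per
#' generation per lineage; interrupted loci with probability `r / k` --
#' `k` is the fold-reduction in mutability caused by the interruption
#' (interruptions divide a locus into shorter perfect tracts, and shorter
#' tracts slip less). The expected mutability of the perfect cohort is
#' `2 g r`; the expected ratio perfect/interrupted is `k`.
#'
#' All ortholog-filter columns are emitted clean (so the cohort passes
#' [filter_orthologs()] untouched) and the realized step counts are kept as
#' truth columns.
#'
#' @param n Loci per cohort.
#' @param r Per-generation, per-lineage slippage probability of a perfect
#'   locus.
#' @param k Fold-reduction of the slippage rate at interrupted loci.
#' @param g Generations per lineage.
#' @param rng_seed Integer seed.
#' @param motif Motif (default `"A"`).
#' @param n0 Ancestral repeat number.
#' @return A tibble of 2n ortholog pairs with the columns read by
#'   [filter_orthologs()], [mutability()] and [stratified_mutability()],
#'   plus truth columns `steps_a`, `steps_b`, `cohort`.
#' @export
gen_ortholog_pairs <- function(n, r = 0.01, k = 4, g = 20, rng_seed = 1,
                               motif = "A", n0 = 12) {
  stopifnot(n >= 1, r >= 0, r <= 1, k >= 1, g >= 0)
  m <- nchar(motif)
  with_seed(rng_seed, {
    one_cohort <- function(nn, rate, cohort, n_int) {
      steps_a <- stats::rbinom(nn, g, rate)
      steps_b <- stats::rbinom(nn, g, rate)
      delta_a <- stats::rbinom(nn, steps_a, 0.5) * 2L - steps_a
      delta_b <- stats::rbinom(nn, steps_b, 0.5) * 2L - steps_b
      rn_a <- n0 + delta_a
      rn_b <- n0 + delta_b
      int_bases <- if (n_int > 0) "T" else ""
      len_a <- rn_a * m + n_int
      tibble(
        pair_id = paste0(cohort, "_", seq_len(nn)),
        motif_a = motif, motif_b = motif, motif_size = m,
        repeat_number_a = rn_a, repeat_number_b = rn_b,
        n_interruptions_a = n_int, n_interruptions_b = n_int,
        interruption_bases_a = int_bases, interruption_bases_b = int_bases,
        interruption_context_a = if (n_int > 0) paste0(motif, "|", motif) else "",
        interruption_context_b = if (n_int > 0) paste0(motif, "|", motif) else "",
        interruption_spec_a = if (n_int > 0)
          paste0(pmax(2, (rn_a %/% 2)) * m, ":", int_bases) else "",
        length_a = len_a,
        flank_identity = 1.0, min_flank_phred = 60L,
        flank_low_complexity = FALSE,
        distance_to_nearest_locus_bp = 1000L,
        steps_a = steps_a, steps_b = steps_b, cohort = cohort
      )
    }
    out <- dplyr::bind_rows(
      one_cohort(n, r, "perfect", 0L),
      one_cohort(n, r / k, "interrupted", 1L)
    )
    attr(out, "manifest") <- list(n = n, r = r, k = k, g = g,
                                  rng_seed = rng_seed, motif = motif, n0 = n0)
    out
  })
}

#' Generate a multi-population variant set over planted perfect loci
#'
#' Builds a synthetic genome of perfect loci in the population length
#' windows, then plants variant records with controlled per-population
#' allele frequencies:
#'
#' * *expected calls*: SNPs (and single-base indels in di+ motifs) strictly
#'   inside the locus minus its terminal units, AF drawn in
#'   `[af_lo, af_hi]` for every population of a planted sharing set, 0
#'   elsewhere;
#' * *AF decoys*: interior SNPs at frequency just below the 0.05 cutoff in
#'   every population;
#' * *terminal decoys*: SNPs inside the first or last repeat unit;
#' * *whole-motif decoys*: indels of exactly one motif unit.
#'
#' Sharing sets cycle through population-specific, 2-, 3- and
#' all-population subsets so the Venn partition is fully exercised. Phased
#' haplotypes with a planted perfect-LD SNP partner and noise SNPs are
#' emitted for LD tests.
#'
#' @param n_expected,n_decoy_af,n_decoy_terminal,n_decoy_wholemotif Record
#'   counts per truth label.
#' @param populations Population labels.
#' @param rng_seed Integer seed.
#' @param af_lo,af_hi Bounds of planted call frequencies.
#' @param n_hap Haplotypes per LD panel.
#' @return A list with `sequences`, `loci_truth`, `variants` (tibble with
#'   `af_<POP>` columns), `truth` (per-record label and sharing class) and
#'   `ld` (planted LD panel: `indel_hap`, `indel_pos`, `snp_haps`,
#'   `snp_pos`, `best_snp`).
#' @export
gen_population_vcf <- function(n_expected = 24, n_decoy_af = 8,
                               n_decoy_terminal = 8, n_decoy_wholemotif = 8,
                               populations = c("AFR", "EUR", "ASN", "AMR"),
                               rng_seed = 1, af_lo = 0.1, af_hi = 0.4,
                               n_hap = 60) {
  n_loci_needed <- n_expected + n_decoy_af + n_decoy_terminal +
    n_decoy_wholemotif
  spec <- tibble(
    motif = c("A", "AC", "AAG"),
    units = c(9L, 7L, 5L),
    n = ceiling(n_loci_needed / 3) + 1L,
    n_interruptions = 0L
  )
  g <- gen_genome(spec, rng_seed = rng_seed, seqname = "chr1")
  loci <- g$truth %>% filter(.data$status == "perfect")
  with_seed(rng_seed + 1L, {
    loci <- loci[sample.int(nrow(loci)), , drop = FALSE]
    stopifnot(nrow(loci) >= n_loci_needed)
    seqfull <- g$sequences[[1]]
    pop_n <- length(populations)
    ## sharing sets cycling over subset sizes 1..pop_n
    subset_cycle <- unlist(lapply(seq_len(pop_n), function(sz)
      utils::combn(populations, sz, simplify = FALSE)), recursive = FALSE)

    vrec <- list(); trec <- list()
    li <- 0L
    take_locus <- function() { li <<- li + 1L; loci[li, ] }
    af_draw <- function() round(runif(1, af_lo, af_hi), 3)

    base_at <- function(pos) substr(seqfull, pos, pos)
    other_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1)

    push <- function(pos, ref, alt, afs, label, pops) {
      row <- tibble(seqnames = "chr1", pos = pos, ref = ref, alt = alt)
      for (p in populations) row[[paste0("af_", p)]] <- unname(afs[p])
      vrec[[length(vrec) + 1L]] <<- row
      trec[[length(trec) + 1L]] <<- tibble(
        seqnames = "chr1", pos = pos, ref = ref, alt = alt, label = label,
        populations = paste(sort(pops), collapse = "+"),
        n_populations = length(pops))
    }

    for (i in seq_len(n_expected)) {
      lc <- take_locus()
      m <- nchar(lc$motif)
      S <- lc$start; E <- lc$end
      interior <- (S + m + 1):(E - m)
      pops <- subset_cycle[[(i - 1L) %% length(subset_cycle) + 1L]]
      afs <- setNames(rep(0, pop_n), populations)
      for (p in pops) afs[p] <- af_draw()
      use_indel <- m >= 2 && i %% 3 == 0
      if (use_indel) {
        pos <- interior[ceiling(length(interior) / 2)]
        anchor <- base_at(pos)
        ins <- other_base(c(base_at(pos + 1)))
        ## single-base insertion breaking periodicity: ensure inserted base
        ## also differs from the base one period later
        cand <- setdiff(c("A", "C", "G", "T"),
                        c(base_at(pos + 1), base_at(pos + 1 - m)))
        ins <- if (length(cand)) cand[1] else ins
        push(pos, anchor, paste0(anchor, ins), afs, "expected-call", pops)
      } else {
        pos <- interior[ceiling(length(interior) / 2)]
        ref <- base_at(pos)
        push(pos, ref, other_base(ref), afs, "expected-call", pops)
      }
    }
    for (i in seq_len(n_decoy_af)) {
      lc <- take_locus()
      m <- nchar(lc$motif)
      interior <- (lc$start + m + 1):(lc$end - m)
      pos <- interior[1]
      ref <- base_at(pos)
      afs <- setNames(rep(0.04, pop_n), populations)
      push(pos, ref, other_base(ref), afs, "decoy-af", populations)
    }
    for (i in seq_len(n_decoy_terminal)) {
      lc <- take_locus()
      pos <- lc$start + 1L            # first base of first repeat unit
      ref <- base_at(pos)
      afs <- setNames(rep(0, pop_n), populations)
      afs[populations[1]] <- af_draw()
      push(pos, ref, other_base(ref), afs, "decoy-terminal", populations[1])
    }
    for (i in seq_len(n_decoy_wholemotif)) {
      lc <- take_locus()
      m <- nchar(lc$motif)
      interior <- (lc$start + m + 1):(lc$end - m)
      pos <- interior[1] - 1L
      ref <- substr(seqfull, pos, pos + m)     # anchor + one whole unit
      afs <- setNames(rep(0, pop_n), populations)
      afs[populations[1]] <- af_draw()
      push(pos, ref, substr(seqfull, pos, pos), afs, "decoy-whole-motif",
           populations[1])
    }
    variants <- dplyr::bind_rows(vrec) %>% arrange(.data$pos)
    truth <- dplyr::bind_rows(trec) %>% arrange(.data$pos)

    ## phased-haplotype LD panel: indel + perfect partner + noise SNPs
    indel_hap <- stats::rbinom(n_hap, 1, 0.3)
    if (sum(indel_hap) == 0) indel_hap[1] <- 1L
    if (sum(indel_hap) == n_hap) indel_hap[1] <- 0L
    indel_pos <- 1e6
    n_noise <- 8L
    snp_pos <- sort(round(runif(n_noise + 1L, indel_pos - 4.5e5,
                                indel_pos + 4.5e5)))
    best_idx <- ceiling((n_noise + 1L) / 2)
    snp_haps <- matrix(stats::rbinom(n_hap * (n_noise + 1L), 1, 0.5),
                       nrow = n_hap)
    snp_haps[, best_idx] <- indel_hap
    colnames(snp_haps) <- paste0("snp", seq_len(n_noise + 1L))
    ld <- list(indel_hap = indel_hap, indel_pos = indel_pos,
               snp_haps = snp_haps, snp_pos = snp_pos,
               best_snp = paste0("snp", best_idx))

    list(sequences = g$sequences, loci_truth = g$truth, variants = variants,
         truth = truth, ld = ld,
         manifest = list(rng_seed = rng_seed, populations = populations,
                         af_lo = af_lo, af_hi = af_hi))
  })
}

#' Build an in-frame reporter template around a repeat structure
#'
#' Assembles upstream coding context, the microsatellite (given as a
#' repeat-structure string, e.g. `"[GT]_10"` or `"[A]_3 T [A]_4"`) and
#' downstream coding context into a stop-free in-frame template, recording
#' the microsatellite bounds. The boundary bases of the contexts are chosen
#' so they cannot extend the repeat.
#'
#' @param structure Repeat-structure string of the microsatellite insert.
#' @param motif The repeat motif.
#' @param template_id Identifier.
#' @return One-row tibble: `template_id`, `seq`, `ms_start`, `ms_end`,
#'   `motif`, `structure`.
#' @export
make_reporter_template <- function(structure, motif,
                                   template_id = structure) {
  ms <- parse_repeat_structure(structure)
  ## upstream candidates of length 15-17 shift the frame the repeat lands
  ## in (some repeat structures encode a stop in one frame only)
  up_pool <- c("ATGGCTACGGAGTGC", "ATGGCTACGGAGTGCC", "ATGGCTACGGAGTGTCC",
               "ATGGCTACGGAGTGG", "ATGGCTACGGAGTGCG", "ATGGCTACGGAGTGTCG")
  down_bases <- c("CTGGACGAAGCACTCGATCTGGTC", "GACTGGACGAAGCACTCGATCTGG",
                  "TCCTGGACGAAGCACTCGATCTGG")
  for (up in up_pool) {
    if (substr(up, nchar(up), nchar(up)) ==
        substr(ms, nchar(motif), nchar(motif))) next
    for (down_base in down_bases) {
      ## boundaries must not continue the repeat phase
      if (substr(down_base, 1, 1) == substr(ms, 1, 1)) next
      len0 <- 12L + (3L - (nchar(up) + nchar(ms) + 12L) %% 3L) %% 3L
      for (len in c(len0, len0 + 3L, len0 + 6L)) {
        if (len > nchar(down_base)) break
        down <- substr(down_base, 1L, len)
        seq <- paste0(up, ms, down)
        codons <- substring(seq, seq(1, nchar(seq) - 2, 3),
                            seq(3, nchar(seq), 3))
        if (any(codons %in% c("TAA", "TAG", "TGA"))) next
        return(tibble(template_id = template_id, seq = seq,
                      ms_start = nchar(up), ms_end = nchar(up) + nchar(ms),
                      motif = motif, structure = structure))
      }
    }
  }
  abort("could not assemble a stop-free in-frame reporter for this structure")
}

#' Generate a reporter-assay mutant collection with a planted spectrum
#'
#' Draws `n_mutants` sequenced mutants from a template, each carrying one
#' planted mutational event, with event classes allocated deterministically
#' in the planted proportions (largest-remainder rounding, order shuffled
#' under the seed), and colony-count triples consistent with the planted
#' mutant-frequency triple.
#'
#' Supported classes: `"unit-deletion"`, `"unit-insertion"`,
#' `"interruption-substitution"`, `"interruption-deletion"`,
#' `"interruption-insertion"`, `"interruption-removal"` (iMS templates
#' only).
#'
#' @param template One-row template tibble from [make_reporter_template()].
#' @param spectrum Named numeric vector of class proportions (sums to 1).
#' @param n_mutants Number of sequenced mutants.
#' @param mf_triple Numeric `c(observed, background, outside)` mutant
#'   frequencies.
#' @param rng_seed Integer seed.
#' @param cm Total colony count per context used to realize `mf_triple`.
#' @return A list with `records` (tibble `record_id`, `template_id`,
#'   `mutant_seq`), `counts` (tibble `context`, `fudr_cm`, `cm`), and
#'   `truth` (planted class per record).
#' @export
gen_mutant_collection <- function(template, spectrum, n_mutants,
                                  mf_triple = c(5e-4, 1e-4, 1e-4),
                                  rng_seed = 1, cm = 1e5) {
  stopifnot(abs(sum(spectrum) - 1) < 1e-8, n_mutants >= 1)
  tpl <- template[1, ]
  m <- nchar(tpl$motif)
  with_seed(rng_seed, {
    ## deterministic largest-remainder allocation of class counts
    raw <- spectrum * n_mutants
    cnt <- floor(raw)
    rem <- n_mutants - sum(cnt)
    if (rem > 0) {
      o <- order(raw - cnt, decreasing = TRUE)
      cnt[o[seq_len(rem)]] <- cnt[o[seq_len(rem)]] + 1
    }
    classes <- rep(names(spectrum), cnt)
    if (length(classes) > 1) classes <- sample(classes, length(classes))
    ms_seq <- substr(tpl$seq, tpl$ms_start + 1, tpl$ms_end)
    records <- purrr::map(seq_len(n_mutants), function(i) {
      mut <- plant_event(tpl, ms_seq, classes[i], m)
      tibble(record_id = paste0("mut", i), template_id = tpl$template_id,
             mutant_seq = mut, planted_class = classes[i])
    }) %>% dplyr::bind_rows()
    counts <- tibble(
      context = c("polymerase", "ssDNA", "outside"),
      fudr_cm = round(mf_triple * cm),
      cm = cm
    )
    list(records = records[, c("record_id", "template_id", "mutant_seq")],
         counts = counts,
         truth = records[, c("record_id", "planted_class")],
         manifest = list(spectrum = spectrum, n_mutants = n_mutants,
                         mf_triple = mf_triple, rng_seed = rng_seed))
  })
}

## construct one mutant carrying one planted event
plant_event <- function(tpl, ms_seq, class, m) {
  lo <- tpl$ms_start + 1L          # 1-based MS bounds in template coords
  hi <- tpl$ms_end
  seq <- tpl$seq
  ch_at <- function(p) substr(seq, p, p)
  interior <- (lo + m):(hi - m)
  switch(
    class,
    "unit-deletion" = {
      ## drop the last complete unit of the (first) perfect tract
      paste0(substr(seq, 1, hi - m), substr(seq, hi + 1, nchar(seq)))
    },
    "unit-insertion" = {
      paste0(substr(seq, 1, hi), substr(seq, hi - m + 1, hi),
             substr(seq, hi + 1, nchar(seq)))
    },
    "interruption-substitution" = {
      pos <- interior[ceiling(length(interior) / 2)]
      alt <- setdiff(c("A", "C", "G", "T"), ch_at(pos))[1]
      paste0(substr(seq, 1, pos - 1), alt, substr(seq, pos + 1, nchar(seq)))
    },
    "interruption-deletion" = {
      if (m < 2) abort("single-base deletion in a mononucleotide run is unit-based")
      pos <- interior[ceiling(length(interior) / 2)]
      paste0(substr(seq, 1, pos - 1), substr(seq, pos + 1, nchar(seq)))
    },
    "interruption-insertion" = {
      pos <- interior[ceiling(length(interior) / 2)]
      ins <- setdiff(c("A", "C", "G", "T"),
                     c(ch_at(pos + 1), ch_at(pos + 1 - m)))[1]
      paste0(substr(seq, 1, pos), ins, substr(seq, pos + 1, nchar(seq)))
    },
    "interruption-removal" = {
      ## delete the interrupting base(s): the MS positions breaking period
      br <- which_interrupting(ms_seq, m)
      if (length(br) == 0)
        abort("interruption-removal planted on a perfect template")
      pos <- lo + br[1] - 1L
      paste0(substr(seq, 1, pos - 1), substr(seq, pos + 1, nchar(seq)))
    },
    abort(paste0("unknown planted class '", class, "'"))
  )
}

## positions (1-based within the MS sequence) of bases that break the
## dominant periodicity, found by run structure rather than the scanner
which_interrupting <- function(ms_seq, m) {
  n <- nchar(ms_seq)
  ch <- strsplit(ms_seq, "")[[1]]
  if (n <= m) return(integer(0))
  brk <- which(ch[seq_len(n - m)] != ch[seq_len(n - m) + m])
  ## a break at i means position i+m differs from its period predecessor
  unique(brk + m)
}
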