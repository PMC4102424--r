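#' Find perfect microsatellite seeds in a DNA sequence
#'
#' Exhaustively scans one sequence for maximal stretches of perfect mono- to
#' tetranucleotide tandem repeats at or above the per-motif-size minimum unit
#' counts of `cfg`. One seed is reported per maximal period-m region,
#' left-aligned, so a run of length not divisible by the motif size
#' contributes only its complete units. Motifs that are repetitions of a
#' shorter motif are reported under the shorter motif only, and N bases act
#' as hard breaks.
#'
#' @param seq A single DNA string over A/C/G/T/N (case-insensitive).
#' @param cfg An `ims_thresholds` object, see [threshold_config()].
#' @return A tibble with one row per seed: `start`, `end` (0-based half-open
#'   offsets), `motif` (as read on the sequence), `motif_size`, `units`,
#'   sorted by `start` then `motif_size`.
#' @examples
#' find_perfect_seeds(strrep("AC", 7), threshold_config("primate"))
#' @export
find_perfect_seeds <- function(seq, cfg = threshold_config("primate")) {
  check_thresholds(cfg)
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- check_dna(seq)
  n <- nchar(seq)
  out <- list()
  if (n > 0) {
    chars <- strsplit(seq, "")[[1]]
    not_n <- chars != "N"
    for (m in 1:4) {
      if (n < m * cfg$min_units[m]) next
      idx <- seq_len(n - m)
      eq <- chars[idx] == chars[idx + m] & not_n[idx] & not_n[idx + m]
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      hit <- which(r$values & r$lengths + m >= m * cfg$min_units[m])
      for (h in hit) {
        i0 <- starts[h] - 1L                  # 0-based region start
        reg_len <- r$lengths[h] + m
        units <- reg_len %/% m
        if (units < cfg$min_units[m]) next
        motif <- substr(seq, i0 + 1L, i0 + m)
        if (!is_primitive_motif(motif)) next
        out[[length(out) + 1L]] <-
          list(start = i0, end = i0 + units * m, motif = motif,
               motif_size = m, units = units)
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(start = integer(), end = integer(), motif = character(),
                  motif_size = integer(), units = integer()))
  }
  res %>%
    mutate(start = as.integer(.data$start), end = as.integer(.data$end),
           motif_size = as.integer(.data$motif_size),
           units = as.integer(.data$units)) %>%
    arrange(.data$start, .data$motif_size)
}

#' Extend a focal seed into a full microsatellite locus
#'
#' Implements the iterative extension algorithm: starting from a perfect
#' seed, both flanks are examined for (a) further seeds of the same motif
#' class (any rotation of the motif, e.g. `[CA]_2` abutting `[AC]_6`) and
#' (b) runs of at least two complete motif units, allowing intervening
#' non-repeat runs of at most `motif_size` bases. Each absorbed intervening
#' run becomes an interruption; phase-shifted same-motif runs that abut
#' directly are merged without an interruption. Extension stops when no
#' further addition of two or more complete units is possible (a candidate
#' terminal addition of exactly one unit is rejected). A locus whose final
#' span touches or overlaps a seed of a *different* motif class is a
#' compound microsatellite and is flagged `"compound-discarded"`.
#'
#' The repeat number is the locus length excluding interrupting bases,
#' divided by the motif size; it is a whole number by construction.
#'
#' @param seq The DNA string the seed was found in.
#' @param focal A one-row tibble (or list) with `start`, `end`, `motif` as
#'   produced by [find_perfect_seeds()].
#' @param cfg An `ims_thresholds` object.
#' @param all_seeds Optional precomputed seed table for `seq` (used for the
#'   compound check); computed if missing.
#' @return A one-row locus tibble with columns `start`, `end`, `motif`,
#'   `motif_size`, `canonical`, `status` (`"perfect"`, `"interrupted"` or
#'   `"compound-discarded"`), `n_interruptions`, `interruption_spec`
#'   (semicolon-joined `offset:bases` entries, offsets relative to locus
#'   start), `repeat_number`, `length` and `seq` (the locus sequence).
#' @examples
#' s <- paste0("TTT", "CACA", strrep("AC", 6), "GT", strrep("AC", 7), "TTT")
#' seed <- find_perfect_seeds(s)[1, ]
#' extend_seed(s, seed)
#' @export
extend_seed <- function(seq, focal, cfg = threshold_config("primate"),
                        all_seeds = NULL) {
  check_thresholds(cfg)
  seq <- check_dna(seq)
  n <- nchar(seq)
  motif <- focal$motif
  m <- nchar(motif)
  cls <- motif_rotations(motif)
  s0 <- as.integer(focal$start)
  e0 <- as.integer(focal$end)
  ints <- list()    # absolute 0-based [start, end) of interruption runs

  ## absorb on the left flank
  repeat {
    advanced <- FALSE
    for (g in 0:m) {
      ce <- s0 - g                       # candidate run end (0-based, excl.)
      if (ce - 2L * m < 0L) next
      if (g > 0L && grepl("N", substr(seq, ce + 1L, s0), fixed = TRUE)) break
      b1 <- substr(seq, ce - m + 1L, ce)
      if (!(b1 %in% cls)) next
      u <- 1L
      while (ce - (u + 1L) * m >= 0L &&
             substr(seq, ce - (u + 1L) * m + 1L, ce - u * m) == b1)
        u <- u + 1L
      if (u >= 2L) {
        if (g > 0L) ints <- c(ints, list(c(ce, s0)))
        s0 <- ce - u * m
        advanced <- TRUE
        break
      }
    }
    if (!advanced) break
  }

  ## absorb on the right flank
  repeat {
    advanced <- FALSE
    for (g in 0:m) {
      cs <- e0 + g                       # candidate run start (0-based)
      if (cs + 2L * m > n) next
      if (g > 0L && grepl("N", substr(seq, e0 + 1L, cs), fixed = TRUE)) break
      b1 <- substr(seq, cs + 1L, cs + m)
      if (!(b1 %in% cls)) next
      u <- 1L
      while (cs + (u + 1L) * m <= n &&
             substr(seq, cs + u * m + 1L, cs + (u + 1L) * m) == b1)
        u <- u + 1L
      if (u >= 2L) {
        if (g > 0L) ints <- c(ints, list(c(e0, cs)))
        e0 <- cs + u * m
        advanced <- TRUE
        break
      }
    }
    if (!advanced) break
  }

  if (is.null(all_seeds)) all_seeds <- find_perfect_seeds(seq, cfg)
  compound <- FALSE
  if (nrow(all_seeds) > 0) {
    other <- all_seeds[rotation_class(all_seeds$motif) != min(cls), ,
                       drop = FALSE]
    compound <- any(other$start <= e0 & other$end >= s0)
  }

  offs <- if (length(ints)) vapply(ints, `[`, numeric(1), 1) - s0 else numeric(0)
  o <- order(offs)
  ints <- ints[o]
  offs <- offs[o]
  int_len <- if (length(ints)) {
    vapply(ints, function(x) x[2] - x[1], numeric(1))
  } else numeric(0)
  spec <- if (length(ints)) {
    paste(vapply(seq_along(ints), function(i) {
      paste0(offs[i], ":", substr(seq, ints[[i]][1] + 1L, ints[[i]][2]))
    }, character(1)), collapse = ";")
  } else ""
  status <- if (compound) "compound-discarded"
            else if (length(ints)) "interrupted" else "perfect"
  len <- e0 - s0
  tibble(
    start = s0, end = e0, motif = motif, motif_size = m,
    canonical = canonical_motif(motif), status = status,
    n_interruptions = length(ints), interruption_spec = spec,
    repeat_number = (len - sum(int_len)) / m,
    length = len, seq = substr(seq, s0 + 1L, e0)
  )
}

#' Scan sequences for microsatellite loci
#'
#' Runs [find_perfect_seeds()] and [extend_seed()] over every sequence of a
#' set, merges seeds that extend to the same locus, and (for a `cfg` with
#' length windows, i.e. the `"population"` preset) filters perfect and
#' interrupted loci to the per-motif-size length windows. Compound loci are
#' retained with status `"compound-discarded"` so discard counts reconcile.
#'
#' @param x A named character vector of DNA sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param cfg An `ims_thresholds` object.
#' @return A locus tibble (columns of [extend_seed()] plus `seqnames` and
#'   `locus_id`), sorted by sequence and start.
#' @export
scan_microsatellites <- function(x, cfg = threshold_config("primate")) {
  check_thresholds(cfg)
  if (inherits(x, "DNAStringSet")) x <- setNames(as.character(x), names(x))
  stopifnot(is.character(x))
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  res <- purrr::imap(x, function(s, nm) {
    s <- check_dna(s)
    seeds <- find_perfect_seeds(s, cfg)
    if (nrow(seeds) == 0) return(NULL)
    loci <- purrr::map(seq_len(nrow(seeds)), function(i) {
      extend_seed(s, seeds[i, ], cfg, all_seeds = seeds)
    }) %>% dplyr::bind_rows()
    loci <- loci %>%
      mutate(rot = rotation_class(.data$motif)) %>%
      distinct(.data$start, .data$end, .data$rot, .keep_all = TRUE)
    ## drop loci contained in a longer locus of the same class
    keep <- rep(TRUE, nrow(loci))
    for (i in seq_len(nrow(loci))) {
      same <- which(loci$rot == loci$rot[i])
      same <- setdiff(same, i)
      if (any(loci$start[same] <= loci$start[i] &
              loci$end[same] >= loci$end[i])) keep[i] <- FALSE
    }
    loci <- loci[keep, , drop = FALSE] %>% select(-"rot")
    loci$seqnames <- nm
    loci
  }) %>% dplyr::bind_rows()
  if (is.null(res) || nrow(res) == 0) {
    return(tibble(seqnames = character(), start = integer(), end = integer(),
                  motif = character(), motif_size = integer(),
                  canonical = character(), status = character(),
                  n_interruptions = integer(), interruption_spec = character(),
                  repeat_number = numeric(), length = integer(),
                  seq = character(), locus_id = character()))
  }
  if (!is.null(cfg$len_window)) {
    keep <- res$status == "compound-discarded" |
      (res$length >= cfg$len_window[res$motif_size, "lo"] &
       res$length <= cfg$len_window[res$motif_size, "hi"])
    res <- res[keep, , drop = FALSE]
  }
  res %>%
    arrange(.data$seqnames, .data$start) %>%
    mutate(locus_id = paste0(.data$seqnames, ":", .data$start, "-", .data$end),
           .before = 1) %>%
    relocate("seqnames", .after = "locus_id")
}

#' Position class of an interruption within its locus
#'
#' Classifies an interruption by where its midpoint falls along the locus:
#' `"middle"` for the central 25% of the length (fractional position in
#' `[0.375, 0.625)`), `"fringe"` for the outer 25% at either end (`< 0.25`
#' or `>= 0.75`), `"other"` in between. The midpoint of an interruption at
#' 0-based offset `o` spanning `l` bases is `o + (l - 1)/2`.
#'
#' @param offset Integer vector, 0-based offset of the interruption within
#'   the locus.
#' @param length Integer vector, interruption length in bases.
#' @param locus_length Integer vector, locus length in bases (> 0).
#' @return Character vector of `"middle"`, `"fringe"`, `"other"`.
#' @examples
#' interruption_position_class(16, 2, 32)   # "middle"
#' interruption_position_class(2, 1, 40)    # "fringe"
#' @export
interruption_position_class <- function(offset, length, locus_length) {
  stopifnot(all(locus_length > 0))
  if (any(offset < 0 | offset + length > locus_length))
    abort("interruption lies outside its locus")
  frac <- (offset + (length - 1) / 2) / locus_length
  dplyr::case_when(
    frac >= 0.375 & frac < 0.625 ~ "middle",
    frac < 0.25 | frac >= 0.75 ~ "fringe",
    TRUE ~ "other"
  )
}

#' Parse an interruption spec string into a tibble
#'
#' @param spec Character vector of `"offset:bases"` entries joined by `";"`,
#'   as emitted in locus tables (`""` for perfect loci).
#' @return A tibble with `idx` (which element of `spec`), `offset`, `bases`,
#'   `length`.
#' @export
parse_interruption_spec <- function(spec) {
  purrr::map2(unname(spec), seq_along(spec), function(s, i) {
    if (is.na(s) || s == "") return(NULL)
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    tibble(idx = i,
           offset = as.integer(vapply(parts, `[`, character(1), 1)),
           bases = vapply(parts, `[`, character(1), 2)) %>%
      mutate(length = nchar(.data$bases))
  }) %>% dplyr::bind_rows()
}
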