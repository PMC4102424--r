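#' Reporter-assay mutant frequency
#'
#' The observed mutant frequency of a reporter reaction is the count of
#' doubly-resistant (mutant) colonies divided by the count of
#' single-selection (total progeny) colonies.
#'
#' @param fudr_cm Mutant colony counts (vectorized).
#' @param cm Total colony counts (> 0).
#' @return Numeric vector of frequencies in `[0, 1]`.
#' @examples
#' mutant_frequency(25, 50000)  # 5e-04
#' @export
mutant_frequency <- function(fudr_cm, cm) {
  if (any(cm <= 0)) abort("total colony count must be positive")
  if (any(fudr_cm < 0 | fudr_cm > cm))
    abort("mutant colony count must lie in [0, cm]")
  fudr_cm / cm
}

#' Background-corrected polymerase error frequency
#'
#' `Pol EF = observed MF - ssDNA background MF - outside-target MF`.
#' Negative differences (background exceeding signal) are floored at 0 with
#' a warning.
#'
#' @param observed,background,outside Mutant frequencies in `[0, 1]`
#'   (vectorized).
#' @return Numeric vector of error frequencies.
#' @examples
#' pol_ef(5e-4, 1e-4, 1e-4)  # 3e-04
#' @export
pol_ef <- function(observed, background, outside = 0) {
  stopifnot(all(observed >= 0 & observed <= 1),
            all(background >= 0 & background <= 1),
            all(outside >= 0 & outside <= 1))
  ef <- observed - background - outside
  if (any(ef < 0)) {
    warn("background exceeds observed mutant frequency; Pol EF floored at 0")
    ef <- pmax(ef, 0)
  }
  ef
}

#' Derive and classify mutational events of a sequenced mutant
#'
#' Aligns a mutant sequence against its reporter template, normalizes indel
#' placement to the 3' end of repeat runs (so calls are deterministic
#' despite placement ambiguity inside repeats), and classifies every
#' difference:
#'
#' * `"unit-based-indel"`: an indel inside the microsatellite whose net
#'   length is a whole number of motif units and whose application leaves
#'   the number of periodicity breaks unchanged (e.g. `[GT]_10 -> [GT]_9`);
#' * `"interruption-substitution"` / `"interruption-insertion"` /
#'   `"interruption-deletion"`: an event inside the microsatellite that
#'   changes its periodicity-break count. Events that *reduce* breaks on an
#'   already-interrupted template (e.g. `A_3 T A_4 -> [A]_7`) carry
#'   `removes_interruption = TRUE`;
#' * `"coding-region"`: an event outside the microsatellite.
#'
#' Detectability follows the reporter-selection rules: every frameshift
#' (net indel length not divisible by 3) is detectable; a base substitution
#' in coding sequence is detectable if it changes the amino acid or creates
#' a stop; a base substitution *inside* the microsatellite is detectable
#' only if it creates a stop codon. The template is read in frame from its
#' first base. Events at most 1 nt apart share a `tandem_group`; groups
#' further apart are nontandem.
#'
#' @param mutant_seq The sequenced mutant (A/C/G/T string).
#' @param template A one-row tibble (or list) with `seq` (the in-frame
#'   reporter sequence), `ms_start`, `ms_end` (0-based half-open bounds of
#'   the microsatellite region) and `motif`.
#' @return A tibble of events with `pos` (1-based template coordinate; for
#'   insertions the base after which the insert sits), `type`, `ref`,
#'   `alt`, `net`, `in_ms`, `class`, `detectable`, `removes_interruption`,
#'   `tandem_group`. Zero rows if the mutant equals the template.
#' @export
classify_events <- function(mutant_seq, template) {
  tseq <- check_dna(template$seq, allow_n = FALSE)
  mseq <- check_dna(mutant_seq, allow_n = FALSE)
  ev <- diff_events(tseq, mseq)
  if (nrow(ev) == 0) return(empty_events())
  ## verify the edit script reproduces the mutant, else the record is
  ## unalignable under our scoring
  if (apply_events(tseq, ev) != mseq)
    abort("record could not be aligned consistently to its template")
  m <- nchar(template$motif)
  ms_lo <- template$ms_start + 1L   # 1-based first MS base
  ms_hi <- template$ms_end          # 1-based last MS base
  ms_ref <- substr(tseq, ms_lo, ms_hi)
  breaks0 <- periodicity_breaks(ms_ref, m)

  n <- nrow(ev)
  in_ms <- logical(n); cls <- character(n)
  detec <- logical(n); rem <- logical(n)
  for (i in seq_len(n)) {
    e <- ev[i, ]
    foot_lo <- e$pos
    foot_hi <- if (e$type == "deletion") e$pos + nchar(e$ref) - 1L else e$pos
    in_ms[i] <- (e$type == "insertion" && e$pos >= ms_lo - 1L &&
                   e$pos < ms_hi) ||
                (e$type != "insertion" && foot_hi >= ms_lo && foot_lo <= ms_hi)
    ## apply this event alone and re-extract the MS region
    one <- apply_events(tseq, e)
    net <- e$net
    ms_new <- substr(one, ms_lo, ms_hi + net)
    breaks1 <- periodicity_breaks(ms_new, m)
    if (!in_ms[i]) {
      cls[i] <- "coding-region"
    } else if (e$type != "substitution" && abs(net) %% m == 0 &&
               breaks1 == breaks0) {
      cls[i] <- "unit-based-indel"
    } else {
      cls[i] <- paste0("interruption-", e$type)
      rem[i] <- breaks1 < breaks0
    }
    ## detectability
    if (e$type != "substitution") {
      detec[i] <- abs(net) %% 3 != 0
    } else {
      k <- (e$pos - 1L) %/% 3L
      ref_codon <- substr(tseq, 3L * k + 1L, 3L * k + 3L)
      alt_codon <- ref_codon
      substr(alt_codon, e$pos - 3L * k, e$pos - 3L * k) <- e$alt
      if (nchar(ref_codon) == 3L) {
        gc <- Biostrings::GENETIC_CODE
        aa_ref <- unname(gc[ref_codon]); aa_alt <- unname(gc[alt_codon])
        detec[i] <- if (in_ms[i]) identical(aa_alt, "*")
                    else !identical(aa_ref, aa_alt)
      }
    }
  }
  ev$in_ms <- in_ms
  ev$class <- cls
  ev$detectable <- detec
  ev$removes_interruption <- rem
  ## tandem grouping: events <= 1 nt apart share a group
  endpt <- ifelse(ev$type == "deletion", ev$pos + nchar(ev$ref) - 1L, ev$pos)
  gap_new <- c(TRUE, ev$pos[-1] - endpt[-length(endpt)] > 1L)
  ev$tandem_group <- cumsum(gap_new)
  ev
}

empty_events <- function() {
  tibble(pos = integer(), type = character(), ref = character(),
         alt = character(), net = integer(), in_ms = logical(),
         class = character(), detectable = logical(),
         removes_interruption = logical(), tandem_group = integer())
}

## count of positions whose base differs from the base one period earlier
periodicity_breaks <- function(seq, m) {
  n <- nchar(seq)
  if (n <= m) return(0L)
  ch <- strsplit(seq, "")[[1]]
  sum(ch[seq_len(n - m)] != ch[seq_len(n - m) + m])
}

## ---- alignment-based edit script -------------------------------------

## Global alignment of mutant vs template; returns substitution /
## insertion / deletion events in template coordinates with indels slid
## maximally 3'.
diff_events <- function(tseq, mseq) {
  if (tseq == mseq) return(empty_events()[0, 1:5])
  aln <- Biostrings::pairwiseAlignment(
    pattern = mseq, subject = tseq, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = TRUE),
    gapOpening = 4, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ev <- list()
  t_pos <- 0L
  i <- 1L
  while (i <= length(p)) {
    if (s[i] != "-" && p[i] != "-") {
      t_pos <- t_pos + 1L
      if (s[i] != p[i]) {
        ev[[length(ev) + 1L]] <- list(pos = t_pos, type = "substitution",
                                      ref = s[i], alt = p[i], net = 0L)
      }
      i <- i + 1L
    } else if (p[i] == "-") {         # deletion from template
      j <- i
      while (j <= length(p) && p[j] == "-") j <- j + 1L
      del <- paste(s[i:(j - 1L)], collapse = "")
      ev[[length(ev) + 1L]] <- list(pos = t_pos + 1L, type = "deletion",
                                    ref = del, alt = "",
                                    net = -nchar(del))
      t_pos <- t_pos + nchar(del)
      i <- j
    } else {                          # insertion into template
      j <- i
      while (j <= length(p) && s[j] == "-") j <- j + 1L
      ins <- paste(p[i:(j - 1L)], collapse = "")
      ev[[length(ev) + 1L]] <- list(pos = t_pos, type = "insertion",
                                    ref = "", alt = ins,
                                    net = nchar(ins))
      i <- j
    }
  }
  ev <- dplyr::bind_rows(ev)
  ## slide indels 3' as far as the sequence allows
  tn <- nchar(tseq)
  for (r in seq_len(nrow(ev))) {
    if (ev$type[r] == "deletion") {
      pos <- ev$pos[r]; del <- ev$ref[r]; L <- nchar(del)
      while (pos + L <= tn &&
             substr(tseq, pos, pos) == substr(tseq, pos + L, pos + L)) {
        pos <- pos + 1L
        del <- substr(tseq, pos, pos + L - 1L)
      }
      ev$pos[r] <- pos; ev$ref[r] <- del
    } else if (ev$type[r] == "insertion") {
      pos <- ev$pos[r]; ins <- ev$alt[r]
      while (pos + 1L <= tn &&
             substr(ins, 1L, 1L) == substr(tseq, pos + 1L, pos + 1L)) {
        ins <- paste0(substr(ins, 2L, nchar(ins)), substr(ins, 1L, 1L))
        pos <- pos + 1L
      }
      ev$pos[r] <- pos; ev$alt[r] <- ins
    }
  }
  ev %>% arrange(.data$pos) %>%
    mutate(pos = as.integer(.data$pos), net = as.integer(.data$net))
}

#' Apply an event list to a template sequence
#'
#' Replays substitution/insertion/deletion events (in template
#' coordinates, as produced by [classify_events()]) onto the template,
#' reconstructing the mutant sequence exactly.
#'
#' @param tseq Template sequence.
#' @param events Event tibble with `pos`, `type`, `ref`, `alt`.
#' @return The edited sequence.
#' @export
apply_events <- function(tseq, events) {
  if (nrow(events) == 0) return(tseq)
  ev <- events[order(events$pos, decreasing = TRUE), , drop = FALSE]
  out <- tseq
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    out <- switch(
      e$type,
      substitution = paste0(substr(out, 1, e$pos - 1), e$alt,
                            substr(out, e$pos + 1, nchar(out))),
      deletion = paste0(substr(out, 1, e$pos - 1),
                        substr(out, e$pos + nchar(e$ref), nchar(out))),
      insertion = paste0(substr(out, 1, e$pos), e$alt,
                         substr(out, e$pos + 1, nchar(out)))
    )
  }
  out
}

#' Classify a collection of mutant records
#'
#' Runs [classify_events()] over a table of sequenced mutants. Records that
#' cannot be aligned consistently to their template are quarantined with a
#' reason rather than dropped silently.
#'
#' @param records Tibble with `record_id`, `template_id`, `mutant_seq`.
#' @param templates Template registry tibble with `template_id`, `seq`,
#'   `ms_start`, `ms_end`, `motif`.
#' @return A list with `events` (all records' events, keyed by
#'   `record_id`/`template_id`) and `quarantine` (tibble of failures).
#' @export
classify_mutants <- function(records, templates) {
  need_col(records, c("record_id", "template_id", "mutant_seq"),
           "mutant classification")
  need_col(templates, c("template_id", "seq", "ms_start", "ms_end", "motif"),
           "template registry")
  ev_out <- list(); quar <- list()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    tpl <- templates[templates$template_id == r$template_id, ]
    if (nrow(tpl) != 1) {
      quar[[length(quar) + 1L]] <-
        tibble(record_id = r$record_id, reason = "unknown template")
      next
    }
    ev <- tryCatch(classify_events(r$mutant_seq, tpl[1, ]),
                   error = function(e) conditionMessage(e))
    if (is.character(ev)) {
      quar[[length(quar) + 1L]] <- tibble(record_id = r$record_id, reason = ev)
      next
    }
    if (nrow(ev) > 0) {
      ev$record_id <- r$record_id
      ev$template_id <- r$template_id
      ev_out[[length(ev_out) + 1L]] <- ev
    }
  }
  list(events = dplyr::bind_rows(ev_out),
       quarantine = dplyr::bind_rows(quar))
}

#' Correct a Pol EF for multiple nontandem events per product
#'
#' A synthesis product carrying several independent (nontandem) detectable
#' errors is selected once but represents several mutational events. The
#' corrected estimate scales the raw Pol EF by the number of detectable
#' nontandem event groups (a tandem group counts once) per sequenced
#' record: `pol_ef_est = pol_ef * groups / n_records`. With exactly one
#' detectable group per record this reduces to `pol_ef`.
#'
#' @param ef Raw Pol EF from [pol_ef()].
#' @param events Classified event tibble (needs `record_id`, `detectable`,
#'   `tandem_group`).
#' @param n_records Number of sequenced records (defaults to the distinct
#'   `record_id`s in `events`; pass explicitly if some records had no
#'   events).
#' @return The corrected error frequency.
#' @export
correct_multiple_events <- function(ef, events,
                                    n_records = dplyr::n_distinct(events$record_id)) {
  if (n_records == 0) abort("no records to correct over")
  det <- events[events$detectable, , drop = FALSE]
  groups <- nrow(dplyr::distinct(det, .data$record_id, .data$tandem_group))
  ef * groups / n_records
}

#' Error frequency of one event class
#'
#' `EF_class = (detectable events in the class / all detectable events) *
#' pol_ef_est`. The class filter may be one or more class labels
#' (`"unit-based-indel"`, `"interruption-substitution"`, ...) or the
#' special label `"interruption-removal"`, which selects events flagged
#' `removes_interruption`.
#'
#' @param events Classified event tibble.
#' @param ef_est Corrected Pol EF ([correct_multiple_events()]).
#' @param class_filter Character vector of class labels, or
#'   `"interruption-removal"`.
#' @return The class-specific error frequency.
#' @examples
#' \dontrun{event_class_ef(events, 3.4e-4, "interruption-removal")}
#' @export
event_class_ef <- function(events, ef_est, class_filter) {
  det <- events[events$detectable, , drop = FALSE]
  if (nrow(det) == 0) abort("no detectable events to form proportions over")
  sel <- if (identical(class_filter, "interruption-removal"))
    det$removes_interruption
  else det$class %in% class_filter
  sum(sel) / nrow(det) * ef_est
}

#' Interruption spectrum of a classified event set
#'
#' Proportions of interruption events created by each mechanism
#' (substitution, single-base insertion, deletion), over detectable *and*
#' undetectable interruption events, plus the fraction of products carrying
#' two or more interruptions among products carrying at least one.
#'
#' @param events Classified event tibble (needs `record_id`, `class`).
#' @return A list with `proportions` (tibble `mechanism`, `n`, `prop`;
#'   empty mechanisms reported with 0) and `multi_interruption_fraction`.
#' @export
spectrum_report <- function(events) {
  mechs <- c("substitution", "insertion", "deletion")
  ints <- events %>% filter(grepl("^interruption-", .data$class)) %>%
    mutate(mechanism = sub("^interruption-", "", .data$class))
  counts <- vapply(mechs, function(k) sum(ints$mechanism == k), integer(1))
  total <- sum(counts)
  props <- tibble(mechanism = mechs, n = counts,
                  prop = if (total > 0) counts / total else rep(0, 3))
  per_rec <- ints %>% count(.data$record_id, name = "k")
  multi <- if (nrow(per_rec) > 0) mean(per_rec$k >= 2) else 0
  list(proportions = props, multi_interruption_fraction = multi)
}

#' Full polymerase error summary for one reaction
#'
#' Combines the colony-count frequencies and the classified events of one
#' polymerase/template reaction into a `PolErrorSummary`-style object:
#' observed/background/outside MFs, the raw and multiple-event-corrected
#' Pol EFs, per-class EFs over the exhaustive event-class partition (which
#' sum to the corrected EF), and the interruption spectrum.
#'
#' @param observed_mf,background_mf,outside_mf Mutant frequencies.
#' @param events Classified event tibble.
#' @param n_records Number of sequenced records (see
#'   [correct_multiple_events()]).
#' @return An object of class `ims_polsum` (list). `tidy()` returns the
#'   per-class EF table; `glance()` the one-row summary.
#' @export
pol_error_summary <- function(observed_mf, background_mf, outside_mf, events,
                              n_records = dplyr::n_distinct(events$record_id)) {
  ef <- pol_ef(observed_mf, background_mf, outside_mf)
  ef_est <- correct_multiple_events(ef, events, n_records)
  classes <- c("unit-based-indel", "interruption-substitution",
               "interruption-insertion", "interruption-deletion",
               "coding-region")
  det <- events[events$detectable, , drop = FALSE]
  class_ef <- tibble(
    class = classes,
    n_detectable = vapply(classes, function(k) sum(det$class == k),
                          integer(1))
  ) %>%
    mutate(prop = if (nrow(det) > 0) .data$n_detectable / nrow(det) else 0,
           ef = .data$prop * ef_est)
  structure(list(observed_mf = observed_mf, background_mf = background_mf,
                 outside_mf = outside_mf, pol_ef = ef, pol_ef_est = ef_est,
                 class_ef = class_ef, spectrum = spectrum_report(events),
                 n_records = n_records, n_events = nrow(events)),
            class = "ims_polsum")
}

#' @export
print.ims_polsum <- function(x, ...) {
  cat("Polymerase error summary\n")
  cat(sprintf("  observed MF %.3g, background %.3g, outside %.3g\n",
              x$observed_mf, x$background_mf, x$outside_mf))
  cat(sprintf("  Pol EF %.3g, corrected Pol EF %.3g (%d records, %d events)\n",
              x$pol_ef, x$pol_ef_est, x$n_records, x$n_events))
  print(x$class_ef)
  invisible(x)
}
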