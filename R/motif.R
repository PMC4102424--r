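#' Motif utilities
#'
#' Microsatellite motifs are DNA strings of 1--4 bases that are *primitive*:
#' a motif must not itself be a tandem repeat of a shorter motif ("ATAT" is
#' not a valid tetranucleotide motif, it is two units of "AT"). Motifs that
#' are rotations of one another ("AC", "CA") describe the same repeat read in
#' a different phase, and motifs that are reverse complements describe the
#' same repeat on the other strand; [canonical_motif()] maps every motif to
#' the lexicographically smallest string over all rotations of the motif and
#' of its reverse complement, giving one label per strand-and-phase
#' equivalence class (e.g. "TG" -> "AC", "T" -> "A").
#'
#' @param motif Character vector of motifs over A/C/G/T.
#' @return `canonical_motif()` returns a character vector of canonical class
#'   labels, the same length as `motif`. It is idempotent.
#' @examples
#' canonical_motif(c("TG", "T", "GAT"))
#' @export
canonical_motif <- function(motif) {
  stopifnot(is.character(motif))
  vapply(motif, function(m) {
    check_motif(m)
    cands <- c(motif_rotations(m), motif_rotations(revcomp(m)))
    min(cands)
  }, character(1), USE.NAMES = FALSE)
}

#' Strand-specific rotation class label of a motif
#'
#' Like [canonical_motif()] but without folding in the reverse complement:
#' the minimum over rotations only. Seed extension works on a single strand,
#' where "AC" and "CA" are the same repeat in different phase but "GT" is a
#' different sequence.
#'
#' @inheritParams canonical_motif
#' @return Character vector of rotation-class labels.
#' @export
rotation_class <- function(motif) {
  vapply(motif, function(m) min(motif_rotations(m)), character(1),
         USE.NAMES = FALSE)
}

motif_rotations <- function(m) {
  n <- nchar(m)
  if (n == 1L) return(m)
  dd <- strsplit(paste0(m, m), "")[[1]]
  vapply(seq_len(n), function(i) paste(dd[i:(i + n - 1L)], collapse = ""),
         character(1))
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, ""), function(s) paste(rev(s), collapse = ""),
                character(1)))
}

#' Is a motif primitive (not a repeat of a shorter motif)?
#' @inheritParams canonical_motif
#' @return Logical vector.
#' @export
is_primitive_motif <- function(motif) {
  vapply(motif, function(m) {
    n <- nchar(m)
    if (n == 1L) return(TRUE)
    for (d in seq_len(n - 1L)) {
      if (n %% d == 0L &&
          m == strrep(substr(m, 1L, d), n %/% d)) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

check_motif <- function(m) {
  if (!grepl("^[ACGT]{1,4}$", m))
    abort(paste0("invalid motif '", m, "': must be 1-4 bases over A/C/G/T"))
  invisible(m)
}

check_dna <- function(seq, allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  seq <- toupper(seq)
  bad <- !grepl(pat, seq)
  if (any(bad))
    abort("sequence contains characters outside the A/C/G/T/N alphabet")
  seq
}
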