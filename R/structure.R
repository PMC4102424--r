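#' Repeat-structure strings
#'
#' Annotated repeat-structure strings describe a microsatellite allele as a
#' mix of repeated groups and literal bases, e.g. `"(CAG)_6 CAA (CAG)_9"` or
#' `"[A]_3 T [A]_4"`. [parse_repeat_structure()] expands such a string to
#' the plain DNA sequence; [compress_to_structure()] performs the reverse,
#' greedily encoding maximal runs of a given motif as `(MOTIF)_k` (a single
#' unit is written without a subscript) and leaving other bases literal.
#'
#' @param struct A structure string. Round `()` and square `[]` brackets are
#'   accepted; whitespace is ignored; the unit count may be written `_6` or
#'   `6`.
#' @return `parse_repeat_structure()`: a single DNA string.
#' @examples
#' parse_repeat_structure("[A]_3 T [A]_4")
#' compress_to_structure("AAATAAAA", "A")
#' @export
parse_repeat_structure <- function(struct) {
  stopifnot(is.character(struct), length(struct) == 1)
  s <- gsub("[[:space:]]", "", struct)
  s <- chartr("[]", "()", s)
  out <- character(0)
  while (nchar(s) > 0) {
    m <- regmatches(s, regexpr("^\\(([ACGT]+)\\)(_?\\d+)?", s))
    if (length(m) == 1 && nchar(m) > 0) {
      motif <- sub("^\\(([ACGT]+)\\).*$", "\\1", m)
      cnt <- sub("^\\([ACGT]+\\)_?", "", m)
      k <- if (cnt == "") 1L else as.integer(cnt)
      out <- c(out, strrep(motif, k))
      s <- substr(s, nchar(m) + 1L, nchar(s))
      next
    }
    m <- regmatches(s, regexpr("^[ACGT]+", s))
    if (length(m) == 1 && nchar(m) > 0) {
      out <- c(out, m)
      s <- substr(s, nchar(m) + 1L, nchar(s))
      next
    }
    abort(paste0("cannot parse repeat-structure string at: '", s, "'"))
  }
  paste(out, collapse = "")
}

#' @rdname parse_repeat_structure
#' @param seq A DNA string to encode.
#' @param motif The repeat motif to encode runs of.
#' @return `compress_to_structure()`: a structure string using round
#'   brackets and `_k` subscripts.
#' @export
compress_to_structure <- function(seq, motif) {
  check_motif(motif)
  m <- nchar(motif)
  n <- nchar(seq)
  out <- character(0)
  lit <- character(0)
  i <- 1L
  flush_lit <- function(out, lit) {
    if (length(lit)) c(out, paste(lit, collapse = "")) else out
  }
  while (i <= n) {
    k <- 0L
    while (i + (k + 1L) * m - 1L <= n &&
           substr(seq, i + k * m, i + (k + 1L) * m - 1L) == motif)
      k <- k + 1L
    if (k >= 1L) {
      out <- flush_lit(out, lit); lit <- character(0)
      out <- c(out, if (k == 1L) paste0("(", motif, ")")
                    else paste0("(", motif, ")_", k))
      i <- i + k * m
    } else {
      lit <- c(lit, substr(seq, i, i))
      i <- i + 1L
    }
  }
  out <- flush_lit(out, lit)
  paste(out, collapse = " ")
}

## ---- low-level sequence edits (1-based, VCF-style anchored alleles) ----

## Apply a normalized biallelic variant to a sequence. `pos` is 1-based and
## points at the first REF base (for indels the shared anchor base).
apply_variant_seq <- function(seq, pos, ref, alt) {
  stopifnot(pos >= 1, pos + nchar(ref) - 1L <= nchar(seq))
  if (substr(seq, pos, pos + nchar(ref) - 1L) != ref)
    abort("REF allele does not match the sequence at `pos`")
  paste0(substr(seq, 1L, pos - 1L), alt,
         substr(seq, pos + nchar(ref), nchar(seq)))
}

## TRUE when every base of `seq` equals the base `m` positions before it
## (perfect period-m structure; a trailing partial unit still counts).
is_periodic <- function(seq, m) {
  n <- nchar(seq)
  if (n <= m) return(TRUE)
  ch <- strsplit(seq, "")[[1]]
  all(ch[seq_len(n - m)] == ch[seq_len(n - m) + m])
}

## Longest run of complete units of `motif` (any rotation) in `seq`,
## in units.
longest_perfect_units <- function(seq, motif) {
  m <- nchar(motif)
  cls <- motif_rotations(motif)
  n <- nchar(seq)
  best <- 0L
  for (start in seq_len(min(n, m))) {
    i <- start
    run <- 0L
    while (i + m - 1L <= n) {
      blk <- substr(seq, i, i + m - 1L)
      if (blk %in% cls &&
          (run == 0L || blk == substr(seq, i - m, i - 1L))) {
        run <- run + 1L
        best <- max(best, run)
      } else {
        run <- 0L
      }
      i <- i + m
    }
  }
  best
}
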