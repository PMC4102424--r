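#' Read and write pipeline file formats
#'
#' Thin wrappers around the standard readers: FASTA through Biostrings,
#' VCF through vcfR, locus tables as BED6+ TSV. Locus tables use 0-based
#' half-open coordinates (BED convention) with the motif as the name
#' column and `round(repeat_number * 100)` as the score; a `pos_1based`
#' column mirrors the 1-based start for convenience. Writing then reading
#' any of these preserves the records exactly.
#'
#' @param path File path.
#' @return `read_fasta()`: a named character vector of sequences.
#' @name ims_io
NULL

#' @rdname ims_io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname ims_io
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), filepath = path)
  invisible(path)
}

#' @rdname ims_io
#' @param loci Locus tibble from [scan_microsatellites()].
#' @export
write_locus_bed <- function(loci, path) {
  bed <- loci %>%
    transmute(chrom = .data$seqnames, start = .data$start, end = .data$end,
              name = .data$motif, score = round(.data$repeat_number * 100),
              strand = ".", status = .data$status,
              n_interruptions = .data$n_interruptions,
              interruption_spec = dplyr::coalesce(.data$interruption_spec, ""),
              pos_1based = .data$start + 1L)
  readr::write_tsv(bed, path, col_names = TRUE)
  invisible(path)
}

#' @rdname ims_io
#' @export
read_locus_bed <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    chrom = "c", start = "i", end = "i", name = "c",
                    score = "d", strand = "c", status = "c",
                    n_interruptions = "i", interruption_spec = "c",
                    pos_1based = "i")) %>%
    mutate(interruption_spec = dplyr::coalesce(.data$interruption_spec, ""))
}

#' @rdname ims_io
#' @param variants Variant tibble (`seqnames`, `pos`, `ref`, `alt`,
#'   `af_<POP>` columns).
#' @export
write_vcf <- function(variants, path) {
  af_cols <- grep("^af_", names(variants), value = TRUE)
  pops <- sub("^af_", "", af_cols)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=imsat",
    vapply(pops, function(p) paste0(
      "##INFO=<ID=AF_", p,
      ",Number=1,Type=Float,Description=\"", p,
      " alternate allele frequency\">"), character(1)),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  info <- apply(as.matrix(variants[, af_cols, drop = FALSE]), 1, function(v)
    paste(paste0("AF_", pops, "=", format(v, trim = TRUE, scientific = FALSE)),
          collapse = ";"))
  body <- paste(variants$seqnames, variants$pos, ".", variants$ref,
                variants$alt, ".", "PASS", info, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname ims_io
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  out <- tibble(seqnames = fix$CHROM, pos = as.integer(fix$POS),
                ref = fix$REF, alt = fix$ALT)
  info <- fix$INFO
  keys <- unique(unlist(lapply(strsplit(info, ";"), function(kv)
    sub("=.*$", "", kv))))
  keys <- grep("^AF_", keys, value = TRUE)
  for (k in keys) {
    val <- vapply(info, function(s) {
      m <- regmatches(s, regexpr(paste0("(^|;)", k, "=[^;]*"), s))
      if (length(m) == 0) NA_real_ else as.numeric(sub(paste0("^;?", k, "="), "", m))
    }, numeric(1), USE.NAMES = FALSE)
    out[[paste0("af_", sub("^AF_", "", k))]] <- val
  }
  out
}
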