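#' Call interruption polymorphisms in perfect microsatellites
#'
#' Intersects a normalized, biallelic population variant table with a set of
#' perfect microsatellite loci and emits one interruption call per
#' (locus, variant, population) where all of the following hold:
#'
#' * the population allele frequency is at least `af_min` (inclusive);
#' * the affected span lies inside the locus *excluding* the first and last
#'   repeat unit (`motif_size` bases at each end) -- a SNP must fall strictly
#'   inside, a deletion's removed bases must all lie inside, and an
#'   insertion point must sit between two non-terminal bases;
#' * for indels, the net inserted/deleted length is not a multiple of the
#'   motif size (whole-motif gains and losses, including 2x and 3x motif
#'   indels, are length polymorphisms, not interruptions);
#' * applying the allele actually breaks the motif periodicity of the locus
#'   sequence (a variant that leaves a perfect repeat, e.g. a partial-unit
#'   extension in phase, is not an interruption).
#'
#' Each call carries its mechanism (`"SNP"`, `"indel-insertion"`,
#' `"indel-deletion"`) and its fate from [classify_fate()].
#'
#' @param variants Tibble with `seqnames`, `pos` (1-based, VCF convention),
#'   `ref`, `alt` (single alleles; multi-allelic rows must be decomposed
#'   first) and one `af_<POP>` column per population.
#' @param loci Perfect-locus tibble from [scan_microsatellites()] (requires
#'   `locus_id`, `seqnames`, `start`, `end`, `motif`, `motif_size`, `seq`,
#'   `status`).
#' @param cfg `ims_thresholds`, used for the death/degeneration bound;
#'   defaults to the population preset.
#' @param af_min Minimum population allele frequency (inclusive).
#' @param populations Population labels to call; default: every `af_<POP>`
#'   column in `variants`.
#' @return A tibble with one row per call: locus fields, variant fields,
#'   `mechanism`, `fate`, `population`, `af`.
#' @export
call_interruptions <- function(variants, loci,
                               cfg = threshold_config("population"),
                               af_min = 0.05, populations = NULL) {
  check_thresholds(cfg)
  need_col(variants, c("seqnames", "pos", "ref", "alt"), "interruption calling")
  need_col(loci, c("locus_id", "seqnames", "start", "end", "motif",
                   "motif_size", "seq", "status"), "interruption calling")
  if (any(loci$status != "perfect"))
    abort("`loci` must contain perfect loci only; filter on status first")
  if (any(grepl(",", variants$alt, fixed = TRUE)))
    abort("multi-allelic records found; decompose `alt` into one allele per row first")
  af_cols <- grep("^af_", names(variants), value = TRUE)
  if (is.null(populations)) populations <- sub("^af_", "", af_cols)
  if (length(populations) == 0)
    abort("no `af_<POP>` columns found and no `populations` given")

  hits <- dplyr::inner_join(
    variants %>% mutate(.vid = dplyr::row_number()),
    loci %>%
      select(locus_id, locus_seqnames = "seqnames", locus_start = "start",
             locus_end = "end", motif, motif_size, locus_seq = "seq"),
    by = c("seqnames" = "locus_seqnames"), relationship = "many-to-many"
  ) %>%
    filter(.data$pos >= .data$locus_start + 1,
           .data$pos <= .data$locus_end)
  if (nrow(hits) == 0) return(empty_calls())

  keep <- logical(nrow(hits))
  mech <- character(nrow(hits))
  fate <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    m <- h$motif_size
    S <- h$locus_start; E <- h$locus_end
    nref <- nchar(h$ref); nalt <- nchar(h$alt)
    if (nref == nalt && nref > 1L) next            # MNP: not SNP nor indel
    if (nref == 1L && nalt == 1L) {
      if (h$pos < S + m + 1 || h$pos > E - m) next
      mech_i <- "SNP"
    } else {
      net <- abs(nalt - nref)
      if (net %% m == 0L) next                     # whole-motif indel
      if (nref > nalt) {                           # deletion (anchored)
        if (h$pos + 1 < S + m + 1 || h$pos + nref - 1 > E - m) next
        mech_i <- "indel-deletion"
      } else {                                     # insertion
        if (h$pos < S + m || h$pos > E - m) next
        mech_i <- "indel-insertion"
      }
    }
    rel <- h$pos - S                               # 1-based within locus
    new_seq <- tryCatch(
      apply_variant_seq(h$locus_seq, rel, h$ref, h$alt),
      error = function(e) NULL)
    if (is.null(new_seq)) next
    if (is_periodic(new_seq, m)) next              # periodicity unbroken
    keep[i] <- TRUE
    mech[i] <- mech_i
    fate[i] <- classify_fate(h$locus_seq, h$motif, rel, h$ref, h$alt, cfg)
  }
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0) return(empty_calls())
  hits$mechanism <- mech[keep]
  hits$fate <- fate[keep]

  purrr::map(populations, function(p) {
    col <- paste0("af_", p)
    need_col(hits, col, paste0("allele frequency for population ", p))
    hits %>%
      filter(.data[[col]] >= af_min) %>%
      transmute(.data$locus_id, .data$seqnames, .data$locus_start,
                .data$locus_end, .data$motif, .data$motif_size,
                .data$pos, .data$ref, .data$alt, .data$mechanism,
                .data$fate, population = p, af = .data[[col]])
  }) %>% dplyr::bind_rows()
}

empty_calls <- function() {
  tibble(locus_id = character(), seqnames = character(),
         locus_start = integer(), locus_end = integer(), motif = character(),
         motif_size = integer(), pos = integer(), ref = character(),
         alt = character(), mechanism = character(), fate = character(),
         population = character(), af = numeric())
}

#' Death or degeneration of an interrupted microsatellite
#'
#' Applies a variant allele to a perfect locus sequence and asks whether any
#' residual perfect tandem stretch of the motif still reaches the mutability
#' threshold. Residual stretches are counted in *complete* motif units; the
#' interruption is a `"degeneration"` if the longest residual stretch spans
#' at least the threshold length in bp (inclusive), otherwise a `"death"`.
#' The threshold is the lower bound of `cfg`'s length window for the motif
#' size (population preset: 8/10/12/16 bp for mono-tetra), or
#' `min_units * motif_size` for a windowless config.
#'
#' @param locus_seq The perfect locus sequence.
#' @param motif The repeat motif.
#' @param pos 1-based position of the variant within `locus_seq`.
#' @param ref,alt Alleles (VCF anchored convention for indels).
#' @param cfg `ims_thresholds`.
#' @return `"death"` or `"degeneration"`.
#' @examples
#' cfg <- threshold_config("population")
#' classify_fate(strrep("A", 10), "A", 9, "A", "T", cfg)  # degeneration
#' classify_fate(strrep("A", 8), "A", 4, "A", "T", cfg)   # death
#' @export
classify_fate <- function(locus_seq, motif, pos, ref, alt, cfg) {
  check_thresholds(cfg)
  m <- nchar(motif)
  bound_bp <- if (!is.null(cfg$len_window)) cfg$len_window[m, "lo"]
              else cfg$min_units[m] * m
  new_seq <- apply_variant_seq(locus_seq, pos, ref, alt)
  units <- longest_perfect_units(new_seq, motif)
  if (units * m >= bound_bp) "degeneration" else "death"
}

#' Partition calls by population sharing
#'
#' Groups calls by (locus, variant) and assigns each distinct interruption
#' to the exact subset of populations it was called in. Counts over subsets
#' sum to the number of distinct interruptions, and the partition is
#' invariant to the processing order of populations.
#'
#' @param calls Call tibble from [call_interruptions()].
#' @return A tibble with `populations` (`"+"`-joined sorted labels),
#'   `n_populations`, `sharing_class` (`"population-specific"`,
#'   `"shared-2"`, `"shared-3"`, `"common-to-all"`) and `n` (distinct
#'   interruptions). The total population count used for
#'   `"common-to-all"` is the number of distinct populations present in
#'   `calls`.
#' @export
sharing_partition <- function(calls) {
  need_col(calls, c("locus_id", "pos", "ref", "alt", "population"),
           "sharing partition")
  k <- dplyr::n_distinct(calls$population)
  calls %>%
    group_by(.data$locus_id, .data$pos, .data$ref, .data$alt) %>%
    summarise(populations = paste(sort(unique(.data$population)),
                                  collapse = "+"),
              n_populations = dplyr::n_distinct(.data$population),
              .groups = "drop") %>%
    count(.data$populations, .data$n_populations, name = "n") %>%
    mutate(sharing_class = dplyr::case_when(
      .data$n_populations == 1 ~ "population-specific",
      .data$n_populations == k ~ "common-to-all",
      TRUE ~ paste0("shared-", .data$n_populations)
    )) %>%
    select("populations", "n_populations", "sharing_class", "n") %>%
    arrange(.data$n_populations, .data$populations)
}

#' Annotate calls with exonic and coding consequences
#'
#' Intersects calls with exon intervals and, where a CDS annotation and the
#' genome sequence are supplied, classifies the coding effect: indels with
#' net length not divisible by 3 are `"frameshift"` (divisible:
#' `"inframe-indel"`); SNPs are translated pre/post through the standard
#' genetic code and classified `"nonsense"`, `"nonsynonymous"` or
#' `"synonymous"`; exonic positions outside any CDS are `"noncoding"`
#' (UTR). Calls outside every exon get `exonic = FALSE` and `effect = NA`.
#'
#' @param calls Call tibble from [call_interruptions()].
#' @param exons Tibble with `seqnames`, `start`, `end` (0-based half-open)
#'   and `gene`.
#' @param cds Optional tibble with `seqnames`, `start`, `end` (0-based
#'   half-open), `strand` (`"+"`/`"-"`) and `phase` (0/1/2 bases to skip
#'   before the first complete codon of the block).
#' @param genome Optional named character vector (or `DNAStringSet`) of the
#'   reference sequences, required to translate SNP codons.
#' @return `calls` with added `exonic`, `gene`, `effect` columns.
#' @export
annotate_exonic <- function(calls, exons, cds = NULL, genome = NULL) {
  need_col(exons, c("seqnames", "start", "end", "gene"), "exon annotation")
  if (inherits(genome, "DNAStringSet"))
    genome <- setNames(as.character(genome), names(genome))
  res <- calls
  res$exonic <- FALSE
  res$gene <- NA_character_
  res$effect <- NA_character_
  for (i in seq_len(nrow(res))) {
    v <- res[i, ]
    ex <- exons %>%
      filter(.data$seqnames == v$seqnames, v$pos > .data$start,
             v$pos <= .data$end)
    if (nrow(ex) == 0) next
    res$exonic[i] <- TRUE
    res$gene[i] <- ex$gene[1]
    res$effect[i] <- "noncoding"
    if (is.null(cds)) next
    cb <- cds %>%
      filter(.data$seqnames == v$seqnames, v$pos > .data$start,
             v$pos <= .data$end)
    if (nrow(cb) == 0) next
    cb <- cb[1, ]
    nref <- nchar(v$ref); nalt <- nchar(v$alt)
    if (nref != nalt) {
      res$effect[i] <- if (abs(nalt - nref) %% 3 != 0) "frameshift"
                       else "inframe-indel"
    } else if (!is.null(genome)) {
      res$effect[i] <- snp_coding_effect(v$seqnames, v$pos, v$ref, v$alt,
                                         cb, genome)
    }
  }
  res
}

snp_coding_effect <- function(chrom, pos, ref, alt, cds_block, genome) {
  gseq <- genome[[chrom]]
  S <- cds_block$start; E <- cds_block$end
  ph <- cds_block$phase
  if (cds_block$strand == "+") {
    off <- (pos - 1) - S - ph
    if (off < 0) { warn("SNP inside CDS phase overhang; treated as noncoding")
                   return("noncoding") }
    c0 <- S + ph + 3 * (off %/% 3)             # 0-based codon start
    if (c0 + 3 > E) { warn("codon spans CDS block boundary; treated as noncoding")
                      return("noncoding") }
    codon <- substr(gseq, c0 + 1, c0 + 3)
    idx <- pos - c0                            # 1..3 within codon
    alt_codon <- codon
    substr(alt_codon, idx, idx) <- alt
  } else {
    c_off <- E - pos                           # 0-based coding coordinate
    off <- c_off - ph
    if (off < 0) { warn("SNP inside CDS phase overhang; treated as noncoding")
                   return("noncoding") }
    cstart <- ph + 3 * (off %/% 3)             # codon start in coding coords
    g_hi <- E - cstart                         # 1-based genome end of codon
    g_lo <- g_hi - 2
    if (g_lo <= S) { warn("codon spans CDS block boundary; treated as noncoding")
                     return("noncoding") }
    fwd <- substr(gseq, g_lo, g_hi)
    codon <- revcomp(fwd)
    idx <- g_hi - pos + 1
    alt_codon_fwd <- fwd
    substr(alt_codon_fwd, pos - g_lo + 1, pos - g_lo + 1) <- alt
    alt_codon <- revcomp(alt_codon_fwd)
  }
  gc <- Biostrings::GENETIC_CODE
  aa_ref <- unname(gc[codon])
  aa_alt <- unname(gc[alt_codon])
  if (is.na(aa_alt) || is.na(aa_ref)) return("noncoding")
  if (aa_alt == "*" && aa_ref != "*") return("nonsense")
  if (aa_alt == aa_ref) return("synonymous")
  "nonsynonymous"
}

#' Per-population call summary (loci, mechanisms, fates)
#'
#' Tabulates, per population, the number of distinct interrupted loci and
#' the SNP/indel x death/degeneration call counts. The number of loci is at
#' most the sum of the four call counts, with equality when no locus
#' carries multiple interruptions.
#'
#' @param calls Call tibble from [call_interruptions()].
#' @return A tibble with one row per population.
#' @export
summarise_calls <- function(calls) {
  calls %>%
    group_by(.data$population) %>%
    summarise(
      total_loci = dplyr::n_distinct(.data$locus_id),
      snp_death = sum(.data$mechanism == "SNP" & .data$fate == "death"),
      snp_degeneration = sum(.data$mechanism == "SNP" &
                               .data$fate == "degeneration"),
      indel_death = sum(.data$mechanism != "SNP" & .data$fate == "death"),
      indel_degeneration = sum(.data$mechanism != "SNP" &
                                 .data$fate == "degeneration"),
      .groups = "drop"
    )
}

#' Reconstruct disease-locus allele structures per population
#'
#' For annotated disease-associated repeat loci (coordinates plus a
#' reference repeat-structure string), applies each overlapping variant to
#' the reference structure and emits, per locus and population, every
#' allele's reconstructed structure string and frequency. The reference
#' allele's frequency is one minus the summed variant frequencies (the
#' variant set is assumed complete and alleles mutually exclusive).
#' Variants that fall outside the annotated structure are flagged and
#' excluded (attribute `"excluded"` of the result).
#'
#' @param variants Variant tibble as in [call_interruptions()].
#' @param disease_loci Tibble with `locus_id`, `seqnames`, `start` (0-based
#'   offset of the structure) and `structure` (see
#'   [parse_repeat_structure()]).
#' @param populations Populations to tabulate; defaults to the `af_<POP>`
#'   columns.
#' @return A tibble with `locus_id`, `population`, `structure`, `frequency`
#'   and `is_reference`.
#' @export
tabulate_disease_loci <- function(variants, disease_loci, populations = NULL) {
  need_col(disease_loci, c("locus_id", "seqnames", "start", "structure"),
           "disease locus table")
  af_cols <- grep("^af_", names(variants), value = TRUE)
  if (is.null(populations)) populations <- sub("^af_", "", af_cols)
  out <- list()
  excluded <- list()
  for (i in seq_len(nrow(disease_loci))) {
    dl <- disease_loci[i, ]
    ref_seq <- parse_repeat_structure(dl$structure)
    motif <- structure_primary_motif(dl$structure)
    len <- nchar(ref_seq)
    v <- variants %>% filter(.data$seqnames == dl$seqnames,
                             .data$pos > dl$start, .data$pos <= dl$start + len)
    ok <- rep(TRUE, nrow(v))
    alt_struct <- character(nrow(v))
    if (nrow(v) > 0) for (j in seq_len(nrow(v))) {
      rel <- v$pos[j] - dl$start
      if (rel + nchar(v$ref[j]) - 1 > len) { ok[j] <- FALSE; next }
      new <- tryCatch(apply_variant_seq(ref_seq, rel, v$ref[j], v$alt[j]),
                      error = function(e) NULL)
      if (is.null(new)) { ok[j] <- FALSE; next }
      alt_struct[j] <- compress_to_structure(new, motif)
    }
    if (any(!ok))
      excluded[[length(excluded) + 1L]] <-
        v[!ok, c("seqnames", "pos", "ref", "alt")] %>%
        mutate(locus_id = dl$locus_id)
    v <- v[ok, , drop = FALSE]
    alt_struct <- alt_struct[ok]
    for (p in populations) {
      col <- paste0("af_", p)
      afs <- if (nrow(v) > 0) v[[col]] else numeric(0)
      nonzero <- afs > 0
      out[[length(out) + 1L]] <- dplyr::bind_rows(
        tibble(locus_id = dl$locus_id, population = p,
               structure = compress_to_structure(ref_seq, motif),
               frequency = 1 - sum(afs[nonzero]), is_reference = TRUE),
        tibble(locus_id = dl$locus_id, population = p,
               structure = alt_struct[nonzero],
               frequency = afs[nonzero], is_reference = FALSE)
      )
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "excluded") <- dplyr::bind_rows(excluded)
  res
}

structure_primary_motif <- function(struct) {
  s <- chartr("[]", "()", gsub("[[:space:]]", "", struct))
  m <- regmatches(s, regexpr("\\(([ACGT]+)\\)", s))
  if (length(m) == 0) abort("structure has no bracketed repeat group")
  sub("^\\(([ACGT]+)\\)$", "\\1", m)
}
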