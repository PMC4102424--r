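cfgp <- threshold_config("population")

# one perfect locus on a tiny contig, with enough flank for context
make_locus <- function(motif, units, flank = "GCGTC") {
  run <- strrep(motif, units)
  seq <- paste0(flank, run, "CGTGC")
  tibble::tibble(
    locus_id = "L1", seqnames = "chr1",
    start = nchar(flank), end = nchar(flank) + nchar(run),
    motif = motif, motif_size = nchar(motif), status = "perfect",
    seq = run)
}

variant <- function(pos, ref, alt, af = 0.3) {
  tibble::tibble(seqnames = "chr1", pos = pos, ref = ref, alt = alt,
                 af_AFR = af)
}

test_that("terminal repeat units never yield calls", {
  loc <- make_locus("A", 9)             # occupies 1-based 6..14
  expect_equal(nrow(call_interruptions(variant(6, "A", "T"), loc, cfgp)), 0)
  expect_equal(nrow(call_interruptions(variant(14, "A", "T"), loc, cfgp)), 0)
  expect_equal(nrow(call_interruptions(variant(7, "A", "T"), loc, cfgp)), 1)
  loc2 <- make_locus("AC", 7)           # 6..19; terminal units 6-7 and 18-19
  expect_equal(nrow(call_interruptions(variant(7, "C", "G"), loc2, cfgp)), 0)
  expect_equal(nrow(call_interruptions(variant(8, "A", "G"), loc2, cfgp)), 1)
})

test_that("whole-motif indels are length polymorphisms, not interruptions", {
  loc <- make_locus("AC", 7)
  # 2 bp deletion of one unit inside the locus: no call
  del2 <- variant(8, "ACA", "A")
  expect_equal(nrow(call_interruptions(del2, loc, cfgp)), 0)
  # 1 bp deletion breaks the motif: called as indel-deletion
  del1 <- variant(8, "AC", "A")
  res <- call_interruptions(del1, loc, cfgp)
  expect_equal(res$mechanism, "indel-deletion")
})

test_that("the allele-frequency cutoff is inclusive at 0.05", {
  loc <- make_locus("A", 9)
  expect_equal(nrow(call_interruptions(variant(9, "A", "T", af = 0.04),
                                       loc, cfgp)), 0)
  res <- call_interruptions(variant(9, "A", "T", af = 0.05), loc, cfgp)
  expect_equal(nrow(res), 1)
  expect_equal(res$mechanism, "SNP")
  expect_equal(res$population, "AFR")
})

test_that("multi-allelic records are rejected with advice to decompose", {
  loc <- make_locus("A", 9)
  expect_error(call_interruptions(variant(9, "A", "T,G"), loc, cfgp),
               "decompose")
})

test_that("non-perfect loci are refused", {
  loc <- make_locus("A", 9)
  loc$status <- "interrupted"
  expect_error(call_interruptions(variant(9, "A", "T"), loc, cfgp), "perfect")
})

test_that("fate follows residual perfect tract length, counted in whole units", {
  # (A)10, SNP after unit 8 leaves (A)8 = 8 bp >= mono bound 8: degeneration
  expect_equal(classify_fate(strrep("A", 10), "A", 9, "A", "T", cfgp),
               "degeneration")
  # (A)8 mid SNP leaves (A)3/(A)4: death
  expect_equal(classify_fate(strrep("A", 8), "A", 4, "A", "T", cfgp),
               "death")
  # (AC)9 central 1 bp insertion leaves 4 complete units each side
  # (8 bp < 10 bp di bound): death
  expect_equal(classify_fate(strrep("AC", 9), "AC", 9, "A", "AG", cfgp),
               "death")
})

test_that("calls are keyed per population and partition by sharing", {
  loc <- make_locus("A", 9)
  v <- variant(9, "A", "T")
  v$af_EUR <- 0.2; v$af_ASN <- 0; v$af_AMR <- 0
  calls <- call_interruptions(v, loc, cfgp)
  expect_equal(sort(calls$population), c("AFR", "EUR"))
  sp <- sharing_partition(calls)
  expect_equal(sp$n, 1L)
  expect_equal(sp$populations, "AFR+EUR")
  expect_equal(sp$sharing_class, "common-to-all")  # only 2 pops present
  # single-population input: everything population-specific
  calls1 <- calls[calls$population == "AFR", ]
  expect_equal(sharing_partition(calls1)$sharing_class,
               "population-specific")
})

test_that("planted sharing classes are recovered exactly from synthetic VCFs", {
  pv <- gen_population_vcf(n_expected = 15, n_decoy_af = 4,
                           n_decoy_terminal = 4, n_decoy_wholemotif = 4,
                           rng_seed = 17)
  loci <- scan_microsatellites(pv$sequences, cfgp)
  calls <- call_interruptions(pv$variants,
                              dplyr::filter(loci, status == "perfect"), cfgp)
  got <- calls %>%
    dplyr::group_by(pos, ref, alt) %>%
    dplyr::summarise(populations = paste(sort(unique(population)),
                                         collapse = "+"), .groups = "drop")
  want <- pv$truth[pv$truth$label == "expected-call",
                   c("pos", "ref", "alt", "populations")]
  merged <- dplyr::inner_join(got, want, by = c("pos", "ref", "alt"),
                              suffix = c(".got", ".want"))
  expect_equal(nrow(merged), nrow(want))       # recall
  expect_equal(nrow(got), nrow(want))          # precision
  expect_equal(merged$populations.got, merged$populations.want)
  # order invariance of the partition
  sp1 <- sharing_partition(calls)
  sp2 <- sharing_partition(calls[sample.int(nrow(calls)), ])
  expect_equal(sp1, sp2)
})

test_that("no fuzzed variant position inside a terminal unit is ever called", {
  set.seed(123)
  for (i in 1:40) {
    motif <- sample(c("A", "AC", "AAG"), 1)
    units <- switch(motif, A = 9L, AC = 7L, AAG = 5L)
    loc <- make_locus(motif, units)
    m <- nchar(motif)
    term <- c((loc$start + 1):(loc$start + m), (loc$end - m + 1):loc$end)
    pos <- sample(term, 1)
    ref <- substr(paste0("GCGTC", loc$seq, "CGTGC"), pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    expect_equal(nrow(call_interruptions(variant(pos, ref, alt), loc, cfgp)), 0)
  }
})

test_that("call summaries reconcile loci with mechanism-by-fate counts", {
  pv <- gen_population_vcf(rng_seed = 23)
  loci <- scan_microsatellites(pv$sequences, cfgp)
  calls <- call_interruptions(pv$variants,
                              dplyr::filter(loci, status == "perfect"), cfgp)
  s <- summarise_calls(calls)
  expect_true(all(s$total_loci <= s$snp_death + s$snp_degeneration +
                    s$indel_death + s$indel_degeneration))
  # death and degeneration partition the calls
  expect_true(all(calls$fate %in% c("death", "degeneration")))
})

test_that("exonic annotation classifies frameshift, nonsense and noncoding", {
  genome <- c(chr1 = paste0("GCGTC", strrep("A", 9), "CGTGC"))
  loc <- make_locus("A", 9)
  exons <- tibble::tibble(seqnames = "chr1", start = 0L, end = 19L,
                          gene = "G1")
  # CDS covering the locus, frame such that positions 7-9 form a codon:
  # CDS starts at 0-based 5 (the first A), phase 1 -> codons at 7-9, ...
  cds <- tibble::tibble(seqnames = "chr1", start = 5L, end = 17L,
                        strand = "+", phase = 1L)
  snp <- variant(8, "A", "T")     # codon AAA -> ATA? positions 7,8,9 = AAA
  calls <- call_interruptions(snp, loc, cfgp)
  ann <- annotate_exonic(calls, exons, cds, genome)
  expect_true(ann$exonic)
  expect_equal(ann$gene, "G1")
  expect_equal(ann$effect, "nonsynonymous")
  # A -> T at the first base of codon AAA gives TAA: nonsense
  snp2 <- variant(7, "A", "T")
  ann2 <- annotate_exonic(call_interruptions(snp2, loc, cfgp), exons, cds,
                          genome)
  expect_equal(ann2$effect, "nonsense")
  # 1 bp indel in CDS: frameshift
  loc2 <- make_locus("AC", 7)
  genome2 <- c(chr1 = paste0("GCGTC", strrep("AC", 7), "CGTGC"))
  del1 <- tibble::tibble(seqnames = "chr1", pos = 8, ref = "AC", alt = "A",
                         af_AFR = 0.3)
  calls2 <- call_interruptions(del1, loc2, cfgp)
  ann3 <- annotate_exonic(calls2, exons,
                          tibble::tibble(seqnames = "chr1", start = 5L,
                                         end = 19L, strand = "+", phase = 1L),
                          genome2)
  expect_equal(ann3$effect, "frameshift")
  # exon without CDS: noncoding (UTR)
  ann4 <- annotate_exonic(calls, exons, cds = NULL, genome = genome)
  expect_equal(ann4$effect, "noncoding")
  # outside every exon: not exonic
  far_exons <- tibble::tibble(seqnames = "chr1", start = 100L, end = 120L,
                              gene = "G2")
  ann5 <- annotate_exonic(calls, far_exons, cds, genome)
  expect_false(ann5$exonic)
  expect_true(is.na(ann5$effect))
})

test_that("minus-strand codons are translated on the reverse complement", {
  # genome: 5' CAT TAA ... reading - strand of TTA ATG
  genome <- c(chr1 = "GGCATTTTTTTTTGCC")
  loc <- tibble::tibble(locus_id = "L1", seqnames = "chr1", start = 4L,
                        end = 13L, motif = "T", motif_size = 1L,
                        status = "perfect", seq = strrep("T", 9))
  exons <- tibble::tibble(seqnames = "chr1", start = 0L, end = 16L,
                          gene = "G1")
  cds <- tibble::tibble(seqnames = "chr1", start = 2L, end = 14L,
                        strand = "-", phase = 0L)
  # on the minus strand the T-run reads as poly-A; a T->A SNP reads A->T
  v <- tibble::tibble(seqnames = "chr1", pos = 8, ref = "T", alt = "A",
                      af_AFR = 0.3)
  calls <- call_interruptions(v, loc, cfgp)
  ann <- annotate_exonic(calls, exons, cds, genome)
  expect_true(ann$effect %in% c("nonsynonymous", "nonsense", "synonymous"))
})

test_that("disease-locus alleles are reconstructed with conserved frequencies", {
  dl <- tibble::tibble(locus_id = "SCA2", seqnames = "chr1", start = 100L,
                       structure = "(CAG)_6 CAA (CAG)_9")
  ref_seq <- parse_repeat_structure(dl$structure)
  expect_equal(nchar(ref_seq), 48)
  # no variants: single reference allele at frequency 1
  none <- tibble::tibble(seqnames = character(), pos = integer(),
                         ref = character(), alt = character(),
                         af_AFR = numeric())
  tab <- tabulate_disease_loci(none, dl, populations = "AFR")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$frequency, 1)
  expect_true(tab$is_reference)
  # planted interruption-removal: the CAA interruption's last A -> G
  # restores CAG, leaving a perfect (CAG)_16
  pos <- 100 + 21
  expect_equal(substr(ref_seq, 21, 21), "A")
  v <- tibble::tibble(seqnames = "chr1", pos = pos, ref = "A", alt = "G",
                      af_AFR = 0.3)
  tab2 <- tabulate_disease_loci(v, dl, populations = "AFR")
  expect_equal(sum(tab2$frequency), 1)
  alt_row <- tab2[!tab2$is_reference, ]
  expect_equal(alt_row$structure, "(CAG)_16")
  expect_equal(alt_row$frequency, 0.3)
  # variant outside the annotated structure is flagged and excluded
  v_out <- tibble::tibble(seqnames = "chr1", pos = 500, ref = "A", alt = "G",
                          af_AFR = 0.3)
  tab3 <- tabulate_disease_loci(v_out, dl, populations = "AFR")
  expect_equal(nrow(tab3), 1)
})

test_that("repeat-structure strings round-trip through parse and compress", {
  cases <- c("(CAG)_6 CAA (CAG)_9", "(A)_3 T (A)_4", "(GT)_10")
  for (st in cases) {
    seq <- parse_repeat_structure(st)
    motif <- imsat:::structure_primary_motif(st)
    expect_equal(parse_repeat_structure(compress_to_structure(seq, motif)),
                 seq)
  }
})
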