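#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end synthetic run: the detection
#' preset, allele-frequency cutoff, population labels, cohort sizes,
#' bootstrap and KS iteration counts and the master seed. The resolved
#' configuration travels with the result so a run is reproducible from its
#' manifest.
#'
#' @param rng_seed Master integer seed; stage seeds are derived from it.
#' @param preset Detection preset for interruption calling.
#' @param af_min Allele-frequency cutoff for calls.
#' @param populations Population labels.
#' @param n_expected,n_decoy_af,n_decoy_terminal,n_decoy_wholemotif Variant
#'   counts for the synthetic population VCF.
#' @param n_ortholog Ortholog pairs per cohort.
#' @param ortholog_r,ortholog_k,ortholog_g Slippage rate, interruption
#'   fold-reduction and generations of the ortholog simulation.
#' @param bootstrap_B Bootstrap resamples for mutability intervals.
#' @param ks_iterations Iterations of the bootstrap KS test.
#' @return A list of class `ims_config`.
#' @export
pipeline_config <- function(rng_seed = 1, preset = "population",
                            af_min = 0.05,
                            populations = c("AFR", "EUR", "ASN", "AMR"),
                            n_expected = 24, n_decoy_af = 8,
                            n_decoy_terminal = 8, n_decoy_wholemotif = 8,
                            n_ortholog = 2000, ortholog_r = 0.01,
                            ortholog_k = 4, ortholog_g = 20,
                            bootstrap_B = 500, ks_iterations = 2000) {
  structure(as.list(environment()), class = "ims_config")
}

#' Run the full synthetic analysis pipeline
#'
#' Chains every stage at desk scale on generated data: synthetic genome and
#' population variants -> locus scan -> interruption calls -> sharing
#' partition and per-population summary -> per-locus F_ST -> heterozygosity
#' distributions with a bootstrap KS comparison -> best-LD partner for the
#' planted indel panel -> ortholog cohorts with mutability estimates ->
#' reporter-assay polymerase error summary. Returns all stage outputs plus
#' a manifest of record counts; each stage function can equally be run by
#' hand on intermediates.
#'
#' @param config An `ims_config` from [pipeline_config()].
#' @return A list of class `ims_pipeline` with elements `loci`, `calls`,
#'   `sharing`, `call_summary`, `fst`, `het`, `ks`, `ld`, `mutability`,
#'   `pol`, `truth`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "ims_config"))
  seed <- config$rng_seed
  cfg <- threshold_config(config$preset)

  synth <- gen_population_vcf(
    n_expected = config$n_expected, n_decoy_af = config$n_decoy_af,
    n_decoy_terminal = config$n_decoy_terminal,
    n_decoy_wholemotif = config$n_decoy_wholemotif,
    populations = config$populations, rng_seed = seed)

  loci <- scan_microsatellites(synth$sequences, cfg)
  perfect <- loci %>% filter(.data$status == "perfect")
  calls <- call_interruptions(synth$variants, perfect, cfg,
                              af_min = config$af_min,
                              populations = config$populations)
  sharing <- sharing_partition(calls)
  call_summary <- summarise_calls(calls)

  ## F_ST over interruptions present in all populations
  af_cols <- paste0("af_", config$populations)
  common_keys <- calls %>%
    distinct(.data$locus_id, .data$pos, .data$ref, .data$alt,
             .data$population) %>%
    count(.data$locus_id, .data$pos, .data$ref, .data$alt) %>%
    filter(.data$n == length(config$populations))
  fst_tbl <- synth$variants %>%
    dplyr::semi_join(common_keys, by = c("pos", "ref", "alt")) %>%
    fst_by_locus(af_cols = af_cols)

  ## heterozygosity of called interruption alleles, first two populations
  het_samples <- purrr::map(config$populations, function(p) {
    heterozygosity(calls$af[calls$population == p])
  })
  names(het_samples) <- config$populations
  nonempty <- which(lengths(het_samples) > 0)
  ks <- if (length(nonempty) >= 2) {
    ks_boot(het_samples[[nonempty[1]]], het_samples[[nonempty[2]]],
            iterations = config$ks_iterations, rng_seed = seed + 3L)
  } else NULL
  het <- het_distribution(unlist(het_samples))

  ld <- max_ld_partner(synth$ld$indel_hap, synth$ld$indel_pos,
                       synth$ld$snp_haps, synth$ld$snp_pos)

  pairs <- gen_ortholog_pairs(config$n_ortholog, r = config$ortholog_r,
                              k = config$ortholog_k, g = config$ortholog_g,
                              rng_seed = seed + 4L)
  filt <- filter_orthologs(pairs)
  mut <- filt$kept %>%
    group_by(.data$cohort) %>%
    group_modify(function(d, key) {
      ci <- bootstrap_ci(d, B = config$bootstrap_B, rng_seed = seed + 5L)
      tibble(mu = mutability(d), ci_low = ci[["ci_low"]],
             ci_high = ci[["ci_high"]], n_loci = nrow(d))
    }) %>% ungroup()

  tpl <- make_reporter_template("[GT]_10", "GT", "GT10")
  spec_pol <- c("unit-deletion" = 0.5, "interruption-substitution" = 0.3,
                "interruption-deletion" = 0.145,
                "interruption-insertion" = 0.055)
  mc <- gen_mutant_collection(tpl, spec_pol, n_mutants = 200,
                              rng_seed = seed + 6L)
  cls <- classify_mutants(mc$records, tpl)
  mf <- mutant_frequency(mc$counts$fudr_cm, mc$counts$cm)
  pol <- pol_error_summary(mf[1], mf[2], mf[3], cls$events,
                           n_records = nrow(mc$records))

  structure(list(
    loci = loci, calls = calls, sharing = sharing,
    call_summary = call_summary, fst = fst_tbl, het = het, ks = ks, ld = ld,
    mutability = mut, pol = pol,
    truth = list(variants = synth$truth, loci = synth$loci_truth,
                 mutants = mc$truth, ld_best = synth$ld$best_snp),
    manifest = list(config = unclass(config),
                    n_loci = nrow(loci), n_perfect = nrow(perfect),
                    n_calls = nrow(calls),
                    n_pairs_kept = nrow(filt$kept),
                    rejections = filt$rejection_log,
                    pol_quarantined = nrow(cls$quarantine))
  ), class = "ims_pipeline")
}

#' @export
print.ims_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("<ims_pipeline> synthetic end-to-end run\n")
  cat(sprintf("  loci: %d (%d perfect)  calls: %d  kept ortholog pairs: %d\n",
              m$n_loci, m$n_perfect, m$n_calls, m$n_pairs_kept))
  cat(sprintf("  mean F_ST: %.4f   KS D: %s\n",
              mean(x$fst$fst, na.rm = TRUE),
              if (is.null(x$ks)) "NA" else sprintf("%.3f", x$ks$statistic)))
  invisible(x)
}
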