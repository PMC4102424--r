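test_that("mutant frequency is a guarded ratio", {
  expect_equal(mutant_frequency(0, 10000), 0)
  expect_equal(mutant_frequency(25, 50000), 5e-4)
  expect_equal(mutant_frequency(50000, 50000), 1)
  expect_error(mutant_frequency(5, 0), "positive")
  expect_error(mutant_frequency(-1, 10), "\\[0, cm\\]")
  expect_error(mutant_frequency(11, 10), "\\[0, cm\\]")
})

test_that("Pol EF subtracts backgrounds and floors at zero with a warning", {
  expect_equal(pol_ef(5e-4, 1e-4, 1e-4), 3e-4)
  expect_equal(pol_ef(1e-4, 1e-4, 0), 0)
  expect_warning(ef <- pol_ef(1e-5, 2e-5, 0), "floored")
  expect_equal(ef, 0)
})

test_that("unit-based indels and interruptions are classified per definition", {
  tpl <- make_reporter_template("[GT]_10", "GT", "GT10")
  # [GT]_10 -> [GT]_9: unit-based deletion, frameshift, detectable
  mut <- paste0(substr(tpl$seq, 1, tpl$ms_end - 2),
                substr(tpl$seq, tpl$ms_end + 1, nchar(tpl$seq)))
  ev <- classify_events(mut, tpl)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$class, "unit-based-indel")
  expect_equal(ev$net, -2L)
  expect_true(ev$detectable)
  # [GT]_10 -> [GT]_5 T [GT]_5 style: mid-run insertion is an interruption
  mid <- tpl$ms_start + 10
  mut2 <- paste0(substr(tpl$seq, 1, mid), "T",
                 substr(tpl$seq, mid + 1, nchar(tpl$seq)))
  ev2 <- classify_events(mut2, tpl)
  expect_equal(ev2$class, "interruption-insertion")
  expect_true(ev2$detectable)  # net 1: frameshift
})

test_that("removing the interrupting base of an iMS template is recognized", {
  tpl <- make_reporter_template("[A]_3 T [A]_4", "A", "A3TA4")
  ms <- substr(tpl$seq, tpl$ms_start + 1, tpl$ms_end)
  expect_equal(ms, "AAATAAAA")
  mut <- sub("AAATAAAA", "AAAAAAA", tpl$seq, fixed = TRUE)
  ev <- classify_events(mut, tpl)
  expect_equal(ev$class, "interruption-deletion")
  expect_true(ev$removes_interruption)
  # the unit-based slippage within a residual tract is not a removal
  mut2 <- sub("AAATAAAA", "AAATAAA", tpl$seq, fixed = TRUE)
  ev2 <- classify_events(mut2, tpl)
  expect_equal(ev2$class, "unit-based-indel")
  expect_false(ev2$removes_interruption)
})

test_that("substitutions in the repeat are detectable only via stop codons", {
  tpl <- make_reporter_template("[A]_8", "A", "A8")
  # the poly-A lands in frame so that an A->T can create TAA
  ms_lo <- tpl$ms_start + 1
  hits <- 0
  for (off in 0:7) {
    pos <- ms_lo + off
    mut <- tpl$seq
    substr(mut, pos, pos) <- "T"
    ev <- classify_events(mut, tpl)
    expect_equal(ev$class, "interruption-substitution")
    k <- (pos - 1) %/% 3
    codon_alt <- substr(mut, 3 * k + 1, 3 * k + 3)
    if (codon_alt %in% c("TAA", "TAG", "TGA")) {
      expect_true(ev$detectable)
      hits <- hits + 1
    } else {
      expect_false(ev$detectable)
    }
  }
  expect_gt(hits, 0)   # at least one placement creates a stop
})

test_that("event lists round-trip onto the template and are order-invariant", {
  tpl <- make_reporter_template("[TC]_11", "TC", "TC11")
  sp <- c("unit-deletion" = 0.3, "interruption-substitution" = 0.4,
          "interruption-deletion" = 0.2, "interruption-insertion" = 0.1)
  mc <- gen_mutant_collection(tpl, sp, 60, rng_seed = 4)
  cl <- classify_mutants(mc$records, tpl)
  expect_equal(nrow(cl$quarantine), 0)
  for (rid in unique(cl$events$record_id)) {
    ev <- cl$events[cl$events$record_id == rid, ]
    mut <- mc$records$mutant_seq[mc$records$record_id == rid]
    expect_equal(apply_events(tpl$seq, ev), mut)
  }
  # classification of a record does not depend on the order records are seen
  cl2 <- classify_mutants(mc$records[rev(seq_len(nrow(mc$records))), ], tpl)
  ev_a <- dplyr::arrange(cl$events, record_id, pos)
  ev_b <- dplyr::arrange(cl2$events, record_id, pos)
  expect_equal(as.data.frame(ev_a), as.data.frame(ev_b))
})

test_that("tandem events group together, nontandem events stay apart", {
  tpl <- make_reporter_template("[GT]_10", "GT", "GT10")
  # two adjacent substitutions (tandem) and one distant substitution
  mut <- tpl$seq
  p1 <- tpl$ms_start + 5
  substr(mut, p1, p1) <- "A"
  substr(mut, p1 + 1, p1 + 1) <- "A"
  p2 <- tpl$ms_start + 15
  alt2 <- setdiff(c("A", "C", "G", "T"), substr(tpl$seq, p2, p2))[1]
  substr(mut, p2, p2) <- alt2
  ev <- classify_events(mut, tpl)
  expect_equal(nrow(ev), 3)
  expect_equal(length(unique(ev$tandem_group)), 2)
})

test_that("the multiple-nontandem correction has its stated limiting behavior", {
  ev_single <- tibble::tibble(record_id = paste0("r", 1:10),
                              detectable = TRUE, tandem_group = 1L)
  expect_equal(correct_multiple_events(2e-4, ev_single), 2e-4)
  # 10 records, 15 detectable nontandem groups -> factor 1.5
  ev_multi <- dplyr::bind_rows(
    ev_single,
    tibble::tibble(record_id = paste0("r", 1:5), detectable = TRUE,
                   tandem_group = 2L))
  expect_equal(correct_multiple_events(2e-4, ev_multi), 3e-4)
  # a tandem pair counts once
  ev_tandem <- tibble::tibble(record_id = c("r1", "r1"), detectable = TRUE,
                              tandem_group = c(1L, 1L))
  expect_equal(correct_multiple_events(2e-4, ev_tandem, n_records = 1), 2e-4)
  expect_error(correct_multiple_events(1e-4, ev_single, n_records = 0),
               "no records")
})

test_that("class-specific EFs follow the printed-proportion arithmetic", {
  ev <- tibble::tibble(
    record_id = paste0("r", 1:74), detectable = TRUE, tandem_group = 1L,
    class = c(rep("interruption-deletion", 2), rep("unit-based-indel", 72)),
    removes_interruption = c(TRUE, TRUE, rep(FALSE, 72)))
  # 2 of 74 events at Pol EF_est 3.4e-4: 9.19e-6
  expect_equal(event_class_ef(ev, 3.4e-4, "interruption-removal"),
               2 / 74 * 3.4e-4)
  expect_equal(round(event_class_ef(ev, 3.4e-4, "interruption-removal"), 7),
               9.2e-6, tolerance = 0.01)
  # all events in one class: EF_class equals the corrected EF
  ev_one <- dplyr::mutate(ev, class = "unit-based-indel")
  expect_equal(event_class_ef(ev_one, 3.4e-4, "unit-based-indel"), 3.4e-4)
  expect_error(event_class_ef(ev[0, ], 1e-4, "unit-based-indel"),
               "no detectable")
})

test_that("exhaustive per-class EFs sum to the corrected Pol EF", {
  tpl <- make_reporter_template("[GT]_10", "GT", "GT10")
  sp <- c("unit-deletion" = 0.5, "interruption-substitution" = 0.25,
          "interruption-deletion" = 0.15, "interruption-insertion" = 0.1)
  mc <- gen_mutant_collection(tpl, sp, 80, mf_triple = c(5e-4, 1e-4, 1e-4),
                              rng_seed = 6)
  cl <- classify_mutants(mc$records, tpl)
  mf <- mutant_frequency(mc$counts$fudr_cm, mc$counts$cm)
  ps <- pol_error_summary(mf[1], mf[2], mf[3], cl$events,
                          n_records = nrow(mc$records))
  expect_equal(ps$pol_ef, 3e-4)
  expect_equal(sum(ps$class_ef$ef), ps$pol_ef_est)
  expect_true(all(ps$class_ef$ef >= 0 & ps$class_ef$ef <= ps$pol_ef_est))
  g <- glance(ps)
  expect_equal(g$pol_ef, 3e-4)
  expect_equal(nrow(tidy(ps)), 5)
})

test_that("spectrum proportions and multi-interruption fraction are exact", {
  tpl <- make_reporter_template("[GT]_10", "GT", "GT10")
  sp <- c("interruption-substitution" = 0.6, "interruption-deletion" = 0.29,
          "interruption-insertion" = 0.11)
  mc <- gen_mutant_collection(tpl, sp, 100, rng_seed = 9)
  cl <- classify_mutants(mc$records, tpl)
  rep <- spectrum_report(cl$events)
  props <- setNames(rep$proportions$prop, rep$proportions$mechanism)
  expect_equal(unname(props["substitution"]), 0.6)
  expect_equal(unname(props["deletion"]), 0.29)
  expect_equal(unname(props["insertion"]), 0.11)
  expect_equal(rep$multi_interruption_fraction, 0)  # one event per product
  # single record: degenerate proportions, no NaN
  one <- cl$events[cl$events$record_id == cl$events$record_id[1], ]
  rep1 <- spectrum_report(one)
  expect_equal(sum(rep1$proportions$prop), 1)
  expect_false(any(is.nan(rep1$proportions$prop)))
  # empty class reported as zero
  expect_true(all(rep$proportions$n >= 0))
})
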