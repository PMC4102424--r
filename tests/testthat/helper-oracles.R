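# Brute-force oracles and fixture generators, written independently of the
# package's scanning code paths (character-vector loops and substring
# checks only).

# every maximal perfect tandem run, found by testing each start position
# and motif size directly. A candidate at start i is the left-aligned
# representative of its periodic region: it is reported only when the base
# before i does not continue the period (region-maximality), and its unit
# count is the greedy complete-unit count to the right.
oracle_seeds <- function(seq, cfg) {
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  cand <- list()
  for (m in 1:4) {
    thr <- cfg$min_units[m]
    i <- 1
    while (i + m * thr - 1 <= n) {
      motif <- substr(seq, i, i + m - 1)
      if (grepl("N", motif, fixed = TRUE) || !is_primitive_motif(motif)) {
        i <- i + 1
        next
      }
      region_left_max <- i == 1 || ch[i - 1] == "N" ||
        ch[i - 1] != ch[i - 1 + m]
      if (!region_left_max) {
        i <- i + 1
        next
      }
      k <- 1
      while (i + (k + 1) * m - 1 <= n &&
             substr(seq, i + k * m, i + (k + 1) * m - 1) == motif)
        k <- k + 1
      if (k >= thr) {
        cand[[length(cand) + 1]] <- data.frame(
          start = i - 1, end = i - 1 + k * m, motif = motif,
          motif_size = m, units = k, stringsAsFactors = FALSE)
      }
      i <- i + 1
    }
  }
  if (length(cand) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          motif = character(), motif_size = integer(),
                          units = integer()))
  }
  d <- do.call(rbind, cand)
  d <- d[order(d$start, d$motif_size), , drop = FALSE]
  rownames(d) <- NULL
  tibble::as_tibble(lapply(d, function(col)
    if (is.numeric(col)) as.integer(col) else col))
}

# textual-definition extension, replayed with character vectors and
# explicit unit-by-unit while loops
oracle_extend <- function(seq, focal, cfg) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  m <- nchar(focal$motif)
  rots <- unique(vapply(seq_len(m), function(i)
    paste(ch0 <- strsplit(paste0(focal$motif, focal$motif), "")[[1]][i:(i + m - 1)],
          collapse = ""), character(1)))
  blk <- function(a) if (a < 1 || a + m - 1 > n) "" else
    paste(ch[a:(a + m - 1)], collapse = "")
  s0 <- focal$start; e0 <- focal$end
  ints <- list()
  repeat {
    moved <- FALSE
    for (g in 0:m) {
      ce <- s0 - g
      first <- blk(ce - m + 1)
      if (!(first %in% rots)) next
      if (g > 0 && any(ch[(ce + 1):s0] == "N")) next
      u <- 0
      a <- ce - m + 1
      while (a >= 1 && blk(a) == first) { u <- u + 1; a <- a - m }
      if (u >= 2) {
        if (g > 0) ints[[length(ints) + 1]] <- c(ce, s0)
        s0 <- ce - u * m
        moved <- TRUE
        break
      }
    }
    if (!moved) break
  }
  repeat {
    moved <- FALSE
    for (g in 0:m) {
      cs <- e0 + g
      first <- blk(cs + 1)
      if (!(first %in% rots)) next
      if (g > 0 && any(ch[(e0 + 1):cs] == "N")) next
      u <- 0
      a <- cs + 1
      while (a + m - 1 <= n && blk(a) == first) { u <- u + 1; a <- a + m }
      if (u >= 2) {
        if (g > 0) ints[[length(ints) + 1]] <- c(e0, cs)
        e0 <- cs + u * m
        moved <- TRUE
        break
      }
    }
    if (!moved) break
  }
  ilen <- if (length(ints)) sum(vapply(ints, function(x) x[2] - x[1],
                                       numeric(1))) else 0
  offs <- if (length(ints))
    sort(vapply(ints, function(x) x[1], numeric(1)) - s0) else numeric(0)
  list(start = s0, end = e0,
       n_interruptions = length(ints),
       interruption_offsets = offs,
       repeat_number = (e0 - s0 - ilen) / m)
}

# repeat-enriched random sequence: random background with planted tandem
# runs of random motifs/lengths (some below threshold)
random_repeaty_seq <- function(len = 300, seed = 1) {
  set.seed(seed)
  out <- character(0)
  total <- 0
  while (total < len) {
    if (runif(1) < 0.45) {
      m <- sample(1:4, 1)
      motif <- paste(sample(c("A", "C", "G", "T"), m, replace = TRUE),
                     collapse = "")
      units <- sample(2:12, 1)
      run <- strrep(motif, units)
      out <- c(out, run)
      total <- total + nchar(run)
    } else {
      k <- sample(3:12, 1)
      fl <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                  collapse = "")
      out <- c(out, fl)
      total <- total + k
    }
  }
  substr(paste(out, collapse = ""), 1, len)
}

# compare seed tables ignoring row order
expect_same_seeds <- function(found, oracle) {
  f <- found[order(found$start, found$motif_size), ]
  o <- oracle[order(oracle$start, oracle$motif_size), ]
  expect_equal(as.data.frame(f), as.data.frame(o), ignore_attr = TRUE)
}
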