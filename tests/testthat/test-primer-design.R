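# Independent copy of the published minimum-product lookup used as oracle.
schedule_oracle <- function(s) {
  if (s <= 9) 70 else if (s <= 11) 80 else if (s <= 14) 90 else
    if (s <= 17) 100 else if (s <= 22) 110 else if (s <= 26) 120 else
    if (s <= 29) 130 else 150
}

test_that("the product-size schedule matches the published table exactly", {
  for (s in 8:36) {
    got <- product_size_schedule(s)
    expect_equal(got$minimum, schedule_oracle(s), info = s)
    expect_equal(got$optimum, 10 * s, info = s)
    expect_equal(got$maximum, 10 * s + 10, info = s)
    expect_false(got$extrapolated)
    expect_lt(got$minimum, got$maximum)
  }
  # monotone minimum and optimum over the table range
  mins <- vapply(8:36, function(s) product_size_schedule(s)$minimum,
                 numeric(1))
  expect_true(all(diff(mins) >= 0))
  expect_error(product_size_schedule(7), "< 8 bp")
  big <- product_size_schedule(41)
  expect_true(big$extrapolated)
  expect_equal(big$minimum, 160)
})

test_that("melting temperature matches a hand-summed nearest-neighbor oracle", {
  # independent summation with the Breslauer tables written out here
  dh <- c(AA = 9.1, AT = 8.6, TA = 6.0, CA = 5.8, GT = 6.5, CT = 7.8,
          GA = 5.6, CG = 11.9, GC = 11.1, GG = 11.0)
  ds <- c(AA = 24.0, AT = 23.9, TA = 16.9, CA = 12.9, GT = 17.3, CT = 20.8,
          GA = 13.5, CG = 27.8, GC = 26.7, GG = 26.6)
  look <- function(tab, k) {
    if (k %in% names(tab)) tab[[k]]
    else tab[[chartr("ACGT", "TGCA", paste0(substr(k, 2, 2),
                                            substr(k, 1, 1)))]]
  }
  tm_oracle <- function(seq) {
    ks <- substring(seq, 1:(nchar(seq) - 1), 2:nchar(seq))
    H <- sum(vapply(ks, look, numeric(1), tab = as.list(dh))) * 1000
    S <- sum(vapply(ks, look, numeric(1), tab = as.list(ds))) + 10.8
    H / (S - 1.987 * log(50e-9 / 4)) - 273.15 + 16.6 * log10(0.05)
  }
  p20 <- "AGCTTGCCATTGACGGTCAA"
  expect_equal(melting_temperature(p20), tm_oracle(p20), tolerance = 1e-6)
  set.seed(60)
  for (i in 1:5) {
    p <- rand_dna(26)
    expect_equal(melting_temperature(p), tm_oracle(p), tolerance = 1e-6)
  }
})

test_that("Tm is duplex-symmetric and increases when A:T becomes G:C", {
  set.seed(61)
  for (i in 1:5) {
    p <- rand_dna(sample(20:30, 1))
    expect_equal(melting_temperature(p), melting_temperature(rc(p)),
                 tolerance = 1e-9)
  }
  p <- "AGCTTGCCATTGACGGTCAAGGCTAA"
  stopifnot(substr(p, 10, 10) == "T")
  q <- p; substr(q, 10, 10) <- "G"
  expect_gt(melting_temperature(q), melting_temperature(p))
  expect_error(melting_temperature("ACGTNACGTTACGT"), "non-ACGT")
  expect_error(melting_temperature("ACGTA"), ">= 10 bp")
})

# Exhaustive enumeration oracle for primer design on a small region: every
# window pair is scored with the same published constraints but independent
# looping logic.
design_oracle <- function(consensus, iv, indel_size) {
  sch <- product_size_schedule(indel_size)
  n <- nchar(consensus)
  wins <- function(lo, hi, side) {
    out <- list()
    for (L in 22:32) for (s in lo:(hi - L)) {
      if (s < lo || s + L > hi) next
      w <- substr(consensus, s + 1, s + L)
      if (grepl("N", w)) next
      p <- if (side == "left") w else rc(w)
      gc <- 100 * nchar(gsub("[^GC]", "", w)) / L
      if (gc < 35 || gc > 60) next
      tm <- melting_temperature(p)
      if (tm < 67 || tm > 69) next
      if (grepl(rc(substr(p, L - 4, L)), p, fixed = TRUE)) next
      out[[length(out) + 1]] <- data.frame(start = s, end = s + L, len = L,
                                           gc = gc, tm = tm, seq = p)
    }
    if (!length(out)) NULL else do.call(rbind, out)
  }
  fw <- wins(max(0, iv[1] - 400), iv[1], "left")
  rv <- wins(iv[2], min(n, iv[2] + 400), "right")
  if (is.null(fw) || is.null(rv)) return(NULL)
  best <- NULL
  for (i in seq_len(nrow(fw))) for (j in seq_len(nrow(rv))) {
    prod <- rv$end[j] - fw$start[i]
    if (prod < sch$minimum || prod > sch$maximum) next
    if (abs(fw$tm[i] - rv$tm[j]) > 2) next
    if (grepl(rc(substr(fw$seq[i], fw$len[i] - 4, fw$len[i])), rv$seq[j],
              fixed = TRUE)) next
    if (grepl(rc(substr(rv$seq[j], rv$len[j] - 4, rv$len[j])), fw$seq[i],
              fixed = TRUE)) next
    pen <- abs(fw$len[i] - 26) + abs(rv$len[j] - 26) +
      0.5 * (abs(fw$gc[i] - 50) + abs(rv$gc[j] - 50)) +
      3 * (abs(fw$tm[i] - 68) + abs(rv$tm[j] - 68)) +
      0.1 * abs(prod - sch$optimum)
    if (is.null(best) || pen < best$penalty)
      best <- list(forward = fw$seq[i], reverse = rv$seq[j], penalty = pen)
  }
  best
}

test_that("primer design agrees with the exhaustive enumeration oracle", {
  set.seed(62)
  tried <- 0
  for (rep in 1:8) {
    cons <- rand_dna(420)
    iv <- c(200, 212)
    reg <- list(consensus = cons, indel_interval = iv, ambiguity_count = 0,
                rejected = FALSE)
    got <- design_primer_pair(reg, 12)
    want <- design_oracle(cons, iv, 12)
    if (is.null(want)) {
      expect_null(got)
    } else {
      tried <- tried + 1
      expect_equal(got$penalty, want$penalty, tolerance = 1e-9)
      expect_identical(got$forward_seq, want$forward)
      expect_identical(got$reverse_seq, want$reverse)
    }
  }
  expect_gte(tried, 3)  # the oracle found designable regions to compare
})

test_that("regions too short for the product window yield no pair", {
  set.seed(63)
  reg <- list(consensus = rand_dna(60), indel_interval = c(20, 30),
              ambiguity_count = 0, rejected = FALSE)
  expect_null(design_primer_pair(reg, 10))
})

test_that("every designed pair honours the full constraint envelope", {
  set.seed(64)
  n_ok <- 0
  for (rep in 1:40) {
    size <- sample(8:36, 1)
    cons <- rand_dna(800)
    iv <- c(390, 390 + size)
    reg <- list(consensus = cons, indel_interval = iv, ambiguity_count = 0,
                rejected = FALSE)
    pair <- design_primer_pair(reg, size)
    if (is.null(pair)) next
    n_ok <- n_ok + 1
    sch <- product_size_schedule(size)
    for (p in c(pair$forward_seq, pair$reverse_seq)) {
      expect_true(nchar(p) >= 22 && nchar(p) <= 32)
      gc <- 100 * nchar(gsub("[^GC]", "", p)) / nchar(p)
      expect_true(gc >= 35 && gc <= 60)
      tm <- melting_temperature(p)
      expect_true(tm >= 67 && tm <= 69)
    }
    expect_lte(abs(pair$tm_forward - pair$tm_reverse), 2)
    expect_gte(pair$product_size_long, sch$minimum)
    expect_lte(pair$product_size_long, sch$maximum)
    expect_equal(pair$product_size_long - pair$product_size_short, size)
    # the product spans the entire indel interval
    expect_lte(pair$forward_interval[2], iv[1])
    expect_gte(pair$reverse_interval[1], iv[2])
  }
  expect_gte(n_ok, 25)
})

test_that("marker names encode chromosome and truncated Mbp position", {
  expect_identical(name_marker(7, 2648500), "NDSU_IND_07_02.6485")
  expect_identical(name_marker(10, 42135500), "NDSU_IND_10_42.1355")
  expect_identical(name_marker(5, 1), "NDSU_IND_05_00.0000")
  # truncation, never rounding
  expect_identical(name_marker(7, 2648599), "NDSU_IND_07_02.6485")
  expect_identical(name_marker(1, 99999), "NDSU_IND_01_00.0999")
  expect_identical(name_marker("scaff_12", 120000), "NDSU_IND_scaff_12_00.1200")
})
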