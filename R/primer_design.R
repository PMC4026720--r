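# Breslauer nearest-neighbor tables (dH kcal/mol, dS cal/mol/K), extended to
# all 16 dinucleotides by duplex symmetry. These are the legacy-primer3-era
# values used by batch primer design tools of the period.
NN_DH <- c(AA = 9.1, AT = 8.6, TA = 6.0, CA = 5.8, GT = 6.5, CT = 7.8,
           GA = 5.6, CG = 11.9, GC = 11.1, GG = 11.0,
           TT = 9.1, TG = 5.8, AC = 6.5, AG = 7.8, TC = 5.6, CC = 11.0)
NN_DS <- c(AA = 24.0, AT = 23.9, TA = 16.9, CA = 12.9, GT = 17.3, CT = 20.8,
           GA = 13.5, CG = 27.8, GC = 26.7, GG = 26.6,
           TT = 24.0, TG = 12.9, AC = 17.3, AG = 20.8, TC = 13.5, CC = 26.6)

#' Nearest-neighbor melting temperature of a primer
#'
#' Breslauer-table thermodynamic Tm with the classic salt and concentration
#' correction: `Tm = dH / (dS + R ln(C/4)) - 273.15 + 16.6 log10([Na+])`,
#' initiation entropy -10.8 cal/mol/K, annealing oligo concentration 50 nM
#' and 50 mM monovalent salt by default. By duplex symmetry
#' `Tm(s) == Tm(revcomp(s))`.
#'
#' @param primer ACGT string (length >= 10, no N).
#' @param dna_nM annealing oligo concentration in nM.
#' @param salt_mM monovalent cation concentration in mM.
#' @return melting temperature in degrees Celsius.
#' @export
melting_temperature <- function(primer, dna_nM = 50, salt_mM = 50) {
  n <- nchar(primer)
  if (n < 10) stopf("primer must be >= 10 bp")
  if (grepl("[^ACGT]", primer)) stopf("primer contains non-ACGT characters")
  stacks <- substring(primer, 1:(n - 1L), 2:n)
  H <- sum(NN_DH[stacks]) * 1000          # cal/mol
  S <- sum(NN_DS[stacks]) + 10.8          # cal/mol/K, incl. initiation
  H / (S - 1.987 * log(dna_nM * 1e-9 / 4)) - 273.15 + 16.6 * log10(salt_mM / 1000)
}

#' Product-size schedule for a given InDel size
#'
#' The admissible PCR product window that keeps both alleles resolvable on a
#' 3% agarose gel: the minimum comes from a fixed lookup table
#' (8-9 bp -> 70, 10-11 -> 80, 12-14 -> 90, 15-17 -> 100, 18-22 -> 110,
#' 23-26 -> 120, 27-29 -> 130, 30-36 -> 150), the optimum is ten times the
#' InDel size and the maximum ten times plus 10. Sizes above 36 bp
#' extrapolate the table's coarsening trend
#' (`150 + 10 * ceil((size - 36) / 5)`) and are flagged.
#'
#' @param indel_size InDel size in bp (>= 8).
#' @return list with `minimum`, `optimum`, `maximum`, `extrapolated`.
#' @export
product_size_schedule <- function(indel_size) {
  if (indel_size < 8) stopf("no product-size schedule for InDels < 8 bp")
  minimum <- if (indel_size <= 9) 70L else if (indel_size <= 11) 80L else
    if (indel_size <= 14) 90L else if (indel_size <= 17) 100L else
    if (indel_size <= 22) 110L else if (indel_size <= 26) 120L else
    if (indel_size <= 29) 130L else if (indel_size <= 36) 150L else
    150L + 10L * as.integer(ceiling((indel_size - 36) / 5))
  list(minimum = minimum,
       optimum = 10L * as.integer(indel_size),
       maximum = 10L * as.integer(indel_size) + 10L,
       extrapolated = indel_size > 36)
}

#' Primer constraint envelope
#'
#' The deliberately stringent envelope that removes any need for per-marker
#' PCR optimization: primer length 22/26/32 (min/opt/max), GC 35/50/60%,
#' Tm 67/68/69 degrees C, at most 2 degrees difference between the pair, and
#' no 3' self- or cross-complementary run of 5 or more bases.
#'
#' @param len,gc,tm numeric triplets (min, opt, max).
#' @param max_tm_diff maximum |Tm_f - Tm_r|.
#' @param self_run 3' complementary run length that disqualifies.
#' @param penalty_weights weights for length, GC, Tm and product-size
#'   deviation in the pair penalty.
#' @return constraint list.
#' @export
primer_constraints <- function(len = c(22, 26, 32), gc = c(35, 50, 60),
                               tm = c(67, 68, 69), max_tm_diff = 2,
                               self_run = 5L,
                               penalty_weights = c(len = 1, gc = 0.5,
                                                   tm = 3, product = 0.1)) {
  stopifnot(len[1] <= len[2], len[2] <= len[3],
            gc[1] <= gc[2], gc[2] <= gc[3], tm[1] <= tm[2], tm[2] <= tm[3])
  list(len = len, gc = gc, tm = tm, max_tm_diff = max_tm_diff,
       self_run = as.integer(self_run), penalty_weights = penalty_weights)
}

# TRUE when the 3' end (last `run` bases) of `a` is reverse-complementary to
# any stretch of `b` (set b = a for the self check).
has_3prime_complement_run <- function(a, b, run = 5L) {
  tail3 <- substr(a, nchar(a) - run + 1L, nchar(a))
  grepl(revcomp(tail3), b, fixed = TRUE)
}

# Enumerate constraint-satisfying primer windows over a consensus stretch.
# Returns 0-based half-open window coordinates on the consensus plus the
# primer sequence (reverse-complemented for the right side).
primer_windows <- function(consensus, lo, hi, side, cons_par) {
  n <- nchar(consensus)
  ch <- strsplit(consensus, "")[[1]]
  stacks <- paste0(ch[-n], ch[-1])
  okstack <- !grepl("N", stacks, fixed = TRUE)
  dh <- ifelse(okstack, NN_DH[stacks], 0)
  ds <- ifelse(okstack, NN_DS[stacks], 0)
  cum_dh <- c(0, cumsum(dh)); cum_ds <- c(0, cumsum(ds))
  cum_gc <- c(0L, cumsum(ch %in% c("G", "C")))
  cum_n <- c(0L, cumsum(ch == "N"))
  rows <- list()
  for (L in cons_par$len[1]:cons_par$len[3]) {
    starts <- seq.int(lo, hi - L)          # 0-based starts, window [s, s+L)
    if (length(starts) == 0 || starts[1] > hi - L) next
    s1 <- starts + 1L                      # 1-based
    nN <- cum_n[s1 + L] - cum_n[s1]
    gc <- 100 * (cum_gc[s1 + L] - cum_gc[s1]) / L
    H <- (cum_dh[s1 + L - 1L] - cum_dh[s1]) * 1000
    S <- (cum_ds[s1 + L - 1L] - cum_ds[s1]) + 10.8
    tm <- H / (S - 1.987 * log(50e-9 / 4)) - 273.15 + 16.6 * log10(0.05)
    ok <- nN == 0 & gc >= cons_par$gc[1] & gc <= cons_par$gc[3] &
      tm >= cons_par$tm[1] & tm <= cons_par$tm[3]
    if (!any(ok)) next
    for (i in which(ok)) {
      wseq <- substr(consensus, s1[i], s1[i] + L - 1L)
      pseq <- if (side == "left") wseq else revcomp(wseq)
      if (has_3prime_complement_run(pseq, pseq, cons_par$self_run)) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = starts[i], end = starts[i] + L, len = L,
        gc = gc[i], tm = tm[i], seq = pseq)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Design the best primer pair for a consensus region
#'
#' Scans every window of length 22-32 left of the InDel interval (forward
#' primer) and right of it (reverse primer, reverse-complemented), keeps
#' windows inside the GC and Tm envelope with clean 3' ends, forms pairs
#' whose long-allele product size falls within the [product_size_schedule()]
#' window with |dTm| <= 2, and returns the pair with the smallest penalty
#' (weighted deviation from optimal length 26, GC 50%, Tm 68 and the optimum
#' product size).
#'
#' @param region result of [build_consensus()] (not rejected).
#' @param indel_size InDel size in bp (>= 8).
#' @param constraints see [primer_constraints()].
#' @return a `PrimerPair` list (`forward_seq`, `reverse_seq`,
#'   `forward_interval`, `reverse_interval` on the consensus,
#'   `tm_forward`, `tm_reverse`, `gc_forward`, `gc_reverse`,
#'   `product_size_long`, `product_size_short`, `penalty`, `extrapolated`)
#'   or `NULL` when no window pair satisfies the envelope.
#' @export
design_primer_pair <- function(region, indel_size,
                               constraints = primer_constraints()) {
  if (!identical(region$rejected, FALSE)) stopf("rejected consensus region")
  sched <- product_size_schedule(indel_size)
  cons <- region$consensus
  iv <- region$indel_interval
  n <- nchar(cons)
  if (n < sched$minimum) return(NULL)
  fw <- primer_windows(cons, max(0L, iv[1] - 400L), iv[1], "left", constraints)
  rv <- primer_windows(cons, iv[2], min(n, iv[2] + 400L), "right", constraints)
  if (is.null(fw) || is.null(rv)) return(NULL)
  pairs <- expand.grid(f = seq_len(nrow(fw)), r = seq_len(nrow(rv)))
  prod_long <- rv$end[pairs$r] - fw$start[pairs$f]
  dtm <- abs(fw$tm[pairs$f] - rv$tm[pairs$r])
  keep <- prod_long >= sched$minimum & prod_long <= sched$maximum &
    dtm <= constraints$max_tm_diff
  if (!any(keep)) return(NULL)
  pairs <- pairs[keep, , drop = FALSE]
  prod_long <- prod_long[keep]
  w <- constraints$penalty_weights
  pen <- w[["len"]] * (abs(fw$len[pairs$f] - constraints$len[2]) +
                         abs(rv$len[pairs$r] - constraints$len[2])) +
    w[["gc"]] * (abs(fw$gc[pairs$f] - constraints$gc[2]) +
                   abs(rv$gc[pairs$r] - constraints$gc[2])) +
    w[["tm"]] * (abs(fw$tm[pairs$f] - constraints$tm[2]) +
                   abs(rv$tm[pairs$r] - constraints$tm[2])) +
    w[["product"]] * abs(prod_long - sched$optimum)
  ord <- order(pen, fw$start[pairs$f], rv$end[pairs$r])
  for (i in ord) {
    f <- fw[pairs$f[i], ]; r <- rv[pairs$r[i], ]
    if (has_3prime_complement_run(f$seq, r$seq, constraints$self_run) ||
        has_3prime_complement_run(r$seq, f$seq, constraints$self_run)) next
    return(list(
      forward_seq = f$seq, reverse_seq = r$seq,
      forward_interval = c(f$start, f$end),
      reverse_interval = c(r$start, r$end),
      tm_forward = f$tm, tm_reverse = r$tm,
      gc_forward = f$gc, gc_reverse = r$gc,
      product_size_long = prod_long[i],
      product_size_short = prod_long[i] - as.integer(indel_size),
      penalty = pen[i], extrapolated = sched$extrapolated))
  }
  NULL
}

#' Position-encoded marker name
#'
#' Markers are named `NDSU_IND_NN_XX.XXXX`: `NN` the zero-padded chromosome
#' number and `XX.XXXX` the physical position in Mbp with four decimals,
#' truncated (not rounded), integer part zero-padded to two digits.
#'
#' @param chromosome chromosome number (integer >= 1) or a scaffold id
#'   string, used verbatim.
#' @param position_bp 1-based physical position in bp.
#' @return the marker name.
#' @export
name_marker <- function(chromosome, position_bp) {
  if (position_bp < 1) stopf("position must be >= 1")
  d <- floor(position_bp / 100)            # units of 0.0001 Mbp
  mb <- as.integer(d %/% 10000)
  frac <- as.integer(d %% 10000)
  chrom <- if (is.numeric(chromosome)) sprintf("%02d", as.integer(chromosome))
           else as.character(chromosome)
  sprintf("NDSU_IND_%s_%02d.%04d", chrom, mb, frac)
}
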