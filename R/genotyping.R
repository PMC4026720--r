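#' In-silico PCR: predicted product sizes of a primer pair on a genome
#'
#' Finds every placement where one primer matches the plus strand and the
#' other primer's reverse complement matches downstream within `max_product`
#' bp, in either orientation. Product size is the distance between the
#' outermost primer 5' ends.
#'
#' @param forward,reverse primer sequences (5'->3').
#' @param genome character vector of sequences (multi-chromosome allowed).
#' @param max_product maximum amplicon size considered (default 2000).
#' @param max_mismatches mismatches tolerated per primer site (default 0,
#'   exact matching).
#' @return integer vector of product sizes (empty = null amplification).
#' @export
insilico_pcr <- function(forward, reverse, genome, max_product = 2000L,
                         max_mismatches = 0L) {
  sizes <- integer(0)
  sites <- function(primer, subject) {
    m <- Biostrings::matchPattern(primer, subject,
                                  max.mismatch = max_mismatches)
    data.frame(start = Biostrings::start(m), end = Biostrings::end(m))
  }
  for (chr in seq_along(genome)) {
    subject <- Biostrings::DNAString(genome[[chr]])
    for (or in 1:2) {
      left <- if (or == 1) forward else reverse
      right <- if (or == 1) reverse else forward
      ls <- sites(left, subject)
      rs <- sites(revcomp(right), subject)
      if (!nrow(ls) || !nrow(rs)) next
      for (i in seq_len(nrow(ls))) {
        prod <- rs$end - ls$start[i] + 1L
        ok <- prod >= nchar(left) + nchar(right) & prod <= max_product
        sizes <- c(sizes, prod[ok])
      }
    }
  }
  sort(unique(sizes))
}

# Collapse band sizes into gel size classes: sizes closer than
# `gel_resolution` (single linkage) merge into one class; classes are
# numbered by ascending size.
band_classes <- function(sizes, gel_resolution) {
  uq <- sort(unique(sizes[!is.na(sizes)]))
  if (!length(uq)) return(rep(NA_integer_, length(sizes)))
  cl <- cumsum(c(1L, diff(uq) > gel_resolution))
  cl[match(sizes, uq)]
}

#' Score markers across genotypes by virtual gel electrophoresis
#'
#' Runs in-silico PCR for every marker on every genotype, collapses band
#' sizes within `gel_resolution` bp of each other into one size class, and
#' calls each (marker, genotype) cell by its class. A marker is polymorphic
#' when at least two classes occur among its non-missing calls. Genotypes are
#' treated as inbred (haploid: one band per locus); when several products
#' amplify, the smallest in the plausible window is scored and the cell is
#' flagged.
#'
#' @param markers data.frame with `name`, `forward_seq`, `reverse_seq`.
#' @param genomes named list: genotype -> character vector of sequences.
#' @param gel_resolution bands within this many bp co-migrate (default 8).
#' @param max_product passed to [insilico_pcr()].
#' @return list with `classes` (markers x genotypes integer matrix, NA =
#'   missing), `sizes` (band sizes), `polymorphic` (named logical),
#'   `polymorphism_rate`, `multiband` (cells with >1 product).
#' @export
score_markers <- function(markers, genomes, gel_resolution = 8L,
                          max_product = 2000L) {
  if (length(genomes) < 2) stopf("need >= 2 genotypes to score")
  gn <- names(genomes)
  sizes <- matrix(NA_integer_, nrow(markers), length(genomes),
                  dimnames = list(markers$name, gn))
  multi <- matrix(FALSE, nrow(markers), length(genomes),
                  dimnames = dimnames(sizes))
  for (i in seq_len(nrow(markers))) {
    for (j in seq_along(genomes)) {
      pr <- insilico_pcr(markers$forward_seq[i], markers$reverse_seq[i],
                         genomes[[j]], max_product = max_product)
      if (length(pr)) {
        sizes[i, j] <- pr[1]
        multi[i, j] <- length(pr) > 1
      }
    }
  }
  classes <- t(apply(sizes, 1, band_classes, gel_resolution = gel_resolution))
  dimnames(classes) <- dimnames(sizes)
  scored <- rowSums(!is.na(classes)) > 0
  polym <- apply(classes, 1, function(x) length(unique(x[!is.na(x)])) >= 2)
  rate <- if (any(scored)) sum(polym[scored]) / sum(scored) else NA_real_
  list(classes = classes, sizes = sizes, polymorphic = polym,
       polymorphism_rate = rate, multiband = multi)
}

#' Can a set of markers be multiplexed in one reaction?
#'
#' Compatible when (1) the product-size windows of the markers — the span
#' from short to long allele, padded by the gel resolution — are pairwise
#' disjoint, (2) no primer's 3' end is reverse-complementary over 5+ bases to
#' any primer of another marker, and (3) every primer Tm sits in the global
#' 67-69 window (true by construction for designed markers, still checked).
#'
#' @param markers data.frame with `name`, `forward_seq`, `reverse_seq`,
#'   `product_long`, `product_short`, `tm_f`, `tm_r`.
#' @param gel_resolution padding around product windows (default 8).
#' @param constraints see [primer_constraints()].
#' @return list with `compatible` (logical) and `violations` (data.frame
#'   `marker_a`, `marker_b`, `type`).
#' @export
multiplex_compatible <- function(markers, gel_resolution = 8L,
                                 constraints = primer_constraints()) {
  n <- nrow(markers)
  if (n < 2 || n > 6) stopf("multiplex sets of 2-6 markers are supported")
  viol <- data.frame(marker_a = character(0), marker_b = character(0),
                     type = character(0))
  for (i in seq_len(n)) {
    bad_tm <- c(markers$tm_f[i], markers$tm_r[i]) < constraints$tm[1] |
      c(markers$tm_f[i], markers$tm_r[i]) > constraints$tm[3]
    if (any(bad_tm))
      viol <- rbind(viol, data.frame(marker_a = markers$name[i],
                                     marker_b = markers$name[i],
                                     type = "tm_out_of_window"))
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    lo_i <- markers$product_short[i] - gel_resolution
    hi_i <- markers$product_long[i] + gel_resolution
    lo_j <- markers$product_short[j] - gel_resolution
    hi_j <- markers$product_long[j] + gel_resolution
    if (lo_i <= hi_j && lo_j <= hi_i)
      viol <- rbind(viol, data.frame(marker_a = markers$name[i],
                                     marker_b = markers$name[j],
                                     type = "size_overlap"))
    pi <- c(markers$forward_seq[i], markers$reverse_seq[i])
    pj <- c(markers$forward_seq[j], markers$reverse_seq[j])
    dimer <- any(vapply(pi, function(a) any(vapply(pj, function(b)
      has_3prime_complement_run(a, b, constraints$self_run) ||
        has_3prime_complement_run(b, a, constraints$self_run),
      logical(1))), logical(1)))
    if (dimer)
      viol <- rbind(viol, data.frame(marker_a = markers$name[i],
                                     marker_b = markers$name[j],
                                     type = "cross_dimer"))
  }
  list(compatible = nrow(viol) == 0, violations = viol)
}

#' Shared-allele distance matrix from a genotype call matrix
#'
#' For inbred (haploid-scored) lines the shared-allele distance reduces to
#' the fraction of co-scored markers at which two genotypes carry different
#' size classes.
#'
#' @param classes markers x genotypes integer matrix (NA = missing).
#' @return symmetric distance matrix with zero diagonal, entries in
#'   `[0, 1]`; `NA` (with a warning) for pairs with no co-scored marker.
#' @export
shared_allele_distance <- function(classes) {
  gn <- colnames(classes)
  if (length(gn) < 2) stopf("need >= 2 genotypes")
  n <- length(gn)
  D <- matrix(0, n, n, dimnames = list(gn, gn))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(classes[, i]) & !is.na(classes[, j])
    if (!any(ok)) {
      warning(sprintf("no co-scored markers for %s / %s", gn[i], gn[j]))
      D[i, j] <- D[j, i] <- NA_real_
    } else {
      D[i, j] <- D[j, i] <- mean(classes[ok, i] != classes[ok, j])
    }
  }
  D
}

#' Fst (heterozygosity-based) per locus and overall
#'
#' Treating size classes as alleles, per-locus
#' `Fst = (Ht - mean(Hs)) / Ht` with `H = 1 - sum(p^2)`, `Ht` computed from
#' the unweighted mean of group allele frequencies and `Hs` the mean of the
#' within-group gene diversities. Loci monomorphic overall (`Ht = 0`) are
#' excluded from the overall mean. Small negatives are clamped to zero.
#'
#' @param classes markers x genotypes integer matrix.
#' @param groups named list of genotype name vectors (>= 2 per group), or a
#'   factor/character vector aligned with `colnames(classes)`.
#' @return list with `per_locus` (data.frame `marker`, `ht`, `hs`, `fst`)
#'   and `overall`.
#' @export
fst <- function(classes, groups) {
  if (!is.list(groups)) {
    groups <- split(colnames(classes), as.character(groups))
  }
  if (length(groups) < 2) stopf("need >= 2 groups")
  if (any(lengths(groups) < 2)) stopf("each group needs >= 2 genotypes")
  per <- lapply(rownames(classes), function(m) {
    x <- classes[m, ]
    freqs <- lapply(groups, function(g) {
      v <- x[g]; v <- v[!is.na(v)]
      if (!length(v)) return(NULL)
      table(factor(v, levels = sort(unique(x[!is.na(x)])))) / length(v)
    })
    freqs <- freqs[!vapply(freqs, is.null, logical(1))]
    if (length(freqs) < 2) return(data.frame(marker = m, ht = NA_real_,
                                             hs = NA_real_, fst = NA_real_))
    pbar <- Reduce(`+`, freqs) / length(freqs)
    ht <- 1 - sum(pbar^2)
    hs <- mean(vapply(freqs, function(p) 1 - sum(p^2), numeric(1)))
    f <- if (ht > 0) max(0, min(1, (ht - hs) / ht)) else NA_real_
    data.frame(marker = m, ht = ht, hs = hs, fst = f)
  })
  per <- do.call(rbind, per)
  list(per_locus = per, overall = mean(per$fst, na.rm = TRUE))
}
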