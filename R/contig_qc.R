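#' GC fraction of a sequence, computed over non-N bases
#'
#' @param sequence character vector of ACGTN sequences.
#' @return numeric vector of GC fractions in `[0, 1]`; `NaN` for all-N input.
#' @export
gc_fraction <- function(sequence) {
  gc <- nchar(gsub("[^GC]", "", sequence))
  acgt <- nchar(gsub("[^ACGT]", "", sequence))
  gc / acgt
}

#' Assembly statistics over a contig set
#'
#' Contigs shorter than `min_length` are excluded before any statistic is
#' computed (the default 120 bp mirrors common practice for short-read
#' assemblies). N50 is the length L such that retained contigs of length >= L
#' together cover at least half the total retained length. GC is computed over
#' non-N bases only.
#'
#' @param contigs data.frame with a `sequence` column, or a character vector
#'   of sequences.
#' @param min_length minimum contig length retained for statistics.
#' @return list with `n_contigs`, `total_length`, `mean_length`, `n50`,
#'   `gc_percent`.
#' @export
assembly_stats <- function(contigs, min_length = 120L) {
  seqs <- if (is.data.frame(contigs)) contigs$sequence else contigs
  lens <- nchar(seqs)
  keep <- lens >= min_length
  if (!any(keep)) stopf("no contig survives the %d bp length filter", min_length)
  seqs <- seqs[keep]; lens <- lens[keep]
  sorted <- sort(lens, decreasing = TRUE)
  csum <- cumsum(sorted)
  n50 <- sorted[which(csum >= sum(sorted) / 2)[1]]
  gc <- sum(nchar(gsub("[^GC]", "", seqs)))
  acgt <- sum(nchar(gsub("[^ACGT]", "", seqs)))
  list(n_contigs = length(lens),
       total_length = sum(lens),
       mean_length = mean(lens),
       n50 = n50,
       gc_percent = 100 * gc / acgt)
}

#' Does a sequence contain a disqualifying run of Ns?
#'
#' Contigs containing more than `max_run` consecutive Ns are excluded from
#' marker candidacy: long ambiguous stretches inside a contig can fake or
#' mis-size an InDel. A run of exactly `max_run` is kept.
#'
#' @param sequence character vector.
#' @param max_run longest tolerated N-run (default 4).
#' @return logical vector: `TRUE` when the contig must be excluded.
#' @export
has_disqualifying_n_run <- function(sequence, max_run = 4L) {
  grepl(sprintf("N{%d,}", max_run + 1L), sequence)
}

#' Per-genotype assembly statistics table
#'
#' @param contigs data.frame with `genotype` and `sequence` columns.
#' @param min_length minimum contig length retained.
#' @return data.frame, one row per genotype, with the [assembly_stats()]
#'   fields.
#' @export
assembly_stats_table <- function(contigs, min_length = 120L) {
  do.call(rbind, lapply(split(contigs, contigs$genotype), function(g) {
    s <- assembly_stats(g, min_length)
    data.frame(genotype = g$genotype[1], n_contigs = s$n_contigs,
               total_length = s$total_length,
               mean_length = round(s$mean_length, 1),
               n50 = s$n50, gc_percent = round(s$gc_percent, 2))
  }))
}
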