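#' Read a SAM/BAM file into alignment records
#'
#' SAM text is converted to BAM in a temporary location and read back through
#' Rsamtools; only mapped records are returned. The pipeline consumes
#' alignments, it never produces them (read mapping is upstream).
#'
#' @param path SAM or BAM file.
#' @return data.frame with `qname`, `chromosome`, `start`, `end`, `cigar`,
#'   `seq`.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             indexDestination = FALSE, overwrite = TRUE)
  }
  ga <- GenomicAlignments::readGAlignments(
    path, param = Rsamtools::ScanBamParam(
      what = c("qname", "seq"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))
  data.frame(
    qname = S4Vectors::mcols(ga)$qname,
    chromosome = as.character(GenomicAlignments::seqnames(ga)),
    start = GenomicAlignments::start(ga),
    end = GenomicAlignments::end(ga),
    cigar = GenomicAlignments::cigar(ga),
    seq = as.character(S4Vectors::mcols(ga)$seq))
}

# Parse a CIGAR string into op letters and lengths.
cigar_runs <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops)) return(NULL)
  data.frame(op = ops, len = lens)
}

#' Call InDels from alignments by pileup
#'
#' Walks each read's CIGAR, collects insertion and deletion events,
#' left-aligns them against the reference, groups identical events and emits
#' calls supported by at least `min_vaf` of the reads spanning the site, with
#' at least `min_depth` spanning reads. Records with malformed CIGARs are
#' skipped with a warning; unmapped-only input yields an empty call set.
#'
#' @param alignments data.frame from [read_alignments()] (or a SAM/BAM path).
#' @param reference named character vector of chromosome sequences.
#' @param min_depth minimum spanning-read count (default 5).
#' @param min_vaf minimum variant allele frequency (default 0.80).
#' @return data.frame of calls sorted by chromosome then position:
#'   `chromosome`, `position` (1-based; first deleted base for deletions, the
#'   base left of the insertion point for insertions), `kind`, `allele`,
#'   `depth`, `supporting`, `vaf`.
#' @export
call_indels <- function(alignments, reference, min_depth = 5L,
                        min_vaf = 0.80) {
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  empty <- data.frame(chromosome = character(0), position = integer(0),
                      kind = character(0), allele = character(0),
                      depth = integer(0), supporting = integer(0),
                      vaf = numeric(0))
  if (nrow(alignments) == 0) return(empty)
  events <- list()
  for (i in seq_len(nrow(alignments))) {
    runs <- cigar_runs(alignments$cigar[i])
    if (is.null(runs) || nrow(runs) == 0) {
      warning(sprintf("skipping record %s: malformed CIGAR",
                      alignments$qname[i]))
      next
    }
    chr <- alignments$chromosome[i]
    ref <- reference[[chr]]
    rpos <- alignments$start[i]   # next reference base (1-based)
    qpos <- 1L                    # next query base
    for (j in seq_len(nrow(runs))) {
      op <- runs$op[j]; len <- runs$len[j]
      if (op %in% c("M", "=", "X")) {
        rpos <- rpos + len; qpos <- qpos + len
      } else if (op == "I") {
        allele <- substr(alignments$seq[i], qpos, qpos + len - 1L)
        anchor <- rpos - 1L       # base left of the insertion point
        while (anchor >= 1L &&
               substr(ref, anchor, anchor) == substr(allele, len, len)) {
          allele <- paste0(substr(ref, anchor, anchor),
                           substr(allele, 1L, len - 1L))
          anchor <- anchor - 1L
        }
        events[[length(events) + 1L]] <- data.frame(
          chromosome = chr, position = anchor, kind = "insertion",
          allele = allele)
        qpos <- qpos + len
      } else if (op == "D" || op == "N") {
        st <- rpos; en <- rpos + len - 1L
        while (st > 1L && substr(ref, st - 1L, st - 1L) == substr(ref, en, en)) {
          st <- st - 1L; en <- en - 1L
        }
        events[[length(events) + 1L]] <- data.frame(
          chromosome = chr, position = st, kind = "deletion",
          allele = substr(ref, st, en))
        rpos <- rpos + len
      } else if (op == "S") {
        qpos <- qpos + len
      } else if (op == "H" || op == "P") {
        # no-op
      }
    }
  }
  if (!length(events)) return(empty)
  ev <- do.call(rbind, events)
  key <- paste(ev$chromosome, ev$position, ev$kind, ev$allele, sep = "\r")
  tab <- table(key)
  uq <- ev[!duplicated(key), , drop = FALSE]
  uq$supporting <- as.integer(tab[paste(uq$chromosome, uq$position, uq$kind,
                                        uq$allele, sep = "\r")])
  # spanning depth: reads covering the deleted base, or both bases flanking
  # an insertion point
  uq$depth <- vapply(seq_len(nrow(uq)), function(i) {
    a <- alignments[alignments$chromosome == uq$chromosome[i], , drop = FALSE]
    p <- uq$position[i]
    if (uq$kind[i] == "insertion")
      sum(a$start <= p & a$end >= p + 1L)
    else
      sum(a$start <= p & a$end >= p)
  }, integer(1))
  uq$vaf <- uq$supporting / uq$depth
  out <- uq[uq$depth >= min_depth & uq$vaf >= min_vaf, , drop = FALSE]
  out <- out[order(out$chromosome, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("chromosome", "position", "kind", "allele", "depth", "supporting",
          "vaf")]
}

#' Genome-wide InDel density summary
#'
#' @param calls call table from [call_indels()].
#' @param genome_size genome size in bp.
#' @param coverage mean sequencing coverage (x).
#' @return list with `n_calls`, `calls_per_mbp`, `calls_per_1x`.
#' @export
summarize_density <- function(calls, genome_size, coverage) {
  if (genome_size <= 0 || coverage <= 0)
    stopf("genome_size and coverage must be positive")
  n <- nrow(calls)
  list(n_calls = n,
       calls_per_mbp = n / (genome_size / 1e6),
       calls_per_1x = n / coverage)
}

#' Simulate error-free alignments of a genotype against the reference
#'
#' Draws reads from a variant-carrying genotype and emits their reference
#' alignments (position + CIGAR) directly from the planted truth, standing in
#' for a read mapper on fixtures. Reads that only partially overlap an event
#' (less than `anchor` aligned bases on either side) are dropped, so every
#' emitted record is unambiguous.
#'
#' @param reference named character vector of chromosome sequences.
#' @param genotype named character vector of the carrier's chromosomes.
#' @param events this genotype's carried events with genotype coordinates,
#'   from [event_genotype_positions()].
#' @param read_length read length in bp (default 100).
#' @param depth target coverage (default 10).
#' @param anchor minimum aligned bases flanking an event within a read.
#' @param seed integer seed.
#' @return data.frame with `qname`, `flag`, `chromosome`, `pos`, `mapq`,
#'   `cigar`, `seq`.
#' @export
simulate_alignments <- function(reference, genotype, events,
                                read_length = 100L, depth = 10L,
                                anchor = 10L, seed = 1L) {
  with_seed(seed, {
    recs <- list()
    for (chr in names(genotype)) {
      glen <- nchar(genotype[[chr]])
      ev <- events[events$chromosome == chr, , drop = FALSE]
      ev <- ev[order(ev$geno_start), , drop = FALSE]
      n_reads <- ceiling(depth * glen / read_length)
      starts <- sample.int(glen - read_length + 1L, n_reads, replace = TRUE)
      for (gs in starts) {
        ge <- gs + read_length - 1L
        hit <- which(ev$geno_start <= ge & ev$geno_end >= gs)
        before <- ev[ev$geno_end < gs, , drop = FALSE]
        shift <- sum(ifelse(before$kind == "insertion", -before$size,
                            before$size))
        rpos <- gs + shift
        if (length(hit) == 0) {
          cig <- sprintf("%dM", read_length)
        } else if (length(hit) > 1) {
          next  # events are planted far apart; skip pathological reads
        } else {
          e <- ev[hit, ]
          if (e$kind == "insertion") {
            a <- e$geno_start - gs
            b <- ge - e$geno_end
            if (a < anchor || b < anchor) next
            cig <- sprintf("%dM%dI%dM", a, e$size, b)
          } else {
            a <- e$geno_start - gs + 1L
            b <- ge - e$geno_start
            if (a < anchor || b < anchor) next
            cig <- sprintf("%dM%dD%dM", a, e$size, b)
          }
        }
        recs[[length(recs) + 1L]] <- data.frame(
          qname = sprintf("rd%06d", length(recs) + 1L), flag = 0L,
          chromosome = chr, pos = rpos, mapq = 60L, cigar = cig,
          seq = substr(genotype[[chr]], gs, ge))
      }
    }
    do.call(rbind, recs)
  })
}

#' Write alignment records as a SAM file
#'
#' @param records data.frame from [simulate_alignments()].
#' @param reference named character vector (for `@SQ` header lines).
#' @param path output path (conventionally `.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, reference, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference), nchar(reference)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                  records$qname, records$flag, records$chromosome,
                  records$pos, records$mapq, records$cigar, records$seq)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write InDel calls as a minimal VCF 4.2 file
#'
#' Calls are converted to VCF convention: the record position is the anchor
#' base left of the event, REF/ALT carry the anchor plus the deleted or
#' inserted bases. INFO holds DP (spanning depth), AD (supporting reads) and
#' AF (variant allele frequency).
#'
#' @param calls call table from [call_indels()].
#' @param reference named character vector of chromosome sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, reference, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(reference),
                   nchar(reference)),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Spanning depth\">",
           "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Supporting reads\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(0)
  if (nrow(calls)) rows <- vapply(seq_len(nrow(calls)), function(i) {
    chr <- calls$chromosome[i]
    if (calls$kind[i] == "deletion") {
      p <- calls$position[i] - 1L
      anchor <- substr(reference[[chr]], p, p)
      ref <- paste0(anchor, calls$allele[i]); alt <- anchor
    } else {
      p <- calls$position[i]
      anchor <- substr(reference[[chr]], p, p)
      ref <- anchor; alt <- paste0(anchor, calls$allele[i])
    }
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AD=%d;AF=%.4f",
            chr, p, ref, alt, calls$depth[i], calls$supporting[i],
            calls$vaf[i])
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
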