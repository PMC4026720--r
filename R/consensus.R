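#' Build an ambiguity-masked consensus region around an InDel
#'
#' The InDel-bearing contigs (two or three) are aligned onto the long-allele
#' scaffold — the sequence that contains the InDel bases — and a consensus is
#' taken column by column: positions where every aligned, non-gap member
#' agrees keep the base, disagreements become N. The InDel interval itself is
#' carried as long-allele sequence (the short alleles are gapped there by
#' construction). The consensus is trimmed to the region covered by all
#' members so both primer flanks are genuinely consensus-supported.
#'
#' @param scaffold long-allele sequence (the query contig for insertions,
#'   or the query with the deleted bases restored / the subject contig for
#'   deletions).
#' @param others character vector of 1-2 further member sequences.
#' @param indel_start 0-based start of the InDel interval on the scaffold.
#' @param indel_size InDel length in bp.
#' @param min_overlap minimum aligned span per member (default 100 bp).
#' @param scoring see [align_scoring()].
#' @param max_ambiguity maximum tolerated fraction of N positions.
#' @return list with `consensus`, `indel_interval` (0-based half-open on the
#'   consensus), `ambiguity_count` and `rejected` (`FALSE`, or a reason
#'   string).
#' @export
build_consensus <- function(scaffold, others, indel_start, indel_size,
                            min_overlap = 100L, scoring = align_scoring(),
                            max_ambiguity = 0.10) {
  n <- nchar(scaffold)
  cons <- strsplit(scaffold, "")[[1]]
  covered_lo <- 0L; covered_hi <- n  # intersection of member spans (0-based)
  disagree <- rep(FALSE, n)
  for (m in others) {
    h <- local_align(scaffold, m, scoring)
    if (is.null(h) ||
        (h$query_interval[2] - h$query_interval[1]) < min_overlap)
      return(list(rejected = "unalignable"))
    subj <- if (h$strand == "-") revcomp(m) else m
    qpos <- h$query_interval[1]; spos <- h$subject_interval_aln[1]
    ops <- h$operations
    for (i in seq_len(nrow(ops))) {
      op <- ops$op[i]; len <- ops$run_length[i]
      if (op == "mismatch") {
        disagree[(qpos + 1L):(qpos + len)] <- TRUE
        qpos <- qpos + len; spos <- spos + len
      } else if (op == "match") {
        qpos <- qpos + len; spos <- spos + len
      } else if (op == "subject_gap") {
        qpos <- qpos + len     # member has no base here; not a disagreement
      } else {
        spos <- spos + len     # member insertion: no scaffold column
      }
    }
    covered_lo <- max(covered_lo, h$query_interval[1])
    covered_hi <- min(covered_hi, h$query_interval[2])
  }
  iv <- c(indel_start, indel_start + indel_size)
  if (covered_lo >= covered_hi || iv[1] < covered_lo || iv[2] > covered_hi)
    return(list(rejected = "indel_outside_consensus"))
  # the indel interval keeps long-allele bases even where short alleles gap out
  mask <- disagree
  mask[(iv[1] + 1L):iv[2]] <- FALSE
  cons[mask] <- "N"
  keep <- (covered_lo + 1L):covered_hi
  consensus <- paste(cons[keep], collapse = "")
  amb <- sum(mask[keep])
  if (amb >= max_ambiguity * length(keep))
    return(list(rejected = "too_ambiguous"))
  list(consensus = consensus,
       indel_interval = c(iv[1] - covered_lo, iv[2] - covered_lo),
       ambiguity_count = amb, rejected = FALSE)
}
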