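#' Build a seed index over a reference genome
#'
#' Forward-strand k-mers with their chromosome and position, used to locate
#' candidate placement loci before exact local alignment.
#'
#' @param reference named character vector of chromosome sequences.
#' @param k seed length (default 16).
#' @return index list used by [screen_unique()].
#' @export
reference_index <- function(reference, k = 16L) {
  per <- lapply(reference, encode_kmers, k = k)
  list(kmers = unlist(per, use.names = FALSE),
       chromosome = rep(names(reference), lengths(per)),
       position = unlist(lapply(per, seq_along), use.names = FALSE),
       sequences = reference, k = k,
       total_length = sum(nchar(reference)))
}

# Candidate placement windows: cluster seed matches per chromosome, merge
# overlapping windows across strands.
placement_windows <- function(query, index) {
  k <- index$k
  n <- nchar(query)
  if (n < k) return(NULL)
  qk <- unique(c(encode_kmers(query, k), encode_kmers(revcomp(query), k)))
  sel <- index$kmers %in% qk
  if (!any(sel)) return(NULL)
  chrom <- index$chromosome[sel]
  pos <- index$position[sel]
  wins <- list()
  for (chr in unique(chrom)) {
    p <- sort(pos[chrom == chr])
    br <- c(0L, which(diff(p) > n), length(p))
    for (i in seq_len(length(br) - 1L)) {
      seg <- p[(br[i] + 1L):br[i + 1L]]
      lo <- max(1L, min(seg) - n)
      hi <- min(nchar(index$sequences[[chr]]), max(seg) + k + n)
      wins[[length(wins) + 1L]] <- data.frame(chromosome = chr,
                                              start = lo, end = hi)
    }
  }
  w <- do.call(rbind, wins)
  # merge overlapping windows on the same chromosome
  out <- list()
  for (chr in unique(w$chromosome)) {
    ww <- w[w$chromosome == chr, , drop = FALSE]
    ww <- ww[order(ww$start), , drop = FALSE]
    cur <- ww[1, ]
    if (nrow(ww) > 1) for (i in 2:nrow(ww)) {
      if (ww$start[i] <= cur$end) cur$end <- max(cur$end, ww$end[i])
      else { out[[length(out) + 1L]] <- cur; cur <- ww[i, ] }
    }
    out[[length(out) + 1L]] <- cur
  }
  do.call(rbind, out)
}

# Map a 0-based query offset through an alignment hit to a 0-based
# coordinate on the as-aligned subject.
map_query_offset <- function(hit, qoff) {
  qpos <- hit$query_interval[1]
  spos <- hit$subject_interval_aln[1]
  ops <- hit$operations
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$run_length[i]
    if (op %in% c("match", "mismatch")) {
      if (qoff < qpos + len) return(spos + (qoff - qpos))
      qpos <- qpos + len; spos <- spos + len
    } else if (op == "subject_gap") {
      if (qoff < qpos + len) return(spos)  # inside query-only sequence
      qpos <- qpos + len
    } else {
      spos <- spos + len
    }
  }
  spos
}

#' Screen a contig for unique placement on the reference
#'
#' Locates candidate loci by shared 16-mers, aligns the contig exactly within
#' each locus window (both strands), and counts loci whose expectation value
#' passes the cutoff. Exactly one qualifying locus yields a placement;
#' two or more mean the contig sits in repetitive sequence and is excluded
#' (`multi_hit`); zero qualifying loci exclude it as unplaceable (`no_hit`).
#'
#' @param contig_seq contig sequence (must already have passed the N-run
#'   filter).
#' @param index a [reference_index()].
#' @param indel_query_pos optional 0-based query offset of the InDel's first
#'   base; when given, the returned `position` is the 1-based forward-strand
#'   reference coordinate aligned to it.
#' @param e_cutoff expectation cutoff (default 1e-50).
#' @param max_hits cap on counted hits (default 20).
#' @param scoring see [align_scoring()].
#' @return list with `status` (`"placed"`, `"multi_hit"`, `"no_hit"`),
#'   `n_hits`, and for placements `chromosome`, `position` (1-based, forward
#'   strand) and `strand`.
#' @export
screen_unique <- function(contig_seq, index, indel_query_pos = NULL,
                          e_cutoff = 1e-50, max_hits = 20L,
                          scoring = align_scoring()) {
  if (is.null(index)) stopf("reference index is required")
  wins <- placement_windows(contig_seq, index)
  hits <- list()
  if (!is.null(wins)) for (i in seq_len(nrow(wins))) {
    wseq <- substr(index$sequences[[wins$chromosome[i]]],
                   wins$start[i], wins$end[i])
    h <- local_align(contig_seq, wseq, scoring)
    if (is.null(h)) next
    h$e_value <- expectation_value(h$score, nchar(contig_seq),
                                   index$total_length)
    if (h$e_value > e_cutoff) next
    h$chromosome <- wins$chromosome[i]
    h$window_start <- wins$start[i]
    h$window_len <- nchar(wseq)
    hits[[length(hits) + 1L]] <- h
    if (length(hits) >= max_hits) break
  }
  if (!length(hits)) return(list(status = "no_hit", n_hits = 0L))
  if (length(hits) >= 2L)
    return(list(status = "multi_hit", n_hits = length(hits)))
  h <- hits[[1]]
  p <- list(status = "placed", n_hits = 1L,
            chromosome = h$chromosome, position = NA_integer_,
            strand = h$strand, hit = h)
  if (!is.null(indel_query_pos))
    p$position <- placement_position(p, indel_query_pos)
  p
}

#' Reference coordinate of a query offset under an accepted placement
#'
#' @param placement a `"placed"` result of [screen_unique()].
#' @param indel_query_pos 0-based query offset.
#' @return 1-based forward-strand reference coordinate.
#' @export
placement_position <- function(placement, indel_query_pos) {
  h <- placement$hit
  s_aln <- map_query_offset(h, indel_query_pos)
  fwd <- if (h$strand == "+") s_aln else h$window_len - 1L - s_aln
  as.integer(h$window_start + fwd)
}
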