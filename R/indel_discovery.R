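#' Extract InDel candidates from a local alignment
#'
#' Each maximal gap run in the alignment becomes one candidate: a gap in the
#' subject means the query carries extra sequence (an insertion relative to
#' the query), a gap in the query means the query lacks sequence present in
#' the subject (a deletion). Gap runs are left-aligned (shifted leftwards
#' through identical bases) before positions are reported, so the same event
#' seen through different subjects lands on identical coordinates.
#'
#' @param hit an `AlignmentHit` from [local_align()].
#' @param query_seq,subject_seq the full sequences the hit was computed on
#'   (forward orientation; the subject is reverse-complemented internally for
#'   minus-strand hits).
#' @param flank maximum flank length captured from the query (default 400).
#' @return data.frame of candidates: `indel_size`, `kind`, `query_position`
#'   (0-based offset of the first affected query base; for deletions, of the
#'   first base after the junction), `indel_seq`, `left_flank`,
#'   `right_flank`, `support`.
#' @export
extract_indels <- function(hit, query_seq, subject_seq, flank = 400L) {
  subj <- if (hit$strand == "-") revcomp(subject_seq) else subject_seq
  qpos <- hit$query_interval[1]       # 0-based cursors
  spos <- hit$subject_interval_aln[1]
  out <- list()
  ops <- hit$operations
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$run_length[i]
    if (op == "subject_gap") {        # insertion relative to query
      p <- qpos; s <- spos
      while (p > hit$query_interval[1] &&
             substr(query_seq, p, p) == substr(query_seq, p + len, p + len)) {
        p <- p - 1L; s <- s - 1L      # 0-based: base p-1 vs p+len-1 (1-based p, p+len)
      }
      out[[length(out) + 1L]] <- data.frame(
        indel_size = len, kind = "insertion", query_position = p,
        indel_seq = substr(query_seq, p + 1L, p + len),
        left_flank = substr(query_seq, max(1L, p - flank + 1L), p),
        right_flank = substr(query_seq, p + len + 1L, p + len + flank),
        support = 1L)
      qpos <- qpos + len
    } else if (op == "query_gap") {   # deletion relative to query
      p <- qpos; s <- spos
      while (p > hit$query_interval[1] &&
             substr(subj, s, s) == substr(subj, s + len, s + len)) {
        p <- p - 1L; s <- s - 1L
      }
      out[[length(out) + 1L]] <- data.frame(
        indel_size = len, kind = "deletion", query_position = p,
        indel_seq = substr(subj, s + 1L, s + len),
        left_flank = substr(query_seq, max(1L, p - flank + 1L), p),
        right_flank = substr(query_seq, p + 1L, p + flank),
        support = 1L)
      spos <- spos + len
    } else {
      qpos <- qpos + len
      spos <- spos + len
    }
  }
  if (!length(out)) return(data.frame(
    indel_size = integer(0), kind = character(0), query_position = integer(0),
    indel_seq = character(0), left_flank = character(0),
    right_flank = character(0), support = integer(0)))
  do.call(rbind, out)
}

#' Discover InDel candidates within a market class
#'
#' Implements both discovery strategies: `three_way` takes each genotype in
#' turn as the query against a database pooling the contigs of the other
#' genotypes of the class (up to two hits kept per query contig), `pairwise`
#' aligns every ordered genotype pair keeping only the best hit. Candidates
#' at the same query locus (same contig, same size and kind, overlapping
#' intervals) are merged and their support — the number of distinct subject
#' genotypes confirming the event — accumulated.
#'
#' @param contig_sets named list: genotype name -> contig data.frame (from
#'   [fragment_to_contigs()] or equivalent, needing `contig_id`, `sequence`).
#' @param mode `"three_way"` (>= 3 genotypes) or `"pairwise"` (>= 2).
#' @param market_class label carried onto candidates.
#' @param e_cutoff expectation cutoff for hits (default 1e-50).
#' @param scoring see [align_scoring()].
#' @return data.frame of merged candidates with `market_class`,
#'   `query_genotype`, `query_contig`, `subject_contigs`,
#'   `subject_genotypes`, plus the [extract_indels()] columns.
#' @export
discover <- function(contig_sets, mode = c("three_way", "pairwise"),
                     market_class = "mc", e_cutoff = 1e-50,
                     scoring = align_scoring()) {
  mode <- match.arg(mode)
  n_geno <- length(contig_sets)
  if (mode == "three_way" && n_geno < 3)
    stopf("three_way discovery needs >= 3 genotypes, got %d", n_geno)
  if (mode == "pairwise" && n_geno < 2)
    stopf("pairwise discovery needs >= 2 genotypes, got %d", n_geno)
  genos <- names(contig_sets)
  geno_of <- unlist(lapply(genos, function(g)
    setNames(rep(g, nrow(contig_sets[[g]])), contig_sets[[g]]$contig_id)))
  raw <- list()
  run_queries <- function(query_set, qgeno, db_df, max_hits) {
    idx <- contig_kmer_index(db_df)
    for (i in seq_len(nrow(query_set))) {
      q <- query_set$sequence[i]
      hits <- best_hits(q, db_df, max_hits = max_hits, e_cutoff = e_cutoff,
                        scoring = scoring, index = idx,
                        query_id = query_set$contig_id[i])
      for (h in hits) {
        cand <- extract_indels(h, q, idx$sequences[[h$subject_id]])
        if (!nrow(cand)) next
        cand$query_genotype <- qgeno
        cand$query_contig <- h$query_id
        cand$subject_contig <- h$subject_id
        cand$subject_genotype <- geno_of[[h$subject_id]]
        raw[[length(raw) + 1L]] <<- cand
      }
    }
  }
  if (mode == "three_way") {
    for (g in genos) {
      db <- do.call(rbind, contig_sets[setdiff(genos, g)])
      run_queries(contig_sets[[g]], g, db, max_hits = 2L)
    }
  } else {
    for (g in genos) for (h in setdiff(genos, g)) {
      run_queries(contig_sets[[g]], g, contig_sets[[h]], max_hits = 1L)
    }
  }
  if (!length(raw)) return(empty_candidates(market_class))
  cand <- do.call(rbind, raw)
  merge_candidates(cand, market_class)
}

empty_candidates <- function(market_class) {
  data.frame(market_class = character(0), query_genotype = character(0),
             query_contig = character(0), query_position = integer(0),
             indel_size = integer(0), kind = character(0),
             indel_seq = character(0), left_flank = character(0),
             right_flank = character(0), support = integer(0),
             subject_contigs = character(0), subject_genotypes = character(0))
}

# Merge candidates sharing a query locus: same contig, kind and size with
# overlapping query intervals. Support counts distinct subject genotypes.
merge_candidates <- function(cand, market_class) {
  out <- list()
  for (key in unique(paste(cand$query_contig, cand$kind, cand$indel_size))) {
    grp <- cand[paste(cand$query_contig, cand$kind, cand$indel_size) == key, ,
                drop = FALSE]
    grp <- grp[order(grp$query_position), , drop = FALSE]
    width <- ifelse(grp$kind == "insertion", grp$indel_size, 1L)
    cl <- integer(nrow(grp)); cur <- 1L; cl[1] <- 1L
    if (nrow(grp) > 1) for (i in 2:nrow(grp)) {
      prev_end <- max(grp$query_position[cl == cur] + width[cl == cur])
      if (grp$query_position[i] < prev_end) cl[i] <- cur
      else { cur <- cur + 1L; cl[i] <- cur }
    }
    for (g in unique(cl)) {
      rows <- grp[cl == g, , drop = FALSE]
      first <- rows[1, , drop = FALSE]
      first$support <- length(unique(rows$subject_genotype))
      first$subject_contigs <- paste(unique(rows$subject_contig), collapse = ",")
      first$subject_genotypes <- paste(unique(rows$subject_genotype), collapse = ",")
      out[[length(out) + 1L]] <- first
    }
  }
  res <- do.call(rbind, out)
  res$market_class <- market_class
  res$subject_contig <- NULL
  res$subject_genotype <- NULL
  rownames(res) <- NULL
  res[, c("market_class", "query_genotype", "query_contig", "query_position",
          "indel_size", "kind", "indel_seq", "left_flank", "right_flank",
          "support", "subject_contigs", "subject_genotypes")]
}

#' Filter InDel candidates by minimum size
#'
#' Small length differences cannot be resolved as distinct bands on a 3%
#' agarose gel, so candidates below `min_size` (default 8 bp) are dropped.
#'
#' @param candidates candidate data.frame.
#' @param min_size minimum InDel size in bp retained.
#' @return the retained rows, order preserved.
#' @export
filter_min_size <- function(candidates, min_size = 8L) {
  candidates[candidates$indel_size >= min_size, , drop = FALSE]
}
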