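#' Default affine-gap nucleotide scoring
#'
#' Integral blastn-style scheme: match +2, mismatch -4, and a gap of length L
#' costs `gap_open + L * gap_extend` = 5 + 5L (megablast's 1/-2/2.5/2.5
#' doubled to stay integral). N never matches anything.
#'
#' @param match,mismatch,gap_open,gap_extend score components.
#' @return list of the four components.
#' @export
align_scoring <- function(match = 2L, mismatch = -4L,
                          gap_open = 5L, gap_extend = 5L) {
  list(match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend)
}

# Substitution matrix over A,C,G,T,N with N scoring as a mismatch everywhere.
scoring_matrix <- function(scoring) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(b, b))
  diag(m)[1:4] <- scoring$match
  m["N", "N"] <- scoring$mismatch
  m
}

#' Optimal local alignment of two sequences (affine gaps, both strands)
#'
#' Exact Smith-Waterman-Gotoh local alignment via
#' [Biostrings::pairwiseAlignment()]; both orientations of the subject are
#' evaluated and the better kept (ties favour the plus strand). Plays the role
#' a blastn hit plays at genome scale, but exactly and at desk scale.
#'
#' @param query,subject character sequences (ACGTN).
#' @param scoring see [align_scoring()].
#' @param both_strands evaluate the reverse complement of the subject too;
#'   set `FALSE` together with `strand_hint = "-"` to align only one
#'   orientation when the winning strand is already known.
#' @param strand_hint `"+"` or `"-"`: the single orientation evaluated when
#'   `both_strands` is `FALSE`.
#' @return an `AlignmentHit`: list with `query_id`, `subject_id` (filled by
#'   callers), `score`, `strand`, `query_interval` and `subject_interval`
#'   (0-based half-open; subject interval always on the forward strand),
#'   `subject_interval_aln` (interval on the strand actually aligned) and
#'   `operations` (data.frame `op` in match/mismatch/query_gap/subject_gap,
#'   `run_length`). `NULL` when no positive-scoring alignment exists.
#' @export
local_align <- function(query, subject, scoring = align_scoring(),
                        both_strands = TRUE, strand_hint = "+") {
  if (!nzchar(query) || !nzchar(subject)) stopf("empty sequence")
  mat <- scoring_matrix(scoring)
  one <- function(subj) {
    Biostrings::pairwiseAlignment(
      Biostrings::DNAString(query), Biostrings::DNAString(subj),
      type = "local", substitutionMatrix = mat,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  }
  if (both_strands) {
    pa_f <- one(subject)
    pa <- pa_f; strand <- "+"
    pa_r <- one(revcomp(subject))
    if (Biostrings::score(pa_r) > Biostrings::score(pa_f)) {
      pa <- pa_r; strand <- "-"
    }
  } else {
    strand <- strand_hint
    pa <- if (strand == "+") one(subject) else one(revcomp(subject))
  }
  sc <- Biostrings::score(pa)
  if (sc <= 0) return(NULL)
  qa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  op <- ifelse(qa == "-", "query_gap",
               ifelse(sa == "-", "subject_gap",
                      ifelse(qa == sa, "match", "mismatch")))
  r <- rle(op)
  qs <- S4Vectors::start(Biostrings::pattern(pa)) - 1L
  qe <- S4Vectors::end(Biostrings::pattern(pa))
  ss <- S4Vectors::start(Biostrings::subject(pa)) - 1L
  se <- S4Vectors::end(Biostrings::subject(pa))
  L <- nchar(subject)
  subj_fwd <- if (strand == "+") c(ss, se) else c(L - se, L - ss)
  list(query_id = NA_character_, subject_id = NA_character_,
       score = sc, strand = strand,
       query_interval = c(qs, qe),
       subject_interval = subj_fwd,
       subject_interval_aln = c(ss, se),
       operations = data.frame(op = r$values, run_length = r$lengths))
}

#' Karlin-Altschul expectation value
#'
#' `E = K * m * n * exp(-lambda * score)` with ungapped nucleotide constants
#' by default. Used only for ordering hits and applying a configurable
#' cutoff, not to reproduce BLAST's gapped calibration.
#'
#' @param score alignment score (on the [align_scoring()] scale).
#' @param query_length,database_length search space dimensions in bp.
#' @param constants list with `lambda` and `K`.
#' @return the expectation value.
#' @export
expectation_value <- function(score, query_length, database_length,
                              constants = list(lambda = 1.28, K = 0.46)) {
  if (any(score < 0)) stopf("score must be >= 0")
  constants$K * query_length * database_length * exp(-constants$lambda * score)
}

# Pack all k-mers of a sequence into numerics (2 bits per base, exact in a
# double for k <= 26). N packs as A, which can only add candidates, never
# hide a true shared k-mer.
encode_kmers <- function(seq, k = 16L) {
  n <- nchar(seq)
  if (n < k) return(numeric(0))
  code <- integer(256)
  code[utf8ToInt("C")] <- 1L
  code[utf8ToInt("G")] <- 2L
  code[utf8ToInt("T")] <- 3L
  c4 <- code[utf8ToInt(seq)]
  v <- numeric(n - k + 1L)
  for (j in 0:(k - 1L)) v <- v * 4 + c4[(1L + j):(n - k + 1L + j)]
  v
}

#' Build a k-mer prefilter index over a contig database
#'
#' @param db named character vector of sequences (names = contig ids), or a
#'   data.frame with `contig_id` and `sequence`.
#' @param k seed length (default 16).
#' @return index list used by [best_hits()].
#' @export
contig_kmer_index <- function(db, k = 16L) {
  if (is.data.frame(db)) db <- setNames(db$sequence, db$contig_id)
  kmers <- lapply(db, encode_kmers, k = k)
  list(kmers = unlist(kmers, use.names = FALSE),
       subject = rep(names(db), lengths(kmers)),
       sequences = db, k = k)
}

seed_candidates <- function(query, index) {
  k <- index$k
  if (nchar(query) < k) return(character(0))
  qk <- unique(c(encode_kmers(query, k), encode_kmers(revcomp(query), k)))
  unique(index$subject[index$kmers %in% qk])
}

#' Best database hits for a query contig
#'
#' Aligns the query against each database sequence (optionally only those
#' sharing a 16-mer seed with the query, which cannot change the result for
#' any pair with a seed-length exact match), converts scores to expectation
#' values against the whole database length, and returns hits with
#' `E <= e_cutoff` sorted by ascending E, then descending score, then
#' subject id, truncated to `max_hits`.
#'
#' @param query character sequence.
#' @param db named character vector / data.frame (see [contig_kmer_index()]).
#' @param max_hits maximum number of hits returned.
#' @param e_cutoff expectation cutoff (default 1e-50).
#' @param scoring see [align_scoring()].
#' @param index optional prebuilt [contig_kmer_index()]; built on the fly
#'   when `NULL`.
#' @param prefilter use the k-mer seed prefilter.
#' @param query_id id recorded on the hits.
#' @return list of `AlignmentHit`s (possibly empty), each with `e_value`.
#' @export
best_hits <- function(query, db, max_hits = 1L, e_cutoff = 1e-50,
                      scoring = align_scoring(), index = NULL,
                      prefilter = TRUE, query_id = NA_character_) {
  if (is.null(index)) index <- contig_kmer_index(db)
  dbl <- sum(nchar(index$sequences))
  ids <- if (prefilter) seed_candidates(query, index) else names(index$sequences)
  if (!length(ids)) return(list())
  # batched score-only pass over both strands; traceback only for the winners
  mat <- scoring_matrix(scoring)
  subs <- Biostrings::DNAStringSet(index$sequences[ids])
  qd <- Biostrings::DNAString(query)
  sc_f <- Biostrings::pairwiseAlignment(
    subs, qd, type = "local", substitutionMatrix = mat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    scoreOnly = TRUE)
  sc_r <- Biostrings::pairwiseAlignment(
    Biostrings::reverseComplement(subs), qd, type = "local",
    substitutionMatrix = mat, gapOpening = scoring$gap_open,
    gapExtension = scoring$gap_extend, scoreOnly = TRUE)
  sc <- pmax(sc_f, sc_r)
  ev <- expectation_value(pmax(sc, 0), nchar(query), dbl)
  keep <- which(sc > 0 & ev <= e_cutoff)
  if (!length(keep)) return(list())
  keep <- keep[order(-sc[keep], ids[keep])]   # E asc == score desc
  keep <- keep[seq_len(min(max_hits, length(keep)))]
  lapply(keep, function(i) {
    strand <- if (sc_f[i] >= sc_r[i]) "+" else "-"
    h <- local_align(query, index$sequences[[ids[i]]], scoring,
                     both_strands = FALSE, strand_hint = strand)
    h$query_id <- query_id
    h$subject_id <- ids[i]
    h$e_value <- ev[i]
    h
  })
}
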