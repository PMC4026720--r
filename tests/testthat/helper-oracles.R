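# Independent brute-force oracles used across the suite.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

rc <- function(x) chartr("ACGTN", "TGCAN",
                         paste(rev(strsplit(x, "")[[1]]), collapse = ""))

# Full-DP Smith-Waterman-Gotoh score (local, affine gaps costing
# open + len * ext), row-vectorized but derived independently of the
# package's aligner. Returns the optimal score only.
sw_oracle_score <- function(q, s, scoring = list(match = 2, mismatch = -4,
                                                 gap_open = 5, gap_extend = 5)) {
  a <- strsplit(q, "")[[1]]; b <- strsplit(s, "")[[1]]
  n <- length(a); m <- length(b)
  open <- scoring$gap_open; ext <- scoring$gap_extend
  Hprev <- numeric(m + 1)
  Fv <- rep(-Inf, m)
  best <- 0
  j <- seq_len(m)
  for (i in seq_len(n)) {
    sub <- ifelse(b == a[i] & a[i] != "N", scoring$match, scoring$mismatch)
    diagv <- Hprev[1:m] + sub
    Fv <- pmax(Fv - ext, Hprev[2:(m + 1)] - open - ext)
    G <- pmax(0, diagv, Fv)
    # within-row gap: H[j] = max(G[j], max_{k<j}(H[k] + k*ext) - open - j*ext),
    # and the running max reduces to cummax(G + j*ext)
    M <- cummax(G + ext * j)
    H <- pmax(G, c(-Inf, M[-m]) - open - ext * j)
    best <- max(best, max(H))
    Hprev <- c(0, H)
  }
  best
}

# Local score considering both subject strands, as best_hits does.
sw_oracle_best_strand <- function(q, s, ...) {
  max(sw_oracle_score(q, s, ...), sw_oracle_score(q, rc(s), ...))
}

# Cophenetic (leaf-to-leaf path length) distances of a phylo tree,
# computed by a simple Floyd-Warshall over the tree graph.
tree_leaf_distances <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  d <- matrix(Inf, nn, nn); diag(d) <- 0
  for (e in seq_len(nrow(tree$edge))) {
    i <- tree$edge[e, 1]; j <- tree$edge[e, 2]
    d[i, j] <- d[j, i] <- tree$edge.length[e]
  }
  for (k in seq_len(nn)) for (i in seq_len(nn)) {
    upd <- d[i, k] + d[k, ]
    d[i, ] <- pmin(d[i, ], upd)
  }
  out <- d[seq_len(n), seq_len(n)]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

# Leaf distance matrix implied by explicitly listed unrooted tree edges.
additive_matrix <- function(leaves, edges) {
  # edges: data.frame from, to, len over arbitrary node names
  nodes <- unique(c(edges$from, edges$to))
  d <- matrix(Inf, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (i in seq_len(nrow(edges))) {
    d[edges$from[i], edges$to[i]] <- d[edges$to[i], edges$from[i]] <- edges$len[i]
  }
  for (k in nodes) d <- pmin(d, outer(d[, k], d[k, ], `+`))
  d[leaves, leaves]
}

# Construct a small SAM fixture in code: `support` reads carry the event,
# the rest plainly match, all spanning the site.
pileup_fixture <- function(ref, n_reads, support, kind = "deletion",
                           size = 6, event_at = 301, read_len = 100,
                           alt = strrep("T", size)) {
  recs <- list()
  for (i in seq_len(n_reads)) {
    start <- event_at - 50 - (i %% 40)  # staggered, all spanning the event
    if (i <= support && kind == "deletion") {
      a <- event_at - start
      cig <- sprintf("%dM%dD%dM", a, size, read_len - a)
      seq <- paste0(substr(ref, start, event_at - 1),
                    substr(ref, event_at + size,
                           event_at + size + (read_len - a) - 1))
    } else if (i <= support && kind == "insertion") {
      a <- event_at - start + 1
      cig <- sprintf("%dM%dI%dM", a, size, read_len - a - size)
      seq <- paste0(substr(ref, start, event_at), alt,
                    substr(ref, event_at + 1,
                           event_at + (read_len - a - size)))
    } else {
      cig <- sprintf("%dM", read_len)
      seq <- substr(ref, start, start + read_len - 1)
    }
    recs[[i]] <- data.frame(qname = sprintf("r%03d", i), flag = 0L,
                            chromosome = "chr01", pos = start, mapq = 60L,
                            cigar = cig, seq = seq)
  }
  do.call(rbind, recs)
}
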