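#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration under the standard Q-criterion. At every step the
#' pair minimizing `Q(i,j) = (m-2) d(i,j) - r(i) - r(j)` is joined; ties are
#' broken lexicographically on the joined clusters' smallest member labels,
#' which makes the result invariant to input taxon order. Negative branch
#' lengths are clamped to zero. The final three clusters are attached to a
#' central node with the closed-form three-point lengths, so a 3-taxon input
#' reduces to exactly those formulas.
#'
#' @param distances complete symmetric numeric matrix with dimnames (or a
#'   `dist`), n >= 3, no missing values.
#' @return an unrooted `phylo` tree (class from the ape package).
#' @export
nj_tree <- function(distances) {
  D <- as.matrix(distances)
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <-
      paste0("t", seq_len(nrow(D)))
  if (any(is.na(D))) stopf("distance matrix has missing entries")
  if (!isTRUE(all.equal(D, t(D)))) stopf("distance matrix must be symmetric")
  n <- nrow(D)
  if (n < 3) stopf("need >= 3 taxa")
  labs <- rownames(D)          # tie-break label: smallest leaf per cluster
  frags <- rownames(D)         # newick fragment per active cluster
  bl <- function(x) sprintf("%.12g", max(0, x))
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    keys <- apply(best, 1, function(ij)
      paste(sort(c(labs[ij[1]], labs[ij[2]])), collapse = "\r"))
    pick <- best[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    newfrag <- sprintf("(%s:%s,%s:%s)", frags[i], bl(bi), frags[j], bl(bj))
    newlab <- min(labs[i], labs[j])
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    labs <- c(labs[keep], newlab)
    frags <- c(frags[keep], newfrag)
    rownames(D2) <- colnames(D2) <- labs
    D <- D2
  }
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frags[1], bl(v1), frags[2], bl(v2), frags[3], bl(v3))
  ape::read.tree(text = nwk)
}

# Canonical bipartition keys of an unrooted tree: for each internal edge,
# the sorted tips on the side not containing the alphabetically first tip.
tree_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  n <- length(tree$tip.label)
  keys <- character(0)
  for (node in setdiff(unique(tree$edge[, 1]), n + 1L)) {
    clade <- ape::extract.clade(tree, node)$tip.label
    if (ref %in% clade) clade <- setdiff(tips, clade)
    if (length(clade) >= 2 && length(clade) <= n - 2)
      keys <- c(keys, paste(sort(clade), collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap support for the neighbor-joining tree of a call matrix
#'
#' Resamples markers (rows) with replacement, rebuilds the shared-allele
#' distance and NJ tree per replicate, and reports for each internal edge of
#' the point-estimate tree the percentage of replicates containing the same
#' bipartition.
#'
#' @param classes markers x genotypes call matrix.
#' @param n_replicates bootstrap replicates (default 1000).
#' @param seed integer seed; results are reproducible given the seed.
#' @return list with `tree` (point-estimate `phylo`, bootstrap percentages as
#'   internal node labels) and `support` (data.frame `bipartition`,
#'   `support`).
#' @export
bootstrap_support <- function(classes, n_replicates = 1000L, seed = 1L) {
  if (ncol(classes) < 4) stopf("need >= 4 genotypes for bootstrap support")
  point <- nj_tree(shared_allele_distance(classes))
  keys <- tree_bipartitions(point)
  counts <- setNames(numeric(length(keys)), keys)
  with_seed(seed, {
    for (b in seq_len(n_replicates)) {
      idx <- sample.int(nrow(classes), replace = TRUE)
      Db <- suppressWarnings(shared_allele_distance(
        classes[idx, , drop = FALSE]))
      if (any(is.na(Db))) next
      bk <- tree_bipartitions(nj_tree(Db))
      hit <- keys %in% bk
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- 100 * counts / n_replicates
  # attach to internal nodes of the point tree
  n <- length(point$tip.label)
  tips <- sort(point$tip.label)
  node_lab <- rep("", point$Nnode)
  for (node in setdiff(unique(point$edge[, 1]), n + 1L)) {
    clade <- ape::extract.clade(point, node)$tip.label
    if (tips[1] %in% clade) clade <- setdiff(tips, clade)
    key <- paste(sort(clade), collapse = "|")
    if (key %in% names(support))
      node_lab[node - n] <- sprintf("%g", support[[key]])
  }
  point$node.label <- node_lab
  list(tree = point,
       support = data.frame(bipartition = names(support),
                            support = unname(support)))
}
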