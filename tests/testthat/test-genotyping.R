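test_that("in-silico PCR predicts product sizes from primer site geometry", {
  set.seed(80)
  g <- rand_dna(3000)
  fwd <- substr(g, 501, 526)           # 26-mer forward site
  rev <- rc(substr(g, 655, 680))       # reverse primer ending at 680
  expect_equal(insilico_pcr(fwd, rev, g), 180)
  expect_equal(insilico_pcr(fwd, rev, rand_dna(3000)), integer(0))
  # swapped orientation finds the same product
  expect_equal(insilico_pcr(rev, fwd, g), 180)
  # allele with a 12 bp deletion inside the amplicon is 12 bp shorter
  g_del <- paste0(substr(g, 1, 600), substr(g, 613, 3000))
  expect_equal(insilico_pcr(fwd, rev, g_del), 168)
})

test_that("virtual gel scoring collapses near-comigrating bands", {
  markers <- data.frame(name = c("m1", "m2"),
                        forward_seq = NA, reverse_seq = NA)
  # bands 7 bp apart at 8 bp resolution are one class
  expect_equal(indelmine:::band_classes(c(100, 107), 8), c(1L, 1L))
  expect_equal(indelmine:::band_classes(c(100, 109), 8), c(1L, 2L))
  expect_equal(indelmine:::band_classes(c(100, NA, 120), 8), c(1L, NA, 2L))
})

test_that("polymorphism rate counts markers with two or more size classes", {
  set.seed(81)
  ref <- rand_dna(4000)
  # 5 markers; 2 polymorphic by planting deletions in genotype B's amplicons
  sites <- seq(300, 3500, by = 700)[1:5]
  mk <- do.call(rbind, lapply(seq_along(sites), function(i) {
    s <- sites[i]
    data.frame(name = sprintf("m%d", i),
               forward_seq = substr(ref, s, s + 25),
               reverse_seq = rc(substr(ref, s + 174, s + 199)))
  }))
  gB <- ref
  for (s in sites[c(2, 4)] + 80)
    gB <- paste0(substr(gB, 1, s), substr(gB, s + 13, nchar(gB)))
  sc <- score_markers(mk, list(gA = ref, gB = gB))
  expect_equal(unname(sc$polymorphic), c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(sc$polymorphism_rate, 0.4)
  # identical genotypes: nothing polymorphic
  sc0 <- score_markers(mk, list(gA = ref, gB = ref))
  expect_equal(sc0$polymorphism_rate, 0)
  # planted 12 bp difference appears as exactly 12 bp between alleles
  expect_equal(sc$sizes["m2", "gA"] - sc$sizes["m2", "gB"], 12L)
})

test_that("multiplex compatibility checks size windows and cross-dimers", {
  mk <- data.frame(
    name = c("a", "b"),
    forward_seq = c("AGCTTGCCATTGACGGTCAAGG", "TGGACCTAAGCACTGGATCACC"),
    reverse_seq = c("CCAGTATTGCCTGAAGCCTTGG", "TTGGCACAGTGACAGGATGAGG"),
    product_long = c(90, 230), product_short = c(70, 200),
    tm_f = c(68, 68), tm_r = c(68, 68))
  v <- multiplex_compatible(mk)
  expect_true(v$compatible)
  mk2 <- mk
  mk2$product_short <- c(100, 125); mk2$product_long <- c(130, 150)
  v2 <- multiplex_compatible(mk2)
  expect_false(v2$compatible)
  expect_true("size_overlap" %in% v2$violations$type)
  mk3 <- mk
  mk3$reverse_seq[2] <- paste0(substr(mk3$reverse_seq[2], 1, 16),
                               rc(substr(mk3$forward_seq[1], 17, 22)))
  v3 <- multiplex_compatible(mk3)
  expect_true("cross_dimer" %in% v3$violations$type)
  mk4 <- mk; mk4$tm_f[1] <- 72
  expect_true("tm_out_of_window" %in%
                multiplex_compatible(mk4)$violations$type)
  expect_error(multiplex_compatible(mk[1, , drop = FALSE]), "2-6")
})

test_that("shared-allele distance is the mismatch fraction over co-scored loci", {
  cls <- matrix(c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
                  1, 1, 1, 2, 2, 1, 1, 2, 1, 1,
                  2, 2, 2, 2, 2, 2, 2, 2, 2, 2), ncol = 3,
                dimnames = list(sprintf("m%d", 1:10), c("g1", "g2", "g3")))
  D <- shared_allele_distance(cls)
  expect_equal(D["g1", "g1"], 0)
  expect_equal(D["g1", "g3"], 1)
  expect_equal(D["g1", "g2"], 0.3)
  expect_equal(D, t(D))
  cls[1:5, 1] <- NA; cls[6:10, 2] <- NA
  expect_warning(shared_allele_distance(cls), "no co-scored")
})

test_that("NJ reproduces three-point closed forms and additive trees exactly", {
  # 3 taxa: unique topology, closed-form lengths
  D <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  expect_setequal(tr$tip.label, c("a", "b", "c"))
  got <- tree_leaf_distances(tr)
  expect_equal(got[rownames(D), colnames(D)], D, tolerance = 1e-9)
  # lengths are (d12+d13-d23)/2 etc.
  expect_equal(sort(tr$edge.length), sort(c(2, 3, 7)), tolerance = 1e-9)

  # additive 4- and 6-taxon metrics: NJ recovers the tree metric exactly
  edges4 <- data.frame(from = c("x", "x", "y", "y", "x2"),
                       to = c("a", "b", "c", "d", "y"), len = c(2, 3, 4, 1, 5))
  edges4$from[5] <- "x"
  D4 <- additive_matrix(c("a", "b", "c", "d"), edges4)
  t4 <- nj_tree(D4)
  expect_equal(tree_leaf_distances(t4)[rownames(D4), colnames(D4)], D4,
               tolerance = 1e-9)

  set.seed(82)
  # random additive 6-taxon tree built from a random topology via ape
  rt <- ape::rtree(6, rooted = FALSE)
  rt$edge.length <- round(rt$edge.length * 10 + 1, 3)
  D6 <- tree_leaf_distances(rt)
  t6 <- nj_tree(D6)
  expect_equal(tree_leaf_distances(t6)[rownames(D6), colnames(D6)], D6,
               tolerance = 1e-9)
  expect_equal(ape::dist.topo(ape::unroot(rt), t6)[1], 0)
})

test_that("NJ topology is invariant to taxon order and matches ape's nj", {
  set.seed(83)
  rt <- ape::rtree(8, rooted = FALSE)
  D <- tree_leaf_distances(rt)
  t1 <- nj_tree(D)
  perm <- sample(rownames(D))
  t2 <- nj_tree(D[perm, perm])
  expect_equal(ape::dist.topo(t1, t2)[1], 0)
  # independent cross-check against ape's implementation
  t_ape <- ape::nj(as.dist(D))
  expect_equal(ape::dist.topo(t1, ape::unroot(t_ape))[1], 0)
})

test_that("bootstrap support separates planted clusters and is reproducible", {
  set.seed(84)
  # 8 genotypes in two clusters of 4; 30 markers split them cleanly, with a
  # few noisy loci
  cls <- matrix(NA_integer_, 30, 8,
                dimnames = list(sprintf("m%02d", 1:30),
                                c(sprintf("A%d", 1:4), sprintf("B%d", 1:4))))
  for (m in 1:30) {
    if (m <= 24) {
      cls[m, 1:4] <- 1L; cls[m, 5:8] <- 2L
    } else {
      cls[m, ] <- sample(1:2, 8, TRUE)
    }
  }
  bs <- bootstrap_support(cls, n_replicates = 200, seed = 9)
  key <- paste(sort(sprintf("B%d", 1:4)), collapse = "|")
  expect_true(key %in% bs$support$bipartition)
  expect_gte(bs$support$support[bs$support$bipartition == key], 95)
  bs2 <- bootstrap_support(cls, n_replicates = 200, seed = 9)
  expect_identical(bs$support, bs2$support)
  # single replicate: support is 0 or 100
  bs1 <- bootstrap_support(cls, n_replicates = 1, seed = 3)
  expect_true(all(bs1$support$support %in% c(0, 100)))
})

test_that("Fst follows the heterozygosity closed form and its bounds", {
  mk <- sprintf("m%d", 1:2)
  # locus 1: p(A group)=0.8, p(B group)=0.2 -> Ht=0.5, Hs=0.32, Fst=0.36
  cls <- matrix(c(1, 1, 1, 1, 2, 1, 2, 2, 2, 2,
                  1, 1, 1, 1, 1, 2, 2, 2, 2, 2), 2, byrow = TRUE,
                dimnames = list(mk, c(sprintf("A%d", 1:5),
                                      sprintf("B%d", 1:5))))
  groups <- list(A = sprintf("A%d", 1:5), B = sprintf("B%d", 1:5))
  f <- fst(cls, groups)
  expect_equal(f$per_locus$fst[1], 0.36, tolerance = 1e-9)
  expect_equal(f$per_locus$fst[2], 1)   # fixed alternative alleles
  # identical frequencies in both groups: 0
  cls0 <- matrix(rep(c(1, 1, 2, 2, 2, 1, 1, 2, 2, 2), 2), 2, byrow = TRUE,
                 dimnames = dimnames(cls))
  expect_equal(fst(cls0, groups)$overall, 0)
  # relabeling allele classes leaves Fst unchanged
  relab <- ifelse(cls == 1, 7L, ifelse(cls == 2, 3L, cls))
  dimnames(relab) <- dimnames(cls)
  expect_equal(fst(relab, groups)$per_locus$fst, f$per_locus$fst)
  expect_error(fst(cls, list(A = "A1", B = colnames(cls)[-1])), ">= 2")
})
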