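test_that("reference generation is deterministic and annotates duplications", {
  r1 <- generate_reference(1, 50000, 0, seed = 1)
  expect_named(r1$sequences, "chr01")
  expect_equal(nchar(r1$sequences[["chr01"]]), 50000)
  expect_equal(nrow(r1$truth$duplicated_segments), 0)

  r2a <- generate_reference(2, c(50000, 30000), 0.1, seed = 7)
  r2b <- generate_reference(2, c(50000, 30000), 0.1, seed = 7)
  expect_identical(r2a, r2b)

  dup <- r2a$truth$duplicated_segments
  copied <- sum(dup$end - dup$start + 1)
  expect_equal(copied, 8000)  # 10% of 80 kb, whole 2 kb blocks
  # every annotated copy is exact
  for (i in seq_len(nrow(dup))) {
    src <- substr(r2a$sequences[[dup$chromosome[i]]], dup$start[i], dup$end[i])
    dst <- substr(r2a$sequences[[dup$copy_chromosome[i]]], dup$copy_start[i],
                  dup$copy_start[i] + (dup$end[i] - dup$start[i]))
    expect_identical(src, dst)
  }
  expect_error(generate_reference(1, 5000, 0, seed = 1), "10 kb")
  expect_error(generate_reference(1, 50000, 0.6, seed = 1), "duplication")
})

test_that("variant planting records exact, length-conserving events", {
  r <- generate_reference(1, 20000, 0, seed = 2)
  # no events, no SNPs: genotype identical to reference
  pv0 <- plant_variants(r, "g1", n_indels_per_genotype = 0, snp_rate = 0,
                        seed = 5)
  expect_identical(pv0$genotypes$g1, r$sequences)

  # single 12 bp deletion: direct length bookkeeping
  s <- r$sequences[[1]]
  del <- apply_variants(s, data.frame(position = 1000, size = 12,
                                      kind = "deletion", alt = ""))
  expect_equal(nchar(del), nchar(s) - 12)
  expect_identical(substr(del, 1, 999), substr(s, 1, 999))
  expect_identical(substr(del, 1000, 1010), substr(s, 1012, 1022))
  ins <- apply_variants(s, data.frame(position = 1000, size = 5,
                                      kind = "insertion", alt = "TTTTT"))
  expect_equal(nchar(ins), nchar(s) + 5)
  expect_identical(substr(ins, 1001, 1005), "TTTTT")

  # 30 indels x 3 genotypes: 90 recorded events, all verifiable in sequence
  r2 <- generate_reference(2, c(50000, 30000), 0.1, seed = 7)
  pv <- plant_variants(r2, c("A", "B", "C"), 30, c(8, 36),
                       min_separation = 400, seed = 3)
  expect_equal(nrow(pv$truth), 90)
  for (g in c("A", "B", "C")) {
    tr <- pv$truth[vapply(strsplit(pv$truth$carriers, ","), function(cs)
      g %in% cs, logical(1)), ]
    net <- sum(ifelse(tr$kind == "insertion", tr$size, -tr$size))
    expect_equal(sum(nchar(pv$genotypes[[g]])) - sum(nchar(r2$sequences)),
                 net, info = g)
    # carried events appear verbatim at their genotype coordinates
    gp <- event_genotype_positions(pv$truth, g)
    for (i in seq_len(nrow(gp))) {
      gseq <- pv$genotypes[[g]][[gp$chromosome[i]]]
      rseq <- r2$sequences[[gp$chromosome[i]]]
      if (gp$kind[i] == "insertion") {
        expect_identical(substr(gseq, gp$geno_start[i], gp$geno_end[i]),
                         gp$alt[i])
      } else {
        # junction joins the reference bases flanking the removed interval
        expect_identical(
          substr(gseq, gp$geno_start[i], gp$geno_end[i]),
          paste0(substr(rseq, gp$position[i] - 1, gp$position[i] - 1),
                 substr(rseq, gp$position[i] + gp$size[i],
                        gp$position[i] + gp$size[i])))
      }
    }
  }
})

test_that("events avoid duplicated segments when asked", {
  r <- generate_reference(2, c(50000, 30000), 0.1, seed = 7)
  pv <- plant_variants(r, c("A", "B"), 15, c(8, 36), seed = 9,
                       avoid_duplications = TRUE)
  dup <- r$truth$duplicated_segments
  for (i in seq_len(nrow(pv$truth))) {
    e <- pv$truth[i, ]
    inside <- (dup$chromosome == e$chromosome &
                 e$position >= dup$start & e$position <= dup$end) |
      (dup$copy_chromosome == e$chromosome &
         e$position >= dup$copy_start &
         e$position <= dup$copy_start + dup$end - dup$start)
    expect_false(any(inside))
  }
})

test_that("contig fragmentation round-trips and injects N-runs at the stated rate", {
  r <- generate_reference(1, 30000, 0, seed = 4)
  ctg <- fragment_to_contigs(r$sequences, 600, 120, n_run_injection_rate = 0,
                             genotype = "g1", seed = 11)
  expect_equal(nrow(ctg), 120)
  expect_true(all(ctg$length >= 120))
  # every clean contig is an exact substring at its recorded start
  for (i in seq_len(nrow(ctg))) {
    expect_identical(ctg$sequence[i],
                     substr(r$sequences[[ctg$chromosome[i]]], ctg$start[i],
                            ctg$start[i] + ctg$length[i] - 1))
  }
  # determinism
  ctg2 <- fragment_to_contigs(r$sequences, 600, 120, 0, genotype = "g1",
                              seed = 11)
  expect_identical(ctg, ctg2)

  # N-run injection bookkeeping
  ctgN <- fragment_to_contigs(r$sequences, 600, 200,
                              n_run_injection_rate = 0.1, genotype = "g1",
                              seed = 12)
  n_injected <- sum(ctgN$n_run_length > 0)
  counted <- sum(grepl("N{3,}", ctgN$sequence))
  expect_equal(counted, n_injected)
  expect_gt(n_injected, 5)   # ~20 expected at rate 0.1
  expect_lt(n_injected, 45)
  expect_true(all(ctgN$n_run_length %in% c(0, 3:8)))
})

test_that("anchored contigs give every event 200 bp flanks in every genotype", {
  sim <- simulate_marker_study(seed = 21, n_chromosomes = 1,
                               chromosome_lengths = 30000,
                               n_indels_per_genotype = 5,
                               duplication_fraction = 0)
  for (g in names(sim$contig_sets)) {
    anchors <- anchors_for_genotype(sim$variants$truth, g)
    ctg <- sim$contig_sets[[g]]
    for (i in seq_len(nrow(anchors))) {
      ok <- any(ctg$chromosome == anchors$chromosome[i] &
                  ctg$start <= anchors$start[i] - 200 &
                  ctg$start + ctg$length - 1 >= anchors$end[i] + 200)
      expect_true(ok, info = sprintf("%s anchor %d", g, i))
    }
  }
})
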