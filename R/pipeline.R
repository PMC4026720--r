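#' Anchor intervals for a genotype: where every planted event lands on its
#' coordinates
#'
#' Carried events map through [event_genotype_positions()]; events the
#' genotype does not carry map through the cumulative length offset of its
#' carried events. Used to guarantee contig coverage with primer-design
#' flanks around every event in every genotype.
#'
#' @param truth event table from [plant_variants()].
#' @param genotype genotype name.
#' @return data.frame `chromosome`, `start`, `end` (1-based genotype
#'   coordinates).
#' @export
anchors_for_genotype <- function(truth, genotype) {
  carried <- event_genotype_positions(truth, genotype)
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    e <- truth[i, ]
    if (e$event_id %in% carried$event_id) {
      cc <- carried[carried$event_id == e$event_id, ]
      rows[[i]] <- data.frame(chromosome = e$chromosome,
                              start = cc$geno_start, end = cc$geno_end)
    } else {
      mine <- carried[carried$chromosome == e$chromosome &
                        truth$position[match(carried$event_id,
                                             truth$event_id)] < e$position, ,
                      drop = FALSE]
      off <- sum(ifelse(mine$kind == "insertion", mine$size, -mine$size))
      g <- e$position + off
      w <- if (e$kind == "deletion") e$size else 1L
      rows[[i]] <- data.frame(chromosome = e$chromosome,
                              start = g, end = g + w)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a complete marker-development study at desk scale
#'
#' Generates a reference with planted duplications, genotypes carrying
#' private InDels and SNPs, and per-genotype contig sets whose anchored
#' contigs guarantee >= 200 bp flanks around every event in every genotype.
#'
#' @param seed master seed (chromosome-, genotype- and contig-level seeds are
#'   derived from it).
#' @param n_chromosomes,chromosome_lengths reference layout.
#' @param genotype_names genotype names (>= 2).
#' @param n_indels_per_genotype private InDels per genotype.
#' @param indel_size_range InDel size range in bp.
#' @param duplication_fraction fraction of the reference in two copies.
#' @param snp_rate per-base SNP rate per genotype.
#' @param contig_length_mean mean contig length.
#' @param contig_coverage total contig bases per genotype as a multiple of
#'   the genome size.
#' @param n_run_injection_rate per-contig N-run injection probability.
#' @return list with `reference`, `variants` (truth + genotypes),
#'   `contig_sets` (named list of contig data.frames).
#' @export
simulate_marker_study <- function(seed = 1L,
                                  n_chromosomes = 2L,
                                  chromosome_lengths = c(50000L, 50000L),
                                  genotype_names = c("gA", "gB", "gC"),
                                  n_indels_per_genotype = 20L,
                                  indel_size_range = c(8L, 36L),
                                  duplication_fraction = 0.08,
                                  snp_rate = 0.001,
                                  contig_length_mean = 700L,
                                  contig_coverage = 1.3,
                                  n_run_injection_rate = 0.05) {
  ref <- generate_reference(n_chromosomes, chromosome_lengths,
                            duplication_fraction, seed = seed)
  pv <- plant_variants(ref, genotype_names, n_indels_per_genotype,
                       indel_size_range, snp_rate = snp_rate,
                       seed = seed + 1L)
  contig_sets <- list()
  for (k in seq_along(genotype_names)) {
    g <- genotype_names[k]
    anchors <- anchors_for_genotype(pv$truth, g)
    genome <- pv$genotypes[[g]]
    n_ctg <- max(nrow(anchors),
                 ceiling(contig_coverage * sum(nchar(genome)) /
                           contig_length_mean))
    contig_sets[[g]] <- fragment_to_contigs(
      genome, contig_length_mean, n_ctg, n_run_injection_rate,
      anchors = anchors, genotype = g, seed = seed + 100L + k)
  }
  list(reference = ref, variants = pv, contig_sets = contig_sets)
}

count_row <- function(stage, n_in, retained, reason = "") {
  data.frame(stage = stage, n_in = n_in, retained = retained,
             excluded = n_in - retained, reason = reason)
}

#' Run the marker-development pipeline end to end
#'
#' Discovery (three-way or pairwise) -> minimum-size filter -> contig N-run
#' filter -> uniqueness screen against the reference -> per-locus
#' deduplication -> consensus building -> primer design -> position-encoded
#' naming. Every filter's input/retained/excluded counts are recorded, and
#' retained + excluded always equals the stage input (no silent drops).
#'
#' @param contig_sets named list: genotype -> contig data.frame.
#' @param reference named character vector of chromosome sequences.
#' @param market_class label for the genotype group.
#' @param mode `"three_way"` or `"pairwise"`.
#' @param config see [pipeline_config()].
#' @return list with `markers` (marker table plus `chromosome_id`, `kind`,
#'   `support`, `query_contig`), `candidates` (post-screen candidate set),
#'   `counts` (per-stage accounting) and `config`.
#' @export
run_marker_pipeline <- function(contig_sets, reference, market_class = "mc",
                                mode = c("three_way", "pairwise"),
                                config = pipeline_config()) {
  mode <- match.arg(mode)
  counts <- list()
  seq_of <- do.call(c, unname(lapply(contig_sets, function(df)
    setNames(df$sequence, df$contig_id))))
  cand <- discover(contig_sets, mode, market_class,
                   e_cutoff = config$e_cutoff, scoring = config$scoring)
  counts[[1]] <- count_row("discovery", nrow(cand), nrow(cand),
                           sprintf("from %d contigs",
                                   sum(vapply(contig_sets, nrow,
                                              integer(1)))))
  n0 <- nrow(cand)
  cand <- filter_min_size(cand, config$min_indel_size)
  counts[[2]] <- count_row("min_indel_size", n0, nrow(cand),
                           sprintf("indel_size < %d", config$min_indel_size))
  n0 <- nrow(cand)
  bad_n <- has_disqualifying_n_run(seq_of[cand$query_contig],
                                   config$n_run_max)
  cand <- cand[!bad_n, , drop = FALSE]
  counts[[3]] <- count_row("n_run_filter", n0, nrow(cand),
                           sprintf("> %d consecutive Ns", config$n_run_max))
  # uniqueness screen
  ridx <- reference_index(reference)
  n0 <- nrow(cand)
  placements <- vector("list", nrow(cand))
  by_contig <- list()   # contigs often carry several candidates: screen once
  for (i in seq_len(nrow(cand))) {
    id <- cand$query_contig[i]
    p <- by_contig[[id]]
    if (is.null(p)) {
      p <- screen_unique(seq_of[[id]], ridx,
                         e_cutoff = config$e_cutoff,
                         max_hits = config$uniqueness_max_hits,
                         scoring = config$scoring)
      by_contig[[id]] <- p
    }
    if (p$status == "placed") {
      # canonical locus anchor: reference base aligned to the last query base
      # left of the event, plus one; identical whichever genotype was the
      # query, so insertion- and deletion-views of one locus coincide
      qoff <- cand$query_position[i]
      p$position <- if (cand$kind[i] == "deletion" && qoff > 0)
        placement_position(p, qoff - 1L) + 1L
      else placement_position(p, qoff)
    }
    placements[[i]] <- p
  }
  status <- vapply(placements, `[[`, character(1), "status")
  cand$chromosome_id <- vapply(placements, function(p)
    if (p$status == "placed") p$chromosome else NA_character_, character(1))
  cand$position_bp <- vapply(placements, function(p)
    if (p$status == "placed") p$position else NA_integer_, integer(1))
  cand$strand <- vapply(placements, function(p)
    if (p$status == "placed") p$strand else NA_character_, character(1))
  cand <- cand[status == "placed", , drop = FALSE]
  counts[[4]] <- count_row(
    "uniqueness_screen", n0, nrow(cand),
    sprintf("multi_hit=%d no_hit=%d", sum(status == "multi_hit"),
            sum(status == "no_hit")))
  # per-locus dedup (same chromosome and size, anchor within 2 bp; the kind
  # is query-relative, so one locus may surface as both kinds)
  n0 <- nrow(cand)
  if (nrow(cand)) {
    cand <- cand[order(cand$chromosome_id, cand$indel_size,
                       cand$position_bp, -cand$support), , drop = FALSE]
    keep <- rep(TRUE, nrow(cand))
    last <- 1L
    for (i in seq_len(nrow(cand))[-1]) {
      same <- cand$chromosome_id[i] == cand$chromosome_id[last] &&
        cand$indel_size[i] == cand$indel_size[last] &&
        abs(cand$position_bp[i] - cand$position_bp[last]) <= 2L
      if (same) keep[i] <- FALSE else last <- i
    }
    cand <- cand[keep, , drop = FALSE]
  }
  counts[[5]] <- count_row("locus_dedup", n0, nrow(cand), "duplicate locus")
  # consensus + primer design
  n0 <- nrow(cand)
  markers <- list()
  reasons <- character(0)
  for (i in seq_len(nrow(cand))) {
    cc <- cand[i, ]
    qseq <- seq_of[[cc$query_contig]]
    members <- unname(seq_of[strsplit(cc$subject_contigs, ",")[[1]]])
    if (cc$kind == "insertion") {
      scaffold <- qseq
    } else {
      scaffold <- paste0(substr(qseq, 1L, cc$query_position),
                         cc$indel_seq,
                         substr(qseq, cc$query_position + 1L, nchar(qseq)))
      members <- c(qseq, members)
    }
    region <- build_consensus(scaffold, members, cc$query_position,
                              cc$indel_size, scoring = config$scoring)
    if (!identical(region$rejected, FALSE)) {
      reasons <- c(reasons, region$rejected)
      next
    }
    pair <- design_primer_pair(region, cc$indel_size, config$primer)
    if (is.null(pair)) {
      reasons <- c(reasons, "no_primer")
      next
    }
    chrom_num <- suppressWarnings(as.integer(gsub("\\D", "",
                                                  cc$chromosome_id)))
    chrom <- if (is.na(chrom_num)) cc$chromosome_id else chrom_num
    markers[[length(markers) + 1L]] <- data.frame(
      name = name_marker(chrom, cc$position_bp),
      market_class = cc$market_class,
      chromosome = if (is.na(chrom_num)) cc$chromosome_id else chrom_num,
      position_bp = cc$position_bp,
      indel_size = cc$indel_size,
      forward_seq = pair$forward_seq, reverse_seq = pair$reverse_seq,
      tm_f = round(pair$tm_forward, 2), tm_r = round(pair$tm_reverse, 2),
      gc_f = round(pair$gc_forward, 2), gc_r = round(pair$gc_reverse, 2),
      product_long = pair$product_size_long,
      product_short = pair$product_size_short,
      chromosome_id = cc$chromosome_id, kind = cc$kind,
      support = cc$support, query_contig = cc$query_contig,
      strand = cc$strand)
  }
  markers <- if (length(markers)) do.call(rbind, markers) else NULL
  n_mark <- if (is.null(markers)) 0L else nrow(markers)
  tab <- table(reasons)
  counts[[6]] <- count_row(
    "consensus_and_primers", n0, n_mark,
    if (length(tab)) paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                           collapse = " ") else "")
  list(markers = markers, candidates = cand,
       counts = do.call(rbind, counts), config = config)
}
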