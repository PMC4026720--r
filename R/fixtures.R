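#' Run an expression under a fixed RNG seed, restoring the caller's RNG state
#'
#' All fixture generators route their randomness through this helper so that
#' the same seed always yields byte-identical output without clobbering the
#' global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic multi-chromosome reference with planted duplications
#'
#' Builds uniform-random ACGT chromosomes and, optionally, copies segments of
#' the genome to second locations so that a chosen fraction of the sequence is
#' present in two exact copies. Every copied block is recorded, which lets
#' downstream tests assert that no marker originates from a duplicated
#' (repetitive) region.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_lengths integer vector of lengths in bp (each >= 10000).
#' @param duplication_fraction fraction (< 0.5) of the total sequence to place
#'   in two copies.
#' @param seed integer seed; output is deterministic given the seed.
#' @param block_length length in bp of each duplicated block (default 2000).
#' @return a list with `sequences` (named character vector, `chr01`, ...) and
#'   `truth`, itself a list with `reference_id`, `duplicated_segments` (a
#'   data.frame with source `chromosome`, `start`, `end` and destination
#'   `copy_chromosome`, `copy_start`, 1-based inclusive) and `seed`.
#' @export
generate_reference <- function(n_chromosomes, chromosome_lengths,
                               duplication_fraction = 0, seed = 1L,
                               block_length = 2000L) {
  if (n_chromosomes < 1 || length(chromosome_lengths) != n_chromosomes)
    stopf("chromosome_lengths must have one entry per chromosome")
  if (any(chromosome_lengths < 10000))
    stopf("chromosome lengths must be >= 10 kb")
  if (duplication_fraction < 0 || duplication_fraction >= 0.5)
    stopf("duplication_fraction must be in [0, 0.5)")
  with_seed(seed, {
    seqs <- setNames(
      vapply(chromosome_lengths, random_dna, character(1)),
      sprintf("chr%02d", seq_len(n_chromosomes))
    )
    dup <- data.frame(chromosome = character(0), start = integer(0),
                      end = integer(0), copy_chromosome = character(0),
                      copy_start = integer(0))
    total <- sum(chromosome_lengths)
    target <- floor(duplication_fraction * total)
    used <- lapply(seqs, function(s) integer(0))  # occupied midpoints per chrom
    copied <- 0L
    tries <- 0L
    while (copied + block_length <= target && tries < 1000L) {
      tries <- tries + 1L
      src_chr <- sample(names(seqs), 1, prob = chromosome_lengths)
      dst_chr <- sample(names(seqs), 1, prob = chromosome_lengths)
      src_start <- sample.int(nchar(seqs[[src_chr]]) - block_length + 1L, 1)
      dst_start <- sample.int(nchar(seqs[[dst_chr]]) - block_length + 1L, 1)
      iv <- function(st) c(st, st + block_length - 1L)
      clash <- function(chr, st) {
        any(vapply(used[[chr]], function(u)
          st <= u + block_length - 1L && st + block_length - 1L >= u,
          logical(1)))
      }
      if (clash(src_chr, src_start) || clash(dst_chr, dst_start)) next
      if (src_chr == dst_chr &&
          src_start <= dst_start + block_length - 1L &&
          dst_start <= src_start + block_length - 1L) next
      block <- substr(seqs[[src_chr]], src_start, src_start + block_length - 1L)
      s <- seqs[[dst_chr]]
      substr(s, dst_start, dst_start + block_length - 1L) <- block
      seqs[[dst_chr]] <- s
      used[[src_chr]] <- c(used[[src_chr]], src_start)
      used[[dst_chr]] <- c(used[[dst_chr]], dst_start)
      dup <- rbind(dup, data.frame(
        chromosome = src_chr, start = src_start,
        end = src_start + block_length - 1L,
        copy_chromosome = dst_chr, copy_start = dst_start))
      copied <- copied + block_length
    }
    list(sequences = seqs,
         truth = list(reference_id = sprintf("synthref_seed%d", seed),
                      duplicated_segments = dup, seed = seed))
  })
}

# Remove [lo, hi] from a set of disjoint intervals (data.frame start/end).
interval_subtract <- function(iv, lo, hi) {
  out <- list()
  for (i in seq_len(nrow(iv))) {
    s <- iv$start[i]; e <- iv$end[i]
    if (hi < s || lo > e) { out[[length(out) + 1L]] <- iv[i, ]; next }
    if (s < lo) out[[length(out) + 1L]] <- data.frame(start = s, end = lo - 1L)
    if (e > hi) out[[length(out) + 1L]] <- data.frame(start = hi + 1L, end = e)
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0)))
  do.call(rbind, out)
}

#' Apply a set of InDel events to a sequence
#'
#' Events use reference coordinates: a deletion removes bases
#' `position..position+size-1`; an insertion places `alt` between `position`
#' and `position + 1`.
#'
#' @param sequence character scalar (ACGTN).
#' @param events data.frame with columns `position`, `size`, `kind`
#'   (`"insertion"`/`"deletion"`) and `alt` (inserted sequence; ignored for
#'   deletions).
#' @return the edited sequence.
#' @export
apply_variants <- function(sequence, events) {
  if (nrow(events) == 0) return(sequence)
  if (any(events$position < 1 | events$position > nchar(sequence)))
    stopf("event position outside sequence bounds")
  events <- events[order(events$position, decreasing = TRUE), , drop = FALSE]
  for (i in seq_len(nrow(events))) {
    p <- events$position[i]; sz <- events$size[i]
    if (events$kind[i] == "deletion") {
      if (p + sz - 1L > nchar(sequence))
        stopf("deletion runs past sequence end")
      sequence <- paste0(substr(sequence, 1L, p - 1L),
                         substr(sequence, p + sz, nchar(sequence)))
    } else {
      sequence <- paste0(substr(sequence, 1L, p),
                         events$alt[i],
                         substr(sequence, p + 1L, nchar(sequence)))
    }
  }
  sequence
}

#' Plant InDels (and SNPs) into genotype copies of a reference
#'
#' Emulates the narrow within-market-class divergence the pipeline mines:
#' each genotype is the reference plus a private (or shared, via
#' `carrier_sets`) set of InDels of known size and position, plus optional
#' random SNPs. Every planted event is recorded with exact reference
#' coordinates, giving a ground truth for recall measurements.
#'
#' @param reference result of [generate_reference()].
#' @param genotype_names character vector of genotype names.
#' @param n_indels_per_genotype number of private InDels per genotype
#'   (ignored when `carrier_sets` is given).
#' @param indel_size_range length-2 integer vector, sizes drawn uniformly;
#'   must lie within `[1, 100]`.
#' @param snp_rate per-base substitution probability per genotype.
#' @param min_separation minimum distance in bp between planted events
#'   (across all genotypes), so flanks and PCR products never interleave.
#' @param avoid_duplications keep events (and their 300 bp margins) out of
#'   annotated duplicated segments.
#' @param carrier_sets optional list of character vectors; one event is
#'   planted per element, carried by exactly the named genotypes.
#' @param seed integer seed.
#' @return list with `genotypes` (list: genotype -> named chromosome vector),
#'   `truth` (data.frame: `event_id`, `chromosome`, `position`, `size`,
#'   `kind`, `alt`, `carriers`) and `snps` (data.frame of substitutions).
#' @export
plant_variants <- function(reference, genotype_names,
                           n_indels_per_genotype = 10L,
                           indel_size_range = c(8L, 36L),
                           snp_rate = 0, min_separation = 600L,
                           avoid_duplications = TRUE,
                           carrier_sets = NULL, seed = 1L) {
  if (indel_size_range[1] < 1 || indel_size_range[2] > 100)
    stopf("indel sizes must lie within [1, 100]")
  seqs <- reference$sequences
  chroms <- names(seqs)
  lens <- nchar(seqs)
  dup <- reference$truth$duplicated_segments
  if (is.null(carrier_sets)) {
    carrier_sets <- rep(as.list(genotype_names), n_indels_per_genotype)
  }
  n_events <- length(carrier_sets)
  with_seed(seed, {
    margin <- 500L
    # free position intervals per chromosome: start outside chromosome-end
    # margins and (optionally) outside duplicated segments and their copies
    free <- lapply(chroms, function(chr) {
      iv <- data.frame(start = margin, end = lens[[chr]] - margin)
      if (avoid_duplications && nrow(dup)) {
        zones <- rbind(
          data.frame(start = dup$start[dup$chromosome == chr] - 300L,
                     end = dup$end[dup$chromosome == chr] + 300L),
          data.frame(start = dup$copy_start[dup$copy_chromosome == chr] - 300L,
                     end = dup$copy_start[dup$copy_chromosome == chr] +
                       (dup$end - dup$start)[dup$copy_chromosome == chr] +
                       300L))
        for (z in seq_len(nrow(zones))) {
          iv <- interval_subtract(iv, zones$start[z], zones$end[z])
        }
      }
      iv
    })
    names(free) <- chroms
    ev <- vector("list", n_events)
    for (i in seq_len(n_events)) {
      widths <- vapply(free, function(iv)
        sum(pmax(0L, iv$end - iv$start + 1L)), numeric(1))
      if (sum(widths) <= 0)
        stopf("could not place %d events without overlap", n_events)
      chr <- sample(chroms, 1, prob = widths)
      iv <- free[[chr]]
      w <- pmax(0L, iv$end - iv$start + 1L)
      row <- sample.int(nrow(iv), 1, prob = w)
      pos <- iv$start[row] + sample.int(w[row], 1) - 1L
      free[[chr]] <- interval_subtract(iv, pos - min_separation,
                                       pos + min_separation)
      sz <- sample(indel_size_range[1]:indel_size_range[2], 1)
      kind <- sample(c("insertion", "deletion"), 1)
      alt <- if (kind == "insertion") random_dna(sz) else
        substr(seqs[[chr]], pos, pos + sz - 1L)
      ev[[i]] <- data.frame(
        event_id = sprintf("ev%04d", i), chromosome = chr, position = pos,
        size = sz, kind = kind, alt = alt,
        carriers = paste(carrier_sets[[i]], collapse = ","))
    }
    truth <- if (n_events) do.call(rbind, ev) else
      data.frame(event_id = character(0), chromosome = character(0),
                 position = integer(0), size = integer(0),
                 kind = character(0), alt = character(0),
                 carriers = character(0))
    snps <- data.frame(genotype = character(0), chromosome = character(0),
                       position = integer(0), ref = character(0),
                       alt = character(0))
    genotypes <- lapply(genotype_names, function(g) {
      gseqs <- seqs
      for (chr in chroms) {
        mine <- truth[truth$chromosome == chr &
                        vapply(strsplit(truth$carriers, ","), function(cs)
                          g %in% cs, logical(1)), , drop = FALSE]
        s <- gseqs[[chr]]
        if (snp_rate > 0) {
          n_snp <- stats::rbinom(1, lens[[chr]], snp_rate)
          if (n_snp > 0) {
            cand <- sample.int(lens[[chr]], n_snp)
            # keep SNPs clear of planted indel intervals
            bad <- vapply(cand, function(p) {
              any(truth$chromosome == chr &
                    p >= truth$position - 1L &
                    p <= truth$position + truth$size + 1L)
            }, logical(1))
            cand <- cand[!bad]
            for (p in cand) {
              old <- substr(s, p, p)
              new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
              substr(s, p, p) <- new
              snps <<- rbind(snps, data.frame(
                genotype = g, chromosome = chr, position = p,
                ref = old, alt = new))
            }
          }
        }
        s <- apply_variants(s, mine)
        gseqs[[chr]] <- s
      }
      gseqs
    })
    names(genotypes) <- genotype_names
    list(genotypes = genotypes, truth = truth, snps = snps)
  })
}

#' Map reference event coordinates onto a carrier genotype's coordinates
#'
#' @param truth event table from [plant_variants()].
#' @param genotype genotype name.
#' @return `truth` rows carried by `genotype`, with added columns
#'   `geno_start`, `geno_end`: the 1-based interval on the genotype sequence
#'   occupied by the event (insertion: the inserted bases; deletion: the two
#'   junction bases flanking the removed interval).
#' @export
event_genotype_positions <- function(truth, genotype) {
  carried <- truth[vapply(strsplit(truth$carriers, ","), function(cs)
    genotype %in% cs, logical(1)), , drop = FALSE]
  out <- carried[0, ]
  for (chr in unique(carried$chromosome)) {
    cc <- carried[carried$chromosome == chr, , drop = FALSE]
    cc <- cc[order(cc$position), , drop = FALSE]
    offset <- 0L
    gs <- ge <- integer(nrow(cc))
    for (i in seq_len(nrow(cc))) {
      if (cc$kind[i] == "insertion") {
        gs[i] <- cc$position[i] + offset + 1L
        ge[i] <- gs[i] + cc$size[i] - 1L
        offset <- offset + cc$size[i]
      } else {
        gs[i] <- cc$position[i] + offset - 1L
        ge[i] <- gs[i] + 1L
        offset <- offset - cc$size[i]
      }
    }
    cc$geno_start <- gs; cc$geno_end <- ge
    out <- rbind(out, cc)
  }
  out
}

#' Fragment a genome into overlapping contigs with optional N-run injection
#'
#' Contig lengths follow a truncated normal (sd = mean/4, floor 120 bp) so the
#' short tail exercises the 120 bp assembly-statistics filter. Optional
#' anchors guarantee that listed positions are covered by at least one contig
#' with at least `min_flank` bp on each side, so primer-design flanks exist
#' around planted InDels.
#'
#' @param genome named character vector of chromosome sequences (genotype
#'   coordinates).
#' @param target_contig_length_mean mean contig length (>= 150 bp).
#' @param n_contigs total number of contigs (anchored contigs included).
#' @param n_run_injection_rate per-contig probability of replacing a short
#'   internal stretch with an N-run of length 3-8.
#' @param anchors optional data.frame with `chromosome`, `start`, `end`
#'   (1-based interval to embed with flanks).
#' @param genotype label recorded on each contig.
#' @param min_flank minimum flank on each side of an anchor (default 200 bp).
#' @param seed integer seed.
#' @return data.frame: `contig_id`, `genotype`, `chromosome`, `start` (1-based
#'   position on the source genome), `length`, `anchored`, `n_run_length`
#'   (0 = clean), `sequence`.
#' @export
fragment_to_contigs <- function(genome, target_contig_length_mean = 600L,
                                n_contigs = 100L, n_run_injection_rate = 0,
                                anchors = NULL, genotype = "g",
                                min_flank = 200L, seed = 1L) {
  if (target_contig_length_mean < 150) stopf("mean contig length must be >= 150 bp")
  lens <- nchar(genome)
  with_seed(seed, {
    draw_len <- function(n, floor_len = 120L) {
      pmax(floor_len, round(rnorm(n, target_contig_length_mean,
                                  target_contig_length_mean / 4)))
    }
    rows <- list()
    k <- 0L
    if (!is.null(anchors) && nrow(anchors)) {
      for (i in seq_len(nrow(anchors))) {
        chr <- anchors$chromosome[i]
        a1 <- anchors$start[i]; a2 <- anchors$end[i]
        L <- max(draw_len(1), (a2 - a1 + 1L) + 2L * min_flank + 50L)
        L <- min(L, lens[[chr]])
        lo <- max(1L, a2 + min_flank - L + 1L)
        hi <- min(a1 - min_flank, lens[[chr]] - L + 1L)
        if (hi < lo) { lo <- max(1L, a1 - min_flank); hi <- lo }
        st <- if (hi > lo) sample(lo:hi, 1) else lo
        k <- k + 1L
        rows[[k]] <- data.frame(chromosome = chr, start = st, length = L,
                                anchored = TRUE)
      }
    }
    n_rand <- max(0L, n_contigs - k)
    if (n_rand > 0) {
      chr <- sample(names(genome), n_rand, replace = TRUE, prob = lens)
      L <- pmin(draw_len(n_rand), lens[chr])
      st <- vapply(seq_len(n_rand), function(i)
        sample.int(lens[[chr[i]]] - L[i] + 1L, 1), integer(1))
      for (i in seq_len(n_rand)) {
        k <- k + 1L
        rows[[k]] <- data.frame(chromosome = chr[i], start = st[i],
                                length = L[i], anchored = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    df$genotype <- genotype
    df$contig_id <- sprintf("%s_ctg%04d", genotype, seq_len(nrow(df)))
    df$sequence <- vapply(seq_len(nrow(df)), function(i)
      substr(genome[[df$chromosome[i]]], df$start[i],
             df$start[i] + df$length[i] - 1L), character(1))
    df$n_run_length <- 0L
    inject <- runif(nrow(df)) < n_run_injection_rate
    for (i in which(inject)) {
      run <- sample(3:8, 1)
      if (df$length[i] < run + 20L) next
      p <- sample.int(df$length[i] - run - 19L, 1) + 10L
      s <- df$sequence[i]
      substr(s, p, p + run - 1L) <- strrep("N", run)
      df$sequence[i] <- s
      df$n_run_length[i] <- run
    }
    rownames(df) <- NULL
    df[, c("contig_id", "genotype", "chromosome", "start", "length",
           "anchored", "n_run_length", "sequence")]
  })
}
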