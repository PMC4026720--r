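#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of sequences (uppercased).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write named sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(seqs)), path)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             comment.char = "")
}

MARKER_TABLE_COLUMNS <- c("name", "market_class", "chromosome", "position_bp",
                          "indel_size", "forward_seq", "reverse_seq",
                          "tm_f", "tm_r", "gc_f", "gc_r",
                          "product_long", "product_short")

#' Write the marker table (frozen column order)
#'
#' Columns, in order: name, market_class, chromosome, position_bp,
#' indel_size, forward_seq, reverse_seq, tm_f, tm_r, gc_f, gc_r,
#' product_long, product_short. Positions are 1-based.
#'
#' @param markers marker data.frame from [run_marker_pipeline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(markers, path) {
  write_tsv(markers[, MARKER_TABLE_COLUMNS, drop = FALSE], path)
}

#' @rdname write_marker_table
#' @export
read_marker_table <- function(path) {
  df <- read_tsv(path)
  missing <- setdiff(MARKER_TABLE_COLUMNS, names(df))
  if (length(missing))
    stopf("marker table lacks columns: %s", paste(missing, collapse = ", "))
  df
}

#' Write candidate InDels as TSV
#'
#' @param candidates candidate data.frame from [discover()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  write_tsv(candidates[, c("market_class", "query_genotype", "query_contig",
                           "query_position", "indel_size", "kind",
                           "support")], path)
}

#' Write marker placements as BED (0-based half-open)
#'
#' Deletions span their removed reference bases; insertions are the
#' zero-width point after the anchor base.
#'
#' @param markers marker data.frame with `chromosome_id`, `position_bp`,
#'   `indel_size`, `kind`, `name`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_placements_bed <- function(markers, path) {
  start0 <- markers$position_bp - 1L
  end0 <- ifelse(markers$kind == "deletion",
                 start0 + markers$indel_size, start0)
  writeLines(sprintf("%s\t%d\t%d\t%s", markers$chromosome_id,
                     as.integer(start0), as.integer(end0), markers$name),
             path)
  invisible(path)
}

#' Write the planted-truth event table as TSV and BED
#'
#' @param truth truth data.frame from [plant_variants()].
#' @param tsv_path,bed_path output paths (either may be `NULL`).
#' @return invisibly, `NULL`.
#' @export
write_truthset <- function(truth, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path)) write_tsv(truth, tsv_path)
  if (!is.null(bed_path)) {
    start0 <- ifelse(truth$kind == "deletion", truth$position - 1L,
                     truth$position)
    end0 <- ifelse(truth$kind == "deletion", start0 + truth$size, start0)
    writeLines(sprintf("%s\t%d\t%d\t%s", truth$chromosome,
                       as.integer(start0), as.integer(end0), truth$event_id),
               bed_path)
  }
  invisible(NULL)
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param D symmetric distance matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(D, path) {
  n <- nrow(D)
  lines <- c(sprintf("%5d", n),
             vapply(seq_len(n), function(i)
               paste(formatC(rownames(D)[i], width = -12),
                     paste(sprintf("%.6f", D[i, ]), collapse = "  ")),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a genotype call matrix as TSV
#'
#' @param classes markers x genotypes matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_call_matrix <- function(classes, path) {
  df <- data.frame(marker = rownames(classes), classes, check.names = FALSE)
  write_tsv(df, path)
}

#' Pipeline configuration with printed-parameter defaults
#'
#' Every threshold defaults to the published envelope, so an empty override
#' reproduces it: min InDel size 8 bp, N-run cap 4, e-value cutoff 1e-50,
#' uniqueness hit cap 20, pileup depth 5, VAF 0.80, gel resolution 8 bp, and
#' the [primer_constraints()] envelope.
#'
#' @param overrides named list, or path to a YAML file, overriding defaults.
#' @return configuration list.
#' @export
pipeline_config <- function(overrides = list()) {
  if (is.character(overrides)) overrides <- yaml::read_yaml(overrides)
  cfg <- list(
    min_indel_size = 8L, n_run_max = 4L, e_cutoff = 1e-50,
    uniqueness_max_hits = 20L, min_depth = 5L, min_vaf = 0.80,
    gel_resolution = 8L, stats_min_length = 120L,
    primer = primer_constraints(), scoring = align_scoring(),
    seed = 1L)
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  stopifnot(cfg$min_indel_size > 0, cfg$n_run_max > 0, cfg$e_cutoff > 0,
            cfg$min_depth > 0, cfg$min_vaf > 0)
  cfg
}

#' Write a plain-text run manifest
#'
#' Records thresholds, seeds and per-stage record counts so a run can be
#' audited and repeated.
#'
#' @param counts per-stage count data.frame from [run_marker_pipeline()].
#' @param config the [pipeline_config()] used.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(counts, config, path) {
  lines <- c(sprintf("indelmine %s",
                     as.character(utils::packageVersion("indelmine"))),
             sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
             "thresholds:",
             sprintf("  min_indel_size: %d", config$min_indel_size),
             sprintf("  n_run_max: %d", config$n_run_max),
             sprintf("  e_cutoff: %g", config$e_cutoff),
             sprintf("  uniqueness_max_hits: %d", config$uniqueness_max_hits),
             sprintf("  min_depth: %d", config$min_depth),
             sprintf("  min_vaf: %g", config$min_vaf),
             sprintf("  gel_resolution: %d", config$gel_resolution),
             sprintf("  seed: %d", config$seed),
             "stage counts:",
             sprintf("  %-28s in=%-6d retained=%-6d excluded=%d (%s)",
                     counts$stage, counts$n_in, counts$retained,
                     counts$excluded, counts$reason))
  writeLines(lines, path)
  invisible(path)
}
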