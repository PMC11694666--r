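#' Read BLAST tabular alignments
#'
#' Reads a tab-separated alignment table. A file with a header row naming
#' `query_id` is read as-is; a headerless file is interpreted as BLAST
#' outfmt-6 (12 columns) with an optional 13th query-length column.
#'
#' @param path File path.
#' @return data.frame with outfmt-6 column names (`query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `mismatches`, `gap_opens`,
#'   `query_start`, `query_end`, `subject_start`, `subject_end`, `e_value`,
#'   `bitscore`, and `query_length` when present).
#' @export
readBlastHits <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("^query_id\t", first)) return(readTsv(path))
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
            "mismatches", "gap_opens", "query_start", "query_end",
            "subject_start", "subject_end", "e_value", "bitscore")
  if (ncol(df) == 13) cols <- c(cols, "query_length")
  if (ncol(df) < 12) stop("expected >= 12 BLAST tabular columns", call. = FALSE)
  names(df)[seq_along(cols)] <- cols
  df
}

#' @rdname readBlastHits
#' @export
readHicLinks <- function(path) {
  df <- readTsv(path)
  .requireCols(df, c("virus_id", "host_id", "sample_id", "contact_count"),
               "Hi-C link table")
  df
}

#' @rdname readBlastHits
#' @export
readSpacerMatches <- function(path) {
  df <- readTsv(path)
  .requireCols(df, c("virus_id", "host_id", "mismatches_plus_gaps",
                     "coverage_percent", "matched_length"),
               "spacer match table")
  df
}

#' @rdname readBlastHits
#' @export
readCountsTable <- function(path) {
  df <- readTsv(path)
  .requireCols(df, c("entity_id", "sample_id", "reads", "genome_length"),
               "count table")
  df
}

#' Read epifluorescence microscopy counts
#'
#' Comma-separated table of per-sample direct counts; the virus-to-microbe
#' ratio column is derived when absent.
#'
#' @param path CSV path with `sample_id`, `vlp_per_ml`, `cells_per_ml`.
#' @return data.frame with a `vmr` column appended.
#' @export
readMicroscopy <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .requireCols(df, c("sample_id", "vlp_per_ml", "cells_per_ml"),
               "microscopy table")
  if (any(df$vlp_per_ml <= 0) || any(df$cells_per_ml <= 0)) {
    stop("microscopy counts must be positive", call. = FALSE)
  }
  df$vmr <- df$vlp_per_ml / df$cells_per_ml
  df
}

#' @rdname readBlastHits
#' @export
readPairwiseSimilarity <- function(path) {
  df <- readTsv(path)
  .requireCols(df, c("a", "b", "ani"), "pairwise similarity table")
  df
}

#' @rdname readBlastHits
#' @export
readBitscores <- function(path) {
  df <- readTsv(path)
  .requireCols(df, c("query_genome", "subject_genome", "summed_bitscore"),
               "bitscore table")
  df
}

#' @rdname readBlastHits
#' @export
readModuleDefinitions <- function(path) {
  df <- readTsv(path)
  .requireCols(df, c("module_id", "step_id"), "module definition table")
  df
}

#' Read genome lengths from TSV or FASTA
#'
#' @param path A two-column TSV (`entity_id`, `genome_length`) or a FASTA
#'   file (`.fa`, `.fasta`, `.fna`), from which sequence widths are taken
#'   (requires the Biostrings package).
#' @return Named numeric vector of lengths in bp.
#' @export
readGenomeLengths <- function(path) {
  if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("reading FASTA lengths requires the Biostrings package", call. = FALSE)
    }
    seqs <- Biostrings::readDNAStringSet(path)
    return(stats::setNames(as.numeric(Biostrings::width(seqs)),
                           sub("\\s.*$", "", names(seqs))))
  }
  df <- readTsv(path)
  .requireCols(df, c("entity_id", "genome_length"), "genome length table")
  stats::setNames(as.numeric(df$genome_length), df$entity_id)
}
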