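#' Read and write FASTA
#'
#' Thin wrappers around Biostrings. `read_fasta` returns a named character
#' vector; `write_fasta` accepts one. Clade labels for reference
#' haplotypes can be carried as a `clade=X` token in the description line
#' and recovered with [parse_clade_labels()].
#'
#' @param path file path.
#' @param sequences named character vector of sequences.
#' @name fasta_io
NULL

#' @rdname fasta_io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' @rdname fasta_io
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::BStringSet(unlist(sequences))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname fasta_io
#' @param headers FASTA description lines (names of [read_fasta()] output).
#' @export
parse_clade_labels <- function(headers) {
  m <- regmatches(headers, regexpr("clade=[^ ]+", headers))
  has <- grepl("clade=", headers)
  labels <- setNames(rep(NA_character_, length(headers)),
                     sub(" .*", "", headers))
  labels[has] <- sub("^clade=", "", m)
  labels[!is.na(labels)]
}

# SAM text I/O. Reads are single-end merged fragments mapped to one
# reference; the sample barcode travels in the BC tag. Coordinates are
# 0-based half-open in memory and 1-based on disk, per SAM convention.

#' Write mapped reads as SAM text
#'
#' @param reads a read table (read_id, barcode, start, end, bases, qual).
#' @param path output path.
#' @param ref_name,ref_length reference name and length for the header.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, ref_name = "mito", ref_length = NULL) {
  if (is.null(ref_length)) ref_length <- max(reads$end)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", ref_name, ref_length)), con)
  ord <- order(reads$start, reads$end)
  r <- reads[ord, , drop = FALSE]
  writeLines(sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\tBC:Z:%s",
                     r$read_id, ref_name, r$start + 1L, r$end - r$start,
                     r$bases, r$qual, r$barcode), con)
  invisible(path)
}

#' Read mapped reads from SAM text
#'
#' Accepts the subset of SAM this pipeline emits: single-end, fully aligned
#' (single `M` CIGAR) records with the barcode in the `BC` tag (or, as a
#' fallback, a `_BC` read-name suffix). Unmapped records are skipped.
#'
#' @param path SAM file path.
#' @return a read table (read_id, barcode, start, end, bases, qual).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0)
    return(new_mapped_reads(character(), character(), integer(), integer(),
                            character(), character()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(f, function(x) x[3] != "*", logical(1))
  f <- f[keep]
  bc <- vapply(f, function(x) {
    tag <- grep("^BC:Z:", x[-(1:11)], value = TRUE)
    if (length(tag)) sub("^BC:Z:", "", tag[1]) else sub(".*_", "", x[1])
  }, character(1))
  start <- vapply(f, function(x) as.integer(x[4]), integer(1)) - 1L
  bases <- vapply(f, `[`, character(1), 10)
  new_mapped_reads(read_id = vapply(f, `[`, character(1), 1), barcode = bc,
                   start = start, end = start + nchar(bases), bases = bases,
                   qual = vapply(f, `[`, character(1), 11))
}

#' Read a feature annotation from a BED-like table
#'
#' Expects BED6-style columns (chrom, start 0-based, end, name, score,
#' strand `+`/`-`) plus a seventh column holding the partition category
#' (`protein_coding`, `control_region`, `tRNA`, `rRNA`).
#'
#' @param path tab-separated file path.
#' @return a feature table (see [feature_table()]).
#' @export
read_features_bed <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 7) stop("expected 7 BED columns (BED6 + category)")
  feature_table(name = x[[4]], start = x[[2]], end = x[[3]],
                strand = ifelse(x[[6]] == "-", "reverse", "forward"),
                category = x[[7]])
}

#' @rdname read_features_bed
#' @param features a feature table.
#' @param chrom reference name for column 1.
#' @export
write_features_bed <- function(features, path, chrom = "mito") {
  x <- data.frame(chrom = chrom, start = features$start, end = features$end,
                  name = features$name, score = 0,
                  strand = ifelse(features$strand == "reverse", "-", "+"),
                  category = features$category)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write simulation truth as JSON
#'
#' @param truth a truth table (from [simulate_reads()] or
#'   [pool_with_bleed()]), or a full `pooled_reads` object.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  if (inherits(truth, "pooled_reads") || inherits(truth, "simulated_reads"))
    truth <- truth$truth
  jsonlite::write_json(truth, path, dataframe = "rows", na = "null")
  invisible(path)
}
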