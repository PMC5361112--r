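#' Extract one annotated feature from a consensus genome
#'
#' Cuts the feature's interval out of a reference-coordinate genome and
#' reverse-complements it when the feature lies on the reverse strand (N
#' maps to N under complement). An origin-wrapping feature (`end <= start`
#' on a circular reference) is extracted as suffix + prefix.
#'
#' @param genome sequence string in reference coordinates (A/C/G/T/N).
#' @param feature a one-row feature table (see [feature_table()]).
#' @return the feature's sequence, 5' to 3' on its own strand.
#' @export
extract_feature <- function(genome, feature) {
  L <- nchar(genome)
  if (feature$start < 0 || feature$start >= L ||
      feature$end < 0 || feature$end > L)
    stop("feature ", feature$name, " outside genome bounds")
  s <- if (feature$end > feature$start) {
    substr(genome, feature$start + 1L, feature$end)
  } else {
    paste0(substr(genome, feature$start + 1L, L),
           if (feature$end > 0) substr(genome, 1L, feature$end) else "")
  }
  if (feature$strand == "reverse") reverse_complement(s) else s
}

#' Concatenate consensus genomes into the four partition blocks
#'
#' For each partition category (protein-coding, control region, tRNA,
#' rRNA), extracts that category's features from every genome in ascending
#' reference-start order, reverse-complementing reverse-strand genes, and
#' concatenates them into one block per sample. All four blocks are emitted
#' even when a category has no features (zero-length block). Inter-genic
#' sites not covered by any feature are dropped.
#'
#' @param genomes named character vector or named list, sample ->
#'   reference-coordinate sequence (all of reference length).
#' @param annotation a feature table, or an [annotated_reference()].
#' @return a list of class `partitioned_alignment`: `blocks` (category ->
#'   named character vector of per-sample block sequences), `map` (feature
#'   coordinates within each block: category, name, block_start, block_end
#'   0-based half-open, ref_start, ref_end, strand, wraps) and `categories`.
#' @export
concatenate_partitions <- function(genomes, annotation) {
  features <- if (inherits(annotation, "annotated_reference"))
    annotation$features else annotation
  genomes <- unlist(genomes)
  if (is.null(names(genomes)) || any(names(genomes) == ""))
    stop("genomes must be named by sample")
  lens <- nchar(genomes)
  if (length(unique(lens)) > 1)
    stop("genome length mismatch for sample(s): ",
         paste(names(genomes)[lens != lens[1]], collapse = ", "))
  L <- lens[[1]]
  flen <- feature_length(features, L)
  blocks <- list()
  map_rows <- list()
  for (cat in FEATURE_CATEGORIES) {
    rows <- which(features$category == cat)
    rows <- rows[order(features$start[rows])]
    blocks[[cat]] <- setNames(rep("", length(genomes)), names(genomes))
    offset <- 0L
    for (r in rows) {
      f <- features[r, ]
      piece <- vapply(genomes, extract_feature, character(1), feature = f)
      blocks[[cat]] <- paste0(blocks[[cat]], piece)
      map_rows[[length(map_rows) + 1L]] <- data.frame(
        category = cat, name = f$name, block_start = offset,
        block_end = offset + flen[r], ref_start = f$start, ref_end = f$end,
        strand = f$strand, wraps = f$end <= f$start,
        stringsAsFactors = FALSE)
      offset <- offset + flen[r]
    }
    names(blocks[[cat]]) <- names(genomes)
  }
  map <- if (length(map_rows)) do.call(rbind, map_rows) else
    data.frame(category = character(), name = character(),
               block_start = integer(), block_end = integer(),
               ref_start = integer(), ref_end = integer(),
               strand = character(), wraps = logical())
  structure(list(blocks = blocks, map = map,
                 categories = FEATURE_CATEGORIES),
            class = "partitioned_alignment")
}

#' @export
print.partitioned_alignment <- function(x, ...) {
  for (cat in x$categories)
    cat(sprintf("%-15s %5d bp x %d sample(s)\n", cat,
                if (length(x$blocks[[cat]])) nchar(x$blocks[[cat]][[1]]) else 0L,
                length(x$blocks[[cat]])))
  invisible(x)
}

#' Write a partitioned alignment as NEXUS with charset partitions
#'
#' Concatenates the category blocks in fixed order and writes a NEXUS file
#' whose `sets` block carries one `charset` line per non-empty category —
#' the hand-off format for downstream partitioned phylogenetic dating.
#'
#' @param pa a [concatenate_partitions()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_partitions_nexus <- function(pa, path) {
  samples <- names(pa$blocks[[1]])
  full <- setNames(rep("", length(samples)), samples)
  charsets <- character()
  offset <- 0L
  for (cat in pa$categories) {
    blk <- pa$blocks[[cat]]
    w <- if (length(blk)) nchar(blk[[1]]) else 0L
    if (w > 0) {
      full <- paste0(full, blk)
      charsets <- c(charsets, sprintf("    charset %s = %d-%d;",
                                      cat, offset + 1L, offset + w))
      offset <- offset + w
    }
  }
  names(full) <- samples
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "BEGIN DATA;",
               sprintf("    DIMENSIONS NTAX=%d NCHAR=%d;",
                       length(samples), offset),
               "    FORMAT DATATYPE=DNA MISSING=N GAP=-;", "    MATRIX"),
             con)
  writeLines(sprintf("    %s  %s", format(samples), full), con)
  writeLines(c("    ;", "END;", "", "BEGIN SETS;", charsets, "END;"), con)
  invisible(path)
}
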