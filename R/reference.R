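DNA_BASES <- c("A", "C", "G", "T")
FEATURE_CATEGORIES <- c("protein_coding", "control_region", "tRNA", "rRNA")

str_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
chars_str <- function(x) paste(x, collapse = "")

#' Build a feature table for an annotated reference
#'
#' Features live in the 0-based, half-open coordinate frame of the reference.
#' A feature with `end <= start` is interpreted as wrapping across the origin
#' of a circular reference (suffix then prefix).
#'
#' @param name character vector of feature identifiers.
#' @param start,end integer vectors, 0-based half-open interval per feature.
#' @param strand character vector, `"forward"` or `"reverse"`.
#' @param category character vector; one of `"protein_coding"`,
#'   `"control_region"`, `"tRNA"`, `"rRNA"`.
#' @return a `data.frame` with one row per feature.
#' @export
feature_table <- function(name, start, end, strand, category) {
  stopifnot(length(name) == length(start), length(start) == length(end),
            length(end) == length(strand), length(strand) == length(category))
  if (!all(strand %in% c("forward", "reverse")))
    stop("strand must be 'forward' or 'reverse'")
  if (!all(category %in% FEATURE_CATEGORIES))
    stop("unknown feature category: ",
         chars_str(setdiff(category, FEATURE_CATEGORIES)))
  data.frame(name = as.character(name), start = as.integer(start),
             end = as.integer(end), strand = as.character(strand),
             category = as.character(category), stringsAsFactors = FALSE)
}

#' Construct an annotated mitochondrial reference
#'
#' Bundles a reference sequence with a typed, stranded feature annotation.
#' This is the shared coordinate frame for every downstream stage: reads are
#' mapped to it, pileups are indexed by it, and partitions are cut from it.
#'
#' @param sequence a single string over A/C/G/T.
#' @param features a feature table as returned by [feature_table()]; may have
#'   zero rows.
#' @param is_circular logical; mitochondria are circular, so `TRUE` by
#'   default. A wrapping feature (`end <= start`) is only legal when set.
#' @return an object of class `annotated_reference`.
#' @export
annotated_reference <- function(sequence, features = feature_table(
                                  character(), integer(), integer(),
                                  character(), character()),
                                is_circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  len <- nchar(sequence)
  if (len == 0) stop("reference sequence must be non-empty")
  if (!grepl("^[ACGT]+$", sequence))
    stop("reference sequence must contain only A, C, G, T")
  validate_features(features, len, is_circular)
  structure(list(sequence = sequence, length = len,
                 is_circular = is_circular, features = features),
            class = "annotated_reference")
}

feature_length <- function(features, ref_length) {
  ifelse(features$end > features$start,
         features$end - features$start,
         (ref_length - features$start) + features$end)
}

validate_features <- function(features, ref_length, is_circular) {
  if (nrow(features) == 0) return(invisible(TRUE))
  if (any(features$start < 0) || any(features$start >= ref_length) ||
      any(features$end < 0) || any(features$end > ref_length))
    stop("feature interval outside [0, reference length)")
  wraps <- features$end <= features$start
  if (any(wraps) && !is_circular)
    stop("wrapping feature on a linear reference: ",
         paste(features$name[wraps], collapse = ", "))
  if (sum(wraps) > 1) stop("at most one origin-wrapping feature is supported")
  # occupancy check on the (possibly circular) coordinate line
  occ <- logical(ref_length)
  for (i in seq_len(nrow(features))) {
    pos <- feature_positions(features[i, ], ref_length)
    if (any(occ[pos + 1L])) stop("features overlap at feature ", features$name[i])
    occ[pos + 1L] <- TRUE
  }
  invisible(TRUE)
}

# 0-based positions covered by one feature row, in reading order
feature_positions <- function(feature, ref_length) {
  if (feature$end > feature$start) {
    seq.int(feature$start, feature$end - 1L)
  } else {
    c(seq.int(feature$start, ref_length - 1L),
      if (feature$end > 0) seq.int(0L, feature$end - 1L) else integer())
  }
}

#' @export
print.annotated_reference <- function(x, ...) {
  cat(sprintf("Annotated %s reference, %d bp, %d feature(s)\n",
              if (x$is_circular) "circular" else "linear",
              x$length, nrow(x$features)))
  if (nrow(x$features) > 0)
    print(table(x$features$category))
  invisible(x)
}

#' Generate a random annotated reference
#'
#' Draws a uniform-random sequence and places non-overlapping features of all
#' four partition categories (protein-coding, control region, tRNA, rRNA) at
#' random positions with random strands. Deterministic for a given seed.
#'
#' @param length reference length in bp (>= 200).
#' @param n_features_per_category number of features of each category.
#' @param seed integer seed.
#' @param feature_length_range integer vector of length 2; each feature's
#'   length is drawn uniformly from this range.
#' @return an [annotated_reference()].
#' @export
generate_reference <- function(length, n_features_per_category = 1, seed = 1,
                               feature_length_range = c(40L, 120L)) {
  if (length <= 0) stop("reference length must be positive")
  if (length < 200) stop("reference length must be at least 200 bp")
  if (n_features_per_category < 1) stop("need at least one feature per category")
  withr::with_seed(seed, {
    seq_chars <- sample(DNA_BASES, length, replace = TRUE)
    k <- 4L * as.integer(n_features_per_category)
    lens <- sample(seq.int(feature_length_range[1], feature_length_range[2]),
                   k, replace = TRUE)
    if (sum(lens) > length)
      stop("reference too short to host the requested features without overlap")
    # distribute the slack as random gaps before each feature
    slack <- length - sum(lens)
    cuts <- sort(sample.int(slack + 1L, k, replace = TRUE) - 1L)
    starts <- cuts + c(0L, cumsum(lens))[seq_len(k)]
    cats <- sample(rep(FEATURE_CATEGORIES, n_features_per_category))
    feats <- feature_table(
      name = sprintf("%s_%02d", cats, stats::ave(seq_len(k), cats, FUN = seq_along)),
      start = starts, end = starts + lens,
      strand = sample(c("forward", "reverse"), k, replace = TRUE),
      category = cats)
    feats <- feats[order(feats$start), , drop = FALSE]
    rownames(feats) <- NULL
    annotated_reference(chars_str(seq_chars), feats, is_circular = TRUE)
  })
}

#' Mutate a reference into a sample haplotype
#'
#' Introduces exactly `n_substitutions` substitutions at positions chosen
#' without replacement; each substituted base is replaced by a different base
#' drawn uniformly. The result is the ground-truth haplotype the consensus
#' pipeline is expected to recover.
#'
#' @param ref an [annotated_reference()] or a plain sequence string.
#' @param n_substitutions number of substituted sites (Hamming distance of
#'   the result from the reference).
#' @param seed integer seed.
#' @return a sequence string of the same length as the reference.
#' @export
mutate_haplotype <- function(ref, n_substitutions, seed = 1) {
  seq <- if (inherits(ref, "annotated_reference")) ref$sequence else ref
  len <- nchar(seq)
  if (n_substitutions < 0 || n_substitutions > len)
    stop("n_substitutions must be between 0 and the reference length")
  if (n_substitutions == 0) return(seq)
  withr::with_seed(seed, {
    chars <- str_chars(seq)
    pos <- sample.int(len, n_substitutions)
    for (p in pos)
      chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
    chars_str(chars)
  })
}

#' Reverse complement of a sequence with N/gap pass-through
#'
#' @param seq sequence string over A/C/G/T/N/-.
#' @return the reverse-complemented string; N and `-` map to themselves.
#' @export
reverse_complement <- function(seq) {
  if (nchar(seq) == 0) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
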