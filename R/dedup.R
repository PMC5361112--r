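#' Collapse one coordinate cluster into a consensus read
#'
#' All PCR copies of a molecule share the molecule's start and end
#' coordinates, so each coordinate cluster is reduced to a single consensus
#' sequence. Columns line up by offset from the shared start
#' (substitution-only world). Each column takes the majority base over
#' members; ties on count are broken by the larger summed Phred quality of
#' the tied bases; a tie that survives the quality comparison becomes N.
#' N bases in members are excluded from the vote.
#'
#' @param cluster a cluster from [cluster_reads()] (all members share
#'   (start, end)).
#' @return a one-row data.frame: start, end, bases, support (number of
#'   collapsed copies).
#' @export
collapse_cluster <- function(cluster) {
  members <- cluster$members
  n <- nrow(members)
  if (is.null(n) || n == 0) stop("cannot collapse an empty cluster")
  len <- cluster$end - cluster$start
  if (any(members$start != cluster$start | members$end != cluster$end))
    stop("cluster members disagree on (start, end)")
  if (n == 1) {
    cons <- members$bases
  } else {
    base_mat <- matrix(unlist(strsplit(members$bases, "", fixed = TRUE)),
                       nrow = n, ncol = len, byrow = TRUE)
    qual_mat <- matrix(unlist(lapply(members$qual, phred_ints)),
                       nrow = n, ncol = len, byrow = TRUE)
    cons_chars <- vapply(seq_len(len), function(j) {
      col <- base_mat[, j]
      ok <- col %in% DNA_BASES
      if (!any(ok)) return("N")
      cnt <- table(col[ok])
      top <- names(cnt)[cnt == max(cnt)]
      if (length(top) == 1) return(top)
      qsum <- vapply(top, function(b) sum(qual_mat[ok, j][col[ok] == b]),
                     numeric(1))
      best <- top[qsum == max(qsum)]
      if (length(best) == 1) best else "N"
    }, character(1))
    cons <- chars_str(cons_chars)
  }
  data.frame(start = cluster$start, end = cluster$end, bases = cons,
             support = n, stringsAsFactors = FALSE)
}

#' Remove PCR duplicates by coordinate-cluster consensus
#'
#' Collapses the reads of one sample (post de-multiplexing) into one
#' consensus read per distinct (start, end) coordinate pair. Deterministic
#' and invariant to input order; applying it to its own output is a no-op.
#'
#' @param reads a read table for one sample, or a list of clusters from
#'   [cluster_reads()] / [demultiplex()].
#' @return a data.frame of consensus reads (start, end, bases, support),
#'   ordered by (start, end), plus a `duplicate_fraction` attribute
#'   (fraction of input copies beyond the first of each molecule).
#' @export
deduplicate <- function(reads) {
  clusters <- if (is.data.frame(reads)) {
    if (is.null(reads$qual))
      reads$qual <- vapply(nchar(reads$bases),
                           function(l) phred_string(rep(30L, l)), character(1))
    if (is.null(reads$barcode)) reads$barcode <- "S"
    cluster_reads(reads)
  } else reads
  if (length(clusters) == 0)
    return(structure(data.frame(start = integer(), end = integer(),
                                bases = character(), support = integer()),
                     duplicate_fraction = NA_real_))
  out <- do.call(rbind, c(lapply(clusters, collapse_cluster),
                          list(make.row.names = FALSE)))
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  total <- sum(out$support)
  attr(out, "duplicate_fraction") <- (total - nrow(out)) / total
  out
}
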