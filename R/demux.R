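#' Read filtering and de-multiplexing policy
#'
#' Thresholds for the quality/length filter and the conservative
#' coordinate-cluster de-multiplexing that guards against barcode bleeding:
#' reads shorter than `min_read_length` or with more than
#' `max_low_quality_bases` bases below `low_quality_threshold` are dropped;
#' coordinate clusters observed fewer than `min_cluster_occurrence` times
#' are discarded, and surviving clusters are assigned to their strictly most
#' frequent barcode (ties discard the cluster).
#'
#' @param min_read_length minimum retained read length (bp).
#' @param max_low_quality_bases maximum tolerated count of low-quality bases
#'   per read.
#' @param low_quality_threshold Phred score below which a base counts as
#'   low-quality.
#' @param min_cluster_occurrence minimum number of read copies a coordinate
#'   cluster must contain to be retained.
#' @return a list of class `filter_policy`.
#' @export
filter_policy <- function(min_read_length = 30L,
                          max_low_quality_bases = 5L,
                          low_quality_threshold = 10L,
                          min_cluster_occurrence = 3L) {
  p <- list(min_read_length = as.integer(min_read_length),
            max_low_quality_bases = as.integer(max_low_quality_bases),
            low_quality_threshold = as.integer(low_quality_threshold),
            min_cluster_occurrence = as.integer(min_cluster_occurrence))
  if (p$min_read_length < 1 || p$low_quality_threshold < 1 ||
      p$min_cluster_occurrence < 1 || p$max_low_quality_bases < 0)
    stop("invalid filter_policy thresholds")
  class(p) <- "filter_policy"
  p
}

#' Quality and length filter for mapped reads
#'
#' Retains a read iff its count of bases below the low-quality Phred
#' threshold does not exceed the allowance *and* its length meets the
#' minimum. Run before clustering, so undersized or low-quality reads never
#' count toward cluster occurrence.
#'
#' @param reads a read table (read_id, barcode, start, end, bases, qual).
#' @param policy a [filter_policy()].
#' @return a list with `reads` (retained rows) and `report`, a one-row
#'   data.frame of attrition counts (`input`, `removed_short`,
#'   `removed_lowq`, `removed`, `retained`; a read failing both criteria is
#'   counted under each but once in `removed`).
#' @export
quality_filter <- function(reads, policy = filter_policy()) {
  len <- reads$end - reads$start
  bad <- nchar(reads$bases) != len | nchar(reads$qual) != len
  if (any(bad))
    stop("malformed read(s), bases/qual length mismatch: ",
         paste(head(reads$read_id[bad], 5), collapse = ", "))
  n_lowq <- vapply(reads$qual, function(q)
    sum(phred_ints(q) < policy$low_quality_threshold), integer(1),
    USE.NAMES = FALSE)
  too_short <- len < policy$min_read_length
  too_lowq <- n_lowq > policy$max_low_quality_bases
  keep <- !too_short & !too_lowq
  list(reads = reads[keep, , drop = FALSE],
       report = data.frame(input = nrow(reads),
                           removed_short = sum(too_short),
                           removed_lowq = sum(too_lowq),
                           removed = sum(!keep), retained = sum(keep)))
}

#' Group mapped reads into coordinate clusters
#'
#' Partitions reads by their exact (start, end) alignment coordinates.
#' Reads sharing both coordinates are presumed PCR copies of one original
#' molecule (plus any bleed copies recorded under a wrong barcode).
#'
#' @param reads a read table.
#' @return a list of clusters, each a list with `start`, `end`, `members`
#'   (read table rows) and `barcode_counts` (named integer vector), ordered
#'   by (start, end).
#' @export
cluster_reads <- function(reads) {
  if (is.null(reads) || nrow(reads) == 0) return(list())
  reads$start <- as.integer(reads$start)
  reads$end <- as.integer(reads$end)
  key <- paste(reads$start, reads$end, sep = ":")
  idx <- split(seq_len(nrow(reads)), key)
  ord <- order(vapply(idx, function(i) reads$start[i[1]], integer(1)),
               vapply(idx, function(i) reads$end[i[1]], integer(1)))
  lapply(idx[ord], function(i) {
    members <- reads[i, , drop = FALSE]
    rownames(members) <- NULL
    counts <- table(members$barcode)
    list(start = members$start[1], end = members$end[1], members = members,
         barcode_counts = setNames(as.integer(counts), names(counts)))
  })
}

#' Conservative de-multiplexing of coordinate clusters
#'
#' Applies the two cluster-level criteria of the conservative barcode-bleed
#' filter: a cluster observed fewer than `min_cluster_occurrence` times is
#' discarded; otherwise the whole cluster is assigned to its strictly most
#' frequent barcode, with minority-barcode members treated as bleed copies
#' of the winner's molecule (kept and reassigned by default, or dropped
#' with `minority = "drop"`); a cluster whose maximum barcode count is tied
#' between several barcodes is discarded.
#'
#' @param clusters list of clusters from [cluster_reads()], one experimental
#'   batch.
#' @param policy a [filter_policy()].
#' @param minority `"keep"` (reassign minority members to the winning
#'   sample) or `"drop"` (discard them).
#' @return a list with `by_sample` (map barcode -> list of retained
#'   clusters, members' barcode set to the winner) and `log`, a data.frame
#'   with one row per input cluster: start, end, size, barcode counts,
#'   fate (`retained`/`discarded`), reason (`assigned`/`too_few`/
#'   `barcode_tie`), winner.
#' @export
demultiplex <- function(clusters, policy = filter_policy(),
                        minority = c("keep", "drop")) {
  minority <- match.arg(minority)
  n <- length(clusters)
  l_start <- integer(n); l_end <- integer(n); l_size <- integer(n)
  l_counts <- character(n); l_fate <- character(n)
  l_reason <- character(n); l_winner <- rep(NA_character_, n)
  by_sample <- list()
  for (i in seq_len(n)) {
    cl <- clusters[[i]]
    size <- nrow(cl$members)
    counts <- cl$barcode_counts
    l_start[i] <- cl$start; l_end[i] <- cl$end; l_size[i] <- size
    l_counts[i] <- paste(sprintf("%s=%d", names(counts), counts),
                         collapse = ";")
    if (size < policy$min_cluster_occurrence) {
      l_fate[i] <- "discarded"; l_reason[i] <- "too_few"
    } else {
      mx <- max(counts)
      winners <- names(counts)[counts == mx]
      if (length(winners) > 1) {
        l_fate[i] <- "discarded"; l_reason[i] <- "barcode_tie"
      } else {
        l_fate[i] <- "retained"; l_reason[i] <- "assigned"
        l_winner[i] <- winners
        out_cl <- cl
        if (minority == "drop") {
          keep <- out_cl$members$barcode == winners
          out_cl$members <- out_cl$members[keep, , drop = FALSE]
        }
        out_cl$members$barcode <- winners
        out_cl$barcode_counts <- setNames(nrow(out_cl$members), winners)
        by_sample[[winners]] <- c(by_sample[[winners]], list(out_cl))
      }
    }
  }
  log <- data.frame(start = l_start, end = l_end, size = l_size,
                    barcode_counts = l_counts, fate = l_fate,
                    reason = l_reason, winner = l_winner,
                    stringsAsFactors = FALSE)
  list(by_sample = by_sample, log = log)
}

#' Run filter, clustering and de-multiplexing in one pass
#'
#' @param reads pooled read table for one experimental batch.
#' @param policy a [filter_policy()].
#' @param minority see [demultiplex()].
#' @return a list with `by_sample`, `demux_log` and `filter_report`.
#' @export
demux_batch <- function(reads, policy = filter_policy(),
                        minority = c("keep", "drop")) {
  qf <- quality_filter(reads, policy)
  dm <- demultiplex(cluster_reads(qf$reads), policy, minority)
  list(by_sample = dm$by_sample, demux_log = dm$log,
       filter_report = qf$report)
}
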