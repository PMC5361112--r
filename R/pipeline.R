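#' Run the full consensus pipeline on a pooled batch
#'
#' Quality/length filtering, conservative coordinate-cluster
#' de-multiplexing, PCR-duplicate collapse, pileup construction and
#' two-tier consensus calling, for every sample of a pooled batch.
#'
#' @param reads pooled read table (e.g. `pool$reads` from
#'   [pool_with_bleed()] or [read_sam()]).
#' @param reference_length reference length (bp), or an
#'   [annotated_reference()].
#' @param policy a [filter_policy()].
#' @param policies list of [calling_policy()] bundles to apply (default:
#'   relaxed and strict).
#' @param minority fate of minority-barcode reads in retained clusters,
#'   see [demultiplex()].
#' @return a list of class `pipeline_result`: `samples` (per barcode: a
#'   list with `unique_reads`, `pileup`, and one `consensus_genome` per
#'   policy name), `demux_log`, `filter_report`.
#' @export
run_pipeline <- function(reads, reference_length,
                         policy = filter_policy(),
                         policies = list(relaxed = relaxed_policy(),
                                         strict = strict_policy()),
                         minority = c("keep", "drop")) {
  if (inherits(reference_length, "annotated_reference"))
    reference_length <- reference_length$length
  dm <- demux_batch(reads, policy, minority)
  samples <- lapply(dm$by_sample, function(clusters) {
    uniq <- deduplicate(clusters)
    pileup <- build_pileup(uniq, reference_length)
    out <- list(unique_reads = uniq, pileup = pileup)
    for (nm in names(policies))
      out[[nm]] <- call_consensus(pileup, policies[[nm]])
    out
  })
  structure(list(samples = samples, demux_log = dm$demux_log,
                 filter_report = dm$filter_report),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d sample(s); %d/%d cluster(s) retained\n",
              length(x$samples), sum(x$demux_log$fate == "retained"),
              nrow(x$demux_log)))
  for (bc in names(x$samples)) {
    s <- x$samples[[bc]]
    gens <- Filter(function(e) inherits(e, "consensus_genome"), s)
    cat(sprintf("  %s: %d unique reads; %s\n", bc, nrow(s$unique_reads),
                paste(vapply(gens, function(g)
                  sprintf("%s %.1f%%N(%s)", g$policy,
                          100 * g$missing_fraction,
                          if (g$included) "in" else "out"), character(1)),
                  collapse = ", ")))
  }
  invisible(x)
}

#' Write per-policy consensus FASTA for a pipeline result
#'
#' One record per sample per policy; the policy name is carried in the
#' description line together with the inclusion verdict.
#'
#' @param result a [run_pipeline()] result.
#' @param path output FASTA path.
#' @param only_included drop genomes that fail their policy's inclusion
#'   bound.
#' @export
write_consensus_fasta <- function(result, path, only_included = FALSE) {
  seqs <- character()
  for (bc in names(result$samples)) {
    for (e in result$samples[[bc]]) {
      if (!inherits(e, "consensus_genome")) next
      if (only_included && !e$included) next
      nm <- sprintf("%s policy=%s missing=%.4f included=%s", bc, e$policy,
                    e$missing_fraction, e$included)
      seqs[nm] <- e$sequence
    }
  }
  write_fasta(seqs, path)
}
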