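#' Base-calling policy (relaxed or strict)
#'
#' A named bundle of the three thresholds that drive consensus calling and
#' genome inclusion. Two standard bundles compensate differently for the
#' deaminated bases present in non-UDG-treated ancient-DNA libraries:
#'
#' * **relaxed** — a base is called where at least 3 non-duplicate reads
#'   cover the site and the majority base has frequency strictly greater
#'   than 1/3; a genome enters the alignment if no more than 33\% of its
#'   sites are N.
#' * **strict** — at least 10-fold unique coverage and majority frequency
#'   strictly greater than 90\%; no more than 20\% of sites missing.
#'
#' "Higher than 33\%" is implemented as strictly greater than 1/3 (one in
#' three), so a perfect three-way split is never called; both majority
#' bounds are exclusive, both inclusion bounds inclusive.
#'
#' @param name policy name.
#' @param min_depth minimum unique-read depth at a site.
#' @param majority_fraction exclusive lower bound on the majority base's
#'   frequency.
#' @param max_missing_fraction inclusive upper bound on the N fraction for
#'   genome inclusion.
#' @return a list of class `calling_policy`.
#' @export
calling_policy <- function(name, min_depth, majority_fraction,
                           max_missing_fraction) {
  if (min_depth < 1) stop("min_depth must be at least 1")
  if (majority_fraction <= 0 || majority_fraction >= 1)
    stop("majority_fraction must be in (0, 1)")
  if (max_missing_fraction <= 0 || max_missing_fraction >= 1)
    stop("max_missing_fraction must be in (0, 1)")
  structure(list(name = name, min_depth = as.integer(min_depth),
                 majority_fraction = majority_fraction,
                 max_missing_fraction = max_missing_fraction,
                 majority_ratio = rationalize(majority_fraction),
                 missing_ratio = rationalize(max_missing_fraction)),
            class = "calling_policy")
}

# small-denominator rational approximation by continued fractions, so that
# threshold comparisons (count/depth vs p/q) can be done in exact integer
# arithmetic: "higher than 1/3" must not call a perfect three-way split.
rationalize <- function(x, tol = 1e-9, max_den = 1e6) {
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; r <- x
  repeat {
    a <- floor(r)
    p <- a * p1 + p0; q <- a * q1 + q0
    if (q > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p; q1 <- q
    if (abs(x - p / q) < tol) break
    r <- 1 / (r - a)
    if (!is.finite(r)) break
  }
  c(num = p1, den = q1)
}

#' @rdname calling_policy
#' @export
relaxed_policy <- function() calling_policy("relaxed", 3L, 1 / 3, 0.33)

#' @rdname calling_policy
#' @export
strict_policy <- function() calling_policy("strict", 10L, 0.90, 0.20)

#' Build a per-site pileup from unique reads
#'
#' Counts A/C/G/T occurrences at every reference position over the unique
#' (post-deduplication) reads covering it. N bases contribute neither to
#' the counts nor to the depth. A direct counting pass over exact
#' coordinates; no realignment.
#'
#' @param unique_reads consensus reads from [deduplicate()] (start, end,
#'   bases) or any read table with those columns.
#' @param reference_length length of the reference (bp).
#' @return a list of class `site_pileup` with `counts` (4 x L integer
#'   matrix, rows A/C/G/T) and `depth` (length-L integer vector).
#' @export
build_pileup <- function(unique_reads, reference_length) {
  L <- as.integer(reference_length)
  counts <- matrix(0L, nrow = 4, ncol = L, dimnames = list(DNA_BASES, NULL))
  if (nrow(unique_reads) > 0) {
    if (any(unique_reads$start < 0 | unique_reads$end > L |
            unique_reads$start >= unique_reads$end))
      stop("read outside [0, reference_length)")
    lens <- unique_reads$end - unique_reads$start
    pos <- unlist(lapply(seq_len(nrow(unique_reads)), function(i)
      seq.int(unique_reads$start[i] + 1L, unique_reads$end[i])))
    base <- unlist(strsplit(unique_reads$bases, "", fixed = TRUE))
    ok <- base %in% DNA_BASES
    bi <- match(base[ok], DNA_BASES)
    tab <- tabulate((pos[ok] - 1L) * 4L + bi, nbins = 4L * L)
    counts[] <- tab
  }
  structure(list(counts = counts, depth = as.integer(colSums(counts)),
                 reference_length = L), class = "site_pileup")
}

#' @export
print.site_pileup <- function(x, ...) {
  cat(sprintf("site_pileup over %d bp; mean depth %.1f, %d uncovered site(s)\n",
              x$reference_length, mean(x$depth), sum(x$depth == 0)))
  invisible(x)
}

#' Call the consensus base at one site
#'
#' Returns the unique maximal base `b` iff the site's depth reaches the
#' policy minimum, `counts[b]/depth` strictly exceeds the majority bound,
#' and `b` is the sole maximum; otherwise N.
#'
#' @param counts named numeric vector of A/C/G/T counts at one site
#'   (missing names count as zero).
#' @param policy a [calling_policy()].
#' @return a single character, one of A/C/G/T/N.
#' @export
call_base <- function(counts, policy) {
  full <- setNames(numeric(4), DNA_BASES)
  full[names(counts)] <- counts
  depth <- sum(full)
  if (depth < policy$min_depth) return("N")
  mx <- max(full)
  top <- DNA_BASES[full == mx]
  if (length(top) > 1) return("N")
  r <- policy$majority_ratio
  if (mx * r["den"] > r["num"] * depth) top else "N"
}

#' Call a consensus genome from a pileup
#'
#' Applies [call_base()] at every reference site (uncovered sites are N),
#' computes the missing fraction over the full reference length, and sets
#' the inclusion verdict by comparison with the policy's missingness bound.
#'
#' @param pileup a [build_pileup()] result.
#' @param policy a [calling_policy()].
#' @return a list of class `consensus_genome`: `sequence` (string over
#'   A/C/G/T/N of reference length), `missing_fraction`, `policy` (name),
#'   `included` (flag), `called_sites` (count of non-N sites).
#' @export
call_consensus <- function(pileup, policy) {
  cnt <- pileup$counts
  depth <- pileup$depth
  mx <- apply(cnt, 2, max)
  n_at_max <- colSums(cnt == rep(mx, each = 4))
  top <- DNA_BASES[apply(cnt, 2, which.max)]
  r <- policy$majority_ratio
  callable <- depth >= policy$min_depth & n_at_max == 1 &
    mx * r["den"] > r["num"] * depth
  calls <- ifelse(callable, top, "N")
  n_missing <- sum(calls == "N")
  L <- pileup$reference_length
  m <- policy$missing_ratio
  structure(list(sequence = chars_str(calls),
                 missing_fraction = n_missing / L,
                 policy = policy$name,
                 included = n_missing * m["den"] <= m["num"] * L,
                 called_sites = L - n_missing),
            class = "consensus_genome")
}

#' @export
print.consensus_genome <- function(x, ...) {
  cat(sprintf("consensus_genome [%s]: %d bp, %.1f%% N, %s\n", x$policy,
              nchar(x$sequence), 100 * x$missing_fraction,
              if (x$included) "included" else "excluded"))
  invisible(x)
}

#' Export a pileup as a VCF-like site table
#'
#' @param pileup a [build_pileup()] result.
#' @return a data.frame with 1-based `pos`, per-base counts and `depth`.
#' @export
pileup_table <- function(pileup) {
  data.frame(pos = seq_len(pileup$reference_length),
             A = pileup$counts["A", ], C = pileup$counts["C", ],
             G = pileup$counts["G", ], T = pileup$counts["T", ],
             depth = pileup$depth)
}
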