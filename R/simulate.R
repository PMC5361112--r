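#' Parameter bundle for the ancient-DNA read simulator
#'
#' The defaults describe a typical non-UDG-treated ancient-DNA library
#' captured in a pooled batch: short fragments (truncated-normal lengths,
#' mean 60 bp on \[30, 150\]), terminal cytosine deamination decaying
#' geometrically into the read (10\% at the first position, halving per
#' position), a low per-base sequencing error rate, on average two extra PCR
#' copies per unique molecule, and a 2\% chance that any emitted copy is
#' recorded under another sample's barcode.
#'
#' @param coverage mean fold-coverage of unique molecules (x).
#' @param fragment_length_mean,fragment_length_sd fragment length
#'   distribution (bp) before truncation.
#' @param min_fragment,max_fragment truncation bounds (bp).
#' @param damage_rate probability of C->T deamination at the 5' terminal
#'   position (and G->A at the 3' terminal position on the read as
#'   sequenced).
#' @param damage_decay geometric decay of the damage probability per
#'   position moving into the read; in \[0, 1).
#' @param error_rate independent per-base sequencing error probability,
#'   applied to every emitted copy.
#' @param duplication_rate expected number of extra PCR copies per unique
#'   molecule (Poisson mean).
#' @param bleed_rate probability that an emitted copy is recorded under a
#'   wrong barcode when samples are pooled.
#' @param base_quality Phred score assigned to ordinary bases.
#' @param lowq_fraction fraction of bases downgraded to `lowq_quality`, so
#'   the quality filter has something to act on.
#' @param lowq_quality Phred score of downgraded bases (below the default
#'   filtering threshold of 10).
#' @return a list of class `simulation_params`.
#' @export
simulation_params <- function(coverage = 30,
                              fragment_length_mean = 60,
                              fragment_length_sd = 15,
                              min_fragment = 30,
                              max_fragment = 150,
                              damage_rate = 0.1,
                              damage_decay = 0.5,
                              error_rate = 0.002,
                              duplication_rate = 2,
                              bleed_rate = 0.02,
                              base_quality = 30L,
                              lowq_fraction = 0,
                              lowq_quality = 2L) {
  p <- list(coverage = coverage,
            fragment_length_mean = fragment_length_mean,
            fragment_length_sd = fragment_length_sd,
            min_fragment = as.integer(min_fragment),
            max_fragment = as.integer(max_fragment),
            damage_rate = damage_rate, damage_decay = damage_decay,
            error_rate = error_rate, duplication_rate = duplication_rate,
            bleed_rate = bleed_rate, base_quality = as.integer(base_quality),
            lowq_fraction = lowq_fraction, lowq_quality = as.integer(lowq_quality))
  for (f in c("damage_rate", "error_rate", "bleed_rate", "lowq_fraction"))
    if (p[[f]] < 0 || p[[f]] > 1) stop(f, " must be in [0, 1]")
  if (p$damage_decay < 0 || p$damage_decay >= 1)
    stop("damage_decay must be in [0, 1)")
  if (p$coverage <= 0) stop("coverage must be positive")
  if (p$duplication_rate < 0) stop("duplication_rate must be non-negative")
  if (p$min_fragment < 1 || p$max_fragment < p$min_fragment)
    stop("fragment bounds must satisfy 1 <= min_fragment <= max_fragment")
  class(p) <- "simulation_params"
  p
}

# mean of the integer-rounded truncated normal used for fragment lengths
truncnorm_mean <- function(mu, sd, a, b) {
  al <- (a - mu) / sd; be <- (b - mu) / sd
  mu + sd * (dnorm(al) - dnorm(be)) / (pnorm(be) - pnorm(al))
}

rtruncnorm_int <- function(n, mu, sd, a, b) {
  u <- runif(n, pnorm(a, mu, sd), pnorm(b, mu, sd))
  pmin(pmax(as.integer(round(qnorm(u, mu, sd))), as.integer(a)), as.integer(b))
}

phred_string <- function(q) intToUtf8(q + 33L)

phred_ints <- function(s) utf8ToInt(s) - 33L

new_mapped_reads <- function(read_id, barcode, start, end, bases, qual) {
  df <- data.frame(read_id = read_id, barcode = barcode,
                   start = as.integer(start), end = as.integer(end),
                   bases = bases, qual = qual, stringsAsFactors = FALSE)
  bad <- nchar(df$bases) != df$end - df$start | nchar(df$qual) != nchar(df$bases)
  if (any(bad))
    stop("malformed read(s): length fields inconsistent for ",
         paste(head(df$read_id[bad], 5), collapse = ", "))
  df
}

#' Simulate ancient-DNA reads from one haplotype
#'
#' Draws unique molecules with truncated-normal fragment lengths and uniform
#' start positions, applies terminal deamination damage once per molecule
#' (so all PCR copies of a molecule share its damage), emits
#' `1 + Poisson(duplication_rate)` copies per molecule with identical start
#' and end coordinates, and overlays independent per-copy sequencing errors
#' and base qualities. Alignment coordinates in the truth are exact.
#'
#' @param haplotype sequence string (the sample's true mitogenome).
#' @param params a [simulation_params()] bundle.
#' @param barcode the sample's barcode identifier.
#' @param seed integer seed.
#' @return a list of class `simulated_reads` with elements `reads` (a read
#'   table: read_id, barcode, start, end, bases, qual) and `truth` (one row
#'   per emitted copy: read_id, molecule_id, true_barcode, observed_barcode,
#'   bleed flag, 0-based damaged and error positions within the read as
#'   comma-separated strings).
#' @export
simulate_reads <- function(haplotype, params = simulation_params(),
                           barcode = "S1", seed = 1) {
  if (!is.character(haplotype) || nchar(haplotype) == 0)
    stop("haplotype must be a non-empty sequence string")
  L <- nchar(haplotype)
  hap <- str_chars(haplotype)
  withr::with_seed(seed, {
    a <- min(params$min_fragment, L)
    b <- min(params$max_fragment, L)
    mean_len <- truncnorm_mean(params$fragment_length_mean,
                               params$fragment_length_sd, a, b)
    n_mol <- rpois(1, params$coverage * L / mean_len)
    if (n_mol == 0) n_mol <- 1
    lens <- rtruncnorm_int(n_mol, params$fragment_length_mean,
                           params$fragment_length_sd, a, b)
    starts <- vapply(lens, function(l) sample.int(L - l + 1L, 1L) - 1L,
                     integer(1))
    ends <- starts + lens

    n_copies <- 1L + rpois(n_mol, params$duplication_rate)
    total <- sum(n_copies)
    # flat accumulators, one slot per emitted copy
    acc_id <- character(total); acc_bases <- character(total)
    acc_qual <- character(total); acc_err <- character(total)
    acc_mol <- character(total); acc_dmg <- character(total)
    acc_start <- integer(total); acc_end <- integer(total)
    slot <- 1L
    for (i in seq_len(n_mol)) {
      frag <- hap[(starts[i] + 1L):ends[i]]
      l <- lens[i]
      # deamination on the molecule: C->T from the 5' end, G->A from the 3'
      p5 <- params$damage_rate * params$damage_decay^(seq_len(l) - 1L)
      p3 <- rev(p5)
      hit5 <- frag == "C" & runif(l) < p5
      hit3 <- frag == "G" & runif(l) < p3
      dmg <- frag
      dmg[hit5] <- "T"
      dmg[hit3] <- "A"
      dmg_pos <- paste(which(hit5 | hit3) - 1L, collapse = ",")
      mol_id <- sprintf("%s_m%06d", barcode, i)

      for (k in seq_len(n_copies[i])) {
        obs <- dmg
        errs <- which(runif(l) < params$error_rate)
        for (e in errs)
          obs[e] <- sample(setdiff(DNA_BASES, obs[e]), 1)
        q <- rep(params$base_quality, l)
        if (params$lowq_fraction > 0) {
          low <- runif(l) < params$lowq_fraction
          q[low] <- params$lowq_quality
        }
        acc_id[slot] <- sprintf("%s_c%02d", mol_id, k)
        acc_bases[slot] <- chars_str(obs)
        acc_qual[slot] <- phred_string(q)
        acc_err[slot] <- paste(errs - 1L, collapse = ",")
        acc_mol[slot] <- mol_id
        acc_dmg[slot] <- dmg_pos
        acc_start[slot] <- starts[i]
        acc_end[slot] <- ends[i]
        slot <- slot + 1L
      }
    }
    out <- list(
      reads = new_mapped_reads(acc_id, barcode, acc_start, acc_end,
                               acc_bases, acc_qual),
      truth = data.frame(read_id = acc_id, molecule_id = acc_mol,
                         true_barcode = barcode, observed_barcode = barcode,
                         bleed = FALSE, damage_pos = acc_dmg,
                         error_pos = acc_err, stringsAsFactors = FALSE),
      haplotype = haplotype, barcode = barcode, params = params)
    class(out) <- "simulated_reads"
    out
  })
}

#' @export
print.simulated_reads <- function(x, ...) {
  cat(sprintf("simulated_reads: %d copies of %d molecules, barcode %s\n",
              nrow(x$reads), length(unique(x$truth$molecule_id)), x$barcode))
  invisible(x)
}

#' Pool barcoded samples with barcode bleeding
#'
#' Emulates index hopping in a pooled capture: each read copy is
#' independently reassigned to a uniformly chosen *other* barcode with
#' probability `bleed_rate`. The truth table records every reassignment.
#'
#' @param per_sample a named list of [simulate_reads()] results (names are
#'   barcodes; each element may also be a bare read table).
#' @param bleed_rate reassignment probability in \[0, 1\].
#' @param seed integer seed.
#' @return a list of class `pooled_reads` with `reads` (pooled read table,
#'   `barcode` column holding the observed barcode) and `truth`.
#' @export
pool_with_bleed <- function(per_sample, bleed_rate = 0.02, seed = 1) {
  if (bleed_rate < 0 || bleed_rate > 1) stop("bleed_rate must be in [0, 1]")
  barcodes <- names(per_sample)
  if (is.null(barcodes) || any(barcodes == ""))
    stop("per_sample must be a named list (names are barcodes)")
  if (bleed_rate > 0 && length(per_sample) < 2)
    stop("bleeding requires at least two samples")
  pieces <- lapply(barcodes, function(bc) {
    x <- per_sample[[bc]]
    if (inherits(x, "simulated_reads")) return(x[c("reads", "truth")])
    list(reads = x,
         truth = data.frame(read_id = x$read_id, molecule_id = NA_character_,
                            true_barcode = x$barcode,
                            observed_barcode = x$barcode, bleed = FALSE,
                            damage_pos = NA_character_,
                            error_pos = NA_character_,
                            stringsAsFactors = FALSE))
  })
  reads <- do.call(rbind, lapply(pieces, `[[`, "reads"))
  truth <- do.call(rbind, lapply(pieces, `[[`, "truth"))
  rownames(reads) <- rownames(truth) <- NULL
  withr::with_seed(seed, {
    if (bleed_rate > 0) {
      hit <- runif(nrow(reads)) < bleed_rate
      for (i in which(hit)) {
        others <- setdiff(barcodes, truth$true_barcode[i])
        new_bc <- if (length(others) == 1) others else sample(others, 1)
        reads$barcode[i] <- new_bc
        truth$observed_barcode[i] <- new_bc
        truth$bleed[i] <- TRUE
      }
    }
  })
  out <- list(reads = reads, truth = truth, barcodes = barcodes)
  class(out) <- "pooled_reads"
  out
}

#' Simulate a complete pooled, barcoded batch
#'
#' Convenience wrapper that mutates one haplotype per sample from a common
#' reference, simulates reads for each, and pools them with barcode
#' bleeding. Returns everything needed to run and score the full pipeline.
#'
#' @param ref an [annotated_reference()].
#' @param n_samples number of barcoded samples in the batch.
#' @param n_substitutions substitutions per sample haplotype.
#' @param params a [simulation_params()] bundle.
#' @param seed integer seed; per-sample streams are derived from it.
#' @return a list with `reference`, `haplotypes` (named character vector),
#'   `pool` (a `pooled_reads` object) and `params`.
#' @export
simulate_batch <- function(ref, n_samples = 5, n_substitutions = 25,
                           params = simulation_params(), seed = 1) {
  barcodes <- sprintf("S%d", seq_len(n_samples))
  sub_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max, n_samples + 1L))
  haps <- setNames(vapply(seq_len(n_samples), function(i)
    mutate_haplotype(ref, n_substitutions, seed = sub_seeds[i]),
    character(1)), barcodes)
  per_sample <- setNames(lapply(seq_len(n_samples), function(i)
    simulate_reads(haps[[i]], params, barcodes[i], seed = sub_seeds[i])),
    barcodes)
  pool <- pool_with_bleed(per_sample, params$bleed_rate,
                          seed = sub_seeds[n_samples + 1L])
  list(reference = ref, haplotypes = haps, pool = pool, params = params)
}
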