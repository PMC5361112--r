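test_that("generated references honour the construction contract", {
  ref <- generate_reference(2000, 1, seed = 7)
  expect_s3_class(ref, "annotated_reference")
  expect_equal(ref$length, 2000)
  expect_equal(nchar(ref$sequence), 2000)
  expect_equal(nrow(ref$features), 4)
  expect_setequal(ref$features$category,
                  c("protein_coding", "control_region", "tRNA", "rRNA"))
  # non-overlap
  o <- order(ref$features$start)
  expect_true(all(ref$features$end[o][-4] <= ref$features$start[o][-1]))

  ref3 <- generate_reference(3000, 3, seed = 2)
  expect_equal(nrow(ref3$features), 12)
  expect_equal(as.vector(table(ref3$features$category)), rep(3L, 4))
})

test_that("degenerate reference arguments are rejected", {
  expect_error(generate_reference(0, 1, seed = 1), "positive")
  expect_error(generate_reference(100, 1, seed = 1), "at least 200")
  expect_error(generate_reference(250, 10, seed = 1), "too short")
})

test_that("generation is deterministic given a seed", {
  expect_identical(generate_reference(1500, 2, seed = 42),
                   generate_reference(1500, 2, seed = 42))
  ref <- generate_reference(1500, 1, seed = 1)
  expect_identical(simulate_reads(ref$sequence, barcode = "S1", seed = 9),
                   simulate_reads(ref$sequence, barcode = "S1", seed = 9))
  expect_false(identical(
    simulate_reads(ref$sequence, barcode = "S1", seed = 9)$reads,
    simulate_reads(ref$sequence, barcode = "S1", seed = 10)$reads))
})

test_that("haplotype mutation hits the requested Hamming distance", {
  ref <- generate_reference(1000, 1, seed = 5)
  expect_identical(mutate_haplotype(ref, 0, seed = 1), ref$sequence)
  hap <- mutate_haplotype(ref, 10, seed = 3)
  expect_equal(sum(chars(hap) != chars(ref$sequence)), 10)
  hap2 <- mutate_haplotype(ref, 1000, seed = 3)
  expect_equal(sum(chars(hap2) != chars(ref$sequence)), 1000)
  expect_error(mutate_haplotype("ACGTACGTAC", 11), "between 0")
})

test_that("noise-free reads are exact substrings of the haplotype", {
  hap <- local({set.seed(1); random_seq(800)})
  p <- simulation_params(coverage = 5, damage_rate = 0, error_rate = 0,
                         duplication_rate = 0)
  sr <- simulate_reads(hap, p, "S1", seed = 2)
  ok <- vapply(seq_len(nrow(sr$reads)), function(i)
    substr(hap, sr$reads$start[i] + 1, sr$reads$end[i]) == sr$reads$bases[i],
    logical(1))
  expect_true(all(ok))
  expect_true(all(!sr$truth$bleed))
  expect_equal(sr$truth$damage_pos, rep("", nrow(sr$truth)))
})

test_that("unique coverage matches the analytic sampling expectation", {
  hap <- local({set.seed(3); random_seq(2000)})
  p <- simulation_params(coverage = 20, duplication_rate = 0,
                         damage_rate = 0, error_rate = 0)
  sr <- simulate_reads(hap, p, "S1", seed = 4)
  total <- sum(sr$reads$end - sr$reads$start)
  # compound Poisson: N ~ Pois(lambda), bases = sum of N iid lengths
  mu_len <- paleomito:::truncnorm_mean(p$fragment_length_mean,
                                       p$fragment_length_sd,
                                       p$min_fragment, p$max_fragment)
  lambda <- 20 * 2000 / mu_len
  sd_total <- sqrt(lambda * (mu_len^2 + p$fragment_length_sd^2))
  expect_lt(abs(total - 20 * 2000), 3 * sd_total)
})

test_that("terminal deamination follows the geometric decay profile", {
  hap <- local({set.seed(7); random_seq(2000)})
  p <- simulation_params(coverage = 350, damage_rate = 0.3,
                         damage_decay = 0.5, error_rate = 0,
                         duplication_rate = 0)
  sr <- simulate_reads(hap, p, "S1", seed = 8)
  expect_gt(nrow(sr$reads), 10000)
  hapc <- chars(hap)
  for (pos in 0:1) {
    is_c <- hapc[sr$reads$start + 1 + pos] == "C"
    obs_t <- substr(sr$reads$bases, pos + 1, pos + 1) == "T"
    n <- sum(is_c)
    rate <- 0.3 * 0.5^pos
    expect_lt(abs(mean(obs_t[is_c]) - rate), 3 * sqrt(rate * (1 - rate) / n))
  }
})

test_that("PCR copies share coordinates and truth records are conserved", {
  hap <- local({set.seed(9); random_seq(1000)})
  p <- simulation_params(coverage = 10, duplication_rate = 2)
  sr <- simulate_reads(hap, p, "S1", seed = 10)
  expect_equal(nrow(sr$reads), nrow(sr$truth))
  expect_setequal(sr$reads$read_id, sr$truth$read_id)
  # every copy of a molecule shares its (start, end)
  key <- paste(sr$reads$start, sr$reads$end)
  mol <- sr$truth$molecule_id[match(sr$reads$read_id, sr$truth$read_id)]
  expect_true(all(tapply(key, mol, function(k) length(unique(k)) == 1)))
  # duplication rate recovers the Poisson mean within 3 sigma
  copies <- table(mol)
  n_mol <- length(copies)
  expect_lt(abs(mean(copies - 1) - 2), 3 * sqrt(2 / n_mol))
})

test_that("barcode bleeding reassigns at the requested rate", {
  hap <- local({set.seed(11); random_seq(1500)})
  p <- simulation_params(coverage = 130, duplication_rate = 1)
  s1 <- simulate_reads(hap, p, "S1", seed = 12)
  s2 <- simulate_reads(hap, p, "S2", seed = 13)

  pool0 <- pool_with_bleed(list(S1 = s1, S2 = s2), bleed_rate = 0, seed = 1)
  expect_equal(nrow(pool0$reads), nrow(s1$reads) + nrow(s2$reads))
  expect_true(all(pool0$reads$barcode == pool0$truth$true_barcode))

  pool <- pool_with_bleed(list(S1 = s1, S2 = s2), bleed_rate = 0.05, seed = 2)
  n <- nrow(pool$reads)
  expect_gt(n, 10000)
  frac <- mean(pool$truth$bleed)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n))
  expect_identical(pool$truth$bleed,
                   pool$truth$observed_barcode != pool$truth$true_barcode)
  expect_identical(pool$reads$barcode, pool$truth$observed_barcode)

  expect_error(pool_with_bleed(list(S1 = s1), bleed_rate = 0.5), "two samples")
  expect_error(pool_with_bleed(list(S1 = s1, S2 = s2), bleed_rate = 1.5),
               "\\[0, 1\\]")
})

test_that("simulation parameter validation catches bad inputs", {
  expect_error(simulation_params(damage_rate = 1.2), "damage_rate")
  expect_error(simulation_params(damage_decay = 1), "damage_decay")
  expect_error(simulation_params(coverage = 0), "coverage")
  expect_error(simulation_params(min_fragment = 0), "fragment")
  expect_error(simulate_reads("", simulation_params()), "non-empty")
})
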