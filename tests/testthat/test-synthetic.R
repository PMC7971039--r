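test_that("defaults state the benchmark world: 850 positive, 2554 negative", {
  p <- synthetic_params()
  expect_equal(p$n_pos, 850L)
  expect_equal(p$n_neg, 2554L)
  expect_equal(p$aptamer_length, c(20L, 80L))
  expect_equal(p$protein_length, c(100L, 400L))
  expect_error(synthetic_params(protein_length = c(20, 50)), "lambda")
  expect_error(synthetic_params(motif = "ACGT", aptamer_length = c(6, 30)),
               "interior motif")
})

test_that("generated data validate, keep the exact class ratio, never collide", {
  ds <- generate_dataset(synthetic_preset("weak", n_total = 200, seed = 3))
  expect_s3_class(ds, "interaction_dataset") # constructor enforces validity
  expect_equal(sum(ds$pairs$label == 1), 50)  # round(200 * 850/3404)
  expect_equal(sum(ds$pairs$label == 0), 150)
  key <- paste(ds$pairs$aptamer_id, ds$pairs$protein_id)
  expect_false(anyDuplicated(key) > 0)
  lens <- nchar(unclass(ds$aptamers))
  expect_true(all(lens >= 20 & lens <= 80))
})

test_that("same seed gives byte-identical files, different seed differs", {
  p <- synthetic_preset("strong", n_total = 60, seed = 11)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_dataset(p, dir = d1)
  generate_dataset(p, dir = d2)
  for (f in c("aptamers.fasta", "proteins.fasta", "pairs.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  p2 <- synthetic_preset("strong", n_total = 60, seed = 12)
  d3 <- withr::local_tempdir()
  generate_dataset(p2, dir = d3)
  expect_false(identical(readLines(file.path(d1, "aptamers.fasta")),
                         readLines(file.path(d3, "aptamers.fasta"))))
  # emitted files are consumable by the readers
  apt <- read_fasta(file.path(d1, "aptamers.fasta"), "dna")
  prot <- read_fasta(file.path(d1, "proteins.fasta"), "protein")
  back <- read_pair_table(file.path(d1, "pairs.csv"), apt, prot)
  expect_equal(nrow(back$pairs), 60)
})

test_that("describe_signal is zero without planted signal", {
  p <- synthetic_params(motif_strength = 0, composition_shift = 0)
  sig <- describe_signal(p)
  expect_equal(sig$expected_kmer_freq_diff, 0)
  expect_equal(unname(sig$expected_aac_diff), rep(0, 20))
})

test_that("motif expectation: 3/37 leading term, exact value matches simulation", {
  p <- synthetic_params(n_pos = 10, n_neg = 10, aptamer_length = c(40, 40),
                        motif = "ACGT", motif_strength = 3, seed = 1)
  sig <- describe_signal(p)
  expect_equal(sig$first_order, 3 / 37, tolerance = 1e-12)
  # exact expectation: truncated-Poisson copies x overwrite correction
  expect_lt(sig$expected_kmer_freq_diff, sig$first_order)
  expect_gt(sig$expected_kmer_freq_diff, 0.9 * sig$first_order)

  # Monte-Carlo cross-check over 10,000 sequences of each class
  big <- synthetic_params(n_pos = 5000, n_neg = 5000,
                          aptamer_length = c(40, 40), motif = "ACGT",
                          motif_strength = 3, seed = 202)
  ds <- generate_dataset(big)
  motif_freq <- function(s) {
    w <- substring(s, 1:(nchar(s) - 3), 4:nchar(s))
    mean(w == "ACGT")
  }
  freqs <- vapply(unclass(ds$aptamers), motif_freq, 0)
  lab <- ds$pairs$label
  diff_hat <- mean(freqs[lab == 1]) - mean(freqs[lab == 0])
  se <- sqrt(var(freqs[lab == 1]) / 5000 + var(freqs[lab == 0]) / 5000)
  expect_lt(abs(diff_hat - describe_signal(big)$expected_kmer_freq_diff), 3 * se)
})

test_that("composition shift moves AAC exactly as the softmax predicts", {
  p <- synthetic_params(n_pos = 2000, n_neg = 2000, composition_shift = 0.5,
                        protein_length = c(120, 120), seed = 77)
  sig <- describe_signal(p)
  expect_equal(sum(sig$expected_aac_diff), 0, tolerance = 1e-12)
  ds <- generate_dataset(p)
  aac <- t(vapply(seq_along(ds$proteins), function(i) {
    aac_vector(ds$proteins[[i]])
  }, numeric(20)))
  lab <- ds$pairs$label
  emp_diff <- colMeans(aac[lab == 1, ]) - colMeans(aac[lab == 0, ])
  se <- sqrt(apply(aac[lab == 1, ], 2, var) / 2000 +
             apply(aac[lab == 0, ], 2, var) / 2000)
  expect_true(all(abs(emp_diff - sig$expected_aac_diff) < 4 * se))
})

test_that("label noise flips the expected share of labels", {
  p0 <- synthetic_params(n_pos = 300, n_neg = 700, noise = 0, seed = 5,
                         protein_length = c(100, 120))
  pn <- synthetic_params(n_pos = 300, n_neg = 700, noise = 0.2, seed = 5,
                         protein_length = c(100, 120))
  l0 <- generate_dataset(p0)$pairs$label
  ln <- generate_dataset(pn)$pairs$label
  flipped <- mean(l0 != ln)
  expect_gt(flipped, 0.1)
  expect_lt(flipped, 0.3)
})
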