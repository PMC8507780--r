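test_that("PWM training applies the background-weighted pseudocount", {
  # two 2-mers, uniform background, pseudocount 1:
  # freq[K, 1] = (1 + 1 * 0.05) / (2 + 1) = 0.35
  pwm <- build_pwm(c("KA", "RA"), pseudocount = 1)
  expect_equal(unname(pwm$freq["K", 1]), 0.35)
  expect_equal(unname(pwm$freq["R", 1]), 0.35)
  expect_equal(unname(pwm$freq["A", 2]), (2 + 0.05) / 3)
  expect_true(all(abs(colSums(pwm$freq) - 1) < 1e-9))

  # vanishing pseudocount: single epitope becomes the consensus
  pwm <- build_pwm("AAAAAAAAA", pseudocount = 1e-9)
  expect_true(all(pwm$freq["A", ] > 1 - 1e-8))

  expect_error(build_pwm(c("KA", "RAA")), "mixed")
  expect_error(build_pwm(character()), "empty")
})

test_that("PWM scoring is summed log-odds against the background", {
  # PWM equal to background scores zero for every peptide
  uniform <- matrix(1 / 20, 20, 9, dimnames = list(AA20, NULL))
  pwm0 <- allele_pwm("null", uniform)
  expect_equal(score_peptide(pwm0, c("ACDEFGHIK", "YYYYYYYYY")), c(0, 0))

  # hand-computed toy score
  pwm <- build_pwm(c("KA", "RA"), pseudocount = 1)
  expected <- log2(0.35 / 0.05) + log2(((2 + 0.05) / 3) / 0.05)
  expect_equal(score_peptide(pwm, "KA"), expected, tolerance = 1e-9)

  # consensus beats any single substitution for a peaked PWM
  pwm <- synthetic_allele_pwms(9)[[1]]
  consensus <- paste(AA20[apply(pwm$freq, 2, which.max)], collapse = "")
  sc0 <- score_peptide(pwm, consensus)
  for (p in c(1, 2, 5, 9)) {
    variant <- consensus
    substr(variant, p, p) <- setdiff(AA20, substr(consensus, p, p))[1]
    expect_gte(sc0, score_peptide(pwm, variant))
  }

  expect_error(score_peptide(pwm, "SHORT"), "length")
  expect_error(score_peptide(pwm, "ACDEFGHIX"), "residue")
})

test_that("percent rank follows the strictly-greater order statistic", {
  bg <- as.numeric(1:999)
  expect_equal(percent_rank(1000, bg), 0)
  expect_equal(percent_rank(0, bg), 100)
  # query at the background median: 499 of 999 strictly greater
  expect_equal(percent_rank(500, bg), 100 * 499 / 999)
  expect_lt(abs(percent_rank(500, bg) - 50), 100 / 999)
  # non-increasing in score
  scores <- c(-5, 0, 3, 700, 1200)
  pr <- percent_rank(scores, bg)
  expect_true(all(diff(pr) <= 0))
  expect_error(percent_rank(1, numeric()), "empty")
})

test_that("ranks of random queries against random backgrounds are uniform", {
  set.seed(21)
  rnd <- function(n) vapply(seq_len(n), function(i) {
    paste(sample(AA20, 9, replace = TRUE), collapse = "")
  }, character(1))
  # a PWM with near-continuous scores so ranks are tie-free
  pwm <- build_pwm(rnd(60))
  bg_scores <- score_peptide(pwm, rnd(2000))
  query <- score_peptide(pwm, rnd(500))
  pr <- percent_rank(query, bg_scores)
  ks <- suppressWarnings(stats::ks.test(pr / 100, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("binder calling picks the best allele and classifies by rank", {
  exp <- small_experiment()
  pwms <- synthetic_allele_pwms(9)
  bgs <- lapply(pwms, background_scores, proteome = exp$proteome_fasta,
                n = 2000, seed = 5)
  # peptides sampled from an allele's own PWM are called strong
  for (k in 1:2) {
    peps <- sample_binder_peptides(pwms[[k]], 200, seed = k)
    cb <- call_binders(peps, pwms, bgs)
    expect_gte(mean(cb$calls$class == "strong"), 0.8)
  }
  # uncovered length is flagged
  cb <- call_binders("ACDEFGHIKLMV", pwms, bgs)
  expect_identical(cb$calls$class, "non")
  expect_false(cb$calls$covered)
  # empty input
  cb <- call_binders(character(), pwms, bgs)
  expect_identical(nrow(cb$calls), 0L)
})

test_that("background scores are reproducible from the recorded seed", {
  exp <- small_experiment()
  pwm <- synthetic_allele_pwms(9)[[1]]
  b1 <- background_scores(pwm, exp$proteome_fasta, n = 500, seed = 42)
  b2 <- background_scores(pwm, exp$proteome_fasta, n = 500, seed = 42)
  expect_identical(b1, b2)
  expect_identical(attr(b1, "seed"), 42)
})

test_that("motif difference z-scores behave as a frequency contrast", {
  set.seed(9)
  peps <- vapply(1:50, function(i) {
    paste(sample(AA20, 9, replace = TRUE), collapse = "")
  }, character(1))
  z <- motif_difference(peps, peps)
  expect_true(all(z == 0))

  # worked example: sample fixed at K in position 1 (n = 100) against a
  # reference with frequency 0.5 -> z = (1 - 0.5)/sqrt(0.25/100) = 10
  sample_set <- rep("KAAAAAAAA", 100)
  reference <- c(rep("KAAAAAAAA", 50), rep("LAAAAAAAA", 50))
  z <- motif_difference(sample_set, reference)
  expect_equal(unname(z["K", 1]), 10, tolerance = 1e-9)

  # swapping sample and reference flips the dominant signs
  z_fwd <- motif_difference(sample_set, reference)
  z_rev <- motif_difference(reference, sample_set)
  expect_lt(unname(z_rev["K", 1]), 0)
  expect_gt(unname(z_fwd["K", 1]), 0)

  expect_error(motif_difference("ACDEFGHIK", "ACDEFGHIKL"), "mixed")
})
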