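test_that("generator configuration is validated", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(frac_kr = 1.2), "fraction")
  expect_error(generator_config(n_replicates = 0), "n_replicates")
  expect_error(generator_config(length_weights = c(`8` = 1)), "named")
  bad_w <- c(`8` = 0.5, `9` = 0.4, `10` = 0, `11` = 0, `12` = 0,
             `13` = 0, `14` = 0)
  expect_error(generator_config(length_weights = bad_w), "sum to 1")
  expect_error(generator_config(frac_light_only = 0.6, frac_reduced = 0.5),
               "frac_light_only")
})

test_that("generation is deterministic and the empty case is empty", {
  cfg <- generator_config(n_peptides = 50, n_proteins = 200,
                          n_interactors = 60, n_known = 20,
                          n_known_in_hci = 10, seed = 3)
  e1 <- generate_experiment(cfg)
  e2 <- generate_experiment(cfg)
  expect_identical(e1, e2)

  empty <- generate_experiment(generator_config(
    n_peptides = 0, n_proteins = 100, n_interactors = 40, n_known = 10,
    n_known_in_hci = 5, seed = 1))
  expect_identical(nrow(empty$peptides), 0L)
  expect_identical(nrow(empty$truth$peptides), 0L)
})

test_that("observed Lys/Arg fraction falls in the exact binomial interval", {
  cfg <- generator_config(n_peptides = 2000, n_proteins = 2500,
                          frac_kr = 0.65, seed = 5)
  exp <- generate_experiment(cfg)
  n_kr <- sum(exp$truth$peptides$has_kr)
  bounds <- stats::qbinom(c(0.005, 0.995), 2000, 0.65)
  expect_gte(n_kr, bounds[1])
  expect_lte(n_kr, bounds[2])
})

test_that("PWM sampling matches the matrix it samples from", {
  # degenerate PWM: every peptide is the consensus
  freq <- matrix(0, 20, 9, dimnames = list(AA20, NULL))
  consensus <- strsplit("LYSARGKWF", "")[[1]]
  for (p in 1:9) freq[consensus[p], p] <- 1
  pwm <- allele_pwm("deg", freq)
  peps <- sample_binder_peptides(pwm, 25, seed = 2)
  expect_true(all(peps == "LYSARGKWF"))

  # n = 0: empty
  expect_identical(sample_binder_peptides(pwm, 0), character(0))

  # uniform PWM: per-position residue counts stay inside the exact
  # binomial 99.9% interval of 1/20 (180 simultaneous checks)
  uni <- allele_pwm("uni", matrix(1 / 20, 20, 9,
                                  dimnames = list(AA20, NULL)))
  peps <- sample_binder_peptides(uni, 10000, seed = 4)
  mat <- do.call(rbind, strsplit(peps, ""))
  bounds <- stats::qbinom(c(0.0005, 0.9995), 10000, 1 / 20)
  for (p in 1:9) {
    counts <- table(factor(mat[, p], levels = AA20))
    expect_true(all(counts >= bounds[1] & counts <= bounds[2]))
  }
})

test_that("peptides are implanted verbatim in their source proteins", {
  exp <- small_experiment()
  tr <- exp$truth$peptides
  expect_identical(length(exp$proteome_fasta),
                   as.integer(exp$config$n_proteins))
  for (i in sample.int(nrow(tr), 25)) {
    expect_true(grepl(tr$peptide[i], exp$proteome_fasta[[tr$protein[i]]],
                      fixed = TRUE))
  }
})

test_that("planted differential fractions are recovered by the pipeline", {
  cfg <- generator_config(n_peptides = 1000, n_proteins = 1500,
                          n_interactors = 300, noise_sd = 0.2, seed = 13)
  exp <- generate_experiment(cfg)
  quant <- quantify_table(exp$peptides)
  dp <- call_differential_presentation(quant)
  frac_red <- dp$counts[["reduced"]] / dp$n_quantified
  frac_inc <- dp$counts[["increased"]] / dp$n_quantified
  expect_lt(abs(frac_red - cfg$frac_reduced), 0.03)
  expect_lt(abs(frac_inc - cfg$frac_increased), 0.03)
})

test_that("truth labels are consistent with planted ratios at the cutoffs", {
  exp <- small_experiment()
  tr <- exp$truth$peptides
  expect_true(all(tr$true_log2[tr$status == "reduced"] <= log2(0.5)))
  expect_true(all(tr$true_log2[tr$status == "increased"] >= log2(2)))
  unc <- tr$true_log2[tr$status == "unchanged"]
  expect_true(all(unc > log2(0.5) & unc < log2(2)))
  ti <- exp$truth$interactors
  expect_true(all(ti$true_log2[ti$status == "increased"] >= log2(1.5)))
  expect_true(all(ti$true_log2[ti$status == "decreased"] <= log2(0.67)))
})

test_that("replicate correlations exceed the design bound", {
  exp <- small_experiment()
  rc <- replicate_correlation(compute_ratios(normalize_channels(exp$peptides)))
  expect_true(all(rc[upper.tri(rc)] > 0.8))
})

test_that("a single-replicate configuration still quantifies", {
  cfg <- generator_config(n_peptides = 60, n_proteins = 150,
                          n_replicates = 1, n_interactors = 40,
                          n_known = 10, n_known_in_hci = 5, seed = 2)
  # at this scale a replicate may have no up-shifted rows to balance with;
  # the generator warns and leaves the channel sums unequal
  exp <- suppressWarnings(generate_experiment(cfg))
  q <- quantify_table(exp$peptides)
  expect_true(any(!is.na(q$ratio_hl)))
  expect_true(all(is.na(q$p_value)))
})
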