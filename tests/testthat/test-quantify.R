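test_that("channel normalization rescales heavy to match light totals", {
  tab <- data.frame(peptide = c("A", "B"), replicate = 1L,
                    intensity_L = c(10, 10), intensity_H = c(5, 5))
  out <- normalize_channels(tab)
  expect_equal(out$intensity_H, c(10, 10))
  r <- compute_ratios(out)
  expect_equal(r$ratio_hl, c(1, 1))

  # already balanced tables are untouched
  bal <- data.frame(peptide = c("A", "B"), replicate = 1L,
                    intensity_L = c(30, 10), intensity_H = c(15, 25))
  expect_equal(normalize_channels(bal)$intensity_H, bal$intensity_H,
               tolerance = 1e-12)

  # random table: post-normalization sums agree to relative 1e-9,
  # and normalization is idempotent
  set.seed(11)
  rnd <- data.frame(peptide = paste0("P", 1:100),
                    replicate = rep(1:2, each = 50),
                    intensity_L = exp(stats::rnorm(100, 10, 1)),
                    intensity_H = exp(stats::rnorm(100, 9, 1)))
  out <- normalize_channels(rnd)
  for (r in 1:2) {
    sel <- out$replicate == r
    expect_equal(sum(out$intensity_H[sel]) / sum(out$intensity_L[sel]), 1,
                 tolerance = 1e-9)
  }
  expect_equal(normalize_channels(out)$intensity_H, out$intensity_H,
               tolerance = 1e-12)
})

test_that("normalization fails informatively on one-channel replicates", {
  tab <- data.frame(peptide = "A", replicate = 2L,
                    intensity_L = 10, intensity_H = NA_real_)
  expect_error(normalize_channels(tab), "replicate '2'")
})

test_that("ratios follow the capped-ratio convention", {
  tab <- data.frame(peptide = c("A", "B", "C", "D"), replicate = 1L,
                    intensity_L = c(100, 100, 50, NA),
                    intensity_H = c(71, NA, 50, NA))
  r <- compute_ratios(tab)
  expect_equal(r$ratio_hl[1], 0.71)
  expect_equal(r$log2_ratio[1], log2(0.71))
  expect_equal(r$log2_ratio[1], -0.494, tolerance = 1e-3)
  expect_equal(r$ratio_hl[2], 0.01)
  expect_identical(r$capped[2], "light_only")
  expect_equal(r$ratio_hl[3], 1)
  expect_equal(r$log2_ratio[3], 0)
  expect_true(is.na(r$ratio_hl[4]))
})

test_that("capping holds across randomized detection patterns", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 200
    tab <- data.frame(peptide = paste0("P", 1:n), replicate = 1L,
                      intensity_L = exp(stats::rnorm(n, 8, 2)),
                      intensity_H = exp(stats::rnorm(n, 8, 2)))
    tab$intensity_L[sample.int(n, 30)] <- NA
    tab$intensity_H[sample.int(n, 30)] <- NA
    r <- compute_ratios(tab)
    hl <- !is.na(tab$intensity_L) & !is.na(tab$intensity_H)
    ho <- is.na(tab$intensity_L) & !is.na(tab$intensity_H)
    lo <- !is.na(tab$intensity_L) & is.na(tab$intensity_H)
    expect_true(all(r$ratio_hl[ho] == 256))
    expect_true(all(r$ratio_hl[lo] == 0.01))
    expect_equal(r$ratio_hl[hl], tab$intensity_H[hl] / tab$intensity_L[hl])
    expect_true(all(is.na(r$ratio_hl[is.na(tab$intensity_L) &
                                       is.na(tab$intensity_H)])))
    expect_true(all(r$ratio_hl >= 0.01 & r$ratio_hl <= 256, na.rm = TRUE) ||
                  all(r$ratio_hl[hl] > 0))
  }
})

test_that("replicate aggregation uses the median and a one-sample t-test", {
  # degenerate variance: no p-value
  q <- aggregate_replicates(compute_ratios(toy_ratio_table(list(c(-1, -1, -1)))))
  expect_equal(q$log2_ratio, -1)
  expect_true(is.na(q$p_value))

  # closed-form t oracle: t = mean/(sd/sqrt(3)), df = 2
  x <- c(0.2, -0.1, 0.5)
  q <- aggregate_replicates(compute_ratios(toy_ratio_table(list(x))))
  expect_equal(q$log2_ratio, stats::median(x), tolerance = 1e-9)
  t_stat <- mean(x) / (stats::sd(x) / sqrt(3))
  p_oracle <- 2 * stats::pt(-abs(t_stat), df = 2)
  expect_equal(q$p_value, p_oracle, tolerance = 1e-12)

  # single replicate: median only
  q <- aggregate_replicates(compute_ratios(toy_ratio_table(list(0.7))))
  expect_equal(q$log2_ratio, 0.7, tolerance = 1e-9)
  expect_true(is.na(q$p_value))
  expect_identical(q$n_reps, 1L)
})

test_that("aggregation is permutation-invariant and excludes capped reps", {
  tab <- compute_ratios(toy_ratio_table(list(c(0.3, 0.1, 0.6),
                                             c(-0.2, -0.4, 0.1))))
  a <- aggregate_replicates(tab)
  perm <- tab[sample.int(nrow(tab)), , drop = FALSE]
  b <- aggregate_replicates(perm)
  b <- b[match(a$peptide, b$peptide), ]
  rownames(b) <- NULL
  expect_equal(a, b)

  # a capped replicate contributes to the median but not the t-test
  tab <- data.frame(peptide = "X", replicate = 1:3,
                    intensity_L = c(100, 100, NA),
                    intensity_H = c(110, 120, 90))
  q <- aggregate_replicates(compute_ratios(tab))
  expect_identical(q$capped, "none")
  expect_identical(q$n_reps, 3L)
  # median over all three replicate log2 ratios (capped one at log2 256)
  expect_equal(q$log2_ratio, stats::median(c(log2(1.1), log2(1.2), 8)))
  # but the t-test sees only the two uncapped replicates
  expect_equal(q$p_value,
               stats::t.test(c(log2(1.1), log2(1.2)), mu = 0)$p.value)
})

test_that("fully one-channel features carry the conventional summary ratio", {
  tab <- data.frame(peptide = rep(c("H", "L"), each = 3), replicate = 1:3,
                    intensity_L = c(NA, NA, NA, 10, 11, 12),
                    intensity_H = c(10, 11, 12, NA, NA, NA))
  q <- aggregate_replicates(compute_ratios(tab))
  expect_equal(q$ratio_hl[q$peptide == "H"], 256)
  expect_identical(q$capped[q$peptide == "H"], "heavy_only")
  expect_equal(q$ratio_hl[q$peptide == "L"], 0.01)
  expect_equal(q$log2_ratio[q$peptide == "L"], log2(0.01))
})

test_that("replicate correlation matrix has the required structure", {
  tab <- compute_ratios(toy_ratio_table(list(c(0.5, 0.5), c(-1, -1),
                                             c(0.2, 0.2), c(1.4, 1.4))))
  r <- replicate_correlation(tab)
  expect_equal(r[1, 2], 1.0)
  expect_equal(diag(r), c(`1` = 1, `2` = 1))
  expect_equal(r, t(r))

  # a replicate vs its negation
  neg <- compute_ratios(toy_ratio_table(list(c(0.5, -0.5), c(-1, 1),
                                             c(0.2, -0.2))))
  expect_equal(replicate_correlation(neg)[1, 2], -1.0)

  # fewer than 3 shared features: absent entry
  sparse <- compute_ratios(toy_ratio_table(list(c(0.5, 0.5), c(-1, 1))))
  expect_true(is.na(replicate_correlation(sparse)[1, 2]))
})
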