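test_that("peptide-protein pairing uses the median over sibling peptides", {
  pep <- toy_quant(paste0("PEP", 1:5), 2^c(0.2, 0.8, 0.4, 1.0, -0.5),
                   protein = c("P1", "P1", "P1", "P2", "P3"))
  prot <- toy_quant(c("P1", "P2", "P3"), 2^c(0.1, 0.9, -0.4))
  pp <- peptide_protein_correlation(pep, prot)
  expect_equal(pp$pairs$peptide_log2[pp$pairs$protein == "P1"], 0.4)
  expect_identical(pp$n, 3L)

  # identical layers: perfect correlation, unit slope
  pep <- toy_quant(paste0("PEP", 1:6), 2^c(-1, -0.5, 0, 0.3, 0.8, 1.4),
                   protein = paste0("P", 1:6))
  prot <- toy_quant(paste0("P", 1:6), 2^c(-1, -0.5, 0, 0.3, 0.8, 1.4))
  pp <- peptide_protein_correlation(pep, prot)
  expect_equal(pp$r, 1)
  expect_equal(pp$slope, 1)

  expect_error(peptide_protein_correlation(
    toy_quant("A", 2, protein = "P1"), toy_quant("P1", 2)), "fewer than 3")
})

test_that("altered-gene selection is a strict magnitude cutoff", {
  prot <- toy_quant(paste0("P", 1:4), 2^c(0.61, 0.59, -0.7, 0),
                    gene = paste0("G", 1:4))
  expect_setequal(select_altered(prot), c("G1", "G3"))
  expect_identical(select_altered(toy_quant("P", 1, gene = "G")),
                   character(0))
})

test_that("hypergeometric p matches exhaustive enumeration on small universes", {
  # worked example: universe 10, set 4, query 3, overlap 3 -> 4/120
  universe <- paste0("g", 1:10)
  sets <- list(S = universe[1:4])
  res <- enrich_gene_sets(universe[1:3], sets, universe)
  expect_equal(res$p, 4 / 120, tolerance = 1e-12)
  expect_equal(res$p, hyper_oracle(universe, sets$S, 3, 3),
               tolerance = 1e-12)

  # randomized small universes against the enumeration oracle
  set.seed(17)
  for (i in 1:8) {
    N <- sample(6:12, 1)
    universe <- paste0("g", seq_len(N))
    members <- sample(universe, sample(2:(N - 1), 1))
    n <- sample(2:(N - 1), 1)
    query <- sample(universe, n)
    k <- sum(query %in% members)
    res <- enrich_gene_sets(query, list(S = members), universe)
    expect_equal(res$p, hyper_oracle(universe, members, n, k),
                 tolerance = 1e-12)
  }

  # certain event: query = set = universe
  u <- paste0("g", 1:5)
  expect_equal(enrich_gene_sets(u, list(S = u), u)$p, 1)
  # zero overlap with a small set: p near 1
  res <- enrich_gene_sets(paste0("g", 1:2), list(S = paste0("g", 9:10)),
                          paste0("g", 1:10))
  expect_gt(res$p, 0.7)
  expect_error(enrich_gene_sets("a", list(S = "a"), character()),
               "empty universe")
})

test_that("BH adjustment is monotone and bounded", {
  set.seed(4)
  universe <- paste0("g", 1:200)
  sets <- lapply(1:15, function(i) sample(universe, 20))
  names(sets) <- paste0("S", 1:15)
  res <- enrich_gene_sets(sample(universe, 40), sets, universe)
  expect_true(all(res$p_adj >= res$p))
  expect_true(all(res$p_adj <= 1))
  expect_true(all(diff(res$p_adj) >= -1e-12))  # sorted by p
})

test_that("activation z-score is the sign-concordance statistic", {
  genes <- paste0("G", 1:9)
  l2 <- stats::setNames(rep(1, 9), genes)
  dirs <- stats::setNames(rep(1, 9), genes)
  expect_equal(activation_zscore(genes, l2, dirs)$z, 3.0)

  # balanced concordance: zero
  l2 <- stats::setNames(c(rep(1, 4), rep(-1, 4)), paste0("G", 1:8))
  dirs <- stats::setNames(rep(1, 8), paste0("G", 1:8))
  expect_equal(activation_zscore(paste0("G", 1:8), l2, dirs)$z, 0)

  # 5 concordant, 1 discordant: 4/sqrt(6)
  l2 <- stats::setNames(c(rep(1, 5), -1), paste0("G", 1:6))
  dirs <- stats::setNames(rep(1, 6), paste0("G", 1:6))
  z <- activation_zscore(paste0("G", 1:6), l2, dirs)
  expect_equal(z$z, 4 / sqrt(6), tolerance = 1e-9)
  expect_identical(z$m, 6L)

  # bounded by sqrt(m); sub-cutoff genes do not contribute
  set.seed(8)
  for (i in 1:5) {
    m <- sample(3:20, 1)
    genes <- paste0("G", seq_len(m))
    l2 <- stats::setNames(stats::runif(m, -2, 2), genes)
    dirs <- stats::setNames(sample(c(-1, 1), m, TRUE), genes)
    z <- activation_zscore(genes, l2, dirs)
    if (!is.na(z$z)) expect_lte(abs(z$z), sqrt(z$m) + 1e-9)
  }
  empty <- activation_zscore("G1", c(G1 = 0.1), c(G1 = 1))
  expect_true(is.na(empty$z))
})

test_that("proteome-interactome correlation distinguishes planted regimes", {
  # identical vectors
  a <- toy_quant(paste0("P", 1:5), 2^c(-1, 0, 0.5, 1, 2))
  pi0 <- proteome_interactome_correlation(a, a)
  expect_equal(pi0$r, 1)

  # planted shared signal at n = 300: strongly significant
  set.seed(31)
  shared <- stats::rnorm(300, 0, 0.4)
  prot <- toy_quant(paste0("P", 1:300), 2^(shared + stats::rnorm(300, 0, 0.15)))
  int <- toy_quant(paste0("P", 1:300), 2^(shared + stats::rnorm(300, 0, 0.15)))
  expect_lt(proteome_interactome_correlation(prot, int)$p, 1e-4)

  # independent layers at n = 300: typically non-significant
  p_null <- vapply(1:3, function(s) {
    set.seed(100 + s)
    prot <- toy_quant(paste0("P", 1:300), 2^stats::rnorm(300, 0, 0.4))
    int <- toy_quant(paste0("P", 1:300), 2^stats::rnorm(300, 0, 0.4))
    proteome_interactome_correlation(prot, int)$p
  }, numeric(1))
  expect_gte(sum(p_null > 0.05), 2L)

  expect_error(proteome_interactome_correlation(
    toy_quant("P1", 2), toy_quant("P1", 2)), "fewer than 3")
})
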