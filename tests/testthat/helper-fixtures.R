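# Shared fixture builders. Experiments are cached per configuration so
# that several test files can reuse the same generated data.

.fixture_cache <- new.env(parent = emptyenv())

# A small but complete experiment: all layers populated, fast to build.
small_experiment <- function(seed = 7) {
  key <- paste0("small_", seed)
  if (!exists(key, envir = .fixture_cache)) {
    cfg <- generator_config(n_peptides = 400, n_proteins = 600,
                            n_interactors = 300, seed = seed)
    assign(key, generate_experiment(cfg), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Long-format intensity table built directly from per-replicate log2
# ratios (one feature per element of `l2_by_rep`); light intensity fixed.
toy_ratio_table <- function(l2_by_rep, base_l = 1000) {
  rows <- list()
  for (i in seq_along(l2_by_rep)) {
    l2 <- l2_by_rep[[i]]
    for (r in seq_along(l2)) {
      rows[[length(rows) + 1]] <- data.frame(
        peptide = paste0("PEP", i), replicate = r,
        intensity_L = base_l, intensity_H = base_l * 2^l2[r],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Quant-table row constructor for peptidome/interactome call tests.
toy_quant <- function(peptide, ratio_hl, capped = "none", p_value = NA_real_,
                      protein = peptide, gene = peptide) {
  n <- length(peptide)
  data.frame(peptide = peptide, protein = protein, gene = gene,
             ratio_hl = ratio_hl, log2_ratio = log2(ratio_hl),
             capped = rep(capped, length.out = n),
             p_value = rep(p_value, length.out = n),
             n_reps = ifelse(is.na(ratio_hl), 0L, 3L),
             stringsAsFactors = FALSE)
}

# Exhaustive hypergeometric oracle: probability that a uniformly drawn
# query of size n from the universe overlaps the set by at least k.
# Enumeration over all combn(N, n) draws; tractable for N <= 12.
hyper_oracle <- function(universe, set_members, n, k) {
  draws <- utils::combn(universe, n)
  hits <- apply(draws, 2, function(d) sum(d %in% set_members) >= k)
  mean(hits)
}
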