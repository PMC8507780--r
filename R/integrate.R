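# Cross-layer integration: peptide-vs-source-protein and
# proteome-vs-interactome correlations, altered-protein selection,
# hypergeometric gene-set over-representation, and directional
# (sign-concordance) activation z-scores.

#' Correlation of peptide presentation with source-protein abundance
#'
#' Pairs each protein's whole-proteome log2 H/L ratio with the median log2
#' ratio of its Class I-presented peptides (median over peptides when a
#' protein sources several). Capped ratios are excluded from both layers:
#' conventional 256/0.01 values are not measurements and would dominate a
#' least-squares fit. Returns the least-squares slope, Pearson's r and its
#' two-sided p-value.
#'
#' @param peptide_quant Per-peptide quantification with a `protein` column
#'   (first/primary source accession).
#' @param protein_quant Per-protein quantification.
#' @return List `slope`, `intercept`, `r`, `p`, `n`, `pairs` (data frame
#'   `protein`, `peptide_log2`, `protein_log2`).
#' @export
peptide_protein_correlation <- function(peptide_quant, protein_quant) {
  pep <- peptide_quant[!is.na(peptide_quant$log2_ratio) &
                         peptide_quant$capped == "none", , drop = FALSE]
  med <- tapply(pep$log2_ratio, pep$protein, stats::median)
  prot <- protein_quant[!is.na(protein_quant$log2_ratio) &
                          protein_quant$capped == "none", , drop = FALSE]
  shared <- intersect(names(med), prot$protein)
  check_that(length(shared) >= 3,
             "peptide_protein_correlation(): fewer than 3 shared proteins")
  pl2 <- prot$log2_ratio[match(shared, prot$protein)]
  pairs <- data.frame(protein = shared,
                      peptide_log2 = as.numeric(med[shared]),
                      protein_log2 = pl2,
                      stringsAsFactors = FALSE)
  fit <- stats::lm(peptide_log2 ~ protein_log2, data = pairs)
  ct <- stats::cor.test(pairs$peptide_log2, pairs$protein_log2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = unname(ct$estimate), p = ct$p.value,
       n = nrow(pairs), pairs = pairs)
}

#' Select significantly altered genes by log2 fold-change magnitude
#'
#' @param protein_quant Per-protein quantification with a `gene` column.
#' @param log2_cutoff Strict magnitude cutoff (default 0.6):
#'   `|log2 ratio| > log2_cutoff`.
#' @return Character vector of gene symbols.
#' @export
select_altered <- function(protein_quant, log2_cutoff = 0.6) {
  ok <- !is.na(protein_quant$log2_ratio) &
    abs(protein_quant$log2_ratio) > log2_cutoff
  unique(protein_quant$gene[ok])
}

#' Hypergeometric gene-set over-representation
#'
#' For each set, the upper-tail hypergeometric probability of observing at
#' least the seen overlap between the query and the set within the
#' universe: `p = P(X >= k)` with `X ~ Hypergeometric(K, N - K, n)`.
#' Benjamini-Hochberg adjustment across sets; results sorted by p.
#' Query genes outside the universe are dropped, and sets are intersected
#' with the universe before counting.
#'
#' @param query Character vector of genes of interest.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe Nonempty character vector of all assayable genes.
#' @return Data frame `set`, `k`, `K`, `n`, `N`, `p`, `p_adj`, sorted by
#'   `p`.
#' @export
enrich_gene_sets <- function(query, gene_sets, universe) {
  universe <- unique(universe)
  check_that(length(universe) > 0, "enrich_gene_sets(): empty universe")
  query <- intersect(unique(query), universe)
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(members)
    k <- length(intersect(query, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}

#' Directional activation z-score for a gene set
#'
#' A sign-concordance score over the set's altered genes: each gene whose
#' fold change passes the [select_altered()] magnitude cutoff and has an
#' annotated expected direction contributes `sign(log2 ratio) *
#' direction`; the z-score is the sum divided by `sqrt(m)` over the `m`
#' contributing genes. Positive values indicate net activation of the
#' pathway in the heavy-labeled condition, negative values net
#' inhibition; the score is bounded by `±sqrt(m)`.
#'
#' @param set_genes Character vector of the set's member genes.
#' @param log2_ratios Named numeric vector of per-gene log2 H/L ratios.
#' @param directions Named numeric vector of expected directions (+1
#'   activating, -1 inhibiting) per gene.
#' @param log2_cutoff Magnitude cutoff for a gene to contribute
#'   (default 0.6).
#' @return List `z` (`NA` when no gene contributes), `m`, `concordant`,
#'   `discordant`.
#' @export
activation_zscore <- function(set_genes, log2_ratios, directions,
                              log2_cutoff = 0.6) {
  g <- intersect(set_genes, names(log2_ratios))
  g <- g[!is.na(log2_ratios[g]) & abs(log2_ratios[g]) > log2_cutoff]
  g <- intersect(g, names(directions))
  m <- length(g)
  if (m == 0) {
    return(list(z = NA_real_, m = 0L, concordant = 0L, discordant = 0L))
  }
  s <- sign(log2_ratios[g]) * directions[g]
  list(z = sum(s) / sqrt(m), m = m,
       concordant = sum(s > 0), discordant = sum(s < 0))
}

#' Correlation of whole-proteome and interactome fold changes
#'
#' Pearson correlation of per-protein log2 H/L ratios between the
#' whole-cell proteome and the Class I interactome over shared,
#' uncapped-quantified accessions.
#'
#' @param protein_quant,interaction_quant Per-protein quantification
#'   tables.
#' @return List `r`, `p`, `n`, `pairs`.
#' @export
proteome_interactome_correlation <- function(protein_quant,
                                             interaction_quant) {
  p1 <- protein_quant[!is.na(protein_quant$log2_ratio) &
                        protein_quant$capped == "none", , drop = FALSE]
  p2 <- interaction_quant[!is.na(interaction_quant$log2_ratio) &
                            interaction_quant$capped == "none", , drop = FALSE]
  shared <- intersect(p1$protein, p2$protein)
  check_that(length(shared) >= 3,
             "proteome_interactome_correlation(): fewer than 3 shared proteins")
  x <- p1$log2_ratio[match(shared, p1$protein)]
  y <- p2$log2_ratio[match(shared, p2$protein)]
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shared),
       pairs = data.frame(protein = shared, proteome_log2 = x,
                          interactome_log2 = y, stringsAsFactors = FALSE))
}
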