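# AP-MS Class I interactome analyses: the high-confidence-interactor
# (HCI) filter, overlap and known-interactor recovery statistics, and
# differential interaction calls.

#' Filter AP-MS identifications to high-confidence interactors
#'
#' A protein is an HCI iff its identification FDR is strictly below
#' `fdr_max`, it was identified with at least `min_unique` unique
#' peptides, and it is absent from the contaminant list. Contaminants are
#' matched by accession, with an optional fallback on gene symbol (common
#' contaminant lists are gene-keyed while search output is
#' accession-keyed). The filter is deterministic, order-independent and
#' idempotent.
#'
#' @param table One row per protein, with columns `protein`, `id_fdr`,
#'   `unique_peptides` (and optionally `gene`).
#' @param contaminants Character vector of contaminant accessions (and/or
#'   gene symbols).
#' @param fdr_max Strict FDR upper bound (default 0.01).
#' @param min_unique Inclusive minimum unique-peptide count (default 2).
#' @return `table` with a logical `hci` column added; attribute `n_hci`
#'   holds the count.
#' @export
filter_hci <- function(table, contaminants = character(),
                       fdr_max = 0.01, min_unique = 2) {
  need <- c("protein", "id_fdr", "unique_peptides")
  check_that(all(need %in% names(table)),
             "filter_hci(): missing column(s): %s",
             paste(setdiff(need, names(table)), collapse = ", "))
  is_contam <- table$protein %in% contaminants
  if ("gene" %in% names(table)) {
    is_contam <- is_contam | table$gene %in% contaminants
  }
  table$hci <- table$id_fdr < fdr_max &
    table$unique_peptides >= min_unique &
    !is_contam
  structure(table, n_hci = sum(table$hci))
}

#' Overlap statistics for two accession sets
#'
#' Counts, intersection, inclusion-exclusion union, and the integer
#' percentage of set B found in set A.
#'
#' @param set_a,set_b Character vectors (deduplicated internally).
#' @return List `n_a`, `n_b`, `n_shared`, `union`, `percent_b_in_a`.
#' @export
overlap_stats <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  shared <- length(intersect(a, b))
  list(n_a = length(a), n_b = length(b), n_shared = shared,
       union = length(a) + length(b) - shared,
       percent_b_in_a = if (length(b) > 0)
         summary_percentages(shared, length(b)) else NA_integer_)
}

#' Recovery of known interactors by an HCI set
#'
#' @param hci Character vector of HCI accessions.
#' @param known Nonempty character vector of known-interactor accessions.
#' @return List `recovered` (count), `percent` (integer percent of the
#'   known list recovered), `novel` (HCIs not in the known list).
#' @export
known_recovery <- function(hci, known) {
  known <- unique(known)
  check_that(length(known) > 0, "known_recovery(): empty known list")
  hci <- unique(hci)
  recovered <- length(intersect(hci, known))
  list(recovered = recovered,
       percent = summary_percentages(recovered, length(known)),
       novel = length(hci) - recovered)
}

#' Differential interaction calls
#'
#' An interactor's association with the Class I complex is called
#' `increased` when `ratio_hl >= up` and the change is statistically
#' significant (`p_value < alpha`), `decreased` when `ratio_hl <= down`
#' with significance, else `unchanged`. Interactors quantified only by a
#' capped ratio carry no p-value by construction, so they are called on
#' the ratio alone.
#'
#' @param quant Per-protein quantification table (columns `protein`,
#'   `ratio_hl`, `capped`, `p_value`).
#' @param up,down Ratio cutoffs (defaults 1.5 and 0.67).
#' @param alpha Significance level for uncapped ratios (default 0.05).
#' @return List with `calls` (quant + `status`), `counts`, `fractions`
#'   (of the quantified total) and `altered_percent` (integer percent
#'   increased + decreased).
#' @export
call_differential_interaction <- function(quant, up = 1.5, down = 0.67,
                                          alpha = 0.05) {
  q <- quant[!is.na(quant$ratio_hl), , drop = FALSE]
  sig <- ifelse(q$capped != "none", TRUE,
                !is.na(q$p_value) & q$p_value < alpha)
  status <- rep("unchanged", nrow(q))
  status[q$ratio_hl >= up & sig] <- "increased"
  status[q$ratio_hl <= down & sig] <- "decreased"
  q$status <- status
  counts <- c(increased = sum(status == "increased"),
              decreased = sum(status == "decreased"),
              unchanged = sum(status == "unchanged"))
  n <- nrow(q)
  fractions <- if (n > 0) counts / n else counts * NA_real_
  list(calls = q, counts = counts, fractions = fractions,
       altered_percent = if (n > 0)
         summary_percentages(counts[["increased"]] + counts[["decreased"]], n)
       else NA_integer_,
       n_quantified = n)
}
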