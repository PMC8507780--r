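# Immunopeptidome-level analyses: the discovery cascade, length and
# SILAC-label-position profiling, differential presentation calls, and the
# global ratio-shift summary.

#' Peptide discovery cascade
#'
#' Applies, in order, the filters that take identified peptides down to
#' the quantifiable 8-14-mer immunopeptidome: (1) all identified peptides;
#' (2) peptides containing at least one Lys or Arg and hence carrying a
#' SILAC label; (3) peptides with a valid (possibly capped) H/L ratio;
#' (4) peptides of length 8-14, the range that fits the HLA Class I
#' binding groove. Counts are monotone non-increasing by construction.
#'
#' @param quant Per-peptide quantification table with columns `peptide`
#'   and `ratio_hl` (`NA` = identified but not quantified).
#' @return An object of class `filter_cascade`: list with counts
#'   `n_identified`, `n_labelable`, `n_quantified`, `n_8_14` and the
#'   per-stage peptide vectors in `stages`.
#' @export
discovery_pipeline <- function(quant) {
  check_that(all(c("peptide", "ratio_hl") %in% names(quant)),
             "discovery_pipeline(): need columns 'peptide' and 'ratio_hl'")
  identified <- quant$peptide
  labelable <- quant[grepl("[KR]", quant$peptide), , drop = FALSE]
  quantified <- labelable[!is.na(labelable$ratio_hl), , drop = FALSE]
  in_range <- quantified[nchar(quantified$peptide) >= 8 &
                           nchar(quantified$peptide) <= 14, , drop = FALSE]
  structure(list(
    n_identified = length(identified),
    n_labelable = nrow(labelable),
    n_quantified = nrow(quantified),
    n_8_14 = nrow(in_range),
    stages = list(identified = identified,
                  labelable = labelable$peptide,
                  quantified = quantified$peptide,
                  in_8_14 = in_range$peptide)
  ), class = "filter_cascade")
}

#' @export
print.filter_cascade <- function(x, ...) {
  cat("Peptide discovery cascade\n")
  cat(sprintf("  identified          : %d\n", x$n_identified))
  cat(sprintf("  >=1 Lys/Arg         : %d (%d%%)\n", x$n_labelable,
              if (x$n_identified > 0)
                summary_percentages(x$n_labelable, x$n_identified) else 0L))
  cat(sprintf("  valid SILAC ratio   : %d\n", x$n_quantified))
  cat(sprintf("  length 8-14         : %d (%d%%)\n", x$n_8_14,
              if (x$n_quantified > 0)
                summary_percentages(x$n_8_14, x$n_quantified) else 0L))
  invisible(x)
}

#' Peptide length distribution
#'
#' Counts peptides of each length 8..14 plus an `other` bin, and reports
#' the modal length over all peptides.
#'
#' @param peptides Character vector of peptide sequences.
#' @return List with `counts` (named integer vector, names "8".."14" and
#'   "other") and `mode` (most frequent length, `NA` if empty).
#' @export
length_distribution <- function(peptides) {
  lens <- nchar(peptides)
  bins <- as.character(8:14)
  counts <- vapply(8:14, function(L) sum(lens == L), integer(1))
  names(counts) <- bins
  counts <- c(counts, other = sum(lens < 8 | lens > 14))
  mode_len <- if (length(lens) == 0) NA_integer_ else {
    tab <- table(lens)
    as.integer(names(tab)[which.max(tab)])
  }
  list(counts = counts, mode = mode_len)
}

#' SILAC label position profile of 9-mer peptides
#'
#' For a set of 9-mers, counts at each of the nine positions how often the
#' residue is Lys or Arg (i.e. carries the heavy label). On HLA Class I
#' ligands these labels are expected to be depleted at the anchor
#' positions 2 and 9.
#'
#' @param peptides Character vector; every element must be exactly 9
#'   residues.
#' @return List with `counts` (integer vector of length 9), `freq`
#'   (counts / number of peptides) and `n`.
#' @export
label_position_profile <- function(peptides) {
  if (length(peptides) == 0) {
    return(list(counts = integer(9), freq = rep(NaN, 9), n = 0L))
  }
  check_that(all(nchar(peptides) == 9),
             "label_position_profile(): all peptides must be 9-mers")
  mat <- do.call(rbind, strsplit(peptides, ""))
  counts <- colSums(mat == "K" | mat == "R")
  list(counts = as.integer(counts), freq = counts / length(peptides),
       n = length(peptides))
}

#' Differential presentation calls at fold-change cutoffs
#'
#' Partitions quantified peptides three ways at inclusive cutoffs:
#' `increased` when `ratio_hl >= up`, `reduced` when `ratio_hl <= down`,
#' `unchanged` otherwise. Capped ratios (256 / 0.01) participate: a
#' heavy-only peptide is `increased`, a light-only peptide `reduced` —
#' the capping convention exists precisely to let one-channel detections
#' enter these calls.
#'
#' @param quant Per-peptide quantification (rows with `NA` `ratio_hl` are
#'   dropped).
#' @param up,down Fold-change cutoffs; defaults 2.0 and 0.5.
#' @return List with `calls` (data frame: key columns + `status`),
#'   `counts` and `percent` (named vectors over
#'   increased/reduced/unchanged; percentages are integer percent of the
#'   quantified total), and `n_quantified`.
#' @export
call_differential_presentation <- function(quant, up = 2.0, down = 0.5) {
  check_that(is.numeric(up) && is.numeric(down) && up > 0 && down > 0,
             "call_differential_presentation(): cutoffs must be positive")
  check_that(down < up,
             "call_differential_presentation(): need down < up")
  q <- quant[!is.na(quant$ratio_hl), , drop = FALSE]
  status <- ifelse(q$ratio_hl >= up, "increased",
                   ifelse(q$ratio_hl <= down, "reduced", "unchanged"))
  q$status <- status
  counts <- c(increased = sum(status == "increased"),
              reduced = sum(status == "reduced"),
              unchanged = sum(status == "unchanged"))
  pct <- if (nrow(q) > 0) {
    vapply(counts, summary_percentages, integer(1), denominator = nrow(q))
  } else c(increased = 0L, reduced = 0L, unchanged = 0L)
  list(calls = q, counts = counts, percent = pct, n_quantified = nrow(q))
}

#' Global shift of the log2 ratio distribution
#'
#' Five-number summary (min, lower quartile, median, upper quartile, max)
#' of the per-peptide log2 H/L ratios, capped values included: this is the
#' distribution whose below-zero median indicates a global reduction of
#' presentation in the heavy-labeled (resistant) line.
#'
#' @param quant Per-peptide quantification table.
#' @return Named numeric vector `min`, `q1`, `median`, `q3`, `max`.
#' @export
global_shift <- function(quant) {
  l2 <- quant$log2_ratio[!is.na(quant$log2_ratio)]
  check_that(length(l2) >= 1, "global_shift(): no quantified peptides")
  q <- stats::quantile(l2, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  c(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
}
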