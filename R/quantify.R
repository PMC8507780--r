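# SILAC ratio quantification: channel normalization, capped ratios,
# replicate aggregation, and replicate correlation. This module is shared
# by the immunopeptidome, whole-proteome and interactome layers; the only
# thing that changes between layers is the key column ("peptide" or
# "protein").

#' Normalize heavy-channel intensities to the light channel
#'
#' Implements "auto" (total-intensity) normalization: within each
#' replicate, heavy intensities are rescaled by the factor
#' `sum(intensity_L) / sum(intensity_H)` computed over the rows where both
#' channels were detected, so that after rescaling the heavy and light
#' channel totals agree. Rows detected in a single channel keep their
#' present channel, rescaled by the same per-replicate factor (heavy) or
#' untouched (light), so capped ratios downstream are on the normalized
#' scale. One-channel rows are excluded from the factor because their
#' conventional ratios are not measurements and would distort the totals.
#'
#' @param table Long-format data frame with columns `replicate`,
#'   `intensity_L`, `intensity_H` (absent detections as `NA`).
#' @return The same data frame with `intensity_H` rescaled per replicate.
#' @export
normalize_channels <- function(table) {
  need <- c("replicate", "intensity_L", "intensity_H")
  check_that(all(need %in% names(table)),
             "normalize_channels(): missing column(s): %s",
             paste(setdiff(need, names(table)), collapse = ", "))
  for (rep_id in unique(table$replicate)) {
    sel <- table$replicate == rep_id
    both <- sel & !is.na(table$intensity_L) & !is.na(table$intensity_H)
    if (!any(both)) {
      stop(sprintf(
        "normalize_channels(): replicate '%s' has no row with both channels detected",
        rep_id))
    }
    fac <- sum(table$intensity_L[both]) / sum(table$intensity_H[both])
    table$intensity_H[sel] <- table$intensity_H[sel] * fac
  }
  table
}

#' Per-replicate H/L ratios with the capped-ratio convention
#'
#' Rows with both channels detected get `ratio_hl = intensity_H /
#' intensity_L`. Rows detected only in the heavy channel get the capped
#' ratio 256 (`capped = "heavy_only"`); rows detected only in the light
#' channel get 0.01 (`capped = "light_only"`). Rows detected in neither
#' channel are identification-only and get `NA` (not quantified).
#'
#' @param table Long-format intensity table (normally the output of
#'   [normalize_channels()]).
#' @return `table` with added columns `ratio_hl`, `log2_ratio`, `capped`.
#' @export
compute_ratios <- function(table) {
  has_l <- !is.na(table$intensity_L)
  has_h <- !is.na(table$intensity_H)
  ratio <- rep(NA_real_, nrow(table))
  capped <- rep(NA_character_, nrow(table))
  both <- has_l & has_h
  ratio[both] <- table$intensity_H[both] / table$intensity_L[both]
  capped[both] <- "none"
  ratio[has_h & !has_l] <- RATIO_CAP_HEAVY
  capped[has_h & !has_l] <- "heavy_only"
  ratio[has_l & !has_h] <- RATIO_CAP_LIGHT
  capped[has_l & !has_h] <- "light_only"
  table$ratio_hl <- ratio
  table$log2_ratio <- log2(ratio)
  table$capped <- capped
  table
}

#' Aggregate per-replicate ratios into one quantification per feature
#'
#' The summary `log2_ratio` is the median of the replicate log2 ratios
#' (capped replicates contribute their conventional values). Robustness to
#' a single outlying or capped replicate is the reason for the median. The
#' p-value is a two-sided one-sample t-test of the *uncapped* replicate
#' log2 ratios against 0, computed only when at least two uncapped
#' replicates with nonzero variance exist; capped ratios are conventions,
#' not measurements, so they never enter the test. A feature is flagged
#' `capped = "heavy_only"`/`"light_only"` only when every quantified
#' replicate is capped in that direction, in which case the summary ratio
#' is the conventional 256/0.01 exactly.
#'
#' @param table Output of [compute_ratios()].
#' @param by Name of the key column to aggregate over (e.g. `"peptide"`
#'   or `"protein"`).
#' @param carry Optional character vector of metadata columns to carry
#'   through (first value per feature).
#' @return Data frame with one row per feature: key column, `ratio_hl`,
#'   `log2_ratio`, `capped`, `p_value`, `n_reps` (number of quantified
#'   replicates). Features quantified in zero replicates are returned with
#'   `NA` ratio (not-quantified marker).
#' @export
aggregate_replicates <- function(table, by = "peptide", carry = character()) {
  check_that(by %in% names(table),
             "aggregate_replicates(): no column '%s'", by)
  keys <- unique(table[[by]])
  out <- data.frame(key = keys, stringsAsFactors = FALSE)
  names(out) <- by
  n <- length(keys)
  out$ratio_hl <- rep(NA_real_, n)
  out$log2_ratio <- rep(NA_real_, n)
  out$capped <- rep(NA_character_, n)
  out$p_value <- rep(NA_real_, n)
  out$n_reps <- rep(0L, n)
  idx <- split(seq_len(nrow(table)), factor(table[[by]], levels = keys))
  for (i in seq_len(n)) {
    rows <- idx[[i]]
    l2 <- table$log2_ratio[rows]
    cp <- table$capped[rows]
    quant <- !is.na(l2)
    out$n_reps[i] <- sum(quant)
    if (!any(quant)) next
    l2q <- l2[quant]
    cpq <- cp[quant]
    if (all(cpq == "heavy_only")) {
      out$ratio_hl[i] <- RATIO_CAP_HEAVY
      out$capped[i] <- "heavy_only"
    } else if (all(cpq == "light_only")) {
      out$ratio_hl[i] <- RATIO_CAP_LIGHT
      out$capped[i] <- "light_only"
    } else {
      out$ratio_hl[i] <- 2^stats::median(l2q)
      out$capped[i] <- "none"
    }
    out$log2_ratio[i] <- log2(out$ratio_hl[i])
    uncapped <- l2q[cpq == "none"]
    if (length(uncapped) >= 2 && stats::sd(uncapped) > 0) {
      out$p_value[i] <- stats::t.test(uncapped, mu = 0)$p.value
    }
  }
  first_rows <- vapply(idx, function(rows) rows[1], integer(1))
  for (cc in carry) {
    out[[cc]] <- table[[cc]][first_rows]
  }
  out
}

#' Pairwise replicate-to-replicate Pearson correlation of log2 ratios
#'
#' For each pair of replicates, Pearson's r is computed over the features
#' quantified without capping in both members of the pair. Pairs sharing
#' fewer than 3 such features get `NA`.
#'
#' @param table Output of [compute_ratios()] (long format, uncapped rows
#'   are used).
#' @param by Key column name.
#' @return Symmetric correlation matrix with unit diagonal, one
#'   row/column per replicate.
#' @export
replicate_correlation <- function(table, by = "peptide") {
  reps <- sort(unique(table$replicate))
  check_that(length(reps) >= 2,
             "replicate_correlation(): need at least 2 replicates")
  ok <- !is.na(table$log2_ratio) & table$capped == "none"
  tab <- table[ok, c(by, "replicate", "log2_ratio")]
  wide <- stats::reshape(tab, idvar = by, timevar = "replicate",
                         direction = "wide")
  mat <- as.matrix(wide[, paste0("log2_ratio.", reps), drop = FALSE])
  k <- length(reps)
  r <- diag(1, k)
  dimnames(r) <- list(reps, reps)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      shared <- stats::complete.cases(mat[, c(i, j)])
      r[i, j] <- r[j, i] <- if (sum(shared) >= 3) {
        stats::cor(mat[shared, i], mat[shared, j])
      } else NA_real_
    }
  }
  r
}

#' Full quantification of a long-format SILAC intensity table
#'
#' Convenience wrapper: [normalize_channels()], then [compute_ratios()],
#' then [aggregate_replicates()].
#'
#' @inheritParams aggregate_replicates
#' @param table Long-format intensity table.
#' @return Per-feature quantification data frame.
#' @export
quantify_table <- function(table, by = "peptide", carry = character()) {
  aggregate_replicates(compute_ratios(normalize_channels(table)),
                       by = by, carry = carry)
}
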