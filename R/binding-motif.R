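# Position-weight-matrix binder calling: a transparent stand-in for
# neural-network MHC binding predictors. PWMs are trained from per-allele
# epitope lists, peptides are scored as summed log-odds against a
# background residue distribution, and scores are converted to percentile
# ranks against random reference-proteome peptides so that the familiar
# "%rank <= 2 = strong binder" convention applies. Precomputed %rank
# columns from an external predictor can be substituted wherever a
# BinderCall table is consumed.

#' Construct an allele PWM object
#'
#' @param allele Allele label (opaque string, e.g. `"HLA-A*02"`).
#' @param freq 20 x L probability matrix, rows named by [AA20], columns =
#'   peptide positions; each column must sum to 1.
#' @param background Length-20 background residue distribution (named by
#'   [AA20]); defaults to uniform.
#' @param pseudocount Pseudocount the matrix was built with (metadata).
#' @return Object of class `allele_pwm`.
#' @export
allele_pwm <- function(allele, freq,
                       background = stats::setNames(rep(1 / 20, 20), AA20),
                       pseudocount = 1) {
  freq <- as.matrix(freq)
  check_that(nrow(freq) == 20 && identical(rownames(freq), AA20),
             "allele_pwm(): freq must have 20 rows named by AA20")
  check_that(all(abs(colSums(freq) - 1) < 1e-9),
             "allele_pwm(): every freq column must sum to 1")
  background <- background[AA20]
  check_that(abs(sum(background) - 1) < 1e-9,
             "allele_pwm(): background must sum to 1")
  structure(list(allele = allele, length = ncol(freq), freq = freq,
                 background = background, pseudocount = pseudocount),
            class = "allele_pwm")
}

#' @export
print.allele_pwm <- function(x, ...) {
  cat(sprintf("PWM for %s, %d-mers (pseudocount %g)\n",
              x$allele, x$length, x$pseudocount))
  consensus <- paste(rownames(x$freq)[apply(x$freq, 2, which.max)],
                     collapse = "")
  cat(sprintf("  consensus: %s\n", consensus))
  invisible(x)
}

#' Train a PWM from an epitope list
#'
#' Position frequencies with a background-weighted pseudocount:
#' `freq[a, p] = (count(a at p) + pseudocount * background[a]) /
#' (n + pseudocount)`.
#'
#' @param epitopes Nonempty character vector of equal-length peptides.
#' @param allele Allele label stored on the PWM.
#' @inheritParams allele_pwm
#' @return An `allele_pwm`.
#' @export
build_pwm <- function(epitopes, allele = "allele",
                      background = stats::setNames(rep(1 / 20, 20), AA20),
                      pseudocount = 1) {
  check_that(length(epitopes) > 0, "build_pwm(): empty epitope list")
  lens <- unique(nchar(epitopes))
  check_that(length(lens) == 1,
             "build_pwm(): epitopes of mixed lengths (%s)",
             paste(lens, collapse = ", "))
  check_that(pseudocount > 0, "build_pwm(): pseudocount must be > 0")
  mat <- do.call(rbind, strsplit(epitopes, ""))
  check_that(all(mat %in% AA20),
             "build_pwm(): non-canonical residue in epitope list")
  n <- length(epitopes)
  bg <- background[AA20]
  freq <- vapply(seq_len(lens), function(p) {
    counts <- table(factor(mat[, p], levels = AA20))
    (as.numeric(counts) + pseudocount * bg) / (n + pseudocount)
  }, numeric(20))
  rownames(freq) <- AA20
  allele_pwm(allele, freq, background = bg, pseudocount = pseudocount)
}

#' Score peptides against a PWM
#'
#' Summed log-odds in bits: `sum_p log2(freq[res_p, p] /
#' background[res_p])`. Zero for any peptide when the PWM equals the
#' background at every position.
#'
#' @param pwm An `allele_pwm`.
#' @param peptides Character vector, all of the PWM's length.
#' @return Numeric score vector.
#' @export
score_peptide <- function(pwm, peptides) {
  if (length(peptides) == 0) return(numeric(0))
  check_that(all(nchar(peptides) == pwm$length),
             "score_peptide(): peptide length != PWM length (%d)", pwm$length)
  mat <- matrix(unlist(strsplit(peptides, "")), ncol = pwm$length,
                byrow = TRUE)
  check_that(all(mat %in% AA20), "score_peptide(): unknown residue")
  lo <- log2(pwm$freq / pwm$background)  # recycles background down columns
  vapply(seq_len(nrow(mat)), function(i) {
    sum(lo[cbind(match(mat[i, ], AA20), seq_len(pwm$length))])
  }, numeric(1))
}

#' Percentile rank of scores against a background score distribution
#'
#' `100 * fraction of background scores strictly greater than the query`,
#' so 0 means stronger than every background peptide. Ties count in the
#' query's favor (strictly-greater convention).
#'
#' @param score Numeric vector of query scores.
#' @param background_scores Nonempty numeric vector of scores of random
#'   reference-proteome peptides of the same length.
#' @return Numeric vector of ranks in `[0, 100]`.
#' @export
percent_rank <- function(score, background_scores) {
  check_that(length(background_scores) > 0,
             "percent_rank(): empty background")
  vapply(score, function(s) 100 * mean(background_scores > s), numeric(1))
}

#' Background scores from a reference proteome
#'
#' Slides a window of the PWM's length over every protein sequence,
#' deduplicates the resulting peptides, draws `n` of them with a recorded
#' seed, and scores them against the PWM. The returned vector carries the
#' seed as attribute `seed` so the %rank pipeline is reproducible.
#'
#' @param pwm An `allele_pwm`.
#' @param proteome Named character vector (or `Biostrings::AAStringSet`)
#'   of protein sequences.
#' @param n Number of background peptides (default 5000; at least 1000 is
#'   recommended for a stable 2% rank cutoff).
#' @param seed Integer seed for the draw.
#' @return Numeric score vector with attribute `seed`.
#' @export
background_scores <- function(pwm, proteome, n = 5000, seed = 1) {
  seqs <- as.character(proteome)
  L <- pwm$length
  windows <- unlist(lapply(seqs, function(s) {
    nc <- nchar(s)
    if (nc < L) return(character(0))
    starts <- seq_len(nc - L + 1)
    substring(s, starts, starts + L - 1)
  }), use.names = FALSE)
  windows <- unique(windows[!grepl("[^ACDEFGHIKLMNPQRSTVWY]", windows)])
  check_that(length(windows) > 0,
             "background_scores(): proteome has no %d-mer windows", L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draw <- windows[sample.int(length(windows), min(n, length(windows)))]
  structure(score_peptide(pwm, draw), seed = seed)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Call binders against a panel of allele PWMs
#'
#' Each peptide is ranked against every allele PWM of matching length; the
#' best (lowest) percentile rank wins. Class is `strong` when the best
#' rank is at most `strong` (default 2.0, the conventional strong-binder
#' cutoff), `weak` when at most `weak` (default 10), else `non`. Peptides
#' whose length no allele covers are classed `non` and flagged
#' `covered = FALSE`.
#'
#' @param peptides Character vector.
#' @param pwms List of `allele_pwm` objects.
#' @param backgrounds List of background score vectors, parallel to
#'   `pwms` (see [background_scores()]).
#' @param strong,weak Percentile-rank cutoffs.
#' @return List with `calls` (data frame: `peptide`, `best_allele`,
#'   `score`, `percent_rank`, `class`, `covered`) and
#'   `strong_by_length` (named count vector of strong binders per length).
#' @export
call_binders <- function(peptides, pwms, backgrounds, strong = 2.0,
                         weak = 10.0) {
  check_that(length(pwms) == length(backgrounds),
             "call_binders(): pwms and backgrounds differ in length")
  n <- length(peptides)
  calls <- data.frame(peptide = peptides,
                      best_allele = rep(NA_character_, n),
                      score = rep(NA_real_, n),
                      percent_rank = rep(NA_real_, n),
                      class = rep("non", n),
                      covered = rep(FALSE, n),
                      stringsAsFactors = FALSE)
  if (n == 0) {
    return(list(calls = calls,
                strong_by_length = stats::setNames(integer(0), character(0))))
  }
  lens <- nchar(peptides)
  for (k in seq_along(pwms)) {
    pwm <- pwms[[k]]
    sel <- which(lens == pwm$length)
    if (length(sel) == 0) next
    sc <- score_peptide(pwm, peptides[sel])
    pr <- percent_rank(sc, backgrounds[[k]])
    better <- is.na(calls$percent_rank[sel]) | pr < calls$percent_rank[sel]
    upd <- sel[better]
    calls$best_allele[upd] <- pwm$allele
    calls$score[upd] <- sc[better]
    calls$percent_rank[upd] <- pr[better]
    calls$covered[sel] <- TRUE
  }
  has <- !is.na(calls$percent_rank)
  calls$class[has] <- ifelse(calls$percent_rank[has] <= strong, "strong",
                             ifelse(calls$percent_rank[has] <= weak,
                                    "weak", "non"))
  strong_len <- table(lens[calls$class == "strong"])
  list(calls = calls,
       strong_by_length = stats::setNames(as.integer(strong_len),
                                          names(strong_len)))
}

#' Per-position, per-residue motif difference z-scores
#'
#' Compares residue frequencies between a sample peptide set and a
#' reference set of the same length:
#' `z[a, p] = (f_sample - f_ref) / sqrt(f_ref * (1 - f_ref) / n_sample)`.
#' Reference frequencies are clamped to
#' `[1/(n_ref + 20), 1 - 1/(n_ref + 20)]` so the denominator never
#' vanishes for residues absent from (or fixed in) the reference.
#'
#' @param sample_set,reference_set Nonempty character vectors of
#'   equal-length peptides.
#' @return 20 x L z-score matrix (rows [AA20]).
#' @export
motif_difference <- function(sample_set, reference_set) {
  check_that(length(sample_set) > 0 && length(reference_set) > 0,
             "motif_difference(): both sets must be nonempty")
  lens <- unique(c(nchar(sample_set), nchar(reference_set)))
  check_that(length(lens) == 1,
             "motif_difference(): mixed peptide lengths")
  pos_freq <- function(peps) {
    mat <- do.call(rbind, strsplit(peps, ""))
    vapply(seq_len(lens), function(p) {
      as.numeric(table(factor(mat[, p], levels = AA20))) / length(peps)
    }, numeric(20))
  }
  f_s <- pos_freq(sample_set)
  f_r <- pos_freq(reference_set)
  eps <- 1 / (length(reference_set) + 20)
  f_rc <- pmin(pmax(f_r, eps), 1 - eps)
  z <- (f_s - f_r) / sqrt(f_rc * (1 - f_rc) / length(sample_set))
  rownames(z) <- AA20
  z
}
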