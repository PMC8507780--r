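# Synthetic SILAC experiment generator with planted ground truth.
#
# Emulates one isogenic sensitive/resistant cell-line pair measured in
# three layers — Class I immunopeptidome, whole-cell proteome and Class I
# AP-MS interactome — so that every downstream stage of the pipeline can
# be validated against known truth without any raw mass-spectrometry data.

# Residues preferred at HLA Class I anchor positions in the synthetic
# motifs (hydrophobic; Lys/Arg are depleted there by construction).
ANCHOR_A <- c("L", "M")
ANCHOR_A_CT <- c("V", "L")
ANCHOR_B <- c("P", "A")
ANCHOR_B_CT <- c("L", "F")

#' Configuration for the synthetic experiment generator
#'
#' Defaults encode the study conditions this generator emulates: 1217
#' identified peptides per cell-line pair with a 9-mer-dominant 8-14-mer
#' length distribution, ~62% Lys/Arg-containing peptides, three biological
#' replicates, a planted global log2 H/L downshift of -0.5, 54% of
#' quantified peptides with reduced (ratio <= 0.5) and 5% with increased
#' (ratio >= 2) presentation, a ~5000-protein whole proteome, and an
#' AP-MS interactome containing contaminants, sub-threshold
#' identifications and 10% + 10% planted differential interactors, with a
#' 407-entry known-interactor list of which 161 fall inside the planted
#' HCI set.
#'
#' @param n_peptides Number of identified immunopeptides.
#' @param n_proteins Number of reference-proteome proteins.
#' @param n_replicates Biological replicates (>= 1).
#' @param length_weights Named probabilities over lengths 8..14 (sum 1).
#' @param frac_kr Fraction of peptides containing >= 1 Lys/Arg.
#' @param frac_quantified Fraction of labelable peptides carrying a valid
#'   SILAC ratio.
#' @param global_log2_shift Center of the planted log2 H/L ratio of
#'   unchanged peptides (the planted global shift).
#' @param frac_reduced,frac_increased Fractions of quantified peptides
#'   with planted ratio <= 0.5 / >= 2.0.
#' @param frac_heavy_only,frac_light_only Fractions of quantified
#'   peptides detected in one channel only (must not exceed
#'   `frac_increased` / `frac_reduced`, from which they are drawn).
#' @param noise_sd Replicate-to-replicate log2-intensity noise (SD).
#' @param contaminant_rate Fraction of interactome rows drawn from the
#'   contaminant list.
#' @param n_interactors Rows in the AP-MS interactome table.
#' @param n_contaminants Size of the contaminant accession list.
#' @param n_known,n_known_in_hci Known-interactor list size and how many
#'   of its entries are planted inside the HCI set.
#' @param n_gene_sets Number of synthetic gene sets.
#' @param seed Integer seed; the whole experiment is deterministic given
#'   the configuration.
#' @return Validated list of class `generator_config`.
#' @export
generator_config <- function(n_peptides = 1217,
                             n_proteins = 5000,
                             n_replicates = 3,
                             length_weights = c(`8` = 0.12, `9` = 0.45,
                                                `10` = 0.18, `11` = 0.10,
                                                `12` = 0.06, `13` = 0.05,
                                                `14` = 0.04),
                             frac_kr = 0.62,
                             frac_quantified = 0.75,
                             global_log2_shift = -0.5,
                             frac_reduced = 0.54,
                             frac_increased = 0.05,
                             frac_heavy_only = 0.02,
                             frac_light_only = 0.02,
                             noise_sd = 0.2,
                             contaminant_rate = 0.1,
                             n_interactors = 600,
                             n_contaminants = 100,
                             n_known = 407,
                             n_known_in_hci = 161,
                             n_gene_sets = 20,
                             seed = 1) {
  cfg <- list(n_peptides = n_peptides, n_proteins = n_proteins,
              n_replicates = n_replicates, length_weights = length_weights,
              frac_kr = frac_kr, frac_quantified = frac_quantified,
              global_log2_shift = global_log2_shift,
              frac_reduced = frac_reduced, frac_increased = frac_increased,
              frac_heavy_only = frac_heavy_only,
              frac_light_only = frac_light_only, noise_sd = noise_sd,
              contaminant_rate = contaminant_rate,
              n_interactors = n_interactors,
              n_contaminants = n_contaminants, n_known = n_known,
              n_known_in_hci = n_known_in_hci, n_gene_sets = n_gene_sets,
              seed = seed)
  for (f in c("frac_kr", "frac_quantified", "frac_reduced",
              "frac_increased", "frac_heavy_only", "frac_light_only",
              "contaminant_rate")) {
    check_that(is_fraction(cfg[[f]]),
               "generator_config(): %s must be a fraction in [0, 1]", f)
  }
  check_that(cfg$n_peptides >= 0 && cfg$n_proteins >= 1,
             "generator_config(): need n_peptides >= 0 and n_proteins >= 1")
  check_that(cfg$n_replicates >= 1,
             "generator_config(): n_replicates must be >= 1")
  check_that(identical(names(length_weights), as.character(8:14)),
             "generator_config(): length_weights must be named '8'..'14'")
  check_that(abs(sum(length_weights) - 1) < 1e-9,
             "generator_config(): length_weights must sum to 1")
  check_that(cfg$frac_reduced + cfg$frac_increased <= 1,
             "generator_config(): frac_reduced + frac_increased > 1")
  check_that(cfg$frac_light_only <= cfg$frac_reduced,
             "generator_config(): frac_light_only must not exceed frac_reduced")
  check_that(cfg$frac_heavy_only <= cfg$frac_increased,
             "generator_config(): frac_heavy_only must not exceed frac_increased")
  check_that(cfg$noise_sd >= 0, "generator_config(): noise_sd must be >= 0")
  check_that(length(seed) == 1 && seed == trunc(seed),
             "generator_config(): seed must be a single integer")
  structure(cfg, class = "generator_config")
}

# size-safe sample: never triggers R's scalar-x expansion
sample_vec <- function(x, k, replace = FALSE) {
  x[sample.int(length(x), k, replace = replace)]
}

# A peaked PWM column: `weight` probability mass shared by the favored
# residues, the remainder spread uniformly over all 20.
peaked_column <- function(favored, weight) {
  p <- rep((1 - weight) / 20, 20)
  names(p) <- AA20
  p[favored] <- p[favored] + weight / length(favored)
  p
}

#' Synthetic allele PWMs with hydrophobic anchors
#'
#' Two fixed synthetic Class I motifs per length: anchor positions 2 and
#' the C-terminus carry a sharp hydrophobic preference (Lys/Arg depleted
#' there), non-anchor positions a mild rotating preference. These motifs
#' are what [generate_experiment()] samples its binder peptides from, and
#' they double as the "trained" PWMs the binder-calling stage should
#' recover.
#'
#' @param lengths Peptide lengths to build matrices for.
#' @param alleles Two allele labels.
#' @return List of `allele_pwm` objects named `"<allele>/<length>"`.
#' @export
synthetic_allele_pwms <- function(lengths = 8:14,
                                  alleles = c("HLA-A*02-syn",
                                              "HLA-B*07-syn")) {
  check_that(length(alleles) == 2,
             "synthetic_allele_pwms(): exactly two allele labels expected")
  mild_sets <- list(c("S", "T", "A"), c("E", "D", "K"), c("G", "N", "Q"),
                    c("V", "I", "T"), c("R", "K", "H"), c("F", "Y", "W"),
                    c("L", "A", "S"))
  build <- function(allele, anchor2, anchor_ct, L) {
    freq <- vapply(seq_len(L), function(p) {
      if (p == 2) peaked_column(anchor2, 0.85)
      else if (p == L) peaked_column(anchor_ct, 0.85)
      else peaked_column(mild_sets[[(p - 1) %% 7 + 1]], 0.30)
    }, numeric(20))
    rownames(freq) <- AA20
    allele_pwm(allele, freq)
  }
  pwms <- list()
  for (L in lengths) {
    pwms[[paste0(alleles[1], "/", L)]] <- build(alleles[1], ANCHOR_A,
                                                ANCHOR_A_CT, L)
    pwms[[paste0(alleles[2], "/", L)]] <- build(alleles[2], ANCHOR_B,
                                                ANCHOR_B_CT, L)
  }
  pwms
}

#' Sample peptides from a PWM
#'
#' Residues drawn independently per position from the PWM's frequency
#' matrix.
#'
#' @param pwm An `allele_pwm`.
#' @param n Number of peptides.
#' @param seed Optional integer seed; when given, the caller's RNG state
#'   is preserved.
#' @return Character vector of `n` peptides.
#' @export
sample_binder_peptides <- function(pwm, n, seed = NULL) {
  check_that(inherits(pwm, "allele_pwm"),
             "sample_binder_peptides(): pwm must be an allele_pwm")
  if (n == 0) return(character(0))
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  mat <- vapply(seq_len(pwm$length), function(p) {
    sample(AA20, n, replace = TRUE, prob = pwm$freq[, p])
  }, character(n))
  if (n == 1) mat <- matrix(mat, nrow = 1)
  apply(mat, 1, paste0, collapse = "")
}

# Force the presence/absence of Lys/Arg on a sampled peptide without
# touching the anchor positions (2 and C-terminal).
enforce_kr <- function(pep, want_kr) {
  chars <- strsplit(pep, "")[[1]]
  L <- length(chars)
  has <- any(chars %in% c("K", "R"))
  if (want_kr && !has) {
    pos <- setdiff(seq_len(L), c(2L, L))
    chars[pos[sample.int(length(pos), 1)]] <- sample(c("K", "R"), 1)
  } else if (!want_kr && has) {
    hit <- which(chars %in% c("K", "R"))
    repl <- setdiff(AA20, c("K", "R"))
    chars[hit] <- sample(repl, length(hit), replace = TRUE)
  }
  paste0(chars, collapse = "")
}

# Scale rows with planted ratio > 1 so that, per replicate, heavy and
# light channel totals agree over rows detected in both channels. Total-
# intensity normalization then leaves the planted ratios untouched (in
# real data this sum-balance is supplied by the dominance of a few highly
# abundant species). Row scaling multiplies both channels, so no ratio
# changes. Skipped (with a warning) when no up-shifted rows exist.
balance_channels <- function(tab, up_rows) {
  for (rep_id in unique(tab$replicate)) {
    sel <- tab$replicate == rep_id & !is.na(tab$intensity_L) &
      !is.na(tab$intensity_H)
    up <- sel & up_rows
    dn <- sel & !up_rows
    d_up <- sum(tab$intensity_H[up] - tab$intensity_L[up])
    d_dn <- sum(tab$intensity_H[dn] - tab$intensity_L[dn])
    if (!any(up) || d_up <= 0 || d_dn >= 0) {
      warning("balance_channels(): cannot balance replicate ", rep_id,
              "; channel sums left unequal")
      next
    }
    f <- -d_dn / d_up
    tab$intensity_L[up] <- tab$intensity_L[up] * f
    tab$intensity_H[up] <- tab$intensity_H[up] * f
  }
  tab
}

# Long-format replicate intensity rows from per-feature base abundances
# and planted log2 ratios. `channel` is "both", "heavy_only",
# "light_only" or "absent".
replicate_intensities <- function(base_log2, true_log2, channel,
                                  n_replicates, noise_sd) {
  n <- length(base_log2)
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    l2l <- base_log2 + stats::rnorm(n, 0, noise_sd)
    l2h <- l2l + true_log2 + stats::rnorm(n, 0, noise_sd)
    il <- 2^l2l
    ih <- 2^l2h
    ih[channel == "heavy_only"] <- 2^(base_log2[channel == "heavy_only"] +
                                        stats::rnorm(sum(channel == "heavy_only"),
                                                     0, noise_sd))
    il[channel %in% c("heavy_only", "absent")] <- NA_real_
    ih[channel %in% c("light_only", "absent")] <- NA_real_
    out[[r]] <- data.frame(replicate = r, intensity_L = il,
                           intensity_H = ih)
  }
  out
}

#' Generate a complete synthetic SILAC experiment
#'
#' Produces the three long-format intensity tables (immunopeptidome,
#' whole proteome, AP-MS interactome), the reference proteome, the
#' contaminant and known-interactor lists, per-allele epitope lists,
#' synthetic gene sets with direction annotations, and the planted truth
#' for every layer. Deterministic given the configuration (including its
#' seed). Peptides are sampled from anchor-constrained allele PWMs and
#' implanted verbatim into their source proteins, so the peptide-to-
#' protein mapping can be verified by string search.
#'
#' @param config A [generator_config()].
#' @return Object of class `silac_experiment`: list with elements
#'   `peptides`, `proteome`, `interactome` (long-format tables),
#'   `proteome_fasta` (named character), `contaminants`,
#'   `known_interactors`, `epitopes` (per-allele peptide lists),
#'   `gene_sets`, `directions`, `truth` (per-layer planted truth) and
#'   `config`.
#' @export
generate_experiment <- function(config = generator_config()) {
  check_that(inherits(config, "generator_config"),
             "generate_experiment(): config must be a generator_config")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  alleles <- c("HLA-A*02-syn", "HLA-B*07-syn")
  pwms <- synthetic_allele_pwms(8:14, alleles)

  ## Reference proteome ----------------------------------------------------
  n_prot <- config$n_proteins
  accessions <- sprintf("SP%05d", seq_len(n_prot))
  genes <- sprintf("GENE%04d", seq_len(n_prot))
  prot_len <- sample(200:600, n_prot, replace = TRUE)
  letters_pool <- sample(AA20, sum(prot_len), replace = TRUE)
  ends <- cumsum(prot_len)
  starts <- c(1, utils::head(ends, -1) + 1)
  big <- paste0(letters_pool, collapse = "")
  prot_seq <- substring(big, starts, ends)
  names(prot_seq) <- accessions

  ## Immunopeptides --------------------------------------------------------
  n_pep <- config$n_peptides
  if (n_pep > 0) {
    lens <- sample(8:14, n_pep, replace = TRUE,
                   prob = config$length_weights)
    pep_allele <- sample(alleles, n_pep, replace = TRUE)
    peptides <- character(n_pep)
    for (al in alleles) {
      for (L in 8:14) {
        sel <- which(pep_allele == al & lens == L)
        if (length(sel) > 0) {
          peptides[sel] <- sample_binder_peptides(
            pwms[[paste0(al, "/", L)]], length(sel))
        }
      }
    }
    want_kr <- stats::rbinom(n_pep, 1, config$frac_kr) == 1
    peptides <- vapply(seq_len(n_pep),
                       function(i) enforce_kr(peptides[i], want_kr[i]),
                       character(1))
    # resolve rare duplicate draws so peptide is a valid key
    while (anyDuplicated(peptides)) {
      d <- which(duplicated(peptides))
      for (i in d) {
        peptides[i] <- enforce_kr(
          sample_binder_peptides(pwms[[paste0(pep_allele[i], "/",
                                              lens[i])]], 1),
          want_kr[i])
      }
    }
    has_kr <- grepl("[KR]", peptides)

    # planted status among quantified peptides
    labelable <- which(has_kr)
    n_quant <- round(config$frac_quantified * length(labelable))
    quantified <- sort(sample_vec(labelable, n_quant))
    status <- rep("not_quantified", n_pep)
    n_red <- round(config$frac_reduced * n_quant)
    n_inc <- round(config$frac_increased * n_quant)
    lab <- sample(c(rep("reduced", n_red), rep("increased", n_inc),
                    rep("unchanged", n_quant - n_red - n_inc)))
    status[quantified] <- lab
    channel <- rep("absent", n_pep)
    channel[quantified] <- "both"
    n_lo <- round(config$frac_light_only * n_quant)
    n_ho <- round(config$frac_heavy_only * n_quant)
    red_idx <- quantified[status[quantified] == "reduced"]
    inc_idx <- quantified[status[quantified] == "increased"]
    if (n_lo > 0) channel[sample_vec(red_idx, n_lo)] <- "light_only"
    if (n_ho > 0) channel[sample_vec(inc_idx, n_ho)] <- "heavy_only"

    true_log2 <- rep(NA_real_, n_pep)
    red <- status == "reduced" & channel == "both"
    inc <- status == "increased" & channel == "both"
    unc <- status == "unchanged"
    true_log2[red] <- stats::runif(sum(red), -2.5, -1.2)
    true_log2[inc] <- stats::runif(sum(inc), 1.2, 2.5)
    true_log2[unc] <- pmin(pmax(config$global_log2_shift +
                                  stats::rnorm(sum(unc), 0, 0.25),
                                -0.8), 0.8)
    true_log2[channel == "light_only"] <- log2(RATIO_CAP_LIGHT)
    true_log2[channel == "heavy_only"] <- log2(RATIO_CAP_HEAVY)

    # implant each peptide into a source protein
    host <- if (n_prot >= n_pep) sample.int(n_prot, n_pep)
            else sample.int(n_prot, n_pep, replace = TRUE)
    occupied <- vector("list", n_prot)
    for (i in seq_len(n_pep)) {
      placed <- FALSE
      for (try_prot in c(host[i], sample.int(n_prot, min(20, n_prot)))) {
        L <- lens[i]
        max_start <- nchar(prot_seq[try_prot]) - L + 1
        if (max_start < 1) next
        for (attempt in 1:20) {
          st <- sample.int(max_start, 1)
          iv <- c(st, st + L - 1)
          clash <- any(vapply(occupied[[try_prot]], function(o) {
            iv[1] <= o[2] && o[1] <= iv[2]
          }, logical(1)))
          if (!clash) {
            s <- prot_seq[try_prot]
            prot_seq[try_prot] <- paste0(substr(s, 1, st - 1), peptides[i],
                                         substr(s, st + L, nchar(s)))
            occupied[[try_prot]] <- c(occupied[[try_prot]], list(iv))
            host[i] <- try_prot
            placed <- TRUE
            break
          }
        }
        if (placed) break
      }
      if (!placed) stop("generate_experiment(): could not place peptide ",
                        peptides[i])
    }
    pep_protein <- accessions[host]

    pep_fdr <- stats::runif(n_pep, 0, 0.01)
    base <- stats::rnorm(n_pep, 21, 1.5)
    reps <- replicate_intensities(base, true_log2, channel,
                                  config$n_replicates, config$noise_sd)
    pep_table <- do.call(rbind, lapply(reps, function(r) {
      data.frame(peptide = peptides, proteins = pep_protein,
                 n_kr = vapply(strsplit(peptides, ""),
                               function(x) sum(x %in% c("K", "R")),
                               integer(1)),
                 replicate = r$replicate, intensity_L = r$intensity_L,
                 intensity_H = r$intensity_H,
                 id_fdr = pep_fdr,
                 stringsAsFactors = FALSE)
    }))
    pep_table <- balance_channels(pep_table,
                                  rep(!is.na(true_log2) & true_log2 > 0,
                                      config$n_replicates))
    pep_truth <- data.frame(peptide = peptides, protein = pep_protein,
                            length = lens, has_kr = has_kr,
                            channel = channel, status = status,
                            true_log2 = true_log2,
                            stringsAsFactors = FALSE)
  } else {
    pep_table <- data.frame(peptide = character(), proteins = character(),
                            n_kr = integer(), replicate = integer(),
                            intensity_L = numeric(), intensity_H = numeric(),
                            id_fdr = numeric(), stringsAsFactors = FALSE)
    pep_truth <- data.frame(peptide = character(), protein = character(),
                            length = integer(), has_kr = logical(),
                            channel = character(), status = character(),
                            true_log2 = numeric(), stringsAsFactors = FALSE)
  }

  ## Whole proteome --------------------------------------------------------
  prot_altered <- stats::rbinom(n_prot, 1, 0.10) == 1
  # non-altered proteins stay clear of the |log2| > 0.6 selection cutoff
  # so planted labels remain consistent with planted ratios
  prot_true <- pmin(pmax(stats::rnorm(n_prot, 0, 0.25), -0.5), 0.5)
  n_alt <- sum(prot_altered)
  prot_true[prot_altered] <- sample(c(-1, 1), n_alt, replace = TRUE) *
    stats::runif(n_alt, 0.7, 1.8)
  prot_base <- stats::rnorm(n_prot, 23, 2)
  prot_reps <- replicate_intensities(prot_base, prot_true,
                                     rep("both", n_prot),
                                     config$n_replicates, config$noise_sd)
  prot_table <- do.call(rbind, lapply(prot_reps, function(r) {
    data.frame(protein = accessions, gene = genes, replicate = r$replicate,
               intensity_L = r$intensity_L, intensity_H = r$intensity_H,
               unique_peptides = 2L + stats::rpois(n_prot, 8),
               id_fdr = stats::runif(n_prot, 0, 0.01),
               stringsAsFactors = FALSE)
  }))
  prot_table <- balance_channels(prot_table,
                                 rep(prot_true > 0, config$n_replicates))
  prot_truth <- data.frame(protein = accessions, gene = genes,
                           true_log2 = prot_true, altered = prot_altered,
                           stringsAsFactors = FALSE)

  ## AP-MS interactome -----------------------------------------------------
  contaminants <- sprintf("CRAP%04d", seq_len(config$n_contaminants))
  n_int <- config$n_interactors
  n_contam_rows <- min(round(config$contaminant_rate * n_int),
                       config$n_contaminants)
  n_clean <- n_int - n_contam_rows
  # clean rows come from non-altered proteome proteins so that the shared
  # proteome signal of unchanged interactors is not itself differential
  clean_pool <- which(!prot_altered)
  check_that(length(clean_pool) >= n_clean,
             "generate_experiment(): too few non-altered proteins for the interactome")
  clean_idx <- sample_vec(clean_pool, n_clean)
  n_low_unique <- round(0.08 * n_clean)
  n_high_fdr <- round(0.08 * n_clean)
  kind <- sample(c(rep("low_unique", n_low_unique),
                   rep("high_fdr", n_high_fdr),
                   rep("hci", n_clean - n_low_unique - n_high_fdr)))
  n_hci <- sum(kind == "hci")
  int_status <- rep("not_hci", n_clean)
  n_int_inc <- round(0.10 * n_hci)
  n_int_dec <- round(0.10 * n_hci)
  hci_lab <- sample(c(rep("increased", n_int_inc), rep("decreased", n_int_dec),
                      rep("unchanged", n_hci - n_int_inc - n_int_dec)))
  int_status[kind == "hci"] <- hci_lab
  # unchanged interactors track their protein's whole-proteome fold change
  # (plus independent noise) and are clamped clear of the 1.5 / 0.67
  # calling cutoffs, keeping planted labels consistent with planted ratios
  int_true <- pmin(pmax(prot_true[clean_idx] +
                          stats::rnorm(n_clean, 0, 0.12), -0.45), 0.45)
  int_true[int_status == "increased"] <-
    stats::runif(sum(int_status == "increased"), 0.9, 1.5)
  int_true[int_status == "decreased"] <-
    -stats::runif(sum(int_status == "decreased"), 0.9, 1.5)

  int_protein <- c(accessions[clean_idx], contaminants[seq_len(n_contam_rows)])
  int_gene <- c(genes[clean_idx],
                contaminants[seq_len(n_contam_rows)])
  int_true_all <- c(int_true, stats::rnorm(n_contam_rows, 0, 0.3))
  int_unique <- integer(n_int)
  int_unique[seq_len(n_clean)] <- ifelse(kind == "low_unique", 1L,
                                         2L + stats::rpois(n_clean, 5))
  int_unique[n_clean + seq_len(n_contam_rows)] <-
    2L + stats::rpois(n_contam_rows, 5)
  int_fdr <- numeric(n_int)
  int_fdr[seq_len(n_clean)] <- ifelse(kind == "high_fdr",
                                      stats::runif(n_clean, 0.01, 0.05),
                                      stats::runif(n_clean, 0, 0.0099))
  int_fdr[n_clean + seq_len(n_contam_rows)] <-
    stats::runif(n_contam_rows, 0, 0.0099)
  int_base <- stats::rnorm(n_int, 20, 1.5)
  int_reps <- replicate_intensities(int_base, int_true_all,
                                    rep("both", n_int),
                                    config$n_replicates, config$noise_sd)
  int_table <- do.call(rbind, lapply(int_reps, function(r) {
    data.frame(protein = int_protein, gene = int_gene,
               replicate = r$replicate, intensity_L = r$intensity_L,
               intensity_H = r$intensity_H, unique_peptides = int_unique,
               id_fdr = int_fdr, stringsAsFactors = FALSE)
  }))
  int_table <- balance_channels(int_table,
                                rep(int_true_all > 0, config$n_replicates))
  int_hci <- c(kind == "hci", rep(FALSE, n_contam_rows))
  int_truth <- data.frame(protein = int_protein, gene = int_gene,
                          hci = int_hci,
                          status = c(int_status, rep("not_hci",
                                                     n_contam_rows)),
                          true_log2 = int_true_all,
                          stringsAsFactors = FALSE)

  ## Known-interactor list -------------------------------------------------
  hci_acc <- int_protein[int_hci]
  n_in <- min(config$n_known_in_hci, length(hci_acc))
  outside_pool <- setdiff(accessions, int_protein)
  n_out <- min(config$n_known - n_in, length(outside_pool))
  known <- c(sample_vec(hci_acc, n_in), sample_vec(outside_pool, n_out))

  ## Epitope lists and gene sets -------------------------------------------
  epitopes <- stats::setNames(lapply(alleles, function(al) {
    sample_binder_peptides(pwms[[paste0(al, "/9")]], 200)
  }), alleles)

  up_genes <- genes[prot_altered & prot_true > 0]
  dn_genes <- genes[prot_altered & prot_true < 0]
  other_genes <- genes[!prot_altered]
  n_sets <- config$n_gene_sets
  gene_sets <- list()
  directions <- list()
  for (s in seq_len(n_sets)) {
    nm <- sprintf("SET_%02d", s)
    if (s <= 3 && length(up_genes) >= 15) {          # planted activated
      members <- c(sample_vec(up_genes, 15),
                   sample_vec(other_genes, 15))
      dir <- rep(1, 30)
    } else if (s <= 6 && length(dn_genes) >= 15) {   # planted inhibited
      members <- c(sample_vec(dn_genes, 15),
                   sample_vec(other_genes, 15))
      dir <- rep(1, 30)
    } else {
      members <- sample_vec(genes, 30)
      dir <- sample(c(-1, 1), 30, replace = TRUE)
    }
    gene_sets[[nm]] <- members
    directions[[nm]] <- data.frame(set = nm, gene = members,
                                   direction = dir,
                                   stringsAsFactors = FALSE)
  }
  directions <- do.call(rbind, directions)
  rownames(directions) <- NULL

  structure(list(
    peptides = pep_table, proteome = prot_table, interactome = int_table,
    proteome_fasta = prot_seq, contaminants = contaminants,
    known_interactors = known, epitopes = epitopes,
    gene_sets = gene_sets, directions = directions,
    truth = list(peptides = pep_truth, proteins = prot_truth,
                 interactors = int_truth),
    config = config
  ), class = "silac_experiment")
}

#' @export
print.silac_experiment <- function(x, ...) {
  cat("Synthetic SILAC experiment\n")
  cat(sprintf("  peptides    : %d identified x %d replicates\n",
              nrow(x$truth$peptides), x$config$n_replicates))
  cat(sprintf("  proteome    : %d proteins\n", nrow(x$truth$proteins)))
  cat(sprintf("  interactome : %d rows (%d planted HCIs)\n",
              nrow(x$truth$interactors), sum(x$truth$interactors$hci)))
  invisible(x)
}
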