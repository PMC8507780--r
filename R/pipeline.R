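# End-to-end orchestration: a single configuration object carries every
# input path and threshold, and run_pipeline() executes quantification ->
# peptidome profiling -> binder calling -> interactome filtering ->
# cross-layer integration, writing stage tables and a reproducible
# summary.

#' Pipeline configuration
#'
#' Collects input paths and every analysis threshold, each with its
#' conventional default: peptidome fold-change cutoffs 2.0/0.5,
#' interactome cutoffs 1.5/0.67 at alpha 0.05, strong/weak binder
#' percentile ranks 2.0/10, altered-protein magnitude |log2| > 0.6,
#' identification FDR < 0.01 with >= 2 unique peptides.
#'
#' @param input_dir Directory holding the standard fixture files (see
#'   [write_fixtures()]); individual paths may be overridden.
#' @param outdir Output directory for stage tables and the summary.
#' @param peptides,proteome,interactome,fasta,contaminants,known,gmt,directions
#'   Explicit file paths (default: standard names under `input_dir`).
#' @param epitopes Named character vector of epitope-list paths, names =
#'   allele labels (default: every `epitopes_*.txt` under `input_dir`).
#' @param pep_up,pep_down Peptidome differential-presentation cutoffs.
#' @param int_up,int_down,alpha Interactome differential cutoffs and
#'   significance level.
#' @param strong_rank,weak_rank Binder-class percentile-rank cutoffs.
#' @param altered_log2 Altered-protein |log2| cutoff.
#' @param fdr_max,min_unique HCI filter thresholds.
#' @param background_n Background peptides per allele for %rank.
#' @param seed Seed for the %rank background draw.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, outdir = file.path(input_dir, "out"),
                            peptides = file.path(input_dir, "peptides.tsv"),
                            proteome = file.path(input_dir, "proteome.tsv"),
                            interactome = file.path(input_dir,
                                                    "interactome.tsv"),
                            fasta = file.path(input_dir,
                                              "reference_proteome.fasta"),
                            contaminants = file.path(input_dir,
                                                     "contaminants.txt"),
                            known = file.path(input_dir,
                                              "known_interactors.txt"),
                            gmt = file.path(input_dir, "gene_sets.gmt"),
                            directions = file.path(input_dir,
                                                   "gene_directions.tsv"),
                            epitopes = NULL,
                            pep_up = 2.0, pep_down = 0.5,
                            int_up = 1.5, int_down = 0.67, alpha = 0.05,
                            strong_rank = 2.0, weak_rank = 10.0,
                            altered_log2 = 0.6,
                            fdr_max = 0.01, min_unique = 2,
                            background_n = 5000, seed = 1) {
  if (is.null(epitopes)) {
    files <- list.files(input_dir, pattern = "^epitopes_.*\\.txt$",
                        full.names = TRUE)
    labels <- sub("^epitopes_(.*)\\.txt$", "\\1", basename(files))
    epitopes <- stats::setNames(files, labels)
  }
  cfg <- list(outdir = outdir, peptides = peptides, proteome = proteome,
              interactome = interactome, fasta = fasta,
              contaminants = contaminants, known = known, gmt = gmt,
              directions = directions, epitopes = epitopes,
              pep_up = pep_up, pep_down = pep_down, int_up = int_up,
              int_down = int_down, alpha = alpha,
              strong_rank = strong_rank, weak_rank = weak_rank,
              altered_log2 = altered_log2, fdr_max = fdr_max,
              min_unique = min_unique, background_n = background_n,
              seed = seed)
  for (f in c("pep_up", "pep_down", "int_up", "int_down", "strong_rank",
              "weak_rank", "altered_log2", "fdr_max", "min_unique")) {
    check_that(is.numeric(cfg[[f]]) && cfg[[f]] > 0,
               "pipeline_config(): %s must be positive", f)
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The file must contain `input_dir`; any other key overrides the
#' matching [pipeline_config()] argument.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  check_that(!is.null(y$input_dir),
             "read_pipeline_config(): 'input_dir' is required")
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes quantification, peptidome profiling, binder calling,
#' interactome filtering and cross-layer integration, writing per-stage
#' TSVs and `summary.yaml` under the configured output directory. Stages
#' whose inputs are missing or empty (interactome, binder calling,
#' enrichment) are skipped and marked absent in the summary; the
#' peptidome stages always run. The run is deterministic given the inputs
#' and the configured seed.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log per-stage row counts to the console.
#' @return (Invisibly) list of class `pipeline_result` with elements
#'   `quant` (per-layer quantifications), `peptidome`, `binders`,
#'   `interactome`, `integration`, `summary`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  check_that(inherits(config, "pipeline_config"),
             "run_pipeline(): config must be a pipeline_config")
  say <- function(...) if (verbose) message(sprintf(...))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  summary <- list()

  ## Peptidome quantification ---------------------------------------------
  pep_raw <- read_peptide_table(config$peptides)
  say("peptides: %d rows in", nrow(pep_raw))
  pep_quant <- quantify_table(pep_raw, by = "peptide", carry = "proteins")
  pep_quant$protein <- sub(";.*$", "", pep_quant$proteins)
  rep_cor <- if (length(unique(pep_raw$replicate)) >= 2) {
    replicate_correlation(compute_ratios(normalize_channels(pep_raw)),
                          by = "peptide")
  } else NULL
  write_tsv(pep_quant[, c("peptide", "protein", "ratio_hl", "log2_ratio",
                          "capped", "p_value", "n_reps")],
            out("peptide_quant.tsv"))

  ## Peptidome profiling ---------------------------------------------------
  cascade <- discovery_pipeline(pep_quant)
  say("cascade: %d -> %d -> %d -> %d", cascade$n_identified,
      cascade$n_labelable, cascade$n_quantified, cascade$n_8_14)
  lengths <- length_distribution(cascade$stages$quantified)
  nine <- cascade$stages$quantified[
    nchar(cascade$stages$quantified) == 9]
  label_profile <- label_position_profile(nine)
  diff_pres <- call_differential_presentation(pep_quant,
                                              up = config$pep_up,
                                              down = config$pep_down)
  shift <- global_shift(pep_quant)
  write_tsv(data.frame(stage = c("identified", "labelable", "quantified",
                                 "in_8_14"),
                       n = c(cascade$n_identified, cascade$n_labelable,
                             cascade$n_quantified, cascade$n_8_14)),
            out("cascade.tsv"))
  write_tsv(diff_pres$calls[, c("peptide", "ratio_hl", "log2_ratio",
                                "capped", "p_value", "status")],
            out("peptide_differential.tsv"))
  summary$peptidome <- list(
    cascade = list(identified = cascade$n_identified,
                   labelable = cascade$n_labelable,
                   quantified = cascade$n_quantified,
                   in_8_14 = cascade$n_8_14),
    length_mode = lengths$mode,
    differential = as.list(diff_pres$counts),
    differential_percent = as.list(diff_pres$percent),
    median_log2 = unname(shift["median"]))

  ## Binder calling ---------------------------------------------------------
  binders <- NULL
  if (length(config$epitopes) > 0 && file.exists(config$fasta)) {
    proteome_seq <- read_proteome_fasta(config$fasta)
    pwms <- list()
    bgs <- list()
    for (al in names(config$epitopes)) {
      eps <- read_accession_list(config$epitopes[[al]])
      if (length(eps) == 0) next
      pwm <- build_pwm(eps, allele = al)
      pwms[[al]] <- pwm
      bgs[[al]] <- background_scores(pwm, proteome_seq,
                                     n = config$background_n,
                                     seed = config$seed)
    }
    if (length(pwms) > 0) {
      covered_len <- unique(vapply(pwms, `[[`, numeric(1), "length"))
      query <- cascade$stages$quantified[
        nchar(cascade$stages$quantified) %in% covered_len]
      binders <- call_binders(query, pwms, bgs,
                              strong = config$strong_rank,
                              weak = config$weak_rank)
      write_tsv(binders$calls, out("binder_calls.tsv"))
      summary$binders <- list(
        n_scored = nrow(binders$calls),
        n_strong = sum(binders$calls$class == "strong"),
        strong_percent = if (nrow(binders$calls) > 0)
          summary_percentages(sum(binders$calls$class == "strong"),
                              nrow(binders$calls)) else NA_integer_)
    }
  }
  if (is.null(binders)) summary$binders <- "absent"

  ## Whole proteome ---------------------------------------------------------
  prot_quant <- NULL
  if (file.exists(config$proteome)) {
    prot_raw <- read_protein_table(config$proteome)
    if (nrow(prot_raw) > 0) {
      prot_quant <- quantify_table(prot_raw, by = "protein",
                                   carry = c("gene", "unique_peptides",
                                             "id_fdr"))
      write_tsv(prot_quant, out("proteome_quant.tsv"))
      summary$proteome <- list(
        n_quantified = sum(!is.na(prot_quant$ratio_hl)),
        n_altered = length(select_altered(prot_quant,
                                          config$altered_log2)))
    }
  }
  if (is.null(prot_quant)) summary$proteome <- "absent"

  ## Interactome ------------------------------------------------------------
  interactome <- NULL
  if (file.exists(config$interactome)) {
    int_raw <- read_protein_table(config$interactome)
    if (nrow(int_raw) > 0) {
      int_quant <- quantify_table(int_raw, by = "protein",
                                  carry = c("gene", "unique_peptides",
                                            "id_fdr"))
      contams <- if (file.exists(config$contaminants)) {
        read_accession_list(config$contaminants)
      } else character()
      int_quant <- filter_hci(int_quant, contams,
                              fdr_max = config$fdr_max,
                              min_unique = config$min_unique)
      hci_quant <- int_quant[int_quant$hci, , drop = FALSE]
      say("interactome: %d proteins, %d HCIs", nrow(int_quant),
          nrow(hci_quant))
      diff_int <- call_differential_interaction(hci_quant,
                                                up = config$int_up,
                                                down = config$int_down,
                                                alpha = config$alpha)
      recovery <- if (file.exists(config$known)) {
        known_recovery(hci_quant$protein,
                       read_accession_list(config$known))
      } else NULL
      write_tsv(int_quant, out("interactome_quant.tsv"))
      write_tsv(diff_int$calls, out("interactome_differential.tsv"))
      interactome <- list(quant = int_quant, hci = hci_quant,
                          differential = diff_int, recovery = recovery)
      summary$interactome <- list(
        n_input = nrow(int_quant), n_hci = nrow(hci_quant),
        differential = as.list(diff_int$counts),
        altered_percent = diff_int$altered_percent,
        known_recovered = if (!is.null(recovery)) recovery$recovered
          else NA_integer_,
        known_percent = if (!is.null(recovery)) recovery$percent
          else NA_integer_,
        novel = if (!is.null(recovery)) recovery$novel else NA_integer_)
    }
  }
  if (is.null(interactome)) summary$interactome <- "absent"

  ## Integration ------------------------------------------------------------
  integration <- list()
  if (!is.null(prot_quant)) {
    pp <- try(peptide_protein_correlation(pep_quant, prot_quant),
              silent = TRUE)
    if (!inherits(pp, "try-error")) {
      integration$peptide_protein <- pp
      summary$peptide_protein <- list(r = pp$r, p = pp$p, n = pp$n)
    }
    altered <- select_altered(prot_quant, config$altered_log2)
    integration$altered_genes <- altered
    if (file.exists(config$gmt)) {
      sets <- read_gmt(config$gmt)
      universe <- unique(prot_quant$gene[!is.na(prot_quant$ratio_hl)])
      enr <- enrich_gene_sets(altered, sets, universe)
      l2 <- stats::setNames(prot_quant$log2_ratio, prot_quant$gene)
      if (file.exists(config$directions)) {
        dirs <- read_directions(config$directions)
        enr$z <- vapply(enr$set, function(nm) {
          d <- dirs[dirs$set == nm, , drop = FALSE]
          activation_zscore(sets[[nm]], l2,
                            stats::setNames(d$direction, d$gene),
                            log2_cutoff = config$altered_log2)$z
        }, numeric(1))
      }
      write_tsv(enr, out("enrichment.tsv"))
      integration$enrichment <- enr
      summary$enrichment <- list(
        n_sets = nrow(enr), n_significant = sum(enr$p_adj < 0.05))
    }
    if (!is.null(interactome)) {
      pi <- try(proteome_interactome_correlation(prot_quant,
                                                 interactome$hci),
                silent = TRUE)
      if (!inherits(pi, "try-error")) {
        integration$proteome_interactome <- pi
        summary$proteome_interactome <- list(r = pi$r, p = pi$p, n = pi$n)
      }
    }
  }

  if (!is.null(rep_cor)) {
    summary$replicate_correlation_min <-
      min(rep_cor[upper.tri(rep_cor)], na.rm = TRUE)
  }
  yaml::write_yaml(summary, out("summary.yaml"))
  res <- structure(list(
    quant = list(peptides = pep_quant, proteome = prot_quant,
                 interactome = if (!is.null(interactome))
                   interactome$quant else NULL),
    peptidome = list(cascade = cascade, lengths = lengths,
                     label_profile = label_profile,
                     differential = diff_pres, shift = shift,
                     replicate_correlation = rep_cor),
    binders = binders, interactome = interactome,
    integration = integration, summary = summary
  ), class = "pipeline_result")
  invisible(res)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("hlaquant pipeline result\n")
  print(x$peptidome$cascade)
  cat(sprintf("  differential: %d increased / %d reduced (of %d quantified)\n",
              x$peptidome$differential$counts[["increased"]],
              x$peptidome$differential$counts[["reduced"]],
              x$peptidome$differential$n_quantified))
  cat(sprintf("  median log2 H/L: %.3f\n", x$peptidome$shift[["median"]]))
  if (!is.null(x$interactome)) {
    cat(sprintf("  HCIs: %d (%d%% altered)\n",
                nrow(x$interactome$hci),
                x$interactome$differential$altered_percent))
  }
  invisible(x)
}
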