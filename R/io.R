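# Readers and writers for the pipeline's plain-text interchange formats:
# tab-separated intensity tables (absent intensities as empty fields),
# FASTA reference proteomes, one-accession-per-line lists, GMT gene sets
# and direction-annotation tables.

# Write a data frame as TSV with full numeric precision and empty fields
# for NA, so that read_tsv() round-trips every value exactly.
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA_character_
      out[[j]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  path
}

read_tsv <- function(path, col_classes) {
  utils::read.delim(path, sep = "\t", header = TRUE, colClasses = col_classes,
                    na.strings = "", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a peptide-level intensity table
#'
#' Columns: `peptide`, `proteins` (semicolon-joined accessions), `n_kr`,
#' `replicate`, `intensity_L`, `intensity_H` (empty = absent), `id_fdr`.
#'
#' @param path TSV file path.
#' @return Long-format data frame.
#' @export
read_peptide_table <- function(path) {
  read_tsv(path, c(peptide = "character", proteins = "character",
                   n_kr = "integer", replicate = "integer",
                   intensity_L = "numeric", intensity_H = "numeric",
                   id_fdr = "numeric"))
}

#' Read a protein-level intensity table (proteome or interactome)
#'
#' Columns: `protein`, `gene`, `replicate`, `intensity_L`, `intensity_H`,
#' `unique_peptides`, `id_fdr`.
#'
#' @param path TSV file path.
#' @return Long-format data frame.
#' @export
read_protein_table <- function(path) {
  read_tsv(path, c(protein = "character", gene = "character",
                   replicate = "integer", intensity_L = "numeric",
                   intensity_H = "numeric", unique_peptides = "integer",
                   id_fdr = "numeric"))
}

#' Read a one-accession-per-line list
#'
#' @param path File path; blank lines and `#` comments are skipped.
#' @return Character vector.
#' @export
read_accession_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read gene sets from a GMT file
#'
#' Thin wrapper over `fgsea::gmtPathways()`.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

# GMT writer for the synthetic fixtures (name, description, members)
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, "synthetic", gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  path
}

#' Read a direction-annotation table
#'
#' Columns `set`, `gene`, `direction` (+1 activating / -1 inhibiting).
#'
#' @param path TSV file path.
#' @return Data frame.
#' @export
read_directions <- function(path) {
  read_tsv(path, c(set = "character", gene = "character",
                   direction = "numeric"))
}

# filesystem-safe fixture name for an allele label
sanitize_allele <- function(allele) {
  gsub("[^A-Za-z0-9]+", "_", allele)
}

#' Write a synthetic experiment to fixture files
#'
#' Writes every layer of a [generate_experiment()] result in the formats
#' the pipeline consumes: `peptides.tsv`, `proteome.tsv`,
#' `interactome.tsv`, `reference_proteome.fasta`, `contaminants.txt`,
#' `known_interactors.txt`, one `epitopes_<allele>.txt` per allele,
#' `gene_sets.gmt`, `gene_directions.tsv`, plus the planted truth
#' (`truth_*.tsv`). Re-reading the tables reproduces every field exactly.
#'
#' @param experiment A `silac_experiment`.
#' @param directory Output directory (created if needed).
#' @return Named character vector of written paths.
#' @export
write_fixtures <- function(experiment, directory) {
  check_that(inherits(experiment, "silac_experiment"),
             "write_fixtures(): not a silac_experiment")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  check_that(dir.exists(directory),
             "write_fixtures(): cannot create directory %s", directory)
  p <- function(f) file.path(directory, f)
  paths <- c(
    peptides = write_tsv(experiment$peptides, p("peptides.tsv")),
    proteome = write_tsv(experiment$proteome, p("proteome.tsv")),
    interactome = write_tsv(experiment$interactome, p("interactome.tsv")),
    truth_peptides = write_tsv(experiment$truth$peptides,
                               p("truth_peptides.tsv")),
    truth_proteins = write_tsv(experiment$truth$proteins,
                               p("truth_proteins.tsv")),
    truth_interactors = write_tsv(experiment$truth$interactors,
                                  p("truth_interactors.tsv")),
    gene_sets = write_gmt(experiment$gene_sets, p("gene_sets.gmt")),
    gene_directions = write_tsv(experiment$directions,
                                p("gene_directions.tsv"))
  )
  fasta <- Biostrings::AAStringSet(experiment$proteome_fasta)
  Biostrings::writeXStringSet(fasta, p("reference_proteome.fasta"))
  paths["fasta"] <- p("reference_proteome.fasta")
  writeLines(experiment$contaminants, p("contaminants.txt"))
  paths["contaminants"] <- p("contaminants.txt")
  writeLines(experiment$known_interactors, p("known_interactors.txt"))
  paths["known_interactors"] <- p("known_interactors.txt")
  for (al in names(experiment$epitopes)) {
    f <- p(sprintf("epitopes_%s.txt", sanitize_allele(al)))
    writeLines(experiment$epitopes[[al]], f)
    paths[paste0("epitopes.", al)] <- f
  }
  paths
}

#' Read a reference proteome FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of protein sequences.
#' @export
read_proteome_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
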