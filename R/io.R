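#' Write a proteome to FASTA with tagged headers
#'
#' Headers carry the record's placement metadata as pipe-separated
#' key-value tags: `>id species|chrom=1AS|pos=123456`.  Contig-derived
#' records keep their `contig|` id prefix.
#'
#' @param proteome Tibble with columns `id`, `species`, `chromosome`,
#'   `arm`, `position`, `residues`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(proteome, path) {
  proteome <- as_tibble(proteome)
  seqs <- Biostrings::AAStringSet(proteome$residues)
  names(seqs) <- sprintf("%s %s|chrom=%s%s|pos=%d",
                         proteome$id, proteome$species,
                         proteome$chromosome, proteome$arm,
                         as.integer(proteome$position))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a tagged-header proteome FASTA
#'
#' Inverse of [write_proteome_fasta()].
#'
#' @param path FASTA file path.
#' @return Tibble with columns `id`, `species`, `chromosome`, `arm`,
#'   `position`, `is_contig`, `residues`.
#' @export
read_proteome_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  hdr <- names(seqs)
  id <- sub("^(\\S+).*$", "\\1", hdr)
  rest <- sub("^\\S+\\s*", "", hdr)
  species <- sub("\\|.*$", "", rest)
  chrom_tag <- sub("^.*chrom=([^|]*).*$", "\\1", rest)
  pos <- as.integer(sub("^.*pos=([0-9]+).*$", "\\1", rest))
  arm <- ifelse(grepl("[SL]$", chrom_tag),
                substring(chrom_tag, nchar(chrom_tag)), "unknown")
  chromosome <- ifelse(arm == "unknown", chrom_tag,
                       substr(chrom_tag, 1L, nchar(chrom_tag) - 1L))
  tibble(id = id, species = species, chromosome = chromosome, arm = arm,
         position = pos, is_contig = startsWith(id, "contig|"),
         residues = as.character(seqs))
}

#' Write / read a Ct panel as CSV
#'
#' Long CSV with columns `sample`, `condition`, `replicate`, `gene`,
#' `ct`; the reference gene and calibrator condition are stored in
#' `#`-prefixed header comment lines.
#'
#' @param ct A `ct_table`.
#' @param path File path.
#' @return `path` invisibly (`write`), or a `ct_table` (`read`).
#' @export
write_ct_csv <- function(ct, path) {
  con <- file(path, "w")
  writeLines(c(paste0("# reference_gene=", attr(ct, "reference_gene")),
               paste0("# calibrator=", attr(ct, "calibrator"))), con)
  close(con)
  readr::write_csv(as_tibble(ct), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_ct_csv
#' @export
read_ct_csv <- function(path) {
  hdr <- readLines(path, n = 2L)
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  attr(out, "reference_gene") <- sub("^# reference_gene=", "", hdr[1])
  attr(out, "calibrator") <- sub("^# calibrator=", "", hdr[2])
  class(out) <- c("ct_table", class(out))
  out
}

#' Write ortholog groups in an InParanoid-style table
#'
#' Tab-separated columns: `group_id`, `species`, `gene_id`, `role`,
#' `confidence`.
#'
#' @param groups An `ortholog_groups` object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_groups_tsv <- function(groups, path) {
  readr::write_tsv(as_tibble(groups)[, c("group_id", "species", "gene_id",
                                         "role", "confidence")], path)
  invisible(path)
}

#' Read a published-style ortholog count table
#'
#' Expects two CSV files: per-ordered-pair counts (`species_a`,
#' `species_b`, `n_orthologous`, `n_groups`) and per-species totals
#' (`species`, `total_genes`).
#'
#' @param counts_path,totals_path CSV file paths.
#' @return An `ortholog_counts` object.
#' @export
read_ortholog_counts <- function(counts_path, totals_path) {
  counts <- readr::read_csv(counts_path, show_col_types = FALSE)
  totals <- readr::read_csv(totals_path, show_col_types = FALSE)
  ortholog_counts(counts, totals)
}

#' Bundled ortholog counts for the Triticeae bZIP families
#'
#' Loads the count matrix reported in the literature for the bZIP
#' transcription-factor families of hexaploid wheat, *Triticum urartu*,
#' *Aegilops tauschii*, barley and *Brachypodium distachyon*: per ordered
#' species pair, the number of family members of the first species with
#' orthologs in the second and the number of shared ortholog groups,
#' plus each family's total size.
#'
#' @return An `ortholog_counts` object over the five species.
#' @export
triticeae_bzip_counts <- function() {
  read_ortholog_counts(
    system.file("extdata", "triticeae_bzip_ortholog_counts.csv",
                package = "orthozip", mustWork = TRUE),
    system.file("extdata", "triticeae_bzip_family_totals.csv",
                package = "orthozip", mustWork = TRUE))
}
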