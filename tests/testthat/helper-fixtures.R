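# Fixture builders shared across test files.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(len, alphabet = setdiff(AA20, "N")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# A residue string guaranteed to contain exactly one bZIP motif at `at`
# (0-based), on an otherwise N-free background.
protein_with_motif <- function(len = 120, at = 20, n_heptads = 3) {
  bg <- setdiff(AA20, "N")
  ch <- sample(bg, len, replace = TRUE)
  ch[at + 1] <- "N"
  ch[at + 9] <- sample(c("R", "K"), 1)
  for (k in seq_len(n_heptads) - 1)
    ch[at + 18 + 7 * k] <- sample(c("L", "I", "V", "F", "M"), 1)
  paste(ch, collapse = "")
}

tiny_cohort <- function(n_genes = 6, dup = 0.3, sub = 0.03, seed = 1,
                        species = c("spA", "spB"), len = 120) {
  simulate_proteomes(sim_config(
    species = species, n_ancestral_genes = n_genes,
    duplication_rate = dup, substitution_rate = sub,
    bzip_fraction = 0.5, contig_fraction = 0,
    mean_protein_length = len, seed = seed))
}

# Long-format Ct table built by hand from a per-condition Ct spec.
manual_ct <- function(target_ct, ref_ct, reference_gene = "ref",
                      calibrator = "cal", n_rep = 2) {
  conds <- names(target_ct)
  rows <- list()
  for (cn in conds) for (r in seq_len(n_rep)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      sample = paste0(cn, "_r", r), condition = cn, replicate = r,
      gene = c("target", reference_gene),
      ct = c(target_ct[[cn]], ref_ct[[cn]]))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "reference_gene") <- reference_gene
  attr(out, "calibrator") <- calibrator
  class(out) <- c("ct_table", class(out))
  out
}
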