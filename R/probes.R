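# Ungapped-style Karlin-Altschul constants for +1/-2 nucleotide scoring.
KA_NUCLEOTIDE <- c(lambda = 1.33, K = 0.621)

align_evalue <- function(raw, m, n, lambda, K) {
  bits <- raw_to_bits(raw, lambda, K)
  K * m * n * 2^(-bits)
}

#' Map microarray probe target sequences to genes by alignment E-values
#'
#' A probe maps to a gene iff both criteria hold: (1) the nucleotide
#' local alignment of the probe's target sequence against the gene's CDS
#' has E-value at most `e_cds` (default 1e-5), and (2) the protein local
#' alignment of the translated probe (best of the three forward frames)
#' against the gene's protein has E-value at most `e_protein` (default
#' 1e-3).  E-values follow `E = K * m * n * 2^-bits` with `m`, `n` the
#' two sequence lengths and bits from the Karlin-Altschul transformation
#' of the raw local-alignment score.  A probe passing for several genes
#' reports all of them, flagged ambiguous.
#'
#' @param probes Tibble with columns `probe_id`, `sequence` (DNA).
#' @param cds Tibble with columns `gene_id`, `sequence` (DNA).
#' @param proteins Tibble with columns `gene_id`, `residues`.
#' @param e_cds,e_protein E-value thresholds for the two criteria.
#'
#' @return A tibble with one row per (probe, gene): `probe_id`,
#'   `gene_id`, `e_value_cds`, `e_value_protein`, `mapped`, `ambiguous`
#'   (mapped to more than one gene).
#' @export
map_probes_to_genes <- function(probes, cds, proteins,
                                e_cds = 1e-5, e_protein = 1e-3) {
  probes <- as_tibble(probes)
  cds <- as_tibble(cds)
  proteins <- as_tibble(proteins)
  nuc_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -2, baseOnly = TRUE)
  blosum <- resolve_submat("BLOSUM62")

  rows <- list()
  for (p in seq_len(nrow(probes))) {
    pseq <- probes$sequence[p]
    frames <- probe_frames(pseq)
    for (g in seq_len(nrow(cds))) {
      gid <- cds$gene_id[g]
      gseq <- cds$sequence[g]
      raw_n <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(pseq), Biostrings::DNAString(gseq),
        type = "local", substitutionMatrix = nuc_mat,
        gapOpening = 5, gapExtension = 2, scoreOnly = TRUE)
      e1 <- align_evalue(max(raw_n, 0), nchar(pseq), nchar(gseq),
                         KA_NUCLEOTIDE[["lambda"]], KA_NUCLEOTIDE[["K"]])
      prot <- proteins$residues[proteins$gene_id == gid]
      e2 <- Inf
      if (length(prot) == 1L && nchar(prot) > 0L) {
        for (fr in frames) {
          if (nchar(fr) == 0L) next
          raw_p <- Biostrings::pairwiseAlignment(
            Biostrings::AAString(fr), Biostrings::AAString(prot),
            type = "local", substitutionMatrix = blosum,
            gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
          e2 <- min(e2, align_evalue(max(raw_p, 0), nchar(fr), nchar(prot),
                                     KA_PROTEIN[["lambda"]],
                                     KA_PROTEIN[["K"]]))
        }
      }
      rows[[length(rows) + 1L]] <- tibble(
        probe_id = probes$probe_id[p], gene_id = gid,
        e_value_cds = e1, e_value_protein = e2,
        mapped = e1 <= e_cds & e2 <= e_protein)
    }
  }
  out <- bind_rows(rows)
  n_hits <- out |> filter(.data$mapped) |> dplyr::count(.data$probe_id)
  out$ambiguous <- out$mapped &
    out$probe_id %in% n_hits$probe_id[n_hits$n > 1L]
  out
}

# Three forward-frame translations of a probe, trimmed to whole codons;
# translation stops at the first stop codon (trailing segment dropped).
probe_frames <- function(dna) {
  vapply(0:2, function(off) {
    sub <- substr(dna, 1L + off, nchar(dna))
    sub <- substr(sub, 1L, 3L * (nchar(sub) %/% 3L))
    if (nchar(sub) < 3L) return("")
    aa <- as.character(suppressWarnings(Biostrings::translate(
      Biostrings::DNAString(sub), if.fuzzy.codon = "solve")))
    sub("\\*.*$", "", aa)
  }, "")
}
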