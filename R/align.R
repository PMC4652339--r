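# Default Karlin-Altschul constants for gapped BLOSUM62 protein scoring
# (gap open 11, extend 1): the conventional values.
KA_PROTEIN <- c(lambda = 0.267, K = 0.041)

raw_to_bits <- function(raw, lambda, K) (lambda * raw - log(K)) / log(2)

#' Local alignment bit score and overlap fraction for one sequence pair
#'
#' Smith-Waterman local alignment with affine gap penalties (a gap of
#' length L costs `gap_open + L * gap_extend`), raw score converted to
#' bits via the Karlin-Altschul transformation
#' `(lambda * S - ln K) / ln 2`.  The overlap fraction is the span of the
#' optimal local alignment on the longer of the two sequences divided by
#' that sequence's length — the quantity the 50 % overlap cutoff is
#' applied to.
#'
#' @param a,b Uppercase amino-acid strings.  An empty sequence yields bit
#'   score 0 and overlap 0 without error.
#' @param matrix Substitution matrix name or matrix (default
#'   `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap parameters (default 11, 1).
#' @param lambda,K Karlin-Altschul constants (defaults are the
#'   conventional gapped BLOSUM62 values 0.267 and 0.041).
#'
#' @return A one-row tibble: `raw_score`, `bit_score`,
#'   `overlap_fraction`.
#' @export
#' @examples
#' local_align_bitscore("HEAGAWGHEE", "PAWHEAE")
local_align_bitscore <- function(a, b, matrix = "BLOSUM62",
                                 gap_open = 11, gap_extend = 1,
                                 lambda = KA_PROTEIN[["lambda"]],
                                 K = KA_PROTEIN[["K"]]) {
  if (nchar(a) == 0L || nchar(b) == 0L)
    return(tibble(raw_score = 0, bit_score = 0, overlap_fraction = 0))
  submat <- resolve_submat(matrix)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = submat, gapOpening = gap_open,
    gapExtension = gap_extend)
  raw <- Biostrings::score(al)
  if (raw <= 0)
    return(tibble(raw_score = max(raw, 0), bit_score = 0,
                  overlap_fraction = 0))
  longer_is_a <- nchar(a) >= nchar(b)
  span <- if (longer_is_a) Biostrings::width(Biostrings::pattern(al))
          else Biostrings::width(Biostrings::subject(al))
  tibble(raw_score = raw,
         bit_score = raw_to_bits(raw, lambda, K),
         overlap_fraction = span / max(nchar(a), nchar(b)))
}

resolve_submat <- function(matrix) {
  if (is.matrix(matrix)) return(matrix)
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  get(matrix, envir = e)
}

#' All-against-all pairwise scoring with the family's cutoffs
#'
#' Scores every unordered pair of sequences drawn from one or two
#' proteomes — cross-species pairs, within-species pairs (needed for
#' in-paralog detection) and self pairs — and retains only pairs passing
#' BOTH retention criteria: bit score at least `bit_cutoff` (default 50
#' bits) and overlap fraction strictly greater than `overlap_cutoff`
#' (default 0.5: the matching region must exceed half of the longer
#' sequence).  Self pairs are always retained (they anchor confidence
#' values).  Scores are symmetric, so each unordered pair appears once.
#'
#' @param proteome_a,proteome_b Tibbles with columns `id`, `species`,
#'   `residues`; `proteome_b` may be `NULL` for a single proteome.
#' @param bit_cutoff,overlap_cutoff Retention cutoffs.
#' @inheritParams local_align_bitscore
#'
#' @return A tibble of class `score_table`: columns `id_a`, `id_b`,
#'   `species_a`, `species_b`, `raw_score`, `bit_score`,
#'   `overlap_fraction`.
#' @export
all_vs_all <- function(proteome_a, proteome_b = NULL,
                       bit_cutoff = 50, overlap_cutoff = 0.5,
                       matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                       lambda = KA_PROTEIN[["lambda"]],
                       K = KA_PROTEIN[["K"]]) {
  prot <- bind_rows(as_tibble(proteome_a),
                    if (!is.null(proteome_b)) as_tibble(proteome_b))
  if (anyDuplicated(prot$id))
    abort("duplicate sequence ids across proteomes.",
          class = "orthozip_input_error")
  m <- nrow(prot)
  if (m == 0L)
    return(structure(tibble(id_a = character(), id_b = character(),
                            species_a = character(), species_b = character(),
                            raw_score = double(), bit_score = double(),
                            overlap_fraction = double()),
                     class = c("score_table", class(tibble()))))
  idx <- which(upper.tri(diag(m), diag = TRUE), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  submat <- resolve_submat(matrix)
  seqs <- Biostrings::AAStringSet(prot$residues)
  al <- Biostrings::pairwiseAlignment(
    seqs[i], seqs[j], type = "local", substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend)
  raw <- Biostrings::score(al)
  len_i <- nchar(prot$residues)[i]
  len_j <- nchar(prot$residues)[j]
  span <- ifelse(len_i >= len_j,
                 Biostrings::width(Biostrings::pattern(al)),
                 Biostrings::width(Biostrings::subject(al)))
  out <- tibble(
    id_a = prot$id[i], id_b = prot$id[j],
    species_a = prot$species[i], species_b = prot$species[j],
    raw_score = raw,
    bit_score = raw_to_bits(raw, lambda, K),
    overlap_fraction = ifelse(raw > 0, span / pmax(len_i, len_j), 0))
  keep <- (out$id_a == out$id_b) |
    (out$bit_score >= bit_cutoff & out$overlap_fraction > overlap_cutoff)
  out <- out[keep, ]
  class(out) <- c("score_table", class(out))
  out
}
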