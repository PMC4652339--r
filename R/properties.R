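# Average (isotope-weighted) residue masses in Da; free amino acid minus
# water.  X is given the unweighted mean of the 20 standard residues.
RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01524

# Default pKa set for the Henderson-Hasselbalch charge model
# (Expasy-style values).
DEFAULT_PKA <- list(
  positive = c(Nterm = 8.0, K = 10.0, R = 12.0, H = 5.98),
  negative = c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
)

protein_net_charge <- function(counts, pH, pka = DEFAULT_PKA) {
  pos <- sum(counts[names(pka$positive)] /
               (1 + 10^(pH - pka$positive)), na.rm = TRUE)
  neg <- sum(counts[names(pka$negative)] /
               (1 + 10^(pka$negative - pH)), na.rm = TRUE)
  pos - neg
}

#' Protein length, molecular weight and isoelectric point
#'
#' Computes, per sequence, the residue count, the molecular weight (sum of
#' average residue masses plus one water) in kDa, and the isoelectric
#' point under a Henderson-Hasselbalch charge model over the termini and
#' the D, E, C, Y, H, K, R side chains, solved by bisection to 0.01 pH
#' units.  When a coding-sequence length is supplied the protein length is
#' checked against `cds_length / 3 - 1` (the stop codon is not
#' translated).
#'
#' @param residues Character vector of uppercase amino-acid strings.
#' @param cds_length Optional integer vector of coding-sequence lengths in
#'   base pairs (must be divisible by 3).
#' @param pka Named list with `positive` and `negative` pKa vectors; see
#'   `orthozip:::DEFAULT_PKA` for the default Expasy-style set.
#'
#' @return A tibble with columns `protein_length`, `molecular_weight`
#'   (kDa), `isoelectric_point` (pH), and `cds_length` when supplied.
#' @export
#' @examples
#' protein_properties("G")   # 0.07507 kDa
protein_properties <- function(residues, cds_length = NULL,
                               pka = DEFAULT_PKA) {
  if (!is.null(cds_length)) {
    if (length(cds_length) != length(residues))
      abort("`cds_length` must match `residues` in length.",
            class = "orthozip_input_error")
    if (any(cds_length %% 3 != 0))
      abort("`cds_length` must be divisible by 3.",
            class = "orthozip_input_error")
  }
  masses <- c(RESIDUE_MASS, X = mean(RESIDUE_MASS))
  one <- function(res) {
    chars <- strsplit(res, "", fixed = TRUE)[[1]]
    bad <- setdiff(unique(chars), names(masses))
    if (length(bad))
      abort(paste0("invalid residue character(s): ",
                   paste(bad, collapse = ", ")),
            class = "orthozip_input_error")
    counts <- table(factor(chars, levels = names(masses)))
    counts <- setNames(as.numeric(counts), names(masses))
    counts[["Nterm"]] <- 1
    counts[["Cterm"]] <- 1
    mw <- sum(counts[names(RESIDUE_MASS)] * RESIDUE_MASS) +
      counts[["X"]] * masses[["X"]] + WATER_MASS
    # bisection: net charge is monotone decreasing in pH
    lo <- 0; hi <- 14
    while (hi - lo > 0.005) {
      mid <- (lo + hi) / 2
      if (protein_net_charge(counts, mid, pka) > 0) lo <- mid else hi <- mid
    }
    c(length = length(chars), mw = mw / 1000, pi = round((lo + hi) / 2, 2))
  }
  vals <- vapply(residues, one, c(length = 0, mw = 0, pi = 0))
  out <- tibble(protein_length = as.integer(vals["length", ]),
                molecular_weight = unname(vals["mw", ]),
                isoelectric_point = unname(vals["pi", ]))
  if (!is.null(cds_length)) {
    expected <- cds_length / 3 - 1
    if (any(out$protein_length != expected))
      warn("protein length disagrees with cds_length/3 - 1 for some records.")
    out$cds_length <- as.integer(cds_length)
  }
  out
}

#' Expected protein length from a coding-sequence length
#'
#' `cds_length / 3 - 1` residues: one codon per residue, stop codon not
#' translated.
#'
#' @param cds_length Integer vector of CDS lengths in base pairs.
#' @return Integer vector of protein lengths.
#' @export
#' @examples
#' cds_to_protein_length(453)  # 150
cds_to_protein_length <- function(cds_length) {
  if (any(cds_length %% 3 != 0))
    abort("`cds_length` must be divisible by 3.",
          class = "orthozip_input_error")
  as.integer(cds_length / 3 - 1)
}

#' Table of family-member protein properties
#'
#' Convenience wrapper building a catalogue-style property table for a set
#' of named family members: assigned name, source id, protein length,
#' molecular weight, isoelectric point, domain location (1-based
#' inclusive) and chromosomal location.
#'
#' @param members Tibble with columns `assigned_name`, `id`, `residues`,
#'   and optionally `domain_start`, `domain_end`, `chromosome`, `arm`.
#' @inheritParams protein_properties
#' @return A tibble, one row per member.
#' @export
family_property_table <- function(members, cds_length = NULL,
                                  pka = DEFAULT_PKA) {
  members <- as_tibble(members)
  props <- protein_properties(members$residues, cds_length, pka)
  out <- tibble(
    gene = members$assigned_name %||% members$id,
    gene_id = members$id,
    pep_aa = props$protein_length,
    pi = props$isoelectric_point,
    mw_kd = round(props$molecular_weight, 2)
  )
  if (!is.null(cds_length)) out$cds_bp <- props$cds_length
  if (all(c("domain_start", "domain_end") %in% names(members)))
    out$bzip_domain_location <- paste0(members$domain_start, "-",
                                       members$domain_end)
  if (all(c("chromosome", "arm") %in% names(members)))
    out$chromosomal_location <- paste0(members$chromosome, members$arm)
  out
}
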