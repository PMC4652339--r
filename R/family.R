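#' Scan a protein sequence for bZIP domains
#'
#' Detects the bZIP signature directly from its definition: a basic region
#' containing the invariant N-x7-R/K core, followed by a leucine zipper —
#' a heptad repeat of Leu or another bulky hydrophobic residue (Ile, Val,
#' Phe, Met) whose first position lies exactly nine residues C-terminal of
#' the basic region's R/K.  A position `i` is reported when the residue at
#' `i` is N, the residue at `i + 8` is R or K, and at least `min_heptads`
#' consecutive heptad positions starting at `i + 8 + zipper_gap` carry a
#' bulky hydrophobic residue.  All (possibly overlapping) hits are
#' reported in ascending order of `basic_start`.
#'
#' @param residues Uppercase amino-acid string (20-letter alphabet plus X).
#' @param min_heptads Minimum number of occupied consecutive heptad
#'   positions for a zipper (default 2: one repeat interval).
#' @param zipper_gap Offset from the basic region's R/K to the first heptad
#'   position (default 9, the literal reading of "exactly nine amino acids
#'   toward the C-terminus"; set 17 to anchor at the end of a 16-residue
#'   basic region instead).
#'
#' @return A tibble with one row per hit: `basic_start` (0-based index of
#'   the invariant N), `basic_end` (index of the R/K, `basic_start + 8`),
#'   `zipper_start`, `heptad_count` (maximal run), `span_start`,
#'   `span_end` (half-open, 0-based).
#' @export
#' @examples
#' scan_bzip_domain("MANAAAAAAAKAAAAAAAALAAAAAALAAA")
scan_bzip_domain <- function(residues, min_heptads = 2L, zipper_gap = 9L) {
  if (length(residues) != 1L || is.na(residues))
    abort("`residues` must be a single string.", class = "orthozip_input_error")
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c(AA_ALPHABET, "X"))
  if (length(bad))
    abort(paste0("invalid residue character(s): ",
                 paste(bad, collapse = ", ")),
          class = "orthozip_input_error")
  L <- length(chars)
  empty <- tibble(basic_start = integer(), basic_end = integer(),
                  zipper_start = integer(), heptad_count = integer(),
                  span_start = integer(), span_end = integer())
  if (L == 0L) return(empty)

  n_pos <- which(chars == "N") - 1L            # 0-based candidate starts
  hits <- list()
  for (i in n_pos) {
    be <- i + 8L
    zs <- be + zipper_gap
    if (zs + 7L * (min_heptads - 1L) >= L) next
    if (!(chars[be + 1L] %in% c("R", "K"))) next
    cnt <- 0L
    k <- zs
    while (k < L && chars[k + 1L] %in% BULKY_HYDROPHOBIC) {
      cnt <- cnt + 1L
      k <- k + 7L
    }
    if (cnt >= min_heptads)
      hits[[length(hits) + 1L]] <- tibble(
        basic_start = i, basic_end = be, zipper_start = zs,
        heptad_count = cnt, span_start = i,
        span_end = zs + 7L * (cnt - 1L) + 1L)
  }
  if (!length(hits)) return(empty)
  bind_rows(hits)
}

#' Scan every record of a proteome for bZIP domains
#'
#' @param proteome Tibble with at least columns `id` and `residues`.
#' @inheritParams scan_bzip_domain
#' @return A tibble of hits, one row per (record, hit), with the record
#'   `id` prepended to the [scan_bzip_domain()] columns.
#' @export
scan_bzip_domains <- function(proteome, min_heptads = 2L, zipper_gap = 9L) {
  proteome <- as_tibble(proteome)
  purrr::map2(proteome$id, proteome$residues, function(id, res) {
    h <- scan_bzip_domain(res, min_heptads, zipper_gap)
    if (nrow(h)) dplyr::bind_cols(tibble(id = id), h) else NULL
  }) |> bind_rows()
}

#' Identify the bZIP family members of a proteome
#'
#' Applies the family-identification pipeline: (1) build the candidate set
#' (records with at least one domain hit, or a user-supplied candidate id
#' list emulating an external pre-scan); (2) remove contig-derived records;
#' (3) remove candidates lacking a verified domain hit; (4) collapse exact
#' duplicate sequences to a non-redundant set (first id kept, in input
#' order).  Audit counts record the size of the set after every stage, plus
#' optional curated additions appended after the scan.
#'
#' @param proteome Tibble with columns `id`, `residues`, and optionally
#'   `species`, `chromosome`, `arm`, `position`, `is_contig`.
#' @param candidates Optional character vector of candidate ids from an
#'   external pre-scan; defaults to all records with a domain hit.
#' @param curated Optional tibble of curated family members (same columns
#'   as `proteome`) appended after the pipeline, mirroring
#'   literature-curated genes added to a scan-derived catalogue.
#' @inheritParams scan_bzip_domain
#'
#' @return An object of class `bzip_family`: list with `members` (tibble,
#'   one row per family member with `domain_start`/`domain_end` of the
#'   first hit, 1-based inclusive) and `audit` (one-row tibble of stage
#'   counts: `n_candidates`, `n_contigs_removed`, `n_domainless_removed`,
#'   `n_duplicates_collapsed`, `n_members`, `n_curated_added`, `n_total`).
#' @export
identify_family <- function(proteome, candidates = NULL, curated = NULL,
                            min_heptads = 2L, zipper_gap = 9L) {
  proteome <- as_tibble(proteome)
  if (!nrow(proteome)) {
    audit <- tibble(n_candidates = 0L, n_contigs_removed = 0L,
                    n_domainless_removed = 0L, n_duplicates_collapsed = 0L,
                    n_members = 0L, n_curated_added = 0L, n_total = 0L)
    return(structure(list(members = proteome, audit = audit),
                     class = "bzip_family"))
  }
  if (!"is_contig" %in% names(proteome))
    proteome$is_contig <- startsWith(proteome$id, "contig|")
  hits <- scan_bzip_domains(proteome, min_heptads, zipper_gap)
  has_hit <- proteome$id %in% hits$id

  cand <- if (is.null(candidates)) proteome[has_hit, ]
          else proteome[proteome$id %in% candidates, ]
  n_candidates <- nrow(cand)

  keep <- !cand$is_contig
  n_contigs_removed <- sum(!keep)
  cand <- cand[keep, ]

  keep <- cand$id %in% hits$id
  n_domainless_removed <- sum(!keep)
  cand <- cand[keep, ]

  dup <- duplicated(cand$residues)
  n_duplicates_collapsed <- sum(dup)
  members <- cand[!dup, ]

  first_hit <- hits |> group_by(.data$id) |> slice(1L) |> ungroup()
  members <- left_join(members,
    first_hit |> mutate(domain_start = .data$span_start + 1L,
                        domain_end = .data$span_end) |>
      select("id", "domain_start", "domain_end"),
    by = "id")

  n_curated_added <- 0L
  if (!is.null(curated) && nrow(curated)) {
    curated <- as_tibble(curated)
    n_curated_added <- nrow(curated)
    members <- bind_rows(members, curated)
  }

  audit <- tibble(n_candidates = n_candidates,
                  n_contigs_removed = n_contigs_removed,
                  n_domainless_removed = n_domainless_removed,
                  n_duplicates_collapsed = n_duplicates_collapsed,
                  n_members = n_candidates - n_contigs_removed -
                    n_domainless_removed - n_duplicates_collapsed,
                  n_curated_added = n_curated_added,
                  n_total = n_candidates - n_contigs_removed -
                    n_domainless_removed - n_duplicates_collapsed +
                    n_curated_added)
  structure(list(members = members, audit = audit), class = "bzip_family")
}

#' @export
print.bzip_family <- function(x, ...) {
  cat("bZIP family:", x$audit$n_total, "members (",
      x$audit$n_candidates, "candidates,",
      x$audit$n_contigs_removed, "contigs removed,",
      x$audit$n_domainless_removed, "without domain,",
      x$audit$n_duplicates_collapsed, "duplicates collapsed,",
      x$audit$n_curated_added, "curated additions )\n")
  invisible(x)
}

#' Assign family gene names by chromosomal order
#'
#' Numbers family members along the genome in the conventional direction:
#' genome letter (A before B before D, alphabetically in general),
#' chromosome 1 through 7, short arm before long arm, then ascending
#' position.  Records without a chromosome placement (labels starting with
#' `"u"`, e.g. `"uA"`) are named after all placed records, ordered by id.
#' Naming is invariant to the input row order.
#'
#' @param members Tibble with columns `id`, `chromosome`, `arm`,
#'   `position` (a `bzip_family` object's `members` is accepted directly).
#' @param prefix Name prefix, e.g. `"TabZIP"`.
#'
#' @return The members tibble with an `assigned_name` column, sorted in
#'   naming order.
#' @export
#' @examples
#' m <- tibble::tibble(id = c("x", "y", "z"),
#'                     chromosome = c("1A", "1A", "2A"),
#'                     arm = c("L", "S", "S"), position = c(50, 100, 10))
#' assign_gene_names(m, "TabZIP")
assign_gene_names <- function(members, prefix = "TabZIP") {
  if (inherits(members, "bzip_family")) members <- members$members
  members <- as_tibble(members)
  req <- c("id", "chromosome", "arm", "position")
  if (!all(req %in% names(members)))
    abort("`members` needs columns id, chromosome, arm, position.",
          class = "orthozip_input_error")
  key <- members[, req]
  if (anyDuplicated(key))
    abort("duplicate (id, chromosome, arm, position) records.",
          class = "orthozip_input_error")
  placed <- grepl("^[0-9]", members$chromosome)
  chrom_num <- suppressWarnings(as.integer(sub("^([0-9]+).*$", "\\1",
                                               members$chromosome)))
  genome <- sub("^[0-9]+", "", members$chromosome)
  arm_rank <- match(members$arm, c("S", "L"))
  arm_rank[is.na(arm_rank)] <- 3L
  ord <- order(!placed,
               ifelse(placed, genome, ""),
               ifelse(placed, chrom_num, 0L),
               ifelse(placed, arm_rank, 0L),
               ifelse(placed, members$position, 0),
               members$id)
  members <- members[ord, ]
  members$assigned_name <- paste0(prefix, seq_len(nrow(members)))
  members
}
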