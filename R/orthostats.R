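#' Build an ortholog count matrix from clustered groups
#'
#' Tallies, for every ordered species pair (A, B), the number of A genes
#' appearing in any ortholog group with B (`n_orthologous`) and the shared
#' number of groups for the pair (`n_groups`).  The matrix is *not*
#' assumed symmetric in `n_orthologous`: post-speciation duplication
#' frequency generally differs between the two species, so the number of
#' A genes with orthologs in B need not equal the number of B genes with
#' orthologs in A.  `n_groups` is symmetric by construction.
#'
#' @param groups Tibble of group memberships over one or more species
#'   pairs, with columns `species_a`, `species_b` (the pair), `group`,
#'   `gene_id`, `species` (the member's species) — the shape of a
#'   `synthetic_cohort`'s `truth_groups`, or of stacked
#'   [cluster_orthologs()] outputs via [groups_to_pair_table()].
#' @param totals Named numeric vector (or two-column tibble
#'   `species`, `total_genes`) of family size per species.
#'
#' @return An object of class `ortholog_counts`: a tibble with one row per
#'   ordered species pair (`species_a`, `species_b`, `n_orthologous`,
#'   `n_groups`) and attribute `totals`.
#' @export
count_matrix <- function(groups, totals) {
  groups <- as_tibble(groups)
  totals <- normalise_totals(totals)
  req <- c("species_a", "species_b", "group", "gene_id", "species")
  if (!all(req %in% names(groups)))
    abort("`groups` needs columns species_a, species_b, group, gene_id, species.",
          class = "orthozip_input_error")
  dup <- groups |>
    distinct(.data$species_a, .data$species_b, .data$group, .data$gene_id) |>
    dplyr::count(.data$species_a, .data$species_b, .data$gene_id) |>
    filter(.data$n > 1L)
  if (nrow(dup))
    abort("a gene appears in two groups of the same species pair.",
          class = "orthozip_input_error")

  rows <- list()
  pairs <- distinct(groups, .data$species_a, .data$species_b)
  for (r in seq_len(nrow(pairs))) {
    pa <- pairs$species_a[r]; pb <- pairs$species_b[r]
    g <- groups[groups$species_a == pa & groups$species_b == pb, ]
    ngr <- dplyr::n_distinct(g$group)
    for (sp in c(pa, pb)) {
      other <- if (sp == pa) pb else pa
      rows[[length(rows) + 1L]] <- tibble(
        species_a = sp, species_b = other,
        n_orthologous = dplyr::n_distinct(g$gene_id[g$species == sp]),
        n_groups = ngr)
    }
  }
  out <- bind_rows(rows) |> arrange(.data$species_a, .data$species_b)
  bad <- out$n_orthologous > totals[out$species_a]
  if (any(bad, na.rm = TRUE))
    abort("n_orthologous exceeds the species total.",
          class = "orthozip_input_error")
  attr(out, "totals") <- totals
  class(out) <- c("ortholog_counts", class(out))
  out
}

normalise_totals <- function(totals) {
  if (is.data.frame(totals)) {
    totals <- setNames(totals$total_genes, totals$species)
  }
  if (is.null(names(totals)))
    abort("`totals` must be named by species.", class = "orthozip_input_error")
  totals
}

#' Assemble an ortholog count matrix from per-pair counts
#'
#' Constructor used when the per-pair counts are already known (for
#' example a published count table) rather than derived from clustered
#' groups.
#'
#' @param counts Tibble with columns `species_a`, `species_b`,
#'   `n_orthologous`, `n_groups` (one row per ordered pair).
#' @inheritParams count_matrix
#' @return An `ortholog_counts` object; see [count_matrix()].
#' @export
ortholog_counts <- function(counts, totals) {
  counts <- as_tibble(counts)[, c("species_a", "species_b",
                                  "n_orthologous", "n_groups")]
  totals <- normalise_totals(totals)
  if (any(counts$n_orthologous > totals[counts$species_a]))
    abort("n_orthologous exceeds the species total.",
          class = "orthozip_input_error")
  chk <- dplyr::inner_join(
    counts, counts,
    by = c(species_a = "species_b", species_b = "species_a"),
    suffix = c("", ".rev"))
  if (any(chk$n_groups != chk$n_groups.rev))
    abort("`n_groups` must be symmetric.", class = "orthozip_input_error")
  if (any(counts$n_groups > pmin(counts$n_orthologous,
                                 chk$n_orthologous.rev[match(
                                   paste(counts$species_a, counts$species_b),
                                   paste(chk$species_a, chk$species_b))])))
    abort("`n_groups` cannot exceed either side's ortholog count.",
          class = "orthozip_input_error")
  out <- arrange(counts, .data$species_a, .data$species_b)
  attr(out, "totals") <- totals
  class(out) <- c("ortholog_counts", class(out))
  out
}

#' Flatten clustered ortholog groups to the per-pair membership shape
#'
#' @param groups An `ortholog_groups` object from [cluster_orthologs()].
#' @return Tibble with columns `species_a`, `species_b`, `group`,
#'   `gene_id`, `species`, suitable for [count_matrix()].
#' @export
groups_to_pair_table <- function(groups) {
  pair <- attr(groups, "species_pair")
  tibble(species_a = pair[1], species_b = pair[2],
         group = as.character(groups$group_id),
         gene_id = groups$gene_id, species = groups$species)
}

#' Average ortholog group size for one species
#'
#' For species A, the mean over its partner species B (with at least one
#' shared group) of `n_orthologous(A, B) / n_groups(A, B)` — the average
#' number of A in-paralogs per ortholog group.
#'
#' @param counts An `ortholog_counts` object.
#' @param species Species label.
#' @return A single number.
#' @export
average_group_size <- function(counts, species) {
  rows <- counts[counts$species_a == species & counts$n_groups > 0, ]
  if (!nrow(rows))
    abort(sprintf("species '%s' has no partner with ortholog groups.",
                  species),
          class = "orthozip_undefined_error")
  mean(rows$n_orthologous / rows$n_groups)
}

#' Orthology distance from species A to species B
#'
#' The fraction of A's family members without any ortholog in B:
#' `dAB = (total_A - n_orthologous_A_to_B) / total_A`.
#'
#' @param total_a Total family size in A (> 0).
#' @param n_orthologous Number of A genes orthologous to B, in
#'   `[0, total_a]`.
#' @return `dAB` in `[0, 1]` (vectorised).
#' @export
#' @examples
#' orthology_distance(182, 76)  # 0.5824
orthology_distance <- function(total_a, n_orthologous) {
  if (any(total_a <= 0))
    abort("`total_a` must be > 0.", class = "orthozip_input_error")
  if (any(n_orthologous < 0 | n_orthologous > total_a))
    abort("`n_orthologous` must lie in [0, total_a].",
          class = "orthozip_input_error")
  (total_a - n_orthologous) / total_a
}

#' Orthology distance matrices from an ortholog count matrix
#'
#' Computes the asymmetric orthology distance `dAB` for every ordered
#' species pair and the symmetrized matrix `(dAB + dBA) / 2` used for the
#' orthophylogram.  A pair with no surviving groups has distance 1 (the
#' formula's limit as orthologs vanish).
#'
#' @param counts An `ortholog_counts` object.
#' @return A list with `asymmetric` (tibble `species_a`, `species_b`,
#'   `d`) and `symmetrized` (square numeric matrix with species dimnames,
#'   zero diagonal).
#' @export
orthology_distance_matrix <- function(counts) {
  totals <- attr(counts, "totals")
  species <- sort(unique(c(counts$species_a, counts$species_b)))
  asym <- counts |>
    mutate(d = orthology_distance(totals[.data$species_a],
                                  .data$n_orthologous)) |>
    select("species_a", "species_b", "d")
  D <- matrix(1, length(species), length(species),
              dimnames = list(species, species))
  diag(D) <- 0
  for (r in seq_len(nrow(asym))) {
    a <- asym$species_a[r]; b <- asym$species_b[r]
    rev_d <- asym$d[asym$species_a == b & asym$species_b == a]
    if (length(rev_d))
      D[a, b] <- D[b, a] <- (asym$d[r] + rev_d) / 2
  }
  list(asymmetric = asym, symmetrized = D)
}
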