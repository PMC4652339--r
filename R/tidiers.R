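#' Tidy a bZIP family result
#'
#' @param x A `bzip_family` from [identify_family()].
#' @param ... Unused.
#' @return The member tibble.
#' @method tidy bzip_family
#' @export
tidy.bzip_family <- function(x, ...) as_tibble(x$members)

#' One-row summary of a bZIP family result (the audit counts)
#'
#' @inheritParams tidy.bzip_family
#' @return The one-row audit tibble; the counts telescope:
#'   `n_candidates - n_contigs_removed - n_domainless_removed -
#'   n_duplicates_collapsed = n_members`.
#' @method glance bzip_family
#' @export
glance.bzip_family <- function(x, ...) x$audit

#' Tidy clustered ortholog groups
#'
#' @param x An `ortholog_groups` from [cluster_orthologs()].
#' @param ... Unused.
#' @return A plain tibble of group memberships.
#' @method tidy ortholog_groups
#' @export
tidy.ortholog_groups <- function(x, ...) {
  out <- as_tibble(x)
  attr(out, "seeds") <- NULL
  attr(out, "species_pair") <- NULL
  out
}

#' One-row summary of clustered ortholog groups
#'
#' @inheritParams tidy.ortholog_groups
#' @return Tibble with `n_groups`, `n_genes`, `n_inparalogs`,
#'   `mean_group_size`.
#' @method glance ortholog_groups
#' @export
glance.ortholog_groups <- function(x, ...) {
  tibble(n_groups = dplyr::n_distinct(x$group_id),
         n_genes = nrow(x),
         n_inparalogs = sum(x$role == "inparalog"),
         mean_group_size = if (nrow(x)) nrow(x) /
           dplyr::n_distinct(x$group_id) else NA_real_)
}

#' Tidy an orthophylogram (merge table)
#'
#' @param x An `orthophylogram` from [upgma()].
#' @param ... Unused.
#' @return Tibble of agglomeration steps: `step`, `height`, `left`,
#'   `right`.
#' @method tidy orthophylogram
#' @export
tidy.orthophylogram <- function(x, ...) x$merges

#' One-row summary of an orthophylogram
#'
#' @inheritParams tidy.orthophylogram
#' @return Tibble with `n_taxa`, `tree_height`, `ultrametric_deviation`
#'   (max absolute difference among root-to-leaf depths).
#' @method glance orthophylogram
#' @export
glance.orthophylogram <- function(x, ...) {
  dep <- leaf_depths(x)
  tibble(n_taxa = length(dep),
         tree_height = max(x$heights$height),
         ultrametric_deviation = max(dep) - min(dep))
}

#' One-row summary of a differential-expression result
#'
#' @param x A `de_result` from [de_filter()].
#' @param ... Unused.
#' @return Tibble with `n_genes`, `n_passing`, `n_up`, `n_down`.
#' @method glance de_result
#' @export
glance.de_result <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_passing = sum(x$passes),
         n_up = sum(x$passes & x$direction == "up"),
         n_down = sum(x$passes & x$direction == "down"))
}
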