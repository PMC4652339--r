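#' UPGMA tree from a symmetrized distance matrix
#'
#' Classical unweighted pair-group agglomeration with arithmetic-mean
#' (size-weighted) cluster distances: at each step the closest pair of
#' clusters is merged at node height `d/2`, and the merged cluster's
#' distance to any other cluster is the size-weighted mean of its parts'
#' distances.  Ties in the minimum distance are broken deterministically
#' by the lexicographically smallest leaf label contained in the candidate
#' pairs, so the result is invariant to the input row/column order.  The
#' output is rooted, binary and ultrametric.
#'
#' @param d Symmetric, zero-diagonal, non-negative numeric matrix with
#'   species labels as dimnames (or a `dist` object).
#'
#' @return An object of class `orthophylogram`: list with `phylo` (an
#'   [ape::phylo] tree with branch lengths), `newick` (serialization),
#'   `heights` (tibble of merge heights), and `merges` (tibble describing
#'   the agglomeration order).
#' @export
#' @examples
#' d <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgma(d)$newick
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    abort("`d` must be a square matrix.", class = "orthozip_input_error")
  labs <- rownames(d)
  if (is.null(labs) || anyDuplicated(labs))
    abort("`d` needs unique row/column names.", class = "orthozip_input_error")
  n <- nrow(d)
  if (n < 2L)
    abort("at least two taxa are required.", class = "orthozip_input_error")
  if (any(d < 0) || any(abs(diag(d)) > 1e-12) || any(abs(d - t(d)) > 1e-9))
    abort("`d` must be symmetric, non-negative, with zero diagonal.",
          class = "orthozip_input_error")

  # order columns by label so tie-breaking is input-order independent
  ord <- order(labs)
  d <- d[ord, ord]
  labs <- labs[ord]

  clusters <- lapply(labs, function(x) x)     # leaf label sets
  sizes <- rep(1L, n)
  heights <- rep(0, n)
  newick <- labs
  active <- rep(TRUE, n)
  D <- d
  merges <- list()

  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    best <- NULL
    for (ii in idx) for (jj in idx) {
      if (jj <= ii) next
      cand <- list(i = ii, j = jj, d = D[ii, jj],
                   key = sort(c(clusters[[ii]], clusters[[jj]])))
      if (is.null(best) || cand$d < best$d - 1e-15 ||
          (abs(cand$d - best$d) <= 1e-15 &&
           tie_before(cand$key, best$key)))
        best <- cand
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    bi <- h - heights[i]
    bj <- h - heights[j]
    new_newick <- sprintf("(%s:%.15g,%s:%.15g)", newick[i], bi,
                          newick[j], bj)
    merges[[step]] <- tibble(
      step = step, height = h,
      left = paste(clusters[[i]], collapse = ","),
      right = paste(clusters[[j]], collapse = ","))
    # size-weighted average distances to the merged cluster
    for (k in idx) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <-
        (sizes[i] * D[i, k] + sizes[j] * D[j, k]) / (sizes[i] + sizes[j])
    }
    clusters[[i]] <- sort(c(clusters[[i]], clusters[[j]]))
    sizes[i] <- sizes[i] + sizes[j]
    heights[i] <- h
    newick[i] <- new_newick
    active[j] <- FALSE
  }
  root <- which(active)
  nwk <- paste0(newick[root], ";")
  phylo <- ape::read.tree(text = nwk)
  structure(list(phylo = phylo, newick = nwk,
                 heights = bind_rows(merges) |>
                   select("step", "height"),
                 merges = bind_rows(merges)),
            class = "orthophylogram")
}

tie_before <- function(a, b) {
  # lexicographic comparison of sorted label vectors
  for (k in seq_len(min(length(a), length(b)))) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  length(a) < length(b)
}

#' @export
print.orthophylogram <- function(x, ...) {
  cat("Orthophylogram over", length(x$phylo$tip.label), "taxa\n")
  cat(x$newick, "\n")
  invisible(x)
}

#' Root-to-leaf depths of an orthophylogram
#'
#' @param x An `orthophylogram`.
#' @return Named numeric vector of root-to-tip path lengths (equal for
#'   all tips, up to numerical noise: the tree is ultrametric).
#' @export
leaf_depths <- function(x) {
  phy <- x$phylo
  nd <- ape::node.depth.edgelength(phy)
  setNames(nd[seq_along(phy$tip.label)], phy$tip.label)
}
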