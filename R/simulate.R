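#' Configuration for the synthetic proteome generator
#'
#' Bundles and validates all parameters of the multi-species proteome
#' simulation.  The generator evolves a set of ancestral protein-coding
#' genes down a known species tree: each internal node is a speciation,
#' each branch accumulates gene duplications (Poisson-distributed per gene)
#' and residue substitutions, and a chosen fraction of ancestral genes
#' carries a planted bZIP domain (basic region with the invariant
#' N-x7-R/K core followed by a leucine-zipper heptad repeat) that is never
#' mutated, so domain-scan sensitivity can be scored against truth.
#'
#' Background residues (and substitutions) for all genes are drawn from the
#' 19-letter alphabet excluding asparagine, so that a record can contain the
#' invariant domain asparagine only where a domain was planted.  This makes
#' the domain scanner's specificity on non-carriers exact by construction
#' rather than merely probable.
#'
#' @param species Character vector of species labels (at least 2).
#' @param speciation_order Newick string over `species` giving the order of
#'   speciation events (a rooted tree; node order defines which splits
#'   happened first).  Default is a ladder in the given species order.
#' @param n_ancestral_genes Number of genes in the common ancestor.
#' @param duplication_rate Expected duplications per gene per lineage
#'   (branch); duplication counts are Poisson with this mean.
#' @param substitution_rate Per-residue replacement probability per lineage,
#'   in `[0, 1)`.
#' @param bzip_fraction Fraction of ancestral genes carrying a planted bZIP
#'   domain, in `[0, 1]`.
#' @param contig_fraction Fraction of emitted records flagged as
#'   contig-derived (id prefixed `"contig|"`), in `[0, 1]`.
#' @param mean_protein_length Mean protein length in residues (Poisson,
#'   floored at 60).
#' @param genome_letters Optional character vector, one genome letter per
#'   species (used in chromosome labels such as `"3A"`); defaults to
#'   `"A"`, `"B"`, `"D"`, `"H"`, `"Bd"`, ... in species order.
#' @param seed Integer random seed; all randomness in the simulation flows
#'   from this one seed.
#'
#' @return An object of class `sim_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(species = c("spA", "spB"), n_ancestral_genes = 5,
#'                   duplication_rate = 0, substitution_rate = 0, seed = 1)
sim_config <- function(species = c("wheat", "T_urartu", "Ae_tauschii",
                                   "barley", "Brachypodium"),
                       speciation_order = NULL,
                       n_ancestral_genes = 100L,
                       duplication_rate = 0.1,
                       substitution_rate = 0.05,
                       bzip_fraction = 0.3,
                       contig_fraction = 0.02,
                       mean_protein_length = 300L,
                       genome_letters = NULL,
                       seed = 1L) {
  if (length(species) < 2L || anyDuplicated(species))
    abort("`species` must be >= 2 distinct labels.", class = "orthozip_config_error")
  if (is.null(speciation_order)) {
    ladder <- species[length(species)]
    for (s in rev(species[-length(species)]))
      ladder <- paste0("(", s, ",", ladder, ")")
    speciation_order <- paste0(ladder, ";")
  }
  tree <- tryCatch(ape::read.tree(text = speciation_order),
                   error = function(e) NULL)
  if (is.null(tree) || !setequal(tree$tip.label, species))
    abort("`speciation_order` must be a newick tree over exactly `species`.",
          class = "orthozip_config_error")
  chk_rate <- function(x, nm, lo = 0, hi = Inf, hi_open = FALSE) {
    bad <- !is.numeric(x) || length(x) != 1L || is.na(x) || x < lo ||
      (if (hi_open) x >= hi else x > hi)
    if (bad) abort(sprintf("`%s` out of range.", nm),
                   class = "orthozip_config_error")
  }
  chk_rate(n_ancestral_genes, "n_ancestral_genes")
  chk_rate(duplication_rate, "duplication_rate")
  chk_rate(substitution_rate, "substitution_rate", 0, 1, hi_open = TRUE)
  chk_rate(bzip_fraction, "bzip_fraction", 0, 1)
  chk_rate(contig_fraction, "contig_fraction", 0, 1)
  chk_rate(mean_protein_length, "mean_protein_length", 1)
  if (is.null(genome_letters))
    genome_letters <- c("A", "B", "D", "H", "Bd", LETTERS)[seq_along(species)]
  structure(list(
    species = as.character(species),
    speciation_order = speciation_order,
    tree = tree,
    n_ancestral_genes = as.integer(n_ancestral_genes),
    duplication_rate = duplication_rate,
    substitution_rate = substitution_rate,
    bzip_fraction = bzip_fraction,
    contig_fraction = contig_fraction,
    mean_protein_length = as.integer(mean_protein_length),
    genome_letters = setNames(genome_letters, species),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Background alphabet: no asparagine, so non-carriers can never satisfy
# the invariant-N constraint of the domain scanner.
sim_background_alphabet <- function() setdiff(AA_ALPHABET, "N")

# Plant one bZIP domain: N at `at`, R/K at `at+8`, four heptad positions
# starting at `at+17`.  Returns list(residues, mask) where mask marks the
# verbatim-preserved span.
plant_bzip_motif <- function(residues, at, n_heptads = 4L) {
  bg <- sim_background_alphabet()
  span_end <- at + 17L + 7L * (n_heptads - 1L)  # last heptad position
  stopifnot(span_end <= length(residues))
  residues[at:span_end] <- sample(bg, span_end - at + 1L, replace = TRUE)
  residues[at] <- "N"
  residues[at + 8L] <- sample(c("R", "K"), 1L)
  residues[at + 17L + 7L * (0:(n_heptads - 1L))] <-
    sample(BULKY_HYDROPHOBIC, n_heptads, replace = TRUE)
  mask <- rep(FALSE, length(residues))
  mask[at:span_end] <- TRUE
  list(residues = residues, mask = mask)
}

# Mutate residues (outside the motif mask) with per-site probability `rate`;
# substitutions are drawn from the N-free background alphabet, always
# different from the current residue.
mutate_residues <- function(residues, mask, rate) {
  if (rate <= 0) return(residues)
  idx <- which(runif(length(residues)) < rate & !mask)
  if (length(idx)) {
    bg <- sim_background_alphabet()
    residues[idx] <- vapply(residues[idx],
                            function(r) sample(setdiff(bg, r), 1L), "")
  }
  residues
}

#' Simulate multi-species proteomes with known orthology truth
#'
#' Evolves `n_ancestral_genes` ancestral proteins down the configured
#' species tree.  Each branch applies, per gene, a Poisson-distributed
#' number of duplications (creating in-paralogs) followed by independent
#' residue substitutions; planted bZIP domains are inherited verbatim.
#' Because the simulation has no gene loss, every gene copy present at a
#' speciation node leaves descendants in both daughter lineages, and the
#' true ortholog groups for a species pair are exactly the descendant sets
#' of the copies present at that pair's last common ancestor — duplicates
#' arising after that speciation are in-paralogs within a group, duplicates
#' arising before it found separate groups.
#'
#' @param config A [sim_config()] object.
#'
#' @return An object of class `synthetic_cohort`: a list with
#'   * `proteomes` — tibble with one row per protein record: `id`,
#'     `species`, `chromosome`, `arm`, `position`, `is_contig`, `residues`;
#'   * `truth_groups` — tibble of true ortholog groups per species pair:
#'     `species_a`, `species_b`, `group`, `gene_id`, `species`;
#'   * `truth_bzip_ids` — character vector of record ids carrying a planted
#'     bZIP domain;
#'   * `config` — the configuration used.
#' @export
#' @examples
#' cohort <- simulate_proteomes(sim_config(species = c("spA", "spB"),
#'   n_ancestral_genes = 5, duplication_rate = 0, substitution_rate = 0,
#'   seed = 1))
#' cohort$proteomes
simulate_proteomes <- function(config) {
  if (!inherits(config, "sim_config"))
    abort("`config` must be a sim_config object.", class = "orthozip_config_error")
  withr::with_seed(config$seed, simulate_proteomes_impl(config))
}

simulate_proteomes_impl <- function(config) {
  tree <- config$tree
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  bg <- sim_background_alphabet()

  n <- config$n_ancestral_genes
  if (n == 0L) {
    empty_prot <- tibble(id = character(), species = character(),
                         chromosome = character(), arm = character(),
                         position = integer(), is_contig = logical(),
                         residues = character())
    empty_truth <- tibble(species_a = character(), species_b = character(),
                          group = character(), gene_id = character(),
                          species = character())
    return(structure(list(proteomes = empty_prot, truth_groups = empty_truth,
                          truth_bzip_ids = character(), config = config),
                     class = "synthetic_cohort"))
  }

  min_len <- 60L
  lens <- pmax(min_len, rpois(n, config$mean_protein_length))
  n_bzip <- round(config$bzip_fraction * n)
  carriers <- if (n_bzip > 0) sort(sample.int(n, n_bzip)) else integer()

  genes <- vector("list", n)
  for (g in seq_len(n)) {
    res <- sample(bg, lens[g], replace = TRUE)
    mask <- rep(FALSE, lens[g])
    if (g %in% carriers) {
      span <- 17L + 7L * 3L + 1L  # 4 heptads
      at <- sample.int(lens[g] - span, 1L)
      pm <- plant_bzip_motif(res, at, n_heptads = 4L)
      res <- pm$residues
      mask <- pm$mask
    }
    genes[[g]] <- list(anc = g, residues = res, mask = mask,
                       node_keys = integer())
  }

  leaf_genes <- vector("list", n_tip)
  names(leaf_genes) <- tree$tip.label
  children_of <- function(node) tree$edge[tree$edge[, 1] == node, 2]

  descend <- function(node, pool) {
    if (node > n_tip) {
      # speciation: stamp each current copy with its key at this node
      for (i in seq_along(pool))
        pool[[i]]$node_keys[[as.character(node)]] <- i
      for (child in children_of(node)) {
        branch_pool <- pool
        # duplications on the branch leading to `child`
        if (config$duplication_rate > 0) {
          for (i in seq_along(pool)) {
            ndup <- rpois(1L, config$duplication_rate)
            if (ndup > 0)
              for (k in seq_len(ndup))
                branch_pool[[length(branch_pool) + 1L]] <- pool[[i]]
          }
        }
        # substitutions, independently per copy
        for (i in seq_along(branch_pool))
          branch_pool[[i]]$residues <- mutate_residues(
            branch_pool[[i]]$residues, branch_pool[[i]]$mask,
            config$substitution_rate)
        descend(child, branch_pool)
      }
    } else {
      leaf_genes[[tree$tip.label[node]]] <<- pool
    }
  }
  descend(root, genes)

  records <- list()
  truth_rows <- list()
  bzip_ids <- character()
  for (sp in config$species) {
    pool <- leaf_genes[[sp]]
    m <- length(pool)
    letter <- config$genome_letters[[sp]]
    ids <- sprintf("%s_g%04d", sp, seq_len(m))
    rec <- tibble(
      id = ids,
      species = sp,
      chromosome = paste0(sample(1:7, m, replace = TRUE), letter),
      arm = sample(c("S", "L"), m, replace = TRUE),
      position = sample.int(1e6L, m, replace = TRUE),
      is_contig = FALSE,
      residues = vapply(pool, function(g) paste(g$residues, collapse = ""), "")
    )
    is_carrier <- vapply(pool, function(g) any(g$mask), TRUE)
    keys <- lapply(pool, `[[`, "node_keys")
    records[[sp]] <- list(rec = rec, keys = keys, carrier = is_carrier)
  }

  # contig marking over all records
  all_rec <- bind_rows(lapply(records, `[[`, "rec"))
  n_all <- nrow(all_rec)
  n_contig <- round(config$contig_fraction * n_all)
  if (n_contig > 0) {
    ci <- sample.int(n_all, n_contig)
    all_rec$is_contig[ci] <- TRUE
    all_rec$id[ci] <- paste0("contig|", all_rec$id[ci])
  }
  # propagate renamed ids back to per-species key tables
  offsets <- cumsum(c(0L, vapply(records, function(r) nrow(r$rec), 1L)))
  for (j in seq_along(records)) {
    rows <- seq_len(nrow(records[[j]]$rec)) + offsets[j]
    records[[j]]$rec <- all_rec[rows, ]
  }

  for (j in seq_along(records)) {
    rc <- records[[j]]
    bzip_ids <- c(bzip_ids, rc$rec$id[rc$carrier])
  }

  # truth groups per unordered species pair: key at the pair's MRCA node
  sp_pairs <- utils::combn(config$species, 2, simplify = FALSE)
  for (pr in sp_pairs) {
    a <- pr[1]; b <- pr[2]
    mrca <- ape::getMRCA(tree, c(a, b))
    key_of <- function(rc) vapply(rc$keys, function(k) k[[as.character(mrca)]], 1L)
    for (sp in c(a, b)) {
      rc <- records[[sp]]
      truth_rows[[length(truth_rows) + 1L]] <- tibble(
        species_a = a, species_b = b,
        group = sprintf("%s|%s|%d", a, b, key_of(rc)),
        gene_id = rc$rec$id, species = sp)
    }
  }
  truth <- bind_rows(truth_rows) |> arrange(.data$species_a, .data$species_b,
                                            .data$group, .data$gene_id)

  structure(list(proteomes = all_rec, truth_groups = truth,
                 truth_bzip_ids = sort(bzip_ids), config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", length(x$config$species), "species,",
      nrow(x$proteomes), "protein records,",
      length(x$truth_bzip_ids), "planted bZIP carriers\n")
  invisible(x)
}

#' Describe planted expression truth for a heterosis panel
#'
#' Defines, per gene, the expression mode planted in an F1/parents panel
#' and the planted effect sizes.  Modes follow the classical heterosis
#' vocabulary: `additive` (F1 at the mid-parent value), `high_parent` /
#' `low_parent` dominance (F1 at one parent), and `over_dominance` /
#' `under_dominance` (F1 beyond both parents by `log2_excess`).
#'
#' @param modes Character vector of planted modes, one per gene; values in
#'   `c("additive", "high_parent", "low_parent", "over_dominance",
#'   "under_dominance")`.
#' @param log2_excess Planted log2 excess of the F1 beyond the nearer
#'   parent for over-/under-dominance genes (recycled; must be > 0).
#' @param parent_lfc Planted log2 fold change between the two parents
#'   (recycled; must be > 0 so the dominance modes are well defined).
#' @param noise_sd Replicate noise standard deviation on the log2 scale.
#' @param n_replicates Replicates per genotype (>= 2).
#' @param seed Integer seed for the panel simulation.
#'
#' @return A tibble of class `expression_truth` with columns `gene`,
#'   `mode`, `log2_excess`, `parent_lfc` and attributes `noise_sd`,
#'   `n_replicates`, `seed`.
#' @export
expression_truth <- function(modes, log2_excess = 2, parent_lfc = 2,
                             noise_sd = 0.2, n_replicates = 3L, seed = 1L) {
  valid <- c("additive", "high_parent", "low_parent",
             "over_dominance", "under_dominance")
  if (!all(modes %in% valid))
    abort("unknown expression mode.", class = "orthozip_config_error")
  if (n_replicates < 2L)
    abort("`n_replicates` must be >= 2.", class = "orthozip_config_error")
  if (noise_sd < 0)
    abort("`noise_sd` must be >= 0.", class = "orthozip_config_error")
  if (any(log2_excess <= 0) || any(parent_lfc <= 0))
    abort("planted effects must be > 0.", class = "orthozip_config_error")
  out <- tibble(
    gene = sprintf("gene%04d", seq_along(modes)),
    mode = modes,
    log2_excess = rep_len(log2_excess, length(modes)),
    parent_lfc = rep_len(parent_lfc, length(modes))
  )
  attr(out, "noise_sd") <- noise_sd
  attr(out, "n_replicates") <- as.integer(n_replicates)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("expression_truth", class(out))
  out
}

#' Simulate a replicated parents/F1 expression panel with planted modes
#'
#' For each gene, two parent means are drawn on the log2 scale (the planted
#' parent fold change decides their separation, with the higher parent
#' chosen at random), and the F1 mean is set by the planted mode on the
#' linear scale: at the arithmetic mid-parent for `additive`, at one parent
#' for the dominance modes, and beyond the higher (lower) parent by the
#' planted log2 excess for over- (under-) dominance.  Replicates add
#' Gaussian noise on the log2 scale.
#'
#' @param truth An [expression_truth()] object.
#' @param genotypes Three genotype labels, interpreted as parent 1,
#'   parent 2, F1.
#'
#' @return A tibble of class `expression_panel`: columns `gene`,
#'   `genotype`, `replicate`, `value` (linear-scale expression), with the
#'   truth attached as attribute `"truth"` (including per-gene parent
#'   assignment of the higher parent).
#' @export
#' @examples
#' tr <- expression_truth(c("additive", "over_dominance"), noise_sd = 0,
#'                        seed = 2)
#' simulate_expression_panel(tr)
simulate_expression_panel <- function(truth,
                                      genotypes = c("P1", "P2", "F1")) {
  if (!inherits(truth, "expression_truth"))
    abort("`truth` must be an expression_truth object.",
          class = "orthozip_config_error")
  if (length(genotypes) != 3L || anyDuplicated(genotypes))
    abort("`genotypes` must be three distinct labels (parent1, parent2, F1).",
          class = "orthozip_config_error")
  n_rep <- attr(truth, "n_replicates")
  noise <- attr(truth, "noise_sd")
  withr::with_seed(attr(truth, "seed"), {
    rows <- purrr::pmap(truth, function(gene, mode, log2_excess, parent_lfc) {
      base <- runif(1, 6, 10)               # log2 of the lower parent mean
      hi_is_p1 <- runif(1) < 0.5
      lo <- 2^base
      hi <- 2^(base + parent_lfc)
      p1 <- if (hi_is_p1) hi else lo
      p2 <- if (hi_is_p1) lo else hi
      f1 <- switch(mode,
        additive       = (p1 + p2) / 2,
        high_parent    = max(p1, p2),
        low_parent     = min(p1, p2),
        over_dominance  = max(p1, p2) * 2^log2_excess,
        under_dominance = min(p1, p2) * 2^-log2_excess)
      means <- setNames(c(p1, p2, f1), genotypes)
      vals <- 2^(rep(log2(means), each = n_rep) +
                   rnorm(3L * n_rep, 0, noise))
      tibble(gene = gene,
             genotype = rep(genotypes, each = n_rep),
             replicate = rep(seq_len(n_rep), 3L),
             value = vals,
             higher_parent = genotypes[if (hi_is_p1) 1L else 2L])
    })
    panel <- bind_rows(rows)
  })
  truth2 <- dplyr::left_join(truth,
    distinct(panel, .data$gene, .data$higher_parent), by = "gene")
  panel$higher_parent <- NULL
  attr(panel, "truth") <- truth2
  attr(panel, "genotypes") <- genotypes
  class(panel) <- c("expression_panel", class(panel))
  panel
}

#' Simulate a qPCR cycle-threshold (Ct) panel with planted fold changes
#'
#' Builds a replicated Ct table for one calibrator condition and one or
#' more treatment conditions such that relative quantification by the
#' 2^-ddCt method recovers the planted fold changes exactly when
#' `noise_sd = 0`.  A planted fold of `f` places the target's treated Ct
#' `log2(f)` cycles below its calibrator Ct (after reference-gene
#' correction): e.g. an 8-fold induction is exactly 3 cycles.
#'
#' @param fold_changes Either a named positive numeric vector (one fold per
#'   gene, a single `"treated"` condition) or a tibble with columns `gene`,
#'   `condition`, `fold` for multi-condition (time-course) panels.
#' @param reference_gene Name of the internal-control gene added to the
#'   table (constant true expression).
#' @param calibrator_sample Label of the calibrator condition.
#' @param noise_sd Gaussian noise standard deviation on the Ct scale.
#' @param n_replicates Replicates per condition (>= 2).
#' @param base_ct_target,base_ct_reference Baseline Ct of targets and of
#'   the reference gene in the calibrator condition.
#' @param seed Integer seed.
#'
#' @return A tibble of class `ct_table`: columns `sample`, `condition`,
#'   `replicate`, `gene`, `ct`; attributes `reference_gene` and
#'   `calibrator`.
#' @export
simulate_ct_panel <- function(fold_changes, reference_gene = "actin",
                              calibrator_sample = "control",
                              noise_sd = 0, n_replicates = 3L,
                              base_ct_target = 28, base_ct_reference = 20,
                              seed = 1L) {
  if (is.numeric(fold_changes)) {
    if (is.null(names(fold_changes)))
      names(fold_changes) <- sprintf("gene%03d", seq_along(fold_changes))
    fc <- tibble(gene = names(fold_changes), condition = "treated",
                 fold = unname(fold_changes))
  } else {
    fc <- as_tibble(fold_changes)
    if (!all(c("gene", "condition", "fold") %in% names(fc)))
      abort("`fold_changes` tibble needs columns gene, condition, fold.",
            class = "orthozip_config_error")
  }
  if (any(!is.finite(fc$fold)) || any(fc$fold <= 0))
    abort("fold changes must be positive.", class = "orthozip_config_error")
  if (reference_gene %in% fc$gene)
    abort("`reference_gene` collides with a target gene.",
          class = "orthozip_config_error")
  if (calibrator_sample %in% fc$condition)
    abort("`calibrator_sample` collides with a treatment condition.",
          class = "orthozip_config_error")
  if (n_replicates < 2L)
    abort("`n_replicates` must be >= 2.", class = "orthozip_config_error")

  conditions <- c(calibrator_sample, unique(fc$condition))
  genes <- unique(fc$gene)
  grid <- tidyr::expand_grid(condition = conditions,
                             replicate = seq_len(n_replicates),
                             gene = c(genes, reference_gene))
  fold_of <- function(gene, condition) {
    if (gene == reference_gene || condition == calibrator_sample) return(1)
    hit <- fc$fold[fc$gene == gene & fc$condition == condition]
    if (length(hit) == 0L) 1 else hit[[1L]]
  }
  base_of <- function(gene) {
    if (gene == reference_gene) base_ct_reference else base_ct_target
  }
  withr::with_seed(seed, {
    grid$ct <- purrr::pmap_dbl(grid, function(condition, replicate, gene) {
      base_of(gene) - log2(fold_of(gene, condition)) + rnorm(1, 0, noise_sd)
    })
  })
  grid$sample <- paste0(grid$condition, "_r", grid$replicate)
  out <- grid[, c("sample", "condition", "replicate", "gene", "ct")]
  attr(out, "reference_gene") <- reference_gene
  attr(out, "calibrator") <- calibrator_sample
  class(out) <- c("ct_table", class(out))
  out
}
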