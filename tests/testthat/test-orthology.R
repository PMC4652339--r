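submat62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

test_that("self-alignment gives full overlap and the diagonal bit score", {
  withr::with_seed(1, s <- random_protein(100, alphabet = AA20))
  r <- local_align_bitscore(s, s)
  expect_equal(r$overlap_fraction, 1.0)
  diag_raw <- sum(diag(submat62[strsplit(s, "")[[1]],
                                strsplit(s, "")[[1]]]))
  expect_equal(r$raw_score, diag_raw)
  expect_equal(r$bit_score, (0.267 * diag_raw - log(0.041)) / log(2))
})

test_that("alignment raw scores match a plain dynamic-programming oracle", {
  expect_equal(local_align_bitscore("HEAGAWGHEE", "PAWHEAE")$raw_score,
               sw_oracle_score("HEAGAWGHEE", "PAWHEAE", submat62))
  withr::with_seed(2, {
    for (i in 1:60) {
      a <- random_protein(sample(5:80, 1), alphabet = AA20)
      b <- random_protein(sample(5:80, 1), alphabet = AA20)
      expect_equal(local_align_bitscore(a, b)$raw_score,
                   sw_oracle_score(a, b, submat62), info = paste(a, b))
    }
  })
})

test_that("empty sequences score zero without error", {
  r <- local_align_bitscore("", "ACDE")
  expect_equal(r$bit_score, 0)
  expect_equal(r$overlap_fraction, 0)
})

test_that("all-vs-all applies both retention criteria", {
  withr::with_seed(3, {
    core <- random_protein(120, alphabet = AA20)
    # same 120-residue core embedded in a much longer partner: high bits
    # but alignment spans < 50 % of the longer sequence
    long_b <- paste0(random_protein(200), core, random_protein(200))
  })
  prot <- tibble::tibble(
    id = c("a1", "b1"), species = c("A", "B"),
    residues = c(core, long_b))
  kept <- all_vs_all(prot[1, ], prot[2, ])
  cross <- kept[kept$id_a != kept$id_b, ]
  expect_equal(nrow(cross), 0)  # fails the >50 % overlap rule
  # the same pair passes when the overlap cutoff is lifted
  kept2 <- all_vs_all(prot[1, ], prot[2, ], overlap_cutoff = 0)
  expect_equal(nrow(kept2[kept2$id_a != kept2$id_b, ]), 1)
  # a high bit cutoff excludes it again: monotone in the cutoff
  co <- tiny_cohort(n_genes = 8, dup = 0.3, sub = 0.05, seed = 9)
  pa <- co$proteomes[co$proteomes$species == "spA", ]
  pb <- co$proteomes[co$proteomes$species == "spB", ]
  n_by_cutoff <- vapply(c(0, 50, 200, 400),
                        function(ct) nrow(all_vs_all(pa, pb, bit_cutoff = ct)),
                        1L)
  expect_true(all(diff(n_by_cutoff) <= 0))
})

test_that("two identical one-gene proteomes form one seed pair at 100 %", {
  withr::with_seed(4, s <- random_protein(100))
  gr <- cluster_orthologs(all_vs_all(
    tibble::tibble(id = "a1", species = "A", residues = s),
    tibble::tibble(id = "b1", species = "B", residues = s)), "A", "B")
  expect_equal(nrow(gr), 2)
  expect_equal(unique(gr$group_id), 1L)
  expect_true(all(gr$role == "seed"))
  expect_true(all(gr$confidence == 100))
})

test_that("a near-copy closer than the seed's partner joins as in-paralog", {
  withr::with_seed(5, {
    a1 <- protein_with_motif(len = 150)
    # a2: a1 with a few substitutions; b1: a1 with more substitutions
    mut <- function(s, k) {
      ch <- strsplit(s, "")[[1]]
      idx <- sample(seq_along(ch), k)
      ch[idx] <- vapply(ch[idx], function(r)
        sample(setdiff(AA20, c(r, "N")), 1), "")
      paste(ch, collapse = "")
    }
    a2 <- mut(a1, 5)
    b1 <- mut(a1, 25)
  })
  pa <- tibble::tibble(id = c("a1", "a2"), species = "A",
                       residues = c(a1, a2))
  pb <- tibble::tibble(id = "b1", species = "B", residues = b1)
  gr <- cluster_orthologs(all_vs_all(pa, pb), "A", "B")
  expect_equal(nrow(gr), 3)
  expect_equal(unique(gr$group_id), 1L)
  expect_equal(gr$role[gr$gene_id == "a2"], "inparalog")
  expect_true(gr$confidence[gr$gene_id == "a2"] > 0)
})

test_that("unrelated gene families split into separate groups", {
  withr::with_seed(6, {
    f1 <- random_protein(120)
    f2 <- random_protein(120)
  })
  pa <- tibble::tibble(id = c("a1", "a2"), species = "A",
                       residues = c(f1, f2))
  pb <- tibble::tibble(id = c("b1", "b2"), species = "B",
                       residues = c(f1, f2))
  gr <- cluster_orthologs(all_vs_all(pa, pb), "A", "B")
  expect_equal(dplyr::n_distinct(gr$group_id), 2)
  expect_equal(nrow(gr), 4)
  grp_of <- setNames(gr$group_id, gr$gene_id)
  expect_equal(grp_of[["a1"]], grp_of[["b1"]])
  expect_equal(grp_of[["a2"]], grp_of[["b2"]])
  expect_false(grp_of[["a1"]] == grp_of[["a2"]])
})

test_that("clustering matches the brute-force rule implementation", {
  withr::with_seed(7, {
    cases <- data.frame(seed = sample.int(1e6, 30),
                        n_genes = sample(3:9, 30, replace = TRUE))
  })
  for (k in seq_len(nrow(cases))) {
    sd <- cases$seed[k]
    co <- tiny_cohort(n_genes = cases$n_genes[k], dup = 0.4, sub = 0.06,
                      seed = sd, len = 90)
    pa <- co$proteomes[co$proteomes$species == "spA", ]
    pb <- co$proteomes[co$proteomes$species == "spB", ]
    sc <- all_vs_all(pa, pb)
    got <- cluster_orthologs(sc, "spA", "spB")
    want <- bf_cluster(sc, "spA", "spB")
    got_df <- as.data.frame(got)[order(got$gene_id),
                                 c("gene_id", "role", "confidence")]
    want_df <- want[order(want$id), c("id", "role", "conf")]
    expect_equal(got_df$gene_id, want_df$id, info = sd)
    expect_equal(got_df$role, want_df$role, info = sd)
    expect_equal(got_df$confidence, want_df$conf, info = sd)
    # same partition of genes into groups
    part <- function(df, gid, id) {
      split(df[[id]], df[[gid]]) |> lapply(sort) |>
        (\(x) x[order(vapply(x, `[`, "", 1))])() |> unname()
    }
    expect_equal(part(as.data.frame(got), "group_id", "gene_id"),
                 part(want, "gid", "id"), info = sd)
  }
})

test_that("swapping the species labels permutes nothing but the labels", {
  co <- tiny_cohort(n_genes = 8, dup = 0.4, sub = 0.05, seed = 31)
  pa <- co$proteomes[co$proteomes$species == "spA", ]
  pb <- co$proteomes[co$proteomes$species == "spB", ]
  sc <- all_vs_all(pa, pb)
  g1 <- cluster_orthologs(sc, "spA", "spB")
  g2 <- cluster_orthologs(sc, "spB", "spA")
  part <- function(g) {
    unname(lapply(split(g$gene_id, g$group_id), sort)) |>
      (\(x) x[order(vapply(x, `[`, "", 1))])()
  }
  expect_equal(part(g1), part(g2))
  strip <- function(g) data.frame(gene_id = g$gene_id, role = g$role,
                                  confidence = g$confidence)[
                                    order(g$gene_id), ]
  expect_equal(strip(g1), strip(g2), ignore_attr = TRUE)
})

test_that("zero-evolution cohorts cluster to the exact truth at 100 %", {
  co <- simulate_proteomes(sim_config(
    species = c("spA", "spB"), n_ancestral_genes = 10,
    duplication_rate = 0, substitution_rate = 0, bzip_fraction = 0.5,
    contig_fraction = 0, mean_protein_length = 130, seed = 13))
  pa <- co$proteomes[co$proteomes$species == "spA", ]
  pb <- co$proteomes[co$proteomes$species == "spB", ]
  gr <- cluster_orthologs(all_vs_all(pa, pb), "spA", "spB")
  expect_true(all(gr$confidence == 100))
  sizes <- table(gr$group_id)
  expect_true(all(sizes == 2))
  # partition equals the simulated truth
  truth_part <- unname(lapply(split(co$truth_groups$gene_id,
                                    co$truth_groups$group), sort))
  got_part <- unname(lapply(split(gr$gene_id, gr$group_id), sort))
  key <- function(x) vapply(x, paste, "", collapse = "+")
  expect_setequal(key(got_part), key(truth_part))
})

test_that("more than two species in the score table is an error", {
  sc <- tibble::tibble(id_a = "x", id_b = "y", species_a = "A",
                       species_b = "C", raw_score = 100, bit_score = 60,
                       overlap_fraction = 1)
  expect_error(cluster_orthologs(sc, "A", "B"),
               class = "orthozip_input_error")
})
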