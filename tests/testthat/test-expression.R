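test_that("ddCt relative expression follows its closed forms", {
  # all Cts equal across conditions: every fold 1
  ct <- manual_ct(target_ct = list(cal = 25, trt = 25),
                  ref_ct = list(cal = 20, trt = 20))
  rel <- delta_delta_ct(ct)
  expect_true(all(rel$fold == 1))
  # target one cycle lower, reference unchanged: fold 2
  ct <- manual_ct(target_ct = list(cal = 25, trt = 24),
                  ref_ct = list(cal = 20, trt = 20))
  rel <- delta_delta_ct(ct)
  expect_equal(rel$fold[rel$condition == "trt"], 2)
  # ddCt of +2: fold 0.25
  ct <- manual_ct(target_ct = list(cal = 25, trt = 27),
                  ref_ct = list(cal = 20, trt = 20))
  rel <- delta_delta_ct(ct)
  expect_equal(rel$fold[rel$condition == "trt"], 0.25)
  # reference correction: both shifted by the reference leaves fold 1
  ct <- manual_ct(target_ct = list(cal = 25, trt = 26),
                  ref_ct = list(cal = 20, trt = 21))
  rel <- delta_delta_ct(ct)
  expect_equal(rel$fold[rel$condition == "trt"], 1)
})

test_that("a missing reference gene or calibrator is an error", {
  ct <- manual_ct(target_ct = list(cal = 25, trt = 24),
                  ref_ct = list(cal = 20, trt = 20))
  expect_error(delta_delta_ct(ct, reference_gene = "nope"),
               class = "orthozip_input_error")
  expect_error(delta_delta_ct(ct, calibrator = "nope"),
               class = "orthozip_input_error")
  ct2 <- ct[!(ct$gene == "ref" & ct$condition == "trt"), ]
  attr(ct2, "reference_gene") <- "ref"; attr(ct2, "calibrator") <- "cal"
  expect_error(delta_delta_ct(ct2), class = "orthozip_input_error")
})

test_that("ddCt inverts the Ct simulator exactly at zero noise", {
  folds <- c(a = 0.2, b = 1, c = 5, d = 16)
  rel <- delta_delta_ct(simulate_ct_panel(folds, noise_sd = 0, seed = 8))
  trt <- rel[rel$condition == "treated", ]
  expect_equal(trt$fold[match(names(folds), trt$gene)], unname(folds))
  cal <- rel[rel$condition == "control", ]
  expect_true(all(cal$fold == 1))
})

test_that("the DE filter applies the conjunction rule with BH adjustment", {
  # constant matrix: no gene passes, zero-variance genes get p = 1
  const <- tidyr::expand_grid(gene = paste0("g", 1:5),
                              group = c("c", "t"), replicate = 1:3)
  const$value <- 5
  res <- de_filter(const[, c("gene", "group", "value")], c("c", "t"))
  expect_true(all(res$p_value == 1))
  expect_false(any(res$passes))
  # planted 4-fold genes at small noise all pass with correct direction
  withr::with_seed(12, {
    mk <- function(gene, mu_c, mu_t) tibble::tibble(
      gene = gene,
      group = rep(c("c", "t"), each = 3),
      value = c(mu_c + rnorm(3, 0, 0.1), mu_t + rnorm(3, 0, 0.1)))
    planted <- dplyr::bind_rows(lapply(1:10, function(i)
      mk(sprintf("up%02d", i), 8, 10)))      # +2 log2 = 4-fold up
    nulls <- dplyr::bind_rows(lapply(1:10, function(i)
      mk(sprintf("nl%02d", i), 8, 8)))
  })
  res <- de_filter(dplyr::bind_rows(planted, nulls), c("c", "t"))
  up <- res[startsWith(res$gene, "up"), ]
  expect_true(all(up$passes))
  expect_true(all(up$direction == "up"))
  expect_true(all(res$p_adjusted >= res$p_value))
})

test_that("BH-adjusted p is monotone in rank and the passing set shrinks
           with alpha", {
  withr::with_seed(14, {
    df <- tidyr::expand_grid(gene = sprintf("g%03d", 1:50),
                             group = c("c", "t"), replicate = 1:3)
    df$value <- rnorm(nrow(df), 8, 1)
  })
  res <- de_filter(df[, c("gene", "group", "value")], c("c", "t"))
  o <- order(res$p_value)
  expect_true(all(diff(res$p_adjusted[o]) >= -1e-12))
  res_strict <- de_filter(df[, c("gene", "group", "value")], c("c", "t"),
                          alpha = 0.01)
  expect_true(all(res_strict$gene[res_strict$passes] %in%
                    res$gene[res$passes]))
  expect_error(de_filter(df[df$replicate == 1, c("gene", "group", "value")],
                         c("c", "t")),
               class = "orthozip_input_error")
})

test_that("type-I error of the DE t-test is near nominal on null panels", {
  withr::with_seed(5, {
    df <- tidyr::expand_grid(gene = sprintf("g%04d", 1:2000),
                             group = c("c", "t"), replicate = 1:3)
    df$value <- rnorm(nrow(df), 8, 0.5)
  })
  res <- de_filter(df[, c("gene", "group", "value")], c("c", "t"))
  frac <- mean(res$p_value < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("responsiveness classes follow the 10-fold and band rules", {
  expect_equal(responsiveness_class(c(1, 12, 30, 8)), "strong")
  expect_equal(responsiveness_class(c(1, 59.4, 2)), "strong")
  expect_equal(responsiveness_class(c(1, 1.1, 0.95)), "unresponsive")
  expect_equal(responsiveness_class(c(1, 3, 6)), "weak")
  expect_equal(responsiveness_class(c(1, 0.4, 0.8)), "weak")  # repressed
  expect_equal(responsiveness_class(c(1, 10)), "weak")  # threshold is strict
  expect_error(responsiveness_class(1), class = "orthozip_input_error")
  df <- tibble::tibble(gene = rep(c("a", "b"), each = 3),
                       time = rep(c(0, 6, 12), 2),
                       fold = c(1, 2, 30, 1, 1.2, 0.9))
  cls <- classify_responsiveness(df)
  expect_equal(cls$class, c("strong", "unresponsive"))
})

test_that("expression-mode calls follow the two t-test decision rules", {
  over <- classify_expression_mode(c(10, 10.2, 9.8), c(5, 5.1, 4.9),
                                   c(6, 6.2, 5.8))
  expect_equal(over$mode, "over_dominance")
  expect_lt(over$p_parent1, 0.05)
  expect_lt(over$p_parent2, 0.05)
  expect_equal(over$mid_parent_deviation, 1)
  low <- classify_expression_mode(c(2, 2.1, 1.9), c(8, 8.2, 7.8),
                                  c(2.05, 1.95, 2.0))
  expect_equal(low$mode, "low_parent")
  same <- classify_expression_mode(c(5, 5.2, 4.8), c(5, 5.2, 4.8),
                                   c(5, 5.2, 4.8))
  expect_equal(same$mode, "unclassified")
  under <- classify_expression_mode(c(1, 1.05, 0.95), c(8, 8.2, 7.8),
                                    c(3, 3.1, 2.9))
  expect_equal(under$mode, "under_dominance")
  expect_warning(
    deg <- classify_expression_mode(c(2, 2), c(3, 3), c(4, 4)),
    "zero-variance")
  expect_equal(deg$mode, "unclassified")
})

test_that("mode calls are invariant under swapping the parent labels", {
  withr::with_seed(16, {
    for (i in 1:20) {
      f1 <- 2^rnorm(3, sample(4:9, 1), 0.2)
      p1 <- 2^rnorm(3, sample(4:9, 1), 0.2)
      p2 <- 2^rnorm(3, sample(4:9, 1), 0.2)
      a <- classify_expression_mode(f1, p1, p2)
      b <- classify_expression_mode(f1, p2, p1)
      expect_equal(a$mode, b$mode)
      expect_equal(a$p_parent1, b$p_parent2)
      expect_equal(a$mid_parent_deviation, b$mid_parent_deviation)
    }
  })
  expect_error(classify_expression_mode(1, c(1, 2), c(1, 2)),
               class = "orthozip_input_error")
})

test_that("probe mapping enforces both E-value criteria", {
  withr::with_seed(18, {
    # a CDS whose translation is clean (built from non-stop codons)
    codons <- c("GCT", "GAA", "AAA", "CTG", "ATG", "TTC", "GGT", "CAT",
                "ATC", "CCA", "TCT", "ACC")
    cds_seq <- paste(sample(codons, 300, replace = TRUE), collapse = "")
    probe_hit <- substr(cds_seq, 91, 150)           # exact 60-nt substring
    probe_rand <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                        collapse = "")
  })
  prot_seq <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds_seq)))
  probes <- tibble::tibble(probe_id = c("hit", "rand"),
                           sequence = c(probe_hit, probe_rand))
  cds <- tibble::tibble(gene_id = "g1", sequence = cds_seq)
  prot <- tibble::tibble(gene_id = "g1", residues = prot_seq)
  map <- map_probes_to_genes(probes, cds, prot)
  expect_true(map$mapped[map$probe_id == "hit"])
  expect_lt(map$e_value_cds[map$probe_id == "hit"], 1e-5)
  expect_false(map$mapped[map$probe_id == "rand"])
  expect_gt(map$e_value_cds[map$probe_id == "rand"], 1e-5)
  expect_false(any(map$ambiguous))
  # conjunction: perfect CDS hit but an unrelated protein fails criterion 2
  withr::with_seed(19, other_prot <- random_protein(120, alphabet = AA20))
  map2 <- map_probes_to_genes(probes[1, ], cds,
                              tibble::tibble(gene_id = "g1",
                                             residues = other_prot))
  expect_false(map2$mapped)
  expect_lt(map2$e_value_cds, 1e-5)
  expect_gt(map2$e_value_protein, 1e-3)
})

test_that("probe E-values equal the direct Karlin-Altschul formula", {
  withr::with_seed(20, {
    probe <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                   collapse = "")
    cds_seq <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                     collapse = "")
  })
  nuc_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -2, baseOnly = TRUE)
  raw <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(probe), Biostrings::DNAString(cds_seq),
    type = "local", substitutionMatrix = nuc_mat, gapOpening = 5,
    gapExtension = 2, scoreOnly = TRUE)
  want <- evalue_oracle(raw, 60, 500, 1.33, 0.621)
  map <- map_probes_to_genes(
    tibble::tibble(probe_id = "p", sequence = probe),
    tibble::tibble(gene_id = "g", sequence = cds_seq),
    tibble::tibble(gene_id = "g", residues = "M"))
  expect_equal(map$e_value_cds, want, tolerance = 1e-12)
})
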