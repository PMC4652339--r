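#' Relative quantification by the 2^-ddCt method
#'
#' For each gene and condition, the replicate-mean Ct of the target is
#' corrected by the replicate-mean Ct of the reference gene (dCt), the
#' calibrator condition's dCt is subtracted (ddCt), and the relative
#' expression is `2^-ddCt`.  Replicate-level folds (each replicate's dCt
#' against the calibrator-mean dCt) are retained for downstream
#' statistics.
#'
#' @param ct A `ct_table` tibble (columns `condition`, `replicate`,
#'   `gene`, `ct`), e.g. from [simulate_ct_panel()] or [read_ct_csv()].
#' @param reference_gene Internal-control gene id; defaults to the
#'   table's `reference_gene` attribute.
#' @param calibrator Calibrator condition label; defaults to the table's
#'   `calibrator` attribute.
#'
#' @return A tibble of class `relative_expression`: `gene`, `condition`,
#'   `fold` (calibrator condition = 1 exactly at zero noise), with
#'   attribute `"replicate_folds"` (tibble `gene`, `condition`,
#'   `replicate`, `fold`).
#' @export
delta_delta_ct <- function(ct, reference_gene = NULL, calibrator = NULL) {
  ct <- as_tibble(ct)
  reference_gene <- reference_gene %||% attr(ct, "reference_gene")
  calibrator <- calibrator %||% attr(ct, "calibrator")
  if (is.null(reference_gene) || is.null(calibrator))
    abort("reference gene and calibrator must be given.",
          class = "orthozip_input_error")
  if (!reference_gene %in% ct$gene)
    abort("reference gene absent from the Ct table.",
          class = "orthozip_input_error")
  if (!calibrator %in% ct$condition)
    abort("calibrator condition absent from the Ct table.",
          class = "orthozip_input_error")
  if (any(!is.finite(ct$ct)))
    abort("non-finite Ct values.", class = "orthozip_input_error")

  ref <- ct |> filter(.data$gene == reference_gene) |>
    group_by(.data$condition) |>
    summarise(ref_ct = mean(.data$ct), n_ref = dplyr::n(), .groups = "drop")
  n_cond <- dplyr::n_distinct(ct$condition)
  if (nrow(ref) < n_cond)
    abort("reference gene is missing in some condition.",
          class = "orthozip_input_error")

  targets <- ct |> filter(.data$gene != reference_gene) |>
    left_join(ref, by = "condition") |>
    mutate(dct = .data$ct - .data$ref_ct)

  cal_dct <- targets |> filter(.data$condition == calibrator) |>
    group_by(.data$gene) |>
    summarise(cal_dct = mean(.data$dct), .groups = "drop")

  rep_folds <- targets |> left_join(cal_dct, by = "gene") |>
    mutate(fold = 2^-(.data$dct - .data$cal_dct)) |>
    select("gene", "condition", "replicate", "fold")

  out <- targets |> group_by(.data$gene, .data$condition) |>
    summarise(dct = mean(.data$dct), .groups = "drop") |>
    left_join(cal_dct, by = "gene") |>
    mutate(fold = 2^-(.data$dct - .data$cal_dct)) |>
    select("gene", "condition", "fold")
  attr(out, "replicate_folds") <- rep_folds
  class(out) <- c("relative_expression", class(out))
  out
}

#' Differential-expression filter (two-group t-test with BH adjustment)
#'
#' Per gene, a two-sided Welch t-test on log2 expression values between
#' the two groups of the contrast, Benjamini-Hochberg adjustment across
#' all genes tested, and the conjunction decision rule: a gene passes iff
#' both the raw p-value and the adjusted p-value are below `alpha`.
#' Direction is the sign of the mean difference (`group2 - group1`:
#' `"up"` if the second group is higher).  Genes with zero variance in
#' both groups are assigned p = 1.
#'
#' @param data Long tibble with columns `gene`, `group`, `value` (log2
#'   expression, one row per replicate).
#' @param groups Optional length-2 character vector selecting and ordering
#'   the contrast's groups (default: the two groups present, first-seen
#'   order).
#' @param alpha Significance level for both raw and adjusted p (default
#'   0.05).
#'
#' @return A tibble of class `de_result`: `gene`, `mean_diff` (log2,
#'   group2 - group1), `direction`, `p_value`, `p_adjusted`, `passes`.
#' @export
de_filter <- function(data, groups = NULL, alpha = 0.05) {
  data <- as_tibble(data)
  req <- c("gene", "group", "value")
  if (!all(req %in% names(data)))
    abort("`data` needs columns gene, group, value.",
          class = "orthozip_input_error")
  if (is.null(groups)) groups <- unique(data$group)
  if (length(groups) != 2L)
    abort("exactly two groups are required for the contrast.",
          class = "orthozip_input_error")
  data <- data[data$group %in% groups, ]
  counts <- data |> dplyr::count(.data$gene, .data$group)
  if (any(counts$n < 2L) ||
      nrow(counts) < 2L * dplyr::n_distinct(data$gene))
    abort("each gene needs >= 2 replicates in both groups.",
          class = "orthozip_input_error")

  res <- data |> group_by(.data$gene) |>
    summarise(
      mean_diff = mean(.data$value[.data$group == groups[2]]) -
        mean(.data$value[.data$group == groups[1]]),
      p_value = welch_p(.data$value[.data$group == groups[1]],
                        .data$value[.data$group == groups[2]]),
      .groups = "drop")
  res$p_adjusted <- p.adjust(res$p_value, method = "BH")
  res$direction <- ifelse(res$mean_diff >= 0, "up", "down")
  res$passes <- res$p_value < alpha & res$p_adjusted < alpha
  out <- res[, c("gene", "mean_diff", "direction", "p_value",
                 "p_adjusted", "passes")]
  class(out) <- c("de_result", class(out))
  out
}

# Welch two-sided p; degenerate zero-variance pairs get p = 1.
welch_p <- function(x, y) {
  if (stats::var(x) + stats::var(y) == 0) return(1)
  t.test(x, y, var.equal = FALSE)$p.value
}

#' Low-temperature responsiveness class of an expression time course
#'
#' Given a relative-expression time course (first value the untreated
#' reference, equal to 1), a gene is `"strong"` when its highest
#' post-treatment fold exceeds `threshold` (default 10 times the
#' untreated control), `"weak"` when it is responsive — maximum fold at
#' least `band` or minimum fold at most `1/band` (default 2-fold band) —
#' without exceeding the threshold, and `"unresponsive"` otherwise.
#'
#' @param course Numeric vector of relative expressions; the first entry
#'   is the untreated reference.
#' @param threshold Strong-response threshold on the maximum fold
#'   (default 10).
#' @param band Fold-change band defining "responsive" (default 2).
#' @return One of `"strong"`, `"weak"`, `"unresponsive"`.
#' @export
#' @examples
#' responsiveness_class(c(1, 12, 30, 8))   # "strong"
responsiveness_class <- function(course, threshold = 10, band = 2) {
  if (length(course) < 2L)
    abort("`course` needs the reference plus >= 1 post-treatment value.",
          class = "orthozip_input_error")
  post <- course[-1]
  if (max(post) > threshold) return("strong")
  if (max(post) >= band || min(post) <= 1 / band) return("weak")
  "unresponsive"
}

#' Classify responsiveness for many genes
#'
#' @param data Tibble with columns `gene`, `time`, `fold`; the earliest
#'   time per gene is the untreated reference.
#' @inheritParams responsiveness_class
#' @return Tibble `gene`, `max_fold`, `min_fold`, `class`.
#' @export
classify_responsiveness <- function(data, threshold = 10, band = 2) {
  data <- as_tibble(data) |> arrange(.data$gene, .data$time)
  data |> group_by(.data$gene) |>
    summarise(max_fold = max(.data$fold[-1]),
              min_fold = min(.data$fold[-1]),
              class = responsiveness_class(.data$fold, threshold, band),
              .groups = "drop")
}

#' Heterosis expression mode of one gene
#'
#' Two-sided Welch t-tests compare the F1's replicates with each parent's.
#' The gene is called `over_dominance` (`under_dominance`) when the F1 is
#' significantly different from both parents and its mean lies above
#' (below) both parent means; `high_parent` (`low_parent`) dominance when
#' it differs significantly from exactly one parent and its mean is nearer
#' the higher (lower) parent; otherwise `unclassified`.  Values are tested
#' on the log2 scale.
#'
#' @param f1,parent1,parent2 Numeric replicate vectors (linear scale,
#'   >= 2 replicates each).
#' @param alpha Significance level (default 0.05).
#' @param log2_input Set `TRUE` if the replicates are already log2.
#'
#' @return A one-row tibble (`ModeCall`): `mode`, `p_parent1`,
#'   `p_parent2`, `mid_parent_deviation` (sign of the F1 mean minus the
#'   mid-parent mean, linear scale).
#' @export
#' @examples
#' classify_expression_mode(c(10, 10.2, 9.8), c(5, 5.1, 4.9),
#'                          c(6, 6.2, 5.8))     # over_dominance
classify_expression_mode <- function(f1, parent1, parent2, alpha = 0.05,
                                     log2_input = FALSE) {
  if (length(f1) < 2L || length(parent1) < 2L || length(parent2) < 2L)
    abort("each genotype needs >= 2 replicates.",
          class = "orthozip_input_error")
  lf1 <- if (log2_input) f1 else log2(f1)
  lp1 <- if (log2_input) parent1 else log2(parent1)
  lp2 <- if (log2_input) parent2 else log2(parent2)
  if (stats::var(lf1) == 0 && stats::var(lp1) == 0 &&
      stats::var(lp2) == 0) {
    warn("degenerate zero-variance replicates; mode is unclassified.")
    return(tibble(mode = "unclassified", p_parent1 = NA_real_,
                  p_parent2 = NA_real_, mid_parent_deviation = NA_real_))
  }
  p1v <- welch_p(lf1, lp1)
  p2v <- welch_p(lf1, lp2)
  m_f1 <- mean(lf1); m_p1 <- mean(lp1); m_p2 <- mean(lp2)
  mid <- if (log2_input) (m_p1 + m_p2) / 2
         else log2((mean(parent1) + mean(parent2)) / 2)
  sig1 <- p1v < alpha
  sig2 <- p2v < alpha
  mode <- "unclassified"
  if (sig1 && sig2) {
    if (m_f1 > max(m_p1, m_p2)) mode <- "over_dominance"
    else if (m_f1 < min(m_p1, m_p2)) mode <- "under_dominance"
  } else if (xor(sig1, sig2)) {
    hi <- max(m_p1, m_p2); lo <- min(m_p1, m_p2)
    mode <- if (abs(m_f1 - hi) <= abs(m_f1 - lo)) "high_parent"
            else "low_parent"
  }
  tibble(mode = mode, p_parent1 = p1v, p_parent2 = p2v,
         mid_parent_deviation = sign(m_f1 - mid))
}

#' Classify heterosis expression modes across a panel
#'
#' @param panel Long tibble with columns `gene`, `genotype`, `replicate`,
#'   `value` (an `expression_panel` is accepted directly).
#' @param genotypes Three labels (parent1, parent2, F1); defaults to the
#'   panel's `genotypes` attribute or the first three seen.
#' @inheritParams classify_expression_mode
#' @return A tibble of class `mode_calls`, one row per gene: `gene`,
#'   `mode`, `p_parent1`, `p_parent2`, `mid_parent_deviation`.
#' @export
classify_expression_modes <- function(panel, genotypes = NULL,
                                      alpha = 0.05, log2_input = FALSE) {
  panel <- as_tibble(panel)
  genotypes <- genotypes %||% attr(panel, "genotypes") %||%
    unique(panel$genotype)[1:3]
  out <- panel |> group_by(.data$gene) |>
    dplyr::group_modify(function(df, key) {
      classify_expression_mode(
        df$value[df$genotype == genotypes[3]],
        df$value[df$genotype == genotypes[1]],
        df$value[df$genotype == genotypes[2]],
        alpha = alpha, log2_input = log2_input)
    }) |> ungroup()
  class(out) <- c("mode_calls", class(out))
  out
}
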