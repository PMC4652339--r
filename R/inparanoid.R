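#' Cluster two species' genes into ortholog groups with in-paralogs
#'
#' Deterministic seed-and-attach orthology clustering in the InParanoid
#' tradition, on a filtered pairwise score table:
#'
#' 1. *Seeds*: every mutually best-scoring cross-species pair (ties broken
#'    by lexicographic gene id) becomes a seed ortholog pair.
#' 2. *In-paralogs*: for each seed, every same-species gene whose score to
#'    its seed is at least the seed pair's cross-species score is attached
#'    to the group — such genes are duplicates postdating the speciation,
#'    co-orthologous as a set to the other species' seed.
#' 3. *Confidence*: an in-paralog's confidence is
#'    `100 * (score_to_seed - seed_cross_score) /
#'    (seed_self_score - seed_cross_score)`, clipped to `[0, 100]`;
#'    seeds are fixed at 100.
#' 4. *Resolution*: a gene landing in several candidate groups is assigned
#'    where its confidence is highest; ties go to the higher-scoring seed
#'    pair, then to the lexicographically smaller seed ids.  Seed genes
#'    always remain in their own group.
#'
#' Groups are returned in descending seed-pair score.
#'
#' @param scores A `score_table` from [all_vs_all()] covering exactly two
#'   species (within- and cross-species pairs).
#' @param species_a,species_b The two species labels.
#'
#' @return An object of class `ortholog_groups`: a tibble with one row per
#'   group member — `group_id`, `species`, `gene_id`, `role`
#'   (`"seed"`/`"inparalog"`), `confidence` (percent), `seed_score` (the
#'   group's cross-species seed score, bits) — plus attribute `"seeds"`
#'   (tibble of seed pairs).
#' @export
cluster_orthologs <- function(scores, species_a, species_b) {
  scores <- as_tibble(scores)
  sp_in <- unique(c(scores$species_a, scores$species_b))
  if (!all(sp_in %in% c(species_a, species_b)))
    abort("score table contains species other than the named two.",
          class = "orthozip_input_error")
  if (identical(species_a, species_b))
    abort("`species_a` and `species_b` must differ.",
          class = "orthozip_input_error")

  # symmetric lookup of bit scores
  key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "\r")
  lut <- setNames(scores$bit_score, key(scores$id_a, scores$id_b))
  get_score <- function(x, y) {
    v <- lut[key(x, y)]
    ifelse(is.na(v), -Inf, v)
  }

  species_of <- c(setNames(scores$species_a, scores$id_a),
                  setNames(scores$species_b, scores$id_b))
  genes <- names(species_of)[!duplicated(names(species_of))]
  species_of <- species_of[genes]
  genes_a <- sort(genes[species_of == species_a])
  genes_b <- sort(genes[species_of == species_b])

  cross <- scores[scores$species_a != scores$species_b, ]
  if (!nrow(cross))
    return(empty_groups(species_a, species_b))

  # orient cross pairs as (a in species_a, b in species_b)
  a_id <- ifelse(cross$species_a == species_a, cross$id_a, cross$id_b)
  b_id <- ifelse(cross$species_a == species_a, cross$id_b, cross$id_a)
  cross <- tibble(a = a_id, b = b_id, bits = cross$bit_score)

  best_of <- function(df, from, to) {
    df <- df[order(df[[from]], -df$bits, df[[to]]), ]
    df <- df[!duplicated(df[[from]]), ]
    setNames(df[[to]], df[[from]])
  }
  best_b <- best_of(cross, "a", "b")
  best_a <- best_of(cross, "b", "a")

  seed_a <- names(best_b)[best_a[best_b] == names(best_b)]
  seeds <- tibble(a = seed_a, b = unname(best_b[seed_a]))
  seeds$cross <- mapply(get_score, seeds$a, seeds$b)
  seeds$self_a <- mapply(get_score, seeds$a, seeds$a)
  seeds$self_b <- mapply(get_score, seeds$b, seeds$b)
  seeds <- seeds[order(-seeds$cross, seeds$a, seeds$b), ]
  seeds$group_id <- seq_len(nrow(seeds))

  # candidate memberships: seeds plus same-species genes scoring >= the
  # seed's cross score against the seed
  cand <- list()
  for (r in seq_len(nrow(seeds))) {
    s <- seeds[r, ]
    for (side in c("a", "b")) {
      seed_gene <- s[[side]]
      self <- if (side == "a") s$self_a else s$self_b
      pool <- if (side == "a") genes_a else genes_b
      sc <- vapply(pool, function(g) get_score(g, seed_gene), 0)
      in_grp <- pool[sc >= s$cross]
      conf <- ifelse(pool[match(in_grp, pool)] == seed_gene, 100,
                     conf_value(sc[match(in_grp, pool)], s$cross, self))
      cand[[length(cand) + 1L]] <- tibble(
        group_id = s$group_id,
        species = if (side == "a") species_a else species_b,
        gene_id = in_grp,
        role = ifelse(in_grp == seed_gene, "seed", "inparalog"),
        confidence = conf,
        seed_score = s$cross,
        seed_key = paste(s$a, s$b))
    }
  }
  cand <- bind_rows(cand)

  # resolution: own-seed first, then confidence, seed score, seed ids
  cand <- cand[order(cand$gene_id,
                     cand$role != "seed",
                     -cand$confidence,
                     -cand$seed_score,
                     cand$seed_key), ]
  cand <- cand[!duplicated(cand$gene_id), ]

  out <- cand[, c("group_id", "species", "gene_id", "role", "confidence",
                  "seed_score")]
  out <- out[order(out$group_id, match(out$species, c(species_a, species_b)),
                   -out$confidence, out$gene_id), ]
  attr(out, "seeds") <- seeds[, c("group_id", "a", "b", "cross",
                                  "self_a", "self_b")]
  attr(out, "species_pair") <- c(species_a, species_b)
  class(out) <- c("ortholog_groups", class(out))
  out
}

conf_value <- function(score_to_seed, cross, self) {
  denom <- self - cross
  if (denom <= 0) return(rep(100, length(score_to_seed)))
  pmin(pmax(100 * (score_to_seed - cross) / denom, 0), 100)
}

empty_groups <- function(species_a, species_b) {
  out <- tibble(group_id = integer(), species = character(),
                gene_id = character(), role = character(),
                confidence = double(), seed_score = double())
  attr(out, "seeds") <- tibble(group_id = integer(), a = character(),
                               b = character(), cross = double(),
                               self_a = double(), self_b = double())
  attr(out, "species_pair") <- c(species_a, species_b)
  class(out) <- c("ortholog_groups", class(out))
  out
}
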