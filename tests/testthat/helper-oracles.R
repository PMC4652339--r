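# Independent oracles, written straight from the definitions and kept free
# of any code shared with the package implementation.

# --- Smith-Waterman affine local alignment, plain dynamic programming ----
# Gap of length L costs gap_open + L * gap_extend.
sw_oracle_score <- function(a, b, submat, gap_open = 11, gap_extend = 1) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) return(0)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)     # best ending in a match/mismatch
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in y (consume x)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in x (consume y)
  best <- 0
  open_cost <- gap_open + gap_extend
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[x[i - 1], y[j - 1]]
      M[i, j] <- max(0,
                     M[i - 1, j - 1] + s,
                     Ix[i - 1, j - 1] + s,
                     Iy[i - 1, j - 1] + s)
      Ix[i, j] <- max(M[i - 1, j] - open_cost, Ix[i - 1, j] - gap_extend)
      Iy[i, j] <- max(M[i, j - 1] - open_cost, Iy[i, j - 1] - gap_extend)
      best <- max(best, M[i, j])
    }
  }
  best
}

# --- exhaustive bZIP motif scan ------------------------------------------
scan_oracle <- function(residues, min_heptads = 2, zipper_gap = 9) {
  ch <- strsplit(residues, "")[[1]]
  L <- length(ch)
  hyd <- c("L", "I", "V", "F", "M")
  hits <- NULL
  for (i0 in seq_len(L) - 1L) {          # 0-based start
    if (i0 + 8 >= L) next
    if (ch[i0 + 1] != "N") next
    if (!ch[i0 + 9] %in% c("R", "K")) next
    z0 <- i0 + 8 + zipper_gap
    cnt <- 0
    k <- z0
    while (k < L && ch[k + 1] %in% hyd) { cnt <- cnt + 1; k <- k + 7 }
    if (cnt >= min_heptads)
      hits <- rbind(hits, data.frame(basic_start = i0, heptad_count = cnt))
  }
  if (is.null(hits)) data.frame(basic_start = integer(),
                                heptad_count = integer())
  else hits
}

# --- brute-force InParanoid-style clustering ------------------------------
# Direct rule-by-rule implementation over explicit loops.
bf_cluster <- function(scores, sp_a, sp_b) {
  scores <- as.data.frame(scores)
  gene_sp <- unique(rbind(
    data.frame(id = scores$id_a, sp = scores$species_a),
    data.frame(id = scores$id_b, sp = scores$species_b)))
  sc <- function(x, y) {
    hit <- scores[(scores$id_a == x & scores$id_b == y) |
                  (scores$id_a == y & scores$id_b == x), "bit_score"]
    if (length(hit)) max(hit) else -Inf
  }
  ga <- sort(gene_sp$id[gene_sp$sp == sp_a])
  gb <- sort(gene_sp$id[gene_sp$sp == sp_b])
  # rule 1: mutual best cross pairs (ties -> lexicographic smaller id)
  best <- function(g, pool) {
    s <- vapply(pool, function(h) sc(g, h), 0)
    if (!length(s) || max(s) == -Inf) return(NA_character_)
    cands <- sort(pool[s == max(s)])
    cands[1]
  }
  seeds <- NULL
  for (a in ga) {
    b <- best(a, gb)
    if (!is.na(b) && identical(best(b, ga), a))
      seeds <- rbind(seeds, data.frame(a = a, b = b, cross = sc(a, b)))
  }
  if (is.null(seeds)) return(NULL)
  seeds <- seeds[order(-seeds$cross, seeds$a, seeds$b), , drop = FALSE]
  seeds$gid <- seq_len(nrow(seeds))
  # rules 2-3: candidate members with confidences
  members <- NULL
  for (r in seq_len(nrow(seeds))) {
    s <- seeds[r, ]
    for (side in list(list(seed = s$a, pool = ga, sp = sp_a),
                      list(seed = s$b, pool = gb, sp = sp_b))) {
      self <- sc(side$seed, side$seed)
      for (g in side$pool) {
        v <- sc(g, side$seed)
        if (v >= s$cross) {
          conf <- if (g == side$seed) 100
          else if (self - s$cross <= 0) 100
          else 100 * (v - s$cross) / (self - s$cross)
          conf <- min(max(conf, 0), 100)
          members <- rbind(members, data.frame(
            gid = s$gid, sp = side$sp, id = g,
            role = if (g == side$seed) "seed" else "inparalog",
            conf = conf, seed_score = s$cross,
            seed_key = paste(s$a, s$b)))
        }
      }
    }
  }
  # rule 4: keep best assignment per gene
  out <- NULL
  for (g in unique(members$id)) {
    cand <- members[members$id == g, , drop = FALSE]
    cand <- cand[order(cand$role != "seed", -cand$conf,
                       -cand$seed_score, cand$seed_key), , drop = FALSE]
    out <- rbind(out, cand[1, ])
  }
  out[order(out$gid, out$id), c("gid", "sp", "id", "role", "conf")]
}

# --- independent protein mass / charge models -----------------------------
# masses retyped from a published average-mass table
ORACLE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)

mw_oracle_kda <- function(residues) {
  ch <- strsplit(residues, "")[[1]]
  (sum(ORACLE_MASS[ch]) + 18.01524) / 1000
}

pi_oracle <- function(residues,
                      pka_pos = c(Nterm = 8.0, K = 10.0, R = 12.0, H = 5.98),
                      pka_neg = c(Cterm = 3.55, D = 4.05, E = 4.45,
                                  C = 9.0, Y = 10.0)) {
  ch <- strsplit(residues, "")[[1]]
  cnt <- c(table(ch))
  n_of <- function(r) if (r %in% names(cnt)) cnt[[r]] else 0
  charge <- function(pH) {
    pos <- 1 / (1 + 10^(pH - pka_pos[["Nterm"]])) +
      sum(vapply(c("K", "R", "H"), function(r)
        n_of(r) / (1 + 10^(pH - pka_pos[[r]])), 0))
    neg <- 1 / (1 + 10^(pka_neg[["Cterm"]] - pH)) +
      sum(vapply(c("D", "E", "C", "Y"), function(r)
        n_of(r) / (1 + 10^(pka_neg[[r]] - pH)), 0))
    pos - neg
  }
  grid <- seq(0, 14, by = 0.001)
  grid[which.min(abs(vapply(grid, charge, 0)))]
}

# --- E-value formula ------------------------------------------------------
evalue_oracle <- function(raw, m, n, lambda, K) {
  bits <- (lambda * raw - log(K)) / log(2)
  K * m * n * 2^(-bits)
}
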