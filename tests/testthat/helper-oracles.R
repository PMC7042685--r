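# Small handmade fixtures and independent brute-force oracles used across
# the suite. Oracles are deliberately written as naive enumerations, not
# calls into the package internals.

make_tiny_G <- function() {
  # 5 individuals, 2 populations, 3 loci; one missing genotype
  a1 <- rbind(c(152, 101, 7),
              c(152, 103, 7),
              c(156, 101, 9),
              c(NA,  103, 7),
              c(152, 101, 9))
  a2 <- rbind(c(152, 103, 9),
              c(156, 103, 7),
              c(156, 105, 9),
              c(NA,  103, 9),
              c(156, 101, 7))
  genotype_matrix(a1, a2, ids = paste0("t", 1:5),
                  pops = c("A", "A", "A", "B", "B"),
                  loci = c("L1", "L2", "L3"))
}

# hand-tally multilocus statistics: counts alleles per locus with explicit
# loops over genotype pairs
oracle_site_stats <- function(G, pop = NULL) {
  idx <- if (is.null(pop)) seq_len(n_ind(G)) else which(G$pops == pop)
  A <- I <- He <- Ho <- c()
  for (l in seq_len(n_loc(G))) {
    counts <- list(); n_het <- 0; n_scored <- 0
    for (i in idx) {
      x <- G$a1[i, l]; y <- G$a2[i, l]
      if (is.na(x)) next
      n_scored <- n_scored + 1
      if (x != y) n_het <- n_het + 1
      for (a in c(x, y)) {
        k <- as.character(a)
        counts[[k]] <- (if (is.null(counts[[k]])) 0 else counts[[k]]) + 1
      }
    }
    if (n_scored == 0) next
    p <- unlist(counts) / (2 * n_scored)
    A <- c(A, length(p))
    I <- c(I, -sum(p * log(p)))
    He <- c(He, 1 - sum(p^2))
    Ho <- c(Ho, n_het / n_scored)
  }
  list(A = mean(A), I = mean(I), He = mean(He), Ho = mean(Ho),
       Fis = 1 - mean(Ho) / mean(He))
}

# all-pairs AUC with half-credit for ties
oracle_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Mann-Whitney U (x vs y) by pair counting
oracle_U <- function(x, y) {
  u <- 0
  for (a in x) for (b in y) u <- u + (a > b) + 0.5 * (a == b)
  u
}

# brute-force circular-neighborhood membership: every occupied cell of the
# grid is recomputed from all tree-to-center distances
oracle_membership <- function(G, grid) {
  r <- grid$diameter / 2
  north <- grid$south + grid$nrow * grid$cell_size
  ok <- which(stats::complete.cases(G$coords))
  out <- list()
  for (ci in seq_len(nrow(grid$cells))) {
    row <- grid$cells$row[ci]; col <- grid$cells$col[ci]
    cx <- grid$west + (col - 0.5) * grid$cell_size
    cy <- north - (row - 0.5) * grid$cell_size
    hit <- ok[sqrt((G$coords[ok, 1] - cx)^2 + (G$coords[ok, 2] - cy)^2) <= r]
    out[[ci]] <- sort(hit)
  }
  out
}

# a fast fake base-learner factory for ensemble tests: scores are a fixed
# noisy transform of one environmental layer
mock_fit_fun <- function(layer, noise_seed, flip = FALSE) {
  force(layer); force(noise_seed); force(flip)
  function(p, b, s, seed) {
    structure(list(name = paste0("mock_", layer, "_", noise_seed),
                   predict_fun = function(newdata) {
                     set.seed(noise_seed)
                     x <- newdata[[layer]]
                     x <- (x - min(x)) / max(1e-12, diff(range(x)))
                     if (flip) x <- 1 - x
                     pmin(pmax(x + rnorm(length(x), 0, 0.05), 0), 1)
                   }),
              class = "sdm_model")
  }
}
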