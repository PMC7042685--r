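make_geo_G <- function(coords, pops = NULL, seed = 1) {
  set.seed(seed)
  n <- nrow(coords)
  if (is.null(pops)) pops <- rep("A", n)
  a1 <- matrix(sample(1:6, n * 4, TRUE), n)
  a2 <- matrix(sample(1:6, n * 4, TRUE), n)
  genotype_matrix(a1, a2, pops = pops, coords = coords)
}

test_that("circle membership follows the center-in-circle rule at 5 arc-minutes", {
  # one tree exactly on a cell center
  cs <- 1 / 120
  tree <- c(-75 + 10.5 * cs, 4 + 10.5 * cs)
  G <- make_geo_G(cbind(tree[1], tree[2]))
  grid <- build_neighborhood_grid(G)
  r <- 1 / 12  # 10 arc-minute diameter -> 5 arc-minute radius
  north <- grid$south + grid$nrow * cs
  centers_lon <- grid$west + (grid$cells$col - 0.5) * cs
  centers_lat <- north - (grid$cells$row - 0.5) * cs
  d <- sqrt((centers_lon - tree[1])^2 + (centers_lat - tree[2])^2)
  expect_true(all(d <= r))
  # every in-range center of the full grid is occupied: count matches
  full <- expand.grid(lon = grid$west + (seq_len(grid$ncol) - 0.5) * cs,
                      lat = north - (seq_len(grid$nrow) - 0.5) * cs)
  expect_equal(nrow(grid$cells),
               sum((full$lon - tree[1])^2 + (full$lat - tree[2])^2 <= r^2))
  # a center 6 arc-minutes away is excluded
  expect_false(any(abs(d - 6 / 60) < 1e-9))

  # two trees 4' apart share their overlap cells
  G2 <- make_geo_G(rbind(c(-75, 4), c(-75 + 4 / 60, 4)))
  g2 <- build_neighborhood_grid(G2)
  both <- vapply(g2$cells$trees, function(t) length(t) == 2, logical(1))
  expect_true(any(both))
  mid <- which.min((g2$cells$lon + 75 - 2 / 60)^2 + (g2$cells$lat - 4)^2)
  expect_length(g2$cells$trees[[mid]], 2)
})

test_that("membership of a random 20-tree layout equals the brute-force oracle", {
  set.seed(7)
  coords <- cbind(runif(20, -75.2, -75), runif(20, 4, 4.2))
  G <- make_geo_G(coords)
  grid <- build_neighborhood_grid(G)
  oracle <- oracle_membership(G, grid)
  got <- lapply(grid$cells$trees, sort)
  expect_identical(got, oracle)
  expect_true(all(lengths(got) >= 1))
})

test_that("bootstrap correction is the identity at the minimum sample size", {
  G <- simulate_genotypes(seed = 2)$genotypes
  idx <- which(G$pops == "site_01")  # n = 3
  stat <- divscape:::subset_stat_fun("A")
  bc <- bootstrap_corrected_stat(G, idx, stat, n_boot = 50, subsample = 3)
  expect_identical(bc$mean, stat(G, idx))
  expect_identical(bc$sd, 0)
  # constant statistic: mean constant, sd 0 even with resampling
  bc2 <- bootstrap_corrected_stat(G, which(G$pops == "site_03"),
                                  function(G, i) 42, n_boot = 100,
                                  subsample = 3)
  expect_equal(bc2$mean, 42)
  expect_equal(bc2$sd, 0)
  # too few trees -> no-data
  expect_true(is.na(bootstrap_corrected_stat(G, idx[1:2], stat,
                                             subsample = 3)$mean))
})

test_that("rarefaction lowers allelic richness and matches a high-rep oracle", {
  G <- simulate_genotypes(seed = 4)$genotypes
  idx <- which(G$pops == "site_03")  # n = 14, ZAM-like
  stat <- divscape:::subset_stat_fun("A")
  uncorrected <- stat(G, idx)
  bc <- bootstrap_corrected_stat(G, idx, stat, n_boot = 2000, subsample = 3,
                                 seed = 1)
  expect_lt(bc$mean, uncorrected)
  # independent oracle: fresh RNG stream, plain mean over draws
  set.seed(999)
  oracle <- mean(replicate(5000, stat(G, sample(idx, 3))))
  expect_lt(abs(bc$mean - oracle), 0.05)

  # monotone in subsample size (in expectation)
  bc5 <- bootstrap_corrected_stat(G, idx, stat, n_boot = 2000, subsample = 5,
                                  seed = 1)
  bc10 <- bootstrap_corrected_stat(G, idx, stat, n_boot = 2000,
                                   subsample = 10, seed = 1)
  expect_lt(bc$mean, bc5$mean)
  expect_lt(bc5$mean, bc10$mean)
  expect_lt(bc10$mean, uncorrected)
})

test_that("LCA classification applies the occupancy and frequency thresholds exactly", {
  # 12 populations of 25 individuals; allele 9 placed with controlled
  # occupancy/frequency at each locus of interest
  n_pop <- 12; n_per <- 25
  pops <- rep(sprintf("p%02d", 1:n_pop), each = n_per)
  n <- n_pop * n_per
  base <- function() matrix(sample(1:2, n * 3, TRUE), n)
  set.seed(1)
  a1 <- base(); a2 <- base()
  put <- function(m, locus, pop_ids, k) {
    for (p in pop_ids) {
      idx <- which(pops == p)[seq_len(k)]
      m[idx, locus] <- 9L
    }
    m
  }
  # locus 1: allele 9 in 2/12 pops (16.7% < 25%) at freq 3/50 = 0.06 -> LCA
  a1 <- put(a1, 1, c("p01", "p02"), 3)
  # locus 2: allele 9 in 4/12 pops (33.3%) at high freq -> not LCA
  a1 <- put(a1, 2, c("p01", "p02", "p03", "p04"), 10)
  # locus 3: allele 9 in 1 pop at freq 2/50 = 0.04 -> not LCA
  a1 <- put(a1, 3, "p05", 2)
  G <- genotype_matrix(a1, a2, pops = pops)
  cl <- classify_lca(G)
  expect_true("9" %in% cl$per_locus[[1]])
  expect_false("9" %in% cl$per_locus[[2]])
  expect_false("9" %in% cl$per_locus[[3]])

  # lca_per_locus counts classified alleles present in the set / n_loci
  idx <- which(pops == "p01")
  expect_equal(lca_per_locus(G, idx, cl),
               sum(vapply(seq_len(3), function(l)
                 sum(cl$per_locus[[l]] %in%
                       as.character(c(G$a1[idx, l], G$a2[idx, l]))),
                 numeric(1))) / 3)

  # invariant to individual order and allele relabeling
  perm <- sample(n)
  cl2 <- classify_lca(G[perm])
  expect_identical(lapply(cl$per_locus, sort), lapply(cl2$per_locus, sort))
  relabel <- c(`1` = 11L, `2` = 22L, `9` = 99L)
  G3 <- genotype_matrix(matrix(relabel[as.character(a1)], n),
                        matrix(relabel[as.character(a2)], n), pops = pops)
  cl3 <- classify_lca(G3)
  expect_equal(lengths(cl3$per_locus), lengths(cl$per_locus),
               ignore_attr = TRUE)
  expect_true("99" %in% cl3$per_locus[[1]])
})

test_that("mapped statistics are constant over an isolated site and never mix distant sites", {
  cs <- 1 / 120
  coords <- rbind(c(-75, 4) + cs * runif(2), c(-75.01, 4.01), c(-75.005, 3.995),
                  c(-73, 6), c(-73.01, 6.01), c(-73.005, 5.995))
  G <- make_geo_G(coords, pops = rep(c("W", "E"), each = 3), seed = 3)
  dr <- map_statistic(G, "He", n_boot = 30, subsample = 3, seed = 1)
  # no cell mixes the two sites (they are > 10' apart)
  mixed <- vapply(dr$cells$trees, function(t) any(t <= 3) && any(t > 3),
                  logical(1))
  expect_false(any(mixed))
  # cells holding all three western trees carry exactly the site statistic
  west_cells <- vapply(dr$cells$trees, function(t) identical(sort(t), 1:3),
                       logical(1))
  expect_true(any(west_cells))
  expect_equal(unique(dr$cells$value[west_cells]),
               suppressMessages(site_stats(G, "W", min_ind = 1))$He)
})

test_that("per-cell mapped values match direct recomputation on audited cells", {
  sim <- simulate_genotypes(seed = 6)
  G <- sim$genotypes
  grid <- build_neighborhood_grid(G)
  dr <- map_statistic(G, "Ho", grid = grid, n_boot = 100, seed = 11)
  stat <- divscape:::subset_stat_fun("Ho")
  set.seed(20)
  audit <- sample(nrow(dr$cells), 20)
  for (ci in audit) {
    direct <- bootstrap_corrected_stat(G, dr$cells$trees[[ci]], stat,
                                       n_boot = 100, subsample = 3,
                                       seed = 11)
    expect_equal(dr$cells$value[ci], direct$mean)
  }
  # raster value placement matches the cell table
  ij <- cbind(dr$cells$row, dr$cells$col)
  expect_equal(dr$raster$values[ij], dr$cells$value)

  # permutation invariance to tree input order
  perm <- sample(n_ind(G))
  dr2 <- map_statistic(G[perm], "Ho", n_boot = 100, seed = 11)
  o1 <- dr$cells[order(dr$cells$row, dr$cells$col), c("row", "col", "value")]
  o2 <- dr2$cells[order(dr2$cells$row, dr2$cells$col), c("row", "col", "value")]
  expect_equal(o1, o2, ignore_attr = TRUE)
})
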