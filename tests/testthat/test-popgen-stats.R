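test_that("allele frequencies count gene copies and flag unscored loci", {
  a1 <- rbind(c(152, NA), c(152, NA))
  a2 <- rbind(c(152, NA), c(156, NA))
  G <- genotype_matrix(a1, a2, pops = c("A", "A"), loci = c("L1", "L2"))
  fr <- allele_frequencies(G, by = "population")
  expect_equal(unname(fr$A$L1[c("152", "156")]), c(0.75, 0.25))
  expect_null(fr$A$L2)
  # unscored locus is excluded from the multilocus means
  s <- suppressMessages(site_stats(G, "A", min_ind = 1))
  expect_equal(s$He, 1 - 0.75^2 - 0.25^2)
})

test_that("allele frequencies equal a brute-force tally on synthetic data", {
  G <- simulate_genotypes(seed = 3)$genotypes
  fr <- allele_frequencies(G, by = "population")
  for (p in c("site_01", "site_07")) {
    idx <- which(G$pops == p)
    for (l in c(1, 5, 12)) {
      copies <- c(G$a1[idx, l], G$a2[idx, l])
      copies <- copies[!is.na(copies)]
      tally <- table(copies) / length(copies)
      got <- fr[[p]][[l]]
      expect_equal(got[names(tally)], c(tally)[names(tally)],
                   ignore_attr = TRUE)
    }
  }
})

test_that("site statistics match closed forms and signs", {
  # one locus with frequencies 1/2, 1/2 from two homozygotes
  G <- genotype_matrix(matrix(c(5L, 7L)), matrix(c(5L, 7L)), pops = c("A", "A"))
  s <- site_stats(G)
  expect_equal(s$He, 0.5)
  expect_equal(s$I, log(2))
  expect_equal(s$Ho, 0)
  expect_equal(s$A, 2)
  # unbiased correction multiplies He by 2n/(2n-1)
  expect_equal(site_stats(G, unbiased = TRUE)$He, 0.5 * 4 / 3)

  # every genotype heterozygous a/b: Ho = 1, Fis = 1 - 1/He < 0
  G2 <- genotype_matrix(matrix(rep(5L, 4)), matrix(rep(7L, 4)),
                        pops = rep("A", 4))
  s2 <- site_stats(G2)
  expect_equal(s2$Ho, 1)
  expect_lt(s2$Fis, 0)
  expect_equal(s2$Fis, 1 - 1 / s2$He)
})

test_that("site statistics reproduce an independent hand-tally oracle exactly", {
  G <- make_tiny_G()
  for (p in list("A", NULL)) {
    p <- if (is.null(p)) NULL else p[[1]]
    s <- suppressMessages(site_stats(G, p, min_ind = 1))
    o <- oracle_site_stats(G, p)
    expect_equal(s$A, o$A)
    expect_equal(s$I, o$I)
    expect_equal(s$He, o$He)
    expect_equal(s$Ho, o$Ho)
    expect_equal(s$Fis, o$Fis)
  }
  # random small fixtures
  for (rep in 1:5) {
    set.seed(rep)
    n <- sample(3:5, 1)
    a1 <- matrix(sample(1:4, n * 3, TRUE), n)
    a2 <- matrix(sample(1:4, n * 3, TRUE), n)
    Gr <- genotype_matrix(a1, a2, pops = rep("P", n))
    s <- suppressMessages(site_stats(Gr, min_ind = 1))
    o <- oracle_site_stats(Gr)
    expect_equal(c(s$A, s$I, s$He, s$Ho), c(o$A, o$I, o$He, o$Ho))
  }
})

test_that("Fis permutation test follows the continuity rule and detects inbreeding", {
  G <- make_tiny_G()
  expect_warning(r0 <- fis_permutation_test(G, "A", n_perm = 0), "coarse")
  expect_equal(r0$p_value, 1)

  # power: strong inbreeding at n = 50 is detected in most replicates
  hits <- 0; reps <- 10
  for (r in seq_len(reps)) {
    cfg <- genotype_sim_config(n_pops = 1, n_per_pop = 50, K = 1, Fis = 0.4,
                               admixture_alpha = 0, missing_rate = 0)
    sim <- simulate_genotypes(cfg, seed = 100 + r)
    p <- fis_permutation_test(sim$genotypes, n_perm = 199, seed = r)$p_value
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits / reps, 0.8)

  # approximate size: no inbreeding rejects rarely
  rej <- 0; reps <- 20
  for (r in seq_len(reps)) {
    cfg <- genotype_sim_config(n_pops = 1, n_per_pop = 40, K = 1, Fis = 0,
                               admixture_alpha = 0, missing_rate = 0)
    sim <- simulate_genotypes(cfg, seed = 500 + r)
    p <- fis_permutation_test(sim$genotypes, n_perm = 99, seed = r)$p_value
    rej <- rej + (p < 0.05)
  }
  expect_lte(rej / reps, 0.25)
})

test_that("pairwise Nei F_ST hits the algebraic endpoints", {
  # identical allele frequencies in both populations -> 0
  a1 <- matrix(c(1L, 2L, 1L, 2L), 4)
  a2 <- matrix(c(1L, 2L, 1L, 2L), 4)
  G <- genotype_matrix(a1, a2, pops = c("A", "A", "B", "B"))
  expect_equal(pairwise_fst(G)$fst["A", "B"], 0)

  # populations fixed for different alleles -> 1
  G2 <- genotype_matrix(matrix(c(1L, 1L, 2L, 2L)), matrix(c(1L, 1L, 2L, 2L)),
                        pops = c("A", "A", "B", "B"))
  expect_equal(pairwise_fst(G2)$fst["A", "B"], 1)
})

test_that("F_ST agrees with an independent oracle and is monotone in the generator F", {
  # independent oracle: mean-of-two Hs vs pooled Ht per locus, ratio of sums
  oracle_pair_fst <- function(G, p1, p2) {
    num <- den <- 0
    for (l in seq_len(n_loc(G))) {
      fl <- lapply(c(p1, p2), function(p) {
        idx <- which(G$pops == p)
        a <- c(G$a1[idx, l], G$a2[idx, l]); a <- a[!is.na(a)]
        table(factor(a, levels = sort(unique(c(G$a1[, l], G$a2[, l]))))) /
          length(a)
      })
      hs <- mean(sapply(fl, function(f) 1 - sum(f^2)))
      pbar <- (fl[[1]] + fl[[2]]) / 2
      ht <- 1 - sum(pbar^2)
      num <- num + ht - hs; den <- den + ht
    }
    num / den
  }
  cfg <- genotype_sim_config(n_pops = 10, n_per_pop = 30, K = 10, F = 0.15,
                             admixture_alpha = 0, missing_rate = 0)
  sim <- simulate_genotypes(cfg, seed = 9)
  fst <- pairwise_fst(sim$genotypes)
  pops <- levels(sim$genotypes$pops)
  oracle_vals <- got <- c()
  for (i in 1:4) for (j in (i + 1):5) {
    oracle_vals <- c(oracle_vals,
                     oracle_pair_fst(sim$genotypes, pops[i], pops[j]))
    got <- c(got, fst$fst[pops[i], pops[j]])
  }
  expect_lt(max(abs(got - oracle_vals)), 0.03)
  expect_equal(got, oracle_vals, tolerance = 1e-10)

  # monotonicity in F, paired over common seeds; and the multi-population
  # global estimate recovers F (pairwise G_ST is structurally ~F/2)
  mean_fst <- function(F, seed) {
    cfg <- genotype_sim_config(n_pops = 10, n_per_pop = 30, K = 10, F = F,
                               admixture_alpha = 0, missing_rate = 0)
    f <- pairwise_fst(simulate_genotypes(cfg, seed = seed)$genotypes)
    c(pair = mean(f$fst[upper.tri(f$fst)]), global = f$global)
  }
  for (seed in 1:3) {
    v <- sapply(c(0.02, 0.1, 0.25), mean_fst, seed = seed)
    expect_true(all(diff(v["pair", ]) > 0))
    expect_true(all(diff(v["global", ]) > 0))
  }
  glob <- mean(sapply(1:5, function(s) mean_fst(0.15, s)["global"]))
  expect_lt(abs(glob - 0.15), 0.05)
})
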