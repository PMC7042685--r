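#' Dirichlet random deviates
#'
#' @param n number of draws.
#' @param alpha concentration vector.
#' @return an `n x length(alpha)` matrix with rows summing to 1.
#' @export
rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n,
              length(alpha), byrow = TRUE)
  sw <- rowSums(x)
  sw[sw == 0] <- 1
  x / sw
}

#' Configuration for the genotype generator
#'
#' Defaults emulate the study design the package targets: 100 diploid trees
#' in 12 sites of 3-14 individuals, 12 SSR loci with 13-28 alleles each,
#' four ancestral clusters with Balding-Nichols differentiation `F`,
#' moderate admixture, no inbreeding, and sites scattered over roughly
#' 8 x 8 degrees so neighborhood circles of distant sites never merge.
#'
#' @param n_pops number of sampling sites.
#' @param n_per_pop per-site sample sizes (recycled if scalar).
#' @param n_loci number of loci.
#' @param allele_range range of allele counts per locus (drawn uniformly).
#' @param K number of ancestral clusters; sites are assigned clusters
#'   round-robin.
#' @param F Balding-Nichols differentiation of cluster allele frequencies.
#' @param Fis within-population inbreeding coefficient (-1, 1).
#' @param admixture_alpha symmetric Dirichlet concentration of individual
#'   ancestry around the site's cluster; 0 gives pure (unadmixed)
#'   individuals.
#' @param purity extra Dirichlet weight on the site's own cluster (ignored
#'   when `admixture_alpha = 0`).
#' @param missing_rate fraction of genotypes masked missing.
#' @param site_coords optional `n_pops x 2` matrix (lon, lat); defaults to a
#'   deterministic scatter spanning ~8 x 8 degrees.
#' @param pop_labels site labels.
#' @return a list of class `genotype_sim_config`.
#' @export
genotype_sim_config <- function(n_pops = 12,
                                n_per_pop = c(3, 7, 14, 10, 7, 12, 12, 10,
                                              3, 5, 6, 11),
                                n_loci = 12, allele_range = c(13, 28),
                                K = 4, F = 0.15, Fis = 0,
                                admixture_alpha = 0.3, purity = 2,
                                missing_rate = 0.02, site_coords = NULL,
                                pop_labels = NULL) {
  stopifnot(F > 0, F < 1, Fis > -1, Fis < 1, allele_range[1] >= 2)
  n_per_pop <- rep_len(n_per_pop, n_pops)
  if (is.null(pop_labels))
    pop_labels <- sprintf("site_%02d", seq_len(n_pops))
  if (is.null(site_coords)) site_coords <- default_site_coords(n_pops)
  structure(list(n_pops = n_pops, n_per_pop = n_per_pop, n_loci = n_loci,
                 allele_range = allele_range, K = K, F = F, Fis = Fis,
                 admixture_alpha = admixture_alpha, purity = purity,
                 missing_rate = missing_rate, site_coords = site_coords,
                 pop_labels = pop_labels),
            class = "genotype_sim_config")
}

# deterministic site scatter over ~8 x 8 degrees (northwestern South
# America extent), well separated relative to 10' neighborhoods
default_site_coords <- function(n_pops) {
  g <- ceiling(sqrt(n_pops))
  i <- seq_len(n_pops) - 1
  lon <- -77 + (i %% g) * (8 / g) + 0.13 * sin(i)
  lat <- 2 + (i %/% g) * (8 / g) + 0.13 * cos(2 * i)
  cbind(lon = lon, lat = lat)
}

#' Simulate diploid SSR genotypes under the Balding-Nichols model
#'
#' Per locus, ancestral frequencies are symmetric-Dirichlet draws; each
#' cluster's frequencies are `Dirichlet(p (1-F)/F)` around them (mean `p`,
#' variance `F p (1-p)`). Individual ancestry is Dirichlet around the
#' site's cluster; allele copies are drawn from the individual's mixture
#' frequencies, with the second copy conditioned on the first to inject
#' the target inbreeding (`P(hom a) = p^2 + Fis p (1-p)` in the unadmixed
#' case; infeasible negative values are clipped with a warning). Genotypes
#' are masked missing at `missing_rate`.
#'
#' @param cfg a [genotype_sim_config()].
#' @param seed RNG seed; the generator is reproducible given the seed.
#' @return list with `genotypes` (a [genotype_matrix()] with coordinates)
#'   and `truth` (ancestry `Q`, cluster frequencies `P`, ancestral
#'   frequencies, site-cluster map, and the config).
#' @export
simulate_genotypes <- function(cfg = genotype_sim_config(), seed = 1L) {
  set.seed(seed)
  n <- sum(cfg$n_per_pop)
  L <- cfg$n_loci
  K <- cfg$K
  pop <- rep(cfg$pop_labels, cfg$n_per_pop)
  pop_cluster <- rep_len(seq_len(K), cfg$n_pops)
  names(pop_cluster) <- cfg$pop_labels

  n_alleles <- sample(seq(cfg$allele_range[1], cfg$allele_range[2]), L,
                      replace = TRUE)
  ancestral <- lapply(n_alleles, function(A) rdirichlet(1, rep(1, A))[1, ])
  P <- lapply(seq_len(L), function(l) {
    conc <- ancestral[[l]] * (1 - cfg$F) / cfg$F
    rdirichlet(K, conc)                      # K x alleles
  })

  Q <- matrix(0, n, K)
  ki <- pop_cluster[match(pop, cfg$pop_labels)]
  if (cfg$admixture_alpha <= 0) {
    Q[cbind(seq_len(n), ki)] <- 1
  } else {
    for (i in seq_len(n)) {
      conc <- rep(cfg$admixture_alpha, K)
      conc[ki[i]] <- conc[ki[i]] + cfg$purity
      Q[i, ] <- rdirichlet(1, conc)[1, ]
    }
  }

  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  clipped <- FALSE
  for (l in seq_len(L)) {
    A <- n_alleles[l]
    pmix <- Q %*% P[[l]]                     # n x alleles
    for (i in seq_len(n)) {
      p <- pmix[i, ]
      x <- sample.int(A, 1, prob = p)
      cond <- (1 - cfg$Fis) * p
      cond[x] <- cond[x] + cfg$Fis
      if (cond[x] < 0) { cond[x] <- 0; clipped <- TRUE }
      y <- sample.int(A, 1, prob = cond)
      a1[i, l] <- x; a2[i, l] <- y
    }
  }
  if (clipped)
    warning("negative Fis infeasible for some alleles: conditional clipped at 0")
  if (cfg$missing_rate > 0) {
    mask <- matrix(stats::runif(n * L) < cfg$missing_rate, n, L)
    a1[mask] <- NA_integer_; a2[mask] <- NA_integer_
  }
  coords <- cfg$site_coords[match(pop, cfg$pop_labels), , drop = FALSE] +
    matrix(stats::rnorm(2 * n, 0, 0.01), n, 2)
  colnames(coords) <- c("lon", "lat")
  ids <- paste0(pop, "_", stats::ave(seq_len(n), pop, FUN = seq_along))
  G <- genotype_matrix(a1, a2, ids = ids, pops = pop,
                       loci = sprintf("ssr%02d", seq_len(L)),
                       coords = coords)
  list(genotypes = G,
       truth = list(Q = Q, P = P, ancestral = ancestral,
                    pop_cluster = pop_cluster, n_alleles = n_alleles,
                    config = cfg, seed = seed))
}
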