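# squared inter-individual genetic distance matrix: number of allele
# differences per locus (0/1/2, via shared multiset counts), summed over
# loci; pairs missing at some loci are rescaled by L / L_observed.
genetic_distance_sq <- function(G) {
  n <- n_ind(G); L <- n_loc(G)
  d <- matrix(0, n, n)
  obs <- matrix(0L, n, n)
  for (l in seq_len(L)) {
    a1 <- G$a1[, l]; a2 <- G$a2[, l]
    ok <- !is.na(a1)
    idx <- which(ok)
    if (length(idx) < 2) next
    # shared alleles between 2-allele multisets:
    # sum over alleles of min(count in i, count in j)
    x1 <- a1[idx]; x2 <- a2[idx]
    m <- length(idx)
    shared <- matrix(0, m, m)
    for (i in seq_len(m)) {
      if (x1[i] == x2[i]) {           # i homozygous a/a
        shared[i, ] <- (x1 == x1[i]) + (x2 == x1[i])
      } else {                        # i heterozygous a/b
        shared[i, ] <- pmin((x1 == x1[i]) + (x2 == x1[i]), 1L) +
                       pmin((x1 == x2[i]) + (x2 == x2[i]), 1L)
      }
    }
    dl <- 2 - shared
    d[idx, idx] <- d[idx, idx] + dl
    obs[idx, idx] <- obs[idx, idx] + 1L
  }
  scale <- ifelse(obs > 0, L / obs, NA)
  d <- d * scale
  diag(d) <- 0
  d
}

amova_components <- function(d2, pop) {
  n <- length(pop)
  pops <- unique(pop)
  P <- length(pops)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  sizes <- numeric(P)
  for (k in seq_len(P)) {
    idx <- which(pop == pops[k])
    sizes[k] <- length(idx)
    dk <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(dk[upper.tri(dk)]) / length(idx)
  }
  ss_among <- ss_total - ss_within
  df_among <- P - 1
  df_within <- n - P
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n0 <- (n - sum(sizes^2) / n) / (P - 1)
  sigma_within <- ms_within
  sigma_among <- (ms_among - ms_within) / n0
  tot <- sigma_among + sigma_within
  list(ss = c(among = ss_among, within = ss_within, total = ss_total),
       df = c(among = df_among, within = df_within),
       ms = c(among = ms_among, within = ms_within),
       sigma = c(among = sigma_among, within = sigma_within),
       phi_st = if (tot > 0) sigma_among / tot else NA_real_)
}

#' Two-level analysis of molecular variance (AMOVA)
#'
#' Partitions the variance of squared inter-individual genetic distances
#' (allele-difference counts summed over loci, 0/1/2 per locus, pairwise
#' deletion of missing loci with rescaling) into among- and
#' within-population components following the classical codominant
#' treatment: sums of squares from the distance matrix, mean squares,
#' variance components via the average population size coefficient `n0`,
#' and `Phi_ST = sigma2_among / (sigma2_among + sigma2_within)`. The
#' p-value permutes individuals among populations.
#'
#' @param G a [genotype_matrix()] with >= 2 populations of >= 2 individuals.
#' @param n_perm number of label permutations.
#' @param seed RNG seed for the permutations.
#' @return an object of class `amova_result`: variance components,
#'   percentages of total (summing to 100), `phi_st`, and `p_value`.
#' @export
amova <- function(G, n_perm = 999, seed = 1L) {
  pop <- as.character(G$pops)
  if (any(table(pop) < 2)) stop("amova needs >= 2 individuals per population")
  if (length(unique(pop)) < 2) {
    # degenerate one-level design: all variation is within the single group
    return(structure(list(sigma = c(among = 0, within = NA_real_),
                          pct = c(among = 0, within = 100),
                          phi_st = 0, p_value = NA_real_, n_perm = n_perm),
                     class = "amova_result"))
  }
  d2 <- genetic_distance_sq(G)
  if (all(d2 == 0, na.rm = TRUE)) {
    warning("all individuals identical: variance components are 0, Phi undefined")
    return(structure(list(sigma = c(among = 0, within = 0),
                          pct = c(among = NA_real_, within = NA_real_),
                          phi_st = NA_real_, p_value = NA_real_,
                          ss = NULL, df = NULL, n_perm = n_perm),
                     class = "amova_result"))
  }
  obs <- amova_components(d2, pop)
  sig <- pmax(obs$sigma, 0)
  pct <- 100 * obs$sigma / sum(obs$sigma)
  perm_phi <- numeric(n_perm)
  if (n_perm > 0) {
    set.seed(seed)
    for (b in seq_len(n_perm)) {
      perm_phi[b] <- amova_components(d2, sample(pop))$phi_st
    }
  }
  p <- (1 + sum(perm_phi >= obs$phi_st)) / (n_perm + 1)
  structure(list(sigma = obs$sigma, pct = pct, phi_st = obs$phi_st,
                 p_value = p, ss = obs$ss, df = obs$df, ms = obs$ms,
                 n_perm = n_perm),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (two-level)\n")
  cat(sprintf("  among populations:  sigma2 = %.4f (%5.1f%%)\n",
              x$sigma["among"], x$pct["among"]))
  cat(sprintf("  within populations: sigma2 = %.4f (%5.1f%%)\n",
              x$sigma["within"], x$pct["within"]))
  cat(sprintf("  Phi_ST = %.4f, permutation p = %.4g (%d permutations)\n",
              x$phi_st, x$p_value, x$n_perm))
  invisible(x)
}
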