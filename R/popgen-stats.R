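#' Per-locus allele frequency tables
#'
#' Frequencies are computed from gene copies: each non-missing genotype
#' contributes two copies. Loci with no scored genotype in a group are
#' flagged absent for that group (`NULL` entry) and are excluded from that
#' group's multilocus means downstream.
#'
#' @param G a [genotype_matrix()].
#' @param by `"population"` for one table per population, `"all"` for the
#'   pooled sample.
#' @return a nested list `group -> locus -> named numeric vector` of
#'   frequencies summing to 1; the gene-copy counts are kept in the
#'   `"counts"` attribute of each vector.
#' @export
allele_frequencies <- function(G, by = c("population", "all")) {
  by <- match.arg(by)
  groups <- if (by == "all") list(all = seq_len(n_ind(G)))
            else split(seq_len(n_ind(G)), G$pops)
  lapply(groups, function(idx) {
    if (!length(idx)) stop("empty group in allele_frequencies")
    out <- vector("list", n_loc(G)); names(out) <- G$loci
    for (l in seq_len(n_loc(G))) {
      a <- c(G$a1[idx, l], G$a2[idx, l])
      a <- a[!is.na(a)]
      if (!length(a)) next  # locus absent for this group
      tab <- table(a)
      f <- as.numeric(tab) / sum(tab)
      names(f) <- names(tab)
      attr(f, "counts") <- as.numeric(tab)
      out[[l]] <- f
    }
    out
  })
}

# per-locus diversity components for a set of individuals (allele matrices)
# returns a data.frame with one row per locus; loci with < min_ind scored
# individuals are NA (dropped from multilocus means)
locus_components <- function(a1, a2, unbiased = FALSE, min_ind = 1L) {
  L <- ncol(a1)
  out <- data.frame(A = rep(NA_real_, L), I = NA_real_, He = NA_real_,
                    Ho = NA_real_, n_scored = 0L)
  for (l in seq_len(L)) {
    ok <- !is.na(a1[, l])
    n <- sum(ok)
    out$n_scored[l] <- n
    if (n < min_ind) next
    al <- c(a1[ok, l], a2[ok, l])
    tab <- tabulate(factor(al))
    p <- tab / sum(tab)
    out$A[l] <- sum(p > 0)
    out$I[l] <- -sum(p * log(p))
    he <- 1 - sum(p^2)
    if (unbiased) he <- he * (2 * n) / (2 * n - 1)
    out$He[l] <- he
    out$Ho[l] <- mean(a1[ok, l] != a2[ok, l])
  }
  out
}

#' Multilocus diversity and inbreeding statistics for one sample set
#'
#' Per locus: allelic richness `A` (distinct alleles), Shannon index
#' `I = -sum p log p`, expected heterozygosity `He = 1 - sum p^2` (with the
#' small-sample factor `2n/(2n-1)` when `unbiased = TRUE`) and observed
#' heterozygosity `Ho` (fraction of scored genotypes that are heterozygous).
#' Multilocus values are unweighted means over scored loci, `sd` the standard
#' deviation over loci, and the multilocus inbreeding coefficient is the
#' ratio of means, `Fis = 1 - mean(Ho) / mean(He)`.
#'
#' @param G a [genotype_matrix()].
#' @param population population label to subset to, or `NULL` to use all
#'   individuals in `G`.
#' @param unbiased apply the small-sample correction to `He`?
#' @param min_ind loci scored in fewer individuals than this are dropped
#'   from the multilocus means (with a message).
#' @return an object of class `site_stats`: list with `n`, the multilocus
#'   `A`, `I`, `He`, `Ho`, `Fis`, per-parameter `sd`, and the per-locus
#'   table in `$by_locus`.
#' @export
site_stats <- function(G, population = NULL, unbiased = FALSE, min_ind = 2L) {
  if (!is.null(population)) G <- pop_subset(G, population)
  if (n_ind(G) < 2) stop("site_stats needs at least 2 individuals")
  comp <- locus_components(G$a1, G$a2, unbiased = unbiased, min_ind = min_ind)
  dropped <- comp$n_scored < min_ind
  if (any(dropped))
    message(sum(dropped), " locus/loci with < ", min_ind,
            " scored individuals dropped from multilocus means")
  use <- !dropped & !is.na(comp$He)
  mn <- function(x) mean(x[use])
  sdv <- function(x) stats::sd(x[use])
  He <- mn(comp$He); Ho <- mn(comp$Ho)
  fis <- if (is.finite(He) && He > 0) 1 - Ho / He else NA_real_
  monomorphic <- all(comp$A[use] <= 1)
  structure(list(n = n_ind(G), population = population,
                 A = mn(comp$A), I = mn(comp$I), He = He, Ho = Ho,
                 Fis = if (monomorphic) NA_real_ else fis,
                 sd = c(A = sdv(comp$A), I = sdv(comp$I), He = sdv(comp$He),
                        Ho = sdv(comp$Ho)),
                 monomorphic = monomorphic,
                 unbiased = unbiased, by_locus = comp),
            class = "site_stats")
}

#' @export
print.site_stats <- function(x, ...) {
  cat(sprintf("site_stats (%s, n=%d): A=%.2f I=%.2f He=%.2f Ho=%.2f Fis=%s\n",
              if (is.null(x$population)) "all" else x$population, x$n,
              x$A, x$I, x$He, x$Ho,
              if (is.na(x$Fis)) "undefined (monomorphic)" else sprintf("%.3f", x$Fis)))
  invisible(x)
}

#' Permutation test for the inbreeding coefficient
#'
#' The null distribution is built by shuffling allele copies among the
#' individuals of the population independently at each locus, which destroys
#' any heterozygote deficit or excess while preserving allele frequencies.
#' Two-sided p-value with the `(x+1)/(n+1)` continuity rule.
#'
#' @param G a [genotype_matrix()].
#' @param population population label (`NULL` = all of `G`).
#' @param n_perm number of permutations (a warning is logged below 99).
#' @param seed RNG seed.
#' @return list with `fis`, `p_value` and the permutation values.
#' @export
fis_permutation_test <- function(G, population = NULL, n_perm = 999,
                                 seed = 1L) {
  if (!is.null(population)) G <- pop_subset(G, population)
  if (n_perm < 99) warning("n_perm < 99: permutation p-value will be coarse")
  obs <- site_stats(G)$Fis
  if (is.na(obs)) stop("Fis undefined (monomorphic population)")
  a1 <- G$a1; a2 <- G$a2
  L <- ncol(a1)
  perm_fis <- numeric(n_perm)
  if (n_perm > 0) {
    set.seed(seed)
    for (b in seq_len(n_perm)) {
      p1 <- a1; p2 <- a2
      for (l in seq_len(L)) {
        ok <- which(!is.na(a1[, l]))
        if (length(ok) < 2) next
        copies <- sample(c(a1[ok, l], a2[ok, l]))
        p1[ok, l] <- copies[seq_along(ok)]
        p2[ok, l] <- copies[length(ok) + seq_along(ok)]
      }
      comp <- locus_components(p1, p2)
      use <- !is.na(comp$He)
      perm_fis[b] <- 1 - mean(comp$Ho[use]) / mean(comp$He[use])
    }
  }
  p <- (1 + sum(abs(perm_fis) >= abs(obs))) / (n_perm + 1)
  list(fis = obs, p_value = p, n_perm = n_perm, perm = perm_fis)
}

# Nei F_ST for a set of per-locus frequency lists: ratio of sums over loci of
# (Ht - Hs) and Ht, with Hs the mean within-group He and Ht the He of the
# mean (pooled) frequencies.
nei_fst_from_freqs <- function(freq_groups) {
  loci <- names(freq_groups[[1]])
  num <- 0; den <- 0; n_used <- 0L
  for (l in loci) {
    fl <- lapply(freq_groups, `[[`, l)
    if (any(vapply(fl, is.null, logical(1)))) next
    alleles <- unique(unlist(lapply(fl, names)))
    pm <- matrix(0, length(fl), length(alleles),
                 dimnames = list(NULL, alleles))
    for (g in seq_along(fl)) pm[g, names(fl[[g]])] <- fl[[g]]
    hs <- mean(1 - rowSums(pm^2))
    pbar <- colMeans(pm)
    ht <- 1 - sum(pbar^2)
    num <- num + (ht - hs); den <- den + ht
    n_used <- n_used + 1L
  }
  if (n_used == 0L || den <= 0) return(NA_real_)
  num / den
}

#' Pairwise and global Nei F_ST
#'
#' For each population pair, `F_ST = (H_T - H_S) / H_T` with `H_S` the mean
#' of the two within-population expected heterozygosities and `H_T` the
#' expected heterozygosity of the pooled (mean) frequencies, computed per
#' locus and combined as a ratio of sums over loci. Raw (possibly small
#' negative) values are retained; truncation to `[0, 1]` is applied only in
#' the `display` matrix. The global value uses all populations at once.
#'
#' @param G a [genotype_matrix()] with at least two populations.
#' @return an object of class `fst_matrix`: list with the raw symmetric
#'   matrix `fst`, the truncated `display` matrix, per-population mean
#'   pairwise values `pop_mean`, and `global`.
#' @export
pairwise_fst <- function(G) {
  pops <- levels(G$pops)
  if (length(pops) < 2) stop("pairwise_fst needs at least 2 populations")
  freqs <- allele_frequencies(G, by = "population")
  P <- length(pops)
  m <- matrix(0, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P - 1)) for (j in (i + 1):P) {
    v <- nei_fst_from_freqs(freqs[c(i, j)])
    m[i, j] <- m[j, i] <- v
  }
  if (anyNA(m)) warning("population pair(s) with no shared scored locus: entries NA")
  pop_mean <- vapply(seq_len(P),
                     function(i) mean(m[i, -i], na.rm = TRUE), numeric(1))
  names(pop_mean) <- pops
  disp <- pmin(pmax(m, 0), 1)
  structure(list(fst = m, display = disp, pop_mean = pop_mean,
                 global = nei_fst_from_freqs(freqs)),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("Nei pairwise F_ST (display scale, truncated to [0,1]):\n")
  print(round(x$display, 3))
  cat("\nPer-population mean:", paste(sprintf("%s=%.3f", names(x$pop_mean),
                                              x$pop_mean), collapse = " "),
      sprintf("\nGlobal F_ST: %.3f\n", x$global))
  invisible(x)
}
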