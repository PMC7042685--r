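# encode genotypes as per-locus allele-index matrices for the EM
encode_alleles <- function(G) {
  L <- n_loc(G)
  enc <- vector("list", L)
  for (l in seq_len(L)) {
    codes <- sort(unique(c(G$a1[, l], G$a2[, l])))
    codes <- codes[!is.na(codes)]
    enc[[l]] <- list(codes = codes,
                     i1 = match(G$a1[, l], codes),
                     i2 = match(G$a2[, l], codes))
  }
  enc
}

#' Fit the admixture ancestry model by EM
#'
#' Maximizes the admixture likelihood
#' `L = sum_i sum_l sum_copies log sum_k Q[i,k] P[k,l,a]` in which every
#' individual is a mixture over `K` clusters (ancestry proportions `Q`) and
#' every cluster has its own per-locus allele frequencies `P`. The EM
#' alternates responsibilities per allele copy with closed-form updates of
#' `Q` (mean responsibility over the individual's copies) and `P`
#' (responsibility-weighted allele tallies with Laplace smoothing `alpha` to
#' avoid zero-frequency lock-in). Missing genotypes contribute nothing. The
#' log-likelihood is non-decreasing across iterations up to the smoothing
#' perturbation.
#'
#' @param G a [genotype_matrix()].
#' @param K number of clusters (>= 1).
#' @param seed RNG seed for the random initialization.
#' @param max_iter iteration cap.
#' @param tol absolute log-likelihood convergence tolerance.
#' @param alpha Laplace smoothing pseudo-count on the `P` update.
#' @return an object of class `admixture_fit`: `K`, `Q` (individuals x K,
#'   rows sum to 1), `P` (per locus a K x alleles matrix, rows sum to 1),
#'   `loglik`, the iteration trace, and the seed.
#' @export
fit_admixture <- function(G, K, seed = 1L, max_iter = 500, tol = 1e-6,
                          alpha = 0.01) {
  if (K < 1) stop("K must be >= 1")
  n <- n_ind(G); L <- n_loc(G)
  enc <- encode_alleles(G)
  n_alleles <- vapply(enc, function(e) length(e$codes), integer(1))
  if (K > sum(n_alleles))
    warning("K exceeds the total distinct-allele budget; clusters may empty")
  n_obs <- rowSums(!is.na(G$a1))  # loci scored per individual

  set.seed(seed)
  Q <- matrix(rgamma(n * K, 1), n, K)
  Q <- Q / rowSums(Q)
  P <- vector("list", L)
  for (l in seq_len(L)) {
    base <- tabulate(c(enc[[l]]$i1, enc[[l]]$i2), n_alleles[l])
    base <- base / sum(base)
    pl <- matrix(rep(base, each = K), K, n_alleles[l]) *
      matrix(rgamma(K * n_alleles[l], 20), K, n_alleles[l])
    P[[l]] <- pl / rowSums(pl)
  }

  loglik <- -Inf; trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    Qacc <- matrix(0, n, K)
    tallies <- lapply(seq_len(L), function(l) matrix(0, n_alleles[l], K))
    ll <- 0
    for (l in seq_len(L)) {
      tP <- t(P[[l]])                     # alleles x K
      for (copy in 1:2) {
        a <- if (copy == 1) enc[[l]]$i1 else enc[[l]]$i2
        ok <- which(!is.na(a))
        if (!length(ok)) next
        R <- Q[ok, , drop = FALSE] * tP[a[ok], , drop = FALSE]
        rs <- rowSums(R)
        rs[rs < 1e-300] <- 1e-300
        ll <- ll + sum(log(rs))
        R <- R / rs
        Qacc[ok, ] <- Qacc[ok, ] + R
        tl <- rowsum(R, a[ok])
        tmp <- matrix(0, n_alleles[l], K)
        tmp[as.integer(rownames(tl)), ] <- tl
        tallies[[l]] <- tallies[[l]] + tmp
      }
    }
    # M-step
    Q <- Qacc / (2 * pmax(n_obs, 1))
    Q[n_obs == 0, ] <- 1 / K
    Q <- Q / rowSums(Q)
    for (l in seq_len(L)) {
      pl <- t(tallies[[l]]) + alpha       # K x alleles
      P[[l]] <- pl / rowSums(pl)
    }
    trace <- c(trace, ll)
    if (is.finite(loglik) && abs(ll - loglik) < tol) { loglik <- ll; break }
    loglik <- ll
  }
  names(P) <- G$loci
  colnames(Q) <- paste0("cluster_", seq_len(K))
  rownames(Q) <- G$ids
  structure(list(K = K, Q = Q, P = P, loglik = loglik, trace = trace,
                 n_iter = length(trace), seed = seed, alpha = alpha),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("admixture_fit: K=%d, loglik=%.2f after %d EM iterations (seed %d)\n",
              x$K, x$loglik, x$n_iter, x$seed))
  invisible(x)
}

#' Run the admixture model over a range of K with restarts
#'
#' Mirrors the usual study design (K = 1..Kmax, several independent
#' repetitions per K). Each restart gets a deterministic seed derived from
#' `seed`; the best-log-likelihood fit represents each K and the full
#' K x replicate log-likelihood table feeds [evanno_delta_k()].
#'
#' @param G a [genotype_matrix()].
#' @param K_values integer vector of K values.
#' @param restarts independent repetitions per K.
#' @param seed base RNG seed.
#' @param ... passed to [fit_admixture()].
#' @return list with `best` (named list of best fits per K), `logliks`
#'   (data.frame `K`, `rep`, `loglik`), and `fits` (all fits).
#' @export
run_admixture <- function(G, K_values = 1:8, restarts = 10, seed = 1L, ...) {
  fits <- list(); tab <- NULL
  best <- list()
  for (K in K_values) {
    kfits <- lapply(seq_len(restarts), function(r)
      fit_admixture(G, K, seed = seed + 1009L * K + r, ...))
    ll <- vapply(kfits, `[[`, numeric(1), "loglik")
    tab <- rbind(tab, data.frame(K = K, rep = seq_len(restarts), loglik = ll))
    best[[as.character(K)]] <- kfits[[which.max(ll)]]
    fits <- c(fits, kfits)
  }
  list(best = best, logliks = tab, fits = fits)
}

#' Evanno delta-K table from per-replicate log-likelihoods
#'
#' Computes, per K, the replicate mean and sd of the model log-likelihood,
#' the first difference `L'(K) = L(K) - L(K-1)`, the absolute second
#' difference `|L''(K)| = |L'(K+1) - L'(K)|`, and
#' `deltaK = |L''(K)| / sd(L(K))`. `deltaK` is defined only for interior K;
#' where the replicate sd is zero it is flagged `NA` (division by zero). The
#' supported K is the arg-max of `deltaK`, ties resolved toward the smallest
#' K (parsimony).
#'
#' @param logliks data.frame with columns `K` and `loglik` (one row per
#'   replicate), e.g. the `logliks` element of [run_admixture()] or the
#'   result of [read_structure_logliks()].
#' @return an object of class `delta_k_table`: the per-K table and `best_k`.
#' @export
evanno_delta_k <- function(logliks) {
  if (!all(c("K", "loglik") %in% names(logliks)))
    stop("logliks must have columns K and loglik")
  agg <- do.call(rbind, lapply(split(logliks$loglik, logliks$K), function(x)
    data.frame(mean = mean(x), sd = stats::sd(x), n_rep = length(x))))
  agg$K <- as.integer(rownames(agg))
  agg <- agg[order(agg$K), c("K", "mean", "sd", "n_rep")]
  if (nrow(agg) < 3) stop("need >= 3 consecutive K values")
  if (any(diff(agg$K) != 1)) stop("K values must be consecutive")
  if (any(agg$n_rep < 2))
    warning("fewer than 2 replicates at some K: sd is undefined there")
  kk <- nrow(agg)
  agg$Lp <- c(NA, diff(agg$mean))
  agg$Lpp_abs <- c(NA, abs(diff(agg$Lp[-1])), NA)
  agg$delta_k <- rep(NA_real_, kk)
  interior <- 2:(kk - 1)
  sd_int <- agg$sd[interior]
  zero_sd <- !is.na(sd_int) & sd_int == 0
  if (any(zero_sd))
    warning("sd = 0 at interior K = ",
            paste(agg$K[interior][zero_sd], collapse = ", "),
            ": deltaK undefined there")
  dk <- agg$Lpp_abs[interior] / sd_int
  dk[zero_sd] <- NA_real_
  agg$delta_k[interior] <- dk
  best <- if (all(is.na(agg$delta_k))) NA_integer_ else
    agg$K[which.max(replace(agg$delta_k, is.na(agg$delta_k), -Inf))]
  rownames(agg) <- NULL
  structure(list(table = agg, best_k = best), class = "delta_k_table")
}

#' @export
print.delta_k_table <- function(x, ...) {
  print(transform(x$table, mean = round(mean, 2), sd = round(sd, 4),
                  Lp = round(Lp, 2), Lpp_abs = round(Lpp_abs, 2),
                  delta_k = round(delta_k, 2)))
  cat("best K (max deltaK, ties to smallest):", x$best_k, "\n")
  invisible(x)
}

#' Read log-likelihoods from STRUCTURE results files
#'
#' Extracts `K` ("populations assumed") and the final "Estimated Ln Prob of
#' Data" from each STRUCTURE `_f` output file, producing the table consumed
#' by [evanno_delta_k()] exactly as STRUCTURE HARVESTER does.
#'
#' @param files character vector of STRUCTURE result file paths.
#' @return data.frame with columns `K`, `rep`, `loglik`.
#' @export
read_structure_logliks <- function(files) {
  rows <- lapply(files, function(f) {
    lines <- readLines(f, warn = FALSE)
    kl <- grep("populations assumed", lines, value = TRUE)[1]
    ll <- grep("Estimated Ln Prob of Data", lines, value = TRUE)[1]
    if (is.na(kl) || is.na(ll))
      stop("not a STRUCTURE results file: ", f)
    data.frame(K = as.integer(sub(".*?(\\d+)\\s*populations assumed.*", "\\1", kl)),
               loglik = as.numeric(sub(".*=\\s*", "", ll)))
  })
  out <- do.call(rbind, rows)
  out$rep <- stats::ave(out$K, out$K, FUN = seq_along)
  out[, c("K", "rep", "loglik")]
}

# best column permutation aligning Q to ref (exhaustive K <= 7, greedy above)
align_permutation <- function(Qref, Q) {
  K <- ncol(Q)
  score <- function(perm) sum(Qref * Q[, perm, drop = FALSE])
  if (K <= 7) {
    perms <- permutations_of(K)
    best <- perms[[which.max(vapply(perms, score, numeric(1)))]]
  } else {
    S <- crossprod(Qref, Q)   # K x K similarity
    best <- integer(K)
    used <- logical(K)
    for (k in order(-apply(S, 1, max))) {
      j <- which.max(replace(S[k, ], used, -Inf))
      best[k] <- j; used[j] <- TRUE
    }
  }
  best
}

permutations_of <- function(K) {
  if (K == 1) return(list(1L))
  sub <- permutations_of(K - 1)
  out <- list()
  for (p in sub) for (pos in seq_len(K)) {
    out[[length(out) + 1L]] <- append(p, K, after = pos - 1)
  }
  out
}

#' Align replicate admixture fits across label switching
#'
#' Cluster labels are arbitrary across independent repetitions. The best
#' log-likelihood replicate is the reference; every other replicate's
#' columns are permuted to maximize agreement with it (exhaustive search of
#' permutations up to K = 7, greedy assignment above). Returns the aligned
#' Q matrices and their mean.
#'
#' @param fits list of [fit_admixture()] results at the same K on the same
#'   individuals.
#' @return list with `Q_aligned` (list), `mean_Q`, `reference` (index of the
#'   reference replicate) and the permutations used.
#' @export
align_replicates <- function(fits) {
  if (length(fits) < 2) stop("need >= 2 fits")
  K <- unique(vapply(fits, `[[`, numeric(1), "K"))
  if (length(K) != 1) stop("fits have different K")
  ids <- lapply(fits, function(f) rownames(f$Q))
  if (!all(vapply(ids, identical, logical(1), ids[[1]])))
    stop("fits cover different individual sets")
  ref <- which.max(vapply(fits, `[[`, numeric(1), "loglik"))
  Qref <- fits[[ref]]$Q
  perms <- lapply(fits, function(f) align_permutation(Qref, f$Q))
  Qs <- Map(function(f, p) f$Q[, p, drop = FALSE], fits, perms)
  Qs <- lapply(Qs, function(q) { colnames(q) <- colnames(Qref); q })
  mean_Q <- Reduce(`+`, Qs) / length(Qs)
  list(Q_aligned = Qs, mean_Q = mean_Q, reference = ref,
       permutations = perms)
}
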