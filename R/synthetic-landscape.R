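# smooth a matrix with a separable Gaussian kernel (toroidal edges keep the
# marginal variance stationary; the field is synthetic either way)
smooth_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  sm_cols <- function(x) {
    n <- nrow(x)
    wrap <- outer(seq_len(n), -half:half,
                  function(i, o) ((i + o - 1) %% n) + 1)
    apply(x, 2, function(col) as.numeric(matrix(col[wrap], n) %*% k))
  }
  t(sm_cols(t(sm_cols(m))))
}

#' Configuration for the landscape generator
#'
#' Defaults produce a 100 x 100 grid of spatially autocorrelated,
#' mutually correlated environmental layers, a logistic true-suitability
#' surface and 151 presence cells sampled proportional to suitability --
#' the scale of the presence set the suitability framework is designed
#' for.
#'
#' @param nrow,ncol grid dimensions (>= 50 for spatial tests).
#' @param cell_size cell size in degrees (default 2.5 arc minutes).
#' @param west,south grid origin.
#' @param n_layers number of environmental layers.
#' @param autocorr_sigma Gaussian smoothing radius, in cells, controlling
#'   spatial autocorrelation.
#' @param layer_cor share of variance from a common field, inducing
#'   inter-layer correlation.
#' @param beta true logistic coefficients (recycled/truncated to
#'   `n_layers`).
#' @param beta0 true logistic intercept.
#' @param n_presences number of presence cells to sample.
#' @return a list of class `landscape_sim_config`.
#' @export
landscape_sim_config <- function(nrow = 100, ncol = 100, cell_size = 1 / 24,
                                 west = -77, south = 2, n_layers = 4,
                                 autocorr_sigma = 5, layer_cor = 0.3,
                                 beta = c(4, -3, 2, 0), beta0 = -4,
                                 n_presences = 151) {
  stopifnot(nrow >= 10, ncol >= 10, n_layers >= 1, all(is.finite(beta)))
  structure(list(nrow = nrow, ncol = ncol, cell_size = cell_size,
                 west = west, south = south, n_layers = n_layers,
                 autocorr_sigma = autocorr_sigma, layer_cor = layer_cor,
                 beta = rep_len(beta, n_layers), beta0 = beta0,
                 n_presences = n_presences),
            class = "landscape_sim_config")
}

#' Simulate an environmental landscape with known suitability
#'
#' Environmental layers are standardized smoothed Gaussian noise (optionally
#' sharing a common field so layers are correlated, as real climate and
#' terrain variables are). True suitability is
#' `plogis(beta0 + sum beta_j layer_j)`; presence cells are sampled without
#' replacement with probability proportional to suitability, so at most one
#' presence per cell.
#'
#' @param cfg a [landscape_sim_config()].
#' @param seed RNG seed.
#' @return list with `stack` (an [env_stack()] of layers `env1..envL`),
#'   `presences` (data.frame `lon`, `lat`), and `truth` (`beta`, `beta0`,
#'   the suitability [env_raster()], and the config). All-zero coefficients
#'   yield a uniform surface with a warning.
#' @export
simulate_landscape <- function(cfg = landscape_sim_config(), seed = 1L) {
  set.seed(seed)
  nr <- cfg$nrow; nc <- cfg$ncol
  shared <- smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc),
                          cfg$autocorr_sigma)
  layers <- list()
  for (j in seq_len(cfg$n_layers)) {
    own <- smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc),
                         cfg$autocorr_sigma)
    f <- sqrt(cfg$layer_cor) * shared + sqrt(1 - cfg$layer_cor) * own
    f <- (f - mean(f)) / stats::sd(f)
    layers[[paste0("env", j)]] <- env_raster(f, cfg$west, cfg$south,
                                             cfg$cell_size)
  }
  stack <- env_stack(layers)
  lin <- matrix(cfg$beta0, nr, nc)
  for (j in seq_len(cfg$n_layers))
    lin <- lin + cfg$beta[j] * layers[[j]]$values
  suit <- stats::plogis(lin)
  if (all(cfg$beta == 0))
    warning("all-zero coefficients: suitability surface is uniform")
  cells <- cell_centers(layers[[1]])$grid()
  pick <- sample(nrow(cells), cfg$n_presences, prob = as.vector(suit))
  presences <- data.frame(lon = cells$lon[pick], lat = cells$lat[pick])
  list(stack = stack, presences = presences,
       truth = list(beta = cfg$beta, beta0 = cfg$beta0,
                    suitability = env_raster(suit, cfg$west, cfg$south,
                                             cfg$cell_size),
                    config = cfg, seed = seed))
}
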