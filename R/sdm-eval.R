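#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of presence scores against background
#' scores; ties count one half.
#'
#' @param pos scores at presences.
#' @param neg scores at background points.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(pos, neg) {
  np <- length(pos); nn <- length(neg)
  if (!np || !nn) return(NA_real_)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

# greedy pairwise-distance matching: each test presence (ordered by its
# distance-to-nearest-training-presence) takes the unused background point
# whose own distance-to-nearest-training-presence is closest
pwd_match <- function(test_pres, background, train_pres) {
  dp <- nearest_presence_dist(test_pres$lon, test_pres$lat,
                              train_pres$lon, train_pres$lat)
  db <- nearest_presence_dist(background$lon, background$lat,
                              train_pres$lon, train_pres$lat)
  used <- logical(length(db))
  sel <- integer(0); kept <- integer(0)
  for (i in order(dp)) {
    if (all(used)) break
    j <- which.min(replace(abs(db - dp[i]), used, Inf))
    used[j] <- TRUE
    sel <- c(sel, j); kept <- c(kept, i)
  }
  list(presence_idx = kept, background_idx = sel)
}

#' Calibrated AUC with a geographic null correction
#'
#' k-fold cross-validation of a base learner with correction for spatial
#' sorting bias: in each fold the model is refit on the training folds, test
#' presences are paired with distance-matched background points (greedy
#' nearest match on distance-to-nearest-training-presence, without
#' replacement), and `cAUC = AUC_model - (AUC_null - 0.5)` on the matched
#' evaluation set, capped into `[0, 1]` (the uncapped value is kept). The
#' null evaluated against itself gives 0.5 identically.
#'
#' @param fit_fun function `(presences, background, stack, seed)` returning
#'   an `sdm_model`, e.g. `function(p, b, s, seed)
#'   fit_base_model("logistic", p, b, s, seed)`; pass `NULL` to evaluate the
#'   geographic null model itself.
#' @param presences,background data.frames with `lon`, `lat`.
#' @param stack an [env_stack()].
#' @param k_folds number of folds (>= 2).
#' @param seed RNG seed (fold assignment and refits).
#' @return data.frame with one row per evaluated fold: `fold`, `auc`,
#'   `auc_null`, `cauc`, `cauc_raw`, `n_test`.
#' @export
calibrated_auc <- function(fit_fun, presences, background, stack,
                           k_folds = 4, seed = 1L) {
  if (k_folds < 2) stop("k_folds must be >= 2")
  np <- nrow(presences); nb <- nrow(background)
  set.seed(seed)
  fold_p <- sample(rep_len(seq_len(k_folds), np))
  fold_b <- sample(rep_len(seq_len(k_folds), nb))
  rows <- list()
  for (f in seq_len(k_folds)) {
    train_p <- presences[fold_p != f, , drop = FALSE]
    test_p <- presences[fold_p == f, , drop = FALSE]
    train_b <- background[fold_b != f, , drop = FALSE]
    test_b <- background[fold_b == f, , drop = FALSE]
    if (!nrow(test_b)) { warning("fold ", f, " skipped: no background for matching"); next }
    m <- pwd_match(test_p, test_b, train_p)
    if (length(m$presence_idx) < 2) {
      warning("fold ", f, " skipped: insufficient background for matching")
      next
    }
    ep <- test_p[m$presence_idx, , drop = FALSE]
    eb <- test_b[m$background_idx, , drop = FALSE]
    null <- geographic_null(train_p)
    # null scored on the joint evaluation set so ranks are comparable
    sn <- predict(null, rbind(ep[, c("lon", "lat")], eb[, c("lon", "lat")]))
    auc_null <- auc_score(sn[seq_len(nrow(ep))], sn[-seq_len(nrow(ep))])
    if (is.null(fit_fun)) {
      auc_mod <- auc_null
    } else {
      model <- fit_fun(train_p, train_b, stack, seed + f)
      feats <- function(pts) cbind(stack_extract(stack, pts$lon, pts$lat),
                                   pts[, c("lon", "lat")])
      sp <- predict(model, feats(ep)); sb <- predict(model, feats(eb))
      auc_mod <- auc_score(sp, sb)
    }
    raw <- auc_mod - (auc_null - 0.5)
    rows[[length(rows) + 1L]] <-
      data.frame(fold = f, auc = auc_mod, auc_null = auc_null,
                 cauc = pmin(pmax(raw, 0), 1), cauc_raw = raw,
                 n_test = nrow(ep))
  }
  do.call(rbind, rows)
}

#' Repeated cAUC iterations for model retention
#'
#' Repeats [calibrated_auc()] with distinct seeds and returns one cAUC per
#' iteration (the fold mean), the sampling unit of the Mann-Whitney
#' retention test.
#'
#' @inheritParams calibrated_auc
#' @param iterations number of repetitions.
#' @return numeric vector of per-iteration cAUC values.
#' @export
cauc_iterations <- function(fit_fun, presences, background, stack,
                            iterations = 20, k_folds = 4, seed = 1L) {
  vapply(seq_len(iterations), function(it) {
    cv <- calibrated_auc(fit_fun, presences, background, stack,
                         k_folds = k_folds, seed = seed + 7919L * it)
    mean(cv$cauc)
  }, numeric(1))
}

#' Retain models that beat the geographic null
#'
#' One-sided Mann-Whitney test of each model's per-iteration cAUC sample
#' against the null model's; a model is retained when `p < alpha`. When a
#' model's sample is entirely tied with the null's the test carries no
#' evidence and `p = 1` is reported.
#'
#' @param model_caucs named list of numeric cAUC vectors, one per model.
#' @param null_caucs numeric cAUC vector of the geographic null.
#' @param alpha significance level.
#' @return data.frame with `model`, `p_value`, `retained`.
#' @export
retain_models <- function(model_caucs, null_caucs, alpha = 0.05) {
  rows <- lapply(names(model_caucs), function(nm) {
    x <- model_caucs[[nm]]
    p <- if (max(c(x, null_caucs)) == min(c(x, null_caucs))) 1 else
      suppressWarnings(stats::wilcox.test(x, null_caucs,
                                          alternative = "greater")$p.value)
    data.frame(model = nm, p_value = p, retained = p < alpha)
  })
  do.call(rbind, rows)
}

#' Maximum training sensitivity plus specificity threshold
#'
#' Scans the observed scores as candidate cutoffs and returns the one
#' maximizing sensitivity (fraction of presences scoring `>=` the cutoff)
#' plus specificity (fraction of background scoring `<` it); exact ties in
#' the objective resolve to the lowest threshold.
#'
#' @param pres_scores,bg_scores suitability scores at training presences and
#'   background points.
#' @return the threshold (a warning is issued for degenerate single-score
#'   data).
#' @export
threshold_max_sens_spec <- function(pres_scores, bg_scores) {
  cand <- sort(unique(c(pres_scores, bg_scores)))
  if (length(cand) == 1) {
    warning("degenerate scores: single candidate threshold")
    return(cand)
  }
  obj <- vapply(cand, function(t)
    mean(pres_scores >= t) + mean(bg_scores < t), numeric(1))
  cand[which(obj == max(obj))[1]]
}

#' Consensus of threshold-limited scenario maps
#'
#' Combines binary suitability maps from N scenario projections:
#' `"optimistic"` marks cells suitable in at least one scenario,
#' `"pessimistic"` cells suitable in at least half (`ceiling(N/2)`). The
#' optimistic set always contains the pessimistic set.
#'
#' @param maps list of [env_raster()] objects with 0/1 (or logical) values
#'   on a shared grid.
#' @param rule `"optimistic"` or `"pessimistic"`.
#' @return an [env_raster()] with binary values.
#' @export
consensus <- function(maps, rule = c("optimistic", "pessimistic")) {
  rule <- match.arg(rule)
  if (!length(maps)) stop("need >= 1 binary map")
  g <- maps[[1]]
  acc <- Reduce(`+`, lapply(maps, function(m) {
    v <- m$values
    v[is.na(v)] <- 0
    (v > 0) + 0
  }))
  need <- if (rule == "optimistic") 1L else ceiling(length(maps) / 2)
  env_raster((acc >= need) + 0, g$west, g$south, g$cell_size, g$nodata)
}
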