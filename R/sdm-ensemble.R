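#' Exhaustive anchored ensemble search
#'
#' Enumerates every subset of the retained base models that contains the
#' anchor model (`2^(m-1)` combinations for `m` retained models). Each
#' candidate ensemble predicts the weighted mean of its members'
#' suitabilities, weighted by their mean cross-validated cAUC, and is
#' scored by the cross-validated cAUC of the combined score on shared
#' folds; the arg-max ensemble is returned. Because the anchor-only
#' ensemble is in the search space, the selected ensemble's cAUC is never
#' below the anchor's.
#'
#' @param fit_funs named list of fit functions
#'   `(presences, background, stack, seed) -> sdm_model`, one per retained
#'   model; must include `anchor`.
#' @param anchor name of the anchor model every combination must include.
#' @param presences,background data.frames with `lon`, `lat`.
#' @param stack an [env_stack()].
#' @param k_folds folds shared by all members.
#' @param seed RNG seed.
#' @param max_members combinatorial guard: error above this many retained
#'   models (pre-filter first).
#' @return an object of class `ensemble_model`: `members`, normalized
#'   `weights`, `cauc`, `threshold`-ready member fits on the full data,
#'   `n_combinations`, and the per-subset score table.
#' @export
ensemble_search <- function(fit_funs, anchor, presences, background, stack,
                            k_folds = 4, seed = 1L, max_members = 16) {
  m <- length(fit_funs)
  nms <- names(fit_funs)
  if (!anchor %in% nms) stop("anchor '", anchor, "' not among retained models")
  if (m > max_members)
    stop("combinatorial guard: ", m, " retained models (> ", max_members,
         "); pre-filter before the exhaustive search")

  # shared folds and evaluation sets
  np <- nrow(presences); nb <- nrow(background)
  set.seed(seed)
  fold_p <- sample(rep_len(seq_len(k_folds), np))
  fold_b <- sample(rep_len(seq_len(k_folds), nb))
  folds <- list()
  for (f in seq_len(k_folds)) {
    train_p <- presences[fold_p != f, , drop = FALSE]
    test_p <- presences[fold_p == f, , drop = FALSE]
    train_b <- background[fold_b != f, , drop = FALSE]
    test_b <- background[fold_b == f, , drop = FALSE]
    mt <- pwd_match(test_p, test_b, train_p)
    ep <- test_p[mt$presence_idx, , drop = FALSE]
    eb <- test_b[mt$background_idx, , drop = FALSE]
    null <- geographic_null(train_p)
    sn <- predict(null, rbind(ep[, c("lon", "lat")], eb[, c("lon", "lat")]))
    npos <- nrow(ep)
    feats <- function(pts) cbind(stack_extract(stack, pts$lon, pts$lat),
                                 pts[, c("lon", "lat")])
    scores <- matrix(NA_real_, npos + nrow(eb), m, dimnames = list(NULL, nms))
    for (j in seq_len(m)) {
      mod <- fit_funs[[j]](train_p, train_b, stack, seed + f)
      scores[, j] <- c(predict(mod, feats(ep)), predict(mod, feats(eb)))
    }
    folds[[f]] <- list(scores = scores, npos = npos,
                       auc_null = auc_score(sn[seq_len(npos)], sn[-seq_len(npos)]))
  }

  member_cauc <- setNames(vapply(seq_len(m), function(j) {
    mean(vapply(folds, function(fd) {
      a <- auc_score(fd$scores[seq_len(fd$npos), j],
                     fd$scores[-seq_len(fd$npos), j])
      pmin(pmax(a - (fd$auc_null - 0.5), 0), 1)
    }, numeric(1)))
  }, numeric(1)), nms)

  subset_cauc <- function(members) {
    w <- member_cauc[members]
    w <- w / sum(w)
    mean(vapply(folds, function(fd) {
      s <- as.numeric(fd$scores[, members, drop = FALSE] %*% w)
      a <- auc_score(s[seq_len(fd$npos)], s[-seq_len(fd$npos)])
      pmin(pmax(a - (fd$auc_null - 0.5), 0), 1)
    }, numeric(1)))
  }

  others <- setdiff(nms, anchor)
  n_comb <- 2^length(others)
  tab <- data.frame(members = character(n_comb), size = integer(n_comb),
                    cauc = numeric(n_comb), stringsAsFactors = FALSE)
  best <- NULL; best_cauc <- -Inf
  for (b in seq_len(n_comb) - 1L) {
    incl <- c(anchor, others[bitwAnd(b, 2^(seq_along(others) - 1)) > 0])
    ca <- subset_cauc(incl)
    tab$members[b + 1L] <- paste(incl, collapse = "+")
    tab$size[b + 1L] <- length(incl)
    tab$cauc[b + 1L] <- ca
    if (ca > best_cauc + 1e-12 ||
        (abs(ca - best_cauc) <= 1e-12 && !is.null(best) &&
         length(incl) < length(best))) {
      best <- incl; best_cauc <- ca
    }
  }

  w <- member_cauc[best] / sum(member_cauc[best])
  fits <- lapply(best, function(nm)
    fit_funs[[nm]](presences, background, stack, seed))
  names(fits) <- best
  structure(list(members = best, weights = w, cauc = best_cauc,
                 anchor = anchor, member_cauc = member_cauc,
                 fits = fits, n_combinations = n_comb, table = tab,
                 k_folds = k_folds, seed = seed),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("ensemble_model: %d members (anchor %s) out of %d combinations searched\n",
              length(x$members), x$anchor, x$n_combinations))
  cat("  members:", paste(sprintf("%s (w=%.3f)", x$members, x$weights),
                          collapse = ", "), "\n")
  cat(sprintf("  cross-validated cAUC: %.4f\n", x$cauc))
  invisible(x)
}

#' Predict suitability from an ensemble
#'
#' Weighted mean of the member predictions (a convex combination: the
#' ensemble score lies between the member minimum and maximum cellwise).
#'
#' @param object an `ensemble_model`.
#' @param newdata data.frame with the environmental columns plus `lon`/`lat`.
#' @param ... unused.
#' @return numeric suitability in `[0, 1]`.
#' @export
predict.ensemble_model <- function(object, newdata, ...) {
  S <- vapply(object$fits, function(f) predict(f, newdata),
              numeric(nrow(newdata)))
  as.numeric(S %*% object$weights)
}

#' Project a model over a stack and binarize at a threshold
#'
#' @param model an `sdm_model` or `ensemble_model`.
#' @param stack an [env_stack()] (a projection scenario).
#' @param threshold cutoff from [threshold_max_sens_spec()]; `NULL` returns
#'   the continuous suitability raster.
#' @return an [env_raster()] of suitabilities, or 0/1 when thresholded.
#' @export
project_model <- function(model, stack, threshold = NULL) {
  g <- stack$layers[[1]]
  cells <- stack_cells(stack)
  s <- predict(model, cells)
  vals <- matrix(NA_real_, nrow(g$values), ncol(g$values))
  vals[cbind(cells$row, cells$col)] <- if (is.null(threshold)) s else
    (s >= threshold) + 0
  env_raster(vals, g$west, g$south, g$cell_size, g$nodata)
}
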