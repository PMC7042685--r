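small_landscape <- function(seed = 7, ...) {
  simulate_landscape(landscape_sim_config(...), seed = seed)
}

test_that("background sampling stays inside the buffered hull and respects cell uniqueness", {
  # unit-square presence corners: buffer = 0.1 * sqrt(2)
  pres <- data.frame(lon = c(0, 1, 1, 0), lat = c(0, 0, 1, 1))
  reg <- presence_region(pres)
  expect_equal(reg$largest_axis, sqrt(2))
  expect_equal(reg$buffer, 0.1 * sqrt(2))
  expect_true(all(reg$contains(c(0.5, -0.1, 1.1), c(0.5, -0.05, 1.05))))
  expect_false(reg$contains(1.2, 1.2))

  ls <- small_landscape(nrow = 50, ncol = 50)
  pres <- ls$presences
  bg <- sample_background(pres, ls$stack, max_n = 400, seed = 3)
  expect_lte(nrow(bg), 400)
  reg <- presence_region(pres)
  # geometry audit: brute-force point-in-region check of every sample
  expect_true(all(reg$contains(bg$lon, bg$lat)))
  # at most one background point per cell, and never a presence cell
  key <- function(d) paste(floor(d$lon / ls$stack$layers[[1]]$cell_size),
                           floor(d$lat / ls$stack$layers[[1]]$cell_size))
  expect_false(any(duplicated(key(bg))))
  expect_false(any(key(bg) %in% key(pres)))

  # cell uniqueness binds when the region is small
  few <- small_landscape(nrow = 12, ncol = 12, n_presences = 30)
  bg2 <- sample_background(few$presences, few$stack, max_n = 10000, seed = 1)
  expect_lte(nrow(bg2), 12 * 12 - 30)
  expect_gt(nrow(bg2), 0)
})

test_that("VIF pruning drops collinear layers and matches an exhaustive oracle", {
  set.seed(5)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  df <- data.frame(a = x1, b = x1 + rnorm(n, 0, 1e-8), c = x2)
  out <- vif_prune(df)
  expect_length(out$retained, 2)
  expect_length(intersect(out$retained, c("a", "b")), 1)
  expect_true("c" %in% out$retained)

  # orthogonal layers are untouched
  orth <- data.frame(a = x1, b = x2, c = x3)
  expect_equal(vif_prune(orth)$retained, c("a", "b", "c"))

  # 5-layer instance with a known structure: iterative pruning finds the
  # maximal all-VIF<5 subset identified by exhaustive search
  z <- rnorm(n)
  df5 <- data.frame(a = x1, b = x2, c = x3,
                    d = 0.9 * x1 + 0.9 * x2 + 0.2 * z,
                    e = rnorm(n))
  got <- sort(vif_prune(df5)$retained)
  all_ok <- function(cols) all(vif(df5[cols]) < 5)
  best <- NULL
  for (k in rev(seq_len(5))) {
    subs <- combn(names(df5), k, simplify = FALSE)
    ok <- Filter(all_ok, subs)
    if (length(ok)) { best <- ok; break }
  }
  expect_true(any(vapply(best, function(s) identical(sort(s), got),
                         logical(1))))
  expect_equal(length(got), length(best[[1]]))
})

test_that("the soil depth-weighted mean uses the layer-thickness weights", {
  mk <- function(v) env_raster(matrix(v, 2, 2), 0, 0, 1)
  same <- soil_depth_mean(lapply(rep(8, 5), mk))
  expect_true(all(same$values == 8))
  w <- soil_depth_mean(lapply(c(10, 10, 10, 20, 20), mk))
  expect_true(all(w$values == 17))
  expect_equal(sum(c(0.05, 0.1, 0.15, 0.3, 0.4)), 1)
  miss <- lapply(c(10, 10, 10, 20, 20), mk)
  miss[[2]]$values[1, 1] <- NA
  expect_true(is.na(soil_depth_mean(miss)$values[1, 1]))
})

test_that("reference base learners behave at their fixed points", {
  ls <- small_landscape(seed = 3)
  pres <- ls$presences
  bg <- sample_background(pres, ls$stack, max_n = 400, seed = 1)
  env <- fit_base_model("envelope", pres, bg, ls$stack)
  med <- stack_extract(ls$stack, pres$lon, pres$lat)
  med_cell <- data.frame(t(apply(med, 2, median, na.rm = TRUE)))
  expect_equal(predict(env, med_cell), 1)

  # perfectly separated single variable: training AUC = 1
  g <- env_raster(matrix(seq(0, 1, length.out = 400), 20, 20), 0, 0, 0.1)
  st <- env_stack(list(env1 = g))
  cells <- stack_cells(st)
  hi <- cells[cells$env1 > 0.8, ][1:20, ]
  lo <- cells[cells$env1 < 0.2, ][1:40, ]
  logi <- fit_base_model("logistic", hi, lo, st)
  expect_equal(auc_score(predict(logi, hi), predict(logi, lo)), 1)

  # coefficient recovery: sign and rank follow the generator
  fit <- fit_base_model("logistic", pres, bg, ls$stack)
  beta_hat <- as.numeric(glmnet::coef.glmnet(fit$info$fit))[-1]
  beta_true <- ls$truth$beta
  expect_true(all(sign(beta_hat[beta_true != 0]) ==
                    sign(beta_true[beta_true != 0])))
  expect_equal(order(-abs(beta_hat[1:3])), order(-abs(beta_true[1:3])))

  expect_error(fit_base_model("maxent", pres, bg, ls$stack), "config error")
})

test_that("held-out discrimination on the synthetic landscape is strong", {
  ls <- small_landscape(seed = 9)
  set.seed(1)
  test_idx <- sample(nrow(ls$presences), 50)
  train <- ls$presences[-test_idx, ]
  test <- ls$presences[test_idx, ]
  bg <- sample_background(ls$presences, ls$stack, max_n = 500, seed = 2)
  fit <- fit_base_model("logistic", train, bg, ls$stack)
  feats <- function(p) stack_extract(ls$stack, p$lon, p$lat)
  a <- auc_score(predict(fit, feats(test)), predict(fit, feats(bg)))
  expect_gt(a, 0.8)
})

test_that("the geographic null scores by proximity and exposes spatial sorting bias", {
  train <- data.frame(lon = c(0, 0.1), lat = c(0, 0.1))
  null <- geographic_null(train)
  q <- data.frame(lon = c(0, 0.5, 2), lat = c(0, 0.5, 2))
  s <- predict(null, q)
  expect_equal(s[1], 1)      # at a training presence
  expect_equal(s[3], 0)      # farthest queried point
  expect_true(all(diff(s) < 0))

  # clustered test presences near training ones: null AUC >> 0.5
  set.seed(4)
  trainc <- data.frame(lon = rnorm(30, 0, 0.1), lat = rnorm(30, 0, 0.1))
  testc <- data.frame(lon = rnorm(30, 0, 0.1), lat = rnorm(30, 0, 0.1))
  bgc <- data.frame(lon = runif(100, -2, 2), lat = runif(100, -2, 2))
  nullc <- geographic_null(trainc)
  sc <- predict(nullc, rbind(testc, bgc))
  expect_gt(auc_score(sc[1:30], sc[-(1:30)]), 0.8)
})

test_that("AUC matches the brute-force pair count", {
  expect_equal(auc_score(c(0.9, 0.8), c(0.2, 0.1)), 1)
  set.seed(8)
  for (r in 1:5) {
    pos <- round(runif(20), 2)   # rounding forces ties
    neg <- round(runif(30), 2)
    expect_equal(auc_score(pos, neg), oracle_auc(pos, neg), tolerance = 1e-12)
  }
})

test_that("the calibrated AUC of the geographic null is one half on every fold", {
  ls <- small_landscape(seed = 5, nrow = 60, ncol = 60)
  bg <- sample_background(ls$presences, ls$stack, max_n = 300, seed = 1)
  cv <- calibrated_auc(NULL, ls$presences, bg, ls$stack, k_folds = 4, seed = 2)
  expect_equal(nrow(cv), 4)
  expect_identical(cv$cauc, rep(0.5, 4))
  expect_identical(cv$cauc_raw, rep(0.5, 4))
})

test_that("model retention runs one-sided Mann-Whitney tests with tie handling", {
  ret <- retain_models(list(good = rep(0.9, 20), same = rep(0.5, 20)),
                       rep(0.5, 20))
  expect_true(ret$retained[ret$model == "good"])
  expect_lt(ret$p_value[ret$model == "good"], 0.001)
  expect_false(ret$retained[ret$model == "same"])
  expect_equal(ret$p_value[ret$model == "same"], 1)

  # U statistic agrees with brute-force pair counting
  set.seed(3)
  x <- round(runif(15), 1); y <- round(runif(12), 1)
  W <- suppressWarnings(stats::wilcox.test(x, y,
                                           alternative = "greater"))$statistic
  expect_equal(unname(W), oracle_U(x, y))
})

test_that("threshold selection maximizes sensitivity plus specificity with the tie rule", {
  expect_equal(threshold_max_sens_spec(c(0.8, 0.6), c(0.4, 0.2)), 0.6)
  expect_warning(t1 <- threshold_max_sens_spec(c(0.5, 0.5), c(0.5)),
                 "degenerate")
  expect_equal(t1, 0.5)
  # exhaustive scan agreement on random scores
  set.seed(12)
  for (r in 1:5) {
    ps <- round(runif(15), 2); bs <- round(runif(25), 2)
    cand <- sort(unique(c(ps, bs)))
    obj <- sapply(cand, function(t) mean(ps >= t) + mean(bs < t))
    expect_equal(threshold_max_sens_spec(ps, bs), cand[which.max(obj)])
  }
})

test_that("consensus maps follow the at-least-one and at-least-half rules", {
  set.seed(6)
  maps <- lapply(1:31, function(i)
    env_raster(matrix(rbinom(100, 1, 0.4), 10, 10), 0, 0, 1))
  opt <- consensus(maps, "optimistic")
  pes <- consensus(maps, "pessimistic")
  counts <- Reduce(`+`, lapply(maps, `[[`, "values"))
  expect_equal(opt$values, (counts >= 1) + 0)
  expect_equal(pes$values, (counts >= 16) + 0)
  expect_true(all(opt$values >= pes$values))  # optimistic contains pessimistic
  one <- consensus(maps[1], "optimistic")
  expect_equal(one$values, consensus(maps[1], "pessimistic")$values)
})

test_that("ensemble search enumerates anchored subsets and returns a convex predictor", {
  ls <- small_landscape(seed = 11, nrow = 60, ncol = 60)
  pres <- ls$presences
  bg <- sample_background(pres, ls$stack, max_n = 300, seed = 1)
  ff <- list(logistic = function(p, b, s, sd2) fit_base_model("logistic", p, b, s, sd2),
             envelope = function(p, b, s, sd2) fit_base_model("envelope", p, b, s, sd2))
  ens <- ensemble_search(ff, "logistic", pres, bg, ls$stack, seed = 4)
  expect_equal(ens$n_combinations, 2)
  expect_true("logistic" %in% ens$members)
  expect_equal(sum(ens$weights), 1)
  # selection optimality: never worse than the anchor alone
  anchor_row <- ens$table$cauc[ens$table$members == "logistic"]
  expect_gte(ens$cauc, anchor_row)

  # convex combination: between member min and max cellwise
  cells <- head(stack_cells(ls$stack), 200)
  S <- sapply(ens$fits, function(f) predict(f, cells))
  pred <- predict(ens, cells)
  if (is.null(dim(S))) S <- matrix(S, ncol = length(ens$fits))
  expect_true(all(pred >= apply(S, 1, min) - 1e-12))
  expect_true(all(pred <= apply(S, 1, max) + 1e-12))

  # single retained model: that model with weight 1
  e1 <- ensemble_search(ff["logistic"], "logistic", pres, bg, ls$stack,
                        seed = 4)
  expect_equal(e1$members, "logistic")
  expect_equal(unname(e1$weights), 1)
  expect_equal(e1$n_combinations, 1)

  # combinatorial guard
  many <- setNames(rep(ff["logistic"], 17), paste0("m", 1:17))
  expect_error(ensemble_search(many, "m1", pres, bg, ls$stack),
               "combinatorial guard")
})
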