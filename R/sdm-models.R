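# registry of base learners; entries are functions
# (presences, background, stack, seed, ...) -> sdm_model
.sdm_registry <- new.env(parent = emptyenv())

#' Register a suitability base learner
#'
#' The ensemble machinery is agnostic to the learner: any function that fits
#' on presence/background points over an [env_stack()] and returns an object
#' with a `[0, 1]` `predict` can participate. Two reference learners ship
#' with the package (`"envelope"`, `"logistic"`); others can be plugged in
#' here.
#'
#' @param name model name.
#' @param fit_fun function `(presences, background, stack, seed)` returning
#'   an `sdm_model`.
#' @return invisibly, `name`.
#' @export
register_sdm_model <- function(name, fit_fun) {
  assign(name, fit_fun, envir = .sdm_registry)
  invisible(name)
}

#' List registered base learners
#' @return character vector of model names.
#' @export
sdm_models <- function() sort(ls(.sdm_registry))

new_sdm_model <- function(name, predict_fun, info = list()) {
  structure(list(name = name, predict_fun = predict_fun, info = info),
            class = "sdm_model")
}

#' @export
print.sdm_model <- function(x, ...) {
  cat("sdm_model:", x$name, "\n")
  invisible(x)
}

#' Predict suitability from a fitted base model
#'
#' @param object an `sdm_model`.
#' @param newdata data.frame with the environmental columns used at fit time
#'   (plus `lon`/`lat` for spatial models such as the geographic null).
#' @param ... unused.
#' @return numeric suitability scores in `[0, 1]`.
#' @export
predict.sdm_model <- function(object, newdata, ...) {
  s <- object$predict_fun(newdata)
  pmin(pmax(s, 0), 1)
}

#' Fit a suitability base model by name
#'
#' Reference learners: `"envelope"`, a BIOCLIM-style percentile envelope
#' whose suitability is the fraction of variables falling within the
#' presence `[p5, p95]` range; and `"logistic"`, an L2-regularized logistic
#' regression of presence vs background on standardized features. Both emit
#' suitabilities in `[0, 1]`. Unknown names are looked up in the registry
#' (see [register_sdm_model()]).
#'
#' @param name model name.
#' @param presences,background data.frames with `lon`, `lat`.
#' @param stack an [env_stack()]; the model uses the layers in `vars`.
#' @param seed RNG seed (the reference learners are deterministic given the
#'   data, but plug-ins may use it).
#' @param vars layer names to use (default all).
#' @param ... passed to registered fit functions.
#' @return an `sdm_model`.
#' @export
fit_base_model <- function(name, presences, background, stack, seed = 1L,
                           vars = names(stack$layers), ...) {
  if (exists(name, envir = .sdm_registry)) {
    fit <- get(name, envir = .sdm_registry)
    return(fit(presences, background, stack, seed, vars = vars, ...))
  }
  stop("config error: unknown model '", name, "'; registered: ",
       paste(sdm_models(), collapse = ", "))
}

fit_envelope <- function(presences, background, stack, seed = 1L,
                         vars = names(stack$layers), probs = c(0.05, 0.95),
                         ...) {
  X <- stack_extract(stack, presences$lon, presences$lat)[, vars, drop = FALSE]
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 10) stop("envelope model needs >= 10 presences on data cells")
  lims <- apply(X, 2, stats::quantile, probs = probs, na.rm = TRUE)
  new_sdm_model("envelope", function(newdata) {
    M <- as.matrix(newdata[, vars, drop = FALSE])
    inside <- sweep(M, 2, lims[1, ], ">=") & sweep(M, 2, lims[2, ], "<=")
    rowMeans(inside)
  }, info = list(limits = lims, vars = vars))
}

fit_logistic <- function(presences, background, stack, seed = 1L,
                         vars = names(stack$layers), lambda = 1e-3, ...) {
  Xp <- stack_extract(stack, presences$lon, presences$lat)[, vars, drop = FALSE]
  Xb <- stack_extract(stack, background$lon, background$lat)[, vars, drop = FALSE]
  X <- rbind(Xp, Xb)
  y <- c(rep(1, nrow(Xp)), rep(0, nrow(Xb)))
  ok <- stats::complete.cases(X)
  X <- as.matrix(X[ok, , drop = FALSE]); y <- y[ok]
  if (sum(y) < 10) stop("logistic model needs >= 10 presences on data cells")
  aug <- ncol(X) < 2  # glmnet needs >= 2 columns; pad with a dead column
  if (aug) X <- cbind(X, .aug = 0)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = TRUE)
  new_sdm_model("logistic", function(newdata) {
    M <- as.matrix(newdata[, vars, drop = FALSE])
    if (aug) M <- cbind(M, .aug = 0)
    as.numeric(stats::predict(fit, M, type = "response"))
  }, info = list(fit = fit, vars = vars, lambda = lambda))
}

#' Geographic null model
#'
#' A purely spatial reference model: suitability is a monotone decreasing
#' transform of the distance to the nearest training presence,
#' rank-normalized to `[0, 1]` within the queried point set (a training
#' presence scores 1, the farthest queried point 0). It uses no
#' environmental information; its only skill comes from the spatial
#' sorting of test points, which is exactly the bias the calibrated AUC
#' subtracts.
#'
#' @param presences_train data.frame with `lon`, `lat` of the training
#'   presences.
#' @return an `sdm_model` whose predictions need `lon`/`lat` columns.
#' @export
geographic_null <- function(presences_train) {
  tx <- presences_train$lon; ty <- presences_train$lat
  if (!length(tx)) stop("need >= 1 training presence")
  new_sdm_model("geographic_null", function(newdata) {
    d <- nearest_presence_dist(newdata$lon, newdata$lat, tx, ty)
    n <- length(d)
    if (n == 1) return(1 - as.numeric(d > 0))
    (n - rank(d, ties.method = "average")) / (n - 1)
  }, info = list(train = presences_train))
}

# min distance from each (x, y) to the training presences, degree space
nearest_presence_dist <- function(x, y, tx, ty) {
  vapply(seq_along(x), function(i) min(sqrt((tx - x[i])^2 + (ty - y[i])^2)),
         numeric(1))
}

register_sdm_model("envelope", fit_envelope)
register_sdm_model("logistic", fit_logistic)

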