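# distance from points to a polygon boundary (min over edges), degree space
dist_to_polygon <- function(px, py, poly) {
  nseg <- nrow(poly)
  d <- rep(Inf, length(px))
  for (s in seq_len(nseg)) {
    x1 <- poly[s, 1]; y1 <- poly[s, 2]
    e <- if (s == nseg) 1L else s + 1L
    x2 <- poly[e, 1]; y2 <- poly[e, 2]
    vx <- x2 - x1; vy <- y2 - y1
    len2 <- vx^2 + vy^2
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(pmax(((px - x1) * vx + (py - y1) * vy) / len2, 0), 1)
    d <- pmin(d, sqrt((px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2))
  }
  d
}

#' Buffered convex hull around presence points
#'
#' The calibration region: the convex hull of the presences extended by a
#' buffer equal to 10% of the hull's largest axis (the maximum pairwise
#' distance between presences). A point is inside the region when it falls
#' inside the hull or within the buffer distance of the hull boundary.
#'
#' @param presences data.frame with `lon`, `lat` (>= 3 non-collinear points).
#' @param buffer_frac buffer as a fraction of the largest axis.
#' @return list with the hull vertex matrix `hull`, `buffer` width, and a
#'   membership predicate `contains(lon, lat)`.
#' @export
presence_region <- function(presences, buffer_frac = 0.10) {
  xy <- cbind(presences$lon, presences$lat)
  if (nrow(unique(xy)) < 3) stop("need >= 3 distinct presences")
  h <- grDevices::chull(xy)
  if (length(h) < 3) stop("presences are collinear: no hull area")
  hull <- xy[h, , drop = FALSE]
  axis <- max(stats::dist(xy))
  buffer <- buffer_frac * axis
  contains <- function(lon, lat) {
    inside <- mgcv::in.out(rbind(hull, hull[1, ]), cbind(lon, lat))
    near <- dist_to_polygon(lon, lat, hull) <= buffer
    inside | near
  }
  list(hull = hull, buffer = buffer, largest_axis = axis, contains = contains)
}

#' Sample background points for suitability modeling
#'
#' Uniform sampling over the grid cells of the calibration region (the
#' buffered convex hull of the presences), at most one point per cell and an
#' overall maximum, excluding cells already holding a presence. Cells that
#' are no-data in the environmental stack are excluded.
#'
#' @param presences data.frame with `lon`, `lat`.
#' @param stack an [env_stack()] defining the grid and the no-data mask.
#' @param max_n overall maximum number of background points.
#' @param seed RNG seed.
#' @param buffer_frac buffer fraction of the hull's largest axis.
#' @return data.frame of background cell centers (`lon`, `lat`).
#' @export
sample_background <- function(presences, stack, max_n = 10000, seed = 1L,
                              buffer_frac = 0.10) {
  region <- presence_region(presences, buffer_frac)
  cells <- stack_cells(stack)
  keep <- region$contains(cells$lon, cells$lat)
  cells <- cells[keep, , drop = FALSE]
  pres_cell <- attr(stack_extract(stack, presences$lon, presences$lat), "cell")
  pres_key <- paste(pres_cell$row, pres_cell$col)
  cells <- cells[!paste(cells$row, cells$col) %in% pres_key, , drop = FALSE]
  if (!nrow(cells)) stop("no background cells available in the region")
  set.seed(seed)
  take <- sample(nrow(cells), min(max_n, nrow(cells)))
  out <- cells[take, c("lon", "lat"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing column `j` on all other
#' columns. Perfect collinearity yields `Inf`.
#'
#' @param df numeric data.frame of predictor samples.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(df) {
  df <- as.data.frame(df)
  vars <- names(df)
  out <- setNames(numeric(length(vars)), vars)
  for (j in seq_along(vars)) {
    fit <- stats::lm(stats::reformulate(vars[-j], response = vars[j]),
                     data = df)
    # summary.lm warns on exact fits; collinearity is handled via Inf below
    r2 <- suppressWarnings(summary(fit)$r.squared)
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}

#' Iterative VIF pruning of collinear layers
#'
#' Repeatedly drops the predictor with the highest VIF until all VIFs are
#' below the threshold. Perfectly collinear predictors (VIF infinite) are
#' dropped first; among exact ties the later column is dropped, so the
#' result is deterministic given the sample.
#'
#' @param df numeric data.frame of predictor samples (e.g. [stack_cells()]
#'   values at sampled locations).
#' @param threshold retain only predictors with VIF strictly below this.
#' @return list with `retained` (character), `dropped` (in drop order) and
#'   the final VIF vector.
#' @export
vif_prune <- function(df, threshold = 5) {
  df <- as.data.frame(df)[vapply(df, is.numeric, logical(1))]
  if (ncol(df) < 2) return(list(retained = names(df), dropped = character(),
                                vif = setNames(rep(1, ncol(df)), names(df))))
  dropped <- character()
  repeat {
    v <- vif(df)
    if (all(v < threshold) || ncol(df) <= 1) break
    worst <- which(v == max(v))
    worst <- worst[length(worst)]
    dropped <- c(dropped, names(df)[worst])
    df <- df[, -worst, drop = FALSE]
  }
  list(retained = names(df), dropped = dropped,
       vif = if (ncol(df) > 1) vif(df) else setNames(1, names(df)))
}
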