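#' Replicate trees into 30 arc-second cells via circular neighborhoods
#'
#' Each genotyped tree with coordinates is replicated into every grid cell
#' whose center lies within a circle of the given diameter centred on the
#' tree. Membership is tested in geographic degree space (the distortion at
#' low latitudes is small, about 2% at 10 degrees). The grid is snapped to
#' the global lattice aligned to integer degrees so results do not depend on
#' the data layout.
#'
#' @param G a [genotype_matrix()] with coordinates.
#' @param cell_size cell size in decimal degrees (default 30 arc seconds).
#' @param diameter neighborhood circle diameter in degrees (default 10 arc
#'   minutes).
#' @return an object of class `neighborhood_grid`: grid geometry (`west`,
#'   `south`, `nrow`, `ncol`, `cell_size`) plus a data.frame `cells` with
#'   `row`, `col`, `lon`, `lat`, `n_trees` and a list-column `trees` of
#'   contributing tree indices. Only cells with at least one tree are kept.
#' @export
build_neighborhood_grid <- function(G, cell_size = 1 / 120, diameter = 1 / 6) {
  if (is.null(G$coords)) stop("genotype matrix has no coordinates")
  ok <- stats::complete.cases(G$coords)
  if (!all(ok)) warning(sum(!ok), " tree(s) without coordinates excluded")
  trees <- which(ok)
  if (!length(trees)) stop("no trees with coordinates")
  xy <- G$coords[trees, , drop = FALSE]
  r <- diameter / 2

  # grid snapped to the global integer-degree lattice
  west <- floor((min(xy[, 1]) - r) / cell_size) * cell_size
  east <- ceiling((max(xy[, 1]) + r) / cell_size) * cell_size
  south <- floor((min(xy[, 2]) - r) / cell_size) * cell_size
  north <- ceiling((max(xy[, 2]) + r) / cell_size) * cell_size
  nc <- round((east - west) / cell_size)
  nr <- round((north - south) / cell_size)

  memb_tree <- integer(); memb_cell <- integer()
  for (t in seq_along(trees)) {
    cols <- seq(max(1L, floor((xy[t, 1] - r - west) / cell_size) + 1L),
                min(nc, ceiling((xy[t, 1] + r - west) / cell_size)))
    rows <- seq(max(1L, floor((north - xy[t, 2] - r) / cell_size) + 1L),
                min(nr, ceiling((north - xy[t, 2] + r) / cell_size)))
    cx <- west + (cols - 0.5) * cell_size
    cy <- north - (rows - 0.5) * cell_size
    dd <- outer((cy - xy[t, 2])^2, (cx - xy[t, 1])^2, "+")
    hit <- which(dd <= r^2, arr.ind = TRUE)
    if (nrow(hit)) {
      cell_id <- (cols[hit[, 2]] - 1L) * nr + rows[hit[, 1]]
      memb_tree <- c(memb_tree, rep(trees[t], nrow(hit)))
      memb_cell <- c(memb_cell, cell_id)
    }
  }
  by_cell <- split(memb_tree, memb_cell)
  # stable ordering by individual id so downstream resampling does not
  # depend on the input row order
  by_cell <- lapply(by_cell, function(t) t[order(G$ids[t])])
  cid <- as.integer(names(by_cell))
  col <- (cid - 1L) %/% nr + 1L
  row <- (cid - 1L) %% nr + 1L
  cells <- data.frame(row = row, col = col,
                      lon = west + (col - 0.5) * cell_size,
                      lat = north - (row - 0.5) * cell_size,
                      n_trees = lengths(by_cell))
  cells$trees <- unname(by_cell)
  structure(list(west = west, south = south, nrow = nr, ncol = nc,
                 cell_size = cell_size, diameter = diameter, cells = cells),
            class = "neighborhood_grid")
}

#' @export
print.neighborhood_grid <- function(x, ...) {
  cat(sprintf("neighborhood_grid: %d x %d cells of %.6f deg; %d occupied cells; trees per cell %d-%d\n",
              x$nrow, x$ncol, x$cell_size, nrow(x$cells),
              min(x$cells$n_trees), max(x$cells$n_trees)))
  invisible(x)
}

#' Bootstrap sample-bias correction of a statistic
#'
#' Corrects for unequal per-cell sample sizes by averaging the statistic over
#' `n_boot` subsamples of fixed size drawn from the tree set. The default
#' draws without replacement (rarefaction to the minimum sample size); when
#' the set is exactly the subsample size the statistic is returned directly
#' with `sd = 0`, so corrected and uncorrected values coincide for
#' minimum-size samples.
#'
#' @param G a [genotype_matrix()].
#' @param trees integer indices of the trees in the sample set.
#' @param stat function `(G, trees) -> numeric(1)`.
#' @param n_boot number of bootstrap subsamples.
#' @param subsample subsample size (minimum per-cell sample size).
#' @param seed RNG seed.
#' @param replace draw with replacement instead of rarefaction.
#' @return list with `mean`, `sd` and `n` (the size of the tree set);
#'   `mean = NA` (no-data) when fewer trees than `subsample`.
#' @export
bootstrap_corrected_stat <- function(G, trees, stat, n_boot = 1000,
                                     subsample = 3, seed = 1L,
                                     replace = FALSE) {
  n <- length(trees)
  if (n < subsample) return(list(mean = NA_real_, sd = NA_real_, n = n))
  if (n == subsample && !replace)
    return(list(mean = stat(G, trees), sd = 0, n = n))
  set.seed(seed)
  vals <- vapply(seq_len(n_boot), function(b)
    stat(G, sample(trees, subsample, replace = replace)), numeric(1))
  list(mean = mean(vals, na.rm = TRUE), sd = stats::sd(vals[!is.na(vals)]),
       n = n)
}

# fast multilocus means on a subset (no locus dropping: subsamples are tiny,
# a locus missing in the whole subsample is excluded from the mean)
subset_stat_fun <- function(stat_name, lca = NULL) {
  force(lca)
  function(G, idx) {
    a1 <- G$a1[idx, , drop = FALSE]; a2 <- G$a2[idx, , drop = FALSE]
    if (stat_name == "LCA") return(lca_per_locus(G, idx, lca))
    comp <- locus_components(a1, a2)
    use <- !is.na(comp$He)
    if (!any(use)) return(NA_real_)
    switch(stat_name,
           A = mean(comp$A[use]),
           I = mean(comp$I[use]),
           He = mean(comp$He[use]),
           Ho = mean(comp$Ho[use]),
           Fis = {
             he <- mean(comp$He[use])
             if (he > 0) 1 - mean(comp$Ho[use]) / he else NA_real_
           },
           stop("config error: unknown statistic '", stat_name, "'"))
  }
}

#' Classify locally common alleles (LCA)
#'
#' An allele is locally common when it occurs in fewer than `max_occupancy`
#' of the sampled populations but reaches a frequency above `min_freq` in at
#' least one population where it occurs. The classification is computed once
#' from the full dataset and then consumed by [lca_per_locus()].
#'
#' @param G a [genotype_matrix()] with population labels.
#' @param max_occupancy occupancy threshold as a fraction of populations
#'   (strictly less than; default 0.25).
#' @param min_freq frequency threshold (strictly greater than; default 0.05).
#' @return an object of class `lca_classification`: per locus, the character
#'   vector of locally common allele codes.
#' @export
classify_lca <- function(G, max_occupancy = 0.25, min_freq = 0.05) {
  freqs <- allele_frequencies(G, by = "population")
  P <- length(freqs)
  per_locus <- setNames(vector("list", n_loc(G)), G$loci)
  for (l in seq_len(n_loc(G))) {
    fl <- lapply(freqs, `[[`, l)
    fl <- fl[!vapply(fl, is.null, logical(1))]
    alleles <- unique(unlist(lapply(fl, names)))
    keep <- character()
    for (a in alleles) {
      fa <- vapply(fl, function(f) if (a %in% names(f)) f[[a]] else 0,
                   numeric(1))
      occ <- sum(fa > 0)
      if (occ / P < max_occupancy && any(fa > min_freq)) keep <- c(keep, a)
    }
    per_locus[[l]] <- keep
  }
  structure(list(per_locus = per_locus, n_pops = P,
                 max_occupancy = max_occupancy, min_freq = min_freq),
            class = "lca_classification")
}

#' @export
print.lca_classification <- function(x, ...) {
  cat(sprintf("lca_classification: %d locally common alleles over %d loci (occupancy < %.0f%% of %d populations, frequency > %.0f%%)\n",
              sum(lengths(x$per_locus)), length(x$per_locus),
              100 * x$max_occupancy, x$n_pops, 100 * x$min_freq))
  invisible(x)
}

#' Locally-common-allele richness of a tree set
#'
#' Number of classified locally common alleles present in the set, divided
#' by the number of loci ("LCA per locus"); bootstrap-correctable like any
#' other per-cell statistic.
#'
#' @param G a [genotype_matrix()].
#' @param trees integer indices of the trees in the set.
#' @param classification a [classify_lca()] result computed on the full
#'   dataset.
#' @return numeric LCA-per-locus value (`NA` for an empty set).
#' @export
lca_per_locus <- function(G, trees, classification) {
  if (!length(trees)) return(NA_real_)
  cnt <- 0L
  for (l in seq_len(n_loc(G))) {
    lca <- classification$per_locus[[l]]
    if (!length(lca)) next
    present <- unique(c(G$a1[trees, l], G$a2[trees, l]))
    cnt <- cnt + sum(as.character(lca) %in% as.character(present))
  }
  cnt / n_loc(G)
}

#' Map a bootstrap-corrected diversity statistic onto the grid
#'
#' Applies [bootstrap_corrected_stat()] cell by cell over a
#' [build_neighborhood_grid()]. Cells with fewer trees than `subsample` are
#' no-data. Cells sharing an identical contributing tree set reuse one
#' bootstrap run, so the result is independent of tree input order and cell
#' enumeration order.
#'
#' @param G a [genotype_matrix()] with coordinates.
#' @param stat_name one of `"A"`, `"I"`, `"He"`, `"Ho"`, `"Fis"`, `"LCA"`.
#' @param grid optional precomputed [build_neighborhood_grid()].
#' @param n_boot,subsample,seed,replace passed to
#'   [bootstrap_corrected_stat()].
#' @param cell_size,diameter grid geometry when `grid` is not supplied.
#' @param lca optional precomputed [classify_lca()] (computed from `G` when
#'   needed).
#' @return an object of class `diversity_raster`: the value raster (an
#'   [env_raster()]), the per-cell count raster, the per-cell table, and
#'   metadata (statistic, n_boot, subsample, seed).
#' @export
map_statistic <- function(G, stat_name, grid = NULL, n_boot = 1000,
                          subsample = 3, seed = 1L, replace = FALSE,
                          cell_size = 1 / 120, diameter = 1 / 6,
                          lca = NULL) {
  stat_name <- match.arg(stat_name, c("A", "I", "He", "Ho", "Fis", "LCA"))
  if (is.null(grid)) grid <- build_neighborhood_grid(G, cell_size, diameter)
  if (stat_name == "LCA" && is.null(lca)) lca <- classify_lca(G)
  stat <- subset_stat_fun(stat_name, lca)

  cells <- grid$cells
  key <- vapply(cells$trees, function(tr) paste(sort(tr), collapse = ","),
                character(1))
  uniq <- !duplicated(key)
  res_u <- lapply(which(uniq), function(i)
    bootstrap_corrected_stat(G, cells$trees[[i]], stat, n_boot = n_boot,
                             subsample = subsample, seed = seed,
                             replace = replace))
  names(res_u) <- key[uniq]
  cells$value <- vapply(key, function(k) res_u[[k]]$mean, numeric(1))
  cells$value_sd <- vapply(key, function(k) res_u[[k]]$sd, numeric(1))

  vals <- matrix(NA_real_, grid$nrow, grid$ncol)
  cnts <- matrix(NA_real_, grid$nrow, grid$ncol)
  ij <- cbind(cells$row, cells$col)
  vals[ij] <- cells$value
  cnts[ij] <- cells$n_trees
  structure(list(raster = env_raster(vals, grid$west, grid$south,
                                     grid$cell_size),
                 counts = env_raster(cnts, grid$west, grid$south,
                                     grid$cell_size),
                 cells = cells,
                 stat = stat_name, n_boot = n_boot, subsample = subsample,
                 seed = seed, replace = replace),
            class = "diversity_raster")
}

#' @export
print.diversity_raster <- function(x, ...) {
  cat(sprintf("diversity_raster: statistic %s (n_boot=%d, subsample=%d, seed=%d)\n",
              x$stat, x$n_boot, x$subsample, x$seed))
  print(x$raster)
  invisible(x)
}
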