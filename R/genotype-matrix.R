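#' Diploid codominant genotype matrix
#'
#' The central container for SSR data: per individual and locus an unordered
#' pair of positive integer allele codes (typically fragment sizes), together
#' with a population label and optionally a WGS84 lon/lat coordinate per
#' individual. A genotype is missing only when both allele slots are missing;
#' half-missing genotypes are rejected. Allele code 0 is reserved for missing
#' and never accepted as a real allele.
#'
#' @param a1,a2 integer matrices (individuals x loci) holding the two allele
#'   codes of each genotype; `NA` marks missing. The pair is unordered and is
#'   stored canonically with `a1 <= a2`.
#' @param ids character vector of individual identifiers.
#' @param pops character or factor vector of population labels, one per
#'   individual.
#' @param loci character vector of locus names.
#' @param coords optional numeric matrix (individuals x 2, columns `lon`,
#'   `lat`) of WGS84 decimal-degree tree locations; rows may be `NA`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(a1, a2, ids = NULL, pops, loci = NULL,
                            coords = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  n <- nrow(a1); L <- ncol(a1)
  if (!all(dim(a2) == c(n, L))) stop("a1 and a2 must have identical dimensions")
  if (is.null(ids)) ids <- paste0("ind_", seq_len(n))
  if (is.null(loci)) loci <- paste0("loc_", seq_len(L))
  ids <- as.character(ids); loci <- as.character(loci)
  if (length(ids) != n) stop("ids length must match number of individuals")
  if (length(loci) != L) stop("loci length must match number of loci")
  if (length(pops) != n) stop("every individual needs a population label")
  if (anyNA(pops)) stop("population labels must not be missing")
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) stop("half-missing genotypes are not allowed (both allele slots must be missing together)")
  bad <- (!is.na(a1) & a1 <= 0L) | (!is.na(a2) & a2 <= 0L)
  if (any(bad)) stop("allele codes must be positive integers (0 is reserved for missing)")
  # canonical unordered pair
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  a1 <- lo; a2 <- hi
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 2)
      stop("coords must be an n x 2 (lon, lat) matrix")
    colnames(coords) <- c("lon", "lat")
    ok <- stats::complete.cases(coords)
    if (any(coords[ok, 1] < -180 | coords[ok, 1] > 180 |
            coords[ok, 2] < -90 | coords[ok, 2] > 90))
      stop("coordinates out of WGS84 range")
    rownames(coords) <- ids
  }
  structure(list(a1 = a1, a2 = a2, ids = ids,
                 pops = factor(as.character(pops)), loci = loci,
                 coords = coords),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", n_ind(x), "individuals x", n_loc(x), "loci;",
      nlevels(x$pops), "populations\n")
  cat("  populations:", paste(levels(x$pops), collapse = ", "), "\n")
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing genotypes: %.1f%%; coordinates: %s\n", 100 * miss,
              if (is.null(x$coords)) "none" else "present"))
  invisible(x)
}

#' Number of individuals / loci
#' @param G a [genotype_matrix()].
#' @return integer count.
#' @export
n_ind <- function(G) nrow(G$a1)

#' @rdname n_ind
#' @export
n_loc <- function(G) ncol(G$a1)

#' Subset a genotype matrix by individuals
#'
#' @param x a [genotype_matrix()].
#' @param i integer, logical or character index of individuals to keep.
#' @param ... unused.
#' @return a `genotype_matrix` with the selected individuals.
#' @export
`[.genotype_matrix` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$ids)
  genotype_matrix(x$a1[i, , drop = FALSE], x$a2[i, , drop = FALSE],
                  ids = x$ids[i], pops = as.character(x$pops)[i],
                  loci = x$loci,
                  coords = if (!is.null(x$coords)) x$coords[i, , drop = FALSE])
}

#' Extract the individuals of one population
#' @param G a [genotype_matrix()].
#' @param population a population label present in `G`.
#' @return a `genotype_matrix` restricted to that population.
#' @export
pop_subset <- function(G, population) {
  if (!population %in% levels(G$pops))
    stop("unknown population: ", population)
  G[which(G$pops == population)]
}

#' @method all.equal genotype_matrix
#' @export
all.equal.genotype_matrix <- function(target, current, ...) {
  msg <- character()
  for (f in c("a1", "a2", "ids", "loci")) {
    ae <- all.equal(target[[f]], current[[f]], ...)
    if (!isTRUE(ae)) msg <- c(msg, paste0(f, ": ", paste(ae, collapse = "; ")))
  }
  if (!identical(as.character(target$pops), as.character(current$pops)))
    msg <- c(msg, "population labels differ")
  tc <- !is.null(target$coords); cc <- !is.null(current$coords)
  if (tc != cc) msg <- c(msg, "coordinate presence differs")
  if (tc && cc) {
    ae <- all.equal(unname(target$coords), unname(current$coords), ...)
    if (!isTRUE(ae)) msg <- c(msg, paste0("coords: ", paste(ae, collapse = "; ")))
  }
  if (length(msg)) msg else TRUE
}
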