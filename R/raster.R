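#' Single-band georeferenced grid
#'
#' A minimal north-up raster: a numeric matrix whose first row is the
#' northernmost row, plus the west/south corner of the grid, the (square)
#' cell size in decimal degrees and a no-data marker. Cell extent is
#' half-open `[west, east) x (south, north]`, so every point belongs to
#' exactly one cell.
#'
#' @param values numeric matrix (rows north to south).
#' @param west,south coordinates of the lower-left corner of the grid.
#' @param cell_size cell size in decimal degrees.
#' @param nodata value used to mark no-data on disk (stored as `NA` in
#'   memory).
#' @return an object of class `env_raster`.
#' @export
env_raster <- function(values, west, south, cell_size, nodata = -9999) {
  values <- as.matrix(values)
  structure(list(values = values, west = west, south = south,
                 cell_size = cell_size, nodata = nodata),
            class = "env_raster")
}

#' @export
print.env_raster <- function(x, ...) {
  cat(sprintf("env_raster: %d rows x %d cols, cell %.6f deg, origin (%.4f, %.4f)\n",
              nrow(x$values), ncol(x$values), x$cell_size, x$west, x$south))
  cat(sprintf("  values: [%.4g, %.4g], %d no-data cells\n",
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE)),
              sum(is.na(x$values))))
  invisible(x)
}

#' Cell-center coordinates of a raster
#'
#' @param r an [env_raster()].
#' @return a list with vectors `lon` (west to east) and `lat` (north to
#'   south, matching row order), and a function `grid()` returning the full
#'   cells data.frame (`row`, `col`, `lon`, `lat`, `value`).
#' @export
cell_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  lon <- r$west + (seq_len(nc) - 0.5) * r$cell_size
  lat <- r$south + (nr - seq_len(nr) + 0.5) * r$cell_size
  list(lon = lon, lat = lat,
       grid = function() {
         data.frame(row = rep(seq_len(nr), nc),
                    col = rep(seq_len(nc), each = nr),
                    lon = rep(lon, each = nr), lat = rep(lat, nc),
                    value = as.vector(r$values))
       })
}

#' Read / write an ESRI ASCII grid
#'
#' The plain-text single-band raster interchange format: a six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`)
#' followed by rows of values from north to south.
#'
#' @param path file path.
#' @return [read_raster()]: an [env_raster()]; [write_raster()]: `path`,
#'   invisibly.
#' @export
read_raster <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("raster parse error: incomplete ESRI ASCII header in ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("raster parse error: expected ", hdr$ncols * hdr$nrows,
         " values, got ", length(vals))
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  env_raster(m, west = hdr$xllcorner, south = hdr$yllcorner,
             cell_size = hdr$cellsize, nodata = nodata)
}

#' @rdname read_raster
#' @param r an [env_raster()] to write.
#' @export
write_raster <- function(r, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste("ncols", ncol(r$values)),
               paste("nrows", nrow(r$values)),
               paste("xllcorner", format(r$west, digits = 15)),
               paste("yllcorner", format(r$south, digits = 15)),
               paste("cellsize", format(r$cell_size, digits = 15)),
               paste("NODATA_value", r$nodata)), con)
  m <- r$values
  m[is.na(m)] <- r$nodata
  writeLines(apply(m, 1, function(row) paste(format(row, digits = 15,
                                                    trim = TRUE),
                                             collapse = " ")), con)
  invisible(path)
}

#' Stack of co-registered environmental layers
#'
#' @param layers named list of [env_raster()] objects sharing extent and
#'   resolution. No-data masks are unioned: a cell missing in any layer is
#'   treated as missing in all.
#' @return an object of class `env_stack`.
#' @export
env_stack <- function(layers) {
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    stop("layers must be named")
  g <- layers[[1]]
  for (l in layers[-1]) {
    if (!isTRUE(all.equal(c(dim(l$values), l$west, l$south, l$cell_size),
                          c(dim(g$values), g$west, g$south, g$cell_size))))
      stop("layers are not co-registered (extent/resolution mismatch)")
  }
  mask <- Reduce(`|`, lapply(layers, function(l) is.na(l$values)))
  layers <- lapply(layers, function(l) { l$values[mask] <- NA; l })
  structure(list(layers = layers, mask = mask), class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  g <- x$layers[[1]]
  cat("env_stack:", length(x$layers), "layers (",
      paste(names(x$layers), collapse = ", "), ")\n")
  print(g)
  invisible(x)
}

#' Extract cell values of a stack as a data.frame
#'
#' @param stack an [env_stack()].
#' @param keep_na keep cells that are no-data in any layer?
#' @return data.frame with `row`, `col`, `lon`, `lat` and one column per
#'   layer.
#' @export
stack_cells <- function(stack, keep_na = FALSE) {
  g <- stack$layers[[1]]
  df <- cell_centers(g)$grid()
  df$value <- NULL
  for (nm in names(stack$layers))
    df[[nm]] <- as.vector(stack$layers[[nm]]$values)
  if (!keep_na) df <- df[!as.vector(stack$mask), , drop = FALSE]
  df
}

#' Look up the values of a stack at point locations
#'
#' Points are assigned to cells by the half-open cell-extent convention.
#'
#' @param stack an [env_stack()].
#' @param lon,lat point coordinates.
#' @return data.frame of layer values (NA outside the grid or on no-data).
#' @export
stack_extract <- function(stack, lon, lat) {
  g <- stack$layers[[1]]
  nr <- nrow(g$values); nc <- ncol(g$values)
  col <- floor((lon - g$west) / g$cell_size) + 1L
  row <- nr - floor((lat - g$south - 1e-12) / g$cell_size)
  ok <- col >= 1 & col <= nc & row >= 1 & row <= nr
  out <- as.data.frame(lapply(stack$layers, function(l) {
    v <- rep(NA_real_, length(lon))
    v[ok] <- l$values[cbind(row[ok], col[ok])]
    v
  }))
  names(out) <- names(stack$layers)
  attr(out, "cell") <- data.frame(row = row, col = col)
  out
}

#' Thickness-weighted mean of per-depth soil layers
#'
#' Collapses values reported for the 0-5, 5-15, 15-30, 30-60 and 60-100 cm
#' depth intervals into a single 0-100 cm layer, weighting each interval by
#' its thickness (0.05, 0.10, 0.15, 0.30, 0.40). A cell missing any depth is
#' no-data in the result.
#'
#' @param layers list of five co-registered [env_raster()] objects ordered
#'   shallow to deep.
#' @param weights layer weights; the defaults sum to 1 exactly.
#' @return an [env_raster()].
#' @export
soil_depth_mean <- function(layers, weights = c(0.05, 0.1, 0.15, 0.3, 0.4)) {
  if (length(layers) != length(weights))
    stop("need one layer per depth interval (", length(weights), ")")
  g <- layers[[1]]
  acc <- matrix(0, nrow(g$values), ncol(g$values))
  for (j in seq_along(layers)) {
    if (!isTRUE(all.equal(dim(layers[[j]]$values), dim(g$values))))
      stop("soil layers are not co-registered")
    acc <- acc + weights[j] * layers[[j]]$values
  }
  acc <- acc / sum(weights)
  env_raster(acc, g$west, g$south, g$cell_size, g$nodata)
}
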