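#' Read a GenePop file
#'
#' Parses the GenePop 4.x dialect: a free-text title line, one locus name per
#' line (or a single comma-separated line), `POP` separators, and genotype
#' rows `id , 152156 142142 ...`. Two- and three-digit allele encodings are
#' auto-detected per file; `0000`/`000000` is missing. Population labels are
#' taken from a `pops: A,B,...` tag in the title line when present (written by
#' [write_genepop()]), otherwise `pop_1`, `pop_2`, ... in file order.
#'
#' @param path path to a `.gen` file.
#' @return a [genotype_matrix()] (without coordinates; GenePop carries none).
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 3) stop("GenePop parse error: file too short")
  title <- lines[1]
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("GenePop parse error: no POP line found")
  loc_lines <- lines[2:(first_pop - 1)]
  loci <- trimws(unlist(strsplit(loc_lines, ",")))
  loci <- loci[nzchar(loci)]
  L <- length(loci)
  if (L == 0) stop("GenePop parse error: no locus names before first POP (line ",
                   first_pop, ")")

  pop_breaks <- which(is_pop)
  rows <- list(); row_pop <- integer(); row_id <- character(); row_line <- integer()
  pop_idx <- 0L
  for (i in seq(first_pop, length(lines))) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (is_pop[i]) { pop_idx <- pop_idx + 1L; next }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2) stop("GenePop parse error at line ", i,
                                ": expected 'id , genotypes'")
    id <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) != L)
      stop("GenePop parse error at line ", i, ": ", length(toks),
           " genotypes for ", L, " loci")
    rows[[length(rows) + 1L]] <- toks
    row_pop <- c(row_pop, pop_idx); row_id <- c(row_id, id)
    row_line <- c(row_line, i)
  }
  if (!length(rows)) stop("GenePop parse error: no genotype rows")

  widths <- unique(nchar(unlist(rows)))
  if (length(widths) != 1 || !widths %in% c(4L, 6L))
    stop("GenePop parse error: unknown allele encoding (token widths: ",
         paste(widths, collapse = ","), "); expected uniform 4 or 6 digits")
  w <- widths / 2L
  n <- length(rows)
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  for (r in seq_len(n)) {
    toks <- rows[[r]]
    if (any(grepl("[^0-9]", toks)))
      stop("GenePop parse error at line ", row_line[r], ": non-numeric genotype")
    x1 <- as.integer(substr(toks, 1L, w))
    x2 <- as.integer(substr(toks, w + 1L, 2L * w))
    both0 <- x1 == 0L & x2 == 0L
    if (any(xor(x1 == 0L, x2 == 0L)))
      stop("GenePop parse error at line ", row_line[r],
           ": half-missing genotype (one allele coded 0)")
    x1[both0] <- NA_integer_; x2[both0] <- NA_integer_
    a1[r, ] <- x1; a2[r, ] <- x2
  }

  pop_labels <- paste0("pop_", seq_len(max(row_pop)))
  tag <- regmatches(title, regexpr("pops:\\s*[^;]+", title))
  if (length(tag)) {
    lab <- trimws(strsplit(sub("pops:\\s*", "", tag), ",")[[1]])
    if (length(lab) == max(row_pop)) pop_labels <- lab
  }
  genotype_matrix(a1, a2, ids = row_id, pops = pop_labels[row_pop], loci = loci)
}

#' Write a GenePop file
#'
#' Emits 3-digit encoding by default (2-digit if all allele codes fit).
#' Population labels are recorded in the title line (`pops: A,B,...`) so that
#' [read_genepop()] round-trips them; the file remains valid for other GenePop
#' consumers, which ignore the title. Coordinates are not representable in
#' GenePop and are dropped.
#'
#' @param G a [genotype_matrix()].
#' @param path output path.
#' @param title optional free-text prefix for the title line.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(G, path, title = "divscape export") {
  mx <- suppressWarnings(max(c(G$a1, G$a2), na.rm = TRUE))
  w <- if (is.finite(mx) && mx <= 99) 2L else 3L
  if (is.finite(mx) && mx > 999)
    stop("allele codes exceed 999; not representable in GenePop 3-digit encoding")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0(title, "; pops: ", paste(levels(G$pops), collapse = ",")), con)
  writeLines(G$loci, con)
  fmt <- function(a) ifelse(is.na(a), strrep("0", w), formatC(a, width = w, flag = "0"))
  for (p in levels(G$pops)) {
    writeLines("POP", con)
    idx <- which(G$pops == p)
    for (i in idx) {
      gt <- paste0(fmt(G$a1[i, ]), fmt(G$a2[i, ]))
      writeLines(paste0(G$ids[i], " , ", paste(gt, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Default column mapping for tabular genotype files
#'
#' Describes a wide CSV with two allele columns per locus. `allele_suffix`
#' gives the suffixes appended to each locus name for the two allele columns;
#' loci are auto-detected from paired columns when `loci = NULL`.
#'
#' @param id,pop,lon,lat column names for identifiers, population labels and
#'   coordinates (`lon`/`lat` may be `NULL` for files without coordinates).
#' @param loci character vector of locus names, or `NULL` to auto-detect.
#' @param allele_suffix length-2 character vector of allele column suffixes.
#' @return a list usable as the `dialect` argument of [read_genotype_csv()].
#' @export
csv_dialect <- function(id = "id", pop = "pop", lon = "lon", lat = "lat",
                        loci = NULL, allele_suffix = c("_1", "_2")) {
  list(id = id, pop = pop, lon = lon, lat = lat, loci = loci,
       allele_suffix = allele_suffix)
}

#' Read genotypes from a wide CSV table
#'
#' @param path path to a CSV file.
#' @param dialect a [csv_dialect()] naming the id/pop/coordinate columns and
#'   the per-locus allele column suffixes.
#' @return a [genotype_matrix()] with coordinates attached when present.
#' @export
read_genotype_csv <- function(path, dialect = csv_dialect()) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c(dialect$id, dialect$pop)) {
    if (!col %in% names(df)) stop("config error: mapped column '", col,
                                  "' not found in ", path)
  }
  sfx <- dialect$allele_suffix
  loci <- dialect$loci
  if (is.null(loci)) {
    c1 <- grep(paste0(gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", sfx[1]), "$"),
               names(df), value = TRUE)
    loci <- sub(paste0(gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", sfx[1]), "$"),
                "", c1)
    loci <- loci[paste0(loci, sfx[2]) %in% names(df)]
    if (!length(loci)) stop("config error: no paired allele columns ('<locus>",
                            sfx[1], "', '<locus>", sfx[2], "') found")
  }
  for (l in loci) for (s in sfx) {
    if (!paste0(l, s) %in% names(df))
      stop("config error: mapped column '", paste0(l, s), "' not found")
  }
  n <- nrow(df)
  get_alleles <- function(s) {
    m <- sapply(loci, function(l) {
      v <- df[[paste0(l, s)]]
      if (is.character(v)) v[!nzchar(trimws(v))] <- NA
      vn <- suppressWarnings(as.numeric(v))
      if (any(!is.na(v) & is.na(vn) & nzchar(trimws(as.character(v)))))
        stop("parse error: non-numeric allele in column '", paste0(l, s), "'")
      as.integer(vn)
    })
    matrix(m, nrow = n)
  }
  a1 <- get_alleles(sfx[1]); a2 <- get_alleles(sfx[2])
  coords <- NULL
  if (!is.null(dialect$lon) && !is.null(dialect$lat) &&
      all(c(dialect$lon, dialect$lat) %in% names(df))) {
    coords <- cbind(lon = as.numeric(df[[dialect$lon]]),
                    lat = as.numeric(df[[dialect$lat]]))
    if (all(is.na(coords))) coords <- NULL
  }
  genotype_matrix(a1, a2, ids = as.character(df[[dialect$id]]),
                  pops = df[[dialect$pop]], loci = loci, coords = coords)
}

#' Write genotypes to a wide CSV table
#'
#' @inheritParams read_genotype_csv
#' @param G a [genotype_matrix()].
#' @return `path`, invisibly.
#' @export
write_genotype_csv <- function(G, path, dialect = csv_dialect()) {
  df <- data.frame(G$ids, as.character(G$pops), stringsAsFactors = FALSE)
  names(df) <- c(dialect$id, dialect$pop)
  if (!is.null(G$coords)) {
    df[[dialect$lon]] <- G$coords[, "lon"]
    df[[dialect$lat]] <- G$coords[, "lat"]
  }
  for (j in seq_along(G$loci)) {
    df[[paste0(G$loci[j], dialect$allele_suffix[1])]] <- G$a1[, j]
    df[[paste0(G$loci[j], dialect$allele_suffix[2])]] <- G$a2[, j]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read presence/occurrence points
#'
#' @param path CSV file with `lon` and `lat` columns (any further columns are
#'   kept; a `source` column tags provenance).
#' @param dedup_cells if `TRUE`, keep at most one point per grid cell.
#' @param cell_size grid cell size in decimal degrees used for deduplication
#'   (default 30 arc seconds).
#' @return a data.frame with columns `lon`, `lat` (and any extras).
#' @export
read_occurrences <- function(path, dedup_cells = FALSE, cell_size = 1 / 120) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("lon", "lat") %in% names(df)))
    stop("occurrence file must have 'lon' and 'lat' columns")
  if (any(df$lon < -180 | df$lon > 180 | df$lat < -90 | df$lat > 90, na.rm = TRUE))
    stop("validation error: coordinates out of range")
  if (!"source" %in% names(df)) df$source <- "unknown"
  if (dedup_cells) df <- dedup_occurrences(df, cell_size)
  df
}

#' Deduplicate occurrences to one point per grid cell
#'
#' Cells are addressed on the global lattice aligned to integer degrees; the
#' first point encountered in each cell is retained.
#'
#' @param occ data.frame with `lon`, `lat`.
#' @param cell_size cell size in degrees.
#' @return the deduplicated data.frame.
#' @export
dedup_occurrences <- function(occ, cell_size = 1 / 120) {
  key <- paste(floor(occ$lon / cell_size), floor(occ$lat / cell_size))
  occ[!duplicated(key), , drop = FALSE]
}
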