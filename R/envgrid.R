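#' @include AllGenerics.R
NULL

#' Construct an EnvGrid from matrices
#'
#' Builds the aligned raster stack used throughout the package. Any cell
#' that is \code{NA} in any input layer is masked in all layers (the stack
#' is treated as one coverage area).
#'
#' @param layers named list of numeric matrices, all the same shape; row 1
#'   is the northernmost row.
#' @param xll,yll coordinates of the lower-left corner of the grid (degrees).
#' @param cellSize cell edge length in degrees.
#' @param crs CRS identifier (informational).
#' @return an [EnvGrid-class].
#' @examples
#' g <- envGrid(list(a = matrix(1, 4, 5), b = matrix(2, 4, 5)))
#' nLayers(g)
#' @export
envGrid <- function(layers, xll = 0, yll = 0, cellSize = 1,
                    crs = "EPSG:4326") {
  if (!length(layers)) stop("at least one layer is required")
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    stop("layers must be named")
  dims <- lapply(layers, dim)
  if (length(unique(dims)) != 1L)
    stop("alignment error: all layers must share the same shape")
  d <- dims[[1]]
  vals <- array(NA_real_, dim = c(d, length(layers)))
  for (i in seq_along(layers)) vals[, , i] <- layers[[i]]
  mask <- apply(!is.na(vals), c(1, 2), all)
  # apply the union-of-nodata mask once, at construction
  vals[array(rep(!mask, length(layers)), dim = dim(vals))] <- NA_real_
  new("EnvGrid", values = vals, layerNames = names(layers), mask = mask,
      xll = as.numeric(xll), yll = as.numeric(yll),
      cellSize = as.numeric(cellSize), crs = crs)
}

#' @rdname EnvGrid-accessors
#' @export
setMethod("layerNames", "EnvGrid", function(x) x@layerNames)
#' @rdname EnvGrid-accessors
#' @export
setMethod("gridValues", "EnvGrid", function(x) {
  dimnames(x@values) <- list(NULL, NULL, x@layerNames)
  x@values
})
#' @rdname EnvGrid-accessors
#' @export
setMethod("gridMask", "EnvGrid", function(x) x@mask)
#' @rdname EnvGrid-accessors
#' @export
setMethod("cellSize", "EnvGrid", function(x) x@cellSize)
#' @rdname EnvGrid-accessors
#' @export
setMethod("gridExtent", "EnvGrid", function(x) {
  d <- dim(x@values)
  c(xmin = x@xll, xmax = x@xll + d[2] * x@cellSize,
    ymin = x@yll, ymax = x@yll + d[1] * x@cellSize)
})
#' @rdname EnvGrid-accessors
#' @export
setMethod("nLayers", "EnvGrid", function(x) dim(x@values)[3])

setMethod("show", "EnvGrid", function(object) {
  d <- dim(object@values)
  cat("EnvGrid:", d[3], "layer(s),", d[1], "x", d[2], "cells\n")
  cat("  layers:", paste(utils::head(object@layerNames, 8), collapse = ", "),
      if (d[3] > 8) "...\n" else "\n")
  ext <- gridExtent(object)
  cat(sprintf("  extent: x [%g, %g], y [%g, %g], cell %g deg (%s)\n",
              ext[1], ext[2], ext[3], ext[4], object@cellSize, object@crs))
  cat(sprintf("  valid cells: %d / %d\n", sum(object@mask), prod(d[1:2])))
})

#' Extract one layer of an EnvGrid as a matrix
#'
#' @param x an [EnvGrid-class].
#' @param layer layer name or index.
#' @return numeric matrix with \code{NA} at masked cells.
#' @export
gridLayer <- function(x, layer) {
  stopifnot(is(x, "EnvGrid"))
  if (is.character(layer)) {
    layer <- match(layer, x@layerNames)
    if (is.na(layer)) stop("unknown layer")
  }
  x@values[, , layer]
}

## ---- ESRI ASCII grid I/O -------------------------------------------------

parseAsciiHeader <- function(lines) {
  hdr <- list(nodata_value = -9999)
  n <- 0L
  for (ln in lines) {
    toks <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    key <- tolower(toks[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                   "yllcenter", "cellsize", "nodata_value")) {
      hdr[[key]] <- as.numeric(toks[2])
      n <- n + 1L
    } else break
  }
  hdr$n_header <- n
  if (is.null(hdr$ncols) || is.null(hdr$nrows) || is.null(hdr$cellsize))
    stop("malformed ASCII grid header")
  if (!is.null(hdr$xllcenter)) hdr$xllcorner <- hdr$xllcenter - hdr$cellsize / 2
  if (!is.null(hdr$yllcenter)) hdr$yllcorner <- hdr$yllcenter - hdr$cellsize / 2
  hdr
}

#' Read a single ESRI ASCII grid file
#'
#' @param path path to a \code{.asc} file.
#' @return list with \code{values} (numeric matrix, row 1 = north, nodata as
#'   \code{NA}), \code{xll}, \code{yll}, \code{cellSize}.
#' @export
readAsciiGrid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 7L, warn = FALSE)
  hdr <- parseAsciiHeader(lines)
  vals <- scan(path, what = double(), skip = hdr$n_header, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid data does not match header dimensions: ", path)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  list(values = m, xll = hdr$xllcorner, yll = hdr$yllcorner,
       cellSize = hdr$cellsize)
}

#' Write a matrix as an ESRI ASCII grid file
#'
#' @param values numeric matrix, row 1 = north; \code{NA} written as the
#'   nodata value.
#' @param path output path.
#' @param xll,yll lower-left corner coordinates.
#' @param cellSize cell edge in degrees.
#' @param nodata numeric nodata sentinel.
#' @return the path, invisibly.
#' @export
writeAsciiGrid <- function(values, path, xll = 0, yll = 0, cellSize = 1,
                           nodata = -9999) {
  stopifnot(is.matrix(values))
  hdr <- c(
    paste("ncols", ncol(values)),
    paste("nrows", nrow(values)),
    paste("xllcorner", format(xll, digits = 15)),
    paste("yllcorner", format(yll, digits = 15)),
    paste("cellsize", format(cellSize, digits = 15)),
    paste("NODATA_value", nodata)
  )
  v <- values
  v[is.na(v)] <- nodata
  body <- apply(v, 1, function(r) paste(format(r, digits = 10, trim = TRUE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write every layer of an EnvGrid as ASCII grids
#'
#' @param grid an [EnvGrid-class].
#' @param dir output directory (created if missing).
#' @return character vector of written paths, invisibly.
#' @export
writeEnvGrid <- function(grid, dir) {
  stopifnot(is(grid, "EnvGrid"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(grid@layerNames, ".asc"))
  for (i in seq_along(paths))
    writeAsciiGrid(grid@values[, , i], paths[i], xll = grid@xll,
                   yll = grid@yll, cellSize = grid@cellSize)
  invisible(paths)
}

#' Read and align a stack of ASCII grid rasters
#'
#' All files must share grid shape, origin and cell size; the nodata mask is
#' the union across layers, so any cell missing in one layer is treated as
#' missing in all. Layer order follows input order; layer names default to
#' the file base names.
#'
#' @param paths character vector of \code{.asc} files.
#' @param clipExtent optional \code{c(xmin, xmax, ymin, ymax)} bounding box;
#'   cells whose centres fall inside are retained.
#' @param layerNames optional layer names (default: file base names).
#' @return an [EnvGrid-class].
#' @export
readEnvGrid <- function(paths, clipExtent = NULL, layerNames = NULL) {
  if (!length(paths)) stop("at least one raster file is required")
  if (is.null(layerNames))
    layerNames <- sub("\\.[^.]*$", "", basename(paths))
  rasters <- lapply(paths, readAsciiGrid)
  ref <- rasters[[1]]
  for (r in rasters[-1]) {
    if (!identical(dim(r$values), dim(ref$values)) ||
        abs(r$xll - ref$xll) > 1e-9 || abs(r$yll - ref$yll) > 1e-9 ||
        abs(r$cellSize - ref$cellSize) > 1e-12)
      stop("alignment error: rasters do not share grid shape/origin/cell size")
  }
  layers <- lapply(rasters, `[[`, "values")
  names(layers) <- layerNames
  g <- envGrid(layers, xll = ref$xll, yll = ref$yll, cellSize = ref$cellSize)
  if (!is.null(clipExtent)) g <- clipGrid(g, clipExtent) else g
}

#' Clip an EnvGrid to a bounding box
#'
#' Retains cells whose centres fall inside \code{extent}.
#'
#' @param grid an [EnvGrid-class].
#' @param extent \code{c(xmin, xmax, ymin, ymax)}.
#' @return the clipped [EnvGrid-class].
#' @export
clipGrid <- function(grid, extent) {
  stopifnot(is(grid, "EnvGrid"), length(extent) == 4)
  d <- dim(grid@values)
  cs <- grid@cellSize
  xc <- grid@xll + (seq_len(d[2]) - 0.5) * cs
  yc <- grid@yll + (d[1] - seq_len(d[1]) + 0.5) * cs  # row 1 = north
  keepc <- which(xc >= extent[1] & xc <= extent[2])
  keepr <- which(yc >= extent[3] & yc <= extent[4])
  if (!length(keepc) || !length(keepr))
    stop("extent error: clip extent contains no cells")
  vals <- grid@values[keepr, keepc, , drop = FALSE]
  layers <- lapply(seq_len(d[3]), function(i) vals[, , i, drop = TRUE])
  if (length(keepr) == 1L || length(keepc) == 1L)
    layers <- lapply(layers, matrix, nrow = length(keepr), ncol = length(keepc))
  names(layers) <- grid@layerNames
  envGrid(layers,
          xll = grid@xll + (min(keepc) - 1) * cs,
          yll = grid@yll + (d[1] - max(keepr)) * cs,
          cellSize = cs, crs = grid@crs)
}

## ---- point / cell mapping ------------------------------------------------

# Map lon/lat to (row, col); half-open cell intervals, row 1 at the
# north-west corner. Returns NA for out-of-extent points.
pointToCell <- function(grid, lon, lat) {
  d <- dim(grid@values)
  cs <- grid@cellSize
  col <- floor((lon - grid@xll) / cs) + 1
  rowFromS <- floor((lat - grid@yll) / cs)  # 0-based from the south
  row <- d[1] - rowFromS
  bad <- col < 1 | col > d[2] | row < 1 | row > d[1]
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

cellCenter <- function(grid, row, col) {
  d <- dim(grid@values)
  cs <- grid@cellSize
  cbind(lon = grid@xll + (col - 0.5) * cs,
        lat = grid@yll + (d[1] - row + 0.5) * cs)
}

#' Extract predictor values at point locations
#'
#' Maps each point to its containing cell (half-open intervals, nearest-cell
#' lookup) and returns the layer values there. Points outside the extent or
#' on masked (nodata) cells are dropped; the returned matrix carries a
#' \code{"kept"} logical attribute aligned with the input points and a
#' \code{"report"} attribute with counts.
#'
#' @param grid an [EnvGrid-class].
#' @param points two-column matrix or data.frame of longitude, latitude in
#'   the grid CRS.
#' @return numeric matrix (kept points x layers) with attributes
#'   \code{kept} and \code{report}.
#' @export
gridExtract <- function(grid, points) {
  stopifnot(is(grid, "EnvGrid"))
  points <- as.matrix(points)[, 1:2, drop = FALSE]
  rc <- pointToCell(grid, points[, 1], points[, 2])
  inExtent <- !is.na(rc[, 1])
  onValid <- inExtent
  onValid[inExtent] <- grid@mask[rc[inExtent, , drop = FALSE]]
  if (!any(onValid))
    stop("empty-result error: no points fall on valid cells")
  d <- dim(grid@values)
  idx <- rc[onValid, , drop = FALSE]
  out <- vapply(seq_len(d[3]),
                function(i) grid@values[, , i][idx], numeric(sum(onValid)))
  out <- matrix(out, ncol = d[3],
                dimnames = list(NULL, grid@layerNames))
  attr(out, "kept") <- onValid
  attr(out, "report") <- list(
    n_points = nrow(points), n_kept = sum(onValid),
    n_outside = sum(!inExtent), n_nodata = sum(inExtent & !onValid))
  out
}

#' Sample background points uniformly from valid cells
#'
#' Draws \code{n} distinct valid (non-nodata) cells uniformly without
#' replacement and returns their centre coordinates, the standard
#' presence-background design with a 10,000-point default.
#'
#' @param grid an [EnvGrid-class].
#' @param n number of background points (default 10000).
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return data.frame with columns \code{lon}, \code{lat} and attribute
#'   \code{cells} (row/col indices).
#' @export
sampleBackground <- function(grid, n = 10000, seed = 1L) {
  stopifnot(is(grid, "EnvGrid"))
  valid <- which(grid@mask)
  if (n > length(valid))
    stop("capacity error: requested ", n, " background points but only ",
         length(valid), " valid cells")
  pick <- withLocalSeed(seed, {
    if (n == length(valid)) valid else sample(valid, n)
  })
  d <- dim(grid@values)
  row <- (pick - 1L) %% d[1] + 1L
  col <- (pick - 1L) %/% d[1] + 1L
  xy <- cellCenter(grid, row, col)
  out <- data.frame(lon = xy[, 1], lat = xy[, 2])
  attr(out, "cells") <- cbind(row = row, col = col)
  out
}

## ---- collinearity --------------------------------------------------------

#' Pairwise correlation and VIF report for a predictor matrix
#'
#' Computes the Pearson correlation matrix, its element-wise square, and
#' per-variable variance inflation factors
#' \eqn{VIF_j = 1 / (1 - R^2_j)} from regressing column j on all other
#' columns. Variables involved in perfect collinearity get an infinite VIF
#' (they are reported, not removed). Flags highlight \code{|r| > 0.8},
#' \code{r^2 > 0.8} and \code{VIF > 10}.
#'
#' @param x numeric matrix with column names, >= 2 columns and >= 3 rows.
#' @param rThreshold,r2Threshold,vifThreshold highlight thresholds.
#' @return list of class \code{"CollinearityReport"} with elements \code{r},
#'   \code{r2}, \code{vif}, \code{flags} (list of logical structures) and
#'   the thresholds.
#' @export
collinearity <- function(x, rThreshold = 0.8, r2Threshold = 0.8,
                         vifThreshold = 10) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("at least two columns are required")
  if (nrow(x) < 3) stop("at least three rows are required")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    warning("constant column(s): ", paste(colnames(x)[sds == 0], collapse = ", "),
            "; correlations reported as NA")
  r <- suppressWarnings(stats::cor(x))
  diag(r) <- ifelse(sds > 0, 1, NA_real_)
  vif <- vapply(seq_len(ncol(x)), function(j) {
    if (sds[j] == 0) return(NA_real_)
    others <- x[, -j, drop = FALSE]
    fit <- stats::lm.fit(cbind(1, others), x[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, j] - mean(x[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(x)
  r2 <- r^2
  flags <- list(r = abs(r) > rThreshold & row(r) != col(r),
                r2 = r2 > r2Threshold & row(r2) != col(r2),
                vif = vif > vifThreshold)
  structure(list(r = r, r2 = r2, vif = vif, flags = flags,
                 thresholds = c(r = rThreshold, r2 = r2Threshold,
                                vif = vifThreshold)),
            class = "CollinearityReport")
}

#' @export
print.CollinearityReport <- function(x, ...) {
  cat("Collinearity report (", ncol(x$r), " variables)\n", sep = "")
  cat("flagged |r| >", x$thresholds["r"], ":",
      sum(x$flags$r, na.rm = TRUE) / 2, "pairs\n")
  cat("flagged VIF >", x$thresholds["vif"], ":",
      paste(names(x$vif)[which(x$flags$vif)], collapse = ", "), "\n")
  invisible(x)
}

#' Write a collinearity report as CSV
#'
#' One row per variable: pairwise r and r-squared against every other
#' variable plus the variable's VIF, mirroring the usual wide layout of
#' such supplementary tables.
#'
#' @param report a \code{CollinearityReport}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeCollinearityCsv <- function(report, path) {
  df <- data.frame(variable = colnames(report$r),
                   round(report$r, 4),
                   vif = round(report$vif, 3), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
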