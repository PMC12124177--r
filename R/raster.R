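# Minimal single-band planar raster on km coordinates, with plain-text
# ESRI ASCII grid (.asc) input/output. Cell [i, j] of `values` is row i from
# the top (north) and column j from the left (west), matching the .asc layout.

#' Create a gridded covariate surface
#'
#' @param values numeric matrix (rows top-to-bottom).
#' @param xll,yll coordinates of the lower-left corner (km).
#' @param cellsize cell edge length (km).
#' @param name optional covariate name.
#' @return an object of class `ts_raster`.
#' @export
ts_raster <- function(values, xll = 0, yll = 0, cellsize = 1, name = NULL) {
  stopifnot(is.matrix(values), nrow(values) > 0, ncol(values) > 0,
            cellsize > 0)
  structure(list(values = values, xll = xll, yll = yll, cellsize = cellsize,
                 name = name),
            class = "ts_raster")
}

#' @export
print.ts_raster <- function(x, ...) {
  cat(sprintf("ts_raster%s: %d x %d cells, cellsize %g km, origin (%g, %g)\n",
              if (is.null(x$name)) "" else sprintf(" '%s'", x$name),
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll))
  invisible(x)
}

# x/y coordinates of cell centres.
raster_centers <- function(r) {
  nx <- ncol(r$values)
  ny <- nrow(r$values)
  list(x = r$xll + (seq_len(nx) - 0.5) * r$cellsize,
       y = r$yll + (ny - seq_len(ny) + 0.5) * r$cellsize)  # row 1 = top
}

raster_extent <- function(r) {
  c(xmin = r$xll, xmax = r$xll + ncol(r$values) * r$cellsize,
    ymin = r$yll, ymax = r$yll + nrow(r$values) * r$cellsize)
}

#' Raster values at point coordinates
#'
#' Nearest-cell lookup; points outside the raster extent are an error.
#'
#' @param r a [ts_raster()].
#' @param x,y point coordinates (km).
#' @return numeric vector of cell values.
#' @export
raster_value_at <- function(r, x, y) {
  ext <- raster_extent(r)
  if (any(x < ext["xmin"] | x > ext["xmax"] |
          y < ext["ymin"] | y > ext["ymax"])) {
    fail("point(s) outside the raster extent")
  }
  j <- pmin(pmax(ceiling((x - r$xll) / r$cellsize), 1L), ncol(r$values))
  i <- pmin(pmax(ceiling((ext["ymax"] - y) / r$cellsize), 1L), nrow(r$values))
  r$values[cbind(i, j)]
}

#' Write a raster as an ESRI ASCII grid
#'
#' @param r a [ts_raster()].
#' @param path output file path (conventionally `.asc`).
#' @export
write_ascii_grid <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(r$values)),
               sprintf("nrows %d", nrow(r$values)),
               sprintf("xllcorner %.10g", r$xll),
               sprintf("yllcorner %.10g", r$yll),
               sprintf("cellsize %.10g", r$cellsize),
               "NODATA_value -9999"), con)
  utils::write.table(r$values, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @param name optional covariate name to attach.
#' @return a [ts_raster()].
#' @export
read_ascii_grid <- function(path, name = NULL) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(tolower(hdr), "[[:space:]]+")
  vals <- stats::setNames(vapply(kv, function(p) as.numeric(p[2]), numeric(1)),
                          vapply(kv, `[`, "", 1))
  m <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == vals[["nrows"]], ncol(m) == vals[["ncols"]])
  ts_raster(m, xll = vals[["xllcorner"]], yll = vals[["yllcorner"]],
            cellsize = vals[["cellsize"]], name = name)
}
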