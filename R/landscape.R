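# Seasonal landscape-use areas at two spatial scales and covariate
# exposure. Landscape-scale use is the 95% kernel-density isopleth of a
# period's fixes (>= 25 fixes), a union of sex- and latitude-specific
# travel-distance discs (1-24 fixes), or the previous period's geometry
# carried forward (0 fixes). Home-range-scale exposure reads covariates at
# the fix locations themselves. All geometry is planar, in km.

# Sex- and latitude-band-specific buffer radii (km): average daily distance
# travelled, by latitude group.
BUFFER_RADII_KM <- matrix(
  c(4.4, 6.9,   # >65N     F, M
    3.2, 4.6,   # 55-65N
    2.1, 3.5),  # <55N
  nrow = 3, byrow = TRUE,
  dimnames = list(c(">65N", "55-65N", "<55N"), c("F", "M"))
)

# Bilinear interpolation of a grid surface at points; 0 outside the grid.
interp2 <- function(xg, yg, z, xp, yp) {
  nx <- length(xg)
  ny <- length(yg)
  out <- numeric(length(xp))
  i <- findInterval(xp, xg)
  j <- findInterval(yp, yg)
  ok <- i >= 1 & i < nx & j >= 1 & j < ny
  ii <- i[ok]
  jj <- j[ok]
  tx <- (xp[ok] - xg[ii]) / (xg[ii + 1] - xg[ii])
  ty <- (yp[ok] - yg[jj]) / (yg[jj + 1] - yg[jj])
  out[ok] <- z[cbind(ii, jj)] * (1 - tx) * (1 - ty) +
    z[cbind(ii + 1, jj)] * tx * (1 - ty) +
    z[cbind(ii, jj + 1)] * (1 - tx) * ty +
    z[cbind(ii + 1, jj + 1)] * tx * ty
  out
}

new_use_polygon <- function(method, support, area, polygons, n_fixes,
                            id = NA, period = NA) {
  structure(list(id = id, period = period, scale = "landscape",
                 method = method, support = support, area = area,
                 polygons = polygons, n_fixes = n_fixes),
            class = "use_polygon")
}

#' @export
print.use_polygon <- function(x, ...) {
  cat(sprintf("use_polygon [%s]: %s, area %.1f km^2, %d fixes\n",
              paste(x$id, x$period, sep = "/"), x$method, x$area, x$n_fixes))
  invisible(x)
}

# TRUE for points inside the use geometry.
use_contains <- function(use, x, y) {
  s <- use$support
  if (s$type == "kde") {
    interp2(s$x, s$y, s$z, x, y) >= s$level
  } else {
    ok <- rep(FALSE, length(x))
    for (i in seq_len(nrow(s$centers))) {
      ok <- ok | ((x - s$centers[i, 1])^2 + (y - s$centers[i, 2])^2 <=
                    s$radius^2)
    }
    ok
  }
}

#' Kernel-density home range (95% isopleth)
#'
#' Bivariate Gaussian kernel density estimate on a grid (normal-reference
#' bandwidth per axis by default), from which the smallest density level set
#' containing `level` of the estimated mass is taken as the use area.
#'
#' @param fixes data frame with `x_km`, `y_km` (>= 25 rows).
#' @param level isopleth mass level (default 0.95).
#' @param bandwidth optional `c(hx, hy)` bandwidths (passed to
#'   [MASS::kde2d()]); default normal-reference.
#' @param grid_n grid resolution per axis.
#' @return a `use_polygon` (method `"kde95"`) whose `polygons` element holds
#'   the isopleth contour rings.
#' @export
kde_home_range <- function(fixes, level = 0.95, bandwidth = NULL,
                           grid_n = 128) {
  x <- fixes$x_km
  y <- fixes$y_km
  if (length(x) < 25L) fail("kernel home ranges need at least 25 fixes")
  if (stats::sd(x) < 1e-9 || stats::sd(y) < 1e-9 ||
      abs(stats::cor(x, y)) > 1 - 1e-12) {
    fail("degenerate fixes: identical or collinear locations")
  }
  if (is.null(bandwidth)) {
    bandwidth <- c(MASS::bandwidth.nrd(x), MASS::bandwidth.nrd(y))
  }
  if (any(bandwidth <= 0)) fail("nonpositive KDE bandwidth")
  pad <- 3 * max(bandwidth)
  kd <- MASS::kde2d(x, y, h = bandwidth, n = grid_n,
                    lims = c(range(x) + c(-pad, pad),
                             range(y) + c(-pad, pad)))
  cell <- diff(kd$x[1:2]) * diff(kd$y[1:2])
  mass <- kd$z * cell
  ord <- order(kd$z, decreasing = TRUE)
  cum <- cumsum(mass[ord])
  cut_idx <- which(cum >= level * sum(mass))[1]
  lev <- kd$z[ord][cut_idx]
  area <- sum(kd$z >= lev) * cell
  rings <- grDevices::contourLines(kd$x, kd$y, kd$z, levels = lev)
  new_use_polygon("kde95",
                  support = list(type = "kde", x = kd$x, y = kd$y, z = kd$z,
                                 level = lev),
                  area = area, polygons = rings, n_fixes = length(x))
}

#' Distance-buffer use area
#'
#' Union of discs around each fix, with the sex- and latitude-band-specific
#' average daily travel distance as radius. Used for periods with fewer
#' than 25 fixes.
#'
#' @param fixes data frame with `x_km`, `y_km` (1 to 24 rows).
#' @param sex `"F"` or `"M"`.
#' @param latitude_band `">65N"`, `"55-65N"` or `"<55N"`.
#' @param grid_n resolution of the area-evaluation grid per axis.
#' @return a `use_polygon` (method `"buffer"`). The area is evaluated on a
#'   fine grid over the union of discs.
#' @export
buffer_use <- function(fixes, sex, latitude_band, grid_n = 256) {
  if (nrow(fixes) < 1L) fail("buffer use needs at least one fix")
  if (!sex %in% colnames(BUFFER_RADII_KM)) fail("unknown sex '%s'", sex)
  if (!latitude_band %in% rownames(BUFFER_RADII_KM)) {
    fail("unknown latitude band '%s'", latitude_band)
  }
  r <- BUFFER_RADII_KM[latitude_band, sex]
  centers <- cbind(fixes$x_km, fixes$y_km)
  gx <- seq(min(centers[, 1]) - r, max(centers[, 1]) + r, length.out = grid_n)
  gy <- seq(min(centers[, 2]) - r, max(centers[, 2]) + r, length.out = grid_n)
  cell <- diff(gx[1:2]) * diff(gy[1:2])
  pts <- expand.grid(x = gx, y = gy)
  inside <- rep(FALSE, nrow(pts))
  for (i in seq_len(nrow(centers))) {
    inside <- inside | ((pts$x - centers[i, 1])^2 +
                          (pts$y - centers[i, 2])^2 <= r^2)
  }
  new_use_polygon("buffer",
                  support = list(type = "buffer", centers = centers,
                                 radius = r),
                  area = sum(inside) * cell, polygons = list(),
                  n_fixes = nrow(fixes))
}

#' Carry a use area forward to a period without locations
#'
#' @param previous the previous period's `use_polygon`.
#' @return the same geometry with method `"carried_forward"`.
#' @export
carry_forward <- function(previous) {
  if (is.null(previous)) fail("no previous period to carry forward")
  stopifnot(inherits(previous, "use_polygon"))
  out <- previous
  out$method <- "carried_forward"
  out$n_fixes <- 0L
  out
}

#' Build seasonal use areas for one individual
#'
#' Applies the fix-count rule per seasonal period: >= 25 fixes gives a
#' kernel isopleth, 1-24 fixes a travel-distance buffer, 0 fixes carries
#' the previous period forward. A first period without fixes is dropped
#' with a warning.
#'
#' @param fixes the individual's fix table (`timestamp`, `x_km`, `y_km`).
#' @param periods data frame with `period` labels and `start`/`end` dates
#'   (half-open intervals).
#' @param sex,latitude_band see [buffer_use()].
#' @param kde_threshold fix count at and above which the kernel method is
#'   used (default 25).
#' @return named list of `use_polygon`s (periods without geometry omitted).
#' @export
build_use_polygons <- function(fixes, periods, sex, latitude_band,
                               kde_threshold = 25) {
  out <- list()
  prev <- NULL
  for (i in seq_len(nrow(periods))) {
    sel <- fixes$timestamp >= periods$start[i] &
      fixes$timestamp < periods$end[i]
    fx <- fixes[sel, , drop = FALSE]
    up <- if (nrow(fx) >= kde_threshold) {
      kde_home_range(fx)
    } else if (nrow(fx) >= 1L) {
      buffer_use(fx, sex, latitude_band)
    } else if (!is.null(prev)) {
      carry_forward(prev)
    } else {
      warning(sprintf("period '%s' has no fixes and no previous period; dropped",
                      periods$period[i]), call. = FALSE)
      NULL
    }
    if (!is.null(up)) {
      up$period <- periods$period[i]
      out[[as.character(periods$period[i])]] <- up
      prev <- up
    }
  }
  out
}

#' Extract covariate exposures
#'
#' Landscape scale: the mean of each raster over the cells inside the use
#' geometry. Home-range scale: the mean of the raster values at the fix
#' coordinates. One value per covariate.
#'
#' @param use a `use_polygon` (landscape scale) or a fix data frame with
#'   `x_km`, `y_km` (home-range scale).
#' @param rasters named list of [ts_raster()] covariate surfaces.
#' @param scale `"landscape"` or `"home_range"`.
#' @return named numeric vector of covariate means.
#' @export
extract_covariates <- function(use, rasters, scale = c("landscape",
                                                       "home_range")) {
  scale <- match.arg(scale)
  stopifnot(length(rasters) > 0)
  if (scale == "home_range") {
    stopifnot(is.data.frame(use))
    return(vapply(rasters, function(r) {
      mean(raster_value_at(r, use$x_km, use$y_km))
    }, numeric(1)))
  }
  stopifnot(inherits(use, "use_polygon"))
  vapply(rasters, function(r) {
    ctr <- raster_centers(r)
    grid <- expand.grid(x = ctr$x, y = ctr$y)
    inside <- use_contains(use, grid$x, grid$y)
    if (!any(inside)) fail("use geometry lies outside the raster extent")
    mean(raster_value_at(r, grid$x[inside], grid$y[inside]))
  }, numeric(1))
}

#' Principal-component reduction of covariate exposures
#'
#' Covariates are z-scored over rows, decomposed by PCA, and components
#' explaining at least `threshold` of the variance are retained. The sign
#' convention makes each component's largest-magnitude loading positive.
#'
#' @param X numeric matrix or data frame (rows = exposure records,
#'   columns = covariates; >= 3 rows, >= 2 columns).
#' @param threshold minimum variance fraction to retain (default 0.05).
#' @return an object of class `pc_basis`: list with `loadings`,
#'   `var_frac`, `retained` (component indices) and `scores`.
#' @export
pca_reduce <- function(X, threshold = 0.05) {
  X <- as.matrix(X)
  if (nrow(X) < 3L || ncol(X) < 2L) fail("PCA needs >= 3 rows and >= 2 columns")
  sds <- apply(X, 2, stats::sd)
  if (any(sds < 1e-12)) fail("constant covariate column(s): %s",
                             paste(colnames(X)[sds < 1e-12], collapse = ", "))
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  rot <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = rot, var_frac = var_frac,
                 retained = which(var_frac >= threshold), scores = scores),
            class = "pc_basis")
}

#' @export
print.pc_basis <- function(x, ...) {
  cat(sprintf("PCA: %d components, retained %s (variance %s)\n",
              length(x$var_frac),
              paste0("PC", x$retained, collapse = ", "),
              paste0(round(100 * x$var_frac[x$retained]), "%",
                     collapse = ", ")))
  invisible(x)
}
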