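#' Corner-elevation grid
#'
#' Elevations (m a.s.l.) at the corners of the quadrat lattice: a
#' (nrows + 1) x (ncols + 1) matrix for ncols x nrows quadrats of
#' `spacing` m (default 20), with row 1 the southern edge (y = 0) and column
#' 1 the western edge (x = 0).
#'
#' @param z numeric matrix of corner elevations (rows = south to north).
#' @param spacing quadrat edge length (m), default 20.
#' @return Object of class `"elevation_grid"`.
#' @export
elevation_grid <- function(z, spacing = 20) {
  z <- as.matrix(z)
  if (nrow(z) < 2 || ncol(z) < 2) stop("need at least 2 x 2 corners")
  if (any(!is.finite(z))) stop("corner elevations must be finite")
  structure(list(z = z, spacing = spacing,
                 nrows = nrow(z) - 1, ncols = ncol(z) - 1),
            class = "elevation_grid")
}

#' @rdname elevation_grid
#' @param path CSV file holding the corner matrix (no header, row 1 =
#'   southern edge).
#' @export
read_elevation_grid <- function(path, spacing = 20) {
  z <- as.matrix(utils::read.csv(path, header = FALSE))
  storage.mode(z) <- "double"
  elevation_grid(z, spacing)
}

#' @export
print.elevation_grid <- function(x, ...) {
  cat(sprintf("elevation grid: %d x %d quadrats of %g m, range %.1f-%.1f m\n",
              x$ncols, x$nrows, x$spacing, min(x$z), max(x$z)))
  invisible(x)
}

covariate_grid <- function(v, spacing, name) {
  structure(list(v = v, spacing = spacing, name = name,
                 nrows = nrow(v), ncols = ncol(v)),
            class = "covariate_grid")
}

#' @export
print.covariate_grid <- function(x, ...) {
  cat(sprintf("covariate grid '%s': %d x %d quadrats of %g m\n",
              x$name, x$ncols, x$nrows, x$spacing))
  invisible(x)
}

#' Quadrat-level topographic covariates
#'
#' Per-quadrat covariates from a corner-elevation grid, following the forest
#' dynamics plot (CTFS) conventions: `mean_elevation` is the mean of the four
#' corner elevations; `slope_covariate` is the mean angular slope (degrees)
#' of the four triangular planes defined by taking the quadrat corners three
#' at a time; `convexity` is the focal quadrat's mean elevation minus the
#' mean of its (up to 8) neighbours' mean elevations - positive on ridges,
#' negative in valleys. Edge quadrats use their available neighbours.
#'
#' @param grid an [elevation_grid()].
#' @return A covariate grid (matrix of per-quadrat values, row 1 = south).
#' @examples
#' z <- outer(0:5, 0:5, function(i, j) 20 * j * tan(30 * pi / 180))
#' g <- elevation_grid(z)
#' slope_covariate(g)$v[1, 1] # 30 degrees everywhere
#' @export
mean_elevation <- function(grid) {
  stopifnot(inherits(grid, "elevation_grid"))
  z <- grid$z
  nr <- grid$nrows; nc <- grid$ncols
  v <- (z[1:nr, 1:nc] + z[1:nr, 2:(nc + 1)] +
          z[2:(nr + 1), 1:nc] + z[2:(nr + 1), 2:(nc + 1)]) / 4
  covariate_grid(matrix(v, nr, nc), grid$spacing, "mean_elevation")
}

#' @rdname mean_elevation
#' @export
slope_covariate <- function(grid) {
  stopifnot(inherits(grid, "elevation_grid"))
  z <- grid$z
  s <- grid$spacing
  nr <- grid$nrows; nc <- grid$ncols
  v <- matrix(0, nr, nc)
  # corner offsets of one quadrat: 00 (SW), 10 (SE), 01 (NW), 11 (NE)
  for (i in 1:nr) for (j in 1:nc) {
    p <- rbind(c(0, 0, z[i, j]), c(s, 0, z[i, j + 1]),
               c(0, s, z[i + 1, j]), c(s, s, z[i + 1, j + 1]))
    tri <- combn(4, 3)
    ang <- apply(tri, 2, function(k) {
      a <- p[k[2], ] - p[k[1], ]
      b <- p[k[3], ] - p[k[1], ]
      nrm <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
               a[1] * b[2] - a[2] * b[1])
      acos(abs(nrm[3]) / sqrt(sum(nrm^2))) * 180 / pi
    })
    v[i, j] <- mean(ang)
  }
  covariate_grid(v, s, "slope")
}

#' @rdname mean_elevation
#' @export
convexity <- function(grid) {
  stopifnot(inherits(grid, "elevation_grid"))
  me <- mean_elevation(grid)$v
  nr <- nrow(me); nc <- ncol(me)
  v <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    ii <- max(1, i - 1):min(nr, i + 1)
    jj <- max(1, j - 1):min(nc, j + 1)
    nb <- me[ii, jj]
    v[i, j] <- me[i, j] - (sum(nb) - me[i, j]) / (length(nb) - 1)
  }
  covariate_grid(v, grid$spacing, "convexity")
}

#' Covariate value at tree locations
#'
#' Looks up the covariate of the quadrat containing each location, with
#' half-open quadrat boundaries (a point at x = 20 m belongs to the second
#' column of 20 m quadrats); locations exactly on the upper plot boundary
#' are assigned to the last quadrat.
#'
#' @param cov a covariate grid from [mean_elevation()], [slope_covariate()]
#'   or [convexity()].
#' @param x,y coordinates (m).
#' @return numeric vector of covariate values.
#' @export
covariate_at <- function(cov, x, y) {
  stopifnot(inherits(cov, "covariate_grid"))
  s <- cov$spacing
  ix <- pmin(floor(x / s) + 1, cov$ncols)
  iy <- pmin(floor(y / s) + 1, cov$nrows)
  if (any(ix < 1 | iy < 1 | x > cov$ncols * s | y > cov$nrows * s | !is.finite(x)))
    stop("location outside the covariate grid")
  cov$v[cbind(iy, ix)]
}

#' @rdname covariate_at
#' @param grid an [elevation_grid()].
#' @return `topo_covariates()`: named list of the three covariate grids.
#' @export
topo_covariates <- function(grid) {
  list(mean_elevation = mean_elevation(grid),
       slope = slope_covariate(grid),
       convexity = convexity(grid))
}
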