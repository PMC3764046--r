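#' Distance grid for summary statistics
#'
#' Distances at which ring-based summary statistics are evaluated, together
#' with the ring width. The default analysis grid is a 1 m resolution with a
#' 3 m ring width over 0-50 m; ring inner radii are clipped at 0 so the r = 0
#' ring is the disk of radius w/2.
#'
#' @param r_values strictly increasing distances (m).
#' @param ring_width ring width w (m), > 0.
#' @return Object of class `"radial_grid"` with `r`, `w` and `step` (the
#'   median spacing of `r_values`).
#' @examples
#' radial_grid(0:50, 3)
#' @export
radial_grid <- function(r_values, ring_width = 3) {
  r_values <- as.numeric(r_values)
  if (length(r_values) < 1 || is.unsorted(r_values, strictly = TRUE))
    stop("r_values must be strictly increasing")
  if (any(r_values < 0)) stop("r_values must be >= 0")
  if (ring_width <= 0) stop("ring_width must be > 0")
  step <- if (length(r_values) > 1) stats::median(diff(r_values)) else ring_width
  structure(list(r = r_values, w = ring_width, step = step),
            class = "radial_grid")
}

#' Functional summary curve
#'
#' A summary statistic evaluated on a [radial_grid()]; the container used for
#' g(r), g12(r), K(r), L(r), K2(r), D(r) and Hs(r).
#'
#' @param grid a [radial_grid()].
#' @param values numeric vector, one value per grid distance.
#' @param statistic statistic name (e.g. `"g"`, `"g12"`, `"K2"`).
#' @param normalization the intensity used for normalisation, if any.
#' @return Object of class `"summary_curve"`.
#' @export
summary_curve <- function(grid, values, statistic = "g", normalization = NA_real_) {
  stopifnot(inherits(grid, "radial_grid"))
  if (length(values) != length(grid$r))
    stop("values and grid lengths differ")
  structure(list(grid = grid, r = grid$r, values = as.numeric(values),
                 statistic = statistic, normalization = normalization),
            class = "summary_curve")
}

#' @export
print.summary_curve <- function(x, ...) {
  cat(sprintf("summary curve %s(r): %d distances in [%g, %g] m, ring width %g m\n",
              x$statistic, length(x$r), min(x$r), max(x$r), x$grid$w))
  invisible(x)
}

#' @rdname summary_curve
#' @param x a `summary_curve`.
#' @param ... unused.
#' @export
as.data.frame.summary_curve <- function(x, ...) {
  data.frame(r = x$r, value = x$values, statistic = x$statistic)
}

#' Exact ring area inside a rectangular window
#'
#' Area of the annulus `max(0, r - w/2) <= |u - center| < r + w/2`
#' intersected with the window, by analytic circle-rectangle intersection
#' (difference of two disk-rectangle areas). This is the edge correction
#' used by all ring-based estimators.
#'
#' @param cx,cy ring centers (m), must lie inside the window.
#' @param r ring radius (m), recycled.
#' @param w ring width (m).
#' @param window a [rect_window()].
#' @return numeric vector of areas (m^2).
#' @examples
#' w <- rect_window(0, 0, 1000, 1000)
#' ring_area(500, 500, r = 3, w = 2, window = w) # full annulus pi*(16 - 4)
#' @export
ring_area <- function(cx, cy, r, w, window) {
  stopifnot(inherits(window, "pp_window"), w > 0, all(r >= 0))
  k <- max(length(cx), length(r))
  cx <- rep_len(cx, k); cy <- rep_len(cy, k); r <- rep_len(r, k)
  if (any(!in_window(cx, cy, window)))
    stop("ring center outside the window")
  outer <- cpp_disk_rect_area(cx, cy, r + w / 2, window$xmin, window$ymin,
                              window$xmax, window$ymax)
  inner <- cpp_disk_rect_area(cx, cy, pmax(0, r - w / 2), window$xmin,
                              window$ymin, window$xmax, window$ymax)
  outer - inner
}

ring_area_sums <- function(p, grid) {
  m <- cpp_ring_area_mat(p$x, p$y, grid$r, grid$w, p$window$xmin,
                         p$window$ymin, p$window$xmax, p$window$ymax)
  colSums(m)
}

#' Pair-correlation function (O-ring estimator)
#'
#' Edge-corrected estimate of the pair-correlation function g(r): the mean
#' density of further points at distance r from a typical point of the
#' pattern, divided by the overall intensity. g = 1 under complete spatial
#' randomness, > 1 under aggregation, < 1 under regularity. The estimator
#' sums ordered-pair ring counts over all points and divides by the summed
#' exact ring areas, then by the intensity n/|W|.
#'
#' @param p a [point_pattern()] with n >= 2.
#' @param grid a [radial_grid()].
#' @return A [summary_curve()] with statistic `"g"`.
#' @export
pair_correlation <- function(p, grid) {
  stopifnot(inherits(p, "point_pattern"), inherits(grid, "radial_grid"))
  if (p$n < 2) stop("pair correlation undefined for n < 2")
  cnt <- cpp_ring_counts(p$x, p$y, p$x, p$y, grid$r, grid$w, TRUE)
  ar <- ring_area_sums(p, grid)
  lambda <- intensity_of(p)
  g <- ifelse(ar > 0, cnt / ar / lambda, 0)
  summary_curve(grid, g, "g", lambda)
}

#' Bivariate pair-correlation function g12(r)
#'
#' Relative neighbourhood density of pattern 2 (e.g. offspring) at distance r
#' around the points of pattern 1 (e.g. adults), normalised by the overall
#' intensity of pattern 2. Values above 1 indicate attraction, below 1
#' repulsion/segregation.
#'
#' @param p1,p2 [point_pattern()]s sharing the same window; `p1` is the focal
#'   (antecedent) pattern.
#' @param grid a [radial_grid()].
#' @return A [summary_curve()] with statistic `"g12"`.
#' @export
cross_pair_correlation <- function(p1, p2, grid) {
  stopifnot(inherits(p1, "point_pattern"), inherits(p2, "point_pattern"))
  if (!identical(unclass(p1$window), unclass(p2$window)))
    stop("patterns must share the same window")
  if (p1$n < 1 || p2$n < 1) stop("both patterns must be non-empty")
  cnt <- cpp_ring_counts(p1$x, p1$y, p2$x, p2$y, grid$r, grid$w, FALSE)
  ar <- ring_area_sums(p1, grid)
  lambda2 <- intensity_of(p2)
  g <- ifelse(ar > 0, cnt / ar / lambda2, 0)
  summary_curve(grid, g, "g12", lambda2)
}

#' K2-function: finite-difference derivative of g(r)
#'
#' K2(r) = (g(r + dr) - g(r - dr)) / (2 dr), the expected change in relative
#' neighbourhood density over a small distance range. Unlike g itself, K2 is
#' largely insensitive to larger-scale intensity gradients; under CSR
#' envelopes, K2 below the lower envelope indicates aggregation (rapidly
#' decaying neighbourhood density) and above the upper envelope regularity.
#'
#' @param g a [summary_curve()] of g (or g12) on a uniformly spaced grid.
#' @param delta half-width dr of the finite difference (m); must be a
#'   multiple of the grid step.
#' @return A [summary_curve()] with statistic `"K2"`, on the interior
#'   distances where both r - dr and r + dr are available.
#' @examples
#' g <- summary_curve(radial_grid(0:4, 1), c(5, 3, 2, 1, 1))
#' k2_function(g, 1)$values # centered differences
#' @export
k2_function <- function(g, delta = 1) {
  stopifnot(inherits(g, "summary_curve"))
  r <- g$r
  step <- g$grid$step
  m <- round(delta / step)
  if (m < 1 || abs(m * step - delta) > 1e-9)
    stop("delta must be a positive multiple of the grid step")
  n <- length(r)
  if (n < 2 * m + 1) stop("grid too short for the requested delta")
  idx <- (m + 1):(n - m)
  vals <- (g$values[idx + m] - g$values[idx - m]) / (2 * delta)
  summary_curve(radial_grid(r[idx], g$grid$w), vals, "K2", g$normalization)
}

#' Nearest-neighbour distance distribution D^k(r)
#'
#' Fraction of pattern points whose k-th nearest neighbour lies within
#' distance r; nondecreasing from 0 to 1. No edge correction is applied: the
#' statistic is used for comparisons between patterns in the same window,
#' where the boundary bias is shared.
#'
#' @param p a [point_pattern()] with n > k.
#' @param grid a [radial_grid()].
#' @param k neighbour order (default 1).
#' @return A [summary_curve()] with statistic `"D1"`, `"D2"`, ...
#' @export
nn_distribution <- function(p, grid, k = 1) {
  stopifnot(inherits(p, "point_pattern"), k >= 1)
  if (p$n <= k) stop("nearest-neighbour distribution needs n > k")
  nd <- cpp_knn_dist(p$x, p$y, as.integer(k))[, k]
  vals <- vapply(grid$r, function(r) mean(nd <= r), 0)
  summary_curve(grid, vals, paste0("D", k), intensity_of(p))
}

#' Spherical contact distribution Hs(r)
#'
#' Fraction of systematic test locations (a deterministic square lattice)
#' whose nearest pattern point lies within distance r. Complements D(r):
#' together they summarise gaps and clumps of the pattern.
#'
#' @param p a [point_pattern()] with n >= 1.
#' @param grid a [radial_grid()].
#' @param spacing lattice spacing of test locations (m; default 1).
#' @return A [summary_curve()] with statistic `"Hs"`.
#' @export
spherical_contact <- function(p, grid, spacing = 1) {
  stopifnot(inherits(p, "point_pattern"), spacing > 0)
  if (p$n < 1) stop("spherical contact distribution needs n >= 1")
  lat <- test_lattice(p$window, spacing)
  nd <- cpp_nndist_to(lat$x, lat$y, p$x, p$y)
  vals <- vapply(grid$r, function(r) mean(nd <= r), 0)
  summary_curve(grid, vals, "Hs", intensity_of(p))
}

test_lattice <- function(window, spacing) {
  gx <- seq(window$xmin + spacing / 2, window$xmax, by = spacing)
  gy <- seq(window$ymin + spacing / 2, window$ymax, by = spacing)
  list(x = rep(gx, times = length(gy)), y = rep(gy, each = length(gx)))
}

#' Ripley's K and L functions
#'
#' Cumulative second-order statistics obtained by cumulating contiguous ring
#' counts with the same exact ring-area edge correction as
#' [pair_correlation()]: K(r) is the expected number of further points within
#' r of a typical point divided by the intensity, and L(r) = sqrt(K/pi) is
#' its variance-stabilised version with L(r) = r under CSR.
#'
#' @param p a [point_pattern()] with n >= 2.
#' @param grid a [radial_grid()]; rings of width `grid$step` centred at the
#'   grid distances are used, so a uniform grid gives contiguous rings.
#' @param statistic `"K"` or `"L"`.
#' @return A [summary_curve()].
#' @export
ripley_k <- function(p, grid, statistic = c("K", "L")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(p, "point_pattern"))
  if (p$n < 2) stop("K-function undefined for n < 2")
  s <- grid$step
  if (any(grid$r < s / 2)) stop("K grid values must be >= step/2")
  ctr <- grid$r - s / 2 # rings [r - step, r): K(r) cumulates distances < r
  cnt <- cpp_ring_counts(p$x, p$y, p$x, p$y, ctr, s, TRUE)
  gr <- radial_grid(ctr, s)
  ar <- ring_area_sums(p, gr)
  dens <- ifelse(ar > 0, cnt / ar, 0)
  ro <- ctr + s / 2
  ri <- pmax(0, ctr - s / 2)
  fullann <- pi * (ro^2 - ri^2)
  K <- cumsum(dens * fullann) / intensity_of(p)
  if (statistic == "K") summary_curve(grid, K, "K", intensity_of(p))
  else summary_curve(grid, sqrt(K / pi), "L", intensity_of(p))
}

#' Peak distance of a bivariate association curve
#'
#' The distance of maximal neighbourhood density: argmax of g12 over a
#' distance range (smallest r on ties), with the cumulative peak-distance
#' categories used to tabulate adult-offspring associations: `<1 m`,
#' `>=1 m`, `>=3 m`, `>=5 m`.
#'
#' @param g12 a [summary_curve()].
#' @param range distance range (m) searched, default `c(0, 50)`.
#' @return list with `peak_r`, `peak_value`, logical flags `ge1`, `ge3`,
#'   `ge5` and a `category` label.
#' @export
peak_distance <- function(g12, range = c(0, 50)) {
  stopifnot(inherits(g12, "summary_curve"))
  sel <- g12$r >= range[1] & g12$r <= range[2]
  if (!any(sel)) stop("empty curve over the requested range")
  r <- g12$r[sel]; v <- g12$values[sel]
  i <- which(v == max(v))[1] # smallest r on ties
  pk <- r[i]
  list(peak_r = pk, peak_value = v[i],
       ge1 = pk >= 1, ge3 = pk >= 3, ge5 = pk >= 5,
       category = if (pk < 1) "<1 m" else if (pk < 3) ">=1 m"
                  else if (pk < 5) ">=3 m" else ">=5 m")
}
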