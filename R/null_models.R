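#' Complete spatial randomness sampler
#'
#' Draws n independent uniform points in the window (a binomial process, i.e.
#' CSR conditioned on n). All null-model generators in the package condition
#' on the observed point count so that envelope comparisons are
#' like-for-like.
#'
#' @param n number of points (>= 0).
#' @param window a [rect_window()].
#' @param seed optional integer seed (uses the R RNG; `NULL` leaves the RNG
#'   state alone).
#' @return A [point_pattern()].
#' @export
sample_csr <- function(n, window, seed = NULL) {
  if (n < 0) stop("n must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  point_pattern(runif(n, window$xmin, window$xmax),
                runif(n, window$ymin, window$ymax), window, check = FALSE)
}

#' Thomas cluster process sampler
#'
#' Poisson number of parents at the given intensity, each with a Poisson
#' number of offspring displaced by an isotropic Gaussian; offspring falling
#' outside the window are discarded. Used as the canonical aggregated
#' benchmark pattern.
#'
#' @param parent_intensity parents per m^2.
#' @param mean_offspring mean offspring per parent.
#' @param sigma Gaussian cluster spread (m).
#' @param window a [rect_window()].
#' @param seed optional integer seed.
#' @return A [point_pattern()].
#' @export
sample_thomas <- function(parent_intensity, mean_offspring, sigma, window,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  np <- rpois(1, parent_intensity * window_area(window))
  px <- runif(np, window$xmin, window$xmax)
  py <- runif(np, window$ymin, window$ymax)
  no <- rpois(np, mean_offspring)
  x <- rep(px, no) + rnorm(sum(no), 0, sigma)
  y <- rep(py, no) + rnorm(sum(no), 0, sigma)
  keep <- in_window(x, y, window)
  point_pattern(x[keep], y[keep], window, check = FALSE)
}

#' Kernel estimate of a spatially varying intensity
#'
#' Non-parametric estimate of the intensity lambda2(x) of a pattern on a fine
#' raster, using a 2-D Epanechnikov kernel e_R(d) = (2 / (pi R^2)) (1 -
#' d^2/R^2) for d < R with per-point edge renormalisation (each point's
#' kernel mass inside the window is rescaled to 1), so the surface integrates
#' to n. The default bandwidth R = 30 m targets the neighbourhood within
#' which distance-dependent interactions are expected.
#'
#' @param p a [point_pattern()].
#' @param bandwidth kernel radius R (m), > 0.
#' @param cell raster cell size (m), default 2.
#' @return Object of class `"intensity_surface"`: raster matrix `z`
#'   (rows = y), cell-center coordinates `xc`, `yc`, `cell`, `bandwidth`,
#'   `window` and the surface `integral`.
#' @export
estimate_intensity <- function(p, bandwidth = 30, cell = 2) {
  stopifnot(inherits(p, "point_pattern"))
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  if (p$n < 1) stop("cannot estimate intensity of an empty pattern")
  w <- p$window
  xc <- seq(w$xmin + cell / 2, w$xmax, by = cell)
  yc <- seq(w$ymin + cell / 2, w$ymax, by = cell)
  z <- cpp_epanechnikov_surface(p$x, p$y, xc, yc, bandwidth, cell)
  integral <- sum(z) * cell^2
  # discretisation residue: rescale so the integral equals n exactly
  if (integral > 0) z <- z * (p$n / integral)
  structure(list(z = z, xc = xc, yc = yc, cell = cell, bandwidth = bandwidth,
                 window = w, integral = sum(z) * cell^2),
            class = "intensity_surface")
}

#' @export
print.intensity_surface <- function(x, ...) {
  cat(sprintf("intensity surface: %d x %d cells of %g m, bandwidth %g m, integral %.3f\n",
              length(x$xc), length(x$yc), x$cell, x$bandwidth, x$integral))
  invisible(x)
}

# bilinear interpolation of the raster at arbitrary locations
surface_at <- function(s, x, y) {
  xi <- (x - s$xc[1]) / s$cell
  yi <- (y - s$yc[1]) / s$cell
  nx <- length(s$xc); ny <- length(s$yc)
  x0 <- pmin(pmax(floor(xi), 0), nx - 2); fx <- pmin(pmax(xi - x0, 0), 1)
  y0 <- pmin(pmax(floor(yi), 0), ny - 2); fy <- pmin(pmax(yi - y0, 0), 1)
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  s$z[i00] * (1 - fx) * (1 - fy) + s$z[i01] * fx * (1 - fy) +
    s$z[i10] * (1 - fx) * fy + s$z[i11] * fx * fy
}

#' Heterogeneous Poisson sampler (fixed n)
#'
#' Draws exactly n points by rejection sampling proportional to a kernel
#' intensity surface (bilinear interpolation between raster cells). This is
#' the null model that keeps the large-scale, habitat-driven density
#' variation of an offspring pattern while destroying its small-scale
#' structure.
#'
#' @param surface an [estimate_intensity()] result.
#' @param n number of points to draw.
#' @param seed optional integer seed.
#' @return A [point_pattern()].
#' @export
sample_hp <- function(surface, n, seed = NULL) {
  stopifnot(inherits(surface, "intensity_surface"))
  zmax <- max(surface$z)
  if (zmax <= 0) stop("intensity surface is identically zero")
  if (!is.null(seed)) set.seed(seed)
  w <- surface$window
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n) {
    m <- max(100, 2 * (n - length(xs)))
    px <- runif(m, w$xmin, w$xmax)
    py <- runif(m, w$ymin, w$ymax)
    keep <- runif(m) * zmax < surface_at(surface, px, py)
    xs <- c(xs, px[keep]); ys <- c(ys, py[keep])
  }
  point_pattern(xs[seq_len(n)], ys[seq_len(n)], w, check = FALSE)
}

#' Bounded random displacement null model
#'
#' Relocates each point independently to a uniform location within the
#' intersection of the disk of radius R around its original position and the
#' window. An alternative heterogeneous-Poisson-style null that preserves
#' large-scale density while randomising structure below scale R.
#'
#' @param p a [point_pattern()].
#' @param max_radius maximal displacement R (m), > 0.
#' @param seed optional integer seed.
#' @return A [point_pattern()] with the same number of points.
#' @export
sample_displacement <- function(p, max_radius = 30, seed = NULL) {
  stopifnot(inherits(p, "point_pattern"))
  if (max_radius <= 0) stop("max_radius must be > 0")
  if (!is.null(seed)) set.seed(seed)
  w <- p$window
  nx <- p$x; ny <- p$y
  todo <- seq_len(p$n)
  while (length(todo)) {
    m <- length(todo)
    # uniform in the disk, then keep proposals inside the window
    rr <- max_radius * sqrt(runif(m))
    th <- runif(m, 0, 2 * pi)
    cx <- p$x[todo] + rr * cos(th)
    cy <- p$y[todo] + rr * sin(th)
    ok <- in_window(cx, cy, w)
    nx[todo[ok]] <- cx[ok]; ny[todo[ok]] <- cy[ok]
    todo <- todo[!ok]
  }
  point_pattern(nx, ny, w, check = FALSE)
}

#' Configuration for pattern reconstruction
#'
#' Grids, weights and budget of the improvement-only simulated-annealing
#' reconstruction. The energy is a weighted sum over statistics of the
#' squared deviation between the candidate and the observed curve, each term
#' normalised by the variance of the observed curve over its grid. Defaults:
#' g on 1-50 m (step 1 m, ring width 1 m), L on 1-50 m, Hs on 1-30 m with a
#' 2 m test lattice, D1 and D2 on 1-30 m, equal weights; `max_steps` defaults
#' to 200 n and `stall_limit` to 5000 consecutive rejections.
#'
#' @param stats statistics entering the energy, subset of
#'   `c("g", "L", "Hs", "D1", "D2")`.
#' @param r_g,r_l,r_h,r_d distance grids for g, L, Hs and D^k.
#' @param w_g ring width for g (m).
#' @param hs_spacing test-lattice spacing for Hs (m).
#' @param weights named numeric weights per statistic.
#' @param max_steps proposal budget; `NULL` = 200 * n.
#' @param stall_limit stop after this many consecutive rejections.
#' @param trace_every record the energy every this many proposals (0 = off).
#' @return list of class `"recon_config"`.
#' @export
recon_config <- function(stats = c("g", "L", "Hs", "D1", "D2"),
                         r_g = 1:50, w_g = 1, r_l = 1:50, r_h = 1:30,
                         hs_spacing = 2, r_d = 1:30,
                         weights = NULL, max_steps = NULL, stall_limit = 5000,
                         trace_every = 100) {
  stats <- match.arg(stats, c("g", "L", "Hs", "D1", "D2"), several.ok = TRUE)
  if (!length(stats)) stop("at least one statistic is required")
  wts <- c(g = 1, L = 1, Hs = 1, D1 = 1, D2 = 1)
  wts[setdiff(names(wts), stats)] <- 0
  if (!is.null(weights)) wts[names(weights)] <- weights
  structure(list(stats = stats, r_g = r_g, w_g = w_g, r_l = r_l, r_h = r_h,
                 hs_spacing = hs_spacing, r_d = r_d, weights = wts,
                 max_steps = max_steps, stall_limit = stall_limit,
                 trace_every = trace_every),
            class = "recon_config")
}

norm_of <- function(v) {
  nv <- stats::var(v)
  if (!is.finite(nv) || nv < 1e-12) 1 else nv
}

#' Precompute reconstruction targets
#'
#' Observed summary curves, variance normalisations and the Hs test lattice
#' for [reconstruct_pattern()]; compute once per observed pattern when
#' drawing many null replicates.
#'
#' @param p_obs observed [point_pattern()].
#' @param config a [recon_config()].
#' @return list used by [reconstruct_pattern()].
#' @export
recon_targets <- function(p_obs, config = recon_config()) {
  stopifnot(inherits(p_obs, "point_pattern"), inherits(config, "recon_config"))
  cfg <- config
  use <- cfg$weights
  if (p_obs$n <= 2 && use[["D2"]] > 0) use[["D2"]] <- 0
  grid_g <- radial_grid(cfg$r_g, cfg$w_g)
  step_l <- if (length(cfg$r_l) > 1) stats::median(diff(cfg$r_l)) else 1
  grid_l <- radial_grid(cfg$r_l, step_l)
  grid_d <- radial_grid(cfg$r_d, 1)
  g_obs <- if (use[["g"]] > 0) pair_correlation(p_obs, grid_g)$values else numeric(length(cfg$r_g))
  l_obs <- if (use[["L"]] > 0) ripley_k(p_obs, grid_l, "L")$values else numeric(length(cfg$r_l))
  lat <- test_lattice(p_obs$window, cfg$hs_spacing)
  h_obs <- if (use[["Hs"]] > 0) {
    nd <- cpp_nndist_to(lat$x, lat$y, p_obs$x, p_obs$y)
    vapply(cfg$r_h, function(r) mean(nd <= r), 0)
  } else numeric(length(cfg$r_h))
  d1_obs <- if (use[["D1"]] > 0) nn_distribution(p_obs, grid_d, 1)$values else numeric(length(cfg$r_d))
  d2_obs <- if (use[["D2"]] > 0) nn_distribution(p_obs, grid_d, 2)$values else numeric(length(cfg$r_d))
  list(use = use, step_l = step_l, lat = lat,
       g_obs = g_obs, g_norm = norm_of(g_obs),
       l_obs = l_obs, l_norm = norm_of(l_obs),
       h_obs = h_obs, h_norm = norm_of(h_obs),
       d1_obs = d1_obs, d1_norm = norm_of(d1_obs),
       d2_obs = d2_obs, d2_norm = norm_of(d2_obs))
}

#' Pattern reconstruction by improvement-only simulated annealing
#'
#' Generates a stochastic replicate of an observed pattern that approximates
#' several of its functional summary statistics (pair-correlation, L,
#' spherical contact, nearest-neighbour distributions). Starting from CSR
#' with the observed n (or from a supplied pattern), each step proposes
#' relocating one uniformly chosen point to a uniform location and accepts
#' the move iff the energy does not increase; the algorithm stops after
#' `max_steps` proposals or `stall_limit` consecutive rejections. The result
#' preserves the observed clustering while being independent of any spatial
#' covariate, which is what the covariate-association null model requires.
#'
#' @param p_obs observed [point_pattern()] with n >= 2.
#' @param config a [recon_config()].
#' @param seed optional integer seed.
#' @param init optional starting pattern (default: fresh CSR). Passing
#'   `p_obs` itself yields energy 0 and an immediate fixed point.
#' @param targets optional precomputed [recon_targets()] for `p_obs` (saves
#'   recomputing the observed curves when many replicates are drawn).
#' @return A [point_pattern()] with attribute `recon` holding
#'   `energy_init`, `energy_final`, `steps`, `accepted` and the energy
#'   `trace`.
#' @export
reconstruct_pattern <- function(p_obs, config = recon_config(), seed = NULL,
                                init = NULL, targets = NULL) {
  stopifnot(inherits(p_obs, "point_pattern"), inherits(config, "recon_config"))
  if (p_obs$n < 2) stop("reconstruction needs n >= 2")
  if (!is.null(seed)) set.seed(seed)
  w <- p_obs$window
  n <- p_obs$n
  cfg <- config
  if (is.null(targets)) targets <- recon_targets(p_obs, cfg)
  use <- targets$use
  tg <- targets

  start <- if (is.null(init)) sample_csr(n, w) else init
  if (start$n != n) stop("init pattern must have the observed n")

  max_steps <- if (is.null(cfg$max_steps)) 200L * n else as.integer(cfg$max_steps)

  res <- cpp_reconstruct(start$x, start$y, w$xmin, w$ymin, w$xmax, w$ymax,
                         as.numeric(cfg$r_g), cfg$w_g, tg$g_obs, tg$g_norm,
                         use[["g"]],
                         as.numeric(cfg$r_l) - tg$step_l / 2, tg$step_l,
                         tg$l_obs, tg$l_norm, use[["L"]],
                         as.numeric(cfg$r_h), tg$h_obs, tg$h_norm,
                         use[["Hs"]],
                         if (use[["Hs"]] > 0) tg$lat$x else numeric(0),
                         if (use[["Hs"]] > 0) tg$lat$y else numeric(0),
                         as.numeric(cfg$r_d), tg$d1_obs, tg$d1_norm,
                         use[["D1"]], tg$d2_obs, tg$d2_norm, use[["D2"]],
                         max_steps, as.integer(cfg$stall_limit),
                         as.integer(cfg$trace_every))
  out <- point_pattern(res$x, res$y, w, check = FALSE)
  attr(out, "recon") <- res[c("energy_init", "energy_final", "steps",
                              "accepted", "trace")]
  out
}
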