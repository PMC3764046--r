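#' Synthetic ridge-valley elevation surface
#'
#' Deterministic smooth topography for the synthetic forest: a sinusoidal
#' ridge/valley system plus a few Gaussian hills, sampled at the 20 m quadrat
#' corners. Amplitude 0 gives a flat plot; the default emulates a rugged
#' plot with a couple of hundred meters of relief across a 600 x 400 m
#' window.
#'
#' @param window a [rect_window()].
#' @param base base elevation (m a.s.l.), default 450.
#' @param amplitude ridge/valley amplitude (m), default 60.
#' @param wavelength ridge wavelength (m), default 300.
#' @param hills number of Gaussian hills, default 3 (deterministic layout).
#' @param hill_height hill height (m), default 40.
#' @param spacing corner spacing (m), default 20.
#' @return An [elevation_grid()].
#' @export
make_elevation <- function(window, base = 450, amplitude = 60,
                           wavelength = 300, hills = 3, hill_height = 40,
                           spacing = 20) {
  xs <- seq(window$xmin, window$xmax, by = spacing)
  ys <- seq(window$ymin, window$ymax, by = spacing)
  wx <- window$xmax - window$xmin
  wy <- window$ymax - window$ymin
  z <- outer(ys, xs, function(y, x) {
    v <- base + amplitude * sin(2 * pi * x / wavelength) *
      cos(pi * y / wy)
    if (hills > 0) {
      for (h in seq_len(hills)) {
        hx <- window$xmin + wx * h / (hills + 1)
        hy <- window$ymin + wy * ((h %% 2) * 0.5 + 0.25)
        v <- v + hill_height * exp(-((x - hx)^2 + (y - hy)^2) / (2 * 80^2))
      }
    }
    v
  })
  elevation_grid(z, spacing)
}

standardize_cov <- function(cov) {
  v <- cov$v
  sdev <- stats::sd(as.vector(v))
  if (!is.finite(sdev) || sdev == 0) sdev <- 1
  covariate_grid((v - mean(v)) / sdev, cov$spacing, paste0(cov$name, "_std"))
}

reflect_into <- function(v, lo, hi) {
  span <- hi - lo
  v <- (v - lo) %% (2 * span)
  v <- ifelse(v > span, 2 * span - v, v)
  v + lo
}

#' Place adults with habitat filtering
#'
#' Samples an exact number of adult locations from a log-linear habitat
#' intensity, lambda(quadrat) proportional to exp(sum beta_k v_k) with
#' standardised quadrat covariates v_k; a quadrat is drawn with probability
#' proportional to its intensity and the point is uniform within it.
#' Optionally the pattern is Thomas-clustered on top of the habitat trend:
#' cluster parents are drawn from the habitat intensity and each adult is a
#' Gaussian displacement (sd `cluster_sigma`) from a uniformly chosen
#' parent, reflected into the window.
#'
#' @param n number of adults.
#' @param covariates named list of covariate grids (see [topo_covariates()]).
#' @param beta named coefficients on the standardised covariates (names must
#'   match `covariates`); `NULL` or all zero gives CSR.
#' @param window a [rect_window()].
#' @param cluster_sigma optional Thomas cluster spread (m).
#' @param parents_per_cluster mean adults per cluster parent (used only with
#'   `cluster_sigma`), default 5.
#' @param seed optional integer seed.
#' @return A [point_pattern()] with exactly `n` points.
#' @export
place_adults <- function(n, covariates, beta = NULL, window,
                         cluster_sigma = NULL, parents_per_cluster = 5,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- covariates[[1]]$spacing
  nrq <- covariates[[1]]$nrows; ncq <- covariates[[1]]$ncols
  eta <- matrix(0, nrq, ncq)
  if (!is.null(beta)) {
    for (nm in names(beta)) {
      if (!nm %in% names(covariates))
        stop("no covariate named ", nm)
      eta <- eta + beta[[nm]] * standardize_cov(covariates[[nm]])$v
    }
  }
  prob <- exp(eta - max(eta))
  draw_from_habitat <- function(m) {
    q <- sample.int(nrq * ncq, m, replace = TRUE, prob = as.vector(prob))
    iy <- (q - 1) %% nrq + 1
    ix <- (q - 1) %/% nrq + 1
    list(x = window$xmin + (ix - 1 + runif(m)) * s,
         y = window$ymin + (iy - 1 + runif(m)) * s)
  }
  if (is.null(cluster_sigma)) {
    pts <- draw_from_habitat(n)
  } else {
    np <- max(1, round(n / parents_per_cluster))
    par <- draw_from_habitat(np)
    pick <- sample.int(np, n, replace = TRUE)
    pts <- list(
      x = reflect_into(par$x[pick] + rnorm(n, 0, cluster_sigma),
                       window$xmin, window$xmax),
      y = reflect_into(par$y[pick] + rnorm(n, 0, cluster_sigma),
                       window$ymin, window$ymax))
  }
  point_pattern(pts$x, pts$y, window, check = FALSE)
}

#' Dispersal-limited offspring around adults
#'
#' Each adult produces a Poisson(`mean_offspring`) number of recruits at its
#' own location plus an isotropic Gaussian displacement (sd `sigma_d`),
#' reflected into the window. This is the dispersal-limitation mechanism:
#' most recruits land within a few `sigma_d` of a parent.
#'
#' @param adults a [point_pattern()].
#' @param mean_offspring mean recruits per adult.
#' @param sigma_d dispersal kernel sd (m).
#' @param seed optional integer seed.
#' @return A [point_pattern()] with attribute `parent` (index of the adult).
#' @export
disperse_offspring <- function(adults, mean_offspring, sigma_d, seed = NULL) {
  stopifnot(inherits(adults, "point_pattern"))
  if (!is.null(seed)) set.seed(seed)
  w <- adults$window
  if (adults$n == 0)
    return(point_pattern(numeric(0), numeric(0), w, check = FALSE))
  no <- rpois(adults$n, mean_offspring)
  parent <- rep(seq_len(adults$n), no)
  m <- length(parent)
  x <- reflect_into(adults$x[parent] + rnorm(m, 0, sigma_d), w$xmin, w$xmax)
  y <- reflect_into(adults$y[parent] + rnorm(m, 0, sigma_d), w$ymin, w$ymax)
  out <- point_pattern(x, y, w, check = FALSE)
  attr(out, "parent") <- parent
  out
}

#' Janzen-Connell distance-dependent thinning
#'
#' Each offspring survives with probability p(d) = d^2 / (d^2 + d_jc^2)
#' where d is its distance to the nearest conspecific adult: survival rises
#' smoothly with distance, is 1/2 at d = d_jc, and `d_jc = 0` disables the
#' mechanism.
#'
#' @param offspring,adults [point_pattern()]s in the same window.
#' @param d_jc distance scale of the mortality (m), >= 0.
#' @param seed optional integer seed.
#' @return The surviving offspring as a [point_pattern()].
#' @export
jc_thinning <- function(offspring, adults, d_jc, seed = NULL) {
  stopifnot(inherits(offspring, "point_pattern"), inherits(adults, "point_pattern"))
  if (!is.null(seed)) set.seed(seed)
  if (d_jc <= 0 || offspring$n == 0 || adults$n == 0) return(offspring)
  d <- cpp_nndist_to(offspring$x, offspring$y, adults$x, adults$y)
  pr <- d^2 / (d^2 + d_jc^2)
  keep <- rbinom(offspring$n, 1, pr) == 1
  point_pattern(offspring$x[keep], offspring$y[keep], offspring$window,
                check = FALSE)
}

#' Density-dependent thinning
#'
#' Each point survives with probability exp(-c * k) where k is the number of
#' conspecific neighbours within `radius`; `c = 0` disables the mechanism.
#'
#' @param p a [point_pattern()].
#' @param c_strength thinning strength c, >= 0.
#' @param radius neighbourhood radius (m).
#' @param seed optional integer seed.
#' @return The surviving points as a [point_pattern()].
#' @export
density_thinning <- function(p, c_strength, radius = 5, seed = NULL) {
  stopifnot(inherits(p, "point_pattern"))
  if (!is.null(seed)) set.seed(seed)
  if (c_strength <= 0 || p$n == 0) return(p)
  k <- cpp_count_within(p$x, p$y, radius)
  keep <- rbinom(p$n, 1, exp(-c_strength * k)) == 1
  point_pattern(p$x[keep], p$y[keep], p$window, check = FALSE)
}

#' Hard-core self-thinning
#'
#' Iteratively removes a uniformly chosen member of a conflicting pair until
#' no two survivors are within the hard-core distance h: the spatial
#' signature of competition for space as stems grow.
#'
#' @param p a [point_pattern()].
#' @param h hard-core distance (m).
#' @param seed optional integer seed.
#' @return A [point_pattern()] with min pairwise distance >= h.
#' @export
self_thinning <- function(p, h, seed = NULL) {
  stopifnot(inherits(p, "point_pattern"))
  if (!is.null(seed)) set.seed(seed)
  if (p$n < 2 || h <= 0) return(p)
  x <- p$x; y <- p$y
  alive <- rep(TRUE, p$n)
  repeat {
    idx <- which(alive)
    if (length(idx) < 2) break
    nd <- cpp_knn_dist(x[idx], y[idx], 1L)[, 1]
    conflicted <- idx[nd < h]
    if (!length(conflicted)) break
    victim <- conflicted[sample.int(length(conflicted), 1)]
    alive[victim] <- FALSE
  }
  point_pattern(x[alive], y[alive], p$window, check = FALSE)
}

stage_dbh_range <- function(growth_form, stage) {
  cuts <- stage_cuts[[growth_form]]
  if (is.null(cuts)) stop("unknown growth form: ", growth_form)
  upper_adult <- c(canopy = 60, understory = 30, shrub = 8)[[growth_form]]
  switch(stage,
         sapling = c(1, cuts[1]),
         juvenile = c(cuts[1], cuts[2]),
         adult = c(cuts[2], upper_adult))
}

#' Assemble a stem table from stage patterns
#'
#' Combines per-stage point patterns of one species into stem-table rows,
#' drawing each dbh uniformly within the stage's size class for the species'
#' growth form (so classification round-trips to the intended stage).
#'
#' @param stage_patterns named list with elements `sapling`, `juvenile`,
#'   `adult`, each a [point_pattern()].
#' @param species species code.
#' @param growth_form one of `"shrub"`, `"understory"`, `"canopy"`.
#' @param seed optional integer seed.
#' @return `data.frame` with columns `species, x, y, dbh, growth_form`.
#' @export
assemble_stem_table <- function(stage_patterns, species, growth_form,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(stage_levels(), function(st) {
    p <- stage_patterns[[st]]
    if (is.null(p) || p$n == 0) return(NULL)
    rng <- stage_dbh_range(growth_form, st)
    data.frame(species = species, x = p$x, y = p$y,
               dbh = runif(p$n, rng[1], rng[2] - 1e-9),
               growth_form = growth_form)
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

#' Scenario configuration for the synthetic forest
#'
#' Defines the community the generator emulates: a 600 x 400 m plot with
#' ridge-valley topography, per-species adult counts between 60 and 300,
#' habitat coefficients on the standardised topographic covariates,
#' Thomas-type clustered adults, dispersal-limited recruitment, and
#' switchable Janzen-Connell, density-dependent and hard-core thinning.
#' Per-species fields are recycled across `n_species`.
#'
#' @param window a [rect_window()], default the 600 x 400 m plot.
#' @param n_species number of species, default 10.
#' @param adults per-species adult counts, default evenly spread 60-300.
#' @param growth_form per-species growth forms (recycled).
#' @param beta_elev,beta_convex habitat coefficients (recycled).
#' @param cluster_sigma adult Thomas cluster spread (m; `NA` disables).
#' @param mu_sapling,mu_juvenile mean recruits per adult for the two
#'   offspring cohorts.
#' @param sigma_d dispersal sd (m), default 5.
#' @param d_jc Janzen-Connell scale (m; 0 disables).
#' @param dens_c,dens_radius density-thinning strength and radius (0
#'   disables).
#' @param hardcore_adult hard-core distance applied to adults (m; 0
#'   disables).
#' @param elevation named list of [make_elevation()] arguments.
#' @param seed integer seed for the whole community.
#' @return list of class `"scenario_config"`.
#' @export
scenario_config <- function(window = rect_window(0, 0, 600, 400),
                            n_species = 10,
                            adults = round(seq(60, 300, length.out = n_species)),
                            growth_form = c("canopy", "understory", "shrub"),
                            beta_elev = c(1, -1, 0.5), beta_convex = c(0.5, 0, -0.5),
                            cluster_sigma = 15, mu_sapling = 3, mu_juvenile = 1.5,
                            sigma_d = 5, d_jc = 0, dens_c = 0, dens_radius = 5,
                            hardcore_adult = 0, elevation = list(), seed = 1) {
  structure(list(window = window, n_species = n_species,
                 adults = rep_len(adults, n_species),
                 growth_form = rep_len(growth_form, n_species),
                 beta_elev = rep_len(beta_elev, n_species),
                 beta_convex = rep_len(beta_convex, n_species),
                 cluster_sigma = cluster_sigma,
                 mu_sapling = rep_len(mu_sapling, n_species),
                 mu_juvenile = rep_len(mu_juvenile, n_species),
                 sigma_d = rep_len(sigma_d, n_species),
                 d_jc = rep_len(d_jc, n_species),
                 dens_c = rep_len(dens_c, n_species),
                 dens_radius = dens_radius,
                 hardcore_adult = rep_len(hardcore_adult, n_species),
                 elevation = elevation, seed = seed),
            class = "scenario_config")
}

#' Simulate a synthetic forest community
#'
#' Generates the elevation surface and, per species, adults (habitat-filtered
#' and clustered), then saplings and juveniles as independent dispersal
#' cohorts from the same adults, applies the configured mortality mechanisms
#' (Janzen-Connell distance thinning and density thinning on offspring
#' cohorts, hard-core self-thinning on adults), and assembles the stem
#' table. Fully determined by the scenario seed.
#'
#' @param scenario a [scenario_config()].
#' @return list with `stems` (stem table), `elevation`
#'   ([elevation_grid()]), `covariates`, `patterns` (per species per stage)
#'   and the `scenario`.
#' @export
simulate_community <- function(scenario = scenario_config()) {
  stopifnot(inherits(scenario, "scenario_config"))
  set.seed(scenario$seed)
  w <- scenario$window
  elev <- do.call(make_elevation, c(list(window = w), scenario$elevation))
  covs <- topo_covariates(elev)
  stems <- list(); pats <- list()
  for (i in seq_len(scenario$n_species)) {
    sp <- sprintf("sp%02d", i)
    beta <- list(mean_elevation = scenario$beta_elev[i],
                 convexity = scenario$beta_convex[i])
    cs <- scenario$cluster_sigma
    adults <- place_adults(scenario$adults[i], covs, beta, w,
                           cluster_sigma = if (is.null(cs) || is.na(cs)) NULL else cs)
    if (scenario$hardcore_adult[i] > 0)
      adults <- self_thinning(adults, scenario$hardcore_adult[i])
    cohort <- function(mu) {
      off <- disperse_offspring(adults, mu, scenario$sigma_d[i])
      if (scenario$d_jc[i] > 0)
        off <- jc_thinning(off, adults, scenario$d_jc[i])
      if (scenario$dens_c[i] > 0)
        off <- density_thinning(off, scenario$dens_c[i], scenario$dens_radius)
      off
    }
    stage_pats <- list(sapling = cohort(scenario$mu_sapling[i]),
                       juvenile = cohort(scenario$mu_juvenile[i]),
                       adult = adults)
    pats[[sp]] <- stage_pats
    stems[[sp]] <- assemble_stem_table(stage_pats, sp, scenario$growth_form[i])
  }
  stems <- do.call(rbind, stems)
  rownames(stems) <- NULL
  stems$stage <- classify_stage(stems$dbh, stems$growth_form)
  list(stems = stems, elevation = elev, covariates = covs,
       patterns = pats, scenario = scenario)
}
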