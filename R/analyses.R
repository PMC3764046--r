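#' Analysis configuration
#'
#' Shared knobs of the three community-level analyses. Defaults follow the
#' published protocol: 199 Monte-Carlo simulations, envelope rank 5, 1 m
#' distance resolution with a 3 m ring width over 0-50 m, Epanechnikov
#' bandwidth 30 m, GoF interval 1-25 m for the K2 analysis and 0-50 m for
#' the bivariate analysis.
#'
#' @param n_sims number of null simulations (199).
#' @param env_rank envelope rank k (5).
#' @param min_per_stage species selection floor per stage (40).
#' @param alpha significance level (0.05).
#' @param bandwidth Epanechnikov kernel bandwidth (m, 30).
#' @param intensity_cell intensity raster cell (m, 2).
#' @param recon a [recon_config()] for the reconstruction null.
#' @param seed integer seed for the whole analysis.
#' @param fig2_denominator `"gof"` (only GoF-significant species, as in the
#'   bivariate percentage curves) or `"all"`.
#' @return list of class `"analysis_config"`.
#' @export
analysis_config <- function(n_sims = 199, env_rank = 5, min_per_stage = 40,
                            alpha = 0.05, bandwidth = 30, intensity_cell = 2,
                            recon = recon_config(), seed = 1,
                            fig2_denominator = c("gof", "all")) {
  structure(list(n_sims = n_sims, env_rank = env_rank,
                 min_per_stage = min_per_stage, alpha = alpha,
                 bandwidth = bandwidth, intensity_cell = intensity_cell,
                 recon = recon, seed = seed,
                 fig2_denominator = match.arg(fig2_denominator)),
            class = "analysis_config")
}

stage_patterns_of <- function(stems, species, window) {
  setNames(lapply(stage_levels(), function(st)
    extract_pattern(stems, species, st, window)), stage_levels())
}

#' Habitat-association analysis (Berman tests under reconstruction nulls)
#'
#' For every selected species, life stage and topographic covariate (mean
#' elevation, slope, convexity), runs the Berman test with pattern
#' reconstruction replicates of the observed stage pattern as the null
#' model. Reconstruction replicates are shared across the three covariates
#' of a species-stage. Returns the per-test table plus community summaries:
#' percentage of significant tests per stage and covariate, percentage of
#' species consistently associated (same sign, significant at all three
#' stages, for at least one covariate), species with "opposite" behaviour
#' (adults significantly negative while both offspring stages significantly
#' positive), and the Spearman rank correlation between |Z1| and species
#' abundance per covariate.
#'
#' @param stems stem table (see [read_stem_table()]).
#' @param elev_grid an [elevation_grid()].
#' @param window a [rect_window()].
#' @param config an [analysis_config()].
#' @return list with `table`, `pct_significant`, `consistent_pct`,
#'   `opposite_species`, `abundance_correlation`, `skipped`.
#' @export
analysis1_habitat <- function(stems, elev_grid, window,
                              config = analysis_config()) {
  set.seed(config$seed)
  covs <- topo_covariates(elev_grid)
  species <- select_species(stems, config$min_per_stage)
  if (!length(species)) stop("no species passes the per-stage selection floor")
  abund <- table(stems$species)
  rows <- list(); skipped <- character(0)
  for (sp in species) {
    pats <- stage_patterns_of(stems, sp, window)
    for (st in stage_levels()) {
      p <- pats[[st]]
      if (p$n < 2) {
        skipped <- c(skipped, sprintf("%s/%s", sp, st))
        next
      }
      tg <- recon_targets(p, config$recon)
      nulls <- lapply(seq_len(config$n_sims), function(i)
        reconstruct_pattern(p, config$recon, targets = tg))
      for (cv in names(covs)) {
        b <- berman_test(p, covs[[cv]], nulls)
        rows[[length(rows) + 1]] <- data.frame(
          species = sp, stage = st, covariate = cv, n = p$n,
          S_obs = b$S_obs, mu = b$mu, sigma = b$sigma, Z1 = b$Z1, p = b$p,
          sign = b$sign, significant = abs(b$Z1) > stats::qnorm(1 - config$alpha / 2),
          abundance = as.integer(abund[[sp]]))
      }
    }
  }
  if (length(skipped))
    message("analysis1: skipped empty stage patterns: ",
            paste(skipped, collapse = ", "))
  tab <- do.call(rbind, rows)
  pct <- aggregate(significant ~ stage + covariate, data = tab,
                   FUN = function(z) 100 * mean(z))
  consistent <- vapply(species, function(sp) {
    any(vapply(names(covs), function(cv) {
      sub <- tab[tab$species == sp & tab$covariate == cv, ]
      nrow(sub) == 3 && all(sub$significant) && length(unique(sub$sign)) == 1
    }, TRUE))
  }, TRUE)
  opposite <- vapply(species, function(sp) {
    any(vapply(names(covs), function(cv) {
      sub <- tab[tab$species == sp & tab$covariate == cv, ]
      ad <- sub[sub$stage == "adult", ]; off <- sub[sub$stage != "adult", ]
      nrow(ad) == 1 && nrow(off) == 2 && ad$significant && ad$sign < 0 &&
        all(off$significant) && all(off$sign > 0)
    }, TRUE))
  }, TRUE)
  ab_cor <- vapply(names(covs), function(cv) {
    sub <- tab[tab$covariate == cv, ]
    suppressWarnings(stats::cor(abs(sub$Z1), sub$abundance, method = "spearman"))
  }, 0)
  list(table = tab, pct_significant = pct,
       consistent_pct = 100 * mean(consistent),
       opposite_species = names(opposite)[opposite],
       abundance_correlation = ab_cor, skipped = skipped)
}

k2_curve_of <- function(p, r_full, w, delta) {
  g <- pair_correlation(p, radial_grid(r_full, w))
  k2_function(g, delta)
}

#' Life-stage aggregation analysis (K2 under CSR)
#'
#' For every selected species and life stage, computes the K2-function
#' (finite-difference derivative of the pair-correlation function) and
#' compares it to CSR envelopes over 2-50 m, with the GoF rank test applied
#' over 1-25 m. Community-level outputs are the per-distance percentages of
#' species classified aggregated / random / regular per stage, and the
#' per-species stage-to-stage decline flags at r = 2, 4, 6, 8, 10 m.
#'
#' @inheritParams analysis1_habitat
#' @param k2_delta finite-difference half-width (m), default 1.
#' @param env_range envelope distance interval, default `c(2, 50)`.
#' @param gof_interval GoF interval, default `c(1, 25)`.
#' @return list with `table` (per species-stage GoF and envelope summary),
#'   `states` (per species-stage per-r classification), `percent_by_r`
#'   (per stage), `decline` (see [stage_decline_counts()]), `skipped`.
#' @export
analysis2_k2 <- function(stems, window, config = analysis_config(),
                         k2_delta = 1, env_range = c(2, 50),
                         gof_interval = c(1, 25)) {
  set.seed(config$seed)
  species <- select_species(stems, config$min_per_stage)
  if (!length(species)) stop("no species passes the per-stage selection floor")
  r_full <- 0:(env_range[2] + k2_delta)
  w <- 3
  rows <- list(); states <- list(); k2_by_stage <- list(); skipped <- character(0)
  for (sp in species) {
    pats <- stage_patterns_of(stems, sp, window)
    k2_by_stage[[sp]] <- list()
    for (st in stage_levels()) {
      p <- pats[[st]]
      if (p$n < 2) { skipped <- c(skipped, sprintf("%s/%s", sp, st)); next }
      k2_obs <- k2_curve_of(p, r_full, w, k2_delta)
      sims <- t(vapply(seq_len(config$n_sims), function(i)
        k2_curve_of(sample_csr(p$n, window), r_full, w, k2_delta)$values,
        numeric(length(k2_obs$values))))
      env_sel <- k2_obs$r >= env_range[1] & k2_obs$r <= env_range[2]
      obs_env <- summary_curve(radial_grid(k2_obs$r[env_sel], w),
                               k2_obs$values[env_sel], "K2")
      env <- envelopes(obs_env, sims[, env_sel, drop = FALSE], config$env_rank)
      st8 <- k2_aggregation_state(env)
      gof <- gof_test(k2_obs, sims, gof_interval)
      k2_by_stage[[sp]][[st]] <- k2_obs
      states[[sprintf("%s.%s", sp, st)]] <- data.frame(
        species = sp, stage = st, r = env$r, state = st8)
      rows[[length(rows) + 1]] <- data.frame(
        species = sp, stage = st, n = p$n, gof_p = gof$p,
        gof_significant = gof$p < config$alpha,
        n_aggregated = sum(st8 == "aggregated"),
        n_regular = sum(st8 == "regular"))
    }
  }
  if (length(skipped))
    message("analysis2: skipped stage patterns with n < 2: ",
            paste(skipped, collapse = ", "))
  tab <- do.call(rbind, rows)
  states <- do.call(rbind, states)
  pct <- lapply(setNames(stage_levels(), stage_levels()), function(st) {
    sub <- states[states$stage == st, ]
    if (!nrow(sub)) return(NULL)
    agg <- t(vapply(split(sub$state, sub$r), function(z)
      100 * c(aggregated = mean(z == "aggregated"),
              random = mean(z == "random"),
              regular = mean(z == "regular")), numeric(3)))
    data.frame(r = as.numeric(rownames(agg)), agg)
  })
  decline <- stage_decline_counts(k2_by_stage)
  list(table = tab, states = states, percent_by_r = pct, decline = decline,
       skipped = skipped)
}

#' Adult-offspring association analysis (g12 under a heterogeneous Poisson null)
#'
#' For every selected species and stage pair (juveniles around adults,
#' saplings around adults, saplings around juveniles), computes the
#' bivariate pair-correlation g12 on the 0-50 m grid and compares it to a
#' heterogeneous Poisson null of the younger pattern: the older pattern is
#' kept fixed, the younger is redistributed according to its own
#' Epanechnikov kernel intensity estimate (bandwidth 30 m), which factors
#' out habitat-driven large-scale density variation. Outputs per pair: GoF
#' p over 0-50 m, the envelope-based classification
#' (positive / negative / none), and the peak distance with its category;
#' plus the community per-distance percentage of attraction / repulsion /
#' none (denominator: GoF-significant species by default).
#'
#' @inheritParams analysis1_habitat
#' @return list with `table`, `states`, `percent_by_r` (per pair),
#'   `skipped`.
#' @export
analysis3_association <- function(stems, window, config = analysis_config()) {
  set.seed(config$seed)
  species <- select_species(stems, config$min_per_stage)
  if (!length(species)) stop("no species passes the per-stage selection floor")
  pairs <- list(adult_juvenile = c("adult", "juvenile"),
                adult_sapling = c("adult", "sapling"),
                juvenile_sapling = c("juvenile", "sapling"))
  grid <- radial_grid(0:50, 3)
  rows <- list(); states <- list(); skipped <- character(0)
  for (sp in species) {
    pats <- stage_patterns_of(stems, sp, window)
    for (pr in names(pairs)) {
      p1 <- pats[[pairs[[pr]][1]]]   # older, antecedent pattern
      p2 <- pats[[pairs[[pr]][2]]]   # younger pattern, randomised
      if (p1$n < 1 || p2$n < 1) {
        skipped <- c(skipped, sprintf("%s/%s", sp, pr)); next
      }
      g12 <- cross_pair_correlation(p1, p2, grid)
      surf <- estimate_intensity(p2, config$bandwidth, config$intensity_cell)
      sims <- t(vapply(seq_len(config$n_sims), function(i)
        cross_pair_correlation(p1, sample_hp(surf, p2$n), grid)$values,
        numeric(length(grid$r))))
      env <- envelopes(g12, sims, config$env_rank)
      gof <- gof_test(g12, sims, c(0, 50))
      cls <- classify_association(env, gof, alpha = config$alpha)
      pk <- peak_distance(g12)
      states[[sprintf("%s.%s", sp, pr)]] <- data.frame(
        species = sp, pair = pr, r = env$r, state = env$state,
        gof_significant = gof$p < config$alpha)
      rows[[length(rows) + 1]] <- data.frame(
        species = sp, pair = pr, n1 = p1$n, n2 = p2$n, gof_p = gof$p,
        classification = cls, peak_r = pk$peak_r, peak_category = pk$category,
        n_above = sum(env$state == "above"), n_below = sum(env$state == "below"))
    }
  }
  if (length(skipped))
    message("analysis3: skipped pairs with an empty pattern: ",
            paste(skipped, collapse = ", "))
  tab <- do.call(rbind, rows)
  states <- do.call(rbind, states)
  pct <- lapply(setNames(names(pairs), names(pairs)), function(pr) {
    sub <- states[states$pair == pr, ]
    if (config$fig2_denominator == "gof") sub <- sub[sub$gof_significant, ]
    if (!nrow(sub)) return(NULL)
    agg <- t(vapply(split(sub$state, sub$r), function(z)
      100 * c(attraction = mean(z == "above"),
              none = mean(z == "inside"),
              repulsion = mean(z == "below")), numeric(3)))
    data.frame(r = as.numeric(rownames(agg)), agg)
  })
  list(table = tab, states = states, percent_by_r = pct, skipped = skipped)
}

#' Write analysis result tables to CSV
#'
#' @param result output of one of the analysis functions.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_results <- function(result, dir, prefix) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(result)) {
    obj <- result[[nm]]
    if (is.data.frame(obj)) {
      f <- file.path(dir, sprintf("%s_%s.csv", prefix, nm))
      utils::write.csv(obj, f, row.names = FALSE)
      paths <- c(paths, f)
    } else if (is.list(obj) && length(obj) && all(vapply(obj, is.data.frame, TRUE))) {
      for (sub in names(obj)) {
        f <- file.path(dir, sprintf("%s_%s_%s.csv", prefix, nm, sub))
        utils::write.csv(obj[[sub]], f, row.names = FALSE)
        paths <- c(paths, f)
      }
    }
  }
  invisible(paths)
}
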