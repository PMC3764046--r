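#' Monte-Carlo simulation envelopes
#'
#' Pointwise acceptance band from the k-th lowest and k-th highest simulated
#' value at every distance (default: 5th extremes of 199 simulations, a
#' nominal 5% two-sided pointwise test). The observed curve is classified
#' per distance as below, inside or above the band; only strictly beyond the
#' bounds counts as outside.
#'
#' @param observed a [summary_curve()].
#' @param sims list of [summary_curve()]s on the same grid (>= 2k of them),
#'   or a matrix with one row per simulation.
#' @param k envelope rank (default 5).
#' @return Object of class `"envelope_result"`: `r`, `observed`, `lower`,
#'   `upper`, `state` (factor below/inside/above), `n_sims`, `k`.
#' @export
envelopes <- function(observed, sims, k = 5) {
  stopifnot(inherits(observed, "summary_curve"))
  m <- sims_matrix(sims, observed)
  if (nrow(m) < 2 * k) stop("need at least 2k simulations")
  lower <- unname(apply(m, 2, function(v) sort(v)[k]))
  upper <- unname(apply(m, 2, function(v) sort(v, decreasing = TRUE)[k]))
  obs <- observed$values
  state <- ifelse(obs > upper, "above", ifelse(obs < lower, "below", "inside"))
  structure(list(r = observed$r, observed = obs, lower = lower, upper = upper,
                 state = factor(state, levels = c("below", "inside", "above")),
                 n_sims = nrow(m), k = k, statistic = observed$statistic),
            class = "envelope_result")
}

sims_matrix <- function(sims, observed) {
  if (is.matrix(sims)) {
    if (ncol(sims) != length(observed$r)) stop("simulation grid mismatch")
    return(sims)
  }
  vals <- lapply(sims, function(s) {
    stopifnot(inherits(s, "summary_curve"))
    if (length(s$r) != length(observed$r) ||
        any(abs(s$r - observed$r) > 1e-9))
      stop("simulation grid mismatch")
    s$values
  })
  do.call(rbind, vals)
}

#' @export
print.envelope_result <- function(x, ...) {
  cat(sprintf("envelope result (%s): %d sims, rank %d; outside at %d of %d distances\n",
              x$statistic, x$n_sims, x$k, sum(x$state != "inside"),
              length(x$r)))
  invisible(x)
}

#' Goodness-of-fit rank test over a distance interval
#'
#' The summed-squared-deviation rank test: for every curve i (observed and
#' each simulation), u_i = sum over the interval of (S_i(r) - Sbar_{-i}(r))^2
#' where Sbar_{-i} is the mean of all other curves; the p-value is the rank
#' of u_obs among the simulated u (ties counted as greater-or-equal,
#' conservative): p = (#\{u_sim >= u_obs\} + 1) / (n_sims + 1). This guards
#' the pointwise envelopes against multiple testing across distances.
#'
#' @param observed a [summary_curve()].
#' @param sims list of simulated curves or matrix (rows = sims).
#' @param interval distance interval `c(r_min, r_max)` over which deviations
#'   are summed.
#' @return Object of class `"gof_result"`: `u_obs`, `u_sims`, `p`,
#'   `interval`.
#' @export
gof_test <- function(observed, sims, interval) {
  stopifnot(inherits(observed, "summary_curve"), length(interval) == 2)
  m <- sims_matrix(sims, observed)
  nsim <- nrow(m)
  if (nsim < 2) stop("need at least 2 simulations")
  sel <- observed$r >= interval[1] & observed$r <= interval[2]
  if (!any(sel)) stop("interval outside the curve's grid")
  all_m <- rbind(observed$values[sel], m[, sel, drop = FALSE])
  ncur <- nrow(all_m)
  colsum <- colSums(all_m)
  u <- vapply(seq_len(ncur), function(i) {
    others <- (colsum - all_m[i, ]) / (ncur - 1)
    sum((all_m[i, ] - others)^2)
  }, 0)
  u_obs <- u[1]; u_sims <- u[-1]
  p <- (sum(u_sims >= u_obs) + 1) / (nsim + 1)
  structure(list(u_obs = u_obs, u_sims = u_sims, p = p, interval = interval,
                 n_sims = nsim),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("GoF rank test on [%g, %g] m: u_obs = %.4g, p = %.4g (%d sims)\n",
              x$interval[1], x$interval[2], x$u_obs, x$p, x$n_sims))
  invisible(x)
}

#' Berman covariate-association test
#'
#' Compares the mean covariate value at the points of a pattern, S_obs, to
#' its distribution under replicates of a null model (here typically pattern
#' reconstruction, which preserves clustering while being independent of the
#' covariate). The standardised statistic Z1 = (S_obs - mu) / sigma is
#' referred to the standard normal for a two-sided p-value; the sign of Z1
#' gives the direction of association.
#'
#' @param p observed [point_pattern()].
#' @param covariate a covariate grid (see [mean_elevation()]) or a function
#'   `f(x, y)` returning covariate values.
#' @param null_replicates list of >= 2 null [point_pattern()]s.
#' @return Object of class `"berman_result"`: `S_obs`, `mu`, `sigma`, `Z1`,
#'   `p`, `sign`, `n_sims`.
#' @export
berman_test <- function(p, covariate, null_replicates) {
  stopifnot(inherits(p, "point_pattern"), length(null_replicates) >= 2)
  f <- if (is.function(covariate)) covariate
       else function(x, y) covariate_at(covariate, x, y)
  S_obs <- mean(f(p$x, p$y))
  S_sim <- vapply(null_replicates, function(q) mean(f(q$x, q$y)), 0)
  mu <- mean(S_sim)
  sigma <- stats::sd(S_sim)
  if (!is.finite(sigma) || sigma <= 0)
    stop("degenerate null: zero variance among simulated S values")
  Z1 <- (S_obs - mu) / sigma
  structure(list(S_obs = S_obs, mu = mu, sigma = sigma, Z1 = Z1,
                 p = 2 * stats::pnorm(-abs(Z1)), sign = sign(Z1),
                 n_sims = length(null_replicates)),
            class = "berman_result")
}

#' @export
print.berman_result <- function(x, ...) {
  cat(sprintf("Berman test: S_obs = %.4g, mu = %.4g, sigma = %.4g, Z1 = %.3f, p = %.4g\n",
              x$S_obs, x$mu, x$sigma, x$Z1, x$p))
  invisible(x)
}

#' Classify a bivariate association
#'
#' Conjunction rule combining the GoF test with the simulation envelopes:
#' positive (attraction) iff the GoF p-value is below `alpha` and the
#' observed curve exceeds the upper envelope at at least one distance in
#' `pos_interval`; negative (repulsion) iff GoF is significant and the curve
#' falls below the lower envelope in `neg_interval`; otherwise none. If both
#' are triggered, the direction with more exceedance distances wins, with
#' ties going to positive.
#'
#' @param env an [envelopes()] result.
#' @param gof a [gof_test()] result.
#' @param pos_interval interval checked for attraction, default `c(0, 50)`.
#' @param neg_interval interval checked for repulsion, default `c(0, 10)`.
#' @param alpha GoF significance level, default 0.05.
#' @return `"positive"`, `"negative"` or `"none"`.
#' @export
classify_association <- function(env, gof, pos_interval = c(0, 50),
                                 neg_interval = c(0, 10), alpha = 0.05) {
  stopifnot(inherits(env, "envelope_result"), inherits(gof, "gof_result"))
  if (gof$p >= alpha) return("none")
  n_above <- sum(env$state == "above" & env$r >= pos_interval[1] &
                   env$r <= pos_interval[2])
  n_below <- sum(env$state == "below" & env$r >= neg_interval[1] &
                   env$r <= neg_interval[2])
  if (n_above == 0 && n_below == 0) return("none")
  if (n_above >= n_below) "positive" else "negative"
}

#' Per-distance aggregation state from K2 envelopes
#'
#' Under CSR envelopes of the K2-function, values below the lower envelope
#' indicate aggregation (rapid decay of neighbourhood density), values above
#' the upper envelope regularity, and values inside the band randomness.
#'
#' @param env an [envelopes()] result computed on K2 curves.
#' @return factor per distance with levels
#'   `c("aggregated", "random", "regular")`.
#' @export
k2_aggregation_state <- function(env) {
  stopifnot(inherits(env, "envelope_result"))
  out <- ifelse(env$state == "below", "aggregated",
                ifelse(env$state == "above", "regular", "random"))
  factor(out, levels = c("aggregated", "random", "regular"))
}

#' Stage-to-stage decline in aggregation
#'
#' For each species and each distance in `r_list`, flags whether aggregation
#' declined from sapling to juvenile (K2_sa(r) - K2_ju(r) < 0, strict) and
#' from juvenile to adult (K2_ju(r) - K2_ad(r) < 0); K2 is more negative the
#' stronger the aggregation, so a negative difference means the younger
#' stage was more aggregated. Species missing a stage curve are skipped and
#' reported.
#'
#' @param k2_by_stage named list (per species) of lists with elements
#'   `sapling`, `juvenile`, `adult`, each a K2 [summary_curve()].
#' @param r_list distances (m) at which to evaluate, default
#'   `c(2, 4, 6, 8, 10)`.
#' @return list with `flags` (data.frame species x transition x r),
#'   `counts`/`percent` per transition and r, and `skipped` species.
#' @export
stage_decline_counts <- function(k2_by_stage, r_list = c(2, 4, 6, 8, 10)) {
  skipped <- character(0)
  rows <- list()
  for (sp in names(k2_by_stage)) {
    cur <- k2_by_stage[[sp]]
    if (is.null(cur$sapling) || is.null(cur$juvenile) || is.null(cur$adult)) {
      skipped <- c(skipped, sp)
      next
    }
    at <- function(curve, r) {
      i <- match(TRUE, abs(curve$r - r) < 1e-9)
      if (is.na(i)) stop(sprintf("distance %g not on the K2 grid", r))
      curve$values[i]
    }
    for (r in r_list) {
      rows[[length(rows) + 1]] <- data.frame(
        species = sp, r = r,
        sa_ju = at(cur$sapling, r) - at(cur$juvenile, r) < 0,
        ju_ad = at(cur$juvenile, r) - at(cur$adult, r) < 0)
    }
  }
  if (length(skipped))
    message("stage_decline_counts: skipped species without all three stages: ",
            paste(skipped, collapse = ", "))
  flags <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(0), r = numeric(0), sa_ju = logical(0),
               ju_ad = logical(0))
  counts <- percent <- NULL
  if (nrow(flags)) {
    counts <- aggregate(cbind(sa_ju, ju_ad) ~ r, data = flags, FUN = sum)
    nsp <- length(unique(flags$species))
    percent <- counts
    percent[c("sa_ju", "ju_ad")] <- 100 * counts[c("sa_ju", "ju_ad")] / nsp
  }
  list(flags = flags, counts = counts, percent = percent, skipped = skipped)
}
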