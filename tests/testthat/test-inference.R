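make_curve <- function(vals, r = seq_along(vals)) {
  summary_curve(radial_grid(r, 3), vals)
}

test_that("envelope bounds are the k-th order statistics", {
  obs <- make_curve(c(100, 3))
  sims <- cbind(1:199, rep(2, 199))
  env <- envelopes(obs, sims, k = 5)
  expect_equal(env$lower, c(5, 2))
  expect_equal(env$upper, c(195, 2))
  expect_equal(as.character(env$state), c("inside", "above"))
  # observed equal to a simulated curve is never strictly outside
  obs2 <- make_curve(c(50, 2))
  env2 <- envelopes(obs2, sims, k = 5)
  expect_true(all(env2$state == "inside"))
  expect_error(envelopes(obs, sims[1:8, ], k = 5), "2k")
  expect_error(envelopes(obs, cbind(1:199), k = 5), "mismatch")
})

test_that("envelope rejection rate at one distance is ~2k/(nsims+1) under CSR", {
  w <- rect_window(0, 0, 300, 300)
  grid <- radial_grid(10, 3)
  set.seed(30)
  out <- replicate(150, {
    obs <- pair_correlation(sample_csr(100, w), grid)
    sims <- matrix(replicate(39, pair_correlation(sample_csr(100, w), grid)$values), ncol = 1)
    env <- envelopes(obs, sims, k = 1)   # 2/40 = 5% nominal
    env$state[1] != "inside"
  })
  rate <- mean(out)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.10)
})

test_that("GoF rank test matches the exact rank formula", {
  # hand-built 3-sim example: u_obs strictly largest -> p = 1/4
  obs <- make_curve(c(10, 10))
  sims <- rbind(c(1, 1), c(2, 2), c(1.5, 1.5))
  gof <- gof_test(obs, sims, c(1, 2))
  # oracle: recompute u by direct enumeration
  allc <- rbind(c(10, 10), sims)
  u <- sapply(1:4, function(i) sum((allc[i, ] - colMeans(allc[-i, , drop = FALSE]))^2))
  expect_equal(gof$u_obs, u[1])
  expect_equal(gof$u_sims, u[-1])
  expect_equal(gof$p, 1 / 4)
  expect_error(gof_test(obs, sims, c(5, 6)), "outside")
  # identical curves: p = 1
  same <- matrix(3, 19, 2)
  expect_equal(gof_test(make_curve(c(3, 3)), same, c(1, 2))$p, 1)
})

test_that("GoF p-values are uniform under exchangeability", {
  # exchangeable Gaussian curves: p uniform on {1/20, ..., 1}
  set.seed(31)
  ps <- replicate(400, {
    m <- matrix(rnorm(20 * 5), 20, 5)
    gof_test(make_curve(m[1, ], r = 1:5), m[-1, , drop = FALSE], c(1, 5))$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("Berman statistic and p follow the definition", {
  w <- rect_window(0, 0, 10, 10)
  p <- point_pattern(5, 5, w)
  mk <- function(v) { # replicate whose covariate mean is v
    q <- point_pattern(v, 5, w)
    q
  }
  covf <- function(x, y) x
  b <- berman_test(mk(2), covf, lapply(c(1, 2, 3), mk))
  expect_equal(b$Z1, 0)
  expect_equal(b$p, 1)
  b2 <- berman_test(mk(0.7), covf, lapply(c(0.4, 0.5, 0.6), mk))
  expect_equal(b2$Z1, 2)
  expect_equal(b2$sign, 1)
  expect_equal(b2$p, 2 * pnorm(-2))
  expect_error(berman_test(mk(1), covf, lapply(c(2, 2, 2), mk)), "degenerate")
})

test_that("association classification applies the conjunction rule", {
  mkenv <- function(states, r = seq_along(states)) {
    obs <- numeric(length(states))
    obs[states == "above"] <- 2
    obs[states == "below"] <- -2
    structure(list(r = r, observed = obs, lower = rep(-1, length(r)),
                   upper = rep(1, length(r)),
                   state = factor(states, c("below", "inside", "above")),
                   n_sims = 199, k = 5, statistic = "g12"),
              class = "envelope_result")
  }
  mkgof <- function(p) structure(list(u_obs = 1, u_sims = 1, p = p,
                                      interval = c(0, 50), n_sims = 199),
                                 class = "gof_result")
  st <- rep("inside", 50); st[2:6] <- "above"
  expect_equal(classify_association(mkenv(st), mkgof(0.005)), "positive")
  expect_equal(classify_association(mkenv(st), mkgof(0.20)), "none")
  st2 <- rep("inside", 50); st2[3] <- "below"
  expect_equal(classify_association(mkenv(st2), mkgof(0.01)), "negative")
  # ties go to positive
  st3 <- rep("inside", 50); st3[2] <- "above"; st3[4] <- "below"
  expect_equal(classify_association(mkenv(st3), mkgof(0.01)), "positive")
  # monotone: adding exceedances never flips positive -> none
  st4 <- st; st4[10:20] <- "above"
  expect_equal(classify_association(mkenv(st4), mkgof(0.005)), "positive")
})

test_that("K2 envelope states map below->aggregated, above->regular", {
  obs <- make_curve(c(-3, 0, 3))
  sims <- matrix(rep(c(-1, 0, 1), each = 199), 199, 3)
  env <- envelopes(obs, sims, k = 5)
  st <- k2_aggregation_state(env)
  expect_equal(as.character(st), c("aggregated", "random", "regular"))
})

test_that("K2 under CSR envelopes flags clusters as aggregated at small r", {
  w <- rect_window(0, 0, 300, 300)
  pt <- sample_thomas(50 / 1e4, 8, 2, w, seed = 32)
  r_full <- 0:12
  k2o <- k2_function(pair_correlation(pt, radial_grid(r_full, 3)), 1)
  set.seed(33)
  sims <- t(replicate(99, k2_function(
    pair_correlation(sample_csr(pt$n, w), radial_grid(r_full, 3)), 1)$values))
  env <- envelopes(k2o, sims, k = 3)
  st <- k2_aggregation_state(env)
  expect_true(any(st[env$r <= 5] == "aggregated"))
})

test_that("stage decline counts use strict inequalities per distance", {
  mk <- function(vals) summary_curve(radial_grid(1:10, 3), vals)
  k2s <- list(
    spA = list(sapling = mk(rep(-2, 10)), juvenile = mk(rep(-1, 10)),
               adult = mk(rep(0, 10))),
    spB = list(sapling = mk(rep(-1, 10)), juvenile = mk(rep(-1, 10)),
               adult = mk(rep(-1, 10))))
  out <- stage_decline_counts(k2s)
  fa <- out$flags[out$flags$species == "spA", ]
  expect_true(all(fa$sa_ju) && all(fa$ju_ad))
  fb <- out$flags[out$flags$species == "spB", ]
  expect_false(any(fb$sa_ju) || any(fb$ju_ad))
  expect_equal(out$percent$sa_ju, rep(50, 5)) # 1 of 2 species
  # missing stage -> skipped with message
  k2s$spC <- list(sapling = mk(rep(0, 10)))
  expect_message(out2 <- stage_decline_counts(k2s), "spC")
  expect_equal(out2$skipped, "spC")
})
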