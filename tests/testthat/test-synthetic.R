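test_that("synthetic elevation surfaces behave with amplitude", {
  w <- rect_window(0, 0, 200, 200)
  flat <- make_elevation(w, amplitude = 0, hills = 0)
  expect_true(all(flat$z == flat$z[1, 1]))
  g <- make_elevation(w, amplitude = 50, hills = 0)
  expect_lte(max(g$z) - min(g$z), 100)
  covs <- topo_covariates(make_elevation(w))
  expect_true(all(is.finite(covs$slope$v)))
  expect_gt(max(covs$slope$v), 0)
})

test_that("adults are placed with exact counts and habitat preference", {
  w <- rect_window(0, 0, 400, 400)
  covs <- topo_covariates(make_elevation(w))
  p0 <- place_adults(100, covs, NULL, w, seed = 50)
  expect_equal(p0$n, 100)
  # strong elevation preference: adult-site elevation above plot mean
  me <- covs$mean_elevation
  plot_mean <- mean(me$v)
  ok <- vapply(1:20, function(s) {
    p <- place_adults(80, covs, list(mean_elevation = 2), w, seed = s)
    mean(covariate_at(me, p$x, p$y)) > plot_mean
  }, TRUE)
  expect_gte(mean(ok), 0.95)
  # beta = 0 is CSR-like: chi-square on quadrat counts not systematically off
  set.seed(51)
  pv <- replicate(10, {
    p <- place_adults(200, covs, NULL, w)
    counts <- table(factor(floor(p$x / 40), levels = 0:9),
                    factor(floor(p$y / 40), levels = 0:9))
    suppressWarnings(stats::chisq.test(as.vector(counts))$p.value)
  })
  expect_gt(mean(pv > 0.01), 0.7)
})

test_that("offspring dispersal is Poisson-counted with Rayleigh distances", {
  w <- rect_window(0, 0, 600, 400)
  none <- disperse_offspring(point_pattern(numeric(0), numeric(0), w), 3, 5)
  expect_equal(none$n, 0)
  adults <- sample_csr(200, rect_window(100, 100, 500, 300), seed = 52)
  adults <- point_pattern(adults$x, adults$y, w)
  off <- disperse_offspring(adults, 4, 5, seed = 53)
  expect_lt(abs(off$n - 800), 3 * sqrt(800))
  par <- attr(off, "parent")
  d <- sqrt((off$x - adults$x[par])^2 + (off$y - adults$y[par])^2)
  expect_equal(stats::median(d), 5 * sqrt(2 * log(2)), tolerance = 0.05)
})

test_that("Janzen-Connell thinning follows p(d) = d^2/(d^2 + d_jc^2)", {
  w <- rect_window(0, 0, 100, 100)
  adult <- point_pattern(0, 50, w)
  # offspring all at distance exactly d_jc: survival ~ Binomial(n, 0.5)
  th <- seq(-pi / 2, pi / 2, length.out = 400)
  off <- point_pattern(10 * cos(th), 50 + 10 * sin(th), w)
  surv <- jc_thinning(off, adult, d_jc = 10, seed = 54)
  expect_lt(abs(surv$n - 200), 3 * sqrt(400 * 0.25))
  # d_jc = 0 disables
  expect_equal(jc_thinning(off, adult, 0)$n, off$n)
})

test_that("density and hard-core thinning honour their contracts", {
  w <- rect_window(0, 0, 100, 100)
  p <- sample_csr(200, w, seed = 55)
  expect_identical(density_thinning(p, 0), p)
  dt <- density_thinning(p, 0.5, radius = 10, seed = 56)
  expect_lt(dt$n, p$n)
  # hard core larger than any NN distance: unchanged
  expect_identical(self_thinning(p, 1e-9, seed = 57)$n, p$n)
  st <- self_thinning(p, 5, seed = 58)
  expect_gte(min(dist(cbind(st$x, st$y))), 5)
})

test_that("assembled stem tables round-trip the intended stages", {
  w <- rect_window(0, 0, 100, 100)
  pats <- list(sapling = sample_csr(30, w, seed = 59),
               juvenile = sample_csr(20, w, seed = 60),
               adult = sample_csr(10, w, seed = 61))
  df <- assemble_stem_table(pats, "spX", "canopy", seed = 62)
  expect_equal(nrow(df), 60)
  expect_true(all(df$dbh[51:60] >= 10)) # canopy adults
  st <- classify_stage(df$dbh, df$growth_form)
  expect_equal(as.character(st), rep(stage_levels(), c(30, 20, 10)))
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  back <- read_stem_table(f, w)
  expect_equal(nrow(back), 60)
})

test_that("the community generator is seed-deterministic and window-respecting", {
  sc <- scenario_config(window = rect_window(0, 0, 200, 200), n_species = 3,
                        adults = c(50, 60, 70), seed = 63)
  a <- simulate_community(sc)
  b <- simulate_community(sc)
  expect_identical(a$stems, b$stems)
  expect_true(all(a$stems$x >= 0 & a$stems$x <= 200))
  expect_true(all(a$stems$y >= 0 & a$stems$y <= 200))
  expect_equal(length(unique(a$stems$species)), 3)
  # adults exactly as configured (no thinning switches on)
  expect_equal(as.vector(table(a$stems$species[a$stems$stage == "adult"])),
               c(50, 60, 70))
})

test_that("stronger J-C thinning pushes the offspring density peak outward", {
  w <- rect_window(0, 0, 300, 300)
  grid <- radial_grid(0:20, 3)
  set.seed(64)
  shift <- replicate(10, {
    adults <- sample_csr(60, w)
    off <- disperse_offspring(adults, 8, 4)
    thin <- jc_thinning(off, adults, d_jc = 8)
    g_u <- cross_pair_correlation(adults, off, grid)
    g_t <- cross_pair_correlation(adults, thin, grid)
    peak_distance(g_t, c(0, 20))$peak_r - peak_distance(g_u, c(0, 20))$peak_r
  })
  expect_gt(mean(shift), 0)
})
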