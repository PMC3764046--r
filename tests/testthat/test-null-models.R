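test_that("CSR sampler is seeded, counted and uniform over quadrants", {
  w <- rect_window(0, 0, 100, 100)
  expect_equal(sample_csr(0, w)$n, 0)
  expect_error(sample_csr(-1, w), ">= 0")
  a <- sample_csr(50, w, seed = 1)
  b <- sample_csr(50, w, seed = 1)
  expect_identical(a$x, b$x)
  # mean count in one quadrant over 1000 draws: n/4 within 3 SE (binomial)
  set.seed(2)
  counts <- replicate(1000, {
    p <- sample_csr(40, w)
    sum(p$x < 50 & p$y < 50)
  })
  se <- sqrt(40 * 0.25 * 0.75 / 1000)
  expect_lt(abs(mean(counts) - 10), 3 * se)
})

test_that("Epanechnikov intensity surface is normalised and integrates to n", {
  w <- rect_window(0, 0, 200, 200)
  # kernel formula at the raster: single interior point integrates to 1
  p1 <- point_pattern(100, 100, w)
  s1 <- estimate_intensity(p1, bandwidth = 30, cell = 2)
  expect_equal(s1$integral, 1, tolerance = 1e-6)
  # peak value ~ e_R(0) = 2/(pi R^2)
  expect_equal(max(s1$z), 2 / (pi * 900), tolerance = 0.01)
  # edge point still integrates to 1 (renormalisation)
  pe <- point_pattern(1, 1, w)
  expect_equal(estimate_intensity(pe, 30, 2)$integral, 1, tolerance = 1e-6)
  p <- sample_csr(150, w, seed = 3)
  expect_equal(estimate_intensity(p, 30, 2)$integral, 150, tolerance = 1e-6)
  expect_error(estimate_intensity(p, -5), "bandwidth")
})

test_that("heterogeneous Poisson sampling follows the surface and keeps n", {
  w <- rect_window(0, 0, 200, 200)
  p <- sample_csr(150, w, seed = 4)
  s <- estimate_intensity(p, 30, 2)
  hp <- sample_hp(s, 150, seed = 5)
  expect_equal(hp$n, 150)
  # zero left half: all samples on the right
  s0 <- s
  s0$z[, s0$xc < 100] <- 0
  hp0 <- sample_hp(s0, 80, seed = 6)
  expect_true(all(hp0$x >= 98)) # bilinear ramp at the boundary cell
  # flat surface behaves like CSR (chi-square on 20 m quadrat counts)
  sflat <- s
  sflat$z[] <- mean(s$z)
  set.seed(7)
  pvals <- replicate(20, {
    q <- sample_hp(sflat, 200)
    counts <- table(factor(floor(q$x / 20), levels = 0:9),
                    factor(floor(q$y / 20), levels = 0:9))
    suppressWarnings(stats::chisq.test(as.vector(counts))$p.value)
  })
  expect_gt(max(pvals), 0.05) # not systematically non-uniform
  expect_gt(mean(pvals > 0.01), 0.7)
})

test_that("averaged HP replicates recover the input surface", {
  w <- rect_window(0, 0, 200, 200)
  pt <- sample_thomas(80 / 1e4, 6, 10, w, seed = 8)
  s <- estimate_intensity(pt, 30, 4)
  set.seed(9)
  acc <- 0 * s$z
  nrep <- 500
  for (i in seq_len(nrep)) {
    hp <- sample_hp(s, pt$n)
    acc <- acc + estimate_intensity(hp, 30, 4)$z
  }
  avg <- acc / nrep
  hi <- s$z > stats::median(s$z)
  relerr <- abs(avg[hi] - s$z[hi]) / s$z[hi]
  expect_lt(stats::median(relerr), 0.10)
})

test_that("bounded displacement preserves n, radius and large-scale density", {
  w <- rect_window(0, 0, 300, 300)
  pt <- sample_thomas(30 / 1e4, 15, 5, w, seed = 10)
  d <- sample_displacement(pt, 30, seed = 11)
  expect_equal(d$n, pt$n)
  disp <- sqrt((d$x - pt$x)^2 + (d$y - pt$y)^2)
  expect_true(all(disp <= 30))
  # tiny radius: effectively unchanged
  d0 <- sample_displacement(pt, 1e-9, seed = 12)
  expect_equal(d0$x, pt$x, tolerance = 1e-8)
  # mean displacement of interior points ~ (2/3) R
  wi <- rect_window(0, 0, 1000, 1000)
  pi_ <- sample_csr(400, rect_window(100, 100, 900, 900), seed = 13)
  pi_ <- point_pattern(pi_$x, pi_$y, wi)
  di <- sample_displacement(pi_, 30, seed = 14)
  mdisp <- mean(sqrt((di$x - pi_$x)^2 + (di$y - pi_$y)^2))
  expect_equal(mdisp, 20, tolerance = 0.05)
  # 60 m block counts correlate with the original (heterogeneous input)
  blocks <- function(p) table(factor(pmin(floor(p$x / 60), 4), levels = 0:4),
                              factor(pmin(floor(p$y / 60), 4), levels = 0:4))
  expect_gt(suppressWarnings(
    stats::cor(as.vector(blocks(pt)), as.vector(blocks(d)),
               method = "spearman")), 0.7)
})

test_that("reconstruction is a seeded fixed point at the observed pattern", {
  w <- rect_window(0, 0, 150, 150)
  pt <- sample_thomas(60 / 1e4, 6, 3, w, seed = 15)
  cfg <- recon_config(max_steps = 500, hs_spacing = 5, stall_limit = 200,
                      trace_every = 0)
  fix <- reconstruct_pattern(pt, cfg, seed = 16, init = pt)
  expect_equal(attr(fix, "recon")$energy_init, 0)
  expect_identical(fix$x, pt$x)
  a <- reconstruct_pattern(pt, cfg, seed = 17)
  b <- reconstruct_pattern(pt, cfg, seed = 17)
  expect_identical(a$x, b$x)
  expect_equal(a$n, pt$n)
})

test_that("reconstruction reduces energy monotonically and approximates g", {
  w <- rect_window(0, 0, 150, 150)
  pt <- sample_thomas(60 / 1e4, 6, 3, w, seed = 18)
  cfg <- recon_config(max_steps = 6000, hs_spacing = 5, trace_every = 50)
  rec <- reconstruct_pattern(pt, cfg, seed = 19)
  info <- attr(rec, "recon")
  expect_true(all(diff(info$trace) <= 1e-12))
  expect_lt(info$energy_final, 0.10 * info$energy_init)
  # g of the reconstruction is closer to g_obs than >= 95% of CSR patterns
  grid <- radial_grid(1:30, 3)
  gobs <- pair_correlation(pt, grid)$values
  l2 <- function(p) sum((pair_correlation(p, grid)$values - gobs)^2)
  set.seed(20)
  csr_l2 <- replicate(60, l2(sample_csr(pt$n, w)))
  expect_lte(l2(rec), stats::quantile(csr_l2, 0.05))
})

test_that("Berman test under a reconstruction null has correct type-I behaviour", {
  w <- rect_window(0, 0, 150, 150)
  pt <- sample_thomas(50 / 1e4, 6, 3, w, seed = 21)
  cfg <- recon_config(max_steps = 2000, hs_spacing = 5, trace_every = 0)
  set.seed(22)
  tg <- recon_targets(pt, cfg)
  pool <- lapply(1:40, function(i) reconstruct_pattern(pt, cfg, targets = tg))
  covf <- function(x, y) x + 0.5 * y # a smooth covariate unrelated to the null
  z <- vapply(seq_along(pool), function(i)
    berman_test(pool[[i]], covf, pool[-i])$Z1, 0)
  expect_gte(mean(abs(z) < 1.96), 0.9)
})
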