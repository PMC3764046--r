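test_that("ring areas match closed forms and the Monte-Carlo oracle", {
  big <- rect_window(0, 0, 1000, 1000)
  # interior: full annulus
  expect_equal(ring_area(500, 500, r = 3, w = 2, window = big), pi * (16 - 4))
  # corner: quarter annulus
  expect_equal(ring_area(0, 0, r = 3, w = 2, window = big), pi * (16 - 4) / 4)
  # near an edge: numeric-integration oracle and 1e6-sample MC oracle
  w <- plot_window()
  a <- ring_area(2, 200, r = 3, w = 2, window = w)
  expect_equal(a, ring_area_oracle(2, 200, 3, 2, w), tolerance = 1e-8)
  expect_equal(a, ring_area_mc(2, 200, 3, 2, w), tolerance = 0.005)
  expect_error(ring_area(-1, 0, 3, 2, window = w), "outside")
})

test_that("contiguous ring areas cumulate to the disk-window intersection", {
  w <- rect_window(0, 0, 100, 80)
  cx <- 5; cy <- 70 # near two edges
  rs <- seq(0.5, 29.5, by = 1)
  total <- sum(ring_area(cx, cy, rs, w = 1, window = w))
  expect_equal(total, disk_rect_oracle(cx, cy, 30, w), tolerance = 1e-8)
})

test_that("pair correlation matches manual enumeration on a 3-point fixture", {
  w <- plot_window()
  p <- point_pattern(c(10, 13, 30), c(10, 10, 10), w)
  grid <- radial_grid(3, 2)
  # only the pair (1,2) at distance 3 falls in ring [2,4): 2 ordered pairs
  areas <- sum(ring_area_oracle(10, 10, 3, 2, w),
               ring_area_oracle(13, 10, 3, 2, w),
               ring_area_oracle(30, 10, 3, 2, w))
  expected <- 2 / areas / (3 / window_area(w))
  expect_equal(pair_correlation(p, grid)$values, expected, tolerance = 1e-8)
  expect_error(pair_correlation(point_pattern(1, 1, w), grid), "n < 2")
})

test_that("pair correlation is ~1 under CSR and 0 inside a hard core", {
  w <- rect_window(0, 0, 300, 300)
  set.seed(11)
  gs <- replicate(60, pair_correlation(sample_csr(100, w), radial_grid(10, 3))$values)
  expect_gt(mean(gs), 0.93)
  expect_lt(mean(gs), 1.07)
  # grid with spacing 5 has no pairs within ring [1,3)
  gx <- as.vector(outer(seq(5, 295, 5), rep(1, 59)))
  gy <- as.vector(outer(rep(1, 59), seq(5, 295, 5)))
  ph <- point_pattern(gx, gy, w)
  expect_equal(pair_correlation(ph, radial_grid(2, 2))$values, 0)
})

test_that("pair correlation is translation invariant", {
  w <- rect_window(0, 0, 120, 90)
  p <- sample_csr(80, w, seed = 3)
  g1 <- pair_correlation(p, radial_grid(1:15, 3))$values
  w2 <- rect_window(50, -20, 170, 70)
  p2 <- point_pattern(p$x + 50, p$y - 20, w2)
  g2 <- pair_correlation(p2, radial_grid(1:15, 3))$values
  expect_equal(g1, g2, tolerance = 1e-12)
})

test_that("cross pair correlation detects construction and independence", {
  w <- rect_window(0, 0, 300, 300)
  p1 <- sample_csr(60, w, seed = 4)
  # p2 = p1 shifted by 0.5: huge g12 below 1 m
  p2 <- point_pattern(pmin(p1$x + 0.5, 300), p1$y, w)
  g <- cross_pair_correlation(p1, p2, radial_grid(c(0, 10), 2))
  expect_gt(g$values[1], 10)
  # independent CSR: mean ~ 1 (property over 200 replicates)
  set.seed(5)
  gs <- replicate(200, {
    a <- sample_csr(50, w); b <- sample_csr(70, w)
    cross_pair_correlation(a, b, radial_grid(10, 3))$values
  })
  expect_gt(mean(gs), 0.95)
  expect_lt(mean(gs), 1.05)
  expect_error(cross_pair_correlation(p1, sample_csr(5, rect_window(0, 0, 10, 10))),
               "same window")
})

test_that("a ring of offspring at 6 m around a single adult peaks g12 at 6", {
  w <- rect_window(0, 0, 200, 200)
  p1 <- point_pattern(100, 100, w)
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  p2 <- point_pattern(100 + 6 * cos(th), 100 + 6 * sin(th), w)
  g12 <- cross_pair_correlation(p1, p2, radial_grid(0:20, 1))
  pk <- peak_distance(g12, c(0, 20))
  expect_equal(pk$peak_r, 6)
  expect_true(pk$ge1 && pk$ge3 && pk$ge5)
  expect_equal(pk$category, ">=5 m")
})

test_that("K2 is exactly the centered finite difference of g", {
  grid <- radial_grid(0:10, 3)
  set.seed(8)
  vals <- runif(11)
  g <- summary_curve(grid, vals)
  k2 <- k2_function(g, 1)
  expect_equal(k2$values, (vals[3:11] - vals[1:9]) / 2)
  expect_equal(k2$r, 1:9)
  # worked example: g(1)=3, g(3)=1 -> K2(2) = -1
  g2 <- summary_curve(radial_grid(1:3, 1), c(3, 2, 1))
  expect_equal(k2_function(g2, 1)$values, -1)
  # constant curve -> identically 0
  expect_equal(k2_function(summary_curve(grid, rep(2, 11)), 1)$values, rep(0, 9))
  expect_error(k2_function(summary_curve(radial_grid(1:2, 1), 1:2), 1), "too short")
})

test_that("K2 of a Thomas cluster process is negative at small r", {
  w <- rect_window(0, 0, 300, 300)
  set.seed(21)
  neg <- replicate(20, {
    p <- sample_thomas(50 / 1e4, 8, 2, w)
    g <- pair_correlation(p, radial_grid(0:8, 3))
    all(k2_function(g, 1)$values[2:4] < 0) # r = 2,3,4
  })
  expect_gte(mean(neg), 0.9)
})

test_that("nearest-neighbour distribution matches simple geometry and CSR", {
  w <- rect_window(0, 0, 100, 100)
  p2 <- point_pattern(c(10, 14), c(50, 50), w)
  d <- nn_distribution(p2, radial_grid(c(1, 3.9, 4, 10), 1), 1)
  expect_equal(d$values, c(0, 0, 1, 1))
  expect_error(nn_distribution(p2, radial_grid(1:3, 1), 2), "n > k")
  # regular grid spacing 10: jump at 10
  gx <- as.vector(outer(seq(5, 95, 10), rep(1, 10)))
  gy <- as.vector(outer(rep(1, 10), seq(5, 95, 10)))
  dg <- nn_distribution(point_pattern(gx, gy, w), radial_grid(c(9.9, 10), 1), 1)
  expect_equal(dg$values, c(0, 1))
  # CSR closed form 1 - exp(-lambda pi r^2)
  wb <- rect_window(0, 0, 1000, 1000)
  p <- sample_csr(3000, wb, seed = 6)
  lam <- intensity_of(p)
  rs <- seq(2, 12, 2)
  d1 <- nn_distribution(p, radial_grid(rs, 1), 1)
  expect_equal(d1$values, 1 - exp(-lam * pi * rs^2), tolerance = 0.05)
  expect_true(all(diff(d1$values) >= 0))
})

test_that("spherical contact matches the geometric and Poisson oracles", {
  # single point at the center of a small window: Hs(r) = pi r^2 / |W|
  w <- rect_window(0, 0, 40, 40)
  p <- point_pattern(20, 20, w)
  hs <- spherical_contact(p, radial_grid(c(5, 10), 1), spacing = 0.25)
  expect_equal(hs$values, pi * c(25, 100) / 1600, tolerance = 0.01)
  # CSR closed form
  wb <- rect_window(0, 0, 1000, 1000)
  pc <- sample_csr(3000, wb, seed = 7)
  lam <- intensity_of(pc)
  rs <- seq(2, 12, 2)
  h <- spherical_contact(pc, radial_grid(rs, 1), spacing = 5)
  expect_equal(h$values, 1 - exp(-lam * pi * rs^2), tolerance = 0.05)
  expect_true(all(diff(h$values) >= 0))
  expect_true(all(h$values >= 0 & h$values <= 1))
})

test_that("L is ~r under CSR, above r for clusters, and K is nondecreasing", {
  w <- rect_window(0, 0, 500, 500)
  set.seed(9)
  Ls <- replicate(40, ripley_k(sample_csr(300, w), radial_grid(1:20, 3), "L")$values[c(10, 20)])
  expect_equal(rowMeans(Ls), c(10, 20), tolerance = 0.05)
  pt <- sample_thomas(50 / 1e4, 8, 2, w, seed = 10)
  expect_gt(ripley_k(pt, radial_grid(1:10, 3), "L")$values[5], 5)
  K <- ripley_k(pt, radial_grid(1:30, 3), "K")
  expect_true(all(diff(K$values) >= 0))
})

test_that("peak distance uses the smallest r on ties and categorises", {
  grid <- radial_grid(0:10, 3)
  v <- rep(0, 11); v[c(3, 8)] <- 5 # maxima at r = 2 and 7
  pk <- peak_distance(summary_curve(grid, v), c(0, 10))
  expect_equal(pk$peak_r, 2)
  expect_equal(pk$category, ">=1 m")
  v2 <- c(5, rep(0, 10))
  expect_equal(peak_distance(summary_curve(grid, v2), c(0, 10))$category, "<1 m")
  expect_error(peak_distance(summary_curve(grid, v), c(60, 70)), "empty")
})
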