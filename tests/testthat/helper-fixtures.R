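# Shared fixtures built in code.

plot_window <- function() rect_window(0, 0, 600, 400)

# stem table with controllable per-stage counts for one or more species
make_stems <- function(counts, window = rect_window(0, 0, 100, 100),
                       growth_form = "canopy", seed = 1) {
  set.seed(seed)
  rows <- list()
  gf <- rep_len(growth_form, length(counts))
  for (i in seq_along(counts)) {
    sp <- names(counts)[i]
    cnt <- counts[[i]]  # c(sapling, juvenile, adult)
    for (k in 1:3) {
      st <- stage_levels()[k]
      n <- cnt[k]
      if (n == 0) next
      rng <- switch(paste(gf[i], st),
                    "canopy sapling" = c(1, 5), "canopy juvenile" = c(5, 10),
                    "canopy adult" = c(10, 40),
                    "understory sapling" = c(1, 2.5),
                    "understory juvenile" = c(2.5, 5),
                    "understory adult" = c(5, 20),
                    "shrub sapling" = c(1, 1.5), "shrub juvenile" = c(1.5, 2),
                    "shrub adult" = c(2, 6))
      rows[[length(rows) + 1]] <- data.frame(
        species = sp,
        x = runif(n, window$xmin, window$xmax),
        y = runif(n, window$ymin, window$ymax),
        dbh = runif(n, rng[1], rng[2] - 1e-6),
        growth_form = gf[i])
    }
  }
  df <- do.call(rbind, rows)
  df$stage <- classify_stage(df$dbh, df$growth_form)
  df
}

# independent slow oracle for the disk-rectangle intersection area:
# 1-D numerical integration of the clipped circle height
disk_rect_oracle <- function(cx, cy, rho, w) {
  if (rho <= 0) return(0)
  f <- function(x) {
    h <- sqrt(pmax(0, rho^2 - (x - cx)^2))
    pmin(cy + h, w$ymax) - pmax(cy - h, w$ymin)
  }
  stats::integrate(f, max(w$xmin, cx - rho), min(w$xmax, cx + rho),
                   subdivisions = 2000, rel.tol = 1e-10)$value
}

ring_area_oracle <- function(cx, cy, r, w, win) {
  disk_rect_oracle(cx, cy, r + w / 2, win) -
    disk_rect_oracle(cx, cy, max(0, r - w / 2), win)
}

# Monte-Carlo ring-area oracle; samples the annulus bounding box clipped to
# the window so 1e6 samples give a well-conditioned estimate
ring_area_mc <- function(cx, cy, r, w, win, nsim = 1e6, seed = 42) {
  set.seed(seed)
  ro <- r + w / 2
  x0 <- max(win$xmin, cx - ro); x1 <- min(win$xmax, cx + ro)
  y0 <- max(win$ymin, cy - ro); y1 <- min(win$ymax, cy + ro)
  x <- runif(nsim, x0, x1)
  y <- runif(nsim, y0, y1)
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  inside <- d >= max(0, r - w / 2) & d < ro
  mean(inside) * (x1 - x0) * (y1 - y0)
}
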