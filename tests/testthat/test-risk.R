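mk_grid <- function(n = 4, cell = 1) grid_raster(matrix(0, n, n), 0, 0, cell)

vr <- function(id, day_hour, x, y, fleet = "aquaculture") {
  data.frame(vessel_id = id, fleet = fleet,
             timestamp = as.POSIXct("2020-01-01", tz = "UTC") +
               day_hour[1] * 86400 + day_hour[2] * 3600,
             lon = NA_real_, lat = NA_real_, x = x, y = y,
             stringsAsFactors = FALSE)
}

test_that("vessel density implements the unique-vessels-per-day definition", {
  g <- mk_grid(4)
  # 2-day month: cell (0.5, 0.5) crossed by {A, B} on day 1 and {A} on day 2
  rec <- rbind(vr("A", c(0, 1), 0.5, 0.5), vr("B", c(0, 2), 0.5, 0.5),
               vr("A", c(1, 1), 0.5, 0.5))
  vd <- vessel_density(rec, g)
  expect_equal(vd$values[4, 1], 1.5)  # (2 + 1) / 2
  expect_equal(sum(vd$values), 1.5)

  # pinging twice in one cell in one day still counts once
  rec2 <- rbind(vr("A", c(0, 1), 0.5, 0.5), vr("A", c(0, 5), 0.6, 0.6))
  vd2 <- vessel_density(rec2, g)
  expect_equal(vd2$values[4, 1], 1)

  # one stationary vessel on one day: density 1 in its cell, 0 elsewhere
  rec3 <- vr("A", c(0, 1), 2.5, 2.5)
  vd3 <- vessel_density(rec3, g)
  expect_equal(vd3$values[2, 3], 1)
  expect_equal(sum(vd3$values), 1)
})

test_that("segment crossings credit every traversed cell exactly once", {
  g <- mk_grid(6)
  # consecutive fixes in non-adjacent cells: intermediate cells credited
  rec <- rbind(vr("A", c(0, 1), 0.5, 0.5), vr("A", c(0, 2), 4.5, 0.5))
  vd <- vessel_density(rec, g)
  expect_equal(vd$values[6, 1:5], rep(1, 5))
  expect_equal(sum(vd$values), 5)

  # random segments: the cell walk equals a dense point-sampling oracle
  set.seed(14)
  for (k in 1:10) {
    p0 <- runif(2, 0.05, 5.95); p1 <- runif(2, 0.05, 5.95)
    walk <- ctcrwrisk:::segment_cells(g, p0[1], p0[2], p1[1], p1[2])
    tt <- seq(0, 1, length.out = 20001)
    pts <- cbind(p0[1] + tt * (p1[1] - p0[1]), p0[2] + tt * (p1[2] - p0[2]))
    oracle <- unique(ctcrwrisk:::cell_index(g, pts[, 1], pts[, 2]))
    expect_setequal(paste(walk[, 1], walk[, 2]),
                    paste(oracle[, 1], oracle[, 2]))
  }
})

test_that("mean aggregation to the coarse grid honours masks and alignment", {
  fine <- grid_raster(matrix(1:64, 8, 8), 0, 0, 1)
  ag <- aggregate_mean(fine, 8)
  expect_equal(dim(ag$values), c(1, 1))
  expect_equal(ag$values[1, 1], 32.5)
  expect_equal(ag$cell_size, 8)

  uni <- grid_raster(matrix(4, 16, 16), 0, 0, 1)
  expect_true(all(aggregate_mean(uni, 8)$values == 4))

  half <- grid_raster(matrix(1:64, 8, 8), 0, 0, 1)
  half$values[1:4, ] <- NA
  expect_equal(aggregate_mean(half, 8)$values[1, 1],
               mean(matrix(1:64, 8, 8)[5:8, ]))

  expect_error(aggregate_mean(grid_raster(matrix(0, 9, 9), 0, 0, 1), 8),
               "misaligned")
})

test_that("RPEW normalizes density over residence time", {
  g <- mk_grid(4)
  N <- g; N$values <- matrix(2, 4, 4)
  nu <- g; nu$values <- matrix(0.5, 4, 4)
  r <- rpew(N, nu)
  expect_true(all(abs(r$values - 1 / 16) < 1e-12))
  expect_equal(sum(r$values), 1)

  # scale invariance in N
  N2 <- N; N2$values <- N$values * 7
  expect_equal(rpew(N2, nu)$values, r$values)

  # 2-cell worked example: N = (2, 1), nu = (1, 2) -> (0.8, 0.2)
  N3 <- grid_raster(matrix(c(2, 1), 1, 2), 0, 0, 8)
  nu3 <- grid_raster(matrix(c(1, 2), 1, 2), 0, 0, 8)
  expect_equal(as.vector(rpew(N3, nu3)$values), c(0.8, 0.2))
})

test_that("RPVEW multiplies and renormalizes the three probability fields", {
  k <- 16
  g <- mk_grid(4)
  N <- g; N$values <- matrix(1, 4, 4)
  nu <- g; nu$values <- matrix(1, 4, 4)
  vd <- g; vd$values <- matrix(2, 4, 4)
  rp <- rpvew(N, nu, vd)
  expect_true(all(abs(rp$rpvew$values - 1 / k) < 1e-12))
  for (layer in rp) expect_equal(sum(layer$values), 1)

  # a cell without vessels annihilates risk there regardless of whales
  vd0 <- vd; vd0$values[2, 2] <- 0
  rp0 <- rpvew(N, nu, vd0)
  expect_equal(rp0$rpvew$values[2, 2], 0)

  # 2-cell worked example: N = (1,1), nu = (1,1), VD = (3,1) -> (0.75, 0.25)
  N2 <- grid_raster(matrix(c(1, 1), 1, 2), 0, 0, 8)
  nu2 <- grid_raster(matrix(c(1, 1), 1, 2), 0, 0, 8)
  vd2 <- grid_raster(matrix(c(3, 1), 1, 2), 0, 0, 8)
  expect_equal(as.vector(rpvew(N2, nu2, vd2)$rpvew$values), c(0.75, 0.25))

  vdz <- vd; vdz$values[] <- 0
  expect_error(rpvew(N, nu, vdz), "identically zero")
})

test_that("risk layers sum to one on random fixtures", {
  set.seed(19)
  for (k in 1:5) {
    g <- mk_grid(5)
    N <- g; N$values <- matrix(rexp(25), 5, 5)
    nu <- g; nu$values <- matrix(runif(25, 0.5, 3), 5, 5)
    vd <- g; vd$values <- matrix(rpois(25, 2), 5, 5)
    N$values[sample(25, 3)] <- NA  # masked cells stay out of the sums
    if (sum(vd$values[!is.na(N$values)]) == 0) next
    expect_equal(sum(rpew(N, nu)$values, na.rm = TRUE), 1)
    rp <- rpvew(N, nu, vd)
    for (layer in rp)
      expect_equal(sum(layer$values, na.rm = TRUE), 1)
  }
})

test_that("overlap statistics behave like similarity measures", {
  lay <- function(v) grid_raster(matrix(v, 1, length(v)), 0, 0, 8)

  ident <- overlap_stats(lay(c(0.2, 0.5, 0.3, 0)), lay(c(0.2, 0.5, 0.3, 0)))
  expect_equal(unname(ident), c(1, 1))

  disj <- overlap_stats(lay(c(1, 0)), lay(c(0, 1)))
  expect_equal(unname(disj), c(0, 0))

  # distributions (0.75, 0.25) vs (0.25, 0.75): D = 0.5, I ~ 0.866
  a <- lay(c(0.75, 0.25, 0)); b <- lay(c(0.25, 0.75, 0))
  st <- overlap_stats(a, b)
  expect_equal(unname(st["D"]), 0.5)
  expect_equal(unname(st["I"]),
               1 - 0.5 * ((sqrt(.75) - sqrt(.25))^2 +
                          (sqrt(.25) - sqrt(.75))^2),
               tolerance = 1e-12)
  expect_equal(unname(st["I"]), 0.866, tolerance = 1e-3)

  # symmetry and range on random non-negative layers
  set.seed(23)
  for (k in 1:5) {
    u <- lay(c(rexp(7), 0)); v <- lay(c(rexp(7), 0))
    s1 <- overlap_stats(u, v); s2 <- overlap_stats(v, u)
    expect_equal(s1, s2)
    expect_true(all(s1 >= 0 & s1 <= 1))
  }

  # with zero minima the min-max rescale is a no-op after sum-normalization:
  # doubling a layer leaves both statistics unchanged
  u <- lay(c(rexp(7), 0)); v <- lay(c(rexp(7), 0))
  u2 <- u; u2$values <- u$values * 2
  expect_equal(overlap_stats(u, v), overlap_stats(u2, v))

  expect_error(overlap_stats(lay(rep(2, 4)), lay(c(1, 2, 3, 4))),
               "constant")
})
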