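test_that("distance raster matches exact geometry and a brute-force oracle", {
  g <- grid_template(5, 5, cell = 1000)
  # cell centred exactly on a point feature
  d0 <- compute_distance_raster(g, points = cbind(2500, 2500))
  expect_equal(d0$values[3, 3], 0)
  # 3-4-5 triangle: point at origin corner, centre at (3000, 4000) offsets
  g2 <- grid_template(10, 10, cell = 1000)
  d2 <- compute_distance_raster(g2, points = cbind(0, 0))
  rc <- grid_cell_of(g2, 3000 - 500, 4000 - 500)  # centre (2500, 3500)
  expect_equal(d2$values[rc$row, rc$col], sqrt(2500^2 + 3500^2))
  # brute-force oracle on a toy grid with a polyline densely sampled
  line <- cbind(c(800, 2600, 4100), c(300, 2900, 4800))
  d3 <- compute_distance_raster(g, lines = list(line))
  tseq <- seq(0, 1, length.out = 4001)
  dense <- rbind(
    cbind(line[1, 1] + tseq * (line[2, 1] - line[1, 1]),
          line[1, 2] + tseq * (line[2, 2] - line[1, 2])),
    cbind(line[2, 1] + tseq * (line[3, 1] - line[2, 1]),
          line[2, 2] + tseq * (line[3, 2] - line[2, 2])))
  co <- grid_coords(g)
  oracle <- vapply(seq_len(nrow(co)), function(i)
    sqrt(min((dense[, 1] - co$x[i])^2 + (dense[, 2] - co$y[i])^2)), 0)
  expect_lt(max(abs(as.vector(d3$values) - oracle)), 1.5) # dense-sampling gap
  expect_error(compute_distance_raster(g), "no features")
})

test_that("distance rasters are non-negative and 1-Lipschitz", {
  g <- grid_template(12, 9, cell = 500)
  d <- compute_distance_raster(g, points = cbind(c(1000, 3100), c(800, 4700)))
  expect_true(all(d$values >= 0))
  # horizontal and vertical neighbour differences bounded by the cell size
  expect_true(all(abs(diff(d$values)) <= 500 + 1e-9))
  expect_true(all(abs(t(diff(t(d$values)))) <= 500 + 1e-9))
})

test_that("focal_fill fills from the circular neighbourhood only", {
  m <- matrix(7, 5, 5)
  g <- raster_grid(m, cell = 1000)
  expect_identical(focal_fill(g)$values, g$values)  # no missing: identity
  m2 <- m; m2[3, 3] <- NA
  expect_equal(focal_fill(raster_grid(m2, cell = 1))$values[3, 3], 7)
  # hand-computed mean of enumerated in-circle neighbours
  m3 <- matrix(NA_real_, 5, 5)
  m3[3, 2] <- 1; m3[1, 3] <- 2; m3[4, 4] <- 3; m3[5, 3] <- 6
  # neighbours of (3,3) within 2 cells: (3,2) d=1, (1,3) d=2, (4,4) d=sqrt(2),
  # (5,3) d=2 -> all four in circle, mean 3
  filled <- focal_fill(raster_grid(m3, cell = 1), radius_cells = 2)
  expect_equal(filled$values[3, 3], 3)
  # valid cells never altered; filled values within input range
  w <- small_world()
  sst <- w$stack$layers$sst
  holes <- sst
  set.seed(1)
  idx <- sample(which(!is.na(holes$values)), 40)
  holes$values[idx] <- NA
  ff <- focal_fill(holes)
  valid <- which(!is.na(holes$values))
  expect_identical(ff$values[valid], holes$values[valid])
  rng <- range(holes$values, na.rm = TRUE)
  expect_true(all(ff$values[idx] >= rng[1] & ff$values[idx] <= rng[2],
                  na.rm = TRUE))
  # idempotent once no fillable cells remain (iterate to the fixpoint first)
  ff2 <- ff
  for (i in 1:60) {
    nxt <- focal_fill(ff2)
    if (identical(nxt$values, ff2$values)) break
    ff2 <- nxt
  }
  expect_identical(focal_fill(ff2)$values, ff2$values)
  expect_warning(focal_fill(raster_grid(matrix(NA_real_, 3, 3), cell = 1)),
                 "all cells missing")
})

test_that("bilinear resampling reproduces constants and affine ramps", {
  src <- raster_grid(matrix(4.2, 6, 6), cell = 1000)
  tgt <- grid_template(3, 3, cell = 2000)
  expect_true(all(resample_bilinear(src, tgt)$values == 4.2))
  # 2x2 symmetric case: target centre at the middle of four source centres
  src2 <- raster_grid(matrix(c(0, 1, 1, 2), 2, 2), cell = 1000)
  tgt2 <- grid_template(1, 1, cell = 2000)
  expect_equal(resample_bilinear(src2, tgt2)$values[1, 1], 1)
  # affine field f(x, y) = ax + by is reproduced exactly at interior centres
  g <- grid_template(20, 20, cell = 500)
  co <- grid_coords(g)
  f <- grid_like(g, matrix(2e-3 * co$x - 1e-3 * co$y, 20, 20))
  tgt3 <- grid_template(10, 10, cell = 1000)
  out <- resample_bilinear(f, tgt3)
  co3 <- grid_coords(tgt3)
  expected <- 2e-3 * co3$x - 1e-3 * co3$y
  interior <- co3$x > 500 & co3$x < 9500 & co3$y > 500 & co3$y < 9500
  expect_lt(max(abs(as.vector(out$values) - expected)[interior]), 1e-9)
  expect_error(resample_bilinear(src, grid_template(3, 3, cell = 1000,
                                                    x0 = 1e6, y0 = 1e6)),
               "disjoint")
})

test_that("transform_and_rescale applies tags and preserves order", {
  g <- function(v) raster_grid(matrix(v, 1), cell = 1)
  st <- covariate_stack(list(a = g(c(1, exp(1), exp(2))),
                             b = g(c(5, 5, 5)),
                             c = g(c(0, 1, 4))))
  out <- transform_and_rescale(st, c(a = "log", c = "sqrt"))
  expect_equal(as.vector(out$layers$a$values), c(0, 0.5, 1))
  expect_equal(as.vector(out$layers$b$values), c(0, 0, 0)) # zero range
  expect_equal(as.vector(out$layers$c$values), c(0, 0.5, 1))
  expect_error(
    transform_and_rescale(covariate_stack(list(a = g(c(-1, 2, 3)))),
                          c(a = "log")),
    "negative value under log")
  # rank preservation on a random layer
  set.seed(2)
  v <- rlnorm(50)
  st2 <- covariate_stack(list(z = raster_grid(matrix(v, 5), cell = 1)))
  out2 <- transform_and_rescale(st2, c(z = "log"))
  expect_equal(cor(v, as.vector(out2$layers$z$values), method = "spearman"), 1)
  expect_true(all(out2$layers$z$values >= 0 & out2$layers$z$values <= 1))
})

test_that("collinearity screen enforces thresholds, verified against lm", {
  set.seed(3)
  n <- 200
  ortho <- data.frame(a = rep(c(-1, 1), n / 2), b = rep(c(-1, 1), each = n / 2))
  res <- collinearity_screen(ortho)
  expect_setequal(res$retained, c("a", "b"))
  expect_equal(unname(res$vif), c(1, 1), tolerance = 0.05)
  # duplicated covariate: exactly one dropped
  dup <- data.frame(a = rnorm(n))
  dup$b <- dup$a
  dup$c <- rnorm(n)
  res2 <- collinearity_screen(dup)
  expect_equal(nrow(res2$dropped), 1)
  expect_length(res2$retained, 2)
  # x3 = x1 + x2 + tiny noise: one dropped, survivor VIFs verified vs lm oracle
  tri <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  tri$x3 <- tri$x1 + tri$x2 + rnorm(n, 0, 0.01)
  res3 <- collinearity_screen(tri)
  expect_length(res3$retained, 2)
  for (j in res3$retained) {
    fit <- lm(reformulate(setdiff(res3$retained, j), j),
              data = tri[res3$retained])
    expect_equal(unname(res3$vif[j]), 1 / (1 - summary(fit)$r.squared),
                 tolerance = 1e-8)
    expect_lte(res3$vif[[j]], 4.5)
  }
  cm <- abs(cor(tri[res3$retained]))
  diag(cm) <- 0
  expect_lt(max(cm), 0.7)
})
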