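test_that("quartic kernel density integrates to the point count", {
  g <- grid_template(20, 20, cell = 3000, x0 = 0, y0 = 0)
  expect_true(all(fishing_kde(numeric(0), numeric(0), g)$values == 0))
  # one interior point: cell-area-weighted density integrates to ~1 within
  # 2% once the grid resolves the kernel (500 m cells, 5 km radius)
  gf <- grid_template(60, 60, cell = 500)
  kf <- fishing_kde(15000, 15000, gf, radius_m = 5000)
  expect_equal(sum(kf$values) * 500^2, 1, tolerance = 0.02)
  kde1 <- fishing_kde(30000, 30000, g, radius_m = 5000)
  # two coincident points: exactly twice the single-point surface
  kde2 <- fishing_kde(c(30000, 30000), c(30000, 30000), g, radius_m = 5000)
  expect_equal(kde2$values, 2 * kde1$values)
  # weights mirror point multiplicity
  kdew <- fishing_kde(30000, 30000, g, radius_m = 5000, weights = 2)
  expect_equal(kdew$values, kde2$values)
  # translation equivariance on the grid lattice (+1 cell east, +1 north)
  kde3 <- fishing_kde(33000, 33000, g, radius_m = 5000)
  expect_equal(kde3$values[1:19, 2:20], kde1$values[2:20, 1:19],
               tolerance = 1e-12)
  # linearity in the point set
  kde4 <- fishing_kde(c(30000, 45000), c(30000, 12000), g, radius_m = 5000)
  kde5a <- fishing_kde(30000, 30000, g, radius_m = 5000)
  kde5b <- fishing_kde(45000, 12000, g, radius_m = 5000)
  expect_equal(kde4$values, kde5a$values + kde5b$values)
})

test_that("quantile reclassification splits positive support into thirds", {
  g1 <- grid_template(1, 99, cell = 1000)
  r <- grid_like(g1, matrix(1:99, 1))
  cls <- quantile_reclass(r)
  expect_equal(as.vector(table(cls$values)), c(33, 33, 33))
  # sorting oracle
  expect_true(all(cls$values[1, 1:33] == 1))
  expect_true(all(cls$values[1, 67:99] == 3))
  # zeros forced to class 1, positive gradient split in three
  g2 <- grid_template(1, 100, cell = 1000)
  r2 <- grid_like(g2, matrix(c(rep(0, 90), 1:10), 1))
  cls2 <- quantile_reclass(r2)
  expect_true(all(cls2$values[1, 1:90] == 1))
  expect_equal(as.vector(table(cls2$values[1, 91:100])), c(4, 3, 3))
  expect_warning(quantile_reclass(grid_like(g1, matrix(0, 1, 99))),
                 "all-zero")
  expect_warning(quantile_reclass(grid_like(g1, matrix(2, 1, 99))),
                 "constant")
})

test_that("interaction likelihood follows the summed-class mapping", {
  g <- grid_template(2, 3, cell = 1000)
  a <- grid_like(g, matrix(c(1, 1, 2, 3, 3, 3), 2, 3))
  b <- grid_like(g, matrix(c(1, 2, 2, 1, 2, 3), 2, 3))
  out <- interaction_likelihood(a, b)
  # sums: 2,3 -> 1; 4 -> 2; 5,6 -> 3
  expect_equal(as.vector(out$values), c(1, 1, 2, 2, 3, 3))
  expect_error(interaction_likelihood(grid_like(g, matrix(4, 2, 3)), b),
               "outside 1-3")
})

test_that("exposure/consequence scores are d*w-weighted averages", {
  crit <- function(scores, d, w, dim = "exposure") {
    data.frame(stressor = "s", subregion = "near", dimension = dim,
               criterion = paste0("c", seq_along(scores)), score = scores,
               data_quality = d, weight = w, spatial_layer = NA)
  }
  both <- function(e) rbind(e, crit(2, 1, 1, "consequence"))
  # constant scores: weighted mean is the constant
  expect_equal(ec_scores(both(crit(c(2, 2, 2), c(1, 2, 3), c(3, 2, 1))))$E, 2)
  # hand arithmetic: scores {3,1}, d*w {1,3} -> (3 + 1/3) / (1 + 1/3) = 2.5
  expect_equal(ec_scores(both(crit(c(3, 1), c(1, 3), c(1, 1))))$E, 2.5)
  # omitted criterion identical to dropping the row
  e1 <- ec_scores(both(crit(c(3, 1, 0), c(1, 3, 2), c(1, 1, 3))))$E
  expect_equal(e1, 2.5)
  # scale invariance to multiplying all d*w by a constant is built in:
  # compare d=1,w=1 vs d=3,w=3 patterns scaled jointly
  eA <- ec_scores(both(crit(c(3, 1), c(1, 2), c(2, 1))))$E
  eB <- ec_scores(both(crit(c(3, 1), c(2, 1), c(1, 2))))$E   # same products
  expect_equal(eA, eB)
  expect_error(ec_scores(crit(c(0, 0), c(1, 1), c(1, 1))), "omitted")
  # spatial criterion: cell classes enter as scores
  g <- grid_template(2, 2, cell = 1000)
  lyr <- grid_like(g, matrix(c(1, 2, 3, 2), 2, 2))
  spat <- crit(NA, 2, 3)
  spat$spatial_layer <- "intensity"
  tab <- rbind(crit(3, 1, 1), spat, crit(2, 1, 1, "consequence"))
  ec <- ec_scores(tab, spatial_layers = list(intensity = lyr), template = g)
  w1 <- 1; w2 <- 1 / 6
  expect_equal(ec$E$values, (3 * w1 + lyr$values * w2) / (w1 + w2))
  expect_true(all(ec$E$values >= 1 & ec$E$values <= 3))
})

test_that("risk is Euclidean distance from (1,1), gated by overlap", {
  g <- grid_template(1, 3, cell = 1000)
  E <- grid_like(g, matrix(c(3, 1, 3), 1))
  C <- grid_like(g, matrix(c(3, 1, 1), 1))
  ov <- grid_like(g, matrix(c(1, 1, 1), 1))
  r <- risk_surface(E, C, ov)
  expect_equal(as.vector(r$values), c(2 * sqrt(2), 0, 2))
  expect_equal(round(r$values[1, 1], 2), 2.83)
  # zero outside overlap
  ov0 <- grid_like(g, matrix(c(0, 1, 0), 1))
  expect_equal(as.vector(risk_surface(E, C, ov0)$values), c(0, 0, 0))
})

test_that("cumulative risk sums stressors with subregion statistics", {
  g <- grid_template(2, 2, cell = 1000)
  maxr <- grid_like(g, matrix(2 * sqrt(2), 2, 2))
  sub <- grid_like(g, matrix(c(1, 1, 2, 2), 2, 2))
  cum <- cumulative_and_stats(list(a = maxr, b = maxr), sub)
  expect_equal(round(max(cum$cumulative$values), 2), 5.66)
  expect_equal(cum$cumulative$values, maxr$values * 2)
  # one stressor zero everywhere: cumulative equals the other surface
  zero <- grid_like(g, matrix(0, 2, 2))
  cum2 <- cumulative_and_stats(list(a = maxr, b = zero), sub)
  expect_equal(cum2$cumulative$values, maxr$values)
  # constructed 4-cell case with hand-computed means and maxima
  E <- grid_like(g, matrix(c(3, 2, 1, 2), 2, 2))
  C <- grid_like(g, matrix(c(3, 2, 1, 3), 2, 2))
  ov <- grid_like(g, matrix(c(1, 1, 0, 1), 2, 2))
  r <- risk_surface(E, C, ov)
  st <- cumulative_and_stats(list(s = r), sub, E = list(s = E), C = list(s = C),
                             subregion_names = list("1" = "near", "2" = "off"))
  near <- st$stats[st$stats$subregion == "near", ]
  expect_equal(near$mean_risk, mean(c(2 * sqrt(2), sqrt(2))))
  expect_equal(near$max_risk, 2 * sqrt(2))
  off <- st$stats[st$stats$subregion == "off", ]
  expect_equal(off$n_overlap, 1)
  expect_equal(off$max_risk, sqrt(1 + 4))
  expect_equal(st$ec_scatter$max_E, c(3, 2))
})

test_that("risk is monotone in criterion scores and bounded", {
  set.seed(22)
  base <- data.frame(stressor = "s", subregion = "n",
                     dimension = rep(c("exposure", "consequence"), each = 3),
                     criterion = paste0("c", 1:6),
                     score = sample(1:3, 6, TRUE),
                     data_quality = sample(1:3, 6, TRUE),
                     weight = sample(1:3, 6, TRUE), spatial_layer = NA)
  g <- grid_template(1, 1, cell = 1000)
  ov <- grid_like(g, matrix(1))
  risk_of <- function(tab) {
    ec <- ec_scores(tab, template = g)
    risk_surface(ec$E, ec$C, ov)$values[1, 1]
  }
  r0 <- risk_of(base)
  expect_lte(r0, 2 * sqrt(2))
  for (i in 1:6) {
    if (base$score[i] < 3) {
      up <- base
      up$score[i] <- up$score[i] + 1
      expect_gte(risk_of(up), r0)
    }
  }
})

test_that("subregion raster codes the 5 NM artisanal strip", {
  g <- grid_template(1, 5, cell = 1000)
  d <- grid_like(g, matrix(c(2000, 9260, 9500, 50000, 150000), 1))
  sr <- subregion_raster(d)
  expect_equal(as.vector(sr$values), c(1, 1, 2, 2, NA))
  expect_equal(nrow(uncertainty_table()), 4)
  expect_error(uncertainty_table(presence = "blue"))
})
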