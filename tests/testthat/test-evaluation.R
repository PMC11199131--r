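test_that("AUC matches exhaustive pair enumeration", {
  expect_equal(auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1)), 0.75)
  expect_equal(auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)   # ties count half
  expect_error(auc(c(1, 1), c(0.2, 0.4)), "one class")
  # oracle: concordant-pair fraction with ties at 1/2, random inputs
  set.seed(13)
  for (r in 1:5) {
    n <- sample(20:200, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), 2)   # force some ties
    pos <- which(labels == 1); neg <- which(labels == 0)
    pairs <- expand.grid(i = pos, j = neg)
    conc <- mean((scores[pairs$i] > scores[pairs$j]) +
                   0.5 * (scores[pairs$i] == scores[pairs$j]))
    expect_equal(auc(labels, scores), conc)
  }
})

test_that("max-TSS threshold and confusion metrics behave at the extremes", {
  lab <- c(0, 0, 0, 1, 1, 1)
  sc <- c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)
  cm <- confusion_metrics(lab, sc)
  expect_equal(cm$tss, 1)   # perfect classifier
  # predict-all-positive: sens 1, spec 0, TSS 0
  cm2 <- confusion_metrics(lab, sc, threshold = 0)
  expect_equal(c(cm2$sensitivity, cm2$specificity, cm2$tss), c(1, 0, 0))
  # label-independent scores: TSS near 0 at large n
  set.seed(14)
  lab3 <- rbinom(4000, 1, 0.5)
  sc3 <- runif(4000)
  thr <- max_tss_threshold(lab3[1:2000], sc3[1:2000])
  cm3 <- confusion_metrics(lab3[2001:4000], sc3[2001:4000], thr)
  expect_lt(abs(cm3$tss), 0.1)
  # TSS invariant to class swap with the threshold rule mirrored (threshold
  # between observed scores so tie handling cannot differ)
  cm_mid <- confusion_metrics(lab, sc, threshold = 0.5)
  cm4 <- confusion_metrics(1 - lab, -sc, threshold = -0.5)
  expect_equal(cm4$tss, cm_mid$tss, tolerance = 1e-12)
  expect_equal(cm4$sensitivity, cm_mid$specificity)
})

test_that("Boyce index separates proportional, null and inverted designs", {
  set.seed(15)
  bg <- runif(4000)
  prop <- sample(bg, 1000, prob = bg, replace = TRUE)
  inv <- sample(bg, 1000, prob = 1 - bg, replace = TRUE)
  expect_gt(boyce_index(prop, bg)$cbi, 0.85)
  expect_lt(boyce_index(inv, bg)$cbi, -0.85)
  expect_error(boyce_index(numeric(0), bg), "presence")
  expect_error(boyce_index(rep(1, 10), rep(0, 10), n_windows = 3),
               "valid windows")
  # near-invariance to a strictly monotone transform of the scores
  cbi1 <- boyce_index(prop, bg)$cbi
  cbi2 <- boyce_index(prop^3, bg^3)$cbi
  expect_equal(cbi1, cbi2, tolerance = 0.1)
})

test_that("spatial blocks tile samples and minimise class imbalance", {
  set.seed(16)
  n <- 400
  samples <- data.frame(x = runif(n, 0, 50000), y = runif(n, 0, 50000),
                        label = rbinom(n, 1, 0.5))
  fa <- make_spatial_blocks(samples, 10000, k = 5, n_iter = 100, seed = 77)
  expect_length(fa$fold, n)
  expect_true(all(fa$fold %in% 1:5))
  # every sample falls in exactly one block; fold from its block
  expect_equal(fa$fold, fa$blocks$fold[match(
    paste(floor((samples$x - min(samples$x)) / 10000),
          floor((samples$y - min(samples$y)) / 10000)),
    paste(floor((fa$blocks$xmin - min(samples$x)) / 10000),
          floor((fa$blocks$ymin - min(samples$y)) / 10000)))])
  # the chosen iteration is the evenness minimiser
  expect_equal(fa$evenness, min(fa$evenness_all))
  expect_lte(fa$evenness, median(fa$evenness_all))
  # reproducible under seed
  fa2 <- make_spatial_blocks(samples, 10000, k = 5, n_iter = 100, seed = 77)
  expect_identical(fa$fold, fa2$fold)
  # degenerate: all samples in one block -> warning about empty folds
  one <- data.frame(x = runif(20, 0, 10), y = runif(20, 0, 10),
                    label = rep(c(0, 1), 10))
  expect_warning(make_spatial_blocks(one, 1e6, k = 5, seed = 1),
                 "without presences")
})

test_that("variogram recovers spatial structure scales", {
  set.seed(17)
  # pure white noise: fitted practical range small / flat structure
  n <- 300
  x <- runif(n, 0, 10000); y <- runif(n, 0, 10000)
  z <- rnorm(n)
  vg <- variogram_range(z, x, y)
  expect_lt(vg$psill, 0.5 * var(z) + 0.1)  # little structured variance
  # Gaussian random field with known correlation scale: smoothing with a
  # kernel of sd 8 cells gives practical decorrelation near 2 * sd * sqrt(2)
  # cells (~23 km at 1 km cells); accept [0.5, 2] times that
  hit <- 0
  L <- 2 * 8 * sqrt(2) * 1000
  for (r in 1:10) {
    set.seed(400 + r)
    f <- gaussian_field(120, 120, range_cells = 8, sd = 1)
    idx <- sample(120 * 120, 500)
    rr <- ((idx - 1) %% 120) + 1; cc <- ((idx - 1) %/% 120) + 1
    vgf <- variogram_range(f[cbind(rr, cc)], cc * 1000, rr * 1000,
                           max_lag = 40000)
    if (vgf$range > 0.5 * L && vgf$range < 2 * L) hit <- hit + 1
  }
  expect_gte(hit, 8)
  expect_error(variogram_range(rep(1, 40), runif(40), runif(40)),
               "no spatial structure")
  # gamma at small lags below sample variance (numerical sanity)
  expect_lte(vg$gamma[1], var(z) * 1.3)
})

test_that("cross-validation reports are structured and symmetric", {
  # k = 2 with identical halves: fold metrics equal
  df <- logistic_data(400, c(-0.5, 2.5), seed = 70)
  df2 <- rbind(df, df)
  fold <- rep(1:2, each = 400)
  rep2 <- run_blocked_cv(df2, "x1", fold)
  expect_equal(rep2$folds$auc[1], rep2$folds$auc[2], tolerance = 1e-9)
  # LOIO on synthetic individuals: one row per individual
  s <- mid_samples()
  covs <- c("sst", "chl", "depth")
  rep_l <- run_loio_cv(s, covs)
  expect_equal(sort(rep_l$folds$fold), sort(unique(s$individual_id)))
  expect_true(all(rep_l$folds$tss ==
                    rep_l$folds$sensitivity + rep_l$folds$specificity - 1))
  expect_true(all(rep_l$folds$auc >= 0 & rep_l$folds$auc <= 1))
})
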