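test_that("NEK surface follows a^(d/d0) with log-linear decay", {
  g <- grid_template(9, 9, cell = 1000)
  colony <- c(4500, 4500)
  nk <- nek_surface(g, colony, a = 0.04, d0_km = 1)
  rc <- grid_cell_of(g, colony[1], colony[2])
  expect_equal(nk$raster$values[rc$row, rc$col], 1)        # d = 0 -> 1
  # a = 0.04 at d = 2 km, d0 = 1 -> 0.04^2
  rc2 <- grid_cell_of(g, colony[1] + 2000, colony[2])
  expect_equal(nk$raster$values[rc2$row, rc2$col], 0.0016)
  expect_true(all(nek_surface(g, colony, a = 1)$raster$values == 1))
  # log surface linear in distance with slope log(a)/d0
  co <- grid_coords(g)
  d_km <- sqrt((co$x - colony[1])^2 + (co$y - colony[2])^2) / 1000
  lv <- log(as.vector(nk$raster$values))
  keep <- d_km > 0
  expect_equal(unname(lm(lv[keep] ~ d_km[keep])$coefficients[2]), log(0.04),
               tolerance = 1e-9)
  expect_error(nek_surface(g, colony, a = 0), "\\(0, 1\\]")
  expect_error(nek_surface(g, colony, a = 1.2), "\\(0, 1\\]")
})

test_that("fit_glm recovers parameters and flags degenerate designs", {
  # single covariate with true slope 3: estimate within 2 SE at n = 2000
  df <- logistic_data(2000, c(-1.5, 3), seed = 10)
  m <- fit_glm(df, "x1")
  expect_lt(abs(m$coef[["x1"]] - 3), 2 * m$table$se[m$table$term == "x1"])
  # labels independent of covariates: slope |stat| small, intercept near
  # logit(prevalence)
  df2 <- logistic_data(4000, c(0.4, 0), seed = 11)
  m2 <- fit_glm(df2, "x1")
  expect_lt(abs(m2$table$stat[m2$table$term == "x1"]), 3)
  expect_equal(m2$coef[["(Intercept)"]] + 0.5 * m2$coef[["x1"]],
               logit(mean(df2$label)), tolerance = 0.15)
  # balanced labels, no covariates: intercept ~ 0
  df3 <- data.frame(label = rep(c(0, 1), 100))
  expect_equal(fit_glm(df3, character(0))$coef[["(Intercept)"]], 0,
               tolerance = 1e-8)
  # perfect separation errors with a diagnostic
  sep <- data.frame(x1 = c(1:10, 21:30) / 10, label = rep(c(0, 1), each = 10))
  expect_error(fit_glm(sep, "x1"), "separation")
  # aliased column errors by name
  ali <- logistic_data(200, c(0, 1), seed = 1)
  ali$x2 <- ali$x1
  expect_error(fit_glm(ali, c("x1", "x2")), "x2")
})

test_that("GLM coefficient estimates are unbiased with calibrated intervals", {
  beta <- c(-0.5, 2, -1.5)
  est <- se <- matrix(NA_real_, 50, 2)
  for (r in 1:50) {
    df <- logistic_data(2000, beta, seed = 100 + r)
    m <- fit_glm(df, c("x1", "x2"))
    est[r, ] <- m$coef[c("x1", "x2")]
    se[r, ] <- m$table$se[match(c("x1", "x2"), m$table$term)]
  }
  bias <- colMeans(est) - beta[-1]
  expect_true(all(abs(bias) < 0.1))
  cover <- colMeans(abs(est - rep(beta[-1], each = 50)) < 1.96 * se)
  expect_true(all(cover >= 0.90 & cover <= 0.99))
})

test_that("GLMM estimates random-intercept structure and R2 ordering", {
  # sigma_id = 0: variance estimate ~ 0 and fixed effects match a plain GLM
  df0 <- logistic_data(2700, c(-0.5, 2, -1.5), seed = 30, n_id = 9,
                       sigma_id = 0)
  m0 <- suppressWarnings(fit_glmm(df0, c("x1", "x2")))
  expect_lt(m0$sigma2_id, 0.05)
  g0 <- fit_glm(df0, c("x1", "x2"))
  expect_equal(unname(m0$coef), unname(g0$coef), tolerance = 0.05)
  # conditional R2 >= marginal R2 by definition
  df1 <- logistic_data(2700, c(-0.5, 2, -1.5), seed = 31, n_id = 9,
                       sigma_id = 1)
  m1 <- fit_glmm(df1, c("x1", "x2"))
  expect_gte(m1$r2_conditional, m1$r2_marginal)
  expect_equal(mean(m1$ranef), 0, tolerance = 0.3)
  # single individual falls back to a GLM with a warning
  dfs <- logistic_data(300, c(0, 1), seed = 32, n_id = 1, sigma_id = 0)
  expect_warning(ms <- fit_glmm(dfs, "x1"), "single individual")
  expect_s3_class(ms, "cpf_glm")
})

test_that("prediction surfaces follow the link and respect modes", {
  g <- grid_template(1, 3, cell = 1000)
  st <- covariate_stack(list(x1 = grid_like(g, matrix(c(0.1, 0.5, 0.9), 1))))
  df <- logistic_data(500, c(0, 2), seed = 40, n_id = 5, sigma_id = 0.8)
  m <- fit_glmm(df, "x1")
  # hand-computed inverse logit on the 3-cell stack
  pred <- predict_surface(m, st, mode = "novel")
  eta <- m$coef[["(Intercept)"]] + m$coef[["x1"]] * c(0.1, 0.5, 0.9)
  expect_equal(as.vector(pred$values), 1 / (1 + exp(-eta)), tolerance = 1e-12)
  # conditional minus novel has the sign of b_id everywhere
  id <- names(m$ranef)[which.max(abs(m$ranef))]
  diffs <- predict_surface(m, st, mode = "conditional", id = id)$values -
    pred$values
  expect_true(all(sign(diffs) == sign(m$ranef[[id]])))
  expect_error(predict_surface(m, covariate_stack(list(z = st$layers$x1))),
               "missing covariate")
  # all-zero covariates with zero intercept -> uniform 0.5
  m2 <- list(type = "glm", coef = c("(Intercept)" = 0, x1 = 1),
             covariates = "x1")
  class(m2) <- "cpf_glm"
  st0 <- covariate_stack(list(x1 = grid_like(g, matrix(0, 1, 3))))
  expect_true(all(predict_surface(m2, st0)$values == 0.5))
  # marginal prediction invariant to individual relabelling
  df_rl <- df
  df_rl$individual_id <- chartr("12345", "54321", df_rl$individual_id)
  m_rl <- fit_glmm(df_rl, "x1")
  expect_equal(predict_surface(m_rl, st, mode = "novel")$values, pred$values,
               tolerance = 1e-6)
})

test_that("backward elimination rejects noise and keeps informative sets", {
  # several pure-noise covariates beside one informative: the first covariate
  # eliminated is a noise one and the informative covariate always survives
  # (a lone harmless noise covariate is legitimately kept by the stopping
  # rule, since removing it barely moves the CV AUC)
  ok <- 0
  for (r in 1:10) {
    df <- logistic_data(300, c(-0.5, 3), seed = 200 + r)
    for (j in 1:4) df[[paste0("noise", j)]] <- runif(300)
    out <- backward_eliminate(df, setdiff(names(df), "label"),
                              rep_len(1:5, 300))
    first_ok <- nrow(out$trace) > 1 && grepl("noise", out$trace$removed[2])
    if (first_ok && "x1" %in% out$retained) ok <- ok + 1
  }
  expect_gte(ok, 9)
  # single covariate returned unchanged
  df2 <- logistic_data(300, c(0, 2), seed = 50)
  out2 <- backward_eliminate(df2, "x1", rep_len(1:5, 300))
  expect_equal(out2$retained, "x1")
  # two strong independent covariates: nothing eliminated
  df3 <- logistic_data(1500, c(-0.5, 3, -3), seed = 51)
  out3 <- backward_eliminate(df3, c("x1", "x2"), rep_len(1:5, 1500))
  expect_setequal(out3$retained, c("x1", "x2"))
})

test_that("NEK candidate grid is log-spaced and selection handles one candidate", {
  cand <- nek_candidates()
  expect_length(cand, 10)
  expect_equal(range(cand), c(0.001, 0.9))
  expect_equal(diff(log(cand)), rep(diff(log(cand))[1], 9), tolerance = 1e-12)
  s <- mid_samples()
  w <- mid_world()
  covs <- c("sst", "chl", "depth")
  sel <- select_nek_a(s, covs, w$colony, candidates = 0.05, d0_km = 10)
  expect_equal(sel$a, 0.05)
  expect_equal(nrow(sel$scores), 1)
})

test_that("model JSON serialisation captures coefficients and intercepts", {
  df <- logistic_data(900, c(0, 1.5), seed = 60, n_id = 3, sigma_id = 0.5)
  m <- suppressWarnings(fit_glmm(df, "x1"))
  path <- tempfile(fileext = ".json")
  write_model_json(m, path, meta = list(seed = 60))
  obj <- jsonlite::read_json(path)
  expect_equal(obj$type, "glmm")
  expect_equal(length(obj$random_intercepts), 3)
  expect_equal(obj$meta$seed, 60)
})
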