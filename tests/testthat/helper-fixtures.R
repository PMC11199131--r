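# shared fixtures, built once per test run and memoised

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixture_env)) assign(name, builder(), .fixture_env)
  get(name, .fixture_env)
}

# small synthetic world (60 x 80 km) for fast spatial tests
small_world <- function() {
  fixture("small_world", function() make_environment(seed = 42,
                                                     extent_km = c(60, 80)))
}

# medium world used by sampling-heavy tests
mid_world <- function() {
  fixture("mid_world", function() make_environment(seed = 7,
                                                   extent_km = c(120, 150)))
}

# individual-scheme labeled samples on the medium world
mid_samples <- function() {
  fixture("mid_samples", function() {
    w <- mid_world()
    covs <- c("sst", "chl", "eke", "depth", "slope", "dist_rivers")
    sim <- simulate_tracks(w, n_individuals = 6, fixes_per_id = 150,
                           bad_fix_rate = 0, a_true = 0.05, seed = 11)
    pres <- grid_rarefy(sim$fixes, w$grid, "individual")
    st <- covariate_stack(w$tstack$layers[covs])
    pa <- sample_individual_pa(pres, st, buffer_m = 2000, nu = 0.1, seed = 3)
    s <- rbind(
      data.frame(x = pres$x, y = pres$y, label = 1,
                 individual_id = pres$individual_id),
      data.frame(x = pa$x, y = pa$y, label = 0,
                 individual_id = pa$individual_id))
    cbind(s, extract_covariates(st, s$x, s$y))
  })
}

# labeled logistic data generated directly from the model family
logistic_data <- function(n, beta, seed = 1, n_id = NULL, sigma_id = 0) {
  set.seed(seed)
  k <- length(beta) - 1
  X <- matrix(runif(n * k), n, k)
  colnames(X) <- paste0("x", seq_len(k))
  eta <- beta[1] + X %*% beta[-1]
  df <- as.data.frame(X)
  if (!is.null(n_id)) {
    df$individual_id <- rep_len(paste0("id", seq_len(n_id)), n)
    b <- rnorm(n_id, 0, sigma_id)
    eta <- eta + b[rep_len(seq_len(n_id), n)]
  }
  df$label <- rbinom(n, 1, inv_logit(eta))
  df
}
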