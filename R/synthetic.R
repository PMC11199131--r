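#' Smooth Gaussian random field on a grid
#'
#' White noise smoothed with a separable Gaussian kernel (correlation length
#' about `range_cells`), standardised to zero mean and unit SD. Building
#' block for synthetic covariate fields.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param range_cells smoothing length scale in cells.
#' @param sd output standard deviation.
#' @export
gaussian_field <- function(n_rows, n_cols, range_cells = 10, sd = 1) {
  smoother <- function(n) {
    i <- seq_len(n)
    S <- exp(-outer(i, i, "-")^2 / (2 * range_cells^2))
    S / rowSums(S)
  }
  W <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  f <- smoother(n_rows) %*% W %*% t(smoother(n_cols))
  f <- (f - mean(f)) / stats::sd(f)
  f * sd
}

#' Default true preference coefficients for the synthetic world
#'
#' Named coefficients on the rescaled (0-1) covariates defining the true
#' suitability surface: a productivity-seeking (chlorophyll up), cool-water,
#' shallow-water forager. The remaining covariates (EKE, slope, river and
#' shore distances) are present in the world but carry no true effect, so
#' variable selection has something to reject and the true drivers remain
#' identifiable under profiled pseudo-absences.
#' @export
default_beta_true <- function() {
  c("(Intercept)" = 0.5, chl = 5, sst = -4, depth = -5)
}

#' Generate a synthetic coastal study system
#'
#' Builds a planar study domain emulating an eastern-boundary upwelling
#' coast: a vertical-ish coastline with bays, a central-place colony on the
#' coast, river mouths, and eight covariate layers (SST warming offshore,
#' chlorophyll decaying offshore with river plumes, eddy kinetic energy,
#' depth increasing offshore with a shelf break, slope as the depth gradient,
#' and distances to rivers, shore and shelf). A known true suitability
#' surface, the inverse-logit of `beta_true` on the rescaled covariates, is
#' stored for oracle tests.
#'
#' @param seed RNG seed (the whole world is reproducible from it).
#' @param extent_km domain size c(offshore, alongshore) in km; the default
#'   120 x 300 km gives a long coastline (x = offshore direction) so that
#'   alongshore covariate variation is not swamped by the offshore gradient.
#' @param cell_m cell size (m), default 1 km.
#' @param n_rivers number of river mouths.
#' @param roa_km study-area clip: maximum distance from shore (km).
#' @param shelf_km shelf-break distance from shore (km).
#' @param beta_true named true coefficients (see [default_beta_true()]).
#' @return list (class `synthetic_world`): `grid`, `land_mask`, `coast`,
#'   `colony`, `rivers`, `shelf`, `stack` (raw 8-layer [covariate_stack()]),
#'   `tstack` (transformed + rescaled), `dist_shore`, `suitability`
#'   (`raster_grid` oracle), `roa_mask`, `beta_true`, `seed`.
#' @export
make_environment <- function(seed = 1, extent_km = c(120, 300), cell_m = 1000,
                             n_rivers = 2, roa_km = 100, shelf_km = 30,
                             beta_true = default_beta_true()) {
  stopifnot(extent_km[1] * 1000 / cell_m >= 50,
            extent_km[2] * 1000 / cell_m >= 50)
  n_cols <- round(extent_km[1] * 1000 / cell_m)
  n_rows <- round(extent_km[2] * 1000 / cell_m)
  grid <- grid_template(n_rows, n_cols, cell = cell_m)
  with_seed(seed, {
    ext_y <- n_rows * cell_m
    ys <- seq(0, ext_y, by = 2 * cell_m)
    coast_x <- 18000 + 5000 * sin(2 * pi * ys / 70000) +
      3000 * sin(2 * pi * ys / 23000 + 1)
    coast <- cbind(coast_x, ys)
    shelf <- cbind(coast_x + shelf_km * 1000, ys)
    # rivers confined to one half of the coast so river distance varies
    # mostly alongshore, not as another proxy for distance offshore
    ry <- stats::quantile(ys, seq(0.1, 0.4, length.out = n_rivers))
    rivers <- cbind(stats::approx(ys, coast_x, ry)$y, as.numeric(ry))
    ycol <- ext_y * 0.6   # colony offset from the rivers
    colony <- c(stats::approx(ys, coast_x, ycol)$y + cell_m, ycol)

    dist_shore <- compute_distance_raster(grid, lines = list(coast))
    dist_shelf <- compute_distance_raster(grid, lines = list(shelf))
    dist_rivers <- compute_distance_raster(grid, points = rivers)
    co <- grid_coords(grid)
    coast_at <- stats::approx(ys, coast_x, pmin(pmax(co$y, 0), ext_y),
                              rule = 2)$y
    land <- matrix(as.numeric(co$x < coast_at), n_rows, n_cols)
    land_mask <- grid_like(grid, land)

    d_km <- dist_shore$values / 1000
    at_sea <- land == 0
    depth_base <- ifelse(d_km <= shelf_km, 6.5 * d_km,
                         6.5 * shelf_km + 20 * (d_km - shelf_km))
    depth <- pmax(depth_base * exp(gaussian_field(n_rows, n_cols, 15, 0.5)),
                  1)
    # slope (degrees) from the smooth bathymetric trend, times an
    # independent roughness field, so slope is not a mere proxy for depth
    gx <- depth_base * 0
    gx[, 2:(n_cols - 1)] <- (depth_base[, 3:n_cols] -
                               depth_base[, 1:(n_cols - 2)]) / (2 * cell_m)
    gy <- depth_base * 0
    gy[2:(n_rows - 1), ] <- (depth_base[1:(n_rows - 2), ] -
                               depth_base[3:n_rows, ]) / (2 * cell_m)
    # bounded multiplicative roughness keeps sqrt(slope) well spread after
    # max-rescaling (a heavy-tailed factor would collapse it near zero)
    slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi *
      (0.2 + 1.6 * stats::plogis(gaussian_field(n_rows, n_cols, 8, 2.5)))
    sst <- 15 + 1.5 * pmin(d_km / 100, 3) +
      gaussian_field(n_rows, n_cols, 15, 1.5)
    # chlorophyll driven by river plumes and mesoscale patchiness (not by an
    # offshore trend of its own, which would alias with depth)
    dr_km <- dist_rivers$values / 1000
    plume <- 5 * exp(-dr_km^2 / (2 * 12^2))
    chl <- (0.8 + plume) * exp(gaussian_field(n_rows, n_cols, 12, 1.1))
    eke <- 0.002 + 0.025 *
      stats::plogis(gaussian_field(n_rows, n_cols, 20, 2) +
                      1 * (pmin(d_km / 100, 3) - 0.5))

    mask <- function(m) { m[!at_sea] <- NA_real_; grid_like(grid, m) }
    stack <- covariate_stack(list(
      sst = mask(sst), chl = mask(chl), eke = mask(eke), depth = mask(depth),
      slope = mask(slope), dist_rivers = mask(dist_rivers$values),
      dist_shore = mask(dist_shore$values),
      dist_shelf = mask(dist_shelf$values)))
    tstack <- transform_and_rescale(
      stack, c(chl = "log", depth = "log", slope = "sqrt"))

    eta <- matrix(beta_true[["(Intercept)"]], n_rows, n_cols)
    for (v in setdiff(names(beta_true), "(Intercept)"))
      eta <- eta + beta_true[[v]] * tstack$layers[[v]]$values
    suit <- inv_logit(eta)
    suit[!at_sea] <- NA_real_
    roa <- matrix(as.numeric(at_sea & d_km <= roa_km), n_rows, n_cols)

    structure(list(grid = grid, land_mask = land_mask, coast = coast,
                   colony = colony, rivers = rivers, shelf = shelf,
                   stack = stack, tstack = tstack, dist_shore = dist_shore,
                   suitability = grid_like(grid, suit),
                   roa_mask = grid_like(grid, roa),
                   roa_km = roa_km, beta_true = beta_true, seed = seed),
              class = "synthetic_world")
  })
}

#' Simulate central-place forager GPS tracks
#'
#' Per individual i an intercept `b_i ~ N(0, sigma_id^2)` is drawn and at-sea
#' positions are sampled from the stationary law proportional to
#' `inv_logit(logit(s(x)) + b_i + nek_beta * (a_true^(d(x)/d0) - 1))` over
#' sea cells inside the study area — the same model family the
#' random-intercept GLMM with a NEK fixed effect assumes, so kernel and
#' coefficient recovery are fair tests (`a_true = 1` reduces exactly to
#' suitability-only sampling). Sampling is a Metropolis chain whose proposal
#' is uniform over
#' cells within `0.9 * vmax * fix_interval_s` of the current position — so a
#' clean track can never violate the speed filter while the marginal remains
#' the suitability-times-accessibility product the downstream models assume.
#' Fixes are timestamped every `fix_interval_s` seconds.
#'
#' A fraction `bad_fix_rate` of fixes (kept at least three fix indices apart
#' so each corruption triggers exactly one filter) is corrupted: low
#' satellite count, high residual error, displacement onto land, or a
#' long-range teleport that violates the speed rule. All injected corruptions
#' are logged in a truth table for audit reconciliation.
#'
#' @param world a `synthetic_world`.
#' @param n_individuals number of animals (default 9).
#' @param fixes_per_id fixes per animal (default 300).
#' @param a_true NEK decay coefficient generating the tracks (default 0.05).
#' @param d0_km NEK distance scale (default 10 km, so small decay values give
#'   realistic tens-of-km foraging ranges).
#' @param nek_beta logit-scale weight of the accessibility kernel (default
#'   6: occurrence odds at unreachable distance are e^-6 times the odds at
#'   the colony).
#' @param sigma_id SD of the individual intercepts (default 1).
#' @param bad_fix_rate fraction of fixes corrupted (default 0.05).
#' @param fix_interval_s seconds between fix attempts (default 2400 = 40 min).
#' @param vmax speed-filter threshold emulated by the teleport corruption.
#' @param seed RNG seed.
#' @return list with `fixes` (individual_id, timestamp, x, y, n_satellites,
#'   residual_error), `truth` (individual_id, fix_index, type), `b_i`,
#'   `a_true`, `d0_km`, `seed`.
#' @export
simulate_tracks <- function(world, n_individuals = 9, fixes_per_id = 300,
                            a_true = 0.05, d0_km = 10, nek_beta = 6,
                            sigma_id = 1,
                            bad_fix_rate = 0.05, fix_interval_s = 2400,
                            vmax = 5.5, seed = 1) {
  stopifnot(a_true > 0, a_true <= 1)
  g <- world$grid
  suit <- as.vector(world$suitability$values)
  roa <- as.vector(world$roa_mask$values)
  elig <- which(!is.na(suit) & roa == 1)
  co <- grid_coords(g)
  d_col_km <- sqrt((co$x - world$colony[1])^2 +
                     (co$y - world$colony[2])^2) / 1000
  kern <- a_true^(d_col_km / d0_km)
  land_cells <- which(!is.na(world$land_mask$values) &
                        as.vector(world$land_mask$values) == 1)
  r_m <- 0.9 * vmax * fix_interval_s
  rc <- floor(r_m / g$cell)
  offs <- as.matrix(expand.grid(dr = -rc:rc, dc = -rc:rc))
  offs <- offs[(offs[, 1]^2 + offs[, 2]^2) * g$cell^2 <= r_m^2 &
                 !(offs[, 1] == 0 & offs[, 2] == 0), , drop = FALSE]
  elig_set <- logical(g$n_rows * g$n_cols)
  elig_set[elig] <- TRUE

  neighbours <- function(cell) {
    row <- ((cell - 1L) %% g$n_rows) + 1L
    col <- ((cell - 1L) %/% g$n_rows) + 1L
    rr <- row + offs[, 1]; cc <- col + offs[, 2]
    ok <- rr >= 1L & rr <= g$n_rows & cc >= 1L & cc <= g$n_cols
    nb <- (cc[ok] - 1L) * g$n_rows + rr[ok]
    nb[elig_set[nb]]
  }

  with_seed(seed, {
    t0 <- as.numeric(as.POSIXct("2011-07-01 00:00:00", tz = "UTC"))
    b_i <- stats::rnorm(n_individuals, 0, sigma_id)
    fixes <- list(); truth <- list()
    for (i in seq_len(n_individuals)) {
      id <- sprintf("sasl%02d", i)
      w <- inv_logit(logit(pmin(pmax(suit, 1e-12), 1 - 1e-12)) + b_i[i] +
                       nek_beta * (kern - 1))
      w[!elig_set] <- 0
      cells <- integer(fixes_per_id)
      cells[1] <- sample(elig, 1, prob = w[elig])
      for (k in 2:fixes_per_id) {
        nb <- neighbours(cells[k - 1])
        if (!length(nb)) { cells[k] <- cells[k - 1]; next }
        prop <- if (length(nb) == 1) nb else sample(nb, 1)
        ratio <- (w[prop] * length(nb)) / (w[cells[k - 1]] *
                                             length(neighbours(prop)))
        cells[k] <- if (stats::runif(1) < ratio) prop else cells[k - 1]
      }
      xy <- grid_xy_of(g, cells)
      df <- data.frame(individual_id = id,
                       timestamp = t0 + (seq_len(fixes_per_id) - 1) *
                         fix_interval_s,
                       x = xy$x, y = xy$y,
                       n_satellites = sample(5:11, fixes_per_id, TRUE),
                       residual_error = stats::runif(fixes_per_id, 0, 30))
      n_bad <- floor(bad_fix_rate * fixes_per_id)
      if (n_bad > 0) {
        cand <- sample(3:(fixes_per_id - 1))
        bad_idx <- integer()
        for (ci in cand) {
          if (length(bad_idx) >= n_bad) break
          if (!length(bad_idx) || min(abs(bad_idx - ci)) >= 3)
            bad_idx <- c(bad_idx, ci)
        }
        types <- sample(c("satellites", "residual", "land", "speed"),
                        length(bad_idx), replace = TRUE)
        if (!length(land_cells)) types[types == "land"] <- "satellites"
        for (j in seq_along(bad_idx)) {
          k <- bad_idx[j]
          if (types[j] == "satellites") {
            df$n_satellites[k] <- sample(0:4, 1)
          } else if (types[j] == "residual") {
            df$residual_error[k] <- stats::runif(1, 36, 100)
          } else if (types[j] == "land") {
            lc <- if (length(land_cells) == 1) land_cells else
              sample(land_cells, 1)
            lxy <- grid_xy_of(g, lc)
            df$x[k] <- lxy$x; df$y[k] <- lxy$y
          } else {
            d_from_true <- sqrt((co$x[elig] - df$x[k])^2 +
                                  (co$y[elig] - df$y[k])^2)
            far <- elig[d_from_true > 30000 & d_from_true < 90000]
            tc <- if (length(far) == 1) far else sample(far, 1)
            txy <- grid_xy_of(g, tc)
            df$x[k] <- txy$x; df$y[k] <- txy$y
          }
        }
        truth[[i]] <- data.frame(individual_id = id, fix_index = bad_idx,
                                 type = types)
      }
      fixes[[i]] <- df
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(individual_id = character(), fix_index = integer(),
                 type = character())
    rownames(truth) <- NULL
    list(fixes = do.call(rbind, fixes), truth = truth,
         b_i = setNames(b_i, sprintf("sasl%02d", seq_len(n_individuals))),
         a_true = a_true, d0_km = d0_km, nek_beta = nek_beta, seed = seed)
  })
}

#' Simulate fishing-set locations for two fleets
#'
#' Industrial sets are drawn from an inhomogeneous two-zone process with a
#' stated nearshore share (points inside the 5 NM zone); artisanal sets occur
#' only within 5 NM and are snapped and aggregated to a 1 x 1 nautical-mile
#' grid with counts, mirroring how shipowner reports arrive pre-gridded.
#'
#' @param world a `synthetic_world`.
#' @param n_industrial,n_artisanal numbers of sets.
#' @param nearshore_industrial_frac probability an industrial set falls in
#'   the nearshore zone (default 0.2).
#' @param nearshore_m nearshore boundary (default 5 NM = 9260 m).
#' @param seed RNG seed.
#' @return list with `industrial` (x, y, count = 1) and `artisanal`
#'   (x, y, count aggregated on the 1 NM grid).
#' @export
simulate_fishing <- function(world, n_industrial = 2000, n_artisanal = 800,
                             nearshore_industrial_frac = 0.2,
                             nearshore_m = 9260, seed = 1) {
  stopifnot(nearshore_industrial_frac >= 0, nearshore_industrial_frac <= 1)
  g <- world$grid
  d <- as.vector(world$dist_shore$values)
  sea <- as.vector(world$roa_mask$values) == 1
  # sampling margins keep jittered (and, for artisanal, snapped) points on
  # their own side of the 5 NM boundary: distance to shore is 1-Lipschitz
  jit <- 0.75 * g$cell
  near_cells <- which(sea & d <= nearshore_m - jit)
  off_cells <- which(sea & d > nearshore_m + jit)
  art_cells <- which(sea & d <= nearshore_m - jit - 1852 / sqrt(2))
  co <- grid_coords(g)
  with_seed(seed, {
    jitter_pts <- function(cells) {
      data.frame(x = co$x[cells] + stats::runif(length(cells), -0.5, 0.5) * g$cell,
                 y = co$y[cells] + stats::runif(length(cells), -0.5, 0.5) * g$cell)
    }
    zone_near <- stats::runif(n_industrial) < nearshore_industrial_frac
    ind_cells <- integer(n_industrial)
    if (any(zone_near))
      ind_cells[zone_near] <- sample(near_cells, sum(zone_near), replace = TRUE)
    if (any(!zone_near))
      ind_cells[!zone_near] <- sample(off_cells, sum(!zone_near), replace = TRUE)
    industrial <- jitter_pts(ind_cells)
    industrial$count <- 1
    art <- jitter_pts(sample(art_cells, n_artisanal, replace = TRUE))
    nm <- 1852
    gx <- floor(art$x / nm) * nm + nm / 2
    gy <- floor(art$y / nm) * nm + nm / 2
    agg <- stats::aggregate(list(count = rep(1, n_artisanal)),
                            by = list(x = gx, y = gy), FUN = sum)
    list(industrial = industrial, artisanal = agg)
  })
}
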