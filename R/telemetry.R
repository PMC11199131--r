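#' GPS fix quality filter
#'
#' Flags Fastloc-GPS fixes computed from too few satellites or with high
#' tag-reported residual error. Fixes already carrying a flag from an earlier
#' filter are left untouched, so every removed fix keeps exactly one removal
#' reason (the first triggering filter).
#'
#' @param fixes data.frame with at least `n_satellites` and `residual_error`;
#'   a `flag` column (NA = retained) is added or updated.
#' @param min_sats minimum satellite count retained (default 5, i.e. fixes
#'   with fewer than 5 satellites are removed).
#' @param max_residual maximum residual error retained (default 35; larger
#'   values are removed).
#' @param missing_ok if TRUE and the quality columns are absent, pass fixes
#'   through with a warning (public telemetry deposits often lack them).
#' @return the fix table with a `flag` column (`"satellites"`, `"residual"`
#'   or NA).
#' @export
quality_filter <- function(fixes, min_sats = 5, max_residual = 35,
                           missing_ok = FALSE) {
  fixes <- ensure_flag(fixes)
  has_cols <- all(c("n_satellites", "residual_error") %in% names(fixes))
  if (!has_cols) {
    if (missing_ok) {
      warning("quality fields missing; quality filter skipped")
      return(fixes)
    }
    stop("fixes lack n_satellites / residual_error columns")
  }
  open <- is.na(fixes$flag)
  sat_bad <- open & fixes$n_satellites < min_sats
  fixes$flag[sat_bad] <- "satellites"
  open <- is.na(fixes$flag)
  res_bad <- open & fixes$residual_error > max_residual
  fixes$flag[res_bad] <- "residual"
  fixes
}

#' Land filter
#'
#' Removes fixes whose containing grid cell is land. Fixes outside the mask
#' extent are removed with reason `"out of extent"`.
#'
#' @param fixes fix table with `x`, `y`.
#' @param land_mask `raster_grid` with 1 = land, 0 = water, aligned to the
#'   analysis grid.
#' @return fix table with updated `flag`.
#' @export
land_filter <- function(fixes, land_mask) {
  fixes <- ensure_flag(fixes)
  open <- is.na(fixes$flag)
  v <- grid_value_at(land_mask, fixes$x, fixes$y)
  fixes$flag[open & is.na(v)] <- "out of extent"
  fixes$flag[open & !is.na(v) & v == 1] <- "land"
  fixes
}

#' Travel-speed filter
#'
#' Forward sweep per individual over time-sorted retained fixes: each fix's
#' straight-line speed from the previous retained fix is computed; fixes
#' implying a speed above `vmax` are removed (`"speed"`) and the previous
#' retained fix remains the anchor. Speeds exactly `vmax` are retained.
#' Duplicate timestamps remove the later fix (`"duplicate time"`).
#'
#' @param fixes fix table with `individual_id`, `timestamp` (numeric seconds
#'   or POSIXct), `x`, `y`.
#' @param vmax maximum plausible speed in m/s (default 5.5).
#' @return fix table with updated `flag`.
#' @export
speed_filter <- function(fixes, vmax = 5.5) {
  fixes <- ensure_flag(fixes)
  ts <- as.numeric(fixes$timestamp)
  for (id in unique(fixes$individual_id)) {
    idx <- which(fixes$individual_id == id & is.na(fixes$flag))
    if (length(idx) < 2) next
    idx <- idx[order(ts[idx])]
    tt <- ts[idx]
    if (any(diff(tt) < 0)) {
      bad <- which(diff(tt) < 0)
      stop(sprintf("non-monotone timestamps for individual %s at rows %s",
                   id, paste(idx[bad], collapse = ", ")))
    }
    anchor <- idx[1]
    for (k in idx[-1]) {
      dt <- ts[k] - ts[anchor]
      if (dt == 0) {
        fixes$flag[k] <- "duplicate time"
        next
      }
      sp <- sqrt((fixes$x[k] - fixes$x[anchor])^2 +
                   (fixes$y[k] - fixes$y[anchor])^2) / dt
      if (sp > vmax) fixes$flag[k] <- "speed" else anchor <- k
    }
  }
  fixes
}

#' Clip fixes to the analysis extent
#'
#' Removes fixes farther from shore than `max_dist_m`; balances the relative
#' occurrence area and avoids extrapolating beyond typical foraging range.
#'
#' @param fixes fix table with `x`, `y`.
#' @param dist_shore aligned `raster_grid` of distance to shore (m).
#' @param max_dist_m cutoff (default 100 km).
#' @return fix table with updated `flag` (`"outside ROA"`).
#' @export
clip_to_study_area <- function(fixes, dist_shore, max_dist_m = 100000) {
  fixes <- ensure_flag(fixes)
  open <- is.na(fixes$flag)
  d <- grid_value_at(dist_shore, fixes$x, fixes$y)
  fixes$flag[open & (is.na(d) | d > max_dist_m)] <- "outside ROA"
  fixes
}

#' Run the full fix-filter chain with an audit
#'
#' Applies quality, land, speed and study-area filters in that order and
#' tallies removals by reason. The per-filter counts always sum to
#' raw minus retained.
#'
#' @param fixes raw fix table.
#' @param land_mask land `raster_grid` (1 = land).
#' @param dist_shore distance-to-shore `raster_grid` (m).
#' @param min_sats,max_residual,vmax,max_dist_m filter thresholds.
#' @param missing_ok passed to [quality_filter()].
#' @return list with `fixes` (flagged table), `retained` (unflagged rows) and
#'   `audit` (data.frame reason/count, including `retained`).
#' @export
filter_fixes <- function(fixes, land_mask, dist_shore, min_sats = 5,
                         max_residual = 35, vmax = 5.5, max_dist_m = 100000,
                         missing_ok = FALSE) {
  fixes <- quality_filter(fixes, min_sats, max_residual, missing_ok)
  fixes <- land_filter(fixes, land_mask)
  fixes <- speed_filter(fixes, vmax)
  fixes <- clip_to_study_area(fixes, dist_shore, max_dist_m)
  tab <- table(factor(fixes$flag,
                      levels = c("satellites", "residual", "land",
                                 "out of extent", "speed", "duplicate time",
                                 "outside ROA")))
  audit <- data.frame(reason = c(names(tab), "retained"),
                      count = c(as.integer(tab), sum(is.na(fixes$flag))))
  list(fixes = fixes, retained = fixes[is.na(fixes$flag), , drop = FALSE],
       audit = audit)
}

#' Spatial rarefaction of fixes onto the analysis grid
#'
#' Retains one presence per grid cell (`mode = "population"`) or one per
#' cell and individual (`mode = "individual"`), avoiding pseudoreplication
#' in model fitting. Deterministic: the earliest fix wins (ties broken by
#' individual id, then input order).
#'
#' @param fixes filtered fix table (`individual_id`, `timestamp`, `x`, `y`).
#' @param grid analysis `raster_grid` template.
#' @param mode `"population"` or `"individual"`.
#' @return presence data.frame (individual_id, x, y, cell) with a `mode`
#'   attribute.
#' @export
grid_rarefy <- function(fixes, grid, mode = c("population", "individual")) {
  mode <- match.arg(mode)
  rc <- grid_cell_of(grid, fixes$x, fixes$y)
  df <- data.frame(individual_id = fixes$individual_id,
                   timestamp = as.numeric(fixes$timestamp),
                   x = fixes$x, y = fixes$y, cell = rc$cell)
  df <- df[!is.na(df$cell), , drop = FALSE]
  ord <- order(df$timestamp, as.character(df$individual_id))
  df <- df[ord, , drop = FALSE]
  key <- if (mode == "population") df$cell else
    paste(df$cell, df$individual_id)
  out <- df[!duplicated(key), c("individual_id", "x", "y", "cell")]
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  out
}

#' Random per-individual subsample of fixes
#'
#' Draws up to `n_per_id` fixes per individual uniformly without replacement;
#' used to build a reduced occurrence set that balances individual sampling.
#'
#' @param fixes fix table with `individual_id`.
#' @param n_per_id fixes retained per individual (default 30).
#' @param seed RNG seed for reproducibility.
#' @return subsampled fix table.
#' @export
subsample_per_individual <- function(fixes, n_per_id = 30, seed = NULL) {
  stopifnot(n_per_id >= 1)
  with_seed(seed, {
    keep <- unlist(lapply(split(seq_len(nrow(fixes)), fixes$individual_id),
                          function(i) {
                            if (length(i) <= n_per_id) i else
                              sample(i, n_per_id)
                          }), use.names = FALSE)
    fixes[sort(keep), , drop = FALSE]
  })
}

ensure_flag <- function(fixes) {
  if (!"flag" %in% names(fixes)) fixes$flag <- NA_character_
  fixes
}

#' Read a telemetry fix CSV
#'
#' Expects columns `individual_id` (or `id`), `timestamp` (ISO-8601 or
#' numeric seconds), `x`, `y` in metres, and optionally `n_satellites` and
#' `residual_error`.
#'
#' @param path CSV path.
#' @return fix data.frame with numeric `timestamp` (seconds).
#' @export
read_fixes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"individual_id" %in% names(df) && "id" %in% names(df))
    names(df)[names(df) == "id"] <- "individual_id"
  stopifnot(all(c("individual_id", "timestamp", "x", "y") %in% names(df)))
  if (is.character(df$timestamp))
    df$timestamp <- as.numeric(as.POSIXct(df$timestamp, tz = "UTC"))
  df
}
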