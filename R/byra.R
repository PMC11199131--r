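#' Fishing-intensity kernel density surface
#'
#' Quartic (biweight) kernel density of fishing set locations evaluated at
#' cell centres: each point contributes
#' `(3 / (pi r^2)) * (1 - (d / r)^2)^2` for `d < r`, so the surface is linear
#' in the point set and its integral over the plane equals the (weighted)
#' point count. Pre-aggregated set tables (e.g. artisanal reports on a 1x1
#' nautical-mile grid) enter via `weights`.
#'
#' @param x,y set locations (m).
#' @param grid `raster_grid` template for the density surface (typically a
#'   3 km grid).
#' @param radius_m kernel search radius (default 5000 m).
#' @param weights per-point weights (set counts); default 1.
#' @return `raster_grid` of density (points per m^2); all-zero for an empty
#'   point set.
#' @export
fishing_kde <- function(x, y, grid, radius_m = 5000, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(x))
  stopifnot(length(weights) == length(x), length(x) == length(y))
  v <- matrix(0, grid$n_rows, grid$n_cols)
  if (!length(x)) return(grid_like(grid, v))
  ax <- grid_axes(grid)
  r2 <- radius_m^2
  k0 <- 3 / (pi * r2)
  for (p in seq_along(x)) {
    dx2 <- (ax$x - x[p])^2
    dy2 <- (ax$y - y[p])^2
    cols <- which(dx2 < r2); rows <- which(dy2 < r2)
    if (!length(cols) || !length(rows)) next
    d2 <- outer(dy2[rows], dx2[cols], "+")
    kk <- ifelse(d2 < r2, k0 * (1 - d2 / r2)^2, 0)
    v[rows, cols] <- v[rows, cols] + weights[p] * kk
  }
  grid_like(grid, v)
}

#' Quantile reclassification of a density surface
#'
#' Classifies a continuous relative-density raster into `n_classes` (default
#' 1-3) by the quantiles of its positive cells; zero-density cells get class
#' 1.
#'
#' @param raster a `raster_grid` (non-negative values).
#' @param n_classes number of classes (default 3).
#' @return `raster_grid` of integer classes 1..n_classes.
#' @export
quantile_reclass <- function(raster, n_classes = 3) {
  v <- as.vector(raster$values)
  ok <- !is.na(v)
  out <- rep(NA_real_, length(v))
  out[ok] <- 1
  posi <- ok & v > 0
  if (!any(posi)) {
    warning("all-zero raster; all cells class 1")
  } else {
    q <- stats::quantile(v[posi], seq_len(n_classes - 1) / n_classes,
                         type = 7, names = FALSE)
    if (diff(range(v[posi])) == 0) {
      warning("constant positive raster; single class")
      out[posi] <- 1
    } else {
      cls <- rep(1, sum(posi))
      for (b in q) cls <- cls + (v[posi] > b)
      out[posi] <- cls
    }
  }
  grid_like(raster, matrix(out, raster$n_rows, raster$n_cols))
}

#' Likelihood-of-interaction class layer
#'
#' Cell-by-cell sum of the fishing-intensity class (1-3) and the species
#' distribution class (1-3), reclassified back to 1-3: sums 2-3 -> 1, 4 -> 2,
#' 5-6 -> 3.
#'
#' @param intensity_class,distribution_class aligned 1-3 `raster_grid`s.
#' @return `raster_grid` of classes 1-3.
#' @export
interaction_likelihood <- function(intensity_class, distribution_class) {
  stop_if_misaligned(intensity_class, distribution_class)
  a <- as.vector(intensity_class$values)
  b <- as.vector(distribution_class$values)
  ok <- !is.na(a) & !is.na(b)
  if (any(!(a[ok] %in% 1:3)) || any(!(b[ok] %in% 1:3)))
    stop("class values outside 1-3")
  s <- a + b
  out <- rep(NA_real_, length(a))
  out[ok] <- ifelse(s[ok] <= 3, 1, ifelse(s[ok] == 4, 2, 3))
  grid_like(intensity_class,
            matrix(out, intensity_class$n_rows, intensity_class$n_cols))
}

#' Exposure and consequence scores from a weighted criteria table
#'
#' Each criterion carries a score `x_i` in 1-3 (0 omits it), a data-quality
#' rating `d_i` in 1-3 and an importance weight `w_i` in 1-3; spatially
#' explicit criteria reference a 1-3 class raster instead of a fixed score.
#' The dimension score is the inverse-(d*w)-weighted average
#' `sum(x_i / (d_i w_i)) / sum(1 / (d_i w_i))`, so better-quality,
#' higher-importance criteria count more. Scores lie in \[1, 3\].
#'
#' @param criteria data.frame with columns `dimension`
#'   (`"exposure"`/`"consequence"`), `criterion`, `score` (0-3; NA for
#'   spatial rows), `data_quality`, `weight`, `spatial_layer` (name into
#'   `spatial_layers`, or NA).
#' @param spatial_layers named list of aligned 1-3 class `raster_grid`s
#'   referenced by spatial criteria rows.
#' @param template `raster_grid` geometry for the output when no spatial rows
#'   exist (optional; otherwise scalars are returned).
#' @return list with `E` and `C`: `raster_grid`s when any spatial criterion
#'   or template is present, else scalars.
#' @export
ec_scores <- function(criteria, spatial_layers = list(), template = NULL) {
  dim_score <- function(rows) {
    rows <- rows[is.na(rows$score) | rows$score != 0, , drop = FALSE]
    if (!nrow(rows)) stop("all criteria omitted on a dimension")
    stopifnot(all(rows$data_quality %in% 1:3), all(rows$weight %in% 1:3))
    spatial <- !is.na(rows$spatial_layer) & nzchar(rows$spatial_layer)
    tmpl <- template
    if (any(spatial)) tmpl <- spatial_layers[[rows$spatial_layer[spatial][1]]]
    num <- 0; den <- 0
    for (i in seq_len(nrow(rows))) {
      iw <- 1 / (rows$data_quality[i] * rows$weight[i])
      xi <- if (spatial[i]) {
        ly <- spatial_layers[[rows$spatial_layer[i]]]
        if (is.null(ly)) stop("unknown spatial layer '",
                              rows$spatial_layer[i], "'")
        if (!is.null(tmpl)) stop_if_misaligned(tmpl, ly, "criteria layers")
        ly$values
      } else rows$score[i]
      num <- num + xi * iw
      den <- den + iw
    }
    val <- num / den
    if (!is.null(tmpl) && !is.matrix(val))
      val <- matrix(val, tmpl$n_rows, tmpl$n_cols)
    if (!is.null(tmpl)) grid_like(tmpl, val) else val
  }
  list(E = dim_score(criteria[criteria$dimension == "exposure", , drop = FALSE]),
       C = dim_score(criteria[criteria$dimension == "consequence", , drop = FALSE]))
}

#' Exposure-consequence risk surface
#'
#' Risk is the Euclidean distance from the origin (1, 1) of
#' exposure-consequence space, `sqrt((E - 1)^2 + (C - 1)^2)`, computed only
#' where species distribution and fishing activity overlap; non-overlap cells
#' score 0. The single-stressor maximum (E = C = 3) is `2 * sqrt(2)`, about
#' 2.83.
#'
#' @param E,C exposure / consequence `raster_grid`s (values in \[1, 3\] where
#'   overlap is 1).
#' @param overlap aligned 0/1 `raster_grid` overlap mask.
#' @return `raster_grid` of risk in \[0, 2 sqrt(2)\].
#' @export
risk_surface <- function(E, C, overlap) {
  stop_if_misaligned(E, C); stop_if_misaligned(E, overlap)
  ev <- E$values; cv <- C$values; ov <- overlap$values
  r <- sqrt((ev - 1)^2 + (cv - 1)^2)
  r[is.na(ov) | ov == 0] <- 0
  grid_like(E, r)
}

#' Cumulative risk and subregion statistics
#'
#' Sums per-stressor risk surfaces cell-wise and summarises risk, exposure
#' and consequence by stressor and subregion. Mean risk per subregion is
#' computed over that stressor's overlap cells only (cells actually at risk),
#' recorded in the output metadata.
#'
#' @param risks named list of per-stressor risk `raster_grid`s.
#' @param subregion aligned `raster_grid` of subregion codes (e.g. 1 =
#'   nearshore within 5 NM, 2 = offshore); NA cells are outside all
#'   subregions.
#' @param E,C optional named lists of per-stressor exposure / consequence
#'   rasters for the E-C scatter table.
#' @param subregion_names optional named translation of subregion codes.
#' @return list with `cumulative` (`raster_grid`), `stats` (stressor x
#'   subregion mean/max risk table) and `ec_scatter` (mean and max E and C
#'   per stressor x subregion, NULL when E/C not supplied).
#' @export
cumulative_and_stats <- function(risks, subregion, E = NULL, C = NULL,
                                 subregion_names = NULL) {
  stopifnot(length(risks) >= 1, !is.null(names(risks)))
  tmpl <- risks[[1]]
  for (r in risks) stop_if_misaligned(tmpl, r)
  stop_if_misaligned(tmpl, subregion)
  cum <- matrix(0, tmpl$n_rows, tmpl$n_cols)
  for (r in risks) cum <- cum + r$values
  sub <- as.vector(subregion$values)
  codes <- sort(unique(sub[!is.na(sub)]))
  rows <- list(); ec <- list()
  for (s in names(risks)) {
    rv <- as.vector(risks[[s]]$values)
    for (cd in codes) {
      in_sub <- !is.na(sub) & sub == cd
      at_risk <- in_sub & !is.na(rv) & rv > 0
      nm <- if (!is.null(subregion_names)) subregion_names[[as.character(cd)]]
        else as.character(cd)
      rows[[length(rows) + 1]] <- data.frame(
        stressor = s, subregion = nm,
        n_cells = sum(in_sub), n_overlap = sum(at_risk),
        mean_risk = if (any(at_risk)) mean(rv[at_risk]) else NA_real_,
        max_risk = if (any(in_sub)) max(rv[in_sub], na.rm = TRUE) else NA_real_)
      if (!is.null(E) && !is.null(C)) {
        evv <- as.vector(E[[s]]$values); cvv <- as.vector(C[[s]]$values)
        ec[[length(ec) + 1]] <- data.frame(
          stressor = s, subregion = nm,
          mean_E = if (any(at_risk)) mean(evv[at_risk]) else NA_real_,
          max_E = if (any(at_risk)) max(evv[at_risk]) else NA_real_,
          mean_C = if (any(at_risk)) mean(cvv[at_risk]) else NA_real_,
          max_C = if (any(at_risk)) max(cvv[at_risk]) else NA_real_)
      }
    }
  }
  list(cumulative = grid_like(tmpl, cum),
       stats = do.call(rbind, rows),
       ec_scatter = if (length(ec)) do.call(rbind, ec) else NULL,
       mean_denominator = "overlap cells only")
}

#' Example exposure-consequence criteria table
#'
#' A documented example scoring table for two purse-seine fleets (industrial,
#' artisanal) with the standard bycatch criteria: non-spatial exposure rows
#' (temporal overlap, catchability in gear, management status) plus the two
#' spatially explicit exposure criteria (intensity of fishing activity,
#' likelihood of interaction), and consequence rows covering life history and
#' interaction severity. Scores here are illustrative defaults for the
#' synthetic study system, not published expert ratings; nearshore exposure
#' is scored higher for both fleets.
#'
#' @param stressor stressor name the table is for ("industrial" or
#'   "artisanal").
#' @param subregion subregion name ("nearshore" or "offshore").
#' @return criteria data.frame accepted by [ec_scores()].
#' @export
default_criteria_table <- function(stressor = "industrial",
                                   subregion = "nearshore") {
  near <- subregion == "nearshore"
  art <- stressor == "artisanal"
  exp_score <- function(hi, lo) if (near) hi else lo
  data.frame(
    stressor = stressor, subregion = subregion,
    dimension = c(rep("exposure", 5), rep("consequence", 6)),
    criterion = c("temporal overlap", "catchability in gear",
                  "management status", "intensity of fishing activity",
                  "likelihood of interaction",
                  "age of maturity", "reproductive strategy",
                  "population connectivity", "conservation status",
                  "mortality from gear", "life stages affected"),
    score = c(exp_score(3, 2), if (art) 2 else 3, 2, NA, NA,
              2, 2, 2, 2, if (art) 2 else 3, exp_score(3, 2)),
    data_quality = c(2, 2, 1, 1, 2, 1, 1, 2, 1, 2, 2),
    weight = c(2, 3, 1, 3, 3, 1, 1, 1, 2, 3, 2),
    spatial_layer = c(NA, NA, NA, "intensity", "likelihood",
                      NA, NA, NA, NA, NA, NA))
}

#' Data-uncertainty stoplight table
#'
#' Metadata table characterising the confidence in the four data types
#' feeding the risk model, echoed into risk outputs (green = low uncertainty,
#' yellow = medium, red = high).
#'
#' @param presence,suitability,fishing,bycatch stoplight colour per data
#'   type.
#' @export
uncertainty_table <- function(presence = "yellow", suitability = "yellow",
                              fishing = "green", bycatch = "red") {
  lv <- c("green", "yellow", "red")
  stopifnot(all(c(presence, suitability, fishing, bycatch) %in% lv))
  data.frame(
    data_type = c("animal presence data", "habitat suitability estimation",
                  "fishing effort data", "available bycatch data"),
    uncertainty = c(presence, suitability, fishing, bycatch))
}

#' Subregion raster from distance to shore
#'
#' Codes cells as 1 (nearshore, within `boundary_m` of shore — the 5 NM
#' artisanal zone by default) or 2 (offshore) out to `max_m`; cells beyond
#' `max_m` (or on land, if `land_mask` given) are NA.
#'
#' @param dist_shore distance-to-shore `raster_grid` (m).
#' @param boundary_m nearshore/offshore boundary (default 5 NM = 9260 m).
#' @param max_m outer edge of the assessed area (default 100 km).
#' @param land_mask optional aligned land mask (1 = land) to exclude.
#' @return `raster_grid` of subregion codes.
#' @export
subregion_raster <- function(dist_shore, boundary_m = 9260, max_m = 100000,
                             land_mask = NULL) {
  d <- dist_shore$values
  out <- ifelse(is.na(d) | d > max_m, NA_real_, ifelse(d <= boundary_m, 1, 2))
  if (!is.null(land_mask)) {
    stop_if_misaligned(dist_shore, land_mask)
    out[!is.na(land_mask$values) & land_mask$values == 1] <- NA_real_
  }
  grid_like(dist_shore, out)
}
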