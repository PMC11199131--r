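#' Euclidean distance raster to vector features
#'
#' Fills a grid with the minimum planar distance (metres) from each cell
#' centre to a feature set: points (e.g. river mouths, a colony) and/or
#' polylines (e.g. a coastline or the shelf contour).
#'
#' @param grid a `raster_grid` template supplying the geometry.
#' @param points optional 2-column matrix / data.frame of point features (m).
#' @param lines optional list of 2-column matrices, each a polyline (m).
#' @return a `raster_grid` of distances (m); 0 at cells whose centre lies on
#'   a feature.
#' @export
compute_distance_raster <- function(grid, points = NULL, lines = NULL) {
  if (!is.null(points)) points <- as.matrix(points)
  have_pts <- !is.null(points) && nrow(points) > 0
  have_lin <- !is.null(lines) && length(lines) > 0
  if (!have_pts && !have_lin) stop("no features")
  co <- grid_coords(grid)
  d <- rep(Inf, nrow(co))
  if (have_pts)
    d <- pmin(d, min_dist_to_points(co$x, co$y, points[, 1], points[, 2]))
  if (have_lin) {
    for (ln in lines) {
      ln <- as.matrix(ln)
      for (i in seq_len(nrow(ln) - 1L)) {
        d <- pmin(d, point_segment_distance(co$x, co$y,
                                            ln[i, 1], ln[i, 2],
                                            ln[i + 1L, 1], ln[i + 1L, 2]))
      }
      if (nrow(ln) == 1L)
        d <- pmin(d, sqrt((co$x - ln[1, 1])^2 + (co$y - ln[1, 2])^2))
    }
  }
  grid_like(grid, matrix(d, grid$n_rows, grid$n_cols))
}

#' Fill missing cells with a circular focal mean
#'
#' Missing cells whose circular neighbourhood (cell-centre distance up to
#' `radius_cells` cells) contains at least one valid value are replaced by
#' the mean of the valid neighbours; valid cells are never altered. Used to
#' patch small nearshore gaps in satellite covariates.
#'
#' @param raster a `raster_grid`.
#' @param radius_cells neighbourhood radius in cells (>= 1; default 2).
#' @return a `raster_grid`.
#' @export
focal_fill <- function(raster, radius_cells = 2) {
  stopifnot(radius_cells >= 1)
  v <- raster$values
  if (all(is.na(v))) {
    warning("all cells missing; returned unchanged")
    return(raster)
  }
  r <- floor(radius_cells)
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius_cells^2 &
                 !(offs$dr == 0 & offs$dc == 0), ]
  nr <- nrow(v); nc <- ncol(v)
  sums <- matrix(0, nr, nc); cnts <- matrix(0, nr, nc)
  valid <- !is.na(v)
  vz <- v; vz[!valid] <- 0
  for (k in seq_len(nrow(offs))) {
    dr <- offs$dr[k]; dc <- offs$dc[k]
    rs <- max(1, 1 - dr):min(nr, nr - dr)   # destination rows
    cs <- max(1, 1 - dc):min(nc, nc - dc)
    sums[rs, cs] <- sums[rs, cs] + vz[rs + dr, cs + dc]
    cnts[rs, cs] <- cnts[rs, cs] + valid[rs + dr, cs + dc]
  }
  fill <- is.na(v) & cnts > 0
  v[fill] <- (sums / cnts)[fill]
  grid_like(raster, v)
}

#' Bilinear resampling onto a target grid
#'
#' Each target cell centre is interpolated from the four enclosing source
#' cell centres. Target centres outside the source centre lattice clamp to
#' the edge (nearest valid row/column); missing source corners are dropped
#' with weights renormalised, and cells with no valid corner stay missing.
#'
#' @param raster source `raster_grid`.
#' @param target `raster_grid` template defining the output geometry.
#' @return a `raster_grid` on the target geometry.
#' @export
resample_bilinear <- function(raster, target) {
  sx0 <- raster$x0 + 0.5 * raster$cell
  sy_top <- raster$y0 + (raster$n_rows - 0.5) * raster$cell
  ax <- grid_axes(target)
  # extent overlap check (cell coverage, not centre coverage)
  if (target$x0 >= raster$x0 + raster$n_cols * raster$cell ||
      target$x0 + target$n_cols * target$cell <= raster$x0 ||
      target$y0 >= raster$y0 + raster$n_rows * raster$cell ||
      target$y0 + target$n_rows * target$cell <= raster$y0)
    stop("disjoint extents")
  # fractional source indices of target centres
  fc <- (ax$x - sx0) / raster$cell + 1      # source col coordinate
  fr <- (sy_top - ax$y) / raster$cell + 1   # source row coordinate (top-down)
  out <- matrix(NA_real_, target$n_rows, target$n_cols)
  v <- raster$values
  # clamp to the source centre lattice; edge cells take the nearest row/col
  fr <- pmin(pmax(fr, 1), raster$n_rows)
  fc <- pmin(pmax(fc, 1), raster$n_cols)
  r0 <- pmin(floor(fr), max(raster$n_rows - 1L, 1L)); r1 <- pmin(r0 + 1L, raster$n_rows)
  c0 <- pmin(floor(fc), max(raster$n_cols - 1L, 1L)); c1 <- pmin(c0 + 1L, raster$n_cols)
  wr <- fr - r0
  wc <- fc - c0
  for (i in seq_len(target$n_rows)) {
    vals <- rbind(v[cbind(r0[i], c0)], v[cbind(r0[i], c1)],
                  v[cbind(r1[i], c0)], v[cbind(r1[i], c1)])
    w <- rbind((1 - wr[i]) * (1 - wc), (1 - wr[i]) * wc,
               wr[i] * (1 - wc), wr[i] * wc)
    w[is.na(vals)] <- 0
    vals[is.na(vals)] <- 0
    sw <- colSums(w)
    res <- ifelse(sw > 0, colSums(w * vals) / sw, NA_real_)
    out[i, ] <- res
  }
  grid_like(target, out)
}

#' Aligned covariate stack
#'
#' Named collection of aligned `raster_grid` layers plus per-layer transform
#' tags and min-max rescale bounds (filled by [transform_and_rescale()]).
#'
#' @param layers named list of aligned `raster_grid` objects.
#' @param transforms named character vector (`"none"|"log"|"sqrt"`), filled
#'   once transformed.
#' @param bounds data.frame of per-layer rescale bounds, filled once rescaled.
#' @export
covariate_stack <- function(layers, transforms = NULL, bounds = NULL) {
  stopifnot(length(layers) >= 1, !is.null(names(layers)),
            all(nzchar(names(layers))))
  tmpl <- layers[[1]]
  for (nm in names(layers)) stop_if_misaligned(tmpl, layers[[nm]],
                                               paste("layer", nm))
  structure(list(layers = layers, transforms = transforms, bounds = bounds),
            class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat(sprintf("covariate_stack: %d layers (%s)\n", length(x$layers),
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Transform and 0-1 rescale covariate layers
#'
#' Applies the configured transform per layer (`log` for right-skewed layers
#' such as chlorophyll and depth, `sqrt` for slope, `none` otherwise), then
#' min-max rescales each layer to \[0, 1\] over its non-missing cells. The
#' rescale bounds are computed from the full study-area raster and stored so
#' later predictions reuse identical bounds. A configurable offset is added
#' before `log` when zeros are present (default `1e-6 * max`); negative
#' values under `log`/`sqrt` raise an error naming the layer and cell.
#' Constant layers rescale to all 0.
#'
#' @param stack a [covariate_stack()] of raw layers.
#' @param transforms named character vector over the stack's layer names with
#'   values `"none"`, `"log"` or `"sqrt"`; omitted layers default to
#'   `"none"`.
#' @param log_offset_frac offset added before log when a layer contains
#'   zeros, as a fraction of the layer maximum.
#' @return a `covariate_stack` with transformed, rescaled layers, transform
#'   tags, and a `bounds` data.frame (layer, lo, hi on the transformed scale).
#' @export
transform_and_rescale <- function(stack, transforms = NULL,
                                  log_offset_frac = 1e-6) {
  nm <- names(stack$layers)
  tr <- setNames(rep("none", length(nm)), nm)
  if (!is.null(transforms)) tr[names(transforms)] <- transforms
  stopifnot(all(tr %in% c("none", "log", "sqrt")))
  out <- stack$layers
  bounds <- data.frame(layer = nm, lo = NA_real_, hi = NA_real_,
                       log_offset = 0)
  for (i in seq_along(nm)) {
    g <- out[[i]]
    v <- g$values
    ok <- !is.na(v)
    off <- 0
    if (tr[i] == "log") {
      if (any(v[ok] < 0)) {
        cell <- which(ok & v < 0)[1]
        stop(sprintf("negative value under log in layer '%s' at cell %d",
                     nm[i], cell))
      }
      if (any(v[ok] == 0)) off <- log_offset_frac * max(v[ok])
      v[ok] <- log(v[ok] + off)
    } else if (tr[i] == "sqrt") {
      if (any(v[ok] < 0)) {
        cell <- which(ok & v < 0)[1]
        stop(sprintf("negative value under sqrt in layer '%s' at cell %d",
                     nm[i], cell))
      }
      v[ok] <- sqrt(v[ok])
    }
    lo <- min(v[ok]); hi <- max(v[ok])
    v[ok] <- if (hi > lo) (v[ok] - lo) / (hi - lo) else 0
    bounds$lo[i] <- lo; bounds$hi[i] <- hi; bounds$log_offset[i] <- off
    out[[i]] <- grid_like(g, v)
  }
  covariate_stack(out, transforms = tr, bounds = bounds)
}

#' Covariate values at point locations
#'
#' @param stack a [covariate_stack()].
#' @param x,y point coordinates (m).
#' @return data.frame, one column per layer, of containing-cell values.
#' @export
extract_covariates <- function(stack, x, y) {
  as.data.frame(lapply(stack$layers, grid_value_at, x = x, y = y))
}

#' Collinearity screen by Pearson correlation and VIF
#'
#' Iteratively drops covariates until all pairwise |r| < `r_max` and all
#' variance inflation factors are at most `vif_max`. The worst offending
#' pair's member with the larger mean |r| to all other covariates is dropped
#' first; when only VIF offends, the covariate with the highest VIF is
#' dropped. VIF_j = 1 / (1 - R^2_j) from an ordinary least-squares fit of
#' covariate j on the others.
#'
#' @param samples data.frame of covariate values at presence and absence
#'   points (numeric columns only).
#' @param r_max pairwise Pearson threshold (drop when |r| >= `r_max`).
#' @param vif_max VIF threshold (drop when VIF > `vif_max`).
#' @return list with `retained` (character), `dropped` (data.frame of layer,
#'   trigger, value) and `vif` (named vector for the retained set, NA when
#'   VIF could not be computed).
#' @export
collinearity_screen <- function(samples, r_max = 0.7, vif_max = 4.5) {
  samples <- as.data.frame(samples)
  stopifnot(ncol(samples) >= 2, nrow(samples) >= 3)
  keep <- names(samples)
  dropped <- data.frame(layer = character(), trigger = character(),
                        value = numeric())
  vif_ok <- nrow(samples) > ncol(samples)
  if (!vif_ok) warning("fewer samples than covariates; VIF screen skipped")
  vifs <- function(df) {
    sapply(names(df), function(j) {
      fit <- stats::lm(stats::reformulate(setdiff(names(df), j), response = j),
                       data = df)
      r2 <- summary(fit)$r.squared
      1 / max(1 - r2, 1e-12)
    })
  }
  repeat {
    df <- samples[, keep, drop = FALSE]
    if (length(keep) < 2) break
    cm <- abs(stats::cor(df))
    diag(cm) <- 0
    vf <- if (vif_ok && nrow(df) > ncol(df)) vifs(df) else
      setNames(rep(NA_real_, length(keep)), keep)
    if (max(cm) >= r_max) {
      idx <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      pair <- keep[idx]
      meanr <- rowMeans(cm[pair, , drop = FALSE])
      drop <- pair[which.max(meanr)]
      dropped <- rbind(dropped, data.frame(
        layer = drop, trigger = "pearson_r", value = max(cm)))
    } else if (any(!is.na(vf)) && max(vf, na.rm = TRUE) > vif_max) {
      drop <- keep[which.max(vf)]
      dropped <- rbind(dropped, data.frame(
        layer = drop, trigger = "vif", value = max(vf, na.rm = TRUE)))
    } else break
    keep <- setdiff(keep, drop)
  }
  df <- samples[, keep, drop = FALSE]
  vf <- if (vif_ok && length(keep) >= 2 && nrow(df) > ncol(df)) vifs(df) else
    setNames(rep(NA_real_, length(keep)), keep)
  list(retained = keep, dropped = dropped, vif = vf)
}
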