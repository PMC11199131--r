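#' Environmental profiling with a one-class SVM
#'
#' Fits a one-class support vector machine (RBF kernel) on the covariate
#' vectors observed at presences and classifies every study-area cell as
#' presence-like (environmentally similar, 1) or absence zone (dissimilar,
#' 0). Pseudo-absences are later drawn from the absence zone only, under the
#' assumption that true absences are more likely in environmentally different
#' locations.
#'
#' @param presence_env data.frame of rescaled (0-1) covariate values at
#'   presences (>= 10 rows).
#' @param stack [covariate_stack()] of the same rescaled layers.
#' @param nu OCSVM nu (upper bound on the training-point rejection fraction;
#'   default 0.05).
#' @param gamma RBF width; default `1 / (n_features * mean variance)` of the
#'   presence covariates.
#' @return list with `classification` (a `raster_grid` of 1/0, NA off the
#'   covariate support), `model`, `nu`, `gamma`.
#' @export
ocsvm_profile <- function(presence_env, stack, nu = 0.05, gamma = NULL) {
  presence_env <- as.data.frame(presence_env)[names(stack$layers)]
  presence_env <- presence_env[stats::complete.cases(presence_env), ,
                               drop = FALSE]
  if (nrow(presence_env) < 10) stop("need >= 10 presence rows for profiling")
  vars <- vapply(presence_env, stats::var, 0)
  if (any(vars == 0))
    stop("degenerate covariates (zero variance across presences): ",
         paste(names(vars)[vars == 0], collapse = ", "),
         "; remove them before profiling")
  if (is.null(gamma)) gamma <- 1 / (ncol(presence_env) * mean(vars))
  X <- as.matrix(presence_env)
  fit <- e1071::svm(X, type = "one-classification", kernel = "radial",
                    nu = nu, gamma = gamma, scale = FALSE)
  cellvals <- sapply(stack$layers, function(g) as.vector(g$values))
  ok <- stats::complete.cases(cellvals)
  cls <- rep(NA_real_, nrow(cellvals))
  if (any(ok)) {
    # decision >= 0 is presence-like; small tolerance so training points
    # sitting numerically on the boundary stay inside
    dec <- attr(predict(fit, cellvals[ok, , drop = FALSE],
                        decision.values = TRUE), "decision.values")
    cls[ok] <- as.numeric(dec >= -1e-8)
  }
  tmpl <- stack$layers[[1]]
  classification <- grid_like(tmpl, matrix(cls, tmpl$n_rows, tmpl$n_cols))
  if (mean(cls[ok] == 0) < 0.01)
    warning("no dissimilar background (absence zone nearly empty)")
  list(classification = classification, model = fit, nu = nu, gamma = gamma)
}

#' Population-scheme pseudo-absences
#'
#' Draws pseudo-absence cell centres, one per presence, uniformly without
#' replacement from absence-zone cells lying outside a buffer around every
#' presence point.
#'
#' @param classification profiling result raster (1 presence-like / 0 absence
#'   zone) from [ocsvm_profile()].
#' @param presences presence set from [grid_rarefy()] (needs `x`, `y`).
#' @param buffer_m exclusion radius around presences (default 5000 m).
#' @param seed RNG seed.
#' @param n number of points; default one per presence row.
#' @return data.frame (x, y, cell, individual_id = NA) with attributes
#'   `scheme`, `buffer_m`, `seed`.
#' @export
sample_population_pa <- function(classification, presences, buffer_m = 5000,
                                 seed = NULL, n = nrow(presences)) {
  co <- grid_coords(classification)
  elig <- which(!is.na(co$value) & co$value == 0)
  if (length(elig)) {
    d <- min_dist_to_points(co$x[elig], co$y[elig], presences$x, presences$y)
    elig <- elig[d >= buffer_m]
  }
  if (length(elig) < n)
    stop(sprintf(
      "only %d eligible absence cells for %d pseudo-absences (shortfall %d)",
      length(elig), n, n - length(elig)))
  sel <- with_seed(seed, sample(elig, n))
  out <- data.frame(x = co$x[sel], y = co$y[sel], cell = sel,
                    individual_id = NA_character_)
  attr(out, "scheme") <- "population"
  attr(out, "buffer_m") <- buffer_m
  attr(out, "seed") <- seed
  out
}

#' Individual-scheme pseudo-absences
#'
#' For each individual, fits its own environmental profile and draws as many
#' pseudo-absences as it has presences, restricted to the convex hull of
#' *all* individuals' presences (pooled), outside that individual's presence
#' buffers, and inside that individual's absence zone. Absences for one
#' individual may fall near another individual's presences.
#'
#' @param presences individual-mode presence set from [grid_rarefy()].
#' @param stack rescaled [covariate_stack()].
#' @param buffer_m per-individual presence buffer (default 2000 m).
#' @param nu,gamma OCSVM parameters (see [ocsvm_profile()]).
#' @param seed RNG seed.
#' @param min_presences minimum presences needed to profile an individual on
#'   its own; individuals below it fall back to a profile fitted on all
#'   presences pooled (with a warning) while keeping their own buffers and
#'   counts.
#' @return data.frame (x, y, cell, individual_id) with scheme attributes.
#' @export
sample_individual_pa <- function(presences, stack, buffer_m = 2000,
                                 nu = 0.05, gamma = NULL, seed = NULL,
                                 min_presences = 10) {
  tmpl <- stack$layers[[1]]
  hull <- presence_hull(presences$x, presences$y, tmpl$cell)
  co <- grid_coords(tmpl)
  in_hull <- point_in_polygon(co$x, co$y, hull)
  env_all <- extract_covariates(stack, presences$x, presences$y)
  ids <- unique(presences$individual_id)
  out <- vector("list", length(ids))
  pooled_prof <- NULL
  with_seed(seed, {
    for (k in seq_along(ids)) {
      id <- ids[k]
      rows <- presences$individual_id == id
      if (sum(rows) >= min_presences) {
        prof <- ocsvm_profile(env_all[rows, , drop = FALSE], stack,
                              nu = nu, gamma = gamma)
      } else {
        warning("individual ", id, " has fewer than ", min_presences,
                " presences; using the pooled environmental profile")
        if (is.null(pooled_prof))
          pooled_prof <- ocsvm_profile(env_all, stack, nu = nu, gamma = gamma)
        prof <- pooled_prof
      }
      cls <- as.vector(prof$classification$values)
      elig <- which(in_hull & !is.na(cls) & cls == 0)
      if (length(elig)) {
        d <- min_dist_to_points(co$x[elig], co$y[elig],
                                presences$x[rows], presences$y[rows])
        elig <- elig[d >= buffer_m]
      }
      n_id <- sum(rows)
      if (length(elig) < n_id)
        stop(sprintf("individual %s: only %d eligible cells for %d absences",
                     id, length(elig), n_id))
      sel <- sample(elig, n_id)
      out[[k]] <- data.frame(x = co$x[sel], y = co$y[sel], cell = sel,
                             individual_id = id)
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "scheme") <- "individual"
  attr(out, "buffer_m") <- buffer_m
  attr(out, "seed") <- seed
  out
}

# convex hull of presence points as a closed polygon matrix; degenerate
# (collinear / too few) hulls are inflated by one cell width
presence_hull <- function(x, y, cell) {
  pts <- unique(cbind(as.numeric(x), as.numeric(y)))
  h <- grDevices::chull(pts[, 1], pts[, 2])
  poly <- pts[h, , drop = FALSE]
  area <- 0
  n <- nrow(poly)
  if (n >= 3) {
    j <- c(2:n, 1)
    area <- abs(sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2])) / 2
  }
  if (n < 3 || area < cell^2) {
    # inflate a degenerate hull by one cell width around its bounding box
    rx <- range(pts[, 1]) + c(-cell, cell)
    ry <- range(pts[, 2]) + c(-cell, cell)
    poly <- cbind(c(rx[1], rx[2], rx[2], rx[1]),
                  c(ry[1], ry[1], ry[2], ry[2]))
  }
  poly
}
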