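#' Aggregate per-individual conditional predictions
#'
#' Cell-wise mean or maximum of aligned conditional suitability rasters. The
#' maximum raster is the precautionary choice for risk input: it records the
#' highest predicted suitability across individuals in each cell, guarding
#' against under-estimation from imbalanced tagging.
#'
#' @param rasters list of aligned `raster_grid` conditional predictions.
#' @param mode `"max"` or `"mean"`.
#' @return a `raster_grid`.
#' @export
aggregate_individual <- function(rasters, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  stopifnot(length(rasters) >= 1)
  tmpl <- rasters[[1]]
  for (r in rasters) stop_if_misaligned(tmpl, r)
  arr <- vapply(rasters, function(r) as.vector(r$values),
                numeric(tmpl$n_rows * tmpl$n_cols))
  if (is.null(dim(arr))) arr <- matrix(arr, ncol = length(rasters))
  v <- if (mode == "max") apply(arr, 1, function(z)
    if (all(is.na(z))) NA_real_ else max(z, na.rm = TRUE)) else
      rowMeans(arr)
  grid_like(tmpl, matrix(v, tmpl$n_rows, tmpl$n_cols))
}

#' Tercile classification of a suitability surface
#'
#' Cuts at the 1/3 and 2/3 quantiles (type 7) of non-missing cells; ties go
#' to the lower class.
#'
#' @param raster a `raster_grid`.
#' @return list with `classes` (`raster_grid` of 1-3) and `breaks`.
#' @export
tercile_classify <- function(raster) {
  v <- as.vector(raster$values)
  ok <- !is.na(v)
  q <- stats::quantile(v[ok], c(1 / 3, 2 / 3), type = 7, names = FALSE)
  if (q[1] == q[2] || diff(range(v[ok])) == 0)
    stop("degenerate distribution: terciles undefined")
  cls <- rep(NA_real_, length(v))
  cls[ok] <- 1 + (v[ok] > q[1]) + (v[ok] > q[2])
  list(classes = grid_like(raster, matrix(cls, raster$n_rows, raster$n_cols)),
       breaks = q)
}

#' Default bivariate (potential x realized) overall-suitability mapping
#'
#' 3x3 matrix indexed `[pop tercile, ind tercile]` -> overall class 1-3,
#' emphasising areas of high potential (population) suitability: population
#' tercile 3 is always high; tercile 2 is high only with individual tercile
#' 3; tercile 1 reaches medium only with individual tercile 3.
#' @export
default_bivariate_matrix <- function() {
  matrix(c(1, 1, 2,   # pop tercile 1
           2, 2, 3,   # pop tercile 2
           3, 3, 3),  # pop tercile 3
         nrow = 3, byrow = TRUE,
         dimnames = list(pop = 1:3, ind = 1:3))
}

#' Bivariate classification of potential vs realized suitability
#'
#' Cuts the population (potential) and individual (realized) surfaces at
#' their terciles, forms the 3x3 joint class, and maps it to an overall
#' low / medium / high suitability class.
#'
#' @param pop population-level prediction (`raster_grid`, values 0-1).
#' @param ind aggregated individual-level prediction (aligned, 0-1).
#' @param matrix_map 3x3 integer matrix `[pop, ind] -> 1..3`; default
#'   [default_bivariate_matrix()].
#' @return list (class `bivariate_class_map`): `pop_tercile`, `ind_tercile`,
#'   `joint` (10 * pop + ind), `overall` (1-3), `breaks`, `matrix_map`.
#' @export
bivariate_classify <- function(pop, ind, matrix_map = default_bivariate_matrix()) {
  stop_if_misaligned(pop, ind)
  stopifnot(identical(dim(matrix_map), c(3L, 3L)))
  pt <- tercile_classify(pop)
  it <- tercile_classify(ind)
  p <- as.vector(pt$classes$values); q <- as.vector(it$classes$values)
  ok <- !is.na(p) & !is.na(q)
  joint <- overall <- rep(NA_real_, length(p))
  joint[ok] <- 10 * p[ok] + q[ok]
  overall[ok] <- matrix_map[cbind(p[ok], q[ok])]
  structure(list(
    pop_tercile = pt$classes, ind_tercile = it$classes,
    joint = grid_like(pop, matrix(joint, pop$n_rows, pop$n_cols)),
    overall = grid_like(pop, matrix(overall, pop$n_rows, pop$n_cols)),
    breaks = list(pop = pt$breaks, ind = it$breaks),
    matrix_map = matrix_map), class = "bivariate_class_map")
}

#' Default distribution reclassification for the risk overlap layer
#'
#' Maps the (pop, ind) tercile pair to the 1-3 species-distribution class
#' used by the risk model, emphasising agreement between the two models:
#' class 3 where both terciles are 3, class 2 where both are at least 2,
#' else class 1.
#' @export
default_distribution_matrix <- function() {
  matrix(c(1, 1, 1,
           1, 2, 2,
           1, 2, 3), nrow = 3, byrow = TRUE,
         dimnames = list(pop = 1:3, ind = 1:3))
}

#' Species-distribution class layer for the risk model
#'
#' @param bivmap a `bivariate_class_map`.
#' @param matrix_map 3x3 mapping `[pop, ind] -> 1..3`; default
#'   [default_distribution_matrix()].
#' @return `raster_grid` of classes 1-3.
#' @export
distribution_reclass <- function(bivmap,
                                 matrix_map = default_distribution_matrix()) {
  p <- as.vector(bivmap$pop_tercile$values)
  q <- as.vector(bivmap$ind_tercile$values)
  ok <- !is.na(p) & !is.na(q)
  out <- rep(NA_real_, length(p))
  out[ok] <- matrix_map[cbind(p[ok], q[ok])]
  g <- bivmap$pop_tercile
  grid_like(g, matrix(out, g$n_rows, g$n_cols))
}
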