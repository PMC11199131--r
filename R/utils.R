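#' Inverse logit
#' @param x numeric.
#' @export
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Logit
#' @param p probabilities in (0, 1).
#' @export
logit <- function(p) log(p / (1 - p))

# run code under a local RNG state so package functions are reproducible
# under an explicit seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# minimum distance from points (px, py) to the segment (x1,y1)-(x2,y2)
point_segment_distance <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

# ray-casting point-in-polygon; poly is a 2-column matrix, implicitly closed.
# Points exactly on an edge may fall either side; callers that care buffer.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# pairwise min distance from each point in (px,py) to a set of points
# (qx,qy), computed in column chunks to bound memory
min_dist_to_points <- function(px, py, qx, qy, chunk = 256L) {
  out <- rep(Inf, length(px))
  for (s in seq(1L, length(qx), by = chunk)) {
    idx <- s:min(s + chunk - 1L, length(qx))
    d2 <- outer(px, qx[idx], "-")^2 + outer(py, qy[idx], "-")^2
    out <- pmin(out, sqrt(.rowMins(d2)))
  }
  out
}

.rowMins <- function(m) {
  if (is.null(dim(m))) return(m)
  do.call(pmin, c(as.data.frame(m), na.rm = TRUE))
}
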