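#' Spatial block fold assignment
#'
#' Tiles the sample bounding box with square blocks and randomly assigns
#' blocks to `k` folds, repeating the assignment `n_iter` times and keeping
#' the iteration with the most even dispersal of presences and absences
#' across folds (L1 deviation of per-fold class shares from 1/k).
#'
#' @param samples data.frame with `x`, `y`, `label`.
#' @param block_side_m block side length (m); typically set from the median
#'   variogram range of the environmental layers.
#' @param k number of folds (default 5).
#' @param n_iter random assignments tried (default 100).
#' @param seed RNG seed.
#' @return list (class `fold_assignment`): `fold` (per sample), `blocks`
#'   (block id, fold, xmin, ymin, side), `evenness`, `evenness_all`,
#'   `iteration`, `seed`. Warns when the best iteration leaves a fold without
#'   presences or absences.
#' @export
make_spatial_blocks <- function(samples, block_side_m, k = 5, n_iter = 100,
                                seed = NULL) {
  stopifnot(block_side_m > 0)
  bx <- floor((samples$x - min(samples$x)) / block_side_m)
  by <- floor((samples$y - min(samples$y)) / block_side_m)
  block <- match(paste(bx, by), unique(paste(bx, by)))
  n_blocks <- max(block)
  pres <- samples$label == 1
  best <- NULL
  evenness_all <- numeric(n_iter)
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      assign_f <- sample(rep_len(seq_len(k), n_blocks))
      fold <- assign_f[block]
      ps <- tabulate(fold[pres], k) / max(sum(pres), 1)
      as_ <- tabulate(fold[!pres], k) / max(sum(!pres), 1)
      ev <- sum(abs(ps - 1 / k)) + sum(abs(as_ - 1 / k))
      evenness_all[it] <- ev
      if (is.null(best) || ev < best$evenness)
        best <- list(fold = fold, assign = assign_f, evenness = ev,
                     iteration = it)
    }
  })
  ps <- tabulate(best$fold[pres], k)
  as_ <- tabulate(best$fold[!pres], k)
  if (any(ps == 0) || any(as_ == 0))
    warning("best iteration leaves fold(s) without presences or absences; ",
            "metrics on those folds will be skipped")
  blocks <- data.frame(block = seq_len(n_blocks), fold = best$assign)
  fb <- factor(block, levels = seq_len(n_blocks))
  blocks$xmin <- as.numeric(tapply(min(samples$x) + bx * block_side_m, fb, min))
  blocks$ymin <- as.numeric(tapply(min(samples$y) + by * block_side_m, fb, min))
  blocks$side <- block_side_m
  structure(list(fold = best$fold, blocks = blocks, evenness = best$evenness,
                 evenness_all = evenness_all, iteration = best$iteration,
                 k = k, seed = seed),
            class = "fold_assignment")
}

#' Empirical variogram with a spherical model fit
#'
#' Computes the empirical semivariance
#' `gamma(h) = (1 / (2 |N(h)|)) * sum (z_i - z_j)^2` in distance bins and
#' fits a spherical model (nugget, partial sill, range) by weighted least
#' squares with pair counts as weights. The fitted range is the practical
#' range of spatial autocorrelation; the median range across environmental
#' layers drives the default spatial block size.
#'
#' @param values numeric field values at the sample points.
#' @param x,y point coordinates (m).
#' @param n_lags number of distance bins (default 15).
#' @param max_lag largest lag considered (default half the maximum pairwise
#'   distance).
#' @return list (class `variogram_result`): `lag` (bin centres), `gamma`,
#'   `counts`, `nugget`, `psill`, `range` (practical range, m), `model`.
#' @export
variogram_range <- function(values, x, y, n_lags = 15, max_lag = NULL) {
  stopifnot(length(values) >= 30)
  if (stats::var(values) == 0) stop("no spatial structure")
  d <- as.vector(stats::dist(cbind(x, y)))
  g <- 0.5 * as.vector(stats::dist(values))^2
  if (is.null(max_lag)) max_lag <- max(d) / 2
  inc <- d <= max_lag & d > 0
  breaks <- seq(0, max_lag, length.out = n_lags + 1)
  bin <- cut(d[inc], breaks, include.lowest = TRUE, labels = FALSE)
  gam <- tapply(g[inc], bin, mean)
  cnt <- tapply(g[inc], bin, length)
  ctr <- (breaks[-1] + breaks[-length(breaks)]) / 2
  keep <- !is.na(gam)
  lag <- ctr[as.integer(names(gam))][keep]
  gam <- as.numeric(gam[keep]); cnt <- as.numeric(cnt[keep])
  sph <- function(h, n0, s, r)
    n0 + s * ifelse(h < r, 1.5 * h / r - 0.5 * (h / r)^3, 1)
  obj <- function(p) sum(cnt * (gam - sph(lag, p[1], p[2], p[3]))^2)
  v <- stats::var(values)
  # multi-start WLS: the objective is flat in range when gamma(h) has not
  # plateaued, so take the best of several range initialisations
  opt <- NULL
  for (r0 in max_lag * c(0.25, 0.5, 1)) {
    o <- stats::optim(c(0, v, r0), obj, method = "L-BFGS-B",
                      lower = c(0, 1e-12, max(lag[1], 1e-6) * 0.1),
                      upper = c(2 * v, 5 * v, 2 * max_lag))
    if (is.null(opt) || o$value < opt$value) opt <- o
  }
  structure(list(lag = lag, gamma = gam, counts = cnt,
                 nugget = opt$par[1], psill = opt$par[2],
                 range = opt$par[3], model = "spherical",
                 converged = opt$convergence == 0),
            class = "variogram_result")
}

#' Rank-based AUC
#'
#' Mann-Whitney area under the ROC curve; ties count one half.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores.
#' @export
auc <- function(labels, scores) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: one class only")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold maximising the true skill statistic
#' @param labels 0/1 vector.
#' @param scores numeric scores; a point is predicted present when its score
#'   is at or above the threshold.
#' @export
max_tss_threshold <- function(labels, scores) {
  thr <- sort(unique(scores))
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  best_t <- thr[1]; best_tss <- -Inf
  for (t in thr) {
    pred <- scores >= t
    tss <- sum(pred & pos) / n1 + sum(!pred & !pos) / n0 - 1
    if (tss > best_tss) { best_tss <- tss; best_t <- t }
  }
  best_t
}

#' Sensitivity, specificity and TSS at a threshold
#'
#' When `threshold` is NULL it is chosen to maximise TSS on the supplied
#' data (in cross-validation the threshold is chosen on the training fold and
#' passed here for the test fold).
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores.
#' @param threshold decision threshold (scores >= threshold are presences).
#' @return list with sensitivity, specificity, tss, threshold.
#' @export
confusion_metrics <- function(labels, scores, threshold = NULL) {
  if (is.null(threshold)) threshold <- max_tss_threshold(labels, scores)
  pos <- labels == 1
  pred <- scores >= threshold
  sens <- if (sum(pos)) sum(pred & pos) / sum(pos) else NA_real_
  spec <- if (sum(!pos)) sum(!pred & !pos) / sum(!pos) else NA_real_
  list(sensitivity = sens, specificity = spec, tss = sens + spec - 1,
       threshold = threshold)
}

#' Continuous Boyce index
#'
#' Slides a window of width `window_frac` times the score range across the
#' score range at `n_windows` evenly spaced centres; per window, P is the
#' share of presence scores inside and E the share of background scores
#' inside. The CBI is the Spearman rank correlation between P/E (over windows
#' with E > 0) and the window centre: +1 means predicted suitability ranks
#' presences perfectly, 0 no better than background, -1 inverted.
#'
#' @param presence_scores scores at presences.
#' @param background_scores scores at background / absence points.
#' @param window_frac window width as a fraction of the score range.
#' @param n_windows number of window centres.
#' @return list (class `boyce_result`): `cbi` and `curve` (centre, P, E, PE).
#'   A flat P/E curve (zero variance) yields CBI 0.
#' @export
boyce_index <- function(presence_scores, background_scores,
                        window_frac = 0.1, n_windows = 101) {
  stopifnot(length(presence_scores) >= 1, length(background_scores) >= 1)
  rng <- range(c(presence_scores, background_scores))
  w <- window_frac * diff(rng)
  centres <- seq(rng[1], rng[2], length.out = n_windows)
  P <- E <- numeric(n_windows)
  for (i in seq_len(n_windows)) {
    lo <- centres[i] - w / 2; hi <- centres[i] + w / 2
    P[i] <- mean(presence_scores >= lo & presence_scores <= hi)
    E[i] <- mean(background_scores >= lo & background_scores <= hi)
  }
  valid <- E > 0
  if (sum(valid) < 3) stop("CBI undefined: fewer than 3 valid windows")
  pe <- P[valid] / E[valid]
  cbi <- if (stats::sd(pe) == 0) 0 else
    suppressWarnings(stats::cor(pe, centres[valid], method = "spearman"))
  if (is.na(cbi)) cbi <- 0
  structure(list(cbi = cbi,
                 curve = data.frame(centre = centres, P = P, E = E,
                                    PE = ifelse(E > 0, P / E, NA))),
            class = "boyce_result")
}

cv_fold_metrics <- function(test, threshold) {
  cm <- confusion_metrics(test$label, test$score, threshold)
  cbi <- tryCatch(
    boyce_index(test$score[test$label == 1],
                test$score[test$label == 0])$cbi,
    error = function(e) NA_real_)
  data.frame(auc = auc(test$label, test$score),
             sensitivity = cm$sensitivity, specificity = cm$specificity,
             tss = cm$tss, cbi = cbi, threshold = threshold)
}

finish_report <- function(folds) {
  met <- c("auc", "sensitivity", "specificity", "tss", "cbi")
  structure(list(folds = folds,
                 mean = vapply(folds[met], mean, 0, na.rm = TRUE),
                 sd = vapply(folds[met], stats::sd, 0, na.rm = TRUE)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric_report over %d folds\n", nrow(x$folds)))
  for (m in names(x$mean))
    cat(sprintf("  %-12s %.3f +/- %.3f\n", m, x$mean[m], x$sd[m]))
  invisible(x)
}

#' Spatially blocked cross-validation of a GLM
#'
#' Per fold: fit on the training folds, choose the max-TSS threshold on
#' training scores, evaluate AUC / sensitivity / specificity / TSS / CBI on
#' the held-out fold.
#'
#' @param samples labeled data.frame.
#' @param covariates covariate column names.
#' @param fold integer fold per row (from [make_spatial_blocks()] `$fold`),
#'   or a `fold_assignment`.
#' @return a `metric_report` (per-fold table plus means and SDs); folds with
#'   a single class in train or test are skipped and recorded.
#' @export
run_blocked_cv <- function(samples, covariates, fold) {
  if (inherits(fold, "fold_assignment")) fold <- fold$fold
  out <- list(); skipped <- integer()
  for (f in sort(unique(fold))) {
    tr <- samples[fold != f, , drop = FALSE]
    te <- samples[fold == f, , drop = FALSE]
    if (length(unique(tr$label)) < 2 || length(unique(te$label)) < 2) {
      skipped <- c(skipped, f); next
    }
    # separated training folds are kept: fold metrics are rank-based
    m <- suppressWarnings(fit_glm(tr, covariates, on_separation = "warn"))
    thr <- max_tss_threshold(tr$label, predict_samples(m, tr))
    te$score <- predict_samples(m, te)
    res <- cv_fold_metrics(te, thr)
    res$fold <- f; res$n_test <- nrow(te)
    out[[length(out) + 1]] <- res
  }
  if (!length(out)) stop("no usable folds")
  rep <- finish_report(do.call(rbind, out))
  rep$skipped <- skipped
  rep
}

#' Leave-one-individual-out cross-validation of a GLMM
#'
#' Each individual in turn is held out; the random-intercept GLMM is fitted
#' on the remaining individuals and the held-out individual is predicted in
#' novel mode (random intercept 0), measuring transferability to unseen
#' animals.
#'
#' @param samples labeled data.frame with an individual id column.
#' @param covariates fixed-effect covariate names.
#' @param id_col individual id column.
#' @param nAGQ lme4 integration setting (0 = fast, used inside selection
#'   loops).
#' @param background optional data.frame of covariate rows representing the
#'   available environment (e.g. random study-area cells); when supplied the
#'   Boyce index contrasts held-out presence scores against predicted
#'   background scores rather than the fold's pseudo-absence scores.
#' @return a `metric_report`.
#' @export
run_loio_cv <- function(samples, covariates, id_col = "individual_id",
                        nAGQ = 0, background = NULL) {
  ids <- unique(samples[[id_col]])
  out <- list(); skipped <- character()
  for (id in ids) {
    tr <- samples[samples[[id_col]] != id, , drop = FALSE]
    te <- samples[samples[[id_col]] == id, , drop = FALSE]
    if (length(unique(tr$label)) < 2 || length(unique(te$label)) < 2) {
      skipped <- c(skipped, as.character(id)); next
    }
    m <- suppressWarnings(
      suppressMessages(fit_glmm(tr, covariates, id_col = id_col,
                                nAGQ = nAGQ)))
    thr <- max_tss_threshold(tr$label, predict_samples(m, tr, mode = "novel"))
    te$score <- predict_samples(m, te, mode = "novel")
    res <- cv_fold_metrics(te, thr)
    if (!is.null(background)) {
      bg_score <- predict_samples(m, background, mode = "novel")
      res$cbi <- tryCatch(
        boyce_index(te$score[te$label == 1], bg_score)$cbi,
        error = function(e) NA_real_)
    }
    res$fold <- as.character(id); res$n_test <- nrow(te)
    out[[length(out) + 1]] <- res
  }
  if (!length(out)) stop("no usable folds")
  rep <- finish_report(do.call(rbind, out))
  rep$skipped <- skipped
  rep
}
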