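#' Negative exponential kernel accessibility surface
#'
#' Central-place accessibility layer `a^(d / d0)` where `d` is the Euclidean
#' distance (km) from the colony and `a` in (0, 1] is the decay coefficient:
#' low `a` models limited movement, `a = 1` removes the constraint. The log
#' of the surface is linear in distance with slope `log(a) / d0`.
#'
#' @param grid `raster_grid` template.
#' @param colony length-2 numeric (x, y) of the colony / tagging site (m).
#' @param a decay coefficient in (0, 1].
#' @param d0_km distance scale in km per decay unit (default 1).
#' @return list (class `nek_surface`) with `raster`, `a`, `colony`, `d0_km`.
#' @export
nek_surface <- function(grid, colony, a, d0_km = 1) {
  if (!(is.numeric(a) && length(a) == 1 && a > 0 && a <= 1))
    stop("a must lie in (0, 1]")
  co <- grid_coords(grid)
  d_km <- sqrt((co$x - colony[1])^2 + (co$y - colony[2])^2) / 1000
  vals <- a^(d_km / d0_km)
  structure(list(raster = grid_like(grid, matrix(vals, grid$n_rows, grid$n_cols)),
                 a = a, colony = colony, d0_km = d0_km),
            class = "nek_surface")
}

#' NEK value at point locations
#' @param x,y coordinates (m).
#' @param colony length-2 (x, y) of the colony (m).
#' @param a decay coefficient in (0, 1].
#' @param d0_km distance scale (km).
#' @export
nek_at <- function(x, y, colony, a, d0_km = 1) {
  if (!(a > 0 && a <= 1)) stop("a must lie in (0, 1]")
  a^(sqrt((x - colony[1])^2 + (y - colony[2])^2) / 1000 / d0_km)
}

#' Logarithmic candidate sequence for the NEK decay coefficient
#' @param n number of candidates (default 10).
#' @param lo,hi endpoints of the log-spaced grid (defaults 1e-3, 0.9).
#' @export
nek_candidates <- function(n = 10, lo = 1e-3, hi = 0.9) {
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Binomial GLM for population-level (potential) suitability
#'
#' Maximum-likelihood logistic regression of presence (1) vs pseudo-absence
#' (0) on screened, rescaled covariates. Variable importance is ranked by the
#' absolute Wald statistic of each coefficient.
#'
#' @param samples data.frame with a 0/1 `label` column and covariate columns.
#' @param covariates character vector of covariate column names.
#' @param label_col response column name (default "label").
#' @param on_separation what to do when the classes are perfectly separated:
#'   `"error"` (default) or `"warn"` and keep the fit — rank-based downstream
#'   products (AUC, Boyce, tercile maps) are unaffected by the inflated
#'   coefficients, but their values should not be interpreted.
#' @return object of class `cpf_glm`: coefficient table (estimate, se, stat),
#'   named `coef` vector, `covariates`, `converged`, and the underlying `fit`.
#' @export
fit_glm <- function(samples, covariates, label_col = "label",
                    on_separation = c("error", "warn")) {
  on_separation <- match.arg(on_separation)
  y <- samples[[label_col]]
  if (length(unique(y)) < 2) stop("both classes must be present")
  form <- if (length(covariates))
    stats::reformulate(covariates, response = label_col) else
      stats::as.formula(paste(label_col, "~ 1"))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = samples),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design; aliased columns: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  if (sep_warn) {
    # distinguish true separation (classes fully split by the fit) from
    # ordinary extreme fitted probabilities
    fv <- stats::fitted(fit)
    if (min(fv[y == 1]) > max(fv[y == 0])) {
      msg <- paste0("perfect separation suspected (|coef| up to ",
                    format(max(abs(cf)), digits = 3), ")")
      if (on_separation == "error") stop(msg) else warning(msg)
    }
  }
  sm <- summary(fit)$coefficients
  structure(list(
    type = "glm",
    coef = cf,
    table = data.frame(term = rownames(sm), estimate = sm[, 1],
                       se = sm[, 2], stat = sm[, 3], row.names = NULL),
    covariates = covariates,
    converged = fit$converged,
    fit = fit), class = "cpf_glm")
}

#' Variable importance by absolute Wald statistic
#' @param model a `cpf_glm` or `cpf_glmm`.
#' @return data.frame of non-intercept terms sorted by decreasing |stat|.
#' @export
variable_importance <- function(model) {
  tb <- model$table[model$table$term != "(Intercept)", , drop = FALSE]
  tb$abs_stat <- abs(tb$stat)
  tb[order(-tb$abs_stat), c("term", "estimate", "stat", "abs_stat")]
}

#' Binomial random-intercept GLMM for realized suitability
#'
#' Logistic mixed model with a random intercept per individual, capturing
#' differences in each animal's baseline likelihood of presence; the NEK
#' accessibility layer typically enters as one of the fixed-effect
#' covariates. Reports the variance-partition marginal and conditional R^2
#' (logit-link distribution variance pi^2 / 3).
#'
#' @param samples data.frame with `label`, covariates and an individual id
#'   column.
#' @param covariates character vector of fixed-effect column names.
#' @param id_col individual id column (default "individual_id").
#' @param label_col response column (default "label").
#' @param nAGQ lme4 integration setting; 1 (Laplace) for final fits, 0 for
#'   fast fits inside cross-validation loops.
#' @return object of class `cpf_glmm` with `coef` (fixed effects), `table`,
#'   `ranef` (b_i per individual), `sigma2_id`, `r2_marginal`,
#'   `r2_conditional`, and the underlying `fit`. Falls back to [fit_glm()]
#'   with a warning when only one individual is present.
#' @export
fit_glmm <- function(samples, covariates, id_col = "individual_id",
                     label_col = "label", nAGQ = 1) {
  if (length(unique(samples[[id_col]])) < 2) {
    warning("single individual; falling back to a plain GLM")
    return(fit_glm(samples, covariates, label_col))
  }
  if (length(unique(samples[[label_col]])) < 2)
    stop("both classes must be present")
  rhs <- paste(c(covariates, sprintf("(1 | %s)", id_col)), collapse = " + ")
  form <- stats::as.formula(paste(label_col, "~", rhs))
  fit <- lme4::glmer(form, data = samples, family = stats::binomial(),
                     nAGQ = nAGQ)
  if (!is.null(fit@optinfo$conv$opt) && fit@optinfo$conv$opt != 0) {
    gn <- tryCatch(max(abs(fit@optinfo$derivs$gradient)), error = function(e) NA)
    stop("GLMM did not converge (max |gradient| = ", format(gn), ")")
  }
  beta <- lme4::fixef(fit)
  sm <- summary(fit)$coefficients
  b <- lme4::ranef(fit)[[id_col]][, 1]
  names(b) <- rownames(lme4::ranef(fit)[[id_col]])
  s2 <- as.numeric(lme4::VarCorr(fit)[[id_col]])
  X <- stats::model.matrix(stats::reformulate(c("1", covariates)),
                           data = samples)
  var_f <- stats::var(as.vector(X %*% beta))
  denom <- var_f + s2 + pi^2 / 3
  structure(list(
    type = "glmm",
    coef = beta,
    table = data.frame(term = rownames(sm), estimate = sm[, 1],
                       se = sm[, 2], stat = sm[, 3], row.names = NULL),
    covariates = covariates,
    id_col = id_col,
    ranef = b,
    sigma2_id = s2,
    r2_marginal = var_f / denom,
    r2_conditional = (var_f + s2) / denom,
    fit = fit), class = "cpf_glmm")
}

# linear predictor of a fitted model on new rows; mode controls the random
# intercept: marginal/novel -> 0, conditional -> b_id
model_linpred <- function(model, newdata, mode = "novel", id = NULL) {
  cf <- model$coef
  eta <- rep(cf[["(Intercept)"]], nrow(newdata))
  for (v in model$covariates) {
    if (is.null(newdata[[v]])) stop("missing covariate '", v, "'")
    eta <- eta + cf[[v]] * newdata[[v]]
  }
  if (model$type == "glmm" && mode == "conditional") {
    if (is.null(id)) {
      ids <- as.character(newdata[[model$id_col]])
      b <- model$ranef[ids]
      b[is.na(b)] <- 0
      eta <- eta + b
    } else {
      eta <- eta + model$ranef[[as.character(id)]]
    }
  }
  eta
}

#' Predicted occurrence probability for new samples
#' @param model a `cpf_glm` or `cpf_glmm`.
#' @param newdata data.frame containing the model covariates.
#' @param mode `"marginal"` / `"novel"` (fixed effects only) or
#'   `"conditional"` (adds the individual's random intercept).
#' @param id individual whose intercept to use in conditional mode; default
#'   uses each row's own id column.
#' @export
predict_samples <- function(model, newdata,
                            mode = c("novel", "marginal", "conditional"),
                            id = NULL) {
  mode <- match.arg(mode)
  inv_logit(model_linpred(model, newdata, mode, id))
}

#' Predicted suitability surface
#'
#' Cell-wise inverse-logit of the model linear predictor over a covariate
#' stack. `marginal` / `novel` use fixed effects only (random intercept 0);
#' `conditional` adds a named individual's intercept.
#'
#' @param model a `cpf_glm` or `cpf_glmm`.
#' @param stack [covariate_stack()] holding every model covariate on the
#'   training scale (include the NEK layer, under its covariate name, for
#'   NEK models).
#' @param mode `"marginal"`, `"conditional"` or `"novel"`.
#' @param id individual id (required for conditional mode).
#' @return `raster_grid` of probabilities in (0, 1), NA where any covariate
#'   is missing.
#' @export
predict_surface <- function(model, stack,
                            mode = c("marginal", "conditional", "novel"),
                            id = NULL) {
  mode <- match.arg(mode)
  missing_layers <- setdiff(model$covariates, names(stack$layers))
  if (length(missing_layers))
    stop("missing covariate layer(s): ", paste(missing_layers, collapse = ", "))
  tmpl <- stack$layers[[1]]
  newdata <- as.data.frame(lapply(stack$layers[model$covariates],
                                  function(g) as.vector(g$values)))
  if (!length(model$covariates))
    newdata <- data.frame(row.names = seq_len(tmpl$n_rows * tmpl$n_cols))
  if (mode == "conditional" && is.null(id))
    stop("conditional mode needs an individual id")
  eta <- model_linpred(model, newdata, mode, id)
  p <- inv_logit(eta)
  if (length(model$covariates)) {
    miss <- !stats::complete.cases(newdata)
    p[miss] <- NA_real_
  }
  grid_like(tmpl, matrix(p, tmpl$n_rows, tmpl$n_cols))
}

#' Select the NEK decay coefficient by cross-validated Boyce index
#'
#' For each candidate decay value the NEK accessibility covariate is rebuilt,
#' the GLMM is cross-validated leave-one-individual-out, and the mean
#' held-out continuous Boyce index (novel-individual predictions, random
#' intercept 0) is recorded. The candidate with the highest mean CBI wins;
#' ties go to the smaller (more conservative) decay value.
#'
#' @param samples labeled data.frame with `x`, `y`, `label`, individual ids
#'   and covariate columns.
#' @param covariates fixed-effect covariates alongside the NEK term.
#' @param colony colony location (x, y) in metres.
#' @param candidates candidate decay values (default [nek_candidates()]).
#' @param d0_km NEK distance scale (km).
#' @param id_col individual id column.
#' @param nek_col name for the NEK covariate column (default "nek").
#' @param nAGQ lme4 integration setting inside the CV loop (default 0, fast).
#' @param background optional data.frame with `x`, `y` and covariate columns
#'   for the available environment; the Boyce index is then computed against
#'   predicted background scores (the NEK column is rebuilt per candidate).
#' @return list with `a` (selected), `scores` (data.frame a / mean_cbi /
#'   n_folds).
#' @export
select_nek_a <- function(samples, covariates, colony,
                         candidates = nek_candidates(), d0_km = 1,
                         id_col = "individual_id", nek_col = "nek",
                         nAGQ = 0, background = NULL) {
  candidates <- sort(candidates)
  scores <- data.frame(a = candidates, mean_cbi = NA_real_, n_folds = 0L)
  for (i in seq_along(candidates)) {
    s <- samples
    s[[nek_col]] <- nek_at(s$x, s$y, colony, candidates[i], d0_km)
    bg <- background
    if (!is.null(bg))
      bg[[nek_col]] <- nek_at(bg$x, bg$y, colony, candidates[i], d0_km)
    rep_i <- tryCatch(
      run_loio_cv(s, c(covariates, nek_col), id_col = id_col, nAGQ = nAGQ,
                  background = bg),
      error = function(e) NULL)
    if (!is.null(rep_i)) {
      cbi <- rep_i$folds$cbi
      scores$mean_cbi[i] <- mean(cbi, na.rm = TRUE)
      scores$n_folds[i] <- sum(!is.na(cbi))
    }
  }
  if (all(is.na(scores$mean_cbi)))
    stop("all NEK candidates failed to fit")
  best <- which(scores$mean_cbi == max(scores$mean_cbi, na.rm = TRUE))[1]
  list(a = candidates[best], scores = scores)
}

#' Backward variable elimination guided by cross-validated AUC
#'
#' Starting from the full covariate set, repeatedly removes the covariate
#' whose removal yields the highest mean cross-validated AUC, stopping when
#' no single removal improves the mean AUC by more than `tol`.
#'
#' @param samples labeled data.frame.
#' @param covariates initial covariate names.
#' @param fold integer fold id per row (e.g. from [make_spatial_blocks()]).
#' @param tol minimum AUC improvement to accept a removal (default 0.001).
#' @param label_col response column.
#' @return list with `retained` and `trace` (data.frame step / removed /
#'   mean_auc).
#' @export
backward_eliminate <- function(samples, covariates, fold, tol = 0.001,
                               label_col = "label") {
  cv_auc <- function(covs) {
    aucs <- c()
    for (f in unique(fold)) {
      tr <- samples[fold != f, , drop = FALSE]
      te <- samples[fold == f, , drop = FALSE]
      if (length(unique(tr[[label_col]])) < 2 ||
          length(unique(te[[label_col]])) < 2) next
      m <- tryCatch(
        suppressWarnings(fit_glm(tr, covs, label_col,
                                 on_separation = "warn")),
        error = function(e) NULL)
      if (is.null(m)) next
      aucs <- c(aucs, auc(te[[label_col]], predict_samples(m, te)))
    }
    if (!length(aucs)) NA_real_ else mean(aucs)
  }
  current <- covariates
  trace <- data.frame(step = 0L, removed = NA_character_,
                      mean_auc = cv_auc(current))
  if (is.na(trace$mean_auc[1])) {
    warning("no usable folds; covariate set returned unchanged")
    return(list(retained = current, trace = trace))
  }
  step <- 0L
  while (length(current) > 1) {
    cand <- vapply(current, function(v) cv_auc(setdiff(current, v)), 0)
    if (all(is.na(cand))) break
    best <- which.max(cand)
    if (is.na(cand[best]) ||
        cand[best] <= trace$mean_auc[nrow(trace)] + tol) break
    step <- step + 1L
    removed <- current[best]
    current <- setdiff(current, removed)
    trace <- rbind(trace, data.frame(step = step, removed = removed,
                                     mean_auc = cand[best]))
  }
  list(retained = current, trace = trace)
}

#' Serialize a fitted model to JSON
#' @param model a `cpf_glm` or `cpf_glmm`.
#' @param path output path.
#' @param meta optional named list of extra metadata (seed, transforms, ...).
#' @export
write_model_json <- function(model, path, meta = NULL) {
  obj <- list(type = model$type, coefficients = model$table,
              covariates = model$covariates)
  if (model$type == "glmm") {
    obj$random_intercepts <- as.list(model$ranef)
    obj$sigma2_id <- model$sigma2_id
    obj$r2_marginal <- model$r2_marginal
    obj$r2_conditional <- model$r2_conditional
  }
  if (!is.null(meta)) obj$meta <- meta
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
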