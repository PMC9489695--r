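#' Fit a weighted random forest over effect sizes ("meta-forest")
#'
#' Regression random forest of effect sizes on environmental moderators in
#' which every case carries its meta-analytic weight `w = 1/(v + tau2)`:
#' the weights act as bootstrap sampling probabilities, so heavily weighted
#' (precise) comparisons shape both the resampling and the split losses
#' computed on the resampled trees.  Hyperparameters are chosen by k-fold
#' cross-validation over a small declared grid (trees in `trees_grid`,
#' candidate predictors per split `ceiling(p/3)` and `ceiling(sqrt(p))`,
#' minimum leaf size in `min_node_grid`); the selected model is refit on
#' all data and its CV RMSE and R^2 reported.
#'
#' @param effects data.frame with the outcome and predictor columns; e.g.
#'   the output of [add_effect_sizes()].
#' @param predictors character vector of predictor column names.
#' @param outcome outcome column (default `"lnrr"`).
#' @param weights case weights; `NULL` derives `1/(v + tau2)` from the
#'   `v` column (with [estimate_tau2()]), or uniform weights when no `v`
#'   column exists.
#' @param cv_folds number of cross-validation folds (default 5).
#' @param seed RNG seed; the fit is deterministic given the seed.
#' @param trees_grid,min_node_grid hyperparameter grids.
#' @return Object of class `"metaforest_fit"`: the fitted [ranger::ranger]
#'   forest plus `cv_metrics` (`rmse`, `r_squared`), `best` (chosen
#'   hyperparameters), `predictors`, `factor_levels`, `weights`.
#' @export
fit_metaforest <- function(effects, predictors, outcome = "lnrr",
                           weights = NULL, cv_folds = 5, seed = 1,
                           trees_grid = c(250, 500),
                           min_node_grid = c(3, 5)) {
  stopifnot(all(c(outcome, predictors) %in% names(effects)))
  n <- nrow(effects)
  if (n < 30) stop("too few effects (", n, "); need >= 30")
  y <- effects[[outcome]]
  if (any(!is.finite(y))) stop("non-finite outcome values")
  if (stats::sd(y) == 0)
    stop("outcome is constant: a forest cannot be fit (R^2 undefined)")
  X <- effects[, predictors, drop = FALSE]
  if (anyNA(X)) stop("predictors must be complete (no NA)")
  for (p in predictors)
    if (is.character(X[[p]]) || is.logical(X[[p]])) X[[p]] <- factor(X[[p]])
  if (is.null(weights)) {
    weights <- if ("v" %in% names(effects)) {
      tau2 <- estimate_tau2(y, effects$v)
      1 / (effects$v + tau2)
    } else rep(1, n)
  }
  stopifnot(length(weights) == n, all(weights > 0))

  dat <- cbind(stats::setNames(data.frame(y), ".outcome"), X)
  p <- length(predictors)
  mtry_grid <- unique(c(ceiling(p / 3), ceiling(sqrt(p))))
  grid <- expand.grid(num.trees = trees_grid, mtry = mtry_grid,
                      min.node.size = min_node_grid)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  folds <- sample(rep_len(seq_len(cv_folds), n))

  cv_for <- function(g) {
    pred <- numeric(n)
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      fit <- ranger::ranger(
        dependent.variable.name = ".outcome", data = dat[tr, , drop = FALSE],
        case.weights = weights[tr], num.trees = g$num.trees, mtry = g$mtry,
        min.node.size = g$min.node.size, seed = seed + f, num.threads = 1)
      pred[!tr] <- stats::predict(fit, dat[!tr, , drop = FALSE],
                                  num.threads = 1)$predictions
    }
    c(rmse = sqrt(mean((pred - y)^2)),
      r_squared = 1 - sum((pred - y)^2) / sum((y - mean(y))^2))
  }
  metrics <- t(vapply(seq_len(nrow(grid)), function(i) cv_for(grid[i, ]),
                      numeric(2)))
  best_i <- which.min(metrics[, "rmse"])
  best <- grid[best_i, ]

  forest <- ranger::ranger(
    dependent.variable.name = ".outcome", data = dat,
    case.weights = weights, num.trees = best$num.trees, mtry = best$mtry,
    min.node.size = best$min.node.size, importance = "impurity",
    seed = seed, num.threads = 1)

  structure(
    list(forest = forest,
         cv_metrics = c(rmse = unname(metrics[best_i, "rmse"]),
                        r_squared = unname(metrics[best_i, "r_squared"])),
         cv_grid = cbind(grid, metrics), best = best,
         predictors = predictors, outcome = outcome,
         factor_levels = lapply(Filter(is.factor, X), levels),
         weights = weights, seed = seed),
    class = "metaforest_fit")
}

#' @export
print.metaforest_fit <- function(x, ...) {
  cat(sprintf(
    "Meta-forest: %d trees, mtry %d, min node %d; CV RMSE %.4f, R^2 %.3f\n",
    x$best$num.trees, x$best$mtry, x$best$min.node.size,
    x$cv_metrics["rmse"], x$cv_metrics["r_squared"]))
  invisible(x)
}

#' Split-improvement variable importance of a meta-forest
#'
#' Per-predictor importance as the total decrease of weighted squared
#' error across all splits on that predictor, averaged over trees
#' (impurity importance), normalised to sum to 1.  A predictor never
#' selected for splitting scores 0.
#'
#' @param model a [fit_metaforest()] result.
#' @return data.frame sorted by decreasing importance with columns
#'   `predictor` and `importance`.
#' @export
variable_importance <- function(model) {
  stopifnot(inherits(model, "metaforest_fit"))
  imp <- ranger::importance(model$forest)
  imp <- pmax(imp, 0)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  out <- data.frame(predictor = names(imp), importance = as.numeric(imp))
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  out
}

#' Predict effect sizes with across-tree uncertainty
#'
#' Ensemble mean and standard deviation of the per-tree predictions for
#' every row of a predictor table (e.g. a grid of map cells).  Rows with
#' categorical levels unseen during training are flagged and returned as
#' `NA` rather than silently coerced.
#'
#' @param model a [fit_metaforest()] result.
#' @param newdata data.frame containing the model's predictor columns.
#' @return data.frame with `mean`, `sd` and logical `unseen_level` per row.
#' @export
predict_with_uncertainty <- function(model, newdata) {
  stopifnot(inherits(model, "metaforest_fit"))
  missing <- setdiff(model$predictors, names(newdata))
  if (length(missing) > 0)
    stop("missing predictor column(s): ", paste(missing, collapse = ", "))
  nd <- newdata[, model$predictors, drop = FALSE]
  unseen <- rep(FALSE, nrow(nd))
  for (p in names(model$factor_levels)) {
    lv <- model$factor_levels[[p]]
    unseen <- unseen | !(as.character(nd[[p]]) %in% lv)
    nd[[p]] <- factor(as.character(nd[[p]]), levels = lv)
  }
  out <- data.frame(mean = rep(NA_real_, nrow(nd)),
                    sd = rep(NA_real_, nrow(nd)), unseen_level = unseen)
  ok <- !unseen
  if (any(ok)) {
    pr <- stats::predict(model$forest, nd[ok, , drop = FALSE],
                         predict.all = TRUE, num.threads = 1)$predictions
    pr <- matrix(pr, nrow = sum(ok))
    out$mean[ok] <- rowMeans(pr)
    out$sd[ok] <- apply(pr, 1, stats::sd)
    if (ncol(pr) == 1) out$sd[ok] <- 0
  }
  out
}

#' Aggregate absolute SOC loss over a grid
#'
#' The bookkeeping sum `sum(stock * percent_change / 100)` over grid cells
#' (e.g. kg C or Pg C, in the units of `stock`); negative results are net
#' losses.
#'
#' @param stock per-cell SOC stock.
#' @param percent_change per-cell predicted percentage change.
#' @return Total absolute change in the units of `stock`.
#' @export
aggregate_absolute_loss <- function(stock, percent_change) {
  stopifnot(length(stock) == length(percent_change))
  sum(stock * percent_change / 100)
}
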