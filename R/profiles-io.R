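#' Read a profile-layer table, validating every row
#'
#' Expects a comma-separated table with a header row and columns
#' `profile_id`, `latitude`, `longitude`, `is_cropland`, `top`, `bottom`,
#' `soc_c`, `bd`, `gravel` (one row per soil horizon).  Rows violating the
#' layer invariants -- negative depths, bottom not below top, negative SOC
#' content, non-positive bulk density, gravel outside [0, 100], layers
#' overlapping an earlier layer of the same profile -- are rejected with a
#' per-row diagnostic rather than aborting the read.
#'
#' @param path file path.
#' @return data.frame of accepted rows; rejected rows with their reasons
#'   are attached as the `"rejected"` attribute and reported via
#'   [message()].  An empty file yields an empty table with a warning.
#' @export
read_profiles <- function(path) {
  req <- c("profile_id", "latitude", "longitude", "is_cropland",
           "top", "bottom", "soc_c", "bd", "gravel")
  df <- read_checked(path, req, "profiles")
  if (nrow(df) == 0) return(df)
  reason <- rep(NA_character_, nrow(df))
  flag <- function(cond, why) reason <<- ifelse(is.na(reason) & cond, why, reason)
  num_bad <- !is.finite(df$top) | !is.finite(df$bottom) | !is.finite(df$soc_c)
  flag(num_bad, "unparseable or missing depth/SOC value")
  flag(!num_bad & df$top < 0, "negative depth")
  flag(!num_bad & df$bottom <= df$top, "layer bottom not below top")
  flag(!num_bad & df$soc_c < 0, "negative SOC content")
  flag(!is.na(df$bd) & df$bd <= 0, "non-positive bulk density")
  flag(!is.na(df$gravel) & (df$gravel < 0 | df$gravel > 100),
       "gravel outside [0, 100]")
  # overlap check within profile, in file order
  for (id in unique(df$profile_id)) {
    i <- which(df$profile_id == id & is.na(reason))
    if (length(i) < 2) next
    i <- i[order(df$top[i])]
    ov <- df$top[i][-1] < df$bottom[i][-length(i)] - 1e-9
    if (any(ov)) reason[i[-1][ov]] <- "layer overlaps previous layer"
  }
  finish_read(df, reason, "profile")
}

#' Read a site-environment table, validating every row
#'
#' Expects columns `profile_id`, `mat`, `p01`..`p12` (monthly precipitation,
#' mm, January first), `map`, `landform`, `soil_order`, `biome`,
#' `elevation`, `npp`, `aridity_index`, `hemisphere`.  Rows whose `map`
#' disagrees with the monthly sum (beyond 0.5% or 1 mm), with negative
#' precipitation, or with a hemisphere outside {N, S} are rejected with
#' diagnostics.
#'
#' @param path file path.
#' @return data.frame of accepted rows, with rejected rows in the
#'   `"rejected"` attribute.
#' @export
read_environments <- function(path) {
  pcols <- sprintf("p%02d", 1:12)
  req <- c("profile_id", "mat", pcols, "map", "landform", "soil_order",
           "biome", "elevation", "npp", "aridity_index", "hemisphere")
  df <- read_checked(path, req, "environments")
  if (nrow(df) == 0) return(df)
  reason <- rep(NA_character_, nrow(df))
  flag <- function(cond, why) reason <<- ifelse(is.na(reason) & cond, why, reason)
  flag(!is.finite(df$mat), "unparseable MAT")
  psum <- rowSums(df[, pcols])
  flag(!is.finite(psum) | apply(df[, pcols] < 0, 1, any),
       "missing or negative monthly precipitation")
  flag(is.na(reason) & abs(df$map - psum) > pmax(1, 0.005 * df$map),
       "MAP inconsistent with monthly sum")
  flag(!(df$hemisphere %in% c("N", "S")), "hemisphere not N or S")
  finish_read(df, reason, "environment")
}

read_checked <- function(path, req, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0 || length(readLines(path, n = 1)) == 0) {
    warning("empty ", what, " file: ", path)
    df <- as.data.frame(stats::setNames(rep(list(logical(0)), length(req)), req))
    return(df)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(req, names(df))
  if (length(missing) > 0)
    stop("missing mandatory column(s) in ", what, ": ",
         paste(missing, collapse = ", "))
  if (nrow(df) == 0) warning("no data rows in ", what, " file: ", path)
  df
}

finish_read <- function(df, reason, what) {
  bad <- !is.na(reason)
  rejected <- cbind(row = which(bad), df[bad, , drop = FALSE],
                    reason = reason[bad])
  if (nrow(rejected) > 0)
    message(nrow(rejected), " ", what, " row(s) rejected; see attr(x, ",
            "\"rejected\") for reasons")
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write profile-layer or environment tables
#'
#' Comma-separated, UTF-8, header row; the inverse of [read_profiles()] /
#' [read_environments()].
#'
#' @param x table to write.
#' @param path output file.
#' @export
write_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Impute missing bulk density or gravel with boosted regression trees
#'
#' Trains a gradient-boosted regression-tree ensemble on the complete cases
#' of the target column, using depth geometry, SOC content and (when an
#' environment table is supplied) site covariates, then predicts the
#' missing entries.  Observed values are never altered.  Imputed gravel is
#' clamped to [0, 100]; imputed bulk density to `bd_range`.  An
#' out-of-sample RMSE from a held-out fifth of the complete cases is
#' attached as the `"rmse"` attribute.
#'
#' @param profiles profile-layer table (see [read_profiles()]).
#' @param target `"bd"` or `"gravel"`.
#' @param environments optional site-environment table; when given, `mat`,
#'   `map`, `elevation` and `npp` join the covariates by `profile_id`.
#' @param seed RNG seed; imputation is deterministic given the seed.
#' @param nrounds boosting rounds (default 200).
#' @param bd_range plausible range for imputed bulk density, kg m^-3.
#' @return `profiles` with the target's missing values filled.
#' @export
impute_missing <- function(profiles, target = c("bd", "gravel"),
                           environments = NULL, seed = 1, nrounds = 200,
                           bd_range = c(50, 2700)) {
  target <- match.arg(target)
  y <- profiles[[target]]
  if (!any(is.na(y))) return(profiles)
  covars <- data.frame(top = profiles$top, bottom = profiles$bottom,
                       mid = (profiles$top + profiles$bottom) / 2,
                       thickness = profiles$bottom - profiles$top,
                       soc_c = profiles$soc_c)
  other <- setdiff(c("bd", "gravel"), target)
  if (other %in% names(profiles)) covars[[other]] <- profiles[[other]]
  if (!is.null(environments)) {
    env <- environments[, c("profile_id", "mat", "map", "elevation", "npp")]
    covars <- cbind(covars,
                    env[match(profiles$profile_id, env$profile_id), -1])
  }
  X <- as.matrix(data.matrix(covars))
  complete <- which(!is.na(y))
  if (length(complete) == 0)
    stop("`", target, "` entirely missing: unlearnable")
  if (length(complete) < 30)
    stop("too few complete cases (", length(complete),
         ") to impute `", target, "`; need >= 30")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  hold <- sample(complete, max(1, floor(length(complete) / 5)))
  train <- setdiff(complete, hold)
  params <- list(objective = "reg:squarederror", max_depth = 4, eta = 0.1,
                 nthread = 1, seed = seed)
  boost <- function(idx) {
    xgboost::xgb.train(
      params = params, nrounds = nrounds,
      data = xgboost::xgb.DMatrix(X[idx, , drop = FALSE], label = y[idx]))
  }
  fit_ho <- boost(train)
  rmse <- sqrt(mean((stats::predict(
    fit_ho, xgboost::xgb.DMatrix(X[hold, , drop = FALSE])) - y[hold])^2))
  fit <- boost(complete)
  miss <- which(is.na(y))
  pred <- stats::predict(fit, xgboost::xgb.DMatrix(X[miss, , drop = FALSE]))
  pred <- if (target == "gravel") pmin(pmax(pred, 0), 100)
          else pmin(pmax(pred, bd_range[1]), bd_range[2])
  profiles[[target]][miss] <- pred
  attr(profiles, "rmse") <- stats::setNames(rmse, target)
  message(sprintf("imputed %d missing `%s` value(s); held-out RMSE %.3g",
                  length(miss), target, rmse))
  profiles
}
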