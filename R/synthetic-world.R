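#' Configuration for the synthetic soil-profile world
#'
#' Defines the conditions under which a miniature "world" of georeferenced
#' soil profiles is generated.  Per-layer steady-state SOC stock follows a
#' known temperature law `S_l(T) = I_l / (k0_l * Q10_l^(T/10))` with
#' multiplicative lognormal noise, so the true percentage response to any
#' warming level is available in closed form as ground truth.
#'
#' @param n_profiles number of profiles.
#' @param seed RNG seed; generation is deterministic given the seed.
#' @param mat_range MAT interval (degC), sampled uniformly by default so
#'   every 1 degC class is populated.
#' @param mat_mode `"uniform"` or `"bimodal"` (two-cluster mixture mimicking
#'   latitudinal clustering of real archives).
#' @param map_range MAP interval (mm), sampled uniformly.
#' @param q10_true_by_layer true Q10 per standard layer (all >= 1).
#' @param input_per_degree fractional change of carbon inputs per degC of
#'   MAT (compound); 0 means inputs independent of temperature.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   noise on layer stocks.
#' @param missing_bd_rate,missing_gravel_rate fractions of layer records
#'   whose bulk density / gravel are masked missing.
#' @param landform_levels,soil_order_levels,biome_levels category
#'   vocabularies sampled uniformly.
#' @param precip_archetype_weights probabilities of the three monthly
#'   precipitation archetypes (summer-peaked, winter-peaked, uniform); must
#'   sum to 1.
#' @param cropland_rate fraction of profiles flagged cropland.
#' @param cropland_depletion multiplicative SOC depletion applied to
#'   cropland profiles (default 0.8).
#' @param input_by_layer,k0_by_layer carbon input (kg C m^-2 yr^-1) and
#'   base decay rate (yr^-1) at 0 degC for the three standard layers; both
#'   decline with depth by default, producing depth-decaying SOC.
#' @return validated list of class `"world_config"`.
#' @export
world_config <- function(n_profiles = 2000, seed = 1,
                         mat_range = c(0, 10), mat_mode = "uniform",
                         map_range = c(400, 600),
                         q10_true_by_layer = c(1.7, 1.4, 1.2),
                         input_per_degree = 0, noise_cv = 0.3,
                         missing_bd_rate = 0.1, missing_gravel_rate = 0.1,
                         landform_levels = c("plains", "plateaus", "mountains"),
                         soil_order_levels = c("mollisols", "alfisols",
                                               "inceptisols", "entisols"),
                         biome_levels = c("boreal_forest", "temperate_forest",
                                          "grassland"),
                         precip_archetype_weights = c(0.4, 0.3, 0.3),
                         cropland_rate = 0.1, cropland_depletion = 0.8,
                         input_by_layer = c(0.20, 0.10, 0.04),
                         k0_by_layer = c(0.020, 0.010, 0.005)) {
  cfg <- as.list(environment())
  rates <- c(missing_bd_rate, missing_gravel_rate, cropland_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  if (any(q10_true_by_layer < 1)) stop("`q10_true_by_layer` must be >= 1")
  if (length(q10_true_by_layer) != 3) stop("need three per-layer Q10 values")
  if (diff(mat_range) <= 0 || diff(map_range) <= 0)
    stop("degenerate `mat_range` or `map_range`")
  if (abs(sum(precip_archetype_weights) - 1) > 1e-8)
    stop("`precip_archetype_weights` must sum to 1")
  if (length(precip_archetype_weights) != 3 ||
      any(precip_archetype_weights < 0))
    stop("need three non-negative archetype weights")
  if (noise_cv < 0) stop("`noise_cv` must be >= 0")
  cfg$mat_mode <- match.arg(mat_mode, c("uniform", "bimodal"))
  structure(cfg, class = "world_config")
}

# monthly precipitation shapes (fractions of MAP, January first, N-season)
precip_archetypes <- function() {
  summer <- c(2, 2, 4, 8, 12, 16, 18, 16, 10, 6, 4, 2) / 100
  list(summer = summer,
       winter = summer[c(7:12, 1:6)],
       uniform = rep(1 / 12, 12))
}

#' Generate a synthetic world of soil profiles with known ground truth
#'
#' Draws site climate, categorical covariates and layered soil profiles
#' according to a [world_config()].  Per standard layer the expected SOC
#' stock is `I_l / (k0_l * Q10_l^(MAT/10))` (steady state of the one-pool
#' model), multiplied by lognormal noise with the configured CV; SOC
#' content is back-derived from the stock, a drawn bulk density and gravel
#' fraction, then distributed over randomly placed soil horizons.  BD and
#' gravel are masked missing at the configured rates and cropland profiles
#' receive a fixed multiplicative depletion.
#'
#' @param config a [world_config()].
#' @return Object of class `"soc_world"`: list with `profiles` (one row per
#'   horizon, including profile metadata), `environments` (one row per
#'   profile), `truth` (closed-form percentage response per layer and
#'   warming level 1-5) and `config`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  n <- config$n_profiles
  std <- standard_layers()
  arch <- precip_archetypes()

  mat <- if (config$mat_mode == "uniform") {
    stats::runif(n, config$mat_range[1], config$mat_range[2])
  } else {
    lo <- config$mat_range[1]; hi <- config$mat_range[2]
    centers <- lo + c(0.25, 0.75) * (hi - lo)
    pick <- sample(1:2, n, replace = TRUE)
    pmin(pmax(stats::rnorm(n, centers[pick], (hi - lo) / 8), lo), hi)
  }
  map <- stats::runif(n, config$map_range[1], config$map_range[2])
  arch_id <- sample(c("summer", "winter", "uniform"), n, replace = TRUE,
                    prob = config$precip_archetype_weights)
  landform <- sample(config$landform_levels, n, replace = TRUE)
  soil_order <- sample(config$soil_order_levels, n, replace = TRUE)
  biome <- sample(config$biome_levels, n, replace = TRUE)
  elevation <- stats::runif(n, 0, 2000)
  npp <- pmax(50, 300 + 25 * mat + stats::rnorm(n, 0, 50))
  aridity <- map / (1000 + 50 * mat)
  latitude <- stats::runif(n, 25, 65)
  longitude <- stats::runif(n, -180, 180)
  is_cropland <- stats::runif(n) < config$cropland_rate

  pcols <- sprintf("p%02d", 1:12)
  pm <- t(vapply(seq_len(n), function(i) map[i] * arch[[arch_id[i]]],
                 numeric(12)))
  colnames(pm) <- pcols

  environments <- data.frame(profile_id = sprintf("P%05d", seq_len(n)),
                             mat = mat, pm, map = map,
                             landform = landform, soil_order = soil_order,
                             biome = biome, elevation = elevation, npp = npp,
                             aridity_index = aridity, hemisphere = "N")

  sigma <- sqrt(log(1 + config$noise_cv^2))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    # expected standard-layer stocks under the temperature law
    inp <- config$input_by_layer * (1 + config$input_per_degree)^mat[i]
    stock <- inp / (config$k0_by_layer *
                      config$q10_true_by_layer^(mat[i] / 10))
    if (config$noise_cv > 0)
      stock <- stock * stats::rlnorm(3, meanlog = -sigma^2 / 2, sdlog = sigma)
    if (is_cropland[i]) stock <- stock * config$cropland_depletion

    # back-derive per-standard-layer content from stock, BD and gravel
    bd_l <- pmin(pmax(stats::rnorm(3, 1200 + 100 * std$top / 2, 100),
                      800), 1800)
    gr_l <- 100 * stats::rbeta(3, 2, 15)
    soc_c_l <- 1000 * stock / (std$thickness * bd_l * (1 - gr_l / 100))

    # random horizon boundaries spanning 0-2 m
    br <- sort(c(0, stats::runif(1, 0.1, 0.5), stats::runif(1, 0.6, 1.2),
                 stats::runif(1, 1.3, 1.8), 2))
    tops <- br[-length(br)]; bots <- br[-1]
    hz <- vapply(seq_along(tops), function(j) {
      ov <- pmax(0, pmin(bots[j], std$bottom) - pmax(tops[j], std$top))
      c(sum(soc_c_l * ov) / sum(ov),
        sum(bd_l * ov) / sum(ov),
        sum(gr_l * ov) / sum(ov))
    }, numeric(3))
    rows[[i]] <- data.frame(profile_id = environments$profile_id[i],
                            latitude = latitude[i], longitude = longitude[i],
                            is_cropland = is_cropland[i],
                            top = tops, bottom = bots,
                            soc_c = hz[1, ], bd = hz[2, ], gravel = hz[3, ])
  }
  profiles <- do.call(rbind, rows)
  rownames(profiles) <- NULL
  m <- nrow(profiles)
  profiles$bd[stats::runif(m) < config$missing_bd_rate] <- NA_real_
  profiles$gravel[stats::runif(m) < config$missing_gravel_rate] <- NA_real_

  truth <- expand.grid(layer = std$layer, delta_t = 1:5,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  truth$percent <- steady_state_response(
    rep(config$q10_true_by_layer, 5), truth$delta_t,
    input_ratio(config$input_per_degree, truth$delta_t))

  structure(list(profiles = profiles, environments = environments,
                 truth = truth, config = config),
            class = "soc_world")
}

#' Closed-form true SOC response of a synthetic world
#'
#' `100 * (input_ratio * Q10_true^(-delta_t/10) - 1)` for the requested
#' standard layer, with `input_ratio` defaulting to the world's configured
#' compound carbon-input scenario.
#'
#' @param world a [generate_world()] result.
#' @param layer one of `"0-0.3"`, `"0.3-1"`, `"1-2"`.
#' @param delta_t warming level, degC (>= 0).
#' @param input_ratio carbon-input ratio I_w/I; `NULL` uses the world's
#'   `input_per_degree` compounded over `delta_t`.
#' @return True percentage SOC change (negative = loss).
#' @export
true_response <- function(world, layer, delta_t, input_ratio = NULL) {
  stopifnot(inherits(world, "soc_world"), delta_t >= 0)
  std <- standard_layers()
  i <- match(layer, std$layer)
  if (is.na(i)) stop("unknown layer: ", layer)
  q10 <- world$config$q10_true_by_layer[i]
  if (is.null(input_ratio))
    input_ratio <- (1 + world$config$input_per_degree)^delta_t
  steady_state_response(q10, delta_t, input_ratio)
}

#' @export
print.soc_world <- function(x, ...) {
  cat(sprintf("Synthetic soil-profile world: %d profiles (%d horizons)\n",
              nrow(x$environments), nrow(x$profiles)))
  cat(sprintf("  MAT %.1f to %.1f degC, MAP %.0f to %.0f mm, noise CV %.2f\n",
              min(x$environments$mat), max(x$environments$mat),
              min(x$environments$map), max(x$environments$map),
              x$config$noise_cv))
  cat(sprintf("  true Q10 by layer: %s\n",
              paste(x$config$q10_true_by_layer, collapse = ", ")))
  invisible(x)
}

#' Write a synthetic world to delimited text files
#'
#' Writes `profiles.csv`, `environments.csv` (UTF-8, comma-separated,
#' header row) and `config.txt` (`key: value` lines) into `dir`.
#'
#' @param world a [generate_world()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "soc_world"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pp <- file.path(dir, "profiles.csv")
  pe <- file.path(dir, "environments.csv")
  pc <- file.path(dir, "config.txt")
  utils::write.csv(world$profiles, pp, row.names = FALSE)
  utils::write.csv(world$environments, pe, row.names = FALSE)
  cfg <- world$config
  scal <- vapply(cfg, function(x) is.atomic(x) || is.character(x), logical(1))
  lines <- vapply(names(cfg)[scal], function(k)
    paste0(k, ": ", paste(cfg[[k]], collapse = ",")), character(1))
  writeLines(lines, pc)
  invisible(c(profiles = pp, environments = pe, config = pc))
}
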