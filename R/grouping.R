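#' Precipitation concentration index (PCI)
#'
#' `PCI = 100 * sum(p_i^2) / (sum(p_i))^2` over the 12 monthly totals of a
#' year.  Uniform rain gives the analytic minimum 100/12 (about 8.33); all
#' rain in a single month gives 100.  A matrix input (years in rows) is
#' averaged: years with zero total are undefined and excluded from the mean.
#'
#' @param monthly numeric vector of 12 monthly precipitation totals (mm), or
#'   a matrix/data.frame with 12 columns (one row per year).
#' @return Mean PCI across defined years.
#' @examples
#' compute_pci(rep(50, 12))        # 8.333
#' compute_pci(c(600, rep(0, 11))) # 100
#' @export
compute_pci <- function(monthly) {
  m <- if (is.matrix(monthly) || is.data.frame(monthly)) as.matrix(monthly)
       else matrix(monthly, nrow = 1)
  if (ncol(m) != 12) stop("`monthly` must have 12 monthly values")
  if (any(m < 0, na.rm = TRUE)) stop("negative precipitation")
  tot <- rowSums(m)
  ok <- is.finite(tot) & tot > 0
  if (!any(ok)) stop("PCI undefined: all years have zero total precipitation")
  if (any(!ok)) warning(sum(!ok), " year(s) with zero precipitation excluded")
  pci <- 100 * rowSums(m[ok, , drop = FALSE]^2) / tot[ok]^2
  mean(pci)
}

#' Classify precipitation seasonality from PCI and half-year totals
#'
#' Sites with mean PCI below `uniform_threshold` are labelled "uniform".
#' Otherwise the site is "summer" if the warm-half-year total (April to
#' September in the northern hemisphere, October to March in the southern)
#' exceeds the cold-half-year total, and "winter" otherwise (ties count as
#' winter).  Note that PCI can never fall below 100/12 (about 8.333), so the
#' conventional threshold 8.3 never labels a site uniform; the threshold is
#' configurable for users who want an attainable uniform class.
#'
#' @param pci_mean mean PCI at the site (see [compute_pci()]).
#' @param monthly 12 monthly precipitation totals (mm), January first.
#' @param hemisphere `"N"` or `"S"`.
#' @param uniform_threshold PCI below which precipitation is considered
#'   spread throughout the year (default 8.3).
#' @return One of `"uniform"`, `"summer"`, `"winter"`.
#' @export
classify_seasonality <- function(pci_mean, monthly, hemisphere = "N",
                                 uniform_threshold = 8.3) {
  stopifnot(length(monthly) == 12)
  hemisphere <- match.arg(hemisphere, c("N", "S"))
  if (pci_mean < uniform_threshold) return("uniform")
  apr_sep <- sum(monthly[4:9])
  oct_mar <- sum(monthly[c(10:12, 1:3)])
  warm_half <- if (hemisphere == "N") apr_sep else oct_mar
  cold_half <- if (hemisphere == "N") oct_mar else apr_sep
  if (warm_half > cold_half) "summer" else "winter"
}

#' Assign profiles to 1 degC mean-annual-temperature classes
#'
#' A profile with MAT `t` belongs to the half-open class `[floor(t),
#' floor(t) + 1)`.
#'
#' @param environments site-environment table with columns `profile_id` and
#'   `mat`.
#' @return data.frame with `profile_id` and integer `mat_class` (the lower
#'   class boundary in degC).
#' @export
assign_mat_classes <- function(environments) {
  stopifnot(all(c("profile_id", "mat") %in% names(environments)))
  if (any(is.na(environments$mat))) stop("MAT missing for some profiles")
  data.frame(profile_id = environments$profile_id,
             mat_class = as.integer(floor(environments$mat)))
}

# covariate key shared by an ambient group and its warm counterpart
make_group_key <- function(environments, map_bin_width = 50,
                           uniform_threshold = 8.3, soil_field = "soil_order") {
  pcols <- sprintf("p%02d", 1:12)
  stopifnot(all(pcols %in% names(environments)))
  season <- vapply(seq_len(nrow(environments)), function(i) {
    m <- as.numeric(environments[i, pcols])
    classify_seasonality(compute_pci(m), m, environments$hemisphere[i],
                         uniform_threshold)
  }, character(1))
  paste(environments$landform, environments[[soil_field]], season,
        floor(environments$map / map_bin_width), sep = "|")
}

#' Build ambient-vs-warm paired comparisons (space-for-time substitution)
#'
#' Profiles are binned into 1 degC MAT classes and, within each class, into
#' groups sharing landform, soil order, precipitation seasonality and a
#' `map_bin_width`-mm MAP bin.  For a warming level dT, every ambient class
#' `[i, i+1)` is paired with the warm class `[i+dT, i+dT+1)`: each shared
#' group key yields one comparison, provided both groups have at least
#' `min_n` profiles (so a standard deviation exists) and their mean MAPs
#' differ by less than `map_tolerance_mm`.
#'
#' @param profiles profile-layer table (needs `profile_id`, `is_cropland`).
#' @param environments site-environment table (one row per profile).
#' @param harmonized output of [harmonize_profiles()].
#' @param layer standard layer, one of `"0-0.3"`, `"0.3-1"`, `"1-2"`.
#' @param warming_level warming of interest in degC (1 to 5 in the standard
#'   analysis).
#' @param response `"soc_s"` (stock, default) or `"soc_c"` (content).
#' @param map_tolerance_mm maximum absolute difference of group-mean MAP
#'   between ambient and warm groups (default 50; 25 for the sensitivity
#'   variant).
#' @param min_n minimum profiles per group (default 2, the smallest n with a
#'   defined sd).
#' @param exclude_cropland drop cropland profiles before grouping
#'   (steady-state sensitivity analysis).
#' @param min_group_n optional stricter group-size floor (e.g. 20 for the
#'   "at least 20 profiles" sensitivity analysis); `NULL` to disable.
#' @param map_bin_width width of the MAP bins that enter the group key (mm).
#' @param uniform_threshold PCI threshold for [classify_seasonality()].
#' @param soil_field environment column holding the soil taxon (default
#'   `"soil_order"`; set to `"suborder"` or an FAO/WRB column for alternate
#'   vocabularies).
#' @return data.frame with one row per paired comparison: group key fields,
#'   ambient/warm summaries (`n_a`, `mean_a`, `sd_a`, `map_a`, `mat_a` and
#'   the `_w` counterparts) and moderator columns (`biome`, `landform`,
#'   `soil_order`, `seasonality`, `baseline_soc`, `mat`, `map`,
#'   `delta_t_actual`, `delta_map`, `elevation`, `npp`, `aridity_index`,
#'   `psummer`).  Zero rows when nothing can be paired.
#' @export
build_pairs <- function(profiles, environments, harmonized, layer,
                        warming_level, response = c("soc_s", "soc_c"),
                        map_tolerance_mm = 50, min_n = 2,
                        exclude_cropland = FALSE, min_group_n = NULL,
                        map_bin_width = 50, uniform_threshold = 8.3,
                        soil_field = "soil_order") {
  response <- match.arg(response)
  stopifnot(layer %in% standard_layers()$layer, warming_level >= 1)

  meta <- unique(profiles[, c("profile_id", "is_cropland")])
  env <- merge(environments, meta, by = "profile_id")
  if (exclude_cropland) env <- env[!env$is_cropland, , drop = FALSE]

  h <- harmonized[harmonized$layer == layer & harmonized$coverage &
                    !is.na(harmonized[[response]]), , drop = FALSE]
  env <- merge(env, h[, c("profile_id", response)], by = "profile_id")
  if (nrow(env) == 0) return(empty_pairs())

  env$mat_class <- floor(env$mat)
  env$key <- make_group_key(env, map_bin_width, uniform_threshold, soil_field)
  pcols <- sprintf("p%02d", 1:12)
  env$psummer <- rowSums(env[, pcols[4:9]]) / pmax(env$map, 1e-9)

  grp <- split(env, paste(env$mat_class, env$key, sep = "@"))
  summ <- do.call(rbind, lapply(grp, function(g) {
    data.frame(mat_class = g$mat_class[1], key = g$key[1], n = nrow(g),
               mean = mean(g[[response]]), sd = stats::sd(g[[response]]),
               map = mean(g$map), mat = mean(g$mat),
               biome = names(sort(table(g$biome), decreasing = TRUE))[1],
               landform = g$landform[1],
               soil_order = g[[soil_field]][1],
               seasonality = strsplit(g$key[1], "|", fixed = TRUE)[[1]][3],
               elevation = mean(g$elevation), npp = mean(g$npp),
               aridity_index = mean(g$aridity_index),
               psummer = mean(g$psummer))
  }))
  floor_n <- max(min_n, 2)
  if (!is.null(min_group_n)) floor_n <- max(floor_n, min_group_n)
  summ <- summ[summ$n >= floor_n, , drop = FALSE]
  if (nrow(summ) == 0) return(empty_pairs())

  amb <- summ; warm <- summ
  m <- merge(amb, warm, by = "key", suffixes = c("_a", "_w"))
  m <- m[m$mat_class_w - m$mat_class_a == warming_level &
           abs(m$map_w - m$map_a) < map_tolerance_mm, , drop = FALSE]
  if (nrow(m) == 0) return(empty_pairs())

  out <- data.frame(
    warming_level = warming_level, layer = layer, response = response,
    key = m$key, ambient_class = m$mat_class_a,
    n_a = m$n_a, mean_a = m$mean_a, sd_a = m$sd_a,
    map_a = m$map_a, mat_a = m$mat_a,
    n_w = m$n_w, mean_w = m$mean_w, sd_w = m$sd_w,
    map_w = m$map_w, mat_w = m$mat_w,
    biome = m$biome_a, landform = m$landform_a,
    soil_order = m$soil_order_a, seasonality = m$seasonality_a,
    baseline_soc = m$mean_a, mat = m$mat_a, map = m$map_a,
    delta_t_actual = m$mat_w - m$mat_a, delta_map = m$map_w - m$map_a,
    elevation = m$elevation_a, npp = m$npp_a,
    aridity_index = m$aridity_index_a, psummer = m$psummer_a)
  rownames(out) <- NULL
  out
}

empty_pairs <- function() {
  data.frame(warming_level = integer(), layer = character(),
             response = character(), key = character(),
             ambient_class = integer(),
             n_a = integer(), mean_a = numeric(), sd_a = numeric(),
             map_a = numeric(), mat_a = numeric(),
             n_w = integer(), mean_w = numeric(), sd_w = numeric(),
             map_w = numeric(), mat_w = numeric(),
             biome = character(), landform = character(),
             soil_order = character(), seasonality = character(),
             baseline_soc = numeric(), mat = numeric(), map = numeric(),
             delta_t_actual = numeric(), delta_map = numeric(),
             elevation = numeric(), npp = numeric(),
             aridity_index = numeric(), psummer = numeric())
}
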