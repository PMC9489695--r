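# small worlds shared across test files; kept tiny so the suite stays fast

tiny_world <- function(seed = 42, n = 150, ...) {
  generate_world(world_config(n_profiles = n, seed = seed, ...))
}

# a noiseless, fully observed world: group means reproduce the analytic
# truth exactly, so it serves as ground truth for pairing and pooling
clean_world <- function(seed = 42, n = 150, ...) {
  generate_world(world_config(
    n_profiles = n, seed = seed, noise_cv = 0,
    missing_bd_rate = 0, missing_gravel_rate = 0, cropland_rate = 0, ...))
}

# two MAT classes, one covariate group each: pairing can be enumerated by hand
toy_pair_world <- function(mat_a = c(2.2, 2.8, 2.5), mat_w = c(3.3, 3.6, 3.9),
                           map_w = 520) {
  n <- length(mat_a) + length(mat_w)
  ids <- sprintf("T%02d", seq_len(n))
  pm <- matrix(rep(c(2, 2, 4, 8, 12, 16, 18, 16, 10, 6, 4, 2) * 5, n),
               nrow = n, byrow = TRUE)
  colnames(pm) <- sprintf("p%02d", 1:12)
  env <- data.frame(profile_id = ids, mat = c(mat_a, mat_w), pm,
                    map = rowSums(pm) * 0 + c(rep(510, length(mat_a)),
                                              rep(map_w, length(mat_w))),
                    landform = "plains", soil_order = "mollisols",
                    biome = "grassland", elevation = 300, npp = 500,
                    aridity_index = 0.5, hemisphere = "N")
  # MAP drives the key/tolerance; monthly shape only sets seasonality
  env[sprintf("p%02d", 1:12)] <- env$map / 100 *
    matrix(rep(c(2, 2, 4, 8, 12, 16, 18, 16, 10, 6, 4, 2), each = n), nrow = n)
  prof <- data.frame(profile_id = rep(ids, each = 1), latitude = 45,
                     longitude = 0, is_cropland = FALSE,
                     top = 0, bottom = 2,
                     soc_c = 10 + seq_len(n), bd = 1300, gravel = 5)
  harm <- harmonize_profiles(prof)
  list(profiles = prof, environments = env, harmonized = harm)
}
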