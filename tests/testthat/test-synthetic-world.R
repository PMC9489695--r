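test_that("generation is reproducible given the seed", {
  a <- tiny_world(seed = 123, n = 60)
  b <- tiny_world(seed = 123, n = 60)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$environments, b$environments)
  c <- tiny_world(seed = 124, n = 60)
  expect_false(identical(a$profiles$soc_c, c$profiles$soc_c))
})

test_that("config invariants are enforced", {
  expect_error(world_config(missing_bd_rate = 1.2), "rates")
  expect_error(world_config(q10_true_by_layer = c(0.9, 1.4, 1.2)), ">= 1")
  expect_error(world_config(mat_range = c(5, 5)), "degenerate")
  expect_error(world_config(precip_archetype_weights = c(0.5, 0.5, 0.5)),
               "sum to 1")
  expect_error(world_config(noise_cv = -0.1), "noise_cv")
})

test_that("true_response evaluates the closed form", {
  w <- tiny_world(n = 10)
  expect_equal(true_response(w, "0-0.3", 0), 0)
  expect_equal(round(true_response(w, "0-0.3", 1), 2), -5.17)
  expect_equal(true_response(w, "0-0.3", 10), 100 * (1 / 1.7 - 1))
  # inputs exactly offsetting decay
  expect_equal(true_response(w, "0.3-1", 2, input_ratio = 1.4^0.2), 0,
               tolerance = 1e-12)
  expect_error(true_response(w, "5-7", 1), "unknown layer")
  # the stored truth table agrees with the closed form
  tr <- w$truth[w$truth$layer == "1-2" & w$truth$delta_t == 3, "percent"]
  expect_equal(tr, steady_state_response(1.2, 3))
})

test_that("noiseless harmonized stocks track the temperature law", {
  # horizons are drawn independently of the standard boundaries, so the
  # spline reconstruction of the step-like content is approximate per
  # profile; the law must still hold within that reconstruction error,
  # and exactly for profiles whose horizons happen to align closely
  w <- clean_world(n = 40, seed = 9)
  cfg <- w$config
  std <- standard_layers()
  h <- harmonize_profiles(w$profiles, lambda = 1e-8)
  env <- w$environments
  for (i in c(1, 3)) {
    hi <- h[h$layer == std$layer[i], ]
    hi <- hi[match(env$profile_id, hi$profile_id), ]
    expected <- cfg$input_by_layer[i] /
      (cfg$k0_by_layer[i] * cfg$q10_true_by_layer[i]^(env$mat / 10))
    rel <- hi$soc_s / expected - 1
    expect_lt(max(abs(rel)), 0.25)            # bounded leakage per profile
    # the smooth reconstruction of step-like content carries a small
    # systematic bias; it is shared by ambient and warm groups and cancels
    # in the response ratios (checked by the pooled-recovery test below)
    expect_lt(abs(mean(rel)), 0.10)
  }
})

test_that("noiseless downstream group means hit the analytic truth", {
  w <- clean_world(n = 500, seed = 21)
  h <- harmonize_profiles(w$profiles, lambda = 1e-8)
  pr <- build_pairs(w$profiles, w$environments, h, "0-0.3", 1)
  expect_gt(nrow(pr), 3)
  eff <- add_effect_sizes(pr)
  p <- pool(eff$lnrr, eff$v, method = "DL")
  expect_equal(p$percent_change, true_response(w, "0-0.3", 1),
               tolerance = 0.10 * abs(true_response(w, "0-0.3", 1)))
})

test_that("missingness converges to the configured rates", {
  w <- generate_world(world_config(n_profiles = 2000, seed = 4,
                                   missing_bd_rate = 0.15,
                                   missing_gravel_rate = 0.05))
  m <- nrow(w$profiles)
  # binomial tolerance: 4 standard errors around the configured rate
  for (cs in list(c("bd", 0.15), c("gravel", 0.05))) {
    rate <- as.numeric(cs[2])
    frac <- mean(is.na(w$profiles[[cs[1]]]))
    expect_lt(abs(frac - rate), 4 * sqrt(rate * (1 - rate) / m))
  }
})

test_that("precipitation archetypes have the expected PCI signatures", {
  w <- tiny_world(n = 200, seed = 6)
  pcols <- sprintf("p%02d", 1:12)
  pci <- apply(as.matrix(w$environments[pcols]), 1, compute_pci)
  # uniform archetype sits at the analytic minimum, peaked ones well above
  expect_true(any(abs(pci - 100 / 12) < 1e-9))
  expect_true(all(pci[abs(pci - 100 / 12) > 1e-9] > 9))
  # monthly totals always sum to MAP
  expect_equal(rowSums(w$environments[pcols]), w$environments$map,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("cropland depletion leaves a detectable signal", {
  w <- generate_world(world_config(n_profiles = 600, seed = 13,
                                   noise_cv = 0, cropland_rate = 0.3,
                                   missing_bd_rate = 0,
                                   missing_gravel_rate = 0))
  h <- harmonize_profiles(w$profiles, lambda = 1e-8)
  top <- h[h$layer == "0-0.3", ]
  meta <- unique(w$profiles[, c("profile_id", "is_cropland")])
  top <- merge(top, meta, by = "profile_id")
  env <- w$environments[match(top$profile_id, w$environments$profile_id), ]
  # compare at matched MAT by removing the temperature trend
  detrended <- top$soc_s * w$config$q10_true_by_layer[1]^(env$mat / 10)
  ratio <- mean(detrended[top$is_cropland]) / mean(detrended[!top$is_cropland])
  expect_equal(ratio, w$config$cropland_depletion, tolerance = 0.05)
})

test_that("worlds round-trip through the delimited text format", {
  w <- tiny_world(n = 25, seed = 2)
  d <- withr::local_tempdir()
  paths <- write_world(w, d)
  expect_true(all(file.exists(paths)))
  prof <- read_profiles(paths["profiles"])
  env <- read_environments(paths["environments"])
  expect_equal(nrow(prof), nrow(w$profiles))
  expect_equal(prof$soc_c, w$profiles$soc_c, tolerance = 1e-12)
  expect_equal(env$mat, w$environments$mat, tolerance = 1e-12)
  cfg <- readLines(paths["config"])
  expect_true(any(grepl("^seed: 2$", cfg)))
  expect_true(any(grepl("^q10_true_by_layer: 1.7,1.4,1.2$", cfg)))
})
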