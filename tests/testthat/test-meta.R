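# brute-force random-effects pooling: the oracle recomputes every quantity
# from the printed formulas without reusing package internals
brute_pool <- function(lnrr, v, tau2) {
  w <- 1 / (v + tau2)
  mu <- sum(lnrr * w) / sum(w)
  list(mu = mu, se = sqrt(1 / sum(w)))
}
brute_dl <- function(lnrr, v) {
  w <- 1 / v
  mu <- sum(w * lnrr) / sum(w)
  Q <- sum(w * (lnrr - mu)^2)
  max(0, (Q - (length(lnrr) - 1)) / (sum(w) - sum(w^2) / sum(w)))
}

test_that("effect sizes follow the lnRR delta-method formulas", {
  es <- effect_size(100, 10, 5, 100, 12, 6)
  expect_equal(es$lnrr, 0)
  es2 <- effect_size(100, 10, 5, 50, 8, 4)
  expect_equal(es2$lnrr, log(0.5))
  expect_equal(round(es2$lnrr, 4), -0.6931)
  expect_equal(es2$v, 8^2 / (4 * 50^2) + 10^2 / (5 * 100^2))
  expect_warning(bad <- effect_size(-1, 1, 3, 5, 1, 3), "non-positive")
  expect_true(is.na(bad$lnrr))
})

test_that("degenerate zero-variance effects are dropped with a message", {
  pairs <- data.frame(mean_a = c(10, 10), sd_a = c(0, 1), n_a = 3,
                      mean_w = c(12, 12), sd_w = c(0, 1), n_w = 3)
  expect_message(eff <- add_effect_sizes(pairs), "degenerate")
  expect_equal(nrow(eff), 1)
  expect_equal(nrow(attr(eff, "dropped")), 1)
})

test_that("DerSimonian-Laird tau2 matches the hand-computed oracle", {
  lnrr <- c(-0.10, -0.02, 0.07)
  v <- c(0.004, 0.009, 0.006)
  expect_equal(estimate_tau2(lnrr, v, "DL"), brute_dl(lnrr, v),
               tolerance = 1e-12)
  # scaling all v by c rescales the oracle identically
  for (cc in c(0.5, 2, 10))
    expect_equal(estimate_tau2(lnrr, cc * v, "DL"), brute_dl(lnrr, cc * v),
                 tolerance = 1e-12)
  # identical effects carry no between-comparison variance
  expect_equal(estimate_tau2(rep(-0.05, 4), rep(0.01, 4), "DL"), 0)
  expect_equal(estimate_tau2(rep(-0.05, 4), rep(0.01, 4), "REML"), 0,
               tolerance = 1e-8)
  expect_warning(one <- estimate_tau2(-0.1, 0.01), "fewer than 2")
  expect_equal(one, 0)
})

test_that("REML and DL agree with metafor on a non-trivial set", {
  set.seed(7)
  lnrr <- rnorm(12, -0.05, 0.08)
  v <- runif(12, 0.002, 0.02)
  expect_equal(estimate_tau2(lnrr, v, "REML"),
               as.numeric(metafor::rma.uni(yi = lnrr, vi = v,
                                           method = "REML")$tau2),
               tolerance = 1e-10)
  expect_equal(estimate_tau2(lnrr, v, "DL"),
               as.numeric(metafor::rma.uni(yi = lnrr, vi = v,
                                           method = "DL")$tau2),
               tolerance = 1e-8)
})

test_that("pooling equals the brute-force weighted mean", {
  expect_equal(pool(-0.08, 0.01)$mean_lnrr, -0.08)   # single effect
  # equal variances and tau2 = 0 reduce to the arithmetic mean
  lnrr <- c(-0.10, -0.06, -0.02)
  p <- pool(lnrr, rep(0.01, 3), tau2 = 0)
  expect_equal(p$mean_lnrr, mean(lnrr))
  # five distinct variances against the oracle
  set.seed(11)
  y <- rnorm(5, -0.05, 0.05); vv <- runif(5, 0.001, 0.02)
  for (t2 in c(0, 0.003)) {
    got <- pool(y, vv, tau2 = t2)
    want <- brute_pool(y, vv, t2)
    expect_equal(got$mean_lnrr, want$mu, tolerance = 1e-12)
    expect_equal(got$se, want$se, tolerance = 1e-12)
    expect_equal(got$ci95, want$mu + c(-1.96, 1.96) * want$se,
                 tolerance = 1e-12)
    expect_equal(got$percent_change, (exp(want$mu) - 1) * 100,
                 tolerance = 1e-12)
  }
  # and against metafor with the same fixed tau2
  rma <- metafor::rma.uni(yi = y, vi = vv, tau2 = 0.003)
  got <- pool(y, vv, tau2 = 0.003)
  expect_equal(got$mean_lnrr, as.numeric(rma$beta), tolerance = 1e-10)
  expect_equal(got$se, as.numeric(rma$se), tolerance = 1e-10)
})

test_that("pooled mean lies within the range of its inputs", {
  set.seed(3)
  for (i in 1:20) {
    y <- rnorm(8, 0, 0.1); vv <- runif(8, 0.001, 0.05)
    p <- pool(y, vv)
    expect_gte(p$mean_lnrr, min(y)); expect_lte(p$mean_lnrr, max(y))
  }
})

test_that("back-transform preserves the ordering of pooled responses", {
  mus <- sort(rnorm(6, 0, 0.2))
  pct <- (exp(mus) - 1) * 100
  expect_true(all(diff(pct) > 0))
  expect_true(all(pct > -100))
})

test_that("moderator analysis separates well-separated levels", {
  set.seed(5)
  eff <- data.frame(lnrr = c(rnorm(10, -0.30, 0.01), rnorm(10, 0.00, 0.01)),
                    v = rep(0.0001, 20),
                    grp = rep(c("a", "b"), each = 10))
  m <- moderator_analysis(eff, "grp")
  expect_gt(m$qm, 100)
  expect_lt(m$p, 0.01)
  expect_equal(m$df, 1)
  expect_equal(m$by_level$level, c("a", "b"))
  # all-equal level means give a near-zero statistic
  eff2 <- data.frame(lnrr = rep(c(-0.1, -0.1), 10), v = 0.001,
                     grp = rep(c("a", "b"), 10))
  m2 <- moderator_analysis(eff2, "grp")
  expect_lt(m2$qm, 1e-8)
  # a single level reduces to pool()
  eff3 <- data.frame(lnrr = c(-0.1, -0.05, -0.2), v = c(0.01, 0.02, 0.01),
                     grp = "only")
  m3 <- moderator_analysis(eff3, "grp")
  expect_true(is.na(m3$qm))
  p3 <- pool(eff3$lnrr, eff3$v)
  expect_equal(m3$by_level$percent_change, p3$percent_change,
               tolerance = 1e-8)
})

test_that("warming-level regression recovers exact linear responses", {
  pct <- -(6 + 4.2 * (0:4))
  r <- response_vs_warming(1:5, pct)
  expect_equal(r$slope, -4.2, tolerance = 1e-10)
  expect_equal(r$r_squared, 1, tolerance = 1e-10)
  flat <- response_vs_warming(1:5, rep(-3, 5))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_error(response_vs_warming(1, -5), "at least 2")
})

test_that("field-warming observations bin half-open and pool per bin", {
  set.seed(9)
  n <- 30
  obs <- data.frame(delta_t = c(2.0, 0.1, 5.0, runif(n - 3, 0.2, 6)),
                    mean_a = 100, sd_a = 10, n_a = 5,
                    mean_w = 95, sd_w = 10, n_w = 5,
                    ecosystem = rep(c("forest", "grassland"), length.out = n))
  obs$mean_w <- obs$mean_w + rnorm(n, 0, 2)
  res <- bin_field_warming(obs)
  expect_equal(res$effects$warming_bin[1], "2-3")   # 2.0 -> [2,3)
  expect_equal(res$effects$warming_bin[2], "<1")    # 0.1 -> [0,1)
  expect_equal(res$effects$warming_bin[3], ">5")    # 5.0 -> [5,Inf)
  expect_true(all(res$by_bin$by_level$k >= 1))      # empty bins omitted
  expect_equal(res$by_bin$df, nrow(res$by_bin$by_level) - 1)
  expect_equal(sort(unique(res$by_ecosystem$by_level$level)),
               c("forest", "grassland"))
})
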