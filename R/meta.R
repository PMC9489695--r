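#' Log response ratio and its sampling variance for one comparison
#'
#' `lnRR = ln(mean_w / mean_a)` with the delta-method (Hedges/Gurevitch/
#' Curtis) sampling variance
#' `v = sd_w^2/(n_w * mean_w^2) + sd_a^2/(n_a * mean_a^2)`.
#' Vectorised over comparisons.
#'
#' @param mean_a,sd_a,n_a ambient-group mean, sd and size.
#' @param mean_w,sd_w,n_w warm-group mean, sd and size.
#' @return data.frame with columns `lnrr` and `v`.  Comparisons with a
#'   non-positive mean give `NA` (with a warning); `v = 0` (both sds zero)
#'   is returned as is and should be treated as degenerate by the caller.
#' @export
effect_size <- function(mean_a, sd_a, n_a, mean_w, sd_w, n_w) {
  bad <- !is.na(mean_a) & !is.na(mean_w) & (mean_a <= 0 | mean_w <= 0)
  if (any(bad))
    warning(sum(bad), " comparison(s) with non-positive mean skipped")
  lnrr <- ifelse(bad, NA_real_, log(mean_w / mean_a))
  v <- ifelse(bad, NA_real_,
              sd_w^2 / (n_w * mean_w^2) + sd_a^2 / (n_a * mean_a^2))
  data.frame(lnrr = lnrr, v = v)
}

#' Attach effect sizes to a table of paired comparisons
#'
#' Computes [effect_size()] for every row of a [build_pairs()] table and
#' drops degenerate rows (non-positive means, `NA` or zero sampling
#' variance), recording them in the `"dropped"` attribute.
#'
#' @param pairs output of [build_pairs()] (or any table with the six
#'   summary columns).
#' @return `pairs` with `lnrr` and `v` columns appended; degenerate rows
#'   removed.
#' @export
add_effect_sizes <- function(pairs) {
  es <- effect_size(pairs$mean_a, pairs$sd_a, pairs$n_a,
                    pairs$mean_w, pairs$sd_w, pairs$n_w)
  out <- cbind(pairs, es)
  keep <- !is.na(out$lnrr) & !is.na(out$v) & out$v > 0
  dropped <- out[!keep, , drop = FALSE]
  if (nrow(dropped) > 0)
    message(nrow(dropped), " degenerate effect(s) dropped (zero variance ",
            "or non-positive mean)")
  out <- out[keep, , drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

#' Between-comparison variance of log response ratios
#'
#' Random-effects heterogeneity variance tau^2.  `"REML"` (default) uses
#' restricted maximum likelihood via [metafor::rma.uni()];
#' `"DL"` is the DerSimonian-Laird moment estimator computed in closed
#' form: `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))` with
#' fixed-effect weights `w = 1/v`.
#'
#' @param lnrr effect sizes.
#' @param v within-comparison sampling variances (> 0).
#' @param method `"REML"` or `"DL"`.
#' @return Non-negative tau^2.  Fewer than 2 effects returns 0 with a
#'   warning.
#' @export
estimate_tau2 <- function(lnrr, v, method = c("REML", "DL")) {
  method <- match.arg(method)
  stopifnot(length(lnrr) == length(v), all(v > 0))
  k <- length(lnrr)
  if (k < 2) {
    warning("fewer than 2 effects: tau^2 set to 0")
    return(0)
  }
  if (method == "DL") {
    w <- 1 / v
    mu_fe <- sum(w * lnrr) / sum(w)
    Q <- sum(w * (lnrr - mu_fe)^2)
    return(max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))))
  }
  fit <- tryCatch(
    metafor::rma.uni(yi = lnrr, vi = v, method = "REML"),
    error = function(e) NULL)
  if (is.null(fit))    # rare Fisher-scoring failures: damp the steps
    fit <- tryCatch(
      metafor::rma.uni(yi = lnrr, vi = v, method = "REML",
                       control = list(maxiter = 1000, stepadj = 0.5)),
      error = function(e) NULL)
  if (is.null(fit)) {
    warning("REML did not converge; falling back to DerSimonian-Laird")
    return(estimate_tau2(lnrr, v, "DL"))
  }
  as.numeric(fit$tau2)
}

#' Pool log response ratios with inverse-variance weights
#'
#' Random-effects pooled mean `sum(lnrr * w) / sum(w)` with weights
#' `w = 1/(v + tau2)`, standard error `sqrt(1/sum(w))`, normal 95%
#' confidence interval, and the back-transform to percentage change
#' `(exp(x) - 1) * 100`.
#'
#' @param lnrr effect sizes.
#' @param v sampling variances (> 0).
#' @param tau2 between-comparison variance; `NULL` (default) estimates it
#'   with [estimate_tau2()].
#' @param method tau^2 estimator when `tau2` is `NULL`.
#' @param n_profiles optional total number of profiles behind the effects
#'   (reported only).
#' @return Object of class `"soc_pooled"`: list with `mean_lnrr`, `se`,
#'   `tau2`, `ci95` (on the lnRR scale), `percent_change`, `percent_ci95`,
#'   `k`, `n_profiles`.
#' @export
pool <- function(lnrr, v, tau2 = NULL, method = c("REML", "DL"),
                 n_profiles = NA_integer_) {
  method <- match.arg(method)
  stopifnot(length(lnrr) >= 1, all(v > 0))
  if (is.null(tau2))
    tau2 <- if (length(lnrr) >= 2) estimate_tau2(lnrr, v, method) else 0
  w <- 1 / (v + tau2)
  mu <- sum(lnrr * w) / sum(w)
  se <- sqrt(1 / sum(w))
  ci <- mu + c(-1, 1) * 1.96 * se
  structure(
    list(mean_lnrr = mu, se = se, tau2 = tau2, ci95 = ci,
         percent_change = (exp(mu) - 1) * 100,
         percent_ci95 = (exp(ci) - 1) * 100,
         k = length(lnrr), n_profiles = n_profiles, method = method),
    class = "soc_pooled")
}

#' @export
print.soc_pooled <- function(x, ...) {
  cat(sprintf(
    "Pooled SOC response: %+.2f%% (95%% CI %+.2f to %+.2f), k = %d\n",
    x$percent_change, x$percent_ci95[1], x$percent_ci95[2], x$k))
  cat(sprintf("  lnRR = %+.4f (se %.4f), tau^2 = %.5f (%s)\n",
              x$mean_lnrr, x$se, x$tau2, x$method))
  invisible(x)
}

#' Moderator analysis: pooled responses per level of a categorical moderator
#'
#' Estimates a shared tau^2 under the mixed-effects model with the
#' moderator as the only (categorical) fixed effect, pools each level with
#' weights `1/(v + tau2)`, and tests between-level heterogeneity with
#' `QM = sum_l W_l (mu_l - mu_bar)^2` on `levels - 1` degrees of freedom
#' (chi-squared), where `W_l` is the total weight of level l.
#'
#' @param effects table with `lnrr`, `v` and the moderator column.
#' @param moderator name of the moderator column.
#' @param method tau^2 estimator (shared across levels).
#' @return list with `by_level` (data.frame: level, k, percent change and
#'   CI), `tau2`, `qm`, `df`, `p`.  With a single level `qm` is `NA`.
#' @export
moderator_analysis <- function(effects, moderator, method = c("REML", "DL")) {
  method <- match.arg(method)
  stopifnot(all(c("lnrr", "v", moderator) %in% names(effects)))
  lev <- factor(effects[[moderator]])
  if (nlevels(lev) < 1) stop("moderator has no levels")
  tau2 <- if (nlevels(lev) >= 2 && nrow(effects) > nlevels(lev)) {
    if (method == "REML") {
      fit <- tryCatch(
        metafor::rma.uni(yi = effects$lnrr, vi = effects$v,
                         mods = ~ 0 + lev, method = "REML"),
        error = function(e) NULL)
      if (is.null(fit)) residual_dl_tau2(effects$lnrr, effects$v, lev)
      else as.numeric(fit$tau2)
    } else
      residual_dl_tau2(effects$lnrr, effects$v, lev)
  } else estimate_tau2(effects$lnrr, effects$v, method)
  w <- 1 / (effects$v + tau2)
  by_level <- do.call(rbind, lapply(levels(lev), function(l) {
    i <- lev == l
    p <- pool(effects$lnrr[i], effects$v[i], tau2 = tau2)
    data.frame(level = l, k = sum(i), mean_lnrr = p$mean_lnrr, se = p$se,
               percent_change = p$percent_change,
               ci_lower = p$percent_ci95[1], ci_upper = p$percent_ci95[2])
  }))
  if (nlevels(lev) >= 2) {
    W <- tapply(w, lev, sum)
    mu_l <- by_level$mean_lnrr
    mu_bar <- sum(W * mu_l) / sum(W)
    qm <- sum(W * (mu_l - mu_bar)^2)
    df <- nlevels(lev) - 1
    p <- stats::pchisq(qm, df, lower.tail = FALSE)
  } else {
    qm <- NA_real_; df <- 0L; p <- NA_real_
  }
  list(by_level = by_level, tau2 = tau2, qm = qm, df = df, p = p)
}

# DerSimonian-Laird tau^2 from level-wise residual heterogeneity
residual_dl_tau2 <- function(lnrr, v, lev) {
  w <- 1 / v
  Q <- 0; C <- 0; k <- 0
  for (l in levels(lev)) {
    i <- lev == l
    if (sum(i) < 2) next
    mu <- sum(w[i] * lnrr[i]) / sum(w[i])
    Q <- Q + sum(w[i] * (lnrr[i] - mu)^2)
    C <- C + sum(w[i]) - sum(w[i]^2) / sum(w[i])
    k <- k + sum(i) - 1
  }
  if (C <= 0) return(0)
  max(0, (Q - k) / C)
}

#' Regression of pooled percentage response on warming level
#'
#' Ordinary least squares of the pooled percentage changes on the warming
#' level (degC), as used to report the additional loss per extra degree of
#' warming.
#'
#' @param warming_level numeric vector of warming levels (degC).
#' @param percent_change pooled percentage responses at those levels.
#' @return list with `slope` (% per degC), `intercept`, `r_squared`, `p`
#'   (slope test; `NA` with only 2 points) and the underlying `lm` fit.
#' @export
response_vs_warming <- function(warming_level, percent_change) {
  stopifnot(length(warming_level) == length(percent_change))
  if (length(warming_level) < 2) stop("need at least 2 warming levels")
  fit <- stats::lm(percent_change ~ warming_level)
  s <- suppressWarnings(summary(fit))   # exact fits trip a summary warning
  p <- if (length(warming_level) > 2) s$coefficients[2, 4] else NA_real_
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared, p = p, fit = fit)
}

#' Bin field-warming observations and meta-analyse per bin
#'
#' Field warming experiments report ambient/warmed plot summaries at
#' continuous warming magnitudes; these are binned into the six standard
#' half-open categories [0,1), [1,2), [2,3), [3,4), [4,5), [5,Inf) degC and
#' pooled per bin (and per ecosystem when an `ecosystem` column is
#' present), with a between-bin QM test.  Empty bins are omitted.
#'
#' @param observations data.frame with columns `delta_t`, `mean_a`, `sd_a`,
#'   `n_a`, `mean_w`, `sd_w`, `n_w` and optionally `ecosystem`.
#' @param method tau^2 estimator.
#' @return list with `by_bin` (moderator analysis over warming bins) and,
#'   when available, `by_ecosystem`; the effects table is attached as
#'   `effects`.
#' @export
bin_field_warming <- function(observations, method = c("REML", "DL")) {
  method <- match.arg(method)
  stopifnot(all(c("delta_t", "mean_a", "sd_a", "n_a",
                  "mean_w", "sd_w", "n_w") %in% names(observations)))
  if (any(observations$delta_t < 0)) stop("negative warming magnitude")
  breaks <- c(0, 1, 2, 3, 4, 5, Inf)
  labels <- c("<1", "1-2", "2-3", "3-4", "4-5", ">5")
  observations$warming_bin <- as.character(
    cut(observations$delta_t, breaks, labels, right = FALSE,
        include.lowest = TRUE))
  eff <- add_effect_sizes(observations)
  res <- list(by_bin = moderator_analysis(eff, "warming_bin", method),
              effects = eff)
  if ("ecosystem" %in% names(eff))
    res$by_ecosystem <- moderator_analysis(eff, "ecosystem", method)
  res
}
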