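#' Steady-state SOC response to warming under a one-pool model
#'
#' A one-pool soil-carbon model dC/dt = I - k*C has steady state C = I/k.
#' Scaling the decay rate with temperature as k_w = k * Q10^(dT/10) and
#' allowing carbon inputs to change by a factor `input_ratio`, the relative
#' change between the two steady states is
#' `R = input_ratio * Q10^(-dT/10) - 1`, reported here in percent.
#'
#' @param q10 temperature sensitivity of decomposition (factor per 10 degC);
#'   must be positive.
#' @param delta_t warming level in degC (>= 0); vectorised.
#' @param input_ratio ratio of carbon inputs under warming to ambient inputs
#'   (I_w / I); default 1 (no input change).
#' @return Percentage change of steady-state SOC stock (negative = loss).
#' @examples
#' steady_state_response(2, 10)        # one full Q10 decade: -50
#' steady_state_response(1.7, 1)       # approx -5.17
#' @export
steady_state_response <- function(q10, delta_t, input_ratio = 1) {
  if (any(q10 <= 0)) stop("`q10` must be positive")
  if (any(delta_t < 0)) stop("`delta_t` must be >= 0")
  if (any(input_ratio <= 0)) stop("`input_ratio` must be positive")
  100 * (input_ratio * exp(-0.1 * delta_t * log(q10)) - 1)
}

#' Carbon-input ratio for a compound input-change scenario
#'
#' Inputs are assumed to change by a fixed fraction per degree of warming,
#' compounding multiplicatively: I_w / I = (1 + rate)^delta_t.
#'
#' @param rate fractional change of carbon inputs per degC (e.g. 0.02 for a
#'   2% increase per degC); must be > -1.
#' @param delta_t warming level in degC.
#' @return The input ratio I_w / I.
#' @examples
#' input_ratio(0.02, 5)   # 1.02^5 = 1.1041
#' @export
input_ratio <- function(rate, delta_t) {
  if (any(rate <= -1)) stop("`rate` must be > -1")
  (1 + rate)^delta_t
}

#' Fit the Q10 parameter to estimated SOC responses
#'
#' Bounded one-dimensional least squares: minimises the sum of squared
#' differences between observed percentage responses and the one-pool
#' steady-state prediction [steady_state_response()] over Q10 in `bounds`.
#' With a compound input scenario the fitted Q10 obeys the exact identity
#' `q10(rate) = q10(0) * (1 + rate)^10`.
#'
#' @param delta_t numeric vector of warming levels (degC).
#' @param percent numeric vector of observed percentage SOC changes
#'   (negative = loss), same length as `delta_t`.
#' @param input_rate fractional carbon-input change per degC (see
#'   [input_ratio()]); default 0.
#' @param bounds search interval for Q10 (default `c(1, 10)`).
#' @param weights optional non-negative weights for the squared residuals
#'   (default unweighted).
#' @param tol convergence tolerance of the optimiser (default 1e-8).
#' @return An object of class `"q10_fit"`: list with elements `q10`, `sse`,
#'   `input_rate`, `responses` (data.frame of the points used), `bounds`.
#' @examples
#' r <- steady_state_response(1.5, 1:5)
#' fit_q10(1:5, r)$q10    # recovers 1.5
#' @export
fit_q10 <- function(delta_t, percent, input_rate = 0, bounds = c(1, 10),
                    weights = NULL, tol = 1e-8) {
  stopifnot(length(delta_t) == length(percent))
  if (length(delta_t) < 2) stop("need at least 2 response points to fit Q10")
  if (any(!is.finite(delta_t)) || any(!is.finite(percent)))
    stop("non-finite responses")
  if (is.null(weights)) weights <- rep(1, length(delta_t))
  stopifnot(length(weights) == length(delta_t), all(weights >= 0))
  ir <- input_ratio(input_rate, delta_t)
  sse <- function(q) sum(weights * (100 * (ir * q^(-delta_t / 10) - 1) - percent)^2)
  opt <- stats::optimize(sse, interval = bounds, tol = tol)
  if (!is.finite(opt$objective))
    stop("Q10 optimisation did not converge: non-finite objective at q10 = ",
         format(opt$minimum))
  structure(
    list(q10 = opt$minimum, sse = opt$objective, input_rate = input_rate,
         responses = data.frame(delta_t = delta_t, percent = percent),
         bounds = bounds),
    class = "q10_fit")
}

#' @export
print.q10_fit <- function(x, ...) {
  cat(sprintf("One-pool steady-state Q10 fit\n  Q10 = %.4f (bounds %g-%g)\n",
              x$q10, x$bounds[1], x$bounds[2]))
  cat(sprintf("  carbon-input change: %+.1f%% per degC (compound)\n",
              100 * x$input_rate))
  cat(sprintf("  SSE = %.4g over %d response points\n",
              x$sse, nrow(x$responses)))
  invisible(x)
}
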