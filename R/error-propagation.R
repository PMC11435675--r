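#' First-order relative volumetric error
#'
#' Linearizes \eqn{V = \frac{q}{q+2}\pi H R^2} around the ground truth
#' \eqn{(q_0, H_0, R_0)}:
#' \deqn{\frac{\Delta V}{V_0} \approx \frac{\Delta H}{H_0}
#'   + 2\frac{\Delta R}{R_0} + \frac{2\,\Delta q}{q_0 (q_0 + 2)}.}
#' The radius error is doubled and the q sensitivity decays with
#' \eqn{q_0}, which is why volumetric estimates spread more widely than
#' the underlying parameter estimates.
#'
#' @param dH,dR,dq absolute estimation errors (mm, mm, unitless).
#' @param truth a [bowl_model] holding the ground truth
#'   \eqn{(R_0, H_0, q_0)}.
#' @return First-order relative volume error (dimensionless).
#' @export
relative_volume_error <- function(dH, dR, dq, truth) {
  stopifnot(inherits(truth, "bowl_model"))
  dH / truth$H + 2 * dR / truth$R + 2 * dq / (truth$q * (truth$q + 2))
}

#' Closed-form relative sd of the volume estimate
#'
#' Propagates uncorrelated, zero-mean relative parameter errors through
#' the first-order volume expansion:
#' \deqn{\sigma_V^2 \approx \sigma_H^2 + 4 \sigma_R^2
#'   + \frac{4}{(q_0+2)^2}\,\sigma_q^2,}
#' where every sigma is a \emph{relative} standard deviation (sd of
#' \eqn{\Delta H / H_0}, etc.). The radius term carries a factor 4
#' (amplification) while the q term fades as \eqn{q_0} grows.
#'
#' @param q0 ground-truth shape exponent.
#' @param sigma_H,sigma_R,sigma_q relative sds of the parameter
#'   estimates.
#' @return Relative sd of the volume estimate.
#' @export
sigma_v <- function(q0, sigma_H, sigma_R, sigma_q) {
  stopifnot(q0 > 1, sigma_H >= 0, sigma_R >= 0, sigma_q >= 0)
  sqrt(sigma_H^2 + 4 * sigma_R^2 + 4 / (q0 + 2)^2 * sigma_q^2)
}

#' Monte-Carlo check of the volumetric error propagation
#'
#' Draws independent zero-mean Gaussian relative errors for H, R and q,
#' evaluates the exact volume for each draw and returns the empirical
#' relative sd of the volume — an independent check of the closed form
#' for small sigmas, up to second-order terms and sampling error.
#'
#' @param truth a [bowl_model] (ground truth).
#' @param sigma_H,sigma_R,sigma_q relative sds.
#' @param n_draws number of Monte-Carlo draws (>= 1000).
#' @param seed optional integer seed.
#' @return Empirical relative sd of the volume.
#' @export
monte_carlo_sigma_v <- function(truth, sigma_H, sigma_R, sigma_q,
                                n_draws = 1e5, seed = NULL) {
  stopifnot(inherits(truth, "bowl_model"), n_draws >= 1000)
  if (!is.null(seed)) set.seed(seed)
  H <- truth$H * (1 + stats::rnorm(n_draws, 0, sigma_H))
  R <- truth$R * (1 + stats::rnorm(n_draws, 0, sigma_R))
  q <- truth$q * (1 + stats::rnorm(n_draws, 0, sigma_q))
  ## guard degenerate draws (only relevant for large sigmas)
  ok <- H > 0 & R > 0 & q > 1
  V <- q[ok] / (q[ok] + 2) * pi * H[ok] * R[ok]^2 / 1000
  V0 <- bowl_volume(truth)
  stats::sd(V / V0)
}
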