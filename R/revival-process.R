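#' Expected biomarker level on the revival clock
#'
#' Mean of the revival process for a subject in arm `arm` who dies at time
#' `T`, evaluated at revival time `s = T - t` (years before death):
#' `beta_const + arm offset + beta_T * T + beta_s * s + beta_log * ln(s + delta)`.
#'
#' @param s Revival time(s), years before death; non-negative.
#' @param T Survival (death) time, years from randomization. Recycled
#'   against `s`.
#' @param arm `"control"` or `"prednisone"`.
#' @param params A [revival_params] object.
#' @return Numeric vector of expected biomarker levels.
#' @seealso [null_treatment_mean] for the arm-corrected baseline,
#'   [tolerance_band] for the mean with `+/- 2 sd` limits.
#' @examples
#' revival_mean(s = c(0.5, 1, 2), T = 5, arm = "control", revival_params())
#' @export
revival_mean <- function(s, T, arm = c("control", "prednisone"), params) {
  arm <- match.arg(arm)
  params <- as_revival_params(params)
  if (any(s < 0)) stop("revival time 's' must be non-negative", call. = FALSE)
  offset <- if (arm == "prednisone") params$beta_prednisone else params$beta_control
  params$beta_const + offset + params$beta_T * T + params$beta_s * s +
    params$beta_log * log(s + params$delta)
}

#' Treatment-corrected revival mean
#'
#' The revival mean with both arm offsets removed: the expected biomarker
#' trajectory corrected for the additive treatment effect ("null treatment").
#'
#' @inheritParams revival_mean
#' @return Numeric vector of expected biomarker levels.
#' @export
null_treatment_mean <- function(s, T, params) {
  params <- as_revival_params(params)
  if (any(s < 0)) stop("revival time 's' must be non-negative", call. = FALSE)
  params$beta_const + params$beta_T * T + params$beta_s * s +
    params$beta_log * log(s + params$delta)
}

#' Covariance of biomarker values on the revival clock
#'
#' Within-subject covariance matrix of biomarker values at revival times
#' `s_values`. The diagonal is the total variance
#' `sigma2_b + sigma2_w + sigma2_e`; off-diagonal entries are
#' `sigma2_b + sigma2_w * exp(-|s_i - s_j| / phi)` (shared patient effect
#' plus exponentially decaying serial correlation; measurement error is
#' uncorrelated).
#'
#' @param s_values Non-empty vector of non-negative revival times.
#' @param params A [revival_params] object.
#' @return A symmetric positive-definite matrix.
#' @export
revival_covariance <- function(s_values, params) {
  params <- as_revival_params(params)
  if (length(s_values) == 0L) stop("'s_values' must be non-empty", call. = FALSE)
  if (any(s_values < 0)) stop("revival times must be non-negative", call. = FALSE)
  d <- abs(outer(s_values, s_values, "-"))
  v <- params$sigma2_b + params$sigma2_w * exp(-d / params$phi)
  diag(v) <- diag(v) + params$sigma2_e
  v
}

#' Log-likelihood of a biomarker history given the survival time
#'
#' Log-density of the observed biomarker history under the revival model,
#' conditional on death at time `T`: a multivariate Gaussian with mean
#' [revival_mean] at each `s = T - t` and covariance [revival_covariance].
#' An empty history contributes 0 (a vacuous likelihood).
#'
#' Measurement times may equal `T` (revival time 0, well defined because
#' `delta > 0`) but may not exceed it.
#'
#' @param times Measurement times `t` (years), all `<= T`.
#' @param values Biomarker values, same length as `times`.
#' @param arm `"control"` or `"prednisone"`.
#' @param T Candidate survival time (years).
#' @param params A [revival_params] object.
#' @return The log-likelihood (scalar).
#' @examples
#' p <- revival_params()
#' history_loglik(times = c(0, 1), values = c(80, 70),
#'                arm = "control", T = 3, params = p)
#' @export
history_loglik <- function(times, values, arm = c("control", "prednisone"),
                           T, params) {
  arm <- match.arg(arm)
  params <- as_revival_params(params)
  if (length(times) != length(values))
    stop("'times' and 'values' must have the same length", call. = FALSE)
  if (length(times) == 0L) return(0)
  if (any(times > T))
    stop("all measurement times must be <= T", call. = FALSE)
  drop(.loglik_grid(times, values, arm, T, params))
}

# Vectorized history log-likelihood over a grid of candidate survival times.
# The covariance depends only on the spacings |t_i - t_j| (which the revival
# clock preserves), so one Cholesky factor serves the whole grid; only the
# mean changes with T.
.loglik_grid <- function(times, values, arm, T_grid, params) {
  k <- length(times)
  if (k == 0L) return(rep(0, length(T_grid)))
  V <- revival_covariance(abs(times - min(times)), params)
  R <- chol(V)
  logdet <- 2 * sum(log(diag(R)))
  # residual matrix: one row per grid point
  S <- outer(T_grid, times, "-")            # revival times, grid x k
  offset <- if (arm == "prednisone") params$beta_prednisone else params$beta_control
  M <- params$beta_const + offset + params$beta_T * T_grid +
    params$beta_s * S + params$beta_log * log(S + params$delta)
  E <- matrix(rep(values, each = length(T_grid)), ncol = k) - M
  Z <- E %*% backsolve(R, diag(k))          # rows: R^-T e  via e' R^-1
  q <- rowSums(Z * Z)
  -0.5 * (k * log(2 * pi) + logdet + q)
}

#' Tolerance band around the revival mean
#'
#' The revival mean in follow-up time together with `mean +/- 2 sd` limits,
#' where `sd` is the square root of the total variance. With the default
#' variance budget of 625 the half-width is 50 biomarker units.
#'
#' @param params A [revival_params] object.
#' @param T Survival time (years).
#' @param arm `"control"` or `"prednisone"`.
#' @param t_grid Follow-up times in `[0, T)`.
#' @return A data frame with columns `t`, `mean`, `lower`, `upper`.
#' @export
tolerance_band <- function(params, T, arm = c("control", "prednisone"),
                           t_grid) {
  arm <- match.arg(arm)
  params <- as_revival_params(params)
  if (any(t_grid < 0 | t_grid >= T))
    stop("'t_grid' must lie in [0, T)", call. = FALSE)
  m <- revival_mean(T - t_grid, T, arm, params)
  half <- 2 * sqrt(total_variance(params))
  data.frame(t = t_grid, mean = m, lower = m - half, upper = m + half)
}
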