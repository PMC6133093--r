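#' Revival-process parameters
#'
#' Bundle of all parameters of the reverse-time (revival) biomarker model and
#' of the marginal survival distribution. The biomarker observed at follow-up
#' time `t` on a subject who dies at time `T` is modelled on the revival clock
#' `s = T - t` (time counted backward from death) as
#' \deqn{Y = \beta_0 + \beta_{arm} + \beta_T T + \beta_s s +
#'       \beta_{\log} \ln(s + \delta) + b + W(s) + \epsilon,}
#' with a patient-level random intercept `b` (variance `sigma2_b`), a
#' stationary serial Gaussian process `W` in revival time with exponential
#' correlation of range `phi` (variance `sigma2_w`) and measurement error
#' `epsilon` (variance `sigma2_e`). The marginal survival distribution is
#' exponential with rate `lambda0`.
#'
#' The default coefficients are the package's reference configuration for a
#' prednisone/placebo liver-cirrhosis trial with the prothrombin index (in %)
#' as biomarker: a marginal death rate of 0.164 per year and a total biomarker
#' variance of 625 (sd 25) split across the three components.
#'
#' @param beta_const Constant term of the revival mean (biomarker units).
#' @param beta_control,beta_prednisone Additive arm offsets. Only the
#'   control-arm level (`beta_const + beta_control`) and the arm contrast are
#'   identifiable from data; the three-way split is a reporting convention.
#' @param beta_T Coefficient of the survival time `T` (units per year).
#' @param beta_s Coefficient of the revival time `s` (units per year).
#' @param beta_log Coefficient of `ln(s + delta)`.
#' @param delta Offset (years) inside the logarithm; must be positive. Keeps
#'   the near-death drop of the mean steep but finite.
#' @param sigma2_b Variance of the patient random intercept.
#' @param sigma2_w Variance of the serial process.
#' @param phi Correlation range (years) of the serial process: correlation at
#'   lag `d` in revival time is `exp(-d / phi)`.
#' @param sigma2_e Measurement-error variance.
#' @param lambda0 Marginal exponential death rate (events per year).
#'
#' @return An object of class `revival_params` (a named list).
#' @examples
#' p <- revival_params()
#' p
#' revival_mean(s = 1, T = 3, arm = "prednisone", params = p)
#' @export
revival_params <- function(beta_const = 63.47,
                           beta_control = 2.49,
                           beta_prednisone = 13.56,
                           beta_T = 1.74,
                           beta_s = -2.11,
                           beta_log = 4.66,
                           delta = 0.1,
                           sigma2_b = 300,
                           sigma2_w = 200,
                           phi = 1,
                           sigma2_e = 125,
                           lambda0 = 0.164) {
  p <- list(beta_const = beta_const, beta_control = beta_control,
            beta_prednisone = beta_prednisone, beta_T = beta_T,
            beta_s = beta_s, beta_log = beta_log, delta = delta,
            sigma2_b = sigma2_b, sigma2_w = sigma2_w, phi = phi,
            sigma2_e = sigma2_e, lambda0 = lambda0)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("'", nm, "' must be a finite numeric scalar", call. = FALSE)
  }
  if (p$delta <= 0) stop("'delta' must be positive", call. = FALSE)
  if (p$phi <= 0) stop("'phi' must be positive", call. = FALSE)
  if (p$lambda0 <= 0) stop("'lambda0' must be positive", call. = FALSE)
  if (min(p$sigma2_b, p$sigma2_w, p$sigma2_e) < 0)
    stop("variance components must be non-negative", call. = FALSE)
  structure(p, class = "revival_params")
}

#' Total variance of the revival process
#'
#' Sum of the three variance components (patient effect, serial process,
#' measurement error); the marginal variance of a single biomarker value
#' around the revival mean.
#'
#' @param params A [revival_params] object.
#' @return A scalar; 625 under the default configuration.
#' @export
total_variance <- function(params) {
  params <- as_revival_params(params)
  params$sigma2_b + params$sigma2_w + params$sigma2_e
}

#' Coerce to revival parameters
#'
#' @param x A `revival_params` object or a fitted model carrying one
#'   (see [fit_revival]).
#' @param ... Unused.
#' @return A `revival_params` object.
#' @export
as_revival_params <- function(x, ...) UseMethod("as_revival_params")

#' @export
as_revival_params.revival_params <- function(x, ...) x

#' @export
as_revival_params.default <- function(x, ...)
  stop("cannot interpret object of class '", class(x)[1L],
       "' as revival parameters", call. = FALSE)

#' @export
print.revival_params <- function(x, digits = 4, ...) {
  cat("Revival-process parameters\n")
  cat("  mean:  const =", format(x$beta_const, digits = digits),
      " control =", format(x$beta_control, digits = digits),
      " prednisone =", format(x$beta_prednisone, digits = digits), "\n")
  cat("         T =", format(x$beta_T, digits = digits),
      " s =", format(x$beta_s, digits = digits),
      " ln(s+delta) =", format(x$beta_log, digits = digits),
      " (delta =", format(x$delta, digits = digits), "years)\n")
  cat("  var:   patient =", format(x$sigma2_b, digits = digits),
      " serial =", format(x$sigma2_w, digits = digits),
      "(range", format(x$phi, digits = digits), "y)",
      " error =", format(x$sigma2_e, digits = digits),
      " total =", format(total_variance(x), digits = digits), "\n")
  cat("  marginal survival: exponential, rate lambda0 =",
      format(x$lambda0, digits = digits), "per year\n")
  invisible(x)
}
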