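#' Fit the revival model by maximum likelihood
#'
#' Estimates the mean coefficients of the reverse-time biomarker model on one
#' of three subject subsets, by maximizing the product of per-subject
#' Gaussian history likelihoods (generalized least squares when the variance
#' components are held fixed, which is the default; joint maximization over
#' the variance components is available).
#'
#' The three subsets mirror the standard analysis and its observation-limit
#' alternative:
#' \describe{
#'   \item{`all_uncensored`}{subjects who died, all their measurements;
#'     revival clock `s = T - t` with `T` the observed death time.}
#'   \item{`uncensored_lt_tlim`}{subjects who died before `t_lim`,
#'     measurements before `t_lim`.}
#'   \item{`survivors_ge_tlim`}{subjects still at risk at `t_lim`,
#'     measurements at `t <= t_lim`. Their death times are unknown, so the
#'     revival clock is `s = t_lim - t` and the `T` covariate uses a proxy
#'     (`survivor_T_proxy`): the observed follow-up end (default) or
#'     `t_lim` itself. The choice is recorded in the fit.}
#' }
#'
#' Only the control-arm level (constant plus control offset) and the
#' prednisone-minus-control contrast are identifiable; coefficients are
#' reported in that parametrization as `const` and `prednisone`.
#'
#' @param cohort A `revival_cohort` (see [simulate_cohort], [read_cohort]).
#' @param subset One of `"all_uncensored"`, `"uncensored_lt_tlim"`,
#'   `"survivors_ge_tlim"`.
#' @param t_lim Observation limit (years); defaults to the cohort
#'   configuration's value, or 9.
#' @param params A [revival_params] supplying `delta` and (unless
#'   `estimate_variance = TRUE`) the fixed variance components.
#' @param estimate_variance If `TRUE`, the three variance components and the
#'   serial range are estimated jointly with the mean by ML.
#' @param survivor_T_proxy Stand-in for the unobserved death time of
#'   survivors: `"followup_end"` or `"t_lim"`.
#' @return An object of class `revival_fit` with `coefficients`,
#'   `standard_errors`, `vcov`, `loglik`, `params` (fitted parameter set),
#'   `subset`, `n_subjects`, `n_measurements`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_subjects = 200), seed = 42)
#' fit <- fit_revival(coh, "all_uncensored")
#' summary(fit)
#' @export
fit_revival <- function(cohort,
                        subset = c("all_uncensored", "uncensored_lt_tlim",
                                   "survivors_ge_tlim"),
                        t_lim = NULL,
                        params = NULL,
                        estimate_variance = FALSE,
                        survivor_T_proxy = c("followup_end", "t_lim")) {
  subset <- match.arg(subset)
  survivor_T_proxy <- match.arg(survivor_T_proxy)
  if (!inherits(cohort, "revival_cohort"))
    stop("'cohort' must be a revival_cohort", call. = FALSE)
  if (is.null(t_lim))
    t_lim <- if (!is.null(cohort$config)) cohort$config$t_lim else 9
  if (is.null(params))
    params <- if (!is.null(cohort$config)) cohort$config$params
              else revival_params()
  params <- as_revival_params(params)

  sv <- cohort$survival
  keep <- switch(subset,
    all_uncensored     = sv$status == 1,
    uncensored_lt_tlim = sv$status == 1 & sv$time < t_lim,
    survivors_ge_tlim  = sv$time >= t_lim)
  ids <- sv$id[keep]
  if (!length(ids))
    stop("subset '", subset, "' is empty in this cohort", call. = FALSE)

  # assemble per-subject design pieces
  blocks <- list(); bi <- 0L
  for (j in seq_along(ids)) {
    id <- ids[j]
    row <- sv[sv$id == id, ]
    up_to <- switch(subset, all_uncensored = Inf,
                    uncensored_lt_tlim = min(t_lim, row$time),
                    survivors_ge_tlim = t_lim)
    h <- .subject_history(cohort, id, up_to = up_to)
    if (!length(h$times)) next
    if (subset == "survivors_ge_tlim") {
      s <- t_lim - h$times
      Tcov <- if (survivor_T_proxy == "t_lim") t_lim else row$time
    } else {
      s <- row$time - h$times
      Tcov <- row$time
    }
    bi <- bi + 1L
    blocks[[bi]] <- list(
      s = s, y = h$values,
      X = cbind(const = 1,
                prednisone = as.numeric(row$arm == "prednisone"),
                T = Tcov, s = s, `log(s+delta)` = log(s + params$delta)))
  }
  if (!bi)
    stop("subset '", subset, "' has no measurements", call. = FALSE)

  arm_col <- vapply(blocks, function(b) b$X[1L, "prednisone"], numeric(1))
  if (all(arm_col == arm_col[1L]))
    stop("design is singular: coefficient 'prednisone' is not identifiable ",
         "(only one arm present in subset '", subset, "')", call. = FALSE)

  gls <- function(p) {
    XtVX <- 0; XtVy <- 0; logdet <- 0; yVy <- 0; ktot <- 0L
    for (b in blocks) {
      R <- chol(revival_covariance(b$s, p))
      Xw <- backsolve(R, b$X, transpose = TRUE)
      yw <- backsolve(R, b$y, transpose = TRUE)
      XtVX <- XtVX + crossprod(Xw)
      XtVy <- XtVy + crossprod(Xw, yw)
      yVy <- yVy + sum(yw^2)
      logdet <- logdet + 2 * sum(log(diag(R)))
      ktot <- ktot + length(b$y)
    }
    beta <- tryCatch(solve(XtVX, XtVy), error = function(e)
      stop("design is singular in subset '", subset, "'", call. = FALSE))
    rss <- yVy - 2 * sum(beta * XtVy) + drop(crossprod(beta, XtVX %*% beta))
    ll <- -0.5 * (ktot * log(2 * pi) + logdet + rss)
    list(beta = drop(beta), vcov = solve(XtVX), loglik = ll, k = ktot)
  }

  if (estimate_variance) {
    obj <- function(th) {
      p2 <- params
      p2$sigma2_b <- exp(th[1]); p2$sigma2_w <- exp(th[2])
      p2$phi <- exp(th[3]); p2$sigma2_e <- exp(th[4])
      -gls(p2)$loglik
    }
    th0 <- log(c(params$sigma2_b, params$sigma2_w, params$phi,
                 params$sigma2_e))
    opt <- stats::optim(th0, obj, method = "Nelder-Mead",
                        control = list(maxit = 500))
    params$sigma2_b <- exp(opt$par[1]); params$sigma2_w <- exp(opt$par[2])
    params$phi <- exp(opt$par[3]); params$sigma2_e <- exp(opt$par[4])
  }

  res <- gls(params)
  cf <- res$beta
  names(cf) <- colnames(blocks[[1L]]$X)
  se <- sqrt(diag(res$vcov))
  names(se) <- names(cf)

  fitted_params <- params
  fitted_params$beta_const <- cf[["const"]]
  fitted_params$beta_control <- 0
  fitted_params$beta_prednisone <- cf[["prednisone"]]
  fitted_params$beta_T <- cf[["T"]]
  fitted_params$beta_s <- cf[["s"]]
  fitted_params$beta_log <- cf[["log(s+delta)"]]

  structure(list(coefficients = cf, standard_errors = se, vcov = res$vcov,
                 loglik = res$loglik, params = fitted_params,
                 subset = subset, t_lim = t_lim,
                 survivor_T_proxy = if (subset == "survivors_ge_tlim")
                   survivor_T_proxy else NA_character_,
                 estimate_variance = estimate_variance,
                 n_subjects = bi, n_measurements = res$k,
                 call = match.call()),
            class = "revival_fit")
}

#' @export
print.revival_fit <- function(x, digits = 4, ...) {
  cat("Revival model fit (subset: ", x$subset, ")\n", sep = "")
  print(round(x$coefficients, digits))
  cat("log-likelihood:", format(x$loglik, digits = digits),
      " subjects:", x$n_subjects, " measurements:", x$n_measurements, "\n")
  invisible(x)
}

#' @export
summary.revival_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$standard_errors,
               `z value` = object$coefficients / object$standard_errors)
  structure(list(coefficients = tab, fit = object),
            class = "summary.revival_fit")
}

#' @export
print.summary.revival_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  cat("Revival model fit\n")
  cat("  subset:", f$subset)
  if (!is.na(f$survivor_T_proxy))
    cat(" (T proxy for survivors:", f$survivor_T_proxy, ")")
  cat("\n  subjects:", f$n_subjects, " measurements:", f$n_measurements,
      "\n\nCoefficients (const = control-arm level, prednisone = contrast):\n")
  stats::printCoefmat(x$coefficients, digits = digits)
  v <- f$params
  cat("\nVariance components",
      if (f$estimate_variance) "(estimated):" else "(fixed):",
      "\n  patient:", format(v$sigma2_b, digits = digits),
      " serial:", format(v$sigma2_w, digits = digits),
      "(range", format(v$phi, digits = digits), "y)",
      " error:", format(v$sigma2_e, digits = digits), "\n")
  cat("log-likelihood:", format(f$loglik, digits = digits), "\n")
  invisible(x)
}

#' @export
coef.revival_fit <- function(object, ...) object$coefficients

#' @export
vcov.revival_fit <- function(object, ...) object$vcov

#' @export
logLik.revival_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n_measurements, class = "logLik")
}

#' @export
as_revival_params.revival_fit <- function(x, ...) x$params

#' Predicted biomarker mean from a fitted revival model
#'
#' @param object A `revival_fit`.
#' @param newdata Data frame with columns `s` (revival time), `T`
#'   (survival time) and `arm`.
#' @param interval `"none"` or `"tolerance"` (mean `+/- 2 sd` of a single
#'   new measurement).
#' @param ... Unused.
#' @return A numeric vector, or a data frame with `fit`, `lwr`, `upr`.
#' @export
predict.revival_fit <- function(object, newdata,
                                interval = c("none", "tolerance"), ...) {
  interval <- match.arg(interval)
  p <- object$params
  fit <- vapply(seq_len(nrow(newdata)), function(i)
    revival_mean(newdata$s[i], newdata$T[i], as.character(newdata$arm[i]), p),
    numeric(1))
  if (interval == "none") return(fit)
  half <- 2 * sqrt(total_variance(p))
  data.frame(fit = fit, lwr = fit - half, upr = fit + half)
}

#' Residuals of a fitted revival model
#'
#' Marginal residuals `y - mu(s)` of every measurement used in the fit,
#' optionally scaled by the total standard deviation.
#'
#' @param object A `revival_fit`.
#' @param cohort The cohort the model was fitted to.
#' @param standardized Divide by `sqrt(total variance)`?
#' @param ... Unused.
#' @return Numeric vector of residuals.
#' @export
residuals.revival_fit <- function(object, cohort, standardized = FALSE, ...) {
  dv <- revival_deviations(cohort, object$params,
                           subset = object$subset, t_lim = object$t_lim,
                           survivor_T_proxy = object$survivor_T_proxy)
  if (standardized) dv / sqrt(total_variance(object$params)) else dv
}

#' Simulate cohorts from a fitted revival model
#'
#' @param object A `revival_fit`.
#' @param nsim Number of cohorts.
#' @param seed Integer seed.
#' @param config A [cohort_config] describing the trial design; its
#'   parameter slot is replaced by the fitted parameters.
#' @param ... Unused.
#' @return A list of `revival_cohort` objects (length `nsim`).
#' @export
simulate.revival_fit <- function(object, nsim = 1, seed = NULL,
                                 config = cohort_config(), ...) {
  if (!is.null(seed)) set.seed(seed)
  config$params <- object$params
  lapply(seq_len(nsim), function(i) simulate_cohort(config, seed = NULL))
}

#' Deviations of observed biomarker values from the revival mean
#'
#' For every usable measurement in a subset, the observed value minus the
#' model mean at its revival time. Under the generating model these
#' deviations pool the patient effect, serial process and measurement error,
#' so their standard deviation estimates the square root of the total
#' variance (25 under the default budget of 625).
#'
#' @param cohort A `revival_cohort` whose `T_true` is known for the subset
#'   used (simulated cohorts, or death subsets of imported data).
#' @param params A [revival_params] or `revival_fit`.
#' @param subset Which subjects/measurements to use (see [fit_revival]).
#' @param t_lim Observation limit.
#' @param survivor_T_proxy See [fit_revival].
#' @param use_true_T For simulated cohorts: use the latent true death time
#'   for all subjects (including censored ones), pooling every measurement.
#' @return Numeric vector of deviations.
#' @export
revival_deviations <- function(cohort, params,
                               subset = "all_uncensored",
                               t_lim = 9,
                               survivor_T_proxy = "followup_end",
                               use_true_T = FALSE) {
  params <- as_revival_params(params)
  sv <- cohort$survival
  lg <- cohort$longitudinal
  if (use_true_T) {
    if (anyNA(sv$T_true))
      stop("latent death times unavailable; 'use_true_T' needs a simulated ",
           "cohort", call. = FALSE)
    idx <- match(lg$id, sv$id)
    Tt <- sv$T_true[idx]
    mu <- ifelse(sv$arm[idx] == "prednisone",
                 params$beta_const + params$beta_prednisone,
                 params$beta_const + params$beta_control) +
      params$beta_T * Tt + params$beta_s * (Tt - lg$time) +
      params$beta_log * log(Tt - lg$time + params$delta)
    return(lg$value - mu)
  }
  keep_ids <- switch(subset,
    all_uncensored     = sv$id[sv$status == 1],
    uncensored_lt_tlim = sv$id[sv$status == 1 & sv$time < t_lim],
    survivors_ge_tlim  = sv$id[sv$time >= t_lim],
    stop("unknown subset", call. = FALSE))
  out <- numeric(0)
  for (id in keep_ids) {
    row <- sv[sv$id == id, ]
    h <- .subject_history(cohort, id,
                          up_to = if (subset == "all_uncensored") Inf
                                  else t_lim)
    if (!length(h$times)) next
    if (subset == "survivors_ge_tlim") {
      s <- t_lim - h$times
      Tcov <- if (identical(survivor_T_proxy, "t_lim")) t_lim else row$time
    } else {
      if (subset == "uncensored_lt_tlim") {
        h$values <- h$values[h$times < t_lim]
        h$times <- h$times[h$times < t_lim]
      }
      s <- row$time - h$times
      Tcov <- row$time
    }
    mu <- revival_mean(s, Tcov, row$arm, params)
    out <- c(out, h$values - mu)
  }
  out
}
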