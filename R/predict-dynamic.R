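#' Posterior of the survival time under the exponential-marginal model
#'
#' The predictive distribution of the death time `T` for a subject still at
#' risk at the landmark `t_LM`, combining the exponential marginal (rate
#' `lambda0`) with the revival likelihood of the biomarker history:
#' density over `T > t_LM` proportional to
#' `exp(history_loglik(history | T)) * lambda0 * exp(-lambda0 T)`.
#'
#' The posterior is discretized on grid cells of width `grid_step` from
#' `t_LM` to `t_LM + grid_span`. Each cell's mass is the exact
#' exponential-prior increment times the likelihood at the cell midpoint,
#' accumulated in log space with max subtraction, then normalized. With an
#' empty history this reproduces the memoryless exponential tail exactly on
#' cell boundaries. The prior mass truncated beyond the grid is recorded in
#' attribute `"truncated_prior_mass"`.
#'
#' @param times,values Biomarker history (only `times <= t_LM` used).
#' @param arm `"control"` or `"prednisone"`.
#' @param t_LM Landmark time (years).
#' @param params A [revival_params] or `revival_fit`.
#' @param grid_step Cell width (years).
#' @param grid_span Grid length beyond `t_LM` (years).
#' @return An object of class `predictive_dist`: list with `t_LM`,
#'   `support` (cell midpoints), `lower` (cell lower edges), `weights`
#'   (summing to 1), `atom_mass = 0`, `model = "standard"`.
#' @examples
#' p <- revival_params()
#' d <- posterior_T_standard(numeric(0), numeric(0), "control", 2, p)
#' predictive_survival(d, t_hor = 4)  # H_pred = 2 * lambda0
#' @export
posterior_T_standard <- function(times, values,
                                 arm = c("control", "prednisone"),
                                 t_LM, params,
                                 grid_step = 0.02, grid_span = 60) {
  arm <- match.arg(arm)
  params <- as_revival_params(params)
  keep <- times <= t_LM
  times <- times[keep]; values <- values[keep]
  edges <- seq(t_LM, t_LM + grid_span, by = grid_step)
  mid <- edges[-length(edges)] + grid_step / 2
  # exact prior mass per cell, conditional on T > t_LM
  log_prior <- log(exp(-params$lambda0 * (edges[-length(edges)] - t_LM)) -
                     exp(-params$lambda0 * (edges[-1L] - t_LM)))
  log_lik <- .loglik_grid(times, values, arm, mid, params)
  # the prior tail beyond the grid is kept as one final cell whose
  # likelihood is carried over from the last midpoint; with no data this
  # makes the posterior exactly the memoryless exponential tail
  tail_mass <- exp(-params$lambda0 * grid_span)
  log_prior <- c(log_prior, log(tail_mass))
  log_lik <- c(log_lik, log_lik[length(log_lik)])
  mid <- c(mid, t_LM + grid_span + 1 / params$lambda0)
  lw <- log_prior + log_lik
  m <- max(lw)
  if (!is.finite(m))
    stop("posterior mass underflows on the whole grid; widen 'grid_span' ",
         "or check the history", call. = FALSE)
  w <- exp(lw - m)
  total <- sum(w)
  if (total <= 0)
    stop("posterior mass underflows; widen 'grid_span'", call. = FALSE)
  structure(list(t_LM = t_LM, support = mid,
                 lower = c(edges[-length(edges)], t_LM + grid_span),
                 weights = w / total, atom_mass = 0, t_lim = NA_real_,
                 model = "standard"),
            class = "predictive_dist",
            truncated_prior_mass = tail_mass)
}

#' Kaplan-Meier marginal survival with an observation limit
#'
#' Product-limit estimate of the marginal survival after administratively
#' censoring every subject at `t_lim`. The survival mass remaining at
#' `t_lim` (the residual atom) is carried explicitly: it is the
#' model-free probability of outliving the observation window, about which
#' no further statement is made.
#'
#' @param cohort A `revival_cohort`.
#' @param t_lim Observation limit (years).
#' @return An object of class `km_marginal`: list with `time` (death
#'   times), `surv` (survival just after each death time), `residual`
#'   (mass at `t_lim`), `t_lim` and the underlying
#'   [survival::survfit] object.
#' @export
km_marginal <- function(cohort, t_lim = 9) {
  sv <- cohort$survival
  if (!nrow(sv)) stop("empty cohort", call. = FALSE)
  time <- pmin(sv$time, t_lim)
  status <- ifelse(sv$time >= t_lim, 0L, sv$status)
  fit <- survival::survfit(survival::Surv(time, status) ~ 1)
  dead <- fit$n.event > 0
  if (!any(dead)) warning("no events before t_lim; flat survival curve")
  jump_t <- fit$time[dead]
  jump_s <- fit$surv[dead]
  residual <- if (length(jump_s)) min(jump_s) else 1
  # residual mass at t_lim = KM value after the last death before t_lim
  structure(list(time = jump_t, surv = jump_s, residual = residual,
                 t_lim = t_lim, survfit = fit), class = "km_marginal")
}

#' @export
print.km_marginal <- function(x, digits = 4, ...) {
  cat("Kaplan-Meier marginal survival, observation limit t_lim =",
      x$t_lim, "\n")
  cat("  ", length(x$time), "death times;",
      "residual mass at t_lim:", format(x$residual, digits = digits), "\n")
  invisible(x)
}

#' Marginal window cumulative hazard from a Kaplan-Meier curve
#'
#' The model-free predicted cumulative hazard over `(t_LM, t_hor]` implied
#' by a marginal Kaplan-Meier curve: `-ln(S(t_hor) / S(t_LM))`. This is the
#' (history-free) prediction the alternative model assigns to every subject
#' at risk at the landmark, and the reference against which its simple
#' calibration factor is computed.
#'
#' @param km A [km_marginal] object.
#' @param t_LM Landmark time.
#' @param t_hor Horizon time in `(t_LM, t_lim]`.
#' @return The window cumulative hazard (scalar, `>= 0`).
#' @export
km_window_hazard <- function(km, t_LM, t_hor) {
  if (t_hor <= t_LM) stop("'t_hor' must exceed 't_LM'", call. = FALSE)
  if (t_hor > km$t_lim)
    stop("the Kaplan-Meier marginal makes no statement beyond t_lim",
         call. = FALSE)
  -log(.km_surv_at(km, t_hor) / .km_surv_at(km, t_LM))
}

# KM survival S(t) (left-continuous product-limit value just after t),
# evaluated from a km_marginal object; S(t) = residual for t >= last jump.
.km_surv_at <- function(km, t) {
  vapply(t, function(tt) {
    if (tt >= km$t_lim) return(km$residual)
    j <- km$time <= tt
    if (!any(j)) 1 else km$surv[max(which(j))]
  }, numeric(1))
}

#' Posterior of the survival time under the Kaplan-Meier alternative
#'
#' Predictive distribution of `T` that refuses to extrapolate beyond the
#' observation limit: the prior over death times is the Kaplan-Meier
#' increment at each observed death time in `(t_LM, t_lim)`, plus a single
#' atom for `T >= t_lim` with the KM residual mass. The likelihood of the
#' biomarker history is evaluated under the pre-limit revival fit
#' (`fit_lt`) at each death time, and under the survivor fit
#' (`fit_survivor`, revival clock `s = t_lim - t`, `T` covariate `t_lim`)
#' for the atom. No revival mean is ever evaluated at a survival time
#' beyond `t_lim`, and no imputation of survivor death times is involved.
#'
#' @param times,values Biomarker history (only `times <= t_LM` used).
#' @param arm `"control"` or `"prednisone"`.
#' @param t_LM Landmark time, `< t_lim`.
#' @param km A [km_marginal] object.
#' @param fit_lt Parameters for death times before the limit: a
#'   `revival_fit` on subset `"uncensored_lt_tlim"` or a [revival_params].
#' @param fit_survivor Parameters for the survivor atom: a `revival_fit`
#'   on subset `"survivors_ge_tlim"` or a [revival_params].
#' @param t_lim Observation limit (defaults to the one in `km`).
#' @return A `predictive_dist` with `model = "alternative"`: discrete
#'   support at the KM death times above `t_LM`, plus `atom_mass` for
#'   `T >= t_lim`.
#' @export
posterior_T_alternative <- function(times, values,
                                    arm = c("control", "prednisone"),
                                    t_LM, km, fit_lt, fit_survivor,
                                    t_lim = km$t_lim) {
  arm <- match.arg(arm)
  if (t_LM >= t_lim) stop("'t_LM' must be below 't_lim'", call. = FALSE)
  p_lt <- as_revival_params(fit_lt)
  p_sv <- as_revival_params(fit_survivor)
  keep <- times <= t_LM
  times <- times[keep]; values <- values[keep]

  jumps <- km$time > t_LM & km$time < t_lim
  jump_t <- km$time[jumps]
  prior_jump <- -diff(c(.km_surv_at(km, t_LM), km$surv[jumps]))
  prior_atom <- km$residual
  if (!length(jump_t) && prior_atom <= 0)
    stop("no Kaplan-Meier mass above the landmark", call. = FALSE)

  ll_jump <- if (length(jump_t))
    .loglik_grid(times, values, arm, jump_t, p_lt) else numeric(0)
  # survivor atom: revival clock anchored at the observation limit
  ll_atom <- if (length(times)) {
    s <- t_lim - times
    V <- revival_covariance(s, p_sv)
    mu <- revival_mean(s, t_lim, arm, p_sv)
    R <- chol(V)
    z <- backsolve(R, values - mu, transpose = TRUE)
    -0.5 * (length(s) * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z^2))
  } else 0

  lw <- c(log(prior_jump) + ll_jump, log(prior_atom) + ll_atom)
  m <- max(lw[is.finite(lw)])
  w <- exp(lw - m)
  w <- w / sum(w)
  k <- length(jump_t)
  structure(list(t_LM = t_LM, support = jump_t, lower = jump_t,
                 weights = w[seq_len(k)], atom_mass = w[k + 1L],
                 t_lim = t_lim, model = "alternative"),
            class = "predictive_dist")
}

#' @export
print.predictive_dist <- function(x, digits = 4, ...) {
  cat("Predictive distribution of T (", x$model, " model), t_LM = ",
      x$t_LM, "\n", sep = "")
  cat("  support points:", length(x$support))
  if (x$model == "alternative")
    cat("  atom P(T >= ", x$t_lim, ") = ",
        format(x$atom_mass, digits = digits), sep = "")
  cat("\n")
  invisible(x)
}

#' Predicted conditional survival and cumulative hazard over a window
#'
#' From a predictive distribution of `T`, the probability of surviving to
#' the horizon, `p_surv = P(T > t_hor | at risk at t_LM, history)`, and the
#' implied predicted cumulative hazard `H_pred = -ln(p_surv)` over
#' `(t_LM, t_hor]`.
#'
#' @param dist A `predictive_dist`.
#' @param t_hor Horizon time, `> t_LM` (and `<= t_lim` for the
#'   alternative model).
#' @param subject_id Optional identifier carried through.
#' @return A one-row data frame: `subject_id`, `t_LM`, `t_hor`, `p_surv`,
#'   `H_pred`.
#' @export
predictive_survival <- function(dist, t_hor, subject_id = NA) {
  if (!inherits(dist, "predictive_dist"))
    stop("'dist' must be a predictive_dist", call. = FALSE)
  if (t_hor <= dist$t_LM) stop("'t_hor' must exceed t_LM", call. = FALSE)
  if (dist$model == "alternative" && t_hor > dist$t_lim)
    stop("the alternative model makes no statement beyond t_lim",
         call. = FALSE)
  p_surv <- sum(dist$weights[dist$support > t_hor]) + dist$atom_mass
  if (p_surv <= 0)
    stop("predicted survival mass is zero at the horizon", call. = FALSE)
  data.frame(subject_id = subject_id, t_LM = dist$t_LM, t_hor = t_hor,
             p_surv = min(p_surv, 1), H_pred = -log(min(p_surv, 1)))
}

#' Predicted cumulative hazards for all subjects at risk at a landmark
#'
#' Convenience wrapper: builds the predictive distribution for every
#' subject with follow-up beyond `t_LM` and evaluates it at the horizon.
#'
#' @param cohort A `revival_cohort`.
#' @param t_LM Landmark time.
#' @param t_hor Horizon time.
#' @param model `"standard"` or `"alternative"`.
#' @param params [revival_params] or `revival_fit` (standard model).
#' @param km,fit_lt,fit_survivor Alternative-model inputs (see
#'   [posterior_T_alternative]).
#' @param ... Further arguments to the posterior constructor.
#' @return Data frame with one row per at-risk subject: `subject_id`,
#'   `t_LM`, `t_hor`, `p_surv`, `H_pred`.
#' @export
predict_landmark <- function(cohort, t_LM, t_hor,
                             model = c("standard", "alternative"),
                             params = NULL, km = NULL, fit_lt = NULL,
                             fit_survivor = NULL, ...) {
  model <- match.arg(model)
  sv <- cohort$survival
  ids <- sv$id[sv$time > t_LM]
  out <- lapply(ids, function(id) {
    h <- .subject_history(cohort, id, up_to = t_LM)
    arm <- sv$arm[sv$id == id]
    d <- if (model == "standard")
      posterior_T_standard(h$times, h$values, arm, t_LM, params, ...)
    else
      posterior_T_alternative(h$times, h$values, arm, t_LM, km,
                              fit_lt, fit_survivor, ...)
    predictive_survival(d, t_hor, subject_id = id)
  })
  do.call(rbind, out)
}
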