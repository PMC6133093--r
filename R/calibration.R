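#' Build a landmark dataset with administrative censoring
#'
#' One row per subject still at risk at `t_LM`, carrying the predicted
#' cumulative hazard, the exposure inside the window `(t_LM, t_hor]`
#' (administratively censored at `t_hor`) and the window event indicator.
#' Subjects censored inside the window contribute exposure up to their
#' censoring time with `event = FALSE`.
#'
#' @param cohort A `revival_cohort`.
#' @param predictions Data frame with columns `subject_id` and `H_pred`
#'   (see [predict_landmark]); must cover every at-risk subject.
#' @param t_LM Landmark time (years).
#' @param t_hor Horizon time, `> t_LM`.
#' @return Data frame with columns `subject_id`, `H_pred`, `exposure`,
#'   `event`.
#' @export
build_landmark <- function(cohort, predictions, t_LM, t_hor) {
  if (t_hor <= t_LM) stop("'t_hor' must exceed 't_LM'", call. = FALSE)
  sv <- cohort$survival
  at_risk <- sv[sv$time > t_LM, ]
  miss <- setdiff(at_risk$id, predictions$subject_id)
  if (length(miss))
    stop("missing predictions for at-risk subjects: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  idx <- match(at_risk$id, predictions$subject_id)
  exposure <- pmin(at_risk$time, t_hor) - t_LM
  event <- at_risk$status == 1 & at_risk$time <= t_hor
  data.frame(subject_id = at_risk$id,
             H_pred = predictions$H_pred[idx],
             exposure = exposure, event = event)
}

#' Simple rate-factor calibration
#'
#' One-parameter calibration of the marginal survival inside a landmark
#' window: the model `lambda_cal = c * lambda_ref` fitted to the window
#' deaths and exposure. The maximum-likelihood estimate is
#' `c_hat = deaths / (lambda_ref * total exposure)` with standard error
#' `c_hat / sqrt(deaths)` (exponential-rate asymptotics). A perfectly
#' calibrated marginal gives `c = 1`.
#'
#' @param rows Landmark data frame (see [build_landmark]).
#' @param lambda_ref Reference hazard rate (events per year), e.g. the
#'   marginal `lambda0` of the standard model or the KM-implied window
#'   rate of the alternative model.
#' @return List with `c_hat`, `c_se`, `deaths`, `exposure`.
#' @examples
#' rows <- data.frame(subject_id = 1:3, H_pred = 0.3,
#'                    exposure = c(2, 1, 0.5), event = c(TRUE, TRUE, FALSE))
#' simple_calibration(rows, lambda_ref = 0.164)
#' @export
simple_calibration <- function(rows, lambda_ref) {
  if (lambda_ref <= 0) stop("'lambda_ref' must be positive", call. = FALSE)
  E <- sum(rows$exposure)
  if (E <= 0) stop("total exposure is zero", call. = FALSE)
  D <- sum(rows$event)
  c_hat <- D / (lambda_ref * E)
  list(c_hat = c_hat,
       c_se = if (D > 0) c_hat / sqrt(D) else Inf,
       deaths = D, exposure = E)
}

#' Exponential calibration regression of the predicted cumulative hazard
#'
#' Fits `ln(lambda(t | H_pred)) = alpha_c + beta_c * ln(H_pred)` to a
#' landmark dataset by maximizing the censored-exponential likelihood —
#' equivalently a Poisson regression of the window event count with
#' `ln(exposure)` offset. For a 2-year window, perfect calibration of the
#' predicted conditional survival corresponds to `beta_c = 1` and
#' `alpha_c = ln(0.5) = -0.69` (the constant hazard recovering
#' `H_pred` over 2 years).
#'
#' Rows with `H_pred` numerically zero are dropped (the model is undefined
#' there); the count of dropped rows is returned.
#'
#' @param rows Landmark data frame (see [build_landmark]).
#' @return List with `alpha_hat`, `alpha_se`, `beta_hat`, `beta_se`,
#'   `z` (`beta_hat / beta_se`), `n_dropped`.
#' @export
exp_calibration <- function(rows) {
  drop0 <- rows$H_pred <= .Machine$double.eps
  n_dropped <- sum(drop0)
  rows <- rows[!drop0, , drop = FALSE]
  if (sum(rows$event) < 1) stop("no events in the window", call. = FALSE)
  x <- log(rows$H_pred)
  if (length(unique(x)) < 2L)
    stop("ln(H_pred) is constant: calibration slope not identifiable",
         call. = FALSE)
  fit <- stats::glm(event ~ x, offset = log(exposure),
                    family = stats::poisson(),
                    data = transform(rows, event = as.integer(event)))
  cf <- stats::coef(summary(fit))
  list(alpha_hat = cf[1L, 1L], alpha_se = cf[1L, 2L],
       beta_hat = cf[2L, 1L], beta_se = cf[2L, 2L],
       z = cf[2L, 1L] / cf[2L, 2L], n_dropped = n_dropped)
}

#' Cox proportional-hazards calibration
#'
#' Semi-parametric counterpart of [exp_calibration]: a Cox model with the
#' single covariate `ln(H_pred)`, fitted to the window survival times
#' (Breslow tie handling). Its slope is comparable to the exponential
#' calibration slope but leaves the baseline hazard free.
#'
#' @param rows Landmark data frame (see [build_landmark]).
#' @return List with `beta_cox`, `beta_cox_se`, `z`, `n_dropped`.
#' @export
cox_calibration <- function(rows) {
  drop0 <- rows$H_pred <= .Machine$double.eps
  n_dropped <- sum(drop0)
  rows <- rows[!drop0, , drop = FALSE]
  if (sum(rows$event) < 1) stop("no events in the window", call. = FALSE)
  x <- log(rows$H_pred)
  if (length(unique(x)) < 2L)
    stop("ln(H_pred) is constant: calibration slope not identifiable",
         call. = FALSE)
  fit <- survival::coxph(
    survival::Surv(rows$exposure, as.integer(rows$event)) ~ x,
    ties = "breslow")
  if (!is.finite(fit$coefficients) || sqrt(diag(fit$var)) > 50)
    stop("monotone partial likelihood: Cox calibration did not converge",
         call. = FALSE)
  list(beta_cox = unname(fit$coefficients),
       beta_cox_se = unname(sqrt(diag(fit$var))),
       z = unname(fit$coefficients / sqrt(diag(fit$var))),
       n_dropped = n_dropped)
}

#' Landmark calibration table
#'
#' Runs the whole landmark validation for a sequence of landmark times:
#' dynamic predictions for every at-risk subject, administrative censoring
#' at `t_LM + window`, simple rate-factor calibration, exponential
#' calibration regression and Cox calibration. For the standard model the
#' simple calibration is referenced against the exponential marginal rate
#' `lambda0`; for the alternative model against the KM-implied window rate
#' (model-free, so `c` hovers near 1 by construction).
#'
#' Per-landmark failures (e.g. no events in a window) are recorded as `NA`
#' rows, not raised.
#'
#' @param cohort A `revival_cohort`.
#' @param model `"standard"` or `"alternative"`.
#' @param landmarks Landmark times `t_LM` (years).
#' @param window Horizon offset: `t_hor = t_LM + window`.
#' @param params [revival_params] or `revival_fit` (standard model).
#' @param km,fit_lt,fit_survivor Alternative-model inputs (see
#'   [posterior_T_alternative]); `km` defaults to the cohort's own
#'   Kaplan-Meier at `t_lim`.
#' @param t_lim Observation limit for the alternative model.
#' @param ... Passed to the posterior constructors.
#' @return A data frame of class `calibration_table`: one row per
#'   landmark with columns `t_LM`, `n`, `deaths`, `c_hat`, `c_se`,
#'   `hpred_mean`, `hpred_sd`, `alpha_hat`, `alpha_se`, `beta_hat`,
#'   `beta_se`, `beta_cox`, `beta_cox_se`, `z_exp`, `z_cox`.
#' @export
calibration_table <- function(cohort, model = c("standard", "alternative"),
                              landmarks = 1:7, window = 2,
                              params = NULL, km = NULL, fit_lt = NULL,
                              fit_survivor = NULL, t_lim = 9, ...) {
  model <- match.arg(model)
  if (!length(landmarks)) stop("'landmarks' is empty", call. = FALSE)
  if (model == "alternative" && is.null(km))
    km <- km_marginal(cohort, t_lim)
  rows <- lapply(landmarks, function(t_LM) {
    t_hor <- t_LM + window
    out <- data.frame(t_LM = t_LM, n = NA_integer_, deaths = NA_integer_,
                      c_hat = NA_real_, c_se = NA_real_,
                      hpred_mean = NA_real_, hpred_sd = NA_real_,
                      alpha_hat = NA_real_, alpha_se = NA_real_,
                      beta_hat = NA_real_, beta_se = NA_real_,
                      beta_cox = NA_real_, beta_cox_se = NA_real_,
                      z_exp = NA_real_, z_cox = NA_real_)
    res <- tryCatch({
      preds <- predict_landmark(cohort, t_LM, t_hor, model = model,
                                params = params, km = km, fit_lt = fit_lt,
                                fit_survivor = fit_survivor, ...)
      lm_rows <- build_landmark(cohort, preds, t_LM, t_hor)
      lambda_ref <- if (model == "standard")
        as_revival_params(params)$lambda0
      else {
        s_ratio <- .km_surv_at(km, t_hor) / .km_surv_at(km, t_LM)
        -log(s_ratio) / window
      }
      sc <- simple_calibration(lm_rows, lambda_ref)
      out$n <- nrow(lm_rows); out$deaths <- sc$deaths
      out$c_hat <- sc$c_hat; out$c_se <- sc$c_se
      out$hpred_mean <- mean(lm_rows$H_pred)
      out$hpred_sd <- stats::sd(lm_rows$H_pred)
      ec <- exp_calibration(lm_rows)
      out$alpha_hat <- ec$alpha_hat; out$alpha_se <- ec$alpha_se
      out$beta_hat <- ec$beta_hat; out$beta_se <- ec$beta_se
      out$z_exp <- ec$z
      cc <- cox_calibration(lm_rows)
      out$beta_cox <- cc$beta_cox; out$beta_cox_se <- cc$beta_cox_se
      out$z_cox <- cc$z
      out
    }, error = function(e) {
      warning("landmark t_LM = ", t_LM, ": ", conditionMessage(e),
              call. = FALSE)
      out
    })
    res
  })
  out <- do.call(rbind, rows)
  attr(out, "model") <- model
  attr(out, "window") <- window
  class(out) <- c("calibration_table", "data.frame")
  out
}

#' @export
print.calibration_table <- function(x, digits = 3, ...) {
  cat("Landmark calibration (", attr(x, "model"), " model, window ",
      attr(x, "window"), " years)\n", sep = "")
  cat("perfect calibration reference: beta = 1, alpha = ln(1/window)\n")
  print.data.frame(round_df(x, digits), row.names = FALSE)
  invisible(x)
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}
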