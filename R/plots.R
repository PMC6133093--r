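#' Cohort overview plot
#'
#' Two diagnostic panels. Left: Kaplan-Meier estimates of the survival and
#' censoring distributions, the exponential survival curve at the
#' configured marginal rate, and the fraction still at risk; annotated with
#' the number of subjects at risk at the observation limit and how many of
#' them are censored there or later. Right: per-subject time of the last
#' biomarker measurement against the end of follow-up (subjects ordered by
#' follow-up time), with the 45-degree reference line; the horizontal gap
#' shows how long survival is still observed after the biomarker goes
#' silent.
#'
#' @param cohort A `revival_cohort`.
#' @param lambda0 Marginal rate for the exponential overlay; defaults to
#'   the cohort configuration's value.
#' @param t_lim Observation limit for the annotation; defaults likewise.
#' @return Invisibly, a list with the at-risk and censored counts at
#'   `t_lim`.
#' @export
plot_cohort_overview <- function(cohort, lambda0 = NULL, t_lim = NULL) {
  sv <- cohort$survival
  if (!nrow(sv)) stop("empty cohort", call. = FALSE)
  if (is.null(lambda0))
    lambda0 <- if (!is.null(cohort$config)) cohort$config$params$lambda0
               else 0.164
  if (is.null(t_lim))
    t_lim <- if (!is.null(cohort$config)) cohort$config$t_lim else 9

  n_at_lim <- sum(sv$time >= t_lim)
  n_cens_at_lim <- sum(sv$time >= t_lim & sv$status == 0)

  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))

  km_surv <- survival::survfit(survival::Surv(time, status) ~ 1, data = sv)
  km_cens <- survival::survfit(survival::Surv(time, 1 - status) ~ 1,
                               data = sv)
  tmax <- max(sv$time)
  plot(km_surv, conf.int = FALSE, xlab = "years", ylab = "probability",
       main = "survival, censoring, at risk", col = 1, xlim = c(0, tmax))
  graphics::lines(km_cens, conf.int = FALSE, col = 2)
  curve(exp(-lambda0 * x), from = 0, to = tmax, add = TRUE,
        col = 1, lty = 3)
  tt <- sort(unique(sv$time))
  at_risk <- vapply(tt, function(u) mean(sv$time >= u), numeric(1))
  graphics::lines(tt, at_risk, type = "s", col = 4)
  graphics::abline(v = t_lim, lty = 2, col = "grey")
  graphics::legend("topright", bty = "n", cex = 0.8,
                   col = c(1, 1, 2, 4), lty = c(1, 3, 1, 1),
                   legend = c("KM survival", "exponential fit",
                              "KM censoring", "fraction at risk"))
  graphics::mtext(sprintf("at risk at t=%g: %d (censored: %d)",
                          t_lim, n_at_lim, n_cens_at_lim),
                  side = 3, line = 0, cex = 0.7)

  lg <- cohort$longitudinal
  last_meas <- tapply(lg$time, lg$id, max)
  ord <- order(sv$time)
  ids <- sv$id[ord]
  lm_t <- unname(last_meas[as.character(ids)])
  ypos <- seq_along(ids)
  plot(sv$time[ord], ypos, pch = 16, cex = 0.4, col = 4,
       xlab = "years", ylab = "subject (ordered by follow-up)",
       main = "last measurement vs follow-up end")
  graphics::points(lm_t, ypos, pch = 1, cex = 0.4, col = 2)
  graphics::legend("bottomright", bty = "n", cex = 0.8, pch = c(16, 1),
                   col = c(4, 2),
                   legend = c("follow-up end", "last measurement"))
  invisible(list(n_at_risk_tlim = n_at_lim, n_censored_tlim = n_cens_at_lim))
}

#' Revival mean curves in follow-up time
#'
#' Expected biomarker trajectories `mu(T - t)` plotted against follow-up
#' time `t` for a set of survival times, in the style used to judge how
#' much a biomarker history can say about the death time: solid curves for
#' the treatment-corrected ("null treatment") mean, and dotted
#' `+/- 2 sd` tolerance limits showing the variance budget.
#'
#' @param params A [revival_params] or `revival_fit`.
#' @param T_values Survival times to draw curves for.
#' @param arm Arm for the (optional) arm-specific curves; the solid curves
#'   are always the null-treatment mean.
#' @param band Draw the tolerance band around the largest-`T` curve?
#' @param n_points Points per curve.
#' @return Invisibly, `NULL`.
#' @export
plot_revival_curves <- function(params, T_values = 1:9,
                                arm = c("control", "prednisone"),
                                band = TRUE, n_points = 200) {
  arm <- match.arg(arm)
  params <- as_revival_params(params)
  half <- 2 * sqrt(total_variance(params))
  Tmax <- max(T_values)
  tg <- seq(0, Tmax - 1e-3, length.out = n_points)
  mu_all <- lapply(T_values, function(Tv) {
    t_i <- tg[tg < Tv]
    cbind(t_i, null_treatment_mean(Tv - t_i, Tv, params))
  })
  rng <- range(unlist(lapply(mu_all, function(m) m[, 2])))
  if (band) rng <- rng + c(-half, half)
  plot(NA, xlim = c(0, Tmax), ylim = rng, xlab = "follow-up time t (years)",
       ylab = "expected biomarker level",
       main = "revival mean in follow-up time")
  for (m in mu_all) graphics::lines(m[, 1], m[, 2], col = 1)
  if (band) {
    m <- mu_all[[which.max(T_values)]]
    graphics::lines(m[, 1], m[, 2] + half, lty = 3)
    graphics::lines(m[, 1], m[, 2] - half, lty = 3)
  }
  invisible(NULL)
}

#' @export
plot.revival_fit <- function(x, ...) plot_revival_curves(x, ...)

#' @export
plot.revival_profile <- function(x, ...) {
  plot(x$T_grid, x$ll, type = "l", xlab = "candidate survival time T",
       ylab = "log-likelihood",
       main = sprintf("profile ll(T), t_LM = %g", x$t_LM), ...)
  graphics::abline(v = x$T_max, lty = 2)
  invisible(x)
}

#' @export
plot.predictive_dist <- function(x, ...) {
  plot(x$support, x$weights, type = "h",
       xlab = "survival time T", ylab = "posterior mass",
       main = sprintf("predictive distribution (%s), t_LM = %g",
                      x$model, x$t_LM), ...)
  if (x$model == "alternative" && x$atom_mass > 0)
    graphics::points(x$t_lim, x$atom_mass, pch = 17)
  invisible(x)
}
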