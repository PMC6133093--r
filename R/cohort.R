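#' Cohort-generation configuration
#'
#' Settings for the synthetic trial cohort: marginal survival, arm
#' allocation, a censoring model with heavy early censoring, a visit
#' schedule with imperfect attendance, and the observation limit.
#'
#' The default censoring model is a two-component mixture: with probability
#' `w_early` the censoring time is uniform on (0, 2) years, otherwise uniform
#' on (0, 10) years. This reproduces a high early-censoring rate without
#' committing to a fitted censoring distribution. The default visit schedule
#' is baseline, 3 and 6 months, then yearly through year 9, each visit
#' attended independently with probability `p_attend`. Visits are realized
#' strictly before the end of follow-up; the measurement at the death time
#' itself is never observed.
#'
#' @param n_subjects Number of subjects (positive integer).
#' @param p_prednisone Probability of allocation to the prednisone arm.
#' @param censoring `"mixture"` (the early/late uniform mixture), `"none"`
#'   (no loss to follow-up; administrative censoring at `t_lim` still
#'   applies downstream where requested), or `"uniform"` on
#'   `(0, cens_max)`.
#' @param w_early Mixture weight of the early uniform(0, 2) component.
#' @param cens_max Upper end (years) of the late/uniform component.
#' @param visit_times Strictly increasing planned visit times (years),
#'   starting at 0.
#' @param p_attend Per-visit attendance probability in `[0, 1]`.
#' @param t_lim Observation limit (years): the last time with meaningful
#'   follow-up support.
#' @param params A [revival_params] object: the data-generating truth.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 500,
                          p_prednisone = 0.5,
                          censoring = c("mixture", "none", "uniform"),
                          w_early = 0.3,
                          cens_max = 10,
                          visit_times = c(0, 0.25, 0.5, 1:9),
                          p_attend = 0.9,
                          t_lim = 9,
                          params = revival_params()) {
  censoring <- match.arg(censoring)
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L ||
      n_subjects < 1 || n_subjects != round(n_subjects))
    stop("'n_subjects' must be a positive integer", call. = FALSE)
  if (p_prednisone < 0 || p_prednisone > 1)
    stop("'p_prednisone' must lie in [0, 1]", call. = FALSE)
  if (length(visit_times) < 1L || visit_times[1L] != 0 ||
      any(diff(visit_times) <= 0))
    stop("'visit_times' must be strictly increasing and start at 0",
         call. = FALSE)
  if (p_attend < 0 || p_attend > 1)
    stop("'p_attend' must lie in [0, 1]", call. = FALSE)
  if (t_lim <= 0) stop("'t_lim' must be positive", call. = FALSE)
  if (w_early < 0 || w_early > 1)
    stop("'w_early' must lie in [0, 1]", call. = FALSE)
  if (max(visit_times) > t_lim)
    message("visit schedule extends beyond the observation limit t_lim")
  structure(list(n_subjects = as.integer(n_subjects),
                 p_prednisone = p_prednisone, censoring = censoring,
                 w_early = w_early, cens_max = cens_max,
                 visit_times = visit_times, p_attend = p_attend,
                 t_lim = t_lim, params = as_revival_params(params)),
            class = "cohort_config")
}

.draw_censoring <- function(config, n) {
  switch(config$censoring,
         none = rep(Inf, n),
         uniform = stats::runif(n, 0, config$cens_max),
         mixture = ifelse(stats::runif(n) < config$w_early,
                          stats::runif(n, 0, 2),
                          stats::runif(n, 0, config$cens_max)))
}

#' Simulate a synthetic joint longitudinal-survival cohort
#'
#' Draws death times from the exponential marginal, censoring times from the
#' configured censoring model (independently of death), allocates arms, and
#' realizes biomarker measurements at attended visits strictly before the end
#' of follow-up. Each measurement at follow-up time `t` is
#' `revival_mean(T - t, T, arm) + b_i + W_i(T - t) + e`, with the true
#' (possibly unobserved) death time `T` driving the revival clock.
#'
#' Identical `(config, seed)` pairs yield identical cohorts.
#'
#' @param config A [cohort_config].
#' @param seed Integer seed; set for reproducibility of the whole cohort.
#' @return An object of class `revival_cohort`: a list with
#'   \describe{
#'     \item{survival}{one row per subject: `id`, `arm`, `time` (observed
#'       follow-up end), `status` (1 = death, 0 = censored), `T_true`,
#'       `C` (latent times, retained because the generator knows them).}
#'     \item{longitudinal}{one row per measurement: `id`, `time`, `value`.}
#'     \item{config}{the generating configuration.}
#'   }
#' @examples
#' coh <- simulate_cohort(cohort_config(n_subjects = 50), seed = 1)
#' coh
#' @export
simulate_cohort <- function(config = cohort_config(), seed = NULL) {
  if (!inherits(config, "cohort_config"))
    stop("'config' must be a cohort_config object", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- config$params
  n <- config$n_subjects

  T_true <- stats::rexp(n, rate = p$lambda0)
  arm <- ifelse(stats::runif(n) < config$p_prednisone, "prednisone", "control")
  C <- .draw_censoring(config, n)
  time <- pmin(T_true, C)
  status <- as.integer(T_true <= C)

  long <- vector("list", n)
  sd_e <- sqrt(p$sigma2_e)
  for (i in seq_len(n)) {
    vt <- config$visit_times[config$visit_times < time[i]]
    if (length(vt) && config$p_attend < 1)
      vt <- vt[stats::runif(length(vt)) < config$p_attend]
    if (!length(vt)) next
    s <- T_true[i] - vt
    mu <- revival_mean(s, T_true[i], arm[i], p)
    b <- stats::rnorm(1L, 0, sqrt(p$sigma2_b))
    if (p$sigma2_w > 0) {
      d <- abs(outer(s, s, "-"))
      W <- drop(crossprod(chol(p$sigma2_w * exp(-d / p$phi) +
                                 diag(1e-10, length(s))),
                          stats::rnorm(length(s))))
    } else W <- 0
    y <- mu + b + W + stats::rnorm(length(s), 0, sd_e)
    long[[i]] <- data.frame(id = i, time = vt, value = y)
  }
  long <- if (any(lengths(long) > 0)) do.call(rbind, long) else
    data.frame(id = integer(), time = numeric(), value = numeric())
  rownames(long) <- NULL

  structure(list(
    survival = data.frame(id = seq_len(n), arm = arm, time = time,
                          status = status, T_true = T_true, C = C),
    longitudinal = long,
    config = config), class = "revival_cohort")
}

#' @export
print.revival_cohort <- function(x, ...) {
  sv <- x$survival
  cat("Synthetic revival cohort:", nrow(sv), "subjects,",
      nrow(x$longitudinal), "measurements\n")
  cat("  deaths:", sum(sv$status), " censored:", sum(1 - sv$status),
      " prednisone:", sum(sv$arm == "prednisone"), "\n")
  cat("  follow-up: median", format(stats::median(sv$time), digits = 3),
      "years, max", format(max(sv$time), digits = 3), "years\n")
  invisible(x)
}

#' Export a cohort to plain-text tables
#'
#' Writes the observable part of a cohort as two CSV files: a survival table
#' (`id,time,status,arm`; status 1 = death, 0 = censored) and a longitudinal
#' table (`id,time,value`). Latent quantities (`T_true`, `C`) are not
#' exported.
#'
#' @param cohort A `revival_cohort`.
#' @param survival_file,longitudinal_file Output paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, survival_file, longitudinal_file) {
  if (!inherits(cohort, "revival_cohort") || nrow(cohort$survival) == 0L)
    stop("'cohort' must be a non-empty revival_cohort", call. = FALSE)
  sv <- cohort$survival[, c("id", "time", "status", "arm")]
  utils::write.csv(sv, survival_file, row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$longitudinal, longitudinal_file,
                   row.names = FALSE, quote = FALSE)
  invisible(c(survival_file, longitudinal_file))
}

#' Import a cohort from plain-text tables
#'
#' Reads the two CSV files written by [write_cohort]. The latent death and
#' censoring times are unknown for imported data; `T_true` is set to the
#' observed time for deaths and `NA` otherwise.
#'
#' @param survival_file,longitudinal_file Paths to the two CSV tables.
#' @param config Optional [cohort_config] to attach.
#' @return A `revival_cohort`.
#' @export
read_cohort <- function(survival_file, longitudinal_file, config = NULL) {
  sv <- utils::read.csv(survival_file, stringsAsFactors = FALSE)
  lg <- utils::read.csv(longitudinal_file, stringsAsFactors = FALSE)
  need <- c("id", "time", "status", "arm")
  if (!all(need %in% names(sv)))
    stop("survival table must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  if (!all(c("id", "time", "value") %in% names(lg)))
    stop("longitudinal table must have columns id,time,value", call. = FALSE)
  if (anyDuplicated(sv$id)) stop("duplicate subject ids", call. = FALSE)
  sv$T_true <- ifelse(sv$status == 1, sv$time, NA_real_)
  sv$C <- ifelse(sv$status == 0, sv$time, NA_real_)
  structure(list(survival = sv[, c("id", "arm", "time", "status",
                                   "T_true", "C")],
                 longitudinal = lg, config = config),
            class = "revival_cohort")
}

# Measurement history of one subject up to (and including) a cutoff time.
.subject_history <- function(cohort, id, up_to = Inf) {
  lg <- cohort$longitudinal
  rows <- lg$id == id & lg$time <= up_to
  list(times = lg$time[rows], values = lg$value[rows])
}
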