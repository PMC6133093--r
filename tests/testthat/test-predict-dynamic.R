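test_that("with no data the standard posterior is exactly memoryless", {
  p <- ref_params()
  d <- posterior_T_standard(numeric(0), numeric(0), "control", t_LM = 2,
                            params = p)
  expect_equal(sum(d$weights), 1, tolerance = 1e-8)
  res <- predictive_survival(d, t_hor = 4)
  expect_equal(res$H_pred, p$lambda0 * 2, tolerance = 1e-12)
  expect_equal(res$p_surv, exp(-p$lambda0 * 2), tolerance = 1e-12)
  # no window, no hazard
  tiny <- predictive_survival(d, t_hor = 2.02)
  expect_equal(tiny$H_pred, p$lambda0 * 0.02, tolerance = 1e-12)
  # H_pred nondecreasing in the horizon
  hs <- vapply(c(2.5, 3, 4, 6, 9), function(th)
    predictive_survival(d, th)$H_pred, numeric(1))
  expect_true(all(diff(hs) > 0))
})

test_that("the standard posterior matches an independent normalization oracle", {
  p <- ref_params()
  tt <- 1.5; yy <- 55; arm <- "prednisone"; t_LM <- 2
  d <- posterior_T_standard(tt, yy, arm, t_LM, p)
  # same-grid direct computation without log-space machinery
  lik <- vapply(d$support[-length(d$support)], function(Tv)
    exp(history_loglik(tt, yy, arm, Tv, p)), numeric(1))
  prior <- exp(-p$lambda0 * (d$lower - t_LM))
  prior_inc <- c(-diff(prior), exp(-p$lambda0 * 60))
  w_direct <- prior_inc * c(lik, lik[length(lik)])
  w_direct <- w_direct / sum(w_direct)
  expect_lt(0.5 * sum(abs(w_direct - d$weights)), 1e-10)
  # fine-grid brute force for the survival mass
  fine <- seq(t_LM, t_LM + 80, by = 0.002)
  mid <- fine[-1] - 0.001
  dens <- exp(vapply(mid, function(Tv)
    history_loglik(tt, yy, arm, Tv, p), numeric(1)) +
      dexp(mid, p$lambda0, log = TRUE))
  mass <- dens * diff(fine)
  oracle_psurv <- sum(mass[mid > 4]) / sum(mass)
  expect_equal(predictive_survival(d, 4)$p_surv, oracle_psurv,
               tolerance = 1e-4)
})

test_that("a low biomarker value near the landmark pulls the posterior toward early death", {
  p <- ref_params()
  base <- posterior_T_standard(numeric(0), numeric(0), "control", 2, p)
  low <- posterior_T_standard(2, 20, "control", 2, p)
  expect_lt(predictive_survival(low, 4)$p_surv,
            predictive_survival(base, 4)$p_surv)
  hi <- posterior_T_standard(2, 120, "control", 2, p)
  expect_gt(predictive_survival(hi, 4)$p_surv,
            predictive_survival(base, 4)$p_surv)
})

test_that("the Kaplan-Meier marginal matches hand product-limit calculations", {
  # deaths at 1 and 3, censoring at 2
  coh <- manual_cohort(time = c(1, 2, 3), status = c(1, 0, 1))
  km <- km_marginal(coh, t_lim = 9)
  expect_equal(km$time, c(1, 3))
  expect_equal(km$surv, c(2 / 3, 0))
  expect_equal(km$residual, 0)
  # no censoring: complement of the ECDF
  set.seed(3)
  tt <- sort(rexp(40, 0.3))
  coh2 <- manual_cohort(time = tt, status = rep(1, 40))
  km2 <- km_marginal(coh2, t_lim = max(tt) + 1)
  expect_equal(km2$surv, 1 - seq_along(tt) / 40)
  expect_true(all(diff(km2$surv) <= 0))
  # administrative censoring at t_lim removes later events
  coh3 <- manual_cohort(time = c(1, 10), status = c(1, 1))
  km3 <- km_marginal(coh3, t_lim = 9)
  expect_equal(km3$time, 1)
  expect_equal(km3$residual, 0.5)
})

test_that("the alternative posterior reduces to the KM prior when the history is empty", {
  coh <- small_cohort()
  km <- km_marginal(coh, 9)
  p <- ref_params()
  d <- posterior_T_alternative(numeric(0), numeric(0), "control", 2,
                               km, p, p)
  expect_equal(sum(d$weights) + d$atom_mass, 1, tolerance = 1e-8)
  # weights proportional to the KM increments above the landmark
  s2 <- d$weights[1] # first increment after t_LM
  jumps <- km$time[km$time > 2 & km$time < 9]
  incr <- -diff(c(km$surv[max(which(km$time <= 2))], km$surv[km$time > 2 &
                                                               km$time < 9]))
  expect_equal(d$weights / sum(c(d$weights, d$atom_mass)),
               incr / (sum(incr) + km$residual), tolerance = 1e-10)
  expect_equal(d$atom_mass, km$residual / (sum(incr) + km$residual),
               tolerance = 1e-10)
})

test_that("the alternative posterior matches exact enumeration on its discrete support", {
  coh <- small_cohort()
  km <- km_marginal(coh, 9)
  p_lt <- ref_params()
  p_sv <- revival_params(beta_const = 75, beta_T = 1.4, beta_log = -0.2)
  tt <- c(0.5, 1.5); yy <- c(65, 58); arm <- "prednisone"; t_LM <- 2
  d <- posterior_T_alternative(tt, yy, arm, t_LM, km, p_lt, p_sv)
  # enumeration oracle over the finite support
  jumps <- km$time[km$time > t_LM & km$time < 9]
  sprev <- km$surv[max(which(km$time <= t_LM))]
  incr <- -diff(c(sprev, km$surv[km$time > t_LM & km$time < 9]))
  w <- vapply(seq_along(jumps), function(j)
    incr[j] * exp(history_loglik(tt, yy, arm, jumps[j], p_lt)), numeric(1))
  s <- 9 - tt
  atom <- km$residual * exp(dmvnorm_bruteforce(
    yy, revival_mean(s, 9, arm, p_sv), revival_covariance(s, p_sv)))
  tot <- sum(w) + atom
  expect_equal(d$weights, w / tot, tolerance = 1e-10)
  expect_equal(d$atom_mass, atom / tot, tolerance = 1e-10)
  # no support beyond the observation limit: the model never evaluates a
  # death time past t_lim
  expect_true(all(d$support <= 9))
  expect_true(all(d$support > t_LM))
})

test_that("degenerate KM support collapses the alternative posterior onto the atom", {
  coh <- manual_cohort(time = c(10, 11, 12), status = c(1, 1, 0))
  km <- suppressWarnings(km_marginal(coh, t_lim = 9))
  p <- ref_params()
  d <- posterior_T_alternative(numeric(0), numeric(0), "control", 2, km, p, p)
  expect_equal(d$atom_mass, 1)
  res <- predictive_survival(d, t_hor = 4)
  expect_equal(res$p_surv, 1)
  expect_equal(res$H_pred, 0)
  expect_error(predictive_survival(d, t_hor = 10), "beyond t_lim")
})

test_that("self-simulated predictions are calibrated in the large", {
  coh <- simulate_cohort(cohort_config(n_subjects = 1200), seed = 77)
  p <- coh$config$params
  preds <- predict_landmark(coh, 2, 4, model = "standard", params = p)
  rows <- build_landmark(coh, preds, 2, 4)
  # among at-risk subjects whose window outcome is observed (not censored
  # inside the window), the observed survival fraction matches the mean
  # predicted conditional survival
  sv <- coh$survival
  resolved <- sv[sv$time > 2 & !(sv$status == 0 & sv$time < 4), ]
  obs_surv <- mean(resolved$time > 4)
  expect_equal(mean(exp(-rows$H_pred[match(resolved$id, rows$subject_id)])),
               obs_surv, tolerance = 0.05)
})
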