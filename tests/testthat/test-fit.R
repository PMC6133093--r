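test_that("near-noiseless data recover the mean coefficients almost exactly", {
  truth <- revival_params(beta_control = 0, sigma2_b = 1e-4,
                          sigma2_w = 1e-4, sigma2_e = 1e-4)
  cfg <- cohort_config(n_subjects = 150, params = truth)
  coh <- simulate_cohort(cfg, seed = 12)
  fit <- fit_revival(coh, "all_uncensored", params = truth)
  cf <- coef(fit)
  expect_equal(unname(cf["const"]), truth$beta_const, tolerance = 1e-2)
  expect_equal(unname(cf["prednisone"]), truth$beta_prednisone,
               tolerance = 1e-2)
  expect_equal(unname(cf["T"]), truth$beta_T, tolerance = 1e-2)
  expect_equal(unname(cf["s"]), truth$beta_s, tolerance = 1e-2)
  expect_equal(unname(cf["log(s+delta)"]), truth$beta_log, tolerance = 1e-2)
})

test_that("replicate refits recover the generating truth without bias", {
  # estimable functions of the generator truth: control-arm level and
  # prednisone-control contrast (the three-way constant/arm split is not
  # identifiable from data)
  cfg <- cohort_config(n_subjects = 2000)
  p <- cfg$params
  truth <- c(const = p$beta_const + p$beta_control,
             prednisone = p$beta_prednisone - p$beta_control,
             T = p$beta_T, s = p$beta_s, `log(s+delta)` = p$beta_log)
  reps <- 20
  est <- matrix(NA_real_, reps, 5)
  for (r in seq_len(reps)) {
    coh <- simulate_cohort(cfg, seed = 7000 + r)
    est[r, ] <- coef(fit_revival(coh, "all_uncensored"))
  }
  bias <- colMeans(est) - truth
  mcse <- apply(est, 2, sd) / sqrt(reps)
  expect_true(all(abs(bias) < 2 * mcse + 1e-9),
              info = paste("bias/mcse:", paste(round(bias / mcse, 2),
                                               collapse = " ")))
})

test_that("subset selection and failure modes behave as specified", {
  coh <- simulate_cohort(cohort_config(n_subjects = 400,
                                       censoring = "uniform",
                                       cens_max = 30), seed = 61)
  f_all <- fit_revival(coh, "all_uncensored")
  f_lt <- fit_revival(coh, "uncensored_lt_tlim", t_lim = 9)
  f_sv <- fit_revival(coh, "survivors_ge_tlim", t_lim = 9)
  sv <- coh$survival
  expect_lte(f_lt$n_subjects, sum(sv$status == 1 & sv$time < 9))
  expect_lte(f_sv$n_subjects, sum(sv$time >= 9))
  expect_identical(f_sv$survivor_T_proxy, "followup_end")
  # no subject reaches t_lim -> empty survivor subset
  cfg_short <- cohort_config(n_subjects = 50, censoring = "uniform",
                             cens_max = 2)
  coh_short <- simulate_cohort(cfg_short, seed = 4)
  expect_error(fit_revival(coh_short, "survivors_ge_tlim", t_lim = 9),
               "empty")
  # one arm absent -> singular design named after the missing coefficient
  cfg_1arm <- cohort_config(n_subjects = 50, p_prednisone = 0)
  coh_1arm <- simulate_cohort(cfg_1arm, seed = 4)
  expect_error(fit_revival(coh_1arm, "all_uncensored"), "prednisone")
})

test_that("fit methods expose the usual modelling surface", {
  coh <- small_cohort()
  fit <- fit_revival(coh, "all_uncensored")
  expect_s3_class(fit, "revival_fit")
  expect_length(coef(fit), 5)
  expect_equal(dim(vcov(fit)), c(5L, 5L))
  expect_equal(unname(sqrt(diag(vcov(fit)))), unname(fit$standard_errors))
  expect_s3_class(summary(fit), "summary.revival_fit")
  expect_output(print(fit), "Revival model fit")
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  # predict agrees with the mean function under the fitted parameters
  nd <- data.frame(s = c(0.5, 2), T = c(4, 7),
                   arm = c("control", "prednisone"))
  pr <- predict(fit, nd)
  expect_equal(pr[1], revival_mean(0.5, 4, "control", fit$params))
  expect_equal(pr[2], revival_mean(2, 7, "prednisone", fit$params))
  band <- predict(fit, nd, interval = "tolerance")
  expect_equal(band$upr - band$fit,
               rep(2 * sqrt(total_variance(fit$params)), 2))
  # residuals are centred near zero under the generating model
  rs <- residuals(fit, coh, standardized = TRUE)
  expect_lt(abs(mean(rs)), 0.2)
  # simulate() round-trips through the generator
  sims <- simulate(fit, nsim = 2, seed = 1,
                   config = cohort_config(n_subjects = 30))
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "revival_cohort")
})

test_that("variance components can be estimated jointly", {
  cfg <- cohort_config(n_subjects = 400)
  coh <- simulate_cohort(cfg, seed = 21)
  fit <- fit_revival(coh, "all_uncensored", estimate_variance = TRUE)
  v <- fit$params
  tot <- v$sigma2_b + v$sigma2_w + v$sigma2_e
  expect_equal(tot, 625, tolerance = 0.2)
  expect_gte(fit$loglik,
             fit_revival(coh, "all_uncensored")$loglik - 1e-6)
})
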