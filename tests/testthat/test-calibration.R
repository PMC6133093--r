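test_that("landmark rows apply administrative censoring correctly", {
  coh <- manual_cohort(time = c(3, 7, 2.5, 2), status = c(1, 0, 0, 1))
  preds <- data.frame(subject_id = 1:4, H_pred = c(0.3, 0.2, 0.4, 0.1))
  rows <- build_landmark(coh, preds, t_LM = 2, t_hor = 4)
  expect_identical(rows$subject_id, c(1L, 2L, 3L))  # subject 4 not at risk
  expect_equal(rows$exposure, c(1, 2, 0.5))
  expect_identical(rows$event, c(TRUE, FALSE, FALSE))
  # missing prediction for an at-risk subject is an error
  expect_error(build_landmark(coh, preds[-1, ], 2, 4), "missing predictions")
  expect_error(build_landmark(coh, preds, 4, 4), "exceed")
})

test_that("simple calibration is the exponential-rate MLE", {
  rows <- data.frame(subject_id = 1:10, H_pred = 0.3,
                     exposure = rep(30.49 / 10, 10), event = rep(TRUE, 10))
  sc <- simple_calibration(rows, lambda_ref = 0.164)
  expect_equal(sc$c_hat, 10 / (0.164 * 30.49), tolerance = 1e-12)
  expect_equal(sc$c_se, sc$c_hat / sqrt(10), tolerance = 1e-12)
  expect_equal(round(sc$c_hat, 2), 2)
  expect_equal(round(sc$c_se, 3), 0.632)
  # deaths exactly lambda_ref * exposure -> c = 1
  rows2 <- data.frame(subject_id = 1:5, H_pred = 0.3,
                      exposure = rep(5 / (0.164 * 5), 5),
                      event = rep(TRUE, 5))
  expect_equal(simple_calibration(rows2, 0.164)$c_hat, 1)
  # doubling exposure halves c
  rows3 <- transform(rows, exposure = 2 * exposure)
  expect_equal(simple_calibration(rows3, 0.164)$c_hat, sc$c_hat / 2)
  # zero deaths flagged with infinite se
  rows4 <- transform(rows, event = FALSE)
  sc4 <- simple_calibration(rows4, 0.164)
  expect_equal(sc4$c_hat, 0)
  expect_identical(sc4$c_se, Inf)
  # exact MLE: brute-force 1-D maximization on random instances
  set.seed(14)
  for (i in 1:5) {
    n <- 30
    inst <- data.frame(subject_id = 1:n, H_pred = 0.3,
                       exposure = runif(n, 0.2, 2),
                       event = runif(n) < 0.4)
    if (!any(inst$event)) next
    lref <- runif(1, 0.1, 0.5)
    nll <- function(cc) -(sum(inst$event) * log(cc * lref) -
                            cc * lref * sum(inst$exposure))
    opt <- optimize(nll, c(1e-4, 50))
    expect_equal(simple_calibration(inst, lref)$c_hat, opt$minimum,
                 tolerance = 1e-4)
  }
})

test_that("exponential calibration matches closed forms and a brute-force oracle", {
  # two-group closed form: group A has 2 events over 20 exposure at
  # H = 0.2 (rate 0.1), group B 8 events over 40 exposure at H = 0.4
  # (rate 0.2) -> beta = 1, alpha = ln 0.1 - ln 0.2 = ln 0.5
  rows_b <- data.frame(subject_id = 1:16,
                       H_pred = c(rep(0.2, 8), rep(0.4, 8)),
                       exposure = c(rep(2.5, 8), rep(5, 8)),
                       event = c(rep(TRUE, 2), rep(FALSE, 6),
                                 rep(TRUE, 8)))
  ec <- exp_calibration(rows_b)
  expect_equal(ec$beta_hat, 1, tolerance = 1e-6)
  expect_equal(ec$alpha_hat, log(0.1) - log(0.2), tolerance = 1e-6)
  expect_equal(ec$z, ec$beta_hat / ec$beta_se)
  # scaling all rates by k shifts alpha by ln k, leaves beta alone
  k <- 3
  rows_k <- transform(rows_b, exposure = exposure / k)
  ec_k <- exp_calibration(rows_k)
  expect_equal(ec_k$beta_hat, ec$beta_hat, tolerance = 1e-8)
  expect_equal(ec_k$alpha_hat, ec$alpha_hat + log(k), tolerance = 1e-8)
  # constant H_pred: slope not identifiable
  expect_error(exp_calibration(transform(rows_b, H_pred = 0.3)),
               "not identifiable")
  # brute-force 2-D Newton/grid oracle on a three-level instance
  inst <- data.frame(subject_id = 1:9,
                     H_pred = rep(c(0.1, 0.3, 0.6), each = 3),
                     exposure = rep(c(1.5, 2, 0.8), 3),
                     event = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE,
                               TRUE, TRUE, TRUE))
  nll <- function(th) {
    lam <- exp(th[1] + th[2] * log(inst$H_pred))
    -sum(inst$event * log(lam) - lam * inst$exposure)
  }
  opt <- optim(c(0, 1), nll, method = "BFGS")
  ec3 <- exp_calibration(inst)
  expect_equal(ec3$alpha_hat, opt$par[1], tolerance = 1e-3)
  expect_equal(ec3$beta_hat, opt$par[2], tolerance = 1e-3)
})

test_that("Cox calibration maximizes the written-out partial likelihood", {
  rows <- data.frame(subject_id = 1:4,
                     H_pred = c(0.15, 0.3, 0.5, 0.8),
                     exposure = c(1.2, 0.7, 1.9, 0.4),
                     event = c(TRUE, FALSE, TRUE, TRUE))
  cc <- cox_calibration(rows)
  x <- log(rows$H_pred)
  # brute-force Breslow partial likelihood over the event times
  npl <- function(b) {
    s <- 0
    for (i in which(rows$event)) {
      risk <- rows$exposure >= rows$exposure[i]
      s <- s + b * x[i] - log(sum(exp(b * x[risk])))
    }
    -s
  }
  opt <- optimize(npl, c(-10, 10), tol = 1e-10)
  expect_equal(cc$beta_cox, opt$minimum, tolerance = 1e-6)
  expect_equal(cc$z, cc$beta_cox / cc$beta_cox_se)
  # identical covariate -> non-identifiable
  expect_error(cox_calibration(transform(rows, H_pred = 0.3)),
               "not identifiable")
})

test_that("exponential and Cox calibration slopes agree on large landmark sets", {
  coh <- simulate_cohort(cohort_config(n_subjects = 1500), seed = 55)
  p <- coh$config$params
  preds <- predict_landmark(coh, 2, 4, model = "standard", params = p)
  rows <- build_landmark(coh, preds, 2, 4)
  ec <- exp_calibration(rows)
  cc <- cox_calibration(rows)
  joint_se <- sqrt(ec$beta_se^2 + cc$beta_cox_se^2)
  expect_lt(abs(ec$beta_hat - cc$beta_cox), joint_se)
})

test_that("the calibration table assembles one coherent row per landmark", {
  coh <- small_cohort()
  p <- coh$config$params
  tab <- suppressWarnings(
    calibration_table(coh, "standard", landmarks = 1:7, window = 2,
                      params = p))
  expect_identical(nrow(tab), 7L)
  expect_equal(tab$t_LM, 1:7)
  ok <- !is.na(tab$n)
  expect_true(all(tab$n[ok] >= tab$deaths[ok]))
  expect_true(all(tab$hpred_sd[ok] > 0))
  expect_true(all(tab$c_se[ok] > 0))
  # alternative table runs end to end with the KM marginal (lighter
  # censoring so the survivor subset holds both arms)
  coh2 <- simulate_cohort(cohort_config(n_subjects = 400,
                                        censoring = "uniform",
                                        cens_max = 30), seed = 61)
  f_lt <- fit_revival(coh2, "uncensored_lt_tlim")
  f_sv <- fit_revival(coh2, "survivors_ge_tlim")
  tab2 <- suppressWarnings(
    calibration_table(coh2, "alternative", landmarks = c(2, 4), window = 2,
                      fit_lt = f_lt, fit_survivor = f_sv))
  expect_identical(nrow(tab2), 2L)
  expect_identical(attr(tab2, "model"), "alternative")
})
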