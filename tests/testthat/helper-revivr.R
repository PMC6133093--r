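# Shared fixtures and independent oracles. All fixtures are generated in
# code; no data files are read.

# Brute-force dense multivariate-normal log-density, written from the
# definition (solve + determinant); independent of the Cholesky path used
# inside the package.
dmvnorm_bruteforce <- function(y, mu, V) {
  k <- length(y)
  e <- y - mu
  -0.5 * (k * log(2 * pi) +
            as.numeric(determinant(V, logarithm = TRUE)$modulus) +
            drop(t(e) %*% solve(V) %*% e))
}

# A hand-built cohort (no generator involved) for exact small-instance
# checks: survival rows plus optional measurements.
manual_cohort <- function(time, status, arm = NULL, long = NULL) {
  n <- length(time)
  if (is.null(arm)) arm <- rep("control", n)
  if (is.null(long))
    long <- data.frame(id = integer(), time = numeric(), value = numeric())
  structure(list(
    survival = data.frame(id = seq_len(n), arm = arm, time = time,
                          status = status, T_true = ifelse(status == 1, time, NA),
                          C = ifelse(status == 0, time, NA)),
    longitudinal = long, config = NULL), class = "revival_cohort")
}

# Default parameter set used throughout the tests.
ref_params <- function(...) revival_params(...)

# Small simulated cohort cached per session to keep the suite fast.
small_cohort <- local({
  coh <- NULL
  function() {
    if (is.null(coh)) coh <<- simulate_cohort(
      cohort_config(n_subjects = 300), seed = 20260925)
    coh
  }
})
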