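# Shared fixtures: default protocol, a forward-modelled lesion curve, and
# frozen external-oracle values (statsmodels GEE, pingouin ICC) computed
# independently on the same data.

default_protocol <- function() acquisition_protocol()

# Forward-model a truth curve into noiseless SPGR signal at phase times.
forward_signal <- function(truth, protocol, m0 = 500) {
  conc <- true_concentration_curve(truth, phase_times(protocol))
  spgr_signal(concentration_to_t1(conc, protocol), protocol, m0)
}

simple_truth <- function(bat = 20, ms = 0.03, peak = 38, washout = 0.01) {
  list(bat_true = bat, ms_true = ms, peak_time_true = peak,
       washout_rate = washout)
}

# Gaussian exchangeable GEE fixture and its statsmodels.GEE reference fit.
gee_gaussian_fixture <- function() {
  list(
    data = data.frame(
      id = c(1, 1, 2, 2, 2, 3, 4, 4, 5, 6, 6, 6, 7, 7, 8, 8),
      g = c(0, 1, 0, 0, 1, 1, 0, 1, 1, 0, 1, 1, 0, 0, 1, 1),
      y = c(2.1, 3.4, 1.9, 2.2, 3.1, 3.8, 2.0, 2.9, 3.5, 1.7, 3.0, 3.3,
            2.4, 2.1, 3.6, 3.2)),
    coef = c(2.08244103, 1.24724930),
    se = c(0.07312385, 0.08601661),
    alpha = 0.26042353,
    scale = 0.07097274
  )
}

# Binomial exchangeable GEE fixture and its statsmodels.GEE reference fit.
gee_binomial_fixture <- function() {
  list(
    data = data.frame(
      id = rep(1:10, each = 2),
      x = c(0.1, 0.3, 0.2, 0.8, 0.5, 0.9, 0.4, 0.6, 0.7, 1.0, 0.15, 0.35,
            0.55, 0.95, 0.25, 0.65, 0.45, 0.85, 0.05, 0.75),
      y = c(0, 1, 0, 1, 1, 0, 0, 1, 1, 1, 0, 0, 1, 1, 0, 0, 1, 1, 0, 1)),
    coef = c(-2.77366300, 5.69147983),
    se = c(1.27519639, 2.59973952),
    p = c(0.02962360, 0.02857867),
    alpha = -0.28064126
  )
}

# Two-reader ICC fixture with its pingouin ICC(A,1) reference (ICC exact,
# CI rounded to 2 dp by the reference implementation).
icc_fixture <- function() {
  list(
    reader1 = c(10.2, 11.5, 9.8, 12.1, 10.9, 11.8, 9.5, 10.1, 12.5, 11.0,
                10.4, 9.9),
    reader2 = c(10.5, 11.2, 10.1, 12.5, 10.6, 12.0, 9.2, 10.4, 12.2, 11.3,
                10.1, 10.2),
    icc = 0.95291829,
    ci_2dp = c(0.85, 0.99)
  )
}

# Brute-force AUC oracle: exhaustive pair counting with ties at half.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

# Clustered null cohort for type-I error simulations: lognormal marker
# with a shared patient effect and a group label carrying no effect.
null_cohort <- function(n_patients = 125) {
  n_les <- sample(1:3, n_patients, TRUE, prob = c(111, 11, 3) / 125)
  id <- rep(seq_len(n_patients), n_les)
  n <- length(id)
  data.frame(
    patient_id = id,
    y = exp(rnorm(n_patients, 0, 0.3))[id] * exp(rnorm(n, 0, 0.3)),
    g = rbinom(n, 1, 0.5)
  )
}
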