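#' SPGR steady-state signal
#'
#' Closed-form spoiled gradient-echo signal
#' \deqn{S = M_0 \sin\alpha \frac{1 - E_1}{1 - E_1\cos\alpha}, \quad
#'       E_1 = e^{-TR/T_1}.}
#' Strictly decreasing in T1 for a fixed protocol, which makes the
#' inversion in [invert_t1()] single-valued.
#'
#' @param t1 Longitudinal relaxation time(s) in milliseconds; vectorized.
#' @param protocol An [acquisition_protocol()] supplying TR and flip angle.
#' @param m0 Equilibrium magnetization / scanner scale factor.
#' @return Signal in the same arbitrary units as `m0`.
#' @export
spgr_signal <- function(t1, protocol, m0 = 1) {
  if (any(t1 <= 0)) stop("'t1' must be positive (ms)")
  a <- protocol$flip_angle * pi / 180
  e1 <- exp(-protocol$tr / t1)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Baseline (pre-contrast) signal estimate
#'
#' Mean of the first `n_baseline` samples of a signal time series; these
#' leading phases are treated as acquired before contrast arrival.
#'
#' @param values Numeric vector, or a matrix with one row per voxel and one
#'   column per timepoint.
#' @param n_baseline Number of leading timepoints to average.
#' @return A scalar for a vector input, a per-row vector for a matrix.
#' @export
estimate_baseline <- function(values, n_baseline) {
  n_baseline <- as.integer(n_baseline)
  nt <- if (is.matrix(values)) ncol(values) else length(values)
  if (n_baseline < 1L || n_baseline >= nt)
    stop("'n_baseline' must be in [1, number of timepoints - 1]")
  if (is.matrix(values)) {
    rowMeans(values[, seq_len(n_baseline), drop = FALSE])
  } else {
    mean(values[seq_len(n_baseline)])
  }
}

#' Invert the SPGR ratio equation for post-contrast T1
#'
#' Solves `s_post / s_pre = f(T1_post) / f(T1_pre)` for `T1_post`, where
#' `f` is the SPGR signal of [spgr_signal()]; the scale `m0` cancels in the
#' ratio. With `k = (s_post/s_pre) (1 - E1pre)/(1 - E1pre cos a)` the closed
#' form is `E1post = (1 - k)/(1 - k cos a)` and `T1_post = -TR / log(E1post)`.
#'
#' Samples for which noise pushes `E1post` outside (0, 1) have no physical
#' T1; they are returned as `NaN` with a warning rather than fabricated.
#'
#' @param s_post Post-contrast signal(s); vectorized.
#' @param s_pre Baseline signal (positive scalar or vector recycled against
#'   `s_post`).
#' @param protocol An [acquisition_protocol()].
#' @return `T1_post` in milliseconds (`NaN` where non-physical).
#' @export
invert_t1 <- function(s_post, s_pre, protocol) {
  if (any(s_pre <= 0)) stop("'s_pre' must be positive")
  a <- protocol$flip_angle * pi / 180
  e1pre <- exp(-protocol$tr / protocol$t1_pre)
  k <- (s_post / s_pre) * (1 - e1pre) / (1 - e1pre * cos(a))
  e1post <- (1 - k) / (1 - k * cos(a))
  bad <- !is.finite(e1post) | e1post <= 0 | e1post >= 1
  e1post[bad] <- NA_real_
  t1 <- -protocol$tr / log(e1post)
  t1[bad] <- NaN
  if (any(bad))
    warning(sum(bad), " sample(s) outside the physical SPGR range; NaN returned")
  t1
}

#' Convert post-contrast T1 to gadolinium concentration
#'
#' Fast-exchange linear relaxivity model
#' \deqn{C = \frac{1/T_{1,post} - 1/T_{1,pre}}{r_1}}
#' with T1 in seconds and `r1` in s^-1 mM^-1, giving C in mmol/l.
#'
#' @param t1_post Post-contrast T1 in milliseconds; vectorized, `NaN`
#'   propagated.
#' @param protocol An [acquisition_protocol()] supplying `t1_pre` and
#'   `relaxivity`.
#' @return Concentration in mmol/l.
#' @export
t1_to_concentration <- function(t1_post, protocol) {
  if (any(t1_post <= 0, na.rm = TRUE)) stop("'t1_post' must be positive (ms)")
  (1 / (t1_post / 1000) - 1 / (protocol$t1_pre / 1000)) / protocol$relaxivity
}

#' Concentration to tissue T1 (forward helper)
#'
#' Inverse of [t1_to_concentration()]; used by the synthetic generator to
#' turn a ground-truth concentration curve into tissue T1 and then, via
#' [spgr_signal()], into signal.
#'
#' @param conc Concentration in mmol/l; vectorized.
#' @param protocol An [acquisition_protocol()].
#' @return T1 in milliseconds.
#' @export
concentration_to_t1 <- function(conc, protocol) {
  1000 / (1 / (protocol$t1_pre / 1000) + protocol$relaxivity * conc)
}

#' Convert an SPGR signal time series to concentration
#'
#' Per-timepoint composition of [estimate_baseline()], [invert_t1()] and
#' [t1_to_concentration()]. The conversion is scale invariant: multiplying
#' the whole series by a positive constant leaves the concentrations
#' unchanged. Baseline timepoints of a noiseless series map to exactly 0.
#' Timepoints whose signal is outside the physical SPGR range come back as
#' `NaN` (downstream kinetics treat them as below-floor).
#'
#' @param values Numeric vector (one voxel) or matrix (voxels x timepoints).
#' @param protocol An [acquisition_protocol()].
#' @param n_baseline Number of leading baseline timepoints; defaults to the
#'   protocol's `n_baseline`.
#' @return Concentrations in mmol/l, same shape as `values`.
#' @export
signal_to_concentration <- function(values, protocol,
                                    n_baseline = protocol$n_baseline) {
  s_pre <- estimate_baseline(values, n_baseline)
  if (any(s_pre <= 0))
    stop("baseline signal must be positive; check the input series")
  nbad <- 0L
  t1 <- withCallingHandlers(
    invert_t1(values, s_pre, protocol),
    warning = function(w) {
      nbad <<- nbad + 1L
      invokeRestart("muffleWarning")
    }
  )
  conc <- t1_to_concentration(t1, protocol)
  if (nbad > 0L)
    warning("non-physical signal sample(s) converted to NaN")
  conc
}
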