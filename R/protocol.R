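#' Ultrafast DCE-MRI acquisition protocol
#'
#' Bundles the scanner and sequence constants that govern spoiled
#' gradient-echo (SPGR) signal formation and its inversion to gadolinium
#' concentration. Defaults correspond to a 3T ultrafast breast protocol:
#' TR 3.8 ms, flip angle 12 degrees, 15 phases at 4 s spacing covering the
#' first ~60 s after the start of contrast injection, a fixed pre-contrast
#' breast-tissue T1 of 1444 ms, and a gadobutrol r1 relaxivity of
#' 4.9 s^-1 mM^-1. The first three phases are treated as pre-contrast
#' baseline.
#'
#' @param tr Repetition time in milliseconds.
#' @param flip_angle Flip angle in degrees, in (0, 90).
#' @param dt Phase spacing (reconstructed temporal resolution) in seconds.
#' @param n_phases Number of dynamic phases.
#' @param t1_pre Pre-contrast tissue T1 in milliseconds.
#' @param relaxivity Contrast-agent r1 relaxivity in s^-1 mM^-1.
#' @param n_baseline Number of leading phases treated as pre-contrast
#'   baseline. Must leave at least two post-baseline phases.
#' @param time_origin Timestamp convention for phase `i` (1-based):
#'   `"frame-center"` places it at `(i - 0.5) * dt` seconds after injection
#'   start, `"frame-start"` at `(i - 1) * dt`.
#' @return An object of class `acquisition_protocol`.
#' @seealso [phase_times()], [spgr_signal()], [signal_to_concentration()]
#' @examples
#' p <- acquisition_protocol()
#' phase_times(p)
#' @export
acquisition_protocol <- function(tr = 3.8, flip_angle = 12, dt = 4.0,
                                 n_phases = 15, t1_pre = 1444,
                                 relaxivity = 4.9, n_baseline = 3,
                                 time_origin = c("frame-center", "frame-start")) {
  time_origin <- match.arg(time_origin)
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("'tr' must be a single positive number (ms)")
  if (!is.numeric(flip_angle) || length(flip_angle) != 1L ||
      flip_angle <= 0 || flip_angle >= 90)
    stop("'flip_angle' must lie strictly between 0 and 90 degrees")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be a single positive number (s)")
  if (t1_pre <= 0) stop("'t1_pre' must be positive (ms)")
  if (relaxivity <= 0) stop("'relaxivity' must be positive (s^-1 mM^-1)")
  n_phases <- as.integer(n_phases)
  n_baseline <- as.integer(n_baseline)
  if (n_baseline < 1L) stop("'n_baseline' must be at least 1")
  if (n_phases < n_baseline + 2L)
    stop("'n_phases' must be at least 'n_baseline' + 2")
  structure(
    list(tr = tr, flip_angle = flip_angle, dt = dt, n_phases = n_phases,
         t1_pre = t1_pre, relaxivity = relaxivity, n_baseline = n_baseline,
         time_origin = time_origin),
    class = "acquisition_protocol"
  )
}

#' Phase timestamps of a protocol
#'
#' Times are seconds from the start of contrast injection (acquisition
#' starts simultaneously with injection).
#'
#' @param protocol An [acquisition_protocol()].
#' @return Numeric vector of length `n_phases`, strictly increasing.
#' @export
phase_times <- function(protocol) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  i <- seq_len(protocol$n_phases)
  off <- if (protocol$time_origin == "frame-center") 0.5 else 1
  (i - off) * protocol$dt
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat("Ultrafast DCE acquisition protocol\n")
  cat(sprintf("  TR %.2f ms, flip %.1f deg, %d phases at %.2f s (%s)\n",
              x$tr, x$flip_angle, x$n_phases, x$dt, x$time_origin))
  cat(sprintf("  T1_pre %.0f ms, r1 %.2f /s/mM, %d baseline phases\n",
              x$t1_pre, x$relaxivity, x$n_baseline))
  invisible(x)
}

#' Configuration for the bolus-arrival-time search
#'
#' @param conc_floor Concentration floor in mmol/l; values below it are set
#'   to zero before the log transform, and the floor itself is the argument
#'   of the log for zeroed samples so that gradients stay finite.
#' @param steep_fraction Fraction of the maximum backward log-gradient that
#'   still counts as "steep" when extending the steep-descent run backward
#'   from the peak. A gradient exactly at the threshold counts as steep.
#' @param smooth Apply a 3-point moving average to the concentration curve
#'   before the maximum-slope computation (off by default; slopes are taken
#'   on raw differences).
#' @return An object of class `bat_config`.
#' @export
bat_config <- function(conc_floor = 0.001, steep_fraction = 0.1,
                       smooth = FALSE) {
  if (conc_floor <= 0) stop("'conc_floor' must be positive")
  if (steep_fraction <= 0 || steep_fraction >= 1)
    stop("'steep_fraction' must lie strictly between 0 and 1")
  structure(list(conc_floor = conc_floor, steep_fraction = steep_fraction,
                 smooth = isTRUE(smooth)),
            class = "bat_config")
}

# Evaluate code with a temporary RNG state seeded by `seed`; the caller's
# RNG state is restored afterwards so seeded helpers do not leak.
with_seed <- function(seed, code) {
  if (is.null(seed) || !is.finite(seed))
    stop("a finite integer 'seed' is required; no implicit randomness")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
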