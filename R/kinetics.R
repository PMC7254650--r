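#' Peak of a concentration curve
#'
#' Index of the global maximum of the curve; the first occurrence wins on
#' exact ties. Non-finite samples (flagged by the signal conversion) are
#' treated as below-floor.
#'
#' @param conc Concentration time series in mmol/l.
#' @param conc_floor Enhancement floor in mmol/l; if no sample reaches it
#'   the curve is considered non-enhancing.
#' @return Integer index of the peak timepoint.
#' @export
detect_peak <- function(conc, conc_floor = 0.001) {
  v <- conc
  v[!is.finite(v)] <- 0
  if (all(v < conc_floor))
    stop("no enhancement: all concentrations below the floor")
  which.max(v)
}

#' Bolus arrival time by gradient-based backward search
#'
#' Implements the backward search on the log-transformed concentration
#' curve: (1) values below `conc_floor` are set to zero; (2) the curve is
#' mapped to the log domain with the floor as the argument for zeroed
#' samples, so that pre-arrival samples share one finite constant;
#' (3) the peak timepoint is found; (4) backward gradients
#' `g_i = L_i - L_{i-1}` are formed over the uptake segment; (5) searching
#' backward from the peak, the steep-descent run is the contiguous set of
#' gradients at or above `steep_fraction` of the maximum gradient that
#' contains that maximum; the BAT is the timepoint just before the run —
#' where, walking backward, steep descent gives way to the gradual flat
#' roll-off.
#'
#' Undefined (with a reason) when the curve never enhances, peaks at the
#' first timepoint, or has no positive backward gradient.
#'
#' @param times Phase timestamps in seconds, strictly increasing.
#' @param conc Concentration curve in mmol/l (same length as `times`).
#' @param config A [bat_config()].
#' @return A list with elements `defined` (logical), `bat` (seconds, `NA`
#'   if undefined), `bat_index` (index of the BAT timepoint), `peak_index`,
#'   and `reason` (`NA` or a short diagnostic).
#' @export
compute_bat <- function(times, conc, config = bat_config()) {
  if (length(times) != length(conc))
    stop("'times' and 'conc' must have equal length")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  undefined <- function(reason)
    list(defined = FALSE, bat = NA_real_, bat_index = NA_integer_,
         peak_index = NA_integer_, reason = reason)
  v <- conc
  v[!is.finite(v)] <- 0
  v[v < config$conc_floor] <- 0
  if (all(v == 0)) return(undefined("no-enhancement"))
  L <- log(pmax(v, config$conc_floor))
  p <- which.max(v)
  if (p == 1L) return(undefined("peak-at-first-timepoint"))
  g <- L[2:p] - L[1:(p - 1L)]    # g[i]: backward gradient of step i -> i+1
  g_max <- max(g)
  if (g_max <= 0) return(undefined("non-increasing"))
  thr <- config$steep_fraction * g_max
  b <- which.max(g)              # steepest step, inside the steep run
  while (b > 1L && g[b - 1L] >= thr) b <- b - 1L
  list(defined = TRUE, bat = times[b], bat_index = b, peak_index = p,
       reason = NA_character_)
}

#' Maximum slope of the uptake curve
#'
#' Steepest finite-difference slope of the raw concentration curve over
#' consecutive timepoint pairs inside the window from bolus arrival to the
#' peak, in mmol l^-1 s^-1.
#'
#' @param times Phase timestamps in seconds.
#' @param conc Concentration curve in mmol/l.
#' @param bat_index Index of the BAT timepoint (from [compute_bat()]).
#' @param peak_index Index of the peak timepoint.
#' @param smooth Apply a 3-point moving average before differencing.
#' @return A list with `ms` (the maximum slope) and `index` (the right
#'   endpoint of the winning pair, guaranteed in `(bat_index, peak_index]`).
#' @export
compute_ms <- function(times, conc, bat_index, peak_index, smooth = FALSE) {
  if (!is.finite(bat_index) || !is.finite(peak_index) ||
      bat_index >= peak_index)
    stop("degenerate window: 'bat_index' must be < 'peak_index'")
  v <- conc
  v[!is.finite(v)] <- 0
  if (isTRUE(smooth) && length(v) >= 3L) {
    sm <- stats::filter(v, rep(1 / 3, 3), sides = 2)
    v[!is.na(sm)] <- sm[!is.na(sm)]
  }
  i <- (bat_index + 1L):peak_index
  slopes <- (v[i] - v[i - 1L]) / (times[i] - times[i - 1L])
  k <- which.max(slopes)
  list(ms = slopes[k], index = i[k])
}

# Vectorized per-voxel BAT/MS over a matrix of curves (rows = voxels).
# Same algorithm as compute_bat()/compute_ms() applied row-wise; the
# scalar functions are the reference implementation and the two routes
# are asserted equal in the test suite.
extract_kinetics_matrix <- function(conc, times, config = bat_config()) {
  nv <- nrow(conc)
  nt <- ncol(conc)
  v <- conc
  v[!is.finite(v)] <- 0
  vf <- v
  vf[vf < config$conc_floor] <- 0
  L <- log(pmax(vf, config$conc_floor))
  pk <- max.col(vf, ties.method = "first")
  G <- L[, 2:nt, drop = FALSE] - L[, 1:(nt - 1L), drop = FALSE]
  step <- matrix(seq_len(nt - 1L), nv, nt - 1L, byrow = TRUE)
  G[step > pk - 1L] <- -Inf           # only steps up to the peak count
  g_max <- do.call(pmax, as.data.frame(G))
  defined <- rowSums(vf) > 0 & pk > 1L & g_max > 0
  b <- max.col(G == g_max, ties.method = "first")  # steepest step
  thr <- config$steep_fraction * g_max
  repeat {
    move <- defined & b > 1L
    if (any(move))
      move[move] <- G[cbind(which(move), b[move] - 1L)] >= thr[move]
    if (!any(move)) break
    b[move] <- b[move] - 1L
  }
  bat_index <- ifelse(defined, b, NA_integer_)
  bat <- ifelse(defined, times[b], NA_real_)
  # maximum slope on the raw (unsmoothed, refloored-to-0) curve
  vms <- v
  if (isTRUE(config$smooth) && nt >= 3L) {
    sm <- t(apply(vms, 1L, function(r) {
      f <- stats::filter(r, rep(1 / 3, 3), sides = 2)
      r[!is.na(f)] <- f[!is.na(f)]
      r
    }))
    vms <- sm
  }
  S <- (vms[, 2:nt, drop = FALSE] - vms[, 1:(nt - 1L), drop = FALSE]) /
    matrix(diff(times), nv, nt - 1L, byrow = TRUE)
  has_window <- defined & bat_index < pk
  S[step > pk - 1L | step < ifelse(is.na(bat_index), 1L, bat_index)] <- -Inf
  ms <- do.call(pmax, as.data.frame(S))
  ms <- ifelse(has_window, ms, NA_real_)
  list(defined = defined, bat = bat, bat_index = bat_index,
       peak_index = pk, ms = ms)
}

#' Lesion-level kinetic markers from voxel curves
#'
#' Computes per-voxel BAT and MS for every voxel curve in a lesion and
#' aggregates them to ROI level. The ROI BAT is the arithmetic mean of the
#' per-voxel BATs over voxels with a defined BAT; voxels with an undefined
#' BAT are excluded and counted. The ROI MS is computed, per `ms_mode`,
#' either on the ROI-mean concentration curve of the valid voxels
#' (default) or as the mean of the per-voxel maximum slopes.
#'
#' @param conc Matrix of concentration curves, one row per voxel, one
#'   column per timepoint (a single curve may be given as a vector).
#' @param times Phase timestamps in seconds.
#' @param config A [bat_config()].
#' @param ms_mode `"roi-mean-curve"` or `"voxel-mean"`.
#' @return An object of class `lesion_kinetics`: a list with `ms_roi`,
#'   `bat_roi`, `peak_time_roi`, per-voxel vectors `bat_voxel` and
#'   `ms_voxel` (`NA` where undefined), `n_voxels_valid`, `n_voxels_total`
#'   and `ms_mode`.
#' @export
extract_lesion <- function(conc, times, config = bat_config(),
                           ms_mode = c("roi-mean-curve", "voxel-mean")) {
  ms_mode <- match.arg(ms_mode)
  if (!is.matrix(conc)) conc <- matrix(conc, nrow = 1L)
  nv <- nrow(conc)
  if (ncol(conc) != length(times))
    stop("'conc' must have one column per timepoint")
  km <- extract_kinetics_matrix(conc, times, config)
  bat_voxel <- km$bat
  ms_voxel <- km$ms
  valid <- !is.na(bat_voxel)
  if (!any(valid))
    stop("no voxel with a defined bolus arrival time")
  bat_roi <- mean(bat_voxel[valid])
  mean_curve <- colMeans(conc[valid, , drop = FALSE])
  mean_curve[!is.finite(mean_curve)] <- 0
  bm <- compute_bat(times, mean_curve, config)
  peak_time_roi <- times[detect_peak(mean_curve, config$conc_floor)]
  ms_roi <- if (ms_mode == "roi-mean-curve") {
    if (!bm$defined || bm$bat_index >= bm$peak_index)
      stop("ROI-mean curve has no defined uptake window")
    compute_ms(times, mean_curve, bm$bat_index, bm$peak_index,
               smooth = config$smooth)$ms
  } else {
    mean(ms_voxel[valid], na.rm = TRUE)
  }
  structure(
    list(ms_roi = ms_roi, bat_roi = bat_roi, peak_time_roi = peak_time_roi,
         bat_voxel = bat_voxel, ms_voxel = ms_voxel,
         n_voxels_valid = sum(valid), n_voxels_total = nv,
         ms_mode = ms_mode),
    class = "lesion_kinetics"
  )
}

#' @export
print.lesion_kinetics <- function(x, ...) {
  cat("Lesion kinetics (", x$n_voxels_valid, "/", x$n_voxels_total,
      " voxels valid)\n", sep = "")
  cat(sprintf("  MS  %.4f mmol/l/s (%s)\n", x$ms_roi, x$ms_mode))
  cat(sprintf("  BAT %.2f s, peak %.2f s\n", x$bat_roi, x$peak_time_roi))
  invisible(x)
}
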