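#' Log-normal parameters from a printed median and IQR
#'
#' Cohort kinetic values are modelled as log-normal; published summaries
#' report medians and interquartile ranges, which determine the log-scale
#' location (`log(median)`) and scale (`(log q3 - log q1) / (2 z_0.75)`).
#'
#' @param median,q1,q3 Positive summary statistics.
#' @return A list with `meanlog` and `sdlog` for [stats::rlnorm()].
#' @keywords internal
lognormal_from_median_iqr <- function(median, q1, q3) {
  if (any(c(median, q1, q3) <= 0) || q3 <= q1)
    stop("median/quartiles must be positive with q3 > q1")
  list(meanlog = log(median),
       sdlog = (log(q3) - log(q1)) / (2 * stats::qnorm(0.75)))
}

#' Kinetic priors stratified by histopathology
#'
#' Per-class medians and IQRs (log-normal parameterization) for the
#' maximum slope (mmol l^-1 s^-1) and bolus arrival time (s) of invasive
#' carcinoma and DCIS, at the magnitudes reported for ultrafast breast
#' DCE-MRI cohorts: invasive MS median 0.030 (IQR 0.018-0.054) and BAT
#' 21.9 s (19.7-23.8); DCIS MS 0.013 (0.007-0.029) and BAT 25.3 s
#' (21.3-27.0).
#'
#' @return A data frame with one row per kinetic class, carrying attribute
#'   `stratify = "histopathology"`.
#' @export
kinetic_priors_histopathology <- function() {
  out <- data.frame(
    class = c("invasive", "DCIS"),
    ms_median = c(0.030, 0.013), ms_q1 = c(0.018, 0.007),
    ms_q3 = c(0.054, 0.029),
    bat_median = c(21.9, 25.3), bat_q1 = c(19.7, 21.3),
    bat_q3 = c(23.8, 27.0),
    stringsAsFactors = FALSE
  )
  attr(out, "stratify") <- "histopathology"
  out
}

#' Kinetic priors stratified by molecular subtype
#'
#' As [kinetic_priors_histopathology()] but with invasive carcinoma split
#' into an aggressive stratum (triple negative or HER2 type: MS median
#' 0.049, IQR 0.028-0.059; BAT 19.9 s, 17.9-22.3) and a luminal stratum
#' (MS 0.027, 0.017-0.045; BAT 22.5 s, 20.7-24.8), so that molecular
#' subtype carries a real kinetic contrast in generated cohorts.
#'
#' @return A data frame of priors with attribute `stratify = "subtype"`.
#' @export
kinetic_priors_subtype <- function() {
  out <- data.frame(
    class = c("invasive_aggressive", "invasive_luminal", "DCIS"),
    ms_median = c(0.049, 0.027, 0.013),
    ms_q1 = c(0.028, 0.017, 0.007),
    ms_q3 = c(0.059, 0.045, 0.029),
    bat_median = c(19.9, 22.5, 25.3),
    bat_q1 = c(17.9, 20.7, 21.3),
    bat_q3 = c(22.3, 24.8, 27.0),
    stringsAsFactors = FALSE
  )
  attr(out, "stratify") <- "subtype"
  out
}

#' Specification of a synthetic ultrafast DCE cohort
#'
#' Defaults emulate a 125-patient breast-MRI study: 111 patients with a
#' single lesion, 11 with two and 3 with three (142 lesions in
#' expectation), lesion labels drawn with the published class frequencies,
#' and kinetics drawn from subtype-stratified log-normal priors.
#'
#' @param n_patients Number of patients.
#' @param lesions_per_patient_weights Probabilities of 1, 2 and 3 lesions
#'   per patient; must sum to 1.
#' @param priors A kinetic-priors data frame
#'   ([kinetic_priors_subtype()], the default, or
#'   [kinetic_priors_histopathology()]).
#' @param noise_sigma Acquisition noise standard deviation, relative to
#'   the baseline signal (0.01 emulates a baseline SNR of ~100).
#' @param rise_time_median,rise_time_sdlog Log-normal parameters (median
#'   seconds; log-scale sd) of the uptake duration from bolus arrival to
#'   peak.
#' @param washout_rate Mono-exponential washout rate after the peak, per
#'   second.
#' @param jitter_sd Log-scale sd of the optional multiplicative
#'   within-lesion voxel jitter on MS and BAT (0 = homogeneous lesions).
#' @param seed Integer seed; mandatory, there is no implicit randomness.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 125,
                        lesions_per_patient_weights = c(111, 11, 3) / 125,
                        priors = kinetic_priors_subtype(),
                        noise_sigma = 0.01,
                        rise_time_median = 18, rise_time_sdlog = 0.2,
                        washout_rate = 0.01, jitter_sd = 0,
                        seed) {
  if (missing(seed)) stop("'seed' is mandatory: no implicit randomness")
  w <- lesions_per_patient_weights
  if (length(w) != 3L || any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("'lesions_per_patient_weights' must be 3 non-negative probabilities summing to 1")
  need <- c("class", "ms_median", "ms_q1", "ms_q3",
            "bat_median", "bat_q1", "bat_q3")
  if (!all(need %in% names(priors)))
    stop("'priors' must have columns ", paste(need, collapse = ", "))
  if (any(priors[-1] <= 0)) stop("all prior medians/quartiles must be positive")
  if (n_patients < 1) stop("'n_patients' must be at least 1")
  if (noise_sigma < 0) stop("'noise_sigma' must be non-negative")
  if (washout_rate < 0) stop("'washout_rate' must be non-negative")
  structure(
    list(n_patients = as.integer(n_patients),
         lesions_per_patient_weights = w,
         priors = priors,
         stratify = attr(priors, "stratify") %||% "histopathology",
         noise_sigma = noise_sigma,
         rise_time_median = rise_time_median,
         rise_time_sdlog = rise_time_sdlog,
         washout_rate = washout_rate,
         jitter_sd = jitter_sd,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Published lesion-label frequencies used by the label sampler.
label_frequencies <- function() {
  list(
    histopathology = c(invasive = 124, DCIS = 18),
    lesion_type_invasive = c(mass = 91, NME = 31, focus = 2),
    lesion_type_dcis = c(mass = 5, NME = 13, focus = 0),
    grade = c(`1` = 7, `2` = 48, `3` = 56, `NA` = 13),
    histotype = c(IDC = 98, ILC = 20, mixed = 6),
    molecular = c(TN = 12, HER2 = 21, luminal = 91),
    node = c(positive = 57, negative = 64, `NA` = 3),
    recurrence_available = c(yes = 45, no = 46),   # among luminal
    recurrence = c(high = 2, intermediate = 13, low = 30),
    size_invasive = c(median = 19.5, q1 = 13, q3 = 32.3),
    size_dcis = c(median = 13.5, q1 = 9.3, q3 = 19.5)
  )
}

sample_label <- function(n, freq) {
  lab <- sample(names(freq), n, replace = TRUE, prob = freq / sum(freq))
  lab[lab == "NA"] <- NA_character_
  lab
}

#' Sample per-lesion ground truth for a synthetic cohort
#'
#' Draws the number of lesions per patient, lesion labels
#' (histopathology, lesion type, grade, histotype, molecular subtype,
#' node status, recurrence risk), lesion sizes, and ground-truth kinetics
#' (onset time `bat_true`, uptake slope `ms_true`, peak time, plateau
#' concentration) from the spec's priors. Deterministic for a fixed seed.
#'
#' Onset times are resampled to lie after the baseline phases (first
#' `n_baseline * dt` seconds) so that the leading phases really are
#' pre-contrast; sizes are truncated to 4-70 mm.
#'
#' @param spec A [cohort_spec()].
#' @param protocol An [acquisition_protocol()] (used only for the baseline
#'   window of the onset-time truncation).
#' @return A data frame with one row per lesion: identifiers, labels,
#'   `lesion_size_mm`, kinetic class, and `bat_true`, `ms_true`,
#'   `peak_time_true`, `plateau_conc`, `washout_rate`.
#' @export
sample_cohort <- function(spec, protocol = acquisition_protocol()) {
  stopifnot(inherits(spec, "cohort_spec"))
  fr <- label_frequencies()
  with_seed(spec$seed, {
    n_les <- sample(1:3, spec$n_patients, replace = TRUE,
                    prob = spec$lesions_per_patient_weights)
    patient_id <- rep(sprintf("P%03d", seq_len(spec$n_patients)), n_les)
    n <- length(patient_id)
    lesion_id <- sprintf("L%03d", seq_len(n))
    histopathology <- sample_label(n, fr$histopathology)
    inv <- histopathology == "invasive"
    lesion_type <- character(n)
    lesion_type[inv] <- sample_label(sum(inv), fr$lesion_type_invasive)
    lesion_type[!inv] <- sample_label(sum(!inv), fr$lesion_type_dcis)
    grade <- rep(NA_character_, n)
    histotype <- rep(NA_character_, n)
    molecular <- rep(NA_character_, n)
    node_status <- rep(NA_character_, n)
    recurrence_risk <- rep(NA_character_, n)
    grade[inv] <- sample_label(sum(inv), fr$grade)
    histotype[inv] <- sample_label(sum(inv), fr$histotype)
    molecular[inv] <- sample_label(sum(inv), fr$molecular)
    node_status[inv] <- sample_label(sum(inv), fr$node)
    lum <- inv & molecular == "luminal"
    avail <- lum & sample_label(n, fr$recurrence_available) == "yes"
    recurrence_risk[avail] <- sample_label(sum(avail), fr$recurrence)

    size_par_inv <- lognormal_from_median_iqr(fr$size_invasive["median"],
                                              fr$size_invasive["q1"],
                                              fr$size_invasive["q3"])
    size_par_dcis <- lognormal_from_median_iqr(fr$size_dcis["median"],
                                               fr$size_dcis["q1"],
                                               fr$size_dcis["q3"])
    lesion_size_mm <- numeric(n)
    lesion_size_mm[inv] <- stats::rlnorm(sum(inv), size_par_inv$meanlog,
                                         size_par_inv$sdlog)
    lesion_size_mm[!inv] <- stats::rlnorm(sum(!inv), size_par_dcis$meanlog,
                                          size_par_dcis$sdlog)
    lesion_size_mm <- pmin(pmax(lesion_size_mm, 4), 70)

    kinetic_class <- if (spec$stratify == "subtype") {
      ifelse(!inv, "DCIS",
             ifelse(molecular %in% c("TN", "HER2"),
                    "invasive_aggressive", "invasive_luminal"))
    } else {
      ifelse(inv, "invasive", "DCIS")
    }
    if (!all(kinetic_class %in% spec$priors$class))
      stop("priors are missing kinetic class(es): ",
           paste(setdiff(kinetic_class, spec$priors$class), collapse = ", "))

    ms_true <- numeric(n)
    bat_true <- numeric(n)
    bat_min <- protocol$n_baseline * protocol$dt + protocol$dt / 2
    for (cl in unique(kinetic_class)) {
      idx <- which(kinetic_class == cl)
      row <- spec$priors[spec$priors$class == cl, ]
      mp <- lognormal_from_median_iqr(row$ms_median, row$ms_q1, row$ms_q3)
      bp <- lognormal_from_median_iqr(row$bat_median, row$bat_q1, row$bat_q3)
      ms_true[idx] <- stats::rlnorm(length(idx), mp$meanlog, mp$sdlog)
      b <- stats::rlnorm(length(idx), bp$meanlog, bp$sdlog)
      while (any(b <= bat_min))  # keep onsets after the baseline window
        b[b <= bat_min] <- stats::rlnorm(sum(b <= bat_min), bp$meanlog,
                                         bp$sdlog)
      bat_true[idx] <- b
    }
    rise <- stats::rlnorm(n, log(spec$rise_time_median), spec$rise_time_sdlog)
    peak_time_true <- bat_true + rise
    plateau_conc <- ms_true * rise

    data.frame(
      patient_id = patient_id, lesion_id = lesion_id,
      histopathology = histopathology, lesion_type = lesion_type,
      grade = grade, histotype = histotype, molecular = molecular,
      node_status = node_status, recurrence_risk = recurrence_risk,
      lesion_size_mm = lesion_size_mm, kinetic_class = kinetic_class,
      bat_true = bat_true, ms_true = ms_true,
      peak_time_true = peak_time_true, plateau_conc = plateau_conc,
      washout_rate = spec$washout_rate,
      stringsAsFactors = FALSE
    )
  })
}

#' Ground-truth concentration curve of a lesion
#'
#' Piecewise enhancement model whose defining properties are exactly the
#' two target markers: zero before the onset `bat_true`, a linear rise
#' with slope `ms_true` from onset to `peak_time_true`, and
#' mono-exponential washout from the plateau afterwards. Continuous
#' everywhere; the analytic maximum slope is `ms_true` and the first
#' departure from zero is at `bat_true`.
#'
#' @param truth One lesion's truth: a one-row data frame or list with
#'   `bat_true`, `ms_true`, `peak_time_true`, `washout_rate` (and
#'   optionally `plateau_conc`, recomputed from the others if absent).
#' @param times Sampling times in seconds, non-negative and strictly
#'   increasing.
#' @return Concentrations in mmol/l at `times`.
#' @export
true_concentration_curve <- function(truth, times) {
  if (any(times < 0) || any(diff(times) <= 0))
    stop("'times' must be non-negative and strictly increasing")
  bat <- truth$bat_true
  ms <- truth$ms_true
  pk <- truth$peak_time_true
  w <- truth$washout_rate %||% 0
  if (bat >= pk) stop("'bat_true' must be before 'peak_time_true'")
  plateau <- ms * (pk - bat)
  conc <- numeric(length(times))
  rise <- times > bat & times <= pk
  conc[rise] <- ms * (times[rise] - bat)
  post <- times > pk
  conc[post] <- plateau * exp(-w * (times[post] - pk))
  conc
}

# Voxel-level ground-truth concentration matrix for one lesion, with
# optional multiplicative per-voxel jitter on ms/bat (log-normal, sd on
# the log scale). Jitter keeps onsets after the baseline window.
voxel_concentration_matrix <- function(truth, times, n_voxels,
                                       jitter_sd = 0, bat_min = 0) {
  if (jitter_sd <= 0) {
    one <- true_concentration_curve(truth, times)
    return(matrix(one, nrow = n_voxels, ncol = length(times), byrow = TRUE))
  }
  ms_v <- truth$ms_true * exp(stats::rnorm(n_voxels, 0, jitter_sd))
  bat_v <- pmax(truth$bat_true * exp(stats::rnorm(n_voxels, 0, jitter_sd)),
                bat_min)
  rise <- truth$peak_time_true - truth$bat_true
  out <- matrix(0, n_voxels, length(times))
  for (v in seq_len(n_voxels)) {
    tv <- list(bat_true = bat_v[v], ms_true = ms_v[v],
               peak_time_true = bat_v[v] + rise,
               washout_rate = truth$washout_rate)
    out[v, ] <- true_concentration_curve(tv, times)
  }
  attr(out, "ms_voxel") <- if (jitter_sd > 0) ms_v else NULL
  attr(out, "bat_voxel") <- if (jitter_sd > 0) bat_v else NULL
  out
}

# Ellipsoid lesion mask on an isotropic grid (voxel_mm pitch); semi-axes
# (L/2, 0.75 L/2, 0.75 L/2) for a lesion of longest diameter L mm.
ellipsoid_mask <- function(size_mm, grid_shape, voxel_mm = 1.6) {
  semi <- c(1, 0.75, 0.75) * size_mm / 2 / voxel_mm   # in voxels
  need <- ceiling(2 * semi) + 2
  if (any(grid_shape < need))
    stop(sprintf("grid %s too small for a %.1f mm lesion (needs >= %s)",
                 paste(grid_shape, collapse = "x"), size_mm,
                 paste(need, collapse = "x")))
  ctr <- (grid_shape + 1) / 2
  ix <- (seq_len(grid_shape[1]) - ctr[1]) / semi[1]
  iy <- (seq_len(grid_shape[2]) - ctr[2]) / semi[2]
  iz <- (seq_len(grid_shape[3]) - ctr[3]) / semi[3]
  d2 <- outer(outer(ix^2, iy^2, `+`), iz^2, `+`)
  array(as.integer(d2 <= 1), dim = grid_shape)
}

#' Render one synthetic lesion as a 4D signal volume plus mask
#'
#' Forward model: inside-mask voxels carry the SPGR signal of the lesion's
#' ground-truth concentration curve (optionally with multiplicative
#' within-lesion jitter on slope and onset); outside voxels carry the
#' baseline signal; zero-mean Gaussian noise with standard deviation
#' `noise_sigma * baseline` is added to the magnitude signal everywhere
#' (a high-SNR approximation of Rician noise). Deterministic for a fixed
#' seed.
#'
#' @param truth One lesion's truth row (see [sample_cohort()]), including
#'   `lesion_size_mm`.
#' @param protocol An [acquisition_protocol()].
#' @param grid_shape Integer vector of 3 grid dimensions; defaults to the
#'   smallest grid (plus padding) that holds the lesion ellipsoid at
#'   `voxel_mm` pitch.
#' @param noise_sigma Noise sd relative to the baseline signal.
#' @param seed Integer seed (mandatory when `noise_sigma > 0` or
#'   `jitter_sd > 0`).
#' @param voxel_mm Isotropic voxel pitch in mm.
#' @param m0 Scanner scale factor of the SPGR signal.
#' @param jitter_sd Within-lesion multiplicative jitter (log-scale sd).
#' @return A list with `signal` (4D array x,y,z,t), `mask` (3D integer
#'   array, nonzero = lesion), `times`, and `baseline_signal`.
#' @export
render_lesion_volume <- function(truth, protocol, grid_shape = NULL,
                                 noise_sigma = 0, seed = NULL,
                                 voxel_mm = 1.6, m0 = 500, jitter_sd = 0) {
  times <- phase_times(protocol)
  size <- truth$lesion_size_mm %||% 10
  if (is.null(grid_shape)) {
    semi <- c(1, 0.75, 0.75) * size / 2 / voxel_mm
    grid_shape <- pmax(ceiling(2 * semi) + 4, 8)
  }
  grid_shape <- as.integer(grid_shape)
  mask <- ellipsoid_mask(size, grid_shape, voxel_mm)
  nv <- sum(mask)
  baseline <- spgr_signal(protocol$t1_pre, protocol, m0)
  nt <- length(times)
  render <- function() {
    bat_min <- protocol$n_baseline * protocol$dt
    conc <- voxel_concentration_matrix(truth, times, nv, jitter_sd, bat_min)
    sig_lesion <- spgr_signal(concentration_to_t1(conc, protocol),
                              protocol, m0)
    signal <- array(baseline, dim = c(grid_shape, nt))
    in_mask <- which(mask != 0)
    nxyz <- prod(grid_shape)
    for (ti in seq_len(nt))
      signal[in_mask + (ti - 1) * nxyz] <- sig_lesion[, ti]
    if (noise_sigma > 0)
      signal <- signal + stats::rnorm(length(signal),
                                      sd = noise_sigma * baseline)
    signal
  }
  signal <- if (noise_sigma > 0 || jitter_sd > 0) {
    if (is.null(seed))
      stop("'seed' is required when noise or jitter is enabled")
    with_seed(seed, render())
  } else render()
  list(signal = signal, mask = mask, times = times,
       baseline_signal = baseline)
}

#' Write a full synthetic cohort to disk as a blind fixture
#'
#' Emits, under `out_dir`: per-lesion 4D signal NIfTI files and 3D mask
#' NIfTI files (`images/`, `masks/`), a blind cohort table `cohort.csv`
#' (identifiers, labels and size only — no kinetic truth), the withheld
#' ground truth `truth/truth.csv`, the protocol as YAML, and a
#' `manifest.csv` listing every file with its MD5 checksum. Re-running
#' with the same spec and protocol reproduces identical checksums.
#'
#' @param spec A [cohort_spec()].
#' @param protocol An [acquisition_protocol()].
#' @param out_dir Output directory (created if needed).
#' @param voxel_mm,m0 Passed to [render_lesion_volume()].
#' @return Invisibly, the manifest data frame (`file`, `md5`).
#' @export
write_cohort_fixture <- function(spec, protocol, out_dir,
                                 voxel_mm = 1.6, m0 = 500) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  truth <- sample_cohort(spec, protocol)
  pitch <- c(voxel_mm, voxel_mm, voxel_mm)
  files <- character(0)
  for (i in seq_len(nrow(truth))) {
    vol <- render_lesion_volume(truth[i, ], protocol,
                                noise_sigma = spec$noise_sigma,
                                seed = lesion_seed(spec$seed, i),
                                voxel_mm = voxel_mm, m0 = m0,
                                jitter_sd = spec$jitter_sd)
    img_path <- file.path(out_dir, "images",
                          sprintf("%s.nii.gz", truth$lesion_id[i]))
    msk_path <- file.path(out_dir, "masks",
                          sprintf("%s_mask.nii.gz", truth$lesion_id[i]))
    RNifti::writeNifti(RNifti::asNifti(vol$signal, pixdim = c(pitch, protocol$dt)),
                       img_path)
    RNifti::writeNifti(RNifti::asNifti(vol$mask, pixdim = pitch), msk_path)
    files <- c(files, img_path, msk_path)
  }
  blind_cols <- c("patient_id", "lesion_id", "histopathology", "lesion_type",
                  "grade", "histotype", "molecular", "node_status",
                  "recurrence_risk", "lesion_size_mm")
  cohort_path <- file.path(out_dir, "cohort.csv")
  utils::write.csv(truth[blind_cols], cohort_path, row.names = FALSE)
  truth_path <- file.path(out_dir, "truth", "truth.csv")
  utils::write.csv(truth, truth_path, row.names = FALSE)
  proto_path <- file.path(out_dir, "protocol.yaml")
  yaml::write_yaml(unclass(protocol), proto_path)
  files <- c(files, cohort_path, truth_path, proto_path)
  manifest <- data.frame(file = sub(paste0("^", out_dir, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

# Per-lesion sub-seed derived from the cohort seed; kept within 32-bit range.
lesion_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * i) %% .Machine$integer.max)
}
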