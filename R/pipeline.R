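#' Configuration of an end-to-end synthetic-cohort run
#'
#' @param protocol An [acquisition_protocol()].
#' @param cohort A [cohort_spec()] (carries the mandatory seed).
#' @param bat A [bat_config()].
#' @param ms_mode ROI maximum-slope mode, `"roi-mean-curve"` or
#'   `"voxel-mean"`.
#' @param max_voxels Maximum number of lesion voxels simulated and
#'   analyzed per lesion; larger lesions are represented by this many
#'   voxels. ROI aggregates converge well below the default.
#' @param seed Optional override of the cohort seed.
#' @param verbose Emit per-lesion log lines.
#' @return An object of class `run_config`.
#' @export
run_config <- function(protocol = acquisition_protocol(),
                       cohort, bat = bat_config(),
                       ms_mode = c("roi-mean-curve", "voxel-mean"),
                       max_voxels = 300, seed = NULL, verbose = FALSE) {
  ms_mode <- match.arg(ms_mode)
  stopifnot(inherits(protocol, "acquisition_protocol"),
            inherits(cohort, "cohort_spec"), inherits(bat, "bat_config"))
  if (!is.null(seed)) cohort$seed <- as.integer(seed)
  structure(list(protocol = protocol, cohort = cohort, bat = bat,
                 ms_mode = ms_mode, max_voxels = as.integer(max_voxels),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Run the simulate-extract-stats pipeline
#'
#' Samples a synthetic cohort, renders each lesion's voxel signal curves
#' through the SPGR forward model with acquisition noise, converts the
#' signals back to concentration blind to the ground truth, extracts
#' per-lesion MS and BAT, assembles the cohort table, and runs the full
#' statistical battery. The extraction stage sees only signals, masks and
#' the protocol — never the generator's kinetic truth.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `cohort.csv` (measured markers + labels), `truth/truth.csv`
#'   (withheld ground truth), `contrasts.csv`, `report.json` and
#'   `manifest.csv`.
#' @return Invisibly, a list of class `ufdce_run` with `truth` (ground
#'   truth), `cohort` (measured table), `report` (the [run_study()]
#'   output), `excluded` (per-lesion invalid-voxel counts) and
#'   `manifest` (or `NULL`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  protocol <- config$protocol
  spec <- config$cohort
  truth <- sample_cohort(spec, protocol)
  times <- phase_times(protocol)
  n <- nrow(truth)
  ms <- numeric(n)
  bat <- numeric(n)
  n_valid <- integer(n)
  n_total <- integer(n)
  for (i in seq_len(n)) {
    kin <- simulate_and_extract(truth[i, ], protocol, spec,
                                seed = lesion_seed(spec$seed, i),
                                bat = config$bat, ms_mode = config$ms_mode,
                                max_voxels = config$max_voxels)
    ms[i] <- kin$ms_roi
    bat[i] <- kin$bat_roi
    n_valid[i] <- kin$n_voxels_valid
    n_total[i] <- kin$n_voxels_total
    if (config$verbose)
      message(sprintf("lesion %s: %d/%d voxels valid, MS %.4f, BAT %.1f",
                      truth$lesion_id[i], n_valid[i], n_total[i],
                      ms[i], bat[i]))
  }
  cohort <- truth[c("patient_id", "lesion_id", "histopathology",
                    "lesion_type", "grade", "histotype", "molecular",
                    "node_status", "recurrence_risk", "lesion_size_mm")]
  cohort$ms <- ms
  cohort$bat <- bat
  report <- run_study(cohort)
  excluded <- data.frame(lesion_id = truth$lesion_id,
                         n_voxels_valid = n_valid,
                         n_voxels_total = n_total)
  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "truth"), recursive = TRUE,
               showWarnings = FALSE)
    paths <- c(
      cohort = file.path(out_dir, "cohort.csv"),
      truth = file.path(out_dir, "truth", "truth.csv"),
      contrasts = file.path(out_dir, "contrasts.csv"),
      report = file.path(out_dir, "report.json")
    )
    utils::write.csv(cohort, paths["cohort"], row.names = FALSE)
    utils::write.csv(truth, paths["truth"], row.names = FALSE)
    utils::write.csv(as.data.frame(report), paths["contrasts"],
                     row.names = FALSE)
    jsonlite::write_json(report_to_list(report), paths["report"],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest <- data.frame(
      file = sub(paste0("^", out_dir, "/?"), "", unname(paths)),
      md5 = unname(tools::md5sum(unname(paths))),
      stringsAsFactors = FALSE)
    manifest <- rbind(manifest,
                      data.frame(file = "seed", md5 = as.character(spec$seed)))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  invisible(structure(list(truth = truth, cohort = cohort, report = report,
                           excluded = excluded, manifest = manifest),
                      class = "ufdce_run"))
}

# Forward-model one lesion's in-mask voxel curves and extract kinetics
# without materializing the full 4D volume. Blind by construction: the
# extraction call sees only the noisy signal matrix, times and config.
simulate_and_extract <- function(truth, protocol, spec, seed, bat, ms_mode,
                                 max_voxels = 300) {
  times <- phase_times(protocol)
  n_voxels <- max(1L, min(ellipsoid_voxel_count(truth$lesion_size_mm),
                          max_voxels))
  with_seed(seed, {
    conc <- voxel_concentration_matrix(truth, times, n_voxels,
                                       spec$jitter_sd,
                                       protocol$n_baseline * protocol$dt)
    signal <- spgr_signal(concentration_to_t1(conc, protocol), protocol,
                          m0 = 500)
    if (spec$noise_sigma > 0) {
      baseline <- spgr_signal(protocol$t1_pre, protocol, 500)
      signal <- signal + stats::rnorm(length(signal),
                                      sd = spec$noise_sigma * baseline)
    }
    conc_meas <- suppressWarnings(
      signal_to_concentration(signal, protocol))
    extract_lesion(conc_meas, times, config = bat, ms_mode = ms_mode)
  })
}

ellipsoid_voxel_count <- function(size_mm, voxel_mm = 1.6) {
  semi <- c(1, 0.75, 0.75) * size_mm / 2 / voxel_mm
  round(4 / 3 * pi * prod(semi))
}

#' Extract lesion kinetics from NIfTI files
#'
#' Reads a 4D ultrafast DCE series and a 3D lesion mask (nonzero =
#' inside), converts the in-mask voxel signals to concentration, and
#' extracts the lesion's kinetic markers.
#'
#' @param image_path Path to the 4D NIfTI signal series.
#' @param mask_path Path to the 3D NIfTI mask.
#' @param protocol An [acquisition_protocol()] (supplies the time axis
#'   and conversion constants).
#' @param bat A [bat_config()].
#' @param ms_mode ROI maximum-slope mode.
#' @return A `lesion_kinetics` object (see [extract_lesion()]).
#' @export
extract_from_files <- function(image_path, mask_path, protocol,
                               bat = bat_config(),
                               ms_mode = c("roi-mean-curve", "voxel-mean")) {
  ms_mode <- match.arg(ms_mode)
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  dim_img <- dim(img)
  dim_msk <- dim(msk)
  if (length(dim_img) != 4L)
    stop("image must be a 4D series, got dimensions ",
         paste(dim_img, collapse = "x"))
  if (!identical(as.integer(dim_img[1:3]), as.integer(dim_msk)))
    stop(sprintf("image grid %s does not match mask grid %s",
                 paste(dim_img[1:3], collapse = "x"),
                 paste(dim_msk, collapse = "x")))
  if (dim_img[4] != protocol$n_phases)
    stop(sprintf("image has %d phases but the protocol declares %d",
                 dim_img[4], protocol$n_phases))
  in_mask <- which(msk != 0)
  if (length(in_mask) == 0L) stop("mask is empty: no lesion voxels")
  nxyz <- prod(dim_img[1:3])
  sig <- vapply(seq_len(dim_img[4]),
                function(ti) img[in_mask + (ti - 1) * nxyz],
                numeric(length(in_mask)))
  if (!is.matrix(sig)) sig <- matrix(sig, nrow = 1L)
  conc <- suppressWarnings(signal_to_concentration(sig, protocol))
  extract_lesion(conc, phase_times(protocol), config = bat,
                 ms_mode = ms_mode)
}

#' Read and write run configuration as YAML
#'
#' Serialization is a fixed point: writing a configuration, reading it
#' back and writing it again yields byte-identical YAML.
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly;
#'   `read_run_config` returns the `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  cohort <- unclass(config$cohort)
  cohort$priors_stratify <- cohort$stratify
  cohort$priors <- as.list(cohort$priors)
  cohort$stratify <- NULL
  yaml::write_yaml(list(protocol = unclass(config$protocol),
                        cohort = cohort,
                        bat = unclass(config$bat),
                        ms_mode = config$ms_mode,
                        max_voxels = config$max_voxels,
                        verbose = config$verbose),
                   path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  protocol <- do.call(acquisition_protocol, x$protocol)
  priors <- as.data.frame(x$cohort$priors, stringsAsFactors = FALSE)
  attr(priors, "stratify") <- x$cohort$priors_stratify
  cohort <- cohort_spec(
    n_patients = x$cohort$n_patients,
    lesions_per_patient_weights = unlist(x$cohort$lesions_per_patient_weights),
    priors = priors,
    noise_sigma = x$cohort$noise_sigma,
    rise_time_median = x$cohort$rise_time_median,
    rise_time_sdlog = x$cohort$rise_time_sdlog,
    washout_rate = x$cohort$washout_rate,
    jitter_sd = x$cohort$jitter_sd,
    seed = x$cohort$seed
  )
  run_config(protocol = protocol, cohort = cohort,
             bat = do.call(bat_config, x$bat),
             ms_mode = x$ms_mode,
             max_voxels = x$max_voxels %||% 300,
             verbose = isTRUE(x$verbose))
}

# Plain-list rendering of a study report for JSON serialization.
report_to_list <- function(report) {
  list(
    n_lesions = report$n_lesions,
    n_patients = report$n_patients,
    contrasts = as.data.frame(report),
    logistic = if (is.null(report$logistic$error))
      report$logistic$coefficients else list(error = report$logistic$error),
    auc = if (is.null(report$auc_comparison$error))
      list(full_model = report$auc_comparison$auc1,
           size_alone = report$auc_comparison$auc2,
           delong_p = report$auc_comparison$p_value)
    else list(error = report$auc_comparison$error),
    flagged = report$flagged
  )
}
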