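# Synthetic multi-subject, multi-run dataset generator.
#
# Emulates the statistical structure the replicability analysis assumes:
# a shared smooth truth signal, per-subject smooth deviations (between-
# individual variability), per-run smooth noise (within-individual
# variability), per-run motion summaries, and per-run event designs
# convolved with a double-gamma HRF.

#' Truth-signal specification
#'
#' @param grid_shape Length-3 positive integers, grid size in voxels.
#' @param mask_fractions Ellipsoid mask semi-axis fractions in (0, 1].
#' @param blobs List of blobs, each a list with `center` (length-3 voxel
#'   coordinates, 1-based), `fwhm` (kernel FWHM in voxels, > 0), `amplitude`
#'   (effect size at the blob peak, arbitrary units) and `sign` (+1 or -1).
#'   May be empty for a pure-null truth.
#' @return A `truth_spec` object.
#' @export
truth_spec <- function(grid_shape = c(24L, 24L, 24L),
                       mask_fractions = c(0.9, 0.9, 0.9),
                       blobs = list()) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0))
  for (b in blobs) {
    if (length(b$center) != 3L ||
        any(b$center < 1) || any(b$center > grid_shape)) {
      stop("blob center outside grid", call. = FALSE)
    }
    if (is.null(b$fwhm) || b$fwhm <= 0) stop("blob FWHM must be > 0",
                                             call. = FALSE)
    if (!(b$sign %in% c(-1, 1))) stop("blob sign must be +1 or -1",
                                      call. = FALSE)
  }
  structure(list(grid_shape = grid_shape, mask_fractions = mask_fractions,
                 blobs = blobs),
            class = "truth_spec")
}

#' Evaluate the truth map of a truth specification
#'
#' The truth is a sum of peak-normalized Gaussian blobs (value
#' `sign * amplitude` at each blob center), zeroed outside the ellipsoid
#' mask. Zero blobs give an all-zero (pure-null) map.
#'
#' @param spec A [truth_spec()].
#' @return A [stat_map()].
#' @export
generate_truth_map <- function(spec) {
  stopifnot(inherits(spec, "truth_spec"))
  g <- spec$grid_shape
  mask <- ellipsoid_mask(g, spec$mask_fractions)
  data <- array(0, dim = g)
  for (b in spec$blobs) {
    s2 <- fwhm_to_sigma(b$fwhm)^2
    dx <- (seq_len(g[1]) - b$center[1])^2
    dy <- (seq_len(g[2]) - b$center[2])^2
    dz <- (seq_len(g[3]) - b$center[3])^2
    d2 <- outer(outer(dx, dy, `+`), dz, `+`)
    data <- data + b$sign * b$amplitude * exp(-d2 / (2 * s2))
  }
  stat_map(data, mask)
}

#' Synthetic dataset specification
#'
#' @param truth A [truth_spec()].
#' @param n_subjects Number of participants (>= 4).
#' @param n_runs Functional runs per participant (>= 1).
#' @param sigma_between SD of the per-subject smooth deviation field
#'   (between-individual variability), in truth amplitude units.
#' @param sigma_within SD of the per-run smooth noise field
#'   (within-individual variability), same units.
#' @param noise_fwhm Smoothness (FWHM, voxels) of deviation and noise fields.
#' @param motion_mean,motion_sd Mean and SD of the per-run mean absolute RMS
#'   displacement (mm); draws are reflected at zero.
#' @param motion_noise_coupling Optional coefficient: the run-noise SD is
#'   multiplied by `exp(coupling * motion z-score)`, giving the measurables
#'   regression a recoverable motion effect. Default 0 (independent).
#' @param design List with `n_timepoints`, `onsets` (list of per-event-type
#'   onset vectors, seconds), `durations` (per event type, seconds),
#'   `jitter_sd` (SD of per-run onset jitter, seconds) and `tr` (seconds).
#' @param seed Integer seed; identical spec + seed reproduce the dataset
#'   bit for bit.
#' @return A `synth_spec` object.
#' @export
synth_spec <- function(truth, n_subjects, n_runs = 2L,
                       sigma_between = 0.5, sigma_within = 1,
                       noise_fwhm = 3, motion_mean = 0.25, motion_sd = 0.1,
                       motion_noise_coupling = 0,
                       design = default_design(), seed = 1L) {
  stopifnot(inherits(truth, "truth_spec"))
  if (n_subjects < 4L) {
    stop("n_subjects must be >= 4 (group statistics undefined below that)",
         call. = FALSE)
  }
  stopifnot(n_runs >= 1L, sigma_between >= 0, sigma_within >= 0,
            motion_mean >= 0, motion_sd >= 0)
  structure(list(truth = truth, n_subjects = as.integer(n_subjects),
                 n_runs = as.integer(n_runs),
                 sigma_between = sigma_between, sigma_within = sigma_within,
                 noise_fwhm = noise_fwhm, motion_mean = motion_mean,
                 motion_sd = motion_sd,
                 motion_noise_coupling = motion_noise_coupling,
                 design = design, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Default event design: two event types in a jittered event-related layout
#' @param n_timepoints Number of volumes (TRs).
#' @param tr Repetition time, seconds.
#' @param jitter_sd Onset jitter SD, seconds.
#' @export
default_design <- function(n_timepoints = 120L, tr = 2, jitter_sd = 1.5) {
  total <- n_timepoints * tr
  on_a <- seq(10, total - 30, by = 30)
  on_b <- seq(25, total - 30, by = 30)
  list(n_timepoints = as.integer(n_timepoints), tr = tr,
       onsets = list(a = on_a, b = on_b), durations = c(2, 2),
       jitter_sd = jitter_sd)
}

# SPM-style double-gamma HRF, peak ~5 s, undershoot ~15 s.
double_gamma_hrf <- function(t) {
  stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
}

#' Generate one run's design matrix and contrast
#'
#' Event onsets are jittered (consuming RNG state; seed via the dataset
#' spec or [with_seed()]), boxcars are convolved with a double-gamma HRF
#' sampled at the TR, and an intercept column is appended. The contrast
#' compares the first two event columns (sums to zero over event columns).
#'
#' @param n_timepoints Number of volumes (>= 20).
#' @param event_schedule List as the `design` field of [synth_spec()].
#' @param jitter Logical; apply onset jitter.
#' @return List with `design_matrix` (timepoints x (events + 1)) and
#'   `contrast_vector`.
#' @export
generate_design_matrix <- function(n_timepoints, event_schedule,
                                   jitter = TRUE) {
  if (n_timepoints < 20L) stop("n_timepoints must be >= 20", call. = FALSE)
  sched <- event_schedule
  n_ev <- length(sched$onsets)
  if (n_ev < 2L) stop("need at least 2 event regressors", call. = FALSE)
  tr <- sched$tr
  total <- n_timepoints * tr
  X <- matrix(0, nrow = n_timepoints, ncol = n_ev + 1L)
  hrf <- double_gamma_hrf(seq(0, 30, by = tr))
  tgrid <- (seq_len(n_timepoints) - 1) * tr
  for (e in seq_len(n_ev)) {
    on <- sched$onsets[[e]]
    if (jitter && sched$jitter_sd > 0) {
      on <- on + stats::rnorm(length(on), 0, sched$jitter_sd)
      on <- pmin(pmax(on, 0), total - 1e-9)
    }
    if (any(on < 0) || any(on >= total)) {
      stop("event onsets outside the acquisition window", call. = FALSE)
    }
    dur <- sched$durations[e]
    box <- numeric(n_timepoints)
    for (o in on) {
      box <- box + pmax(0, pmin(tgrid + tr, o + dur) - pmax(tgrid, o)) / tr
    }
    conv <- stats::convolve(box, rev(hrf), type = "open")[seq_len(n_timepoints)]
    X[, e] <- conv
  }
  X[, n_ev + 1L] <- 1
  cvec <- numeric(n_ev + 1L)
  cvec[1:2] <- c(1, -1)
  list(design_matrix = X, contrast_vector = cvec)
}

#' Generate the full synthetic dataset
#'
#' Each run map is `truth + subject_deviation + run_noise`, where the
#' deviation and noise fields are smoothed white noise rescaled to unit
#' in-mask SD and multiplied by `sigma_between` / `sigma_within`. Per-run
#' motion summaries and jittered design matrices are drawn alongside.
#'
#' @param spec A [synth_spec()].
#' @return A `synth_dataset`: list with `spec`, `truth` ([stat_map()]),
#'   `mask`, and `runs`, a list of subject-run records (`subject_id`,
#'   `run_id`, `map`, `motion_rms`, `design_matrix`, `contrast_vector`).
#' @export
generate_subject_maps <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  truth <- generate_truth_map(spec$truth)
  g <- spec$truth$grid_shape
  mask <- truth$mask
  runs <- vector("list", spec$n_subjects * spec$n_runs)
  with_seed(spec$seed, {
    idx <- 0L
    for (s in seq_len(spec$n_subjects)) {
      dev <- if (spec$sigma_between > 0) {
        random_smooth_field(g, spec$noise_fwhm, mask, spec$sigma_between)
      } else {
        array(0, dim = g)
      }
      for (r in seq_len(spec$n_runs)) {
        motion <- abs(stats::rnorm(1, spec$motion_mean, spec$motion_sd))
        sw <- spec$sigma_within
        if (spec$motion_noise_coupling != 0 && spec$motion_sd > 0) {
          zmot <- (motion - spec$motion_mean) / spec$motion_sd
          sw <- sw * exp(spec$motion_noise_coupling * zmot)
        }
        noise <- if (sw > 0) {
          random_smooth_field(g, spec$noise_fwhm, mask, sw)
        } else {
          array(0, dim = g)
        }
        des <- generate_design_matrix(spec$design$n_timepoints, spec$design,
                                      jitter = spec$design$jitter_sd > 0)
        m <- stat_map(truth$data + dev + noise, mask)
        idx <- idx + 1L
        runs[[idx]] <- list(subject_id = sprintf("sub%03d", s),
                            run_id = r, map = m, motion_rms = motion,
                            design_matrix = des$design_matrix,
                            contrast_vector = des$contrast_vector)
      }
    }
  })
  structure(list(spec = spec, truth = truth, mask = mask, runs = runs),
            class = "synth_dataset")
}

#' Write a synthetic dataset to disk
#'
#' One NIfTI-1 volume per run map plus the mask, a CSV sidecar of motion
#' summaries, plain-text design matrices, and a JSON manifest listing every
#' file together with the generating parameters and seed.
#'
#' @param dataset A `synth_dataset` from [generate_subject_maps()].
#' @param directory Output directory (must exist).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
write_dataset <- function(dataset, directory) {
  stopifnot(inherits(dataset, "synth_dataset"))
  if (!dir.exists(directory)) {
    stop("directory does not exist: ", directory, call. = FALSE)
  }
  mask_file <- "mask.nii.gz"
  nifti_write(dataset$mask * 1L, file.path(directory, mask_file),
              datatype = "uint8")
  files <- character(0)
  sidecar <- data.frame(subject_id = character(0), run_id = integer(0),
                        motion_rms = numeric(0), map_file = character(0),
                        design_file = character(0))
  for (rn in dataset$runs) {
    mf <- sprintf("%s_run%02d.nii.gz", rn$subject_id, rn$run_id)
    df <- sprintf("%s_run%02d_design.tsv", rn$subject_id, rn$run_id)
    nifti_write(rn$map$data, file.path(directory, mf), datatype = "float64")
    utils::write.table(rn$design_matrix, file.path(directory, df),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    files <- c(files, mf, df)
    sidecar <- rbind(sidecar,
                     data.frame(subject_id = rn$subject_id, run_id = rn$run_id,
                                motion_rms = rn$motion_rms, map_file = mf,
                                design_file = df))
  }
  utils::write.csv(sidecar, file.path(directory, "runs.csv"),
                   row.names = FALSE)
  spec <- dataset$spec
  manifest <- list(
    n_subjects = spec$n_subjects, n_runs = spec$n_runs, seed = spec$seed,
    sigma_between = spec$sigma_between, sigma_within = spec$sigma_within,
    noise_fwhm = spec$noise_fwhm, grid_shape = spec$truth$grid_shape,
    mask_file = mask_file, sidecar = "runs.csv", files = files)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
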