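test_that("truth maps: empty sum, peak normalization, additivity", {
  g <- c(12L, 12L, 12L)
  empty <- generate_truth_map(truth_spec(g, blobs = list()))
  expect_true(all(empty$data == 0))

  one <- list(center = c(6, 6, 6), fwhm = 3, amplitude = 1.7, sign = 1)
  m1 <- generate_truth_map(truth_spec(g, blobs = list(one)))
  expect_equal(m1$data[6, 6, 6], 1.7)  # kernel peak normalized to 1

  m2 <- generate_truth_map(truth_spec(g, blobs = list(one, one)))
  expect_equal(m2$data, 2 * m1$data, tolerance = 1e-12)

  neg <- list(center = c(4, 4, 6), fwhm = 2, amplitude = 0.5, sign = -1)
  mn <- generate_truth_map(truth_spec(g, blobs = list(neg)))
  expect_equal(mn$data[4, 4, 6], -0.5)
})

test_that("truth spec validation rejects bad blobs", {
  g <- c(10L, 10L, 10L)
  expect_error(truth_spec(g, blobs = list(list(center = c(11, 5, 5),
                                               fwhm = 2, amplitude = 1,
                                               sign = 1))),
               "outside grid")
  expect_error(truth_spec(g, blobs = list(list(center = c(5, 5, 5),
                                               fwhm = 0, amplitude = 1,
                                               sign = 1))),
               "FWHM")
  expect_error(truth_spec(g, blobs = list(list(center = c(5, 5, 5),
                                               fwhm = 2, amplitude = 1,
                                               sign = 2))),
               "sign")
})

test_that("zero-variance spec reproduces the truth exactly; seeds are exact", {
  spec0 <- tiny_spec(sigma_between = 0, sigma_within = 0)
  ds <- generate_subject_maps(spec0)
  truth <- generate_truth_map(spec0$truth)
  for (rn in ds$runs[c(1, 5, 12)]) {
    expect_equal(rn$map$data, truth$data, tolerance = 1e-12)
  }

  a <- generate_subject_maps(tiny_spec(seed = 7))
  b <- generate_subject_maps(tiny_spec(seed = 7))
  expect_identical(lapply(a$runs, function(r) r$map$data),
                   lapply(b$runs, function(r) r$map$data))
  expect_identical(vapply(a$runs, `[[`, numeric(1), "motion_rms"),
                   vapply(b$runs, `[[`, numeric(1), "motion_rms"))
  d <- generate_subject_maps(tiny_spec(seed = 8))
  expect_false(identical(a$runs[[1]]$map$data, d$runs[[1]]$map$data))
})

test_that("between-subject SD matches sigma_between (moment check)", {
  spec <- synth_spec(tiny_truth(), n_subjects = 100L, n_runs = 1L,
                     sigma_between = 2, sigma_within = 0, noise_fwhm = 2,
                     seed = 11L)
  ds <- generate_subject_maps(spec)
  truth <- generate_truth_map(spec$truth)
  vox <- which(ds$mask)[c(50, 200, 400)]
  for (v in vox) {
    vals <- vapply(ds$runs, function(r) r$map$data[v], numeric(1))
    expect_equal(sd(vals - truth$data[v]), 2, tolerance = 0.25)
  }
})

test_that("subject expected maps average to the truth; sigma_between drives decorrelation", {
  spec <- synth_spec(tiny_truth(), n_subjects = 60L, n_runs = 1L,
                     sigma_between = 0.5, sigma_within = 0, noise_fwhm = 2,
                     seed = 3L)
  ds <- generate_subject_maps(spec)
  idx <- which(ds$mask)
  S <- vapply(ds$runs, function(r) r$map$data[idx], numeric(length(idx)))
  truth <- generate_truth_map(spec$truth)$data[idx]
  # mean map -> truth within 3 SE (SE = sigma_between/sqrt(n) per voxel)
  se <- 0.5 / sqrt(60)
  frac_in <- mean(abs(rowMeans(S) - truth) < 3 * se)
  expect_gt(frac_in, 0.95)

  # larger sigma_between -> lower mean between-subject correlation
  mean_between <- function(sb, seed) {
    sp <- synth_spec(tiny_truth(), n_subjects = 50L, n_runs = 1L,
                     sigma_between = sb, sigma_within = 0, noise_fwhm = 2,
                     seed = seed)
    d <- generate_subject_maps(sp)
    M <- vapply(d$runs, function(r) r$map$data[idx], numeric(length(idx)))
    cm <- cor(M)
    mean(cm[upper.tri(cm)])
  }
  expect_gt(mean_between(0.3, 21L), mean_between(1.5, 21L))
})

test_that("design matrices: column count, contrast, jitter behavior", {
  des <- default_design(n_timepoints = 60L)
  out <- with_seed(1, generate_design_matrix(60L, des))
  expect_equal(ncol(out$design_matrix), length(des$onsets) + 1L)
  expect_equal(nrow(out$design_matrix), 60L)
  expect_equal(sum(out$contrast_vector[seq_along(des$onsets)]), 0)
  expect_equal(out$contrast_vector[length(out$contrast_vector)], 0)

  # no jitter -> identical across draws; jitter -> different
  d1 <- generate_design_matrix(60L, des, jitter = FALSE)
  d2 <- generate_design_matrix(60L, des, jitter = FALSE)
  expect_identical(d1$design_matrix, d2$design_matrix)
  j1 <- with_seed(1, generate_design_matrix(60L, des))
  j2 <- with_seed(2, generate_design_matrix(60L, des))
  expect_false(identical(j1$design_matrix, j2$design_matrix))

  bad <- des
  bad$onsets$a <- c(bad$onsets$a, 1e5)
  bad$jitter_sd <- 0
  expect_error(generate_design_matrix(60L, bad, jitter = FALSE),
               "outside")
  expect_error(generate_design_matrix(10L, des), ">= 20")
})

test_that("write_dataset round-trips maps and writes a complete manifest", {
  dir <- withr::local_tempdir()
  spec <- tiny_spec(n_subjects = 4L, n_runs = 2L, seed = 5L)
  ds <- generate_subject_maps(spec)
  manifest <- write_dataset(ds, dir)
  expect_length(manifest$files, 2 * spec$n_subjects * spec$n_runs)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "runs.csv")))

  sidecar <- read.csv(file.path(dir, "runs.csv"))
  expect_equal(nrow(sidecar), spec$n_subjects * spec$n_runs)
  rt <- nifti_read(file.path(dir, sidecar$map_file[3]))
  expect_identical(rt$data, ds$runs[[3]]$map$data)
  mk <- nifti_read(file.path(dir, manifest$mask_file))
  expect_identical(mk$data != 0, ds$mask & TRUE)

  expect_error(write_dataset(ds, file.path(dir, "nope")), "nope")
})

test_that("n_subjects below 4 is rejected", {
  expect_error(tiny_spec(n_subjects = 3L), ">= 4")
})
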