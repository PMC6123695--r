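test_that("smoothness estimator: white noise ~1 voxel, known FWHM recovered", {
  white <- stat_map(with_seed(1, array(rnorm(48^3), dim = c(48, 48, 48))))
  est_w <- estimate_fwhm(white)
  expect_equal(est_w$fwhm_geo, 1, tolerance = 0.2)

  sm <- stat_map(smooth_field(with_seed(2, array(rnorm(48^3),
                                                 dim = c(48, 48, 48))), 4))
  est_s <- estimate_fwhm(sm)
  expect_equal(est_s$fwhm_geo, 4, tolerance = 0.15 * 4)
  expect_equal(est_s$resels, 48^3 / prod(est_s$fwhm_per_axis))

  expect_error(estimate_fwhm(stat_map(array(1, c(8, 8, 8)))), "constant")
})

test_that("proportion threshold selects exactly the top-|z| voxels", {
  g <- c(5L, 5L, 4L)
  z <- with_seed(3, array(rnorm(prod(g)), dim = g))
  m <- stat_map(z)
  cs <- proportion_threshold(m, 0.10)
  n_sel <- sum(cs$signed_mask != 0)
  expect_equal(n_sel, round(0.10 * prod(g)))
  # brute-force ranking oracle
  expected <- sort(order(-abs(z))[seq_len(n_sel)])
  expect_equal(sort(which(cs$signed_mask != 0)), expected)
  sel <- which(cs$signed_mask != 0)
  expect_equal(as.vector(cs$signed_mask[sel]), ifelse(z[sel] >= 0, 1L, -1L))

  expect_equal(sum(proportion_threshold(m, 0)$signed_mask != 0), 0)
  expect_equal(sum(proportion_threshold(m, 1)$signed_mask != 0), prod(g))
  expect_true(all(is.na(vapply(cs$clusters, `[[`, numeric(1),
                               "p_cluster"))))
})

test_that("exact count property holds across random targets (property)", {
  g <- c(6L, 6L, 6L)
  mask <- ellipsoid_mask(g, c(0.9, 0.9, 0.9))
  z <- with_seed(4, array(rnorm(prod(g)), dim = g))
  m <- stat_map(z * mask, mask)
  n_in <- sum(mask)
  for (target in with_seed(5, runif(25))) {
    cs <- proportion_threshold(m, target)
    expect_equal(sum(cs$signed_mask != 0),
                 as.integer(floor(target * n_in + 0.5)))
  }
})

test_that("26-connectivity components match the flood-fill oracle", {
  # corner-touching voxels connect; opposite signs split
  g <- c(4L, 4L, 4L)
  sm <- array(0L, g)
  sm[1, 1, 1] <- 1L
  sm[2, 2, 2] <- 1L
  comps <- label_components(sm)
  expect_length(comps, 1)

  sm2 <- array(0L, g)
  sm2[1, 1, 1] <- 1L
  sm2[2, 1, 1] <- -1L
  expect_length(label_components(sm2), 2)

  # random sparse masks vs brute-force flood fill
  for (seed in 1:10) {
    sgn <- with_seed(seed, array(sample(c(-1L, 0L, 0L, 0L, 1L), 1000,
                                        replace = TRUE),
                                 dim = c(10L, 10L, 10L)))
    got <- label_components(sgn)
    want <- flood_fill_components(sgn)
    key <- function(l) sort(vapply(l, function(c) {
      paste0(c$sign, ":", paste(sort(c$voxels), collapse = ","))
    }, character(1)))
    expect_identical(key(got), key(want))
  }
})

test_that("GRF cluster p-value: boundary, monotonicity, domain error", {
  sm <- structure(list(fwhm_per_axis = c(3, 3, 3), fwhm_geo = 3,
                       resels = 48^3 / 27, n_voxels = 48^3),
                  class = "smoothness_estimate")
  p0 <- grf_cluster_pvalue(0, 2.81, sm)
  E_m <- sm$resels * (4 * log(2))^1.5 * (2.81^2 - 1) *
    exp(-2.81^2 / 2) / (2 * pi)^2
  expect_equal(p0, 1 - exp(-E_m), tolerance = 1e-12)

  sizes <- c(0, 5, 20, 50, 120, 300)
  ps <- vapply(sizes, grf_cluster_pvalue, numeric(1), z_crit = 2.81,
               smoothness = sm)
  expect_true(all(diff(ps) < 0))
  expect_error(grf_cluster_pvalue(10, 0.9, sm), "invalid")
})

test_that("GRF extent threshold is within 2x of Monte-Carlo (small-n check)", {
  # Reduced-n version of the calibration (acceptance runs 200 sims at 48^3):
  # 24 sims on 32^3, FWHM 3, z 2.81, p 0.01.
  g <- c(32L, 32L, 32L)
  maxsz <- vapply(1:24, function(i) with_seed(100 + i, {
    f <- smooth_field(array(rnorm(prod(g)), dim = g), 3)
    f <- (f - mean(f)) / sd(f)
    sgn <- array(0L, dim = g)
    sgn[f > 2.81] <- 1L
    sgn[f < -2.81] <- -1L
    cc <- label_components(sgn)
    if (length(cc)) max(vapply(cc, function(c) length(c$voxels),
                               integer(1))) else 0L
  }), integer(1))
  sm <- structure(list(fwhm_per_axis = c(3, 3, 3), fwhm_geo = 3,
                       resels = prod(g) / 27, n_voxels = prod(g)),
                  class = "smoothness_estimate")
  s <- 0
  while (grf_cluster_pvalue(s, 2.81, sm) >= 0.01) s <- s + 1
  mc99 <- quantile(maxsz, 0.99, names = FALSE)
  expect_gt(s / mc99, 0.5)
  expect_lt(s / mc99, 2.5)  # wider band at this reduced n; 2x at full n
})

test_that("cluster_threshold_grf: empty maps, constructed blob, negation", {
  g <- c(24L, 24L, 24L)
  mask <- ellipsoid_mask(g)
  zero <- stat_map(array(0, g) * mask, mask)
  spec <- threshold_spec("cluster_grf", z_crit = 2.81, cluster_p = 0.01)
  expect_length(cluster_threshold_grf(zero, spec)$clusters, 0)

  # single strong blob on smooth noise -> exactly one surviving + cluster
  blob <- generate_truth_map(truth_spec(g, blobs = list(
    list(center = c(12, 12, 12), fwhm = 5, amplitude = 8, sign = 1))))
  noise <- with_seed(6, smooth_field(array(rnorm(prod(g)), dim = g), 3))
  noise <- noise / sd(noise[mask])
  m <- stat_map((blob$data + noise) * mask, mask)
  cs <- cluster_threshold_grf(m, spec)
  expect_equal(length(cs$clusters), 1)
  expect_equal(cs$clusters[[1]]$sign, 1)
  # oracle: suprathreshold voxels of the surviving cluster all exceed z_crit
  expect_true(all(m$data[cs$clusters[[1]]$voxel_list] > 2.81))

  neg <- stat_map(-m$data, mask)
  cs_neg <- cluster_threshold_grf(neg, spec)
  expect_equal(vapply(cs_neg$clusters, `[[`, numeric(1), "sign"),
               -vapply(cs$clusters, `[[`, numeric(1), "sign"))
  expect_identical(sort(unlist(lapply(cs_neg$clusters, `[[`, "voxel_list"))),
                   sort(unlist(lapply(cs$clusters, `[[`, "voxel_list"))))

  # every surviving voxel at a higher z_crit was suprathreshold at the lower
  spec_hi <- threshold_spec("cluster_grf", z_crit = 3.5, cluster_p = 0.01)
  cs_hi <- cluster_threshold_grf(m, spec_hi)
  hi_vox <- unlist(lapply(cs_hi$clusters, `[[`, "voxel_list"))
  expect_true(all(abs(m$data[hi_vox]) > 2.81))
})

test_that("peaks: max |z|, deterministic tie-break", {
  g <- c(6L, 6L, 6L)
  z <- array(0, g)
  z[2, 2, 2] <- 2.1; z[3, 2, 2] <- 3.0; z[4, 2, 2] <- 2.9
  cs <- proportion_threshold(stat_map(z), 3 / prod(g))
  pk <- find_cluster_peaks(cs)
  expect_equal(pk$peak_z, 3.0)
  expect_equal(pk$peak_voxel, which(z == 3.0))

  z2 <- array(0, g)
  z2[2, 2, 2] <- 2.5; z2[3, 2, 2] <- 2.5   # tie
  cs2 <- proportion_threshold(stat_map(z2), 2 / prod(g))
  pk2 <- find_cluster_peaks(cs2)
  expect_equal(pk2$peak_voxel, min(which(z2 == 2.5)))

  single <- proportion_threshold(stat_map(z2), 1 / prod(g))
  expect_equal(find_cluster_peaks(single)$size, 1)
})

test_that("threshold scaling reproduces the printed full-sample thresholds", {
  expect_equal(scaled_full_sample_threshold(5.08, 200, 279), 6.00)
  expect_equal(scaled_full_sample_threshold(3.50, 214, 463), 5.15)
  expect_equal(scaled_full_sample_threshold(5.08, 200, 463), 7.73)
  expect_equal(scaled_full_sample_threshold(3.50, 214, 279), 4.00)
  # anchors map to themselves
  expect_equal(scaled_full_sample_threshold(5.08, 200, 200), 5.08)
  expect_equal(scaled_full_sample_threshold(3.50, 214, 214), 3.50)
  expect_error(scaled_full_sample_threshold(-1, 200, 279), "positive")
  expect_error(scaled_full_sample_threshold(3.5, 0, 279), "positive")
})
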