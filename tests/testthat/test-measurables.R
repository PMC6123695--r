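test_that("contrast power: orthonormal identity, quadratic scaling, oracle", {
  X <- diag(4)
  expect_equal(contrast_power(X, c(1, 0, 0, 0)), 1)
  X6 <- matrix(c(1, 0, 1, 0, 1, 1, 1, 1, 1, 2, 1, 2), ncol = 2,
               byrow = TRUE)
  cv <- c(0, 1)
  # independent normal-equations oracle
  oracle <- 1 / drop(t(cv) %*% solve(t(X6) %*% X6) %*% cv)
  expect_equal(contrast_power(X6, cv), oracle, tolerance = 1e-12)
  expect_equal(contrast_power(2 * X6, cv), 4 * contrast_power(X6, cv),
               tolerance = 1e-12)
  expect_error(contrast_power(cbind(X6, X6[, 1]), c(0, 1, 0)),
               "rank deficient")
})

test_that("hat outliers: intercept-only zero, planted leverage, rescale invariance", {
  expect_equal(hat_outlier_count(matrix(1, 10, 1)), 0)
  # balanced design plus one extreme-leverage row
  X <- cbind(1, c(rep(c(-1, 1), 10), 50))
  h <- diag(X %*% solve(crossprod(X)) %*% t(X))  # explicit leverage oracle
  expect_equal(hat_outlier_count(X), sum(h > 2 * 2 / nrow(X)))
  expect_gte(hat_outlier_count(X), 1)
  expect_equal(hat_outlier_count(X %*% diag(c(3, 0.1))),
               hat_outlier_count(X))
})

test_that("within/between similarity match brute-force loops", {
  g <- c(6L, 6L, 6L)
  runs <- lapply(1:3, function(i) {
    stat_map(with_seed(i, array(rnorm(prod(g)), g)))
  })
  got <- within_subject_similarity(runs)
  cors <- c(cor(as.vector(runs[[1]]$data), as.vector(runs[[2]]$data)),
            cor(as.vector(runs[[1]]$data), as.vector(runs[[3]]$data)),
            cor(as.vector(runs[[2]]$data), as.vector(runs[[3]]$data)))
  expect_equal(got, mean(cors), tolerance = 1e-12)
  expect_equal(within_subject_similarity(list(runs[[1]], runs[[1]])), 1.0)
  expect_true(is.na(within_subject_similarity(runs[1])))

  B <- between_subject_similarity(runs)
  expect_equal(dim(B), c(3, 3))
  expect_equal(B[1, 2], cors[1], tolerance = 1e-12)
  dup <- between_subject_similarity(list(runs[[1]], runs[[1]]))
  expect_equal(dup[1, 2], 1.0)
})

test_that("pair-level expansion: means, absdiffs, n-1 SDs", {
  pair <- structure(list(sort_index = 1L, k = 3L, P_ids = 1:3,
                         Q_ids = 4:6), class = "pseudo_pair")
  motion <- c(1, 2, 3, 3, 5, 4)
  base <- list(motion = motion, contrast_power = rep(2, 6),
               hat_outliers = rep(0, 6), within_sim = rep(0.5, 6),
               between_sim = diag(6))
  row <- expand_to_pair_level(base, pair)
  expect_equal(row$motion_mean_of_means, (2 + 4) / 2)
  expect_equal(row$motion_diff_of_means, 2)
  # two-pass SD oracle with n-1 denominator
  sd_p <- sqrt(sum((motion[1:3] - 2)^2) / 2)
  sd_q <- sqrt(sum((motion[4:6] - 4)^2) / 2)
  expect_equal(row$motion_mean_of_sds, (sd_p + sd_q) / 2)
  expect_equal(row$motion_diff_of_sds, abs(sd_p - sd_q))
  # identical aggregates -> zero absdiffs
  expect_equal(row$contrast_power_diff_of_means, 0)
  expect_equal(row$contrast_power_diff_of_sds, 0)
  expect_equal(row$sample_size, 3L)
  expect_false(row$incomplete)

  row2 <- expand_to_pair_level(base[-4], pair)
  expect_true(row2$incomplete)
})

# Simulate design rows with controllable outcome structure.
sim_rows <- function(n_per_k, ks = c(8, 16, 32), seed = 1,
                     outcome_fun = function(X) rnorm(nrow(X))) {
  with_seed(seed, {
    rows <- do.call(rbind, lapply(ks, function(k) {
      n <- n_per_k
      df <- data.frame(sort = seq_len(n), sample_size = k)
      for (v in fmrirep:::MEASURABLE_VARS) {
        for (e in fmrirep:::expansion_names(v)) df[[e]] <- rnorm(n)
      }
      df
    }))
    rows$outcome <- outcome_fun(rows)
    rows
  })
}

test_that("task regression: orthogonality contract and span invariance", {
  rows <- sim_rows(40, seed = 2,
                   outcome_fun = function(X) {
                     0.02 * X$sample_size + rnorm(nrow(X))
                   })
  fit <- fit_task_regression(rows)
  Xf <- fit$design
  w <- intersect(fmrirep:::expansion_names("within_sim"), colnames(Xf))
  mid <- intersect(unlist(lapply(c("motion", "contrast_power",
                                   "hat_outliers"),
                                 fmrirep:::expansion_names)), colnames(Xf))
  b <- intersect(fmrirep:::expansion_names("between_sim"), colnames(Xf))
  for (wc in w) for (mc in mid) {
    expect_lt(abs(sum(Xf[, wc] * Xf[, mc])), 1e-8)
  }
  for (bc in b) for (oc in c(mid, w)) {
    expect_lt(abs(sum(Xf[, bc] * Xf[, oc])), 1e-8)
  }
  # span invariance: R^2 equals the un-orthogonalized OLS R^2
  raw <- rows[rows$sample_size < max(rows$sample_size), ]
  reg <- c("sample_size", unlist(lapply(fmrirep:::MEASURABLE_VARS,
                                        fmrirep:::expansion_names)))
  Xr <- scale(as.matrix(raw[, reg]), scale = FALSE)
  yr <- raw$outcome - mean(raw$outcome)
  f <- lm.fit(Xr, yr)
  r2_raw <- 1 - sum(f$residuals^2) / sum(yr^2)
  expect_equal(fit$r2, r2_raw, tolerance = 1e-8)
})

test_that("task regression: null effects small, planted effect recovered", {
  # pure-noise outcome: average |d| stays small
  dvals <- unlist(lapply(1:5, function(s) {
    fit <- fit_task_regression(sim_rows(30, seed = 10 + s))
    abs(fit$effect_size)
  }))
  expect_lt(mean(dvals, na.rm = TRUE), 3)

  # planted sample-size effect: beta recovered within 2 SE
  slope <- 0.05
  rows <- sim_rows(60, seed = 30, outcome_fun = function(X) {
    slope * X$sample_size + rnorm(nrow(X), sd = 0.5)
  })
  fit <- fit_task_regression(rows)
  bhat <- fit$coefficients["sample_size"]
  n <- length(fit$outcome)
  se <- sqrt(fit$sigma2_err / (n - ncol(fit$design))) /
    sqrt(sum(fit$design[, "sample_size"]^2))
  expect_lt(abs(bhat - slope) / se, 2.5)
  expect_equal(names(which.max(fit$delta_r2)), "sample_size")
})

test_that("effect size and delta R2 behave per definition", {
  rows <- sim_rows(50, seed = 40, outcome_fun = function(X) {
    2 * X$motion_mean_of_means + rnorm(nrow(X), sd = 0.3)
  })
  fit <- fit_task_regression(rows)
  # oracle: recompute d for the motion block from the fitted pieces
  XtXinv <- solve(crossprod(fit$design))
  d_oracle <- fit$coefficients / sqrt(fit$sigma2_err * diag(XtXinv))
  mo <- intersect(fmrirep:::expansion_names("motion"), colnames(fit$design))
  expect_equal(unname(block_effect_size(fit, "motion")),
               unname(d_oracle[mo][which.max(abs(d_oracle[mo]))]),
               tolerance = 1e-10)
  # outcome built from one motion expansion -> delta R2 near 1, others small
  expect_gt(block_delta_r2(fit, "motion"), 0.8)
  expect_true(all(fit$delta_r2 >= 0, na.rm = TRUE))
  expect_lt(block_delta_r2(fit, "hat_outliers"), 0.1)
})

test_that("degenerate regressors are dropped, not fatal", {
  rows <- sim_rows(30, seed = 50)
  rows$contrast_power_mean_of_means <- 5  # constant -> zero variance
  fit <- fit_task_regression(rows)
  expect_true("contrast_power_mean_of_means" %in% fit$dropped)
  rows2 <- sim_rows(30, seed = 51)
  rows2[fmrirep:::expansion_names("within_sim")] <- NA_real_
  fit2 <- fit_task_regression(rows2)
  expect_true(all(fmrirep:::expansion_names("within_sim") %in% fit2$dropped))
  expect_true(is.na(block_effect_size(fit2, "within_sim")))
})

test_that("MAP aggregation matches the conjugate-posterior oracle", {
  vals <- c(1.0, 1.2, 1.4)
  n <- 3
  s2 <- var(vals)
  oracle <- (n * mean(vals) / s2) / (n / s2 + 1)  # Normal(0,1) prior
  expect_equal(map_aggregate(vals, "effect_size"), oracle,
               tolerance = 1e-12)
  expect_equal(map_aggregate(c(0, 0, 0), "effect_size"), 0)
  # enormous across-task variance -> prior dominates -> ~0
  expect_lt(abs(map_aggregate(c(-50, 60), "effect_size")), 0.1)

  r2s <- c(0.2, 0.3, 0.4)
  y <- qlogis(r2s)
  mu <- (3 * mean(y) / var(y) + (-20) / 100) / (3 / var(y) + 1 / 100)
  expect_equal(map_aggregate(r2s, "delta_r2"), plogis(mu),
               tolerance = 1e-12)
  expect_gt(map_aggregate(r2s, "delta_r2"), 0)
  expect_lt(map_aggregate(r2s, "delta_r2"), 1)
  expect_error(map_aggregate(0.5, "delta_r2"), ">= 2")
})
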