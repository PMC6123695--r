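# "Measurables": per-participant data-quality variables, their expansion to
# pseudo-replicate-pair level, the orthogonalized task-wise OLS regression
# of unthresholded similarity, and MAP shrinkage aggregation across tasks.

MEASURABLE_VARS <- c("motion", "contrast_power", "hat_outliers",
                     "within_sim", "between_sim")
EXPANSIONS <- c("mean_of_means", "diff_of_means", "mean_of_sds",
                "diff_of_sds")

expansion_names <- function(var) paste(var, EXPANSIONS, sep = "_")

#' Contrast power of a design matrix
#'
#' Reciprocal of the contrast precision `c (X'X)^{-1} c'` -- a design
#' efficiency measure for contrast `c` (averaged over runs upstream).
#'
#' @param X Design matrix (full column rank).
#' @param cvec Contrast vector, length `ncol(X)`.
#' @return `1 / (c (X'X)^{-1} c')`.
#' @export
contrast_power <- function(X, cvec) {
  X <- as.matrix(X)
  stopifnot(length(cvec) == ncol(X))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dep <- colnames(X) %||% paste0("col", seq_len(ncol(X)))
    dep <- dep[qx$pivot[-seq_len(qx$rank)]]
    stop("design matrix is rank deficient; dependent columns: ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  prec <- drop(t(cvec) %*% solve(crossprod(X)) %*% cvec)
  1 / prec
}

#' Count high-leverage rows of a design matrix
#'
#' Diagonal entries of the hat matrix `X (X'X)^{-1} X'` exceeding
#' `2 * rank / nrows`.
#'
#' @param X Design matrix (full column rank).
#' @return Integer count of leverage outliers.
#' @export
hat_outlier_count <- function(X) {
  X <- as.matrix(X)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  Q <- qr.Q(qx)
  h <- rowSums(Q^2)
  sum(h > 2 * qx$rank / nrow(X))
}

#' Within-subject map similarity
#'
#' Mean over all unordered run pairs of the in-mask Pearson correlation
#' between one subject's run-level maps.
#'
#' @param run_maps List of >= 2 [stat_map()]s (one subject's runs).
#' @return Mean pairwise correlation, or `NA` for a single run.
#' @export
within_subject_similarity <- function(run_maps) {
  if (length(run_maps) < 2L) return(NA_real_)
  mask <- Reduce(`&`, lapply(run_maps, `[[`, "mask"))
  V <- vapply(run_maps, function(m) m$data[mask], numeric(sum(mask)))
  cm <- stats::cor(V)
  mean(cm[upper.tri(cm)])
}

#' Between-subject map similarity
#'
#' Whole-brain (in-mask) correlation between subject-level maps for every
#' unordered pair of participants.
#'
#' @param subject_maps List of >= 2 subject-level [stat_map()]s, or an
#'   in-mask value matrix (voxels x subjects).
#' @return Symmetric correlation matrix (diagonal 1).
#' @export
between_subject_similarity <- function(subject_maps) {
  if (is.matrix(subject_maps)) return(stats::cor(subject_maps))
  if (length(subject_maps) < 2L) stop("need >= 2 subjects", call. = FALSE)
  mask <- Reduce(`&`, lapply(subject_maps, `[[`, "mask"))
  V <- vapply(subject_maps, function(m) m$data[mask], numeric(sum(mask)))
  stats::cor(V)
}

# Mean and sample SD over a pseudo-replicate's members (subject-level
# variable) or member pairs (between-subject similarity matrix).
replicate_aggregate <- function(x, ids) {
  vals <- if (is.matrix(x)) {
    sub <- x[ids, ids, drop = FALSE]
    sub[upper.tri(sub)]
  } else {
    x[ids]
  }
  c(mean = mean(vals), sd = stats::sd(vals))
}

#' Expand base measurables to one pseudo-replicate-pair design row
#'
#' For each base variable, the per-member values are aggregated to
#' (mean, SD) within each of P and Q, then combined across the pair as the
#' arithmetic mean and the absolute difference -- four regressors per base
#' variable -- plus the sample size.
#'
#' @param base Named list of base measurables: subject-level numeric
#'   vectors for `motion`, `contrast_power`, `hat_outliers`, `within_sim`,
#'   and the subject-pair correlation matrix for `between_sim`.
#' @param pair A `pseudo_pair` (P_ids, Q_ids, k, sort_index).
#' @return Named list (one design row); `incomplete` flags missing base
#'   values.
#' @export
expand_to_pair_level <- function(base, pair) {
  row <- list(sort = pair$sort_index, sample_size = pair$k)
  incomplete <- FALSE
  for (v in MEASURABLE_VARS) {
    x <- base[[v]]
    if (is.null(x) || (!is.matrix(x) && all(is.na(x)))) {
      row[expansion_names(v)] <- NA_real_
      incomplete <- TRUE
      next
    }
    p <- replicate_aggregate(x, pair$P_ids)
    q <- replicate_aggregate(x, pair$Q_ids)
    nm <- expansion_names(v)
    row[[nm[1]]] <- (p["mean"] + q["mean"]) / 2
    row[[nm[2]]] <- abs(p["mean"] - q["mean"])
    row[[nm[3]]] <- (p["sd"] + q["sd"]) / 2
    row[[nm[4]]] <- abs(p["sd"] - q["sd"])
    if (anyNA(unlist(row[nm]))) incomplete <- TRUE
  }
  row$incomplete <- incomplete
  lapply(row, unname)
}

# Residualize each column of M on the column span of B (joint projection).
orthogonalize_block <- function(M, B) {
  if (!ncol(B)) return(M)
  qb <- qr(B)
  M - qr.Q(qb)[, seq_len(qb$rank), drop = FALSE] %*%
    (t(qr.Q(qb)[, seq_len(qb$rank), drop = FALSE]) %*% M)
}

#' Task-wise orthogonalized regression of replicability on measurables
#'
#' Procedure per task: (1) drop all rows at the task's largest sample size;
#' (2) demean the outcome and all 21 regressors; (3) order regressors as
#' sample_size, motion (4), contrast power (4), hat outliers (4),
#' within-subject similarity (4), between-subject similarity (4);
#' (4) orthogonalize the within block with respect to the 12 regressors of
#' the motion/contrast/hat blocks, and the between block with respect to
#' those 12 plus the orthogonalized within 4; (5) drop regressors with
#' near-zero variance (relative tolerance 1e-12); (6) ordinary least
#' squares.
#'
#' @param rows data.frame of design rows (from [expand_to_pair_level()])
#'   with an `outcome` column (the pair's Pearson similarity) and `k`.
#' @return A `task_regression`: `coefficients`, `sigma2_err` (sum of
#'   squared residuals), `effect_size` and `delta_r2` per block, `dropped`,
#'   `design` (the orthogonalized design matrix), `r2`.
#' @export
fit_task_regression <- function(rows) {
  rows <- as.data.frame(rows)
  ks <- unique(rows$sample_size)
  if (length(ks) < 3L) {
    stop("need >= 3 sample sizes (>= 2 after dropping the largest)",
         call. = FALSE)
  }
  rows <- rows[rows$sample_size < max(ks), , drop = FALSE]
  reg_names <- c("sample_size",
                 unlist(lapply(MEASURABLE_VARS, expansion_names)))
  X <- as.matrix(rows[, reg_names, drop = FALSE])
  y <- rows$outcome
  all_na_cols <- colnames(X)[colSums(!is.na(X)) == 0]
  use_cols <- setdiff(colnames(X), all_na_cols)
  keep_rows <- stats::complete.cases(X[, use_cols, drop = FALSE]) &
    is.finite(y)
  X <- X[keep_rows, , drop = FALSE]
  y <- y[keep_rows]
  # demean
  y <- y - mean(y)
  X[, use_cols] <- sweep(X[, use_cols, drop = FALSE], 2,
                         colMeans(X[, use_cols, drop = FALSE]))
  dropped <- all_na_cols

  blk <- function(v) expansion_names(v)
  mid <- c(blk("motion"), blk("contrast_power"), blk("hat_outliers"))
  usable <- function(cols) {
    cols[cols %in% colnames(X) & colSums(is.na(X[, cols, drop = FALSE])) == 0]
  }
  Xo <- X
  w_cols <- usable(blk("within_sim"))
  if (length(w_cols)) {
    Xo[, w_cols] <- orthogonalize_block(X[, w_cols, drop = FALSE],
                                        X[, usable(mid), drop = FALSE])
  }
  b_cols <- usable(blk("between_sim"))
  if (length(b_cols)) {
    Xo[, b_cols] <- orthogonalize_block(
      X[, b_cols, drop = FALSE],
      cbind(X[, usable(mid), drop = FALSE],
            Xo[, w_cols, drop = FALSE]))
  }
  # drop degenerate (near-zero variance or all-NA) regressors
  vars <- apply(Xo, 2, function(col) {
    if (anyNA(col)) 0 else stats::var(col)
  })
  tol <- 1e-12 * max(vars, 1e-300)
  degenerate <- names(vars)[vars <= tol]
  dropped <- union(dropped, degenerate)
  keep <- setdiff(reg_names, dropped)
  if (!length(keep)) stop("all regressors degenerate", call. = FALSE)
  Xf <- Xo[, keep, drop = FALSE]
  # guard residual collinearity via pivoted QR
  qx <- qr(Xf)
  if (qx$rank < ncol(Xf)) {
    aliased <- colnames(Xf)[qx$pivot[-seq_len(qx$rank)]]
    dropped <- union(dropped, aliased)
    keep <- setdiff(keep, aliased)
    Xf <- Xo[, keep, drop = FALSE]
    qx <- qr(Xf)
  }
  beta <- qr.coef(qx, y)
  resid <- y - drop(Xf %*% beta)
  sigma2 <- sum(resid^2)
  XtXinv <- chol2inv(chol(crossprod(Xf)))
  d_all <- beta / sqrt(sigma2 * diag(XtXinv))
  r2_full <- 1 - sigma2 / sum(y^2)

  blocks <- c("sample_size", MEASURABLE_VARS)
  effect_size <- delta_r2 <- stats::setNames(rep(NA_real_, length(blocks)),
                                             blocks)
  for (b in blocks) {
    cols <- if (b == "sample_size") "sample_size" else expansion_names(b)
    cols <- intersect(cols, keep)
    if (!length(cols)) next
    dvals <- d_all[cols]
    effect_size[b] <- dvals[which.max(abs(dvals))]
    Xr <- Xf[, setdiff(keep, cols), drop = FALSE]
    sigma2_r <- if (ncol(Xr)) {
      br <- qr.coef(qr(Xr), y)
      sum((y - drop(Xr %*% br))^2)
    } else {
      sum(y^2)
    }
    delta_r2[b] <- max(0, (sigma2_r - sigma2) / sum(y^2))
  }
  structure(list(coefficients = beta, sigma2_err = sigma2,
                 effect_size = effect_size, delta_r2 = delta_r2,
                 dropped = dropped, r2 = r2_full, design = Xf, outcome = y),
            class = "task_regression")
}

#' Per-block effect size from a fitted task regression
#'
#' `d_i = beta_i / sqrt(sigma2_err * [(X'X)^{-1}]_ii)` (the usual z-value
#' formula without the reciprocal degrees of freedom), maximized in
#' absolute value over the block's surviving expansions, sign kept.
#'
#' @param fit A [fit_task_regression()] result.
#' @param base_variable Block name (`"sample_size"` or a measurable).
#' @return Signed effect size, or `NA` if no expansion survived.
#' @export
block_effect_size <- function(fit, base_variable) {
  stopifnot(inherits(fit, "task_regression"))
  fit$effect_size[[base_variable]]
}

#' Per-block delta R-squared
#'
#' `R^2(full) - R^2(full minus the block's surviving expansions)`, floored
#' at 0.
#'
#' @inheritParams block_effect_size
#' @export
block_delta_r2 <- function(fit, base_variable) {
  stopifnot(inherits(fit, "task_regression"))
  fit$delta_r2[[base_variable]]
}

#' MAP shrinkage aggregation across tasks
#'
#' Effect sizes: posterior mean of the across-task mean under a
#' `Normal(0, 1)` prior with plug-in across-task variance `s^2`:
#' `mu = (n xbar / s^2) / (n / s^2 + 1)`. Delta R-squared values are
#' clamped to (0, 1), logit-transformed, shrunk toward -20 under a
#' `Normal(-20, 10^2)` prior in the transformed scale, and mapped back
#' through the logistic.
#'
#' @param values Per-task values (>= 2, NAs dropped).
#' @param kind `"effect_size"` or `"delta_r2"`.
#' @return The MAP-aggregated value.
#' @export
map_aggregate <- function(values, kind = c("effect_size", "delta_r2")) {
  kind <- match.arg(kind)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("need >= 2 task values (variance undefined)",
                   call. = FALSE)
  if (kind == "effect_size") {
    s2 <- max(stats::var(values), 1e-12)
    (n * mean(values) / s2) / (n / s2 + 1)
  } else {
    y <- stats::qlogis(pmin(pmax(values, 1e-8), 1 - 1e-8))
    s2 <- max(stats::var(y), 1e-12)
    mu <- (n * mean(y) / s2 + (-20) / 100) / (n / s2 + 1 / 100)
    stats::plogis(mu)
  }
}
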