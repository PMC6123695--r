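# Replicability statistics between paired maps: Pearson similarity of
# unthresholded maps, sign-sensitive Jaccard overlap of thresholded maps,
# peak hit rate, and the peak-height logistic analysis.

#' Pearson similarity of two unthresholded group maps
#'
#' Product-moment correlation of the vectorized map values over the common
#' mask (both masks, both maps nonzero).
#'
#' @param p,q `group_map`s or [stat_map()]s of the same shape.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_similarity <- function(p, q) {
  pm <- if (is_group_map(p)) p$zmap else p
  qm <- if (is_group_map(q)) q$zmap else q
  m <- common_mask(pm, qm)
  x <- pm$data[m]
  y <- qm$data[m]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance inside the common mask", call. = FALSE)
  }
  stats::cor(x, y)
}

signed_mask_of <- function(x) {
  if (inherits(x, "cluster_set")) x$signed_mask else x
}

#' Sign-sensitive Jaccard overlap
#'
#' `|same-sign suprathreshold in both| / |suprathreshold in either|`.
#' A voxel suprathreshold with discordant signs counts once in the union
#' and never in the intersection. An empty union scores 0 (an empty
#' outcome is a replication failure, not a skip).
#'
#' @param a,b `cluster_set`s (or signed \{-1,0,1\} arrays) on one grid.
#' @return Jaccard statistic in `[0, 1]`.
#' @export
jaccard_signed <- function(a, b) {
  sa <- signed_mask_of(a)
  sb <- signed_mask_of(b)
  stopifnot(identical(dim(sa), dim(sb)))
  inter <- sum(sa != 0L & sa == sb)
  union <- sum(sa != 0L | sb != 0L)
  if (union == 0L) return(0)
  inter / union
}

#' Peak hit rate between two thresholded maps
#'
#' Direction a -> b is the fraction of a's cluster peaks whose voxel is
#' suprathreshold in b with matching sign (a positive peak landing in a
#' negative cluster does not count). The value is the mean of the two
#' directions; a direction with zero peaks is excluded from the mean, and
#' if both maps are empty the rate is 0.
#'
#' @param a,b `cluster_set`s on one grid.
#' @return Hit rate in `[0, 1]`.
#' @export
peak_hit_rate <- function(a, b) {
  dir_ab <- peak_hit_direction(a, b)
  dir_ba <- peak_hit_direction(b, a)
  vals <- c(dir_ab, dir_ba)
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(0)
  mean(vals)
}

# Fraction of `from`'s peaks replicated in `into`; NA if `from` has no peaks.
peak_hit_direction <- function(from, into) {
  pk <- find_cluster_peaks(from)
  if (!nrow(pk)) return(NA_real_)
  sm <- signed_mask_of(into)
  mean(sm[pk$peak_voxel] == pk$sign)
}

#' Logistic regression of peak replication on peak height
#'
#' Maximum-likelihood logistic fit of the binary replication outcome on
#' peak z, typically pooled over tasks within one sample size. Complete
#' (or quasi-complete) separation is detected and refit by Firth's
#' penalized likelihood, flagged in the result.
#'
#' @param peak_z Numeric peak heights.
#' @param replicated 0/1 outcomes (peak suprathreshold in counterpart map).
#' @return List with `intercept`, `slope`, `se`, `separation` (logical),
#'   and `predict(z)` giving the fitted replication probability.
#' @export
peak_height_logistic <- function(peak_z, replicated) {
  stopifnot(length(peak_z) == length(replicated))
  keep <- is.finite(peak_z) & !is.na(replicated)
  z <- peak_z[keep]
  y <- as.integer(replicated[keep])
  if (length(unique(z)) < 2L) {
    stop("need >= 2 distinct peak heights", call. = FALSE)
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ z, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (length(unique(y)) < 2L) separation <- TRUE
  if (!separation && any(abs(stats::coef(fit)) > 15)) separation <- TRUE
  if (separation) {
    warning("separation detected in peak-height logistic fit; ",
            "using Firth penalized likelihood", call. = FALSE)
    fit_co <- firth_logistic(cbind(1, z), y)
    co <- fit_co$coef
    se <- fit_co$se
  } else {
    co <- unname(stats::coef(fit))
    se <- unname(sqrt(diag(stats::vcov(fit))))
  }
  list(intercept = co[1], slope = co[2], se = se, separation = separation,
       predict = function(znew) stats::plogis(co[1] + co[2] * znew))
}

# Firth bias-reduced logistic regression: IRLS on the score adjusted by
# hat-matrix leverages (penalty = Jeffreys prior). Handles separation.
firth_logistic <- function(X, y, max_iter = 200, tol = 1e-8) {
  X <- as.matrix(X)
  beta <- numeric(ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    XW <- X * sqrt(w)
    XtWX <- crossprod(XW)
    inv <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(inv)) break
    h <- rowSums((XW %*% inv) * XW)
    U <- crossprod(X, y - mu + h * (0.5 - mu))
    delta <- drop(inv %*% U)
    if (max(abs(delta)) > 5) delta <- delta * 5 / max(abs(delta))
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  eta <- drop(X %*% beta)
  w <- stats::plogis(eta) * (1 - stats::plogis(eta))
  vc <- solve(crossprod(X * sqrt(w)))
  list(coef = unname(beta), se = sqrt(diag(vc)))
}
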