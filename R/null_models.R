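# Smoothness-matched null model: parameterize the observed smoothness and
# robust intensity range of real group maps, simulate smoothed null maps,
# and score each real map by the 95th percentile of its null statistics.

#' Fit a null model from a set of real group maps
#'
#' Normal parameterization (sample mean, sample SD) of the per-map FWHM
#' geometric means and of the per-map robust min and max (2nd and 98th
#' in-mask percentiles).
#'
#' @param real_maps List of >= 2 `group_map`s or [stat_map()]s.
#' @param n_null_maps Number of null maps to simulate per real map
#'   (default 1000).
#' @return A `null_model`: `fwhm_mean`, `fwhm_sd`, `rmin_mean`, `rmin_sd`,
#'   `rmax_mean`, `rmax_sd`, `n_null_maps`.
#' @export
fit_null_model <- function(real_maps, n_null_maps = 1000L) {
  if (length(real_maps) < 2L) stop("need >= 2 real maps", call. = FALSE)
  fw <- vapply(real_maps, function(m) estimate_fwhm(m)$fwhm_geo, numeric(1))
  rmin <- vapply(real_maps, function(m) {
    percentile(mask_values(if (is_group_map(m)) m$zmap else m), 0.02)
  }, numeric(1))
  rmax <- vapply(real_maps, function(m) {
    percentile(mask_values(if (is_group_map(m)) m$zmap else m), 0.98)
  }, numeric(1))
  structure(list(fwhm_mean = mean(fw), fwhm_sd = stats::sd(fw),
                 rmin_mean = mean(rmin), rmin_sd = stats::sd(rmin),
                 rmax_mean = mean(rmax), rmax_sd = stats::sd(rmax),
                 n_null_maps = as.integer(n_null_maps)),
            class = "null_model")
}

#' Simulate one smoothness-matched null map
#'
#' Standard-normal white noise, Gaussian-smoothed with a FWHM drawn from
#' `Normal(fwhm_mean, fwhm_sd)` truncated at 0.5 voxel, then linearly
#' rescaled so its own 2nd/98th in-mask percentiles equal a sampled robust
#' min/max pair (redrawn until max > min; error after 100 redraws).
#' Consumes RNG state; seed with [with_seed()].
#'
#' @param model A [fit_null_model()] result.
#' @param mask 3D logical mask shared with the real data.
#' @return A [stat_map()].
#' @export
sample_null_map <- function(model, mask) {
  stopifnot(inherits(model, "null_model"))
  g <- dim(mask)
  fwhm <- max(stats::rnorm(1, model$fwhm_mean, model$fwhm_sd), 0.5)
  ok <- FALSE
  for (i in seq_len(100L)) {
    rmin <- stats::rnorm(1, model$rmin_mean, model$rmin_sd)
    rmax <- stats::rnorm(1, model$rmax_mean, model$rmax_sd)
    if (rmax > rmin) { ok <- TRUE; break }
  }
  if (!ok) stop("degenerate robust range after 100 redraws", call. = FALSE)
  f <- smooth_field(array(stats::rnorm(prod(g)), dim = g), fwhm)
  v <- f[mask]
  p2 <- percentile(v, 0.02)
  p98 <- percentile(v, 0.98)
  b <- (rmax - rmin) / (p98 - p2)
  f <- rmin + b * (f - p2)
  f[!mask] <- 0
  stat_map(f, mask)
}

#' Simulate a reusable ensemble of null maps
#'
#' The in-mask values of `n` null maps, plus per-map |z| rankings so the
#' ensemble can be proportion-thresholded at any count without resampling.
#'
#' @param model A `null_model`.
#' @param mask 3D logical mask.
#' @param n Number of null maps (defaults to `model$n_null_maps`).
#' @param seed Integer seed.
#' @return A `null_ensemble`: `values` (in-mask voxels x n), `rank`
#'   (position of each voxel in the per-map |value| descending order),
#'   `sign`, `mask`, `mask_idx`.
#' @export
simulate_null_ensemble <- function(model, mask, n = model$n_null_maps,
                                   seed = 1L) {
  idx <- which(mask)
  V <- length(idx)
  values <- matrix(0, V, n)
  with_seed(seed, {
    for (j in seq_len(n)) {
      values[, j] <- sample_null_map(model, mask)$data[idx]
    }
  })
  rank <- matrix(0L, V, n)
  for (j in seq_len(n)) {
    ord <- order(-abs(values[, j]), idx)
    rank[ord, j] <- seq_len(V)
  }
  structure(list(values = values, rank = rank,
                 sign = ifelse(values >= 0, 1L, -1L),
                 mask = mask, mask_idx = idx, n = n, model = model),
            class = "null_ensemble")
}

#' Null statistic for one real map
#'
#' For each simulated null map, computes the requested metric between the
#' real map and the null, and returns the 95th percentile (linear
#' interpolation between order statistics) over the null maps:
#' \itemize{
#'   \item `pearson`: correlation with the real unthresholded map;
#'   \item `jaccard_voxel`, `jaccard_cluster`: the null is two-tailed
#'     proportion-thresholded at the real map's suprathreshold proportion,
#'     then signed Jaccard against the real thresholded map;
#'   \item `peak_hit`: the real map's cluster peaks are classified against
#'     the null's proportion-thresholded signed mask (sign-sensitive).
#' }
#' A real thresholded map with no suprathreshold voxels scores 0.
#'
#' @param real A `group_map` (pearson) or `cluster_set` (thresholded
#'   metrics).
#' @param model A `null_model` (ignored when `ensemble` is given).
#' @param metric One of `"pearson"`, `"jaccard_voxel"`, `"jaccard_cluster"`,
#'   `"peak_hit"`.
#' @param seed Seed for ad-hoc simulation when no ensemble is supplied.
#' @param ensemble Optional [simulate_null_ensemble()] (shared across real
#'   maps, as when 1000 nulls are drawn once per task and sample size).
#' @return The 95th-percentile null value.
#' @export
null_statistic_for_map <- function(real, model, metric, seed = 1L,
                                   ensemble = NULL) {
  metric <- match.arg(metric, c("pearson", "jaccard_voxel",
                                "jaccard_cluster", "peak_hit"))
  if (is.null(ensemble)) {
    mask <- if (metric == "pearson") {
      (if (is_group_map(real)) real$zmap else real)$mask
    } else {
      stopifnot(inherits(real, "cluster_set"))
      src <- real$source
      (if (is_group_map(src)) src$zmap else src)$mask
    }
    ensemble <- simulate_null_ensemble(model, mask, seed = seed)
  }
  percentile(null_statistics(real, ensemble, metric), 0.95)
}

# Vector of per-null-map statistics for one real map.
null_statistics <- function(real, ens, metric) {
  if (metric == "pearson") {
    zm <- if (is_group_map(real)) real$zmap else real
    x <- zm$data[ens$mask_idx]
    keep <- x != 0
    return(drop(stats::cor(x[keep], ens$values[keep, , drop = FALSE])))
  }
  stopifnot(inherits(real, "cluster_set"))
  sm <- real$signed_mask
  sel <- which(sm != 0L)
  n_i <- length(sel)
  if (n_i == 0L) return(numeric(ens$n))
  if (metric %in% c("jaccard_voxel", "jaccard_cluster")) {
    # Null suprathreshold set at matched proportion = rank <= n_i.
    pos <- match(sel, ens$mask_idx)
    pos <- pos[!is.na(pos)]
    R <- ens$rank[pos, , drop = FALSE] <= n_i
    S <- ens$sign[pos, , drop = FALSE]
    same <- colSums(R & S == as.vector(sm[ens$mask_idx[pos]]))
    inter_any <- colSums(R)
    union <- n_i + n_i - inter_any
    return(ifelse(union == 0, 0, same / union))
  }
  # peak_hit: classify real peaks against the null's thresholded mask
  pk <- find_cluster_peaks(real)
  if (!nrow(pk)) return(numeric(ens$n))
  pos <- match(pk$peak_voxel, ens$mask_idx)
  ok <- !is.na(pos)
  if (!any(ok)) return(numeric(ens$n))
  R <- ens$rank[pos[ok], , drop = FALSE] <= n_i
  S <- ens$sign[pos[ok], , drop = FALSE]
  hits <- R & (S == pk$sign[ok])
  colMeans(hits)
}

#' Average per-map null statistics into null curves
#'
#' @param null_records data.frame with columns `task`, `k`, `metric`,
#'   `threshold_label`, `value` (one row per real map).
#' @return data.frame with one row per (task, k, metric, threshold_label)
#'   holding the mean null value.
#' @export
null_curves <- function(null_records) {
  agg <- stats::aggregate(
    value ~ task + k + metric + threshold_label,
    data = null_records, FUN = mean)
  agg[order(agg$task, agg$metric, agg$threshold_label, agg$k), ]
}
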