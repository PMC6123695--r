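# Group-level model: one-sample t -> z stand-in for a mixed-effects tool.
#
# Subject-level maps are combined by a voxelwise one-sample t-test and the
# t statistic is mapped to a z statistic by matching cumulative probability
# (z = qnorm(pt(t, df))). This deliberately replaces the reference
# mixed-effects group model: every downstream replicability metric consumes
# a group z-map and is agnostic to how it was fit.

Z_CLAMP <- 38  # double-precision-safe normal quantile range

#' Combine one subject's runs into a subject-level map
#'
#' Voxelwise arithmetic mean of the run maps (a simplified fixed-effects
#' combination; all runs weighted equally).
#'
#' @param runs List of subject-run records (each with a `map` [stat_map()]),
#'   or a list of `stat_map`s.
#' @return A [stat_map()].
#' @export
subject_map <- function(runs) {
  if (length(runs) < 1L) stop("need at least one run", call. = FALSE)
  maps <- lapply(runs, function(r) if (is_stat_map(r)) r else r$map)
  shp <- dim(maps[[1]]$data)
  for (m in maps) {
    if (!identical(dim(m$data), shp)) {
      stop("run maps have mismatched shapes", call. = FALSE)
    }
  }
  acc <- Reduce(`+`, lapply(maps, `[[`, "data")) / length(maps)
  mask <- Reduce(`&`, lapply(maps, `[[`, "mask"))
  stat_map(acc * mask, mask, maps[[1]]$voxel_size)
}

# Map t (df) to z by two-sided-symmetric cumulative matching, computed in
# the tail's log domain so large |t| does not saturate; clamped at +/- 38.
t_to_z <- function(t, df) {
  z <- numeric(length(t))
  neg <- t <= 0
  z[neg] <- stats::qnorm(stats::pt(t[neg], df, log.p = TRUE), log.p = TRUE)
  z[!neg] <- -stats::qnorm(stats::pt(-t[!neg], df, log.p = TRUE),
                           log.p = TRUE)
  pmin(pmax(z, -Z_CLAMP), Z_CLAMP)
}

# Core one-sample t -> z on an (in-mask voxels x k) value matrix.
# Returns the z vector; sd = 0 voxels get the clamp with the mean's sign.
group_z_values <- function(V, warn_degenerate = TRUE) {
  k <- ncol(V)
  m <- rowMeans(V)
  s <- sqrt(pmax(rowSums((V - m)^2) / (k - 1), 0))
  deg <- s == 0
  t <- numeric(length(m))
  t[!deg] <- m[!deg] / (s[!deg] / sqrt(k))
  z <- t_to_z(t, k - 1)
  if (any(deg)) {
    if (warn_degenerate) {
      warning(sum(deg), " voxel(s) with zero variance across subjects; ",
              "z set to clamped value", call. = FALSE)
    }
    z[deg] <- sign(m[deg]) * Z_CLAMP
  }
  z
}

#' Group-level z map from subject-level maps
#'
#' Voxelwise one-sample t = mean / (sd / sqrt(k)) with df = k - 1, converted
#' to z by cumulative-probability matching and clamped at |z| = 38. The
#' group mask is the intersection of the member masks.
#'
#' @param maps List of k subject-level [stat_map()]s (k >= 4).
#' @param k Sample size; must equal `length(maps)`.
#' @param member_ids Optional participant identifiers.
#' @param label `"P"` or `"Q"` (pseudo-replicate arm), or `""`.
#' @return A `group_map`: list with `zmap` ([stat_map()]), `k`,
#'   `member_ids`, `label`.
#' @export
compute_group_zmap <- function(maps, k = length(maps),
                               member_ids = NULL, label = "") {
  if (k != length(maps)) stop("k must equal the number of maps",
                              call. = FALSE)
  if (k < 4L) stop("need k >= 4 subject maps", call. = FALSE)
  shp <- dim(maps[[1]]$data)
  mask <- Reduce(`&`, lapply(maps, `[[`, "mask"))
  V <- vapply(maps, function(m) m$data[mask], numeric(sum(mask)))
  z <- group_z_values(V)
  data <- array(0, dim = shp)
  data[mask] <- z
  group_map(stat_map(data, mask, maps[[1]]$voxel_size), k = k,
            member_ids = member_ids %||% as.character(seq_len(k)),
            label = label)
}

group_map <- function(zmap, k, member_ids, label = "") {
  stopifnot(is_stat_map(zmap), length(member_ids) == k)
  structure(list(zmap = zmap, k = as.integer(k),
                 member_ids = member_ids, label = label),
            class = "group_map")
}

is_group_map <- function(x) inherits(x, "group_map")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Filename convention for persisted group maps.
group_map_filename <- function(task, sort, label, k) {
  sprintf("%s_%04d_%s_k%d.nii.gz", task, sort, label, k)
}
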