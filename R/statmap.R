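# StatMap: the universal currency of the pipeline -- a 3D volumetric
# statistic (or contrast-estimate) image together with its analysis mask
# and voxel geometry.

#' Construct a StatMap
#'
#' A `stat_map` holds a 3D array of statistic values, a boolean mask of the
#' analysis volume, and the voxel size in mm. Values outside the mask are
#' forced to zero; values inside must be finite.
#'
#' @param data 3D numeric array.
#' @param mask 3D logical (or 0/1 numeric) array of the same shape.
#' @param voxel_size Length-3 numeric, voxel dimensions in mm.
#' @return An object of class `stat_map`.
#' @export
stat_map <- function(data, mask = NULL, voxel_size = c(1, 1, 1)) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dim = dim(data))
  if (!identical(dim(mask), dim(data))) {
    stop("mask shape does not match data shape", call. = FALSE)
  }
  mask <- array(as.logical(mask != 0), dim = dim(data))
  if (any(!is.finite(data[mask]))) {
    stop("non-finite values inside the mask", call. = FALSE)
  }
  data[!mask] <- 0
  structure(list(data = data, mask = mask,
                 voxel_size = as.double(voxel_size)),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<stat_map> %dx%dx%d, %d in-mask voxels, voxel %s mm\n",
              d[1], d[2], d[3], sum(x$mask),
              paste(signif(x$voxel_size, 3), collapse = "x")))
  invisible(x)
}

is_stat_map <- function(x) inherits(x, "stat_map")

# In-mask values as a vector (fixed voxel order: column-major / x fastest).
mask_values <- function(map) map$data[map$mask]

#' Ellipsoid analysis mask
#'
#' Builds a centered ellipsoid mask on a voxel grid; `axis_fractions` are the
#' semi-axes as fractions of the half-grid extent along each dimension.
#'
#' @param grid_shape Length-3 integer grid dimensions.
#' @param axis_fractions Length-3 numeric in (0, 1].
#' @return 3D logical array.
#' @export
ellipsoid_mask <- function(grid_shape, axis_fractions = c(0.9, 0.9, 0.9)) {
  stopifnot(length(grid_shape) == 3L, length(axis_fractions) == 3L)
  if (any(axis_fractions <= 0) || any(axis_fractions > 1)) {
    stop("axis fractions must be in (0, 1]", call. = FALSE)
  }
  ctr <- (grid_shape + 1) / 2
  semi <- axis_fractions * (grid_shape - 1) / 2
  ax <- lapply(1:3, function(a) ((seq_len(grid_shape[a]) - ctr[a]) / semi[a])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  d2 <= 1
}

#' Common mask of two StatMaps
#'
#' Voxels inside both masks and with nonzero data in both maps (zero data is
#' treated as "outside field of view", matching the convention of removing
#' voxels that were zero in either map).
#'
#' @param a,b `stat_map` objects of the same shape.
#' @return 3D logical array.
#' @export
common_mask <- function(a, b) {
  if (is_group_map(a)) a <- a$zmap
  if (is_group_map(b)) b <- b$zmap
  stopifnot(is_stat_map(a), is_stat_map(b))
  if (!identical(dim(a$data), dim(b$data))) {
    stop("maps have different shapes", call. = FALSE)
  }
  m <- a$mask & b$mask & (a$data != 0) & (b$data != 0)
  if (!any(m)) stop("common mask is empty: no comparable voxels",
                    call. = FALSE)
  m
}
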