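# Shared fixtures and independent brute-force oracles.

tiny_truth <- function(blobs = list(list(center = c(6, 6, 6), fwhm = 3,
                                         amplitude = 1, sign = 1)),
                       grid = c(12L, 12L, 12L)) {
  truth_spec(grid, mask_fractions = c(0.95, 0.95, 0.95), blobs = blobs)
}

tiny_spec <- function(n_subjects = 6L, n_runs = 2L, sigma_between = 0.5,
                      sigma_within = 1, seed = 42L, ...) {
  synth_spec(tiny_truth(), n_subjects = n_subjects, n_runs = n_runs,
             sigma_between = sigma_between, sigma_within = sigma_within,
             noise_fwhm = 2, seed = seed, ...)
}

# Brute-force flood fill (6/26-connectivity) over a signed mask; the
# independent oracle for label_components.
flood_fill_components <- function(signed_mask) {
  d <- dim(signed_mask)
  coords <- function(i) {
    i0 <- i - 1L
    c(i0 %% d[1] + 1L, (i0 %/% d[1]) %% d[2] + 1L, i0 %/% (d[1] * d[2]) + 1L)
  }
  out <- list()
  for (s in c(1L, -1L)) {
    left <- which(signed_mask == s)
    visited <- logical(prod(d))
    for (seed_vox in left) {
      if (visited[seed_vox]) next
      comp <- integer(0)
      queue <- seed_vox
      visited[seed_vox] <- TRUE
      while (length(queue)) {
        v <- queue[1]
        queue <- queue[-1]
        comp <- c(comp, v)
        cv <- coords(v)
        for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
          if (dx == 0 && dy == 0 && dz == 0) next
          n <- cv + c(dx, dy, dz)
          if (any(n < 1) || any(n > d)) next
          ni <- (n[1] - 1L) + (n[2] - 1L) * d[1] + (n[3] - 1L) * d[1] * d[2] + 1L
          if (!visited[ni] && signed_mask[ni] == s) {
            visited[ni] <- TRUE
            queue <- c(queue, ni)
          }
        }
      }
      out[[length(out) + 1L]] <- list(sign = s, voxels = sort(comp))
    }
  }
  out
}

# Brute-force sign-sensitive Jaccard from raw voxel sets.
jaccard_brute <- function(sa, sb) {
  inter <- 0L
  union <- 0L
  for (v in seq_along(sa)) {
    a <- sa[v]; b <- sb[v]
    if (a != 0L || b != 0L) union <- union + 1L
    if (a != 0L && a == b) inter <- inter + 1L
  }
  if (union == 0L) return(0)
  inter / union
}
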