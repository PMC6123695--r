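# Pseudo-replicate resampling: repeated random disjoint P/Q participant
# splits with nested sample-size prefixes, shareable across tasks that
# have identical participants.

#' Build a split plan
#'
#' Each sort is one uniform random permutation of all participants: the
#' first floor(N/2) form the P order, the next floor(N/2) the Q order (for
#' odd N the leftover participant is unused in that sort). The first k
#' entries of each order give the sample-size-k pseudo-replicate, so
#' prefixes are nested across k within a sort.
#'
#' @param n_total Number of participants.
#' @param n_sorts Number of random sorts (>= 1).
#' @param k_grid Increasing vector of sample sizes, all <= floor(n_total/2).
#' @param seed Integer seed; identical arguments + seed give an identical
#'   plan.
#' @return A `split_plan`: list with `n_total`, `k_grid`, `seed`, and
#'   `sorts`, a list of `list(P = <ids>, Q = <ids>)` integer orders.
#' @export
make_split_plan <- function(n_total, n_sorts, k_grid, seed = 1L) {
  half <- n_total %/% 2L
  bad <- k_grid[k_grid > half]
  if (length(bad)) {
    stop("k values exceed floor(N/2) = ", half, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (n_sorts < 1L) stop("n_sorts must be >= 1", call. = FALSE)
  k_grid <- sort(unique(as.integer(k_grid)))
  sorts <- with_seed(seed, lapply(seq_len(n_sorts), function(i) {
    perm <- sample.int(n_total)
    list(P = perm[seq_len(half)], Q = perm[half + seq_len(half)])
  }))
  structure(list(n_total = as.integer(n_total), n_sorts = as.integer(n_sorts),
                 k_grid = k_grid, seed = as.integer(seed), sorts = sorts),
            class = "split_plan")
}

#' Enumerate pseudo-replicate pairs of a plan
#'
#' Yields every (sort, k) combination exactly once, ordered by sort then k.
#' A k larger than floor(N/2) for a given task can be filtered upstream
#' ("in-range k").
#'
#' @param plan A [make_split_plan()] plan.
#' @param k_grid Optional subset of the plan's k grid to iterate.
#' @return List of `pseudo_pair`s: `sort_index`, `k`, `P_ids`, `Q_ids`.
#' @export
iterate_pseudo_pairs <- function(plan, k_grid = plan$k_grid) {
  stopifnot(inherits(plan, "split_plan"))
  out <- vector("list", plan$n_sorts * length(k_grid))
  i <- 0L
  for (s in seq_len(plan$n_sorts)) {
    srt <- plan$sorts[[s]]
    for (k in k_grid) {
      i <- i + 1L
      out[[i]] <- structure(list(sort_index = s, k = as.integer(k),
                                 P_ids = srt$P[seq_len(k)],
                                 Q_ids = srt$Q[seq_len(k)]),
                            class = "pseudo_pair")
    }
  }
  out[seq_len(i)]
}

#' Serialize a split plan to JSON (for exact reproducibility and cross-task
#' sharing)
#' @param plan A `split_plan`.
#' @param path Output path.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  sorts <- lapply(seq_len(nrow_or_len(p$sorts)), function(i) {
    s <- if (is.data.frame(p$sorts)) p$sorts[i, ] else p$sorts[[i]]
    list(P = as.integer(unlist(s$P)), Q = as.integer(unlist(s$Q)))
  })
  structure(list(n_total = as.integer(p$n_total),
                 n_sorts = as.integer(p$n_sorts),
                 k_grid = as.integer(p$k_grid), seed = as.integer(p$seed),
                 sorts = sorts),
            class = "split_plan")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
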