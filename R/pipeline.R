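# Experiment orchestration: tasks x sorts x k grid x metrics, with
# full-sample reference proportions, smoothness-matched nulls, curve
# summaries, and the measurables regression inputs.

ALL_METRICS <- c("pearson", "jaccard_voxel", "jaccard_cluster", "peak_hit")

#' Declare a synthetic task for an experiment
#'
#' @param name Task name.
#' @param spec A [synth_spec()] (its seed is re-derived from the experiment
#'   seed so one experiment seed reproduces everything).
#' @param share_group Tasks with the same group id share one split plan
#'   (identical participants, identical sorts).
#' @return A task descriptor.
#' @export
synth_task <- function(name, spec, share_group = name) {
  stopifnot(inherits(spec, "synth_spec"))
  list(name = name, spec = spec, share_group = share_group,
       n_total = spec$n_subjects)
}

#' Experiment configuration
#'
#' @param tasks List of [synth_task()] descriptors.
#' @param k_grid Sample sizes; each task runs the in-range subset
#'   (k <= floor(N/2)).
#' @param n_sorts Number of random P/Q sorts per shared-participant group.
#' @param n_null_maps Null maps per (task, k).
#' @param seed Master seed; every stage derives its stream from it.
#' @param metrics Subset of `pearson`, `jaccard_voxel`, `jaccard_cluster`,
#'   `peak_hit`.
#' @param cluster_liberal,cluster_conservative Cluster-forming z and
#'   cluster-level p for the two pseudo-replicate GRF thresholds.
#' @param anchor_liberal,anchor_conservative Full-sample threshold anchors
#'   `(z, n)`; each task's full-sample threshold is the anchor scaled by
#'   `sqrt(N_task / n_anchor)` (half-up, 2 decimals).
#' @param full_sample_cluster_p Cluster p for full-sample thresholding.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(tasks, k_grid = c(16L, 36L, 64L),
                              n_sorts = 50L, n_null_maps = 100L, seed = 1L,
                              metrics = ALL_METRICS,
                              cluster_liberal = list(z = 1.96, p = 0.05),
                              cluster_conservative = list(z = 2.81, p = 0.01),
                              anchor_liberal = list(z = 3.50, n = 214),
                              anchor_conservative = list(z = 5.08, n = 200),
                              full_sample_cluster_p = 0.01) {
  stopifnot(length(tasks) >= 1L, all(metrics %in% ALL_METRICS))
  for (th in list(cluster_liberal, cluster_conservative,
                  anchor_liberal, anchor_conservative)) {
    if (th$z <= 0) stop("thresholds must be positive", call. = FALSE)
  }
  nm <- vapply(tasks, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate task names", call. = FALSE)
  names(tasks) <- nm
  structure(list(tasks = tasks, k_grid = sort(unique(as.integer(k_grid))),
                 n_sorts = as.integer(n_sorts),
                 n_null_maps = as.integer(n_null_maps),
                 seed = as.integer(seed), metrics = metrics,
                 cluster_liberal = cluster_liberal,
                 cluster_conservative = cluster_conservative,
                 anchor_liberal = anchor_liberal,
                 anchor_conservative = anchor_conservative,
                 full_sample_cluster_p = full_sample_cluster_p),
            class = "experiment_config")
}

# Generate one task's data and reduce it to what the pipeline needs:
# subject-level in-mask value matrix + per-subject measurables.
build_task_data <- function(task, config) {
  spec <- task$spec
  spec$seed <- derive_seed(config$seed, paste0("data_", task$name))
  ds <- generate_subject_maps(spec)
  mask <- ds$mask
  idx <- which(mask)
  V <- length(idx)
  n <- spec$n_subjects
  S <- matrix(0, V, n)
  motion <- cpower <- hat_out <- within <- numeric(n)
  by_subj <- split(ds$runs, vapply(ds$runs, `[[`, character(1),
                                   "subject_id"))
  by_subj <- by_subj[order(names(by_subj))]
  for (s in seq_len(n)) {
    runs <- by_subj[[s]]
    R <- vapply(runs, function(r) r$map$data[idx], numeric(V))
    S[, s] <- rowMeans(R)
    within[s] <- if (length(runs) >= 2L) {
      cm <- stats::cor(R)
      mean(cm[upper.tri(cm)])
    } else {
      NA_real_
    }
    motion[s] <- mean(vapply(runs, `[[`, numeric(1), "motion_rms"))
    cpower[s] <- mean(vapply(runs, function(r) {
      contrast_power(r$design_matrix, r$contrast_vector)
    }, numeric(1)))
    hat_out[s] <- mean(vapply(runs, function(r) {
      hat_outlier_count(r$design_matrix)
    }, numeric(1)))
  }
  list(name = task$name, spec = spec, mask = mask, mask_idx = idx,
       grid = dim(mask), n = n, S = S, truth = ds$truth,
       base = list(motion = motion, contrast_power = cpower,
                   hat_outliers = hat_out, within_sim = within,
                   between_sim = stats::cor(S)))
}

# z map (as group_map) for a subject subset of a task's value matrix.
group_map_from_subset <- function(td, ids, label = "") {
  z <- group_z_values(td$S[, ids, drop = FALSE], warn_degenerate = FALSE)
  arr <- array(0, dim = td$grid)
  arr[td$mask_idx] <- z
  group_map(stat_map(arr, td$mask), k = length(ids),
            member_ids = as.character(ids), label = label)
}

#' Full-sample reference: suprathreshold proportions per threshold label
#'
#' Builds the group z map from all N participants, applies two-tailed GRF
#' cluster thresholding at the task's scaled liberal and conservative
#' full-sample thresholds (cluster p per config), and returns the
#' proportion of in-mask voxels suprathreshold at each -- the target
#' proportions for proportion-based thresholding.
#'
#' @param td Task data from the experiment runner (or a `group_map` via
#'   `full_map`).
#' @param config An [experiment_config()].
#' @return List with `liberal`, `conservative` proportions and the two z
#'   thresholds used.
#' @export
run_full_sample_reference <- function(td, config) {
  full <- group_map_from_subset(td, seq_len(td$n), label = "full")
  out <- list()
  for (lab in c("liberal", "conservative")) {
    anchor <- config[[paste0("anchor_", lab)]]
    zc <- scaled_full_sample_threshold(anchor$z, anchor$n, td$n)
    cs <- cluster_threshold_grf(full, threshold_spec(
      "cluster_grf", z_crit = zc, cluster_p = config$full_sample_cluster_p))
    prop <- sum(cs$signed_mask != 0L) / length(td$mask_idx)
    if (prop == 0) {
      warning("task ", td$name, ": empty full-sample thresholded map (",
              lab, "); reference proportion 0", call. = FALSE)
    }
    out[[lab]] <- prop
    out[[paste0("z_", lab)]] <- zc
  }
  out
}

#' Run the full pseudo-replicate experiment
#'
#' For every task, sort, and in-range k: builds the P and Q group z maps,
#' computes the requested similarity metrics at the configured thresholds,
#' fits a smoothness-matched null model per (task, k), and scores every
#' real map against a shared ensemble of null maps. Tasks with the same
#' `share_group` reuse one split plan. Fully reproducible from
#' `config$seed`.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory: writes `records.csv`,
#'   `null_curves.csv`, `peaks.csv`, `reference.json`, `plans/*.json`.
#' @param verbose Print progress lines (task, sort, k, stage).
#' @return A results bundle: `records`, `null_records`, `null_curves`,
#'   `peaks`, `reference`, `measurables` (per-task base variables and pair
#'   rows), `plans`, `config`.
#' @export
run_experiment <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  groups <- unique(vapply(config$tasks, `[[`, character(1), "share_group"))
  plans <- list()
  for (g in groups) {
    n_tot <- unique(vapply(
      config$tasks[vapply(config$tasks, `[[`, character(1),
                          "share_group") == g],
      `[[`, numeric(1), "n_total"))
    if (length(n_tot) != 1L) {
      stop("tasks sharing group '", g, "' have different N", call. = FALSE)
    }
    kg <- config$k_grid[config$k_grid <= n_tot %/% 2L]
    plans[[g]] <- make_split_plan(n_tot, config$n_sorts, kg,
                                  seed = derive_seed(config$seed,
                                                     paste0("plan_", g)))
  }

  records <- list()
  null_records <- list()
  peaks_rows <- list()
  reference <- list()
  measurables <- list()

  lab_specs <- list(
    liberal = threshold_spec("cluster_grf",
                             z_crit = config$cluster_liberal$z,
                             cluster_p = config$cluster_liberal$p),
    conservative = threshold_spec("cluster_grf",
                                  z_crit = config$cluster_conservative$z,
                                  cluster_p = config$cluster_conservative$p))

  for (task in config$tasks) {
    say("task %s: generating data", task$name)
    td <- build_task_data(task, config)
    plan <- plans[[task$share_group]]
    ref <- run_full_sample_reference(td, config)
    reference[[task$name]] <- ref
    kg <- plan$k_grid

    # per-k stores for null fitting/scoring
    store <- list()
    for (k in kg) store[[as.character(k)]] <- list(maps = list(),
                                                   sets = list())

    for (pair in iterate_pseudo_pairs(plan)) {
      k <- pair$k
      kk <- as.character(k)
      arms <- list(P = pair$P_ids, Q = pair$Q_ids)
      gm <- lapply(names(arms), function(a) {
        group_map_from_subset(td, arms[[a]], label = a)
      })
      names(gm) <- names(arms)
      cell <- list(task = task$name, sort = pair$sort_index, k = k)

      if ("pearson" %in% config$metrics) {
        r <- pearson_similarity(gm$P, gm$Q)
        records[[length(records) + 1L]] <-
          c(cell, metric = "pearson", threshold_label = "none", value = r)
      }
      sets <- list()
      for (lab in c("liberal", "conservative")) {
        if ("jaccard_voxel" %in% config$metrics) {
          csP <- proportion_threshold(gm$P, ref[[lab]])
          csQ <- proportion_threshold(gm$Q, ref[[lab]])
          records[[length(records) + 1L]] <-
            c(cell, metric = "jaccard_voxel", threshold_label = lab,
              value = jaccard_signed(csP, csQ))
          sets[[paste0("voxel_", lab)]] <- list(P = csP, Q = csQ)
        }
        if (any(c("jaccard_cluster", "peak_hit") %in% config$metrics)) {
          gP <- cluster_threshold_grf(gm$P, lab_specs[[lab]])
          gQ <- cluster_threshold_grf(gm$Q, lab_specs[[lab]])
          if ("jaccard_cluster" %in% config$metrics) {
            records[[length(records) + 1L]] <-
              c(cell, metric = "jaccard_cluster", threshold_label = lab,
                value = jaccard_signed(gP, gQ))
          }
          if ("peak_hit" %in% config$metrics) {
            records[[length(records) + 1L]] <-
              c(cell, metric = "peak_hit", threshold_label = lab,
                value = peak_hit_rate(gP, gQ))
            for (dir in list(c("P", "Q"), c("Q", "P"))) {
              from <- if (dir[1] == "P") gP else gQ
              into <- if (dir[1] == "P") gQ else gP
              pk <- find_cluster_peaks(from)
              if (nrow(pk)) {
                peaks_rows[[length(peaks_rows) + 1L]] <- data.frame(
                  task = task$name, sort = pair$sort_index, k = k,
                  threshold_label = lab, direction = paste(dir,
                                                           collapse = "->"),
                  peak_z = pk$peak_z,
                  replicated = as.integer(
                    signed_mask_of(into)[pk$peak_voxel] == pk$sign))
              }
            }
          }
          sets[[paste0("cluster_", lab)]] <- list(P = gP, Q = gQ)
        }
      }
      for (a in names(arms)) {
        store[[kk]]$maps[[paste0(pair$sort_index, a)]] <-
          list(gm = gm[[a]], sort = pair$sort_index, arm = a,
               sets = lapply(sets, `[[`, a))
      }
    }

    # Nulls: one model + one shared ensemble per (task, k)
    for (kk in names(store)) {
      k <- as.integer(kk)
      say("task %s k=%d: null model", task$name, k)
      maps <- store[[kk]]$maps
      model <- fit_null_model(lapply(maps, function(m) m$gm),
                              n_null_maps = config$n_null_maps)
      ens <- simulate_null_ensemble(
        model, td$mask, n = config$n_null_maps,
        seed = derive_seed(config$seed, paste0("null_", task$name, "_", kk)))
      for (m in maps) {
        add_null <- function(metric, lab, real) {
          null_records[[length(null_records) + 1L]] <<- list(
            task = task$name, sort = m$sort, arm = m$arm, k = k,
            metric = metric, threshold_label = lab,
            value = percentile(null_statistics(real, ens, metric), 0.95))
        }
        if ("pearson" %in% config$metrics) add_null("pearson", "none", m$gm)
        for (lab in c("liberal", "conservative")) {
          if ("jaccard_voxel" %in% config$metrics) {
            add_null("jaccard_voxel", lab, m$sets[[paste0("voxel_", lab)]])
          }
          if ("jaccard_cluster" %in% config$metrics) {
            add_null("jaccard_cluster", lab,
                     m$sets[[paste0("cluster_", lab)]])
          }
          if ("peak_hit" %in% config$metrics) {
            add_null("peak_hit", lab, m$sets[[paste0("cluster_", lab)]])
          }
        }
      }
      store[[kk]] <- list()  # release
    }
    measurables[[task$name]] <- list(base = td$base, n = td$n,
                                     k_grid = kg)
    rm(td)
  }

  records <- do.call(rbind, lapply(records, as.data.frame))
  null_records <- do.call(rbind, lapply(null_records, as.data.frame))
  peaks <- if (length(peaks_rows)) do.call(rbind, peaks_rows) else NULL
  curves <- null_curves(null_records)
  res <- list(records = records, null_records = null_records,
              null_curves = curves, peaks = peaks, reference = reference,
              measurables = measurables, plans = plans, config = config)
  class(res) <- "replicability_results"
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

write_results <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$records, file.path(out_dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(res$null_curves, file.path(out_dir, "null_curves.csv"),
                   row.names = FALSE)
  if (!is.null(res$peaks)) {
    utils::write.csv(res$peaks, file.path(out_dir, "peaks.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(res$reference, file.path(out_dir, "reference.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pd <- file.path(out_dir, "plans")
  dir.create(pd, showWarnings = FALSE)
  for (g in names(res$plans)) {
    write_split_plan(res$plans[[g]], file.path(pd, paste0(g, ".json")))
  }
  invisible(out_dir)
}

#' Summarize replicability curves
#'
#' Per task and sample size, the mean and SD of each metric over sorts;
#' across tasks, the mean of the task means and the mean within-task SD
#' (SDs are qualitative, as resampling overlap makes sorts
#' non-independent).
#'
#' @param records Tidy records data.frame (task, sort, k, metric,
#'   threshold_label, value).
#' @return List with `per_task` and `across_tasks` data.frames.
#' @export
summarize_curves <- function(records) {
  per_task <- stats::aggregate(
    value ~ task + k + metric + threshold_label, data = records,
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  per_task <- do.call(data.frame, per_task)
  names(per_task)[names(per_task) == "value.mean"] <- "mean"
  names(per_task)[names(per_task) == "value.sd"] <- "sd"
  across <- stats::aggregate(
    cbind(mean, sd) ~ k + metric + threshold_label, data = per_task,
    FUN = mean)
  names(across)[names(across) == "mean"] <- "mean_of_task_means"
  names(across)[names(across) == "sd"] <- "mean_within_task_sd"
  list(per_task = per_task[order(per_task$metric, per_task$threshold_label,
                                 per_task$task, per_task$k), ],
       across_tasks = across[order(across$metric, across$threshold_label,
                                   across$k), ])
}

#' Build measurables design rows and fit the per-task regressions
#'
#' Expands each task's base measurables to pseudo-replicate-pair level,
#' joins the Pearson outcome from the records, fits the orthogonalized
#' task-wise regression, and MAP-aggregates effect sizes and delta R^2
#' across tasks.
#'
#' @param res A [run_experiment()] results bundle.
#' @param tasks Optional subset of task names (default: all tasks).
#' @return List with `rows` (per-task design rows), `fits` (per-task
#'   [fit_task_regression()]), `aggregate` (data.frame of d_MAP and
#'   delta R^2_MAP per block), `priors`.
#' @export
measurables_analysis <- function(res, tasks = names(res$measurables)) {
  rows_by_task <- list()
  fits <- list()
  pearson <- res$records[res$records$metric == "pearson", ]
  for (tn in tasks) {
    mi <- res$measurables[[tn]]
    plan <- res$plans[[res$config$tasks[[tn]]$share_group]]
    prs <- pearson[pearson$task == tn, ]
    rows <- list()
    for (pair in iterate_pseudo_pairs(plan, mi$k_grid)) {
      row <- expand_to_pair_level(mi$base, pair)
      out <- prs$value[prs$sort == pair$sort_index & prs$k == pair$k]
      row$outcome <- if (length(out) == 1L) out else NA_real_
      row$task <- tn
      rows[[length(rows) + 1L]] <- row
    }
    df <- do.call(rbind, lapply(rows, function(r) {
      as.data.frame(r[setdiff(names(r), "incomplete")])
    }))
    rows_by_task[[tn]] <- df
    fits[[tn]] <- fit_task_regression(df)
  }
  blocks <- c("sample_size", MEASURABLE_VARS)
  agg <- data.frame(block = blocks, d_map = NA_real_,
                    delta_r2_map = NA_real_)
  for (i in seq_along(blocks)) {
    d <- vapply(fits, block_effect_size, numeric(1), blocks[i])
    r <- vapply(fits, block_delta_r2, numeric(1), blocks[i])
    if (sum(!is.na(d)) >= 2L) agg$d_map[i] <- map_aggregate(d, "effect_size")
    if (sum(!is.na(r)) >= 2L) {
      agg$delta_r2_map[i] <- map_aggregate(r, "delta_r2")
    }
  }
  list(rows = rows_by_task, fits = fits, aggregate = agg,
       priors = list(effect_size = "Normal(0, 1)",
                     delta_r2 = "Normal(-20, 10^2) on logit scale"))
}

#' The canonical synthetic replicability suite
#'
#' Three signal-bearing tasks differing only in between-subject variability
#' (sigma_between 0.3, 0.5, 0.8) plus one pure-null task, all with N = 200
#' participants, 2 runs, within-subject noise SD 1 at smoothness FWHM 3 on
#' a 24^3 grid, and a shared truth of four FWHM-4 blobs (amplitudes +1.0,
#' +0.8, +0.6, -0.8). All four tasks share one split plan (identical
#' participants). This is the package's stated desk-scale world for
#' qualitative reproduction of the replicability-vs-sample-size curves.
#'
#' @param seed Master seed.
#' @param n_sorts Sorts per split plan (default 50).
#' @param n_null_maps Null maps per (task, k) (default 100).
#' @param k_grid Sample sizes (default 16, 36, 64).
#' @param include_null Include the pure-null task (default TRUE).
#' @return An [experiment_config()].
#' @export
synthetic_suite_config <- function(seed = 1L, n_sorts = 50L,
                                   n_null_maps = 100L,
                                   k_grid = c(16L, 36L, 64L),
                                   include_null = TRUE) {
  blobs <- list(
    list(center = c(8, 8, 12), fwhm = 4, amplitude = 1.0, sign = 1),
    list(center = c(16, 16, 12), fwhm = 4, amplitude = 0.8, sign = 1),
    list(center = c(8, 16, 8), fwhm = 4, amplitude = 0.6, sign = 1),
    list(center = c(16, 8, 16), fwhm = 4, amplitude = 0.8, sign = -1))
  truth <- truth_spec(c(24L, 24L, 24L), blobs = blobs)
  null_truth <- truth_spec(c(24L, 24L, 24L), blobs = list())
  mk <- function(name, tr, sb) {
    synth_task(name, synth_spec(tr, n_subjects = 200L, n_runs = 2L,
                                sigma_between = sb, sigma_within = 1,
                                noise_fwhm = 3),
               share_group = "suite")
  }
  tasks <- list(mk("lowbv", truth, 0.3), mk("midbv", truth, 0.5),
                mk("highbv", truth, 0.8))
  if (include_null) {
    tasks <- c(tasks, list(mk("purenull", null_truth, 0.5)))
  }
  experiment_config(tasks, k_grid = k_grid, n_sorts = n_sorts,
                    n_null_maps = n_null_maps, seed = seed)
}
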