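PIPELINE_STAGES <- c("simulate", "preprocess", "static", "dynamic",
                     "states", "graphs", "stats", "report")

#' Run configuration
#'
#' All tunable parameters of the pipeline in one validated, serializable
#' object. Defaults are the analysis defaults used throughout the package:
#' 22-TR Gaussian-tapered windows (sigma 3 TR, step 1), sparsity sweep
#' 0.08-0.48 in 0.01 steps, k-means with 500 iterations and 150 restarts
#' over k = 2..8, 100/20 random graph references (static/dynamic) and FDR
#' at q = 0.05.
#'
#' @param input_dir directory with a cohort (written by [write_cohort()] or
#'   hand-assembled in the same layout).
#' @param output_dir directory for all stage outputs.
#' @param tr_seconds repetition time (s) attached to time courses on read.
#' @param discard_volumes leading volumes dropped before conditioning when
#'   consuming raw scans (synthetic cohorts are generated post-discard and
#'   are recognized as such).
#' @param window_length,sigma,step sliding-window parameters (TR units).
#' @param sparsity_min,sparsity_max,sparsity_step sparsity grid.
#' @param k_min,k_max candidate state counts.
#' @param kmeans_max_iter,kmeans_replicates k-means control parameters.
#' @param n_rand_static,n_rand_dynamic random references per threshold.
#' @param q_fdr FDR level.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param cohort named list of overrides for [cohort_spec()] scalar knobs
#'   (`n_hc`, `n_ltle`, `n_rtle`, `n_components`, `n_timepoints`,
#'   `tr_seconds`, `within_strength`, `between_strength`, `jitter_sd`,
#'   `noise_sd`, `null`).
#' @param dynamic_graph_metrics compute across-window graph-metric
#'   variance in the graphs stage (the costliest stage; metrics restricted
#'   to `dynamic_metrics`).
#' @param dynamic_metrics metrics tracked per window.
#' @param max_silhouette_n silhouette subsample cap in state selection.
#' @return object of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, output_dir = tempfile("dynfc"),
                       tr_seconds = 2, discard_volumes = 10L, window_length = 22L,
                       sigma = 3, step = 1L,
                       sparsity_min = 0.08, sparsity_max = 0.48,
                       sparsity_step = 0.01,
                       k_min = 2L, k_max = 8L,
                       kmeans_max_iter = 500L, kmeans_replicates = 150L,
                       n_rand_static = 100L, n_rand_dynamic = 20L,
                       q_fdr = 0.05, seed = 1L,
                       cohort = list(),
                       dynamic_graph_metrics = FALSE,
                       dynamic_metrics = c("eg", "eloc"),
                       max_silhouette_n = 5000L) {
  cfg <- list(input_dir = input_dir, output_dir = output_dir,
              tr_seconds = tr_seconds,
              discard_volumes = as.integer(discard_volumes),
              window_length = as.integer(window_length), sigma = sigma,
              step = as.integer(step),
              sparsity_min = sparsity_min, sparsity_max = sparsity_max,
              sparsity_step = sparsity_step,
              k_min = as.integer(k_min), k_max = as.integer(k_max),
              kmeans_max_iter = as.integer(kmeans_max_iter),
              kmeans_replicates = as.integer(kmeans_replicates),
              n_rand_static = as.integer(n_rand_static),
              n_rand_dynamic = as.integer(n_rand_dynamic),
              q_fdr = q_fdr, seed = as.integer(seed), cohort = cohort,
              dynamic_graph_metrics = isTRUE(dynamic_graph_metrics),
              dynamic_metrics = dynamic_metrics,
              max_silhouette_n = as.integer(max_silhouette_n))
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$discard_volumes >= 0, cfg$window_length >= 3,
            cfg$sigma > 0, cfg$step >= 1,
            cfg$sparsity_min > 0, cfg$sparsity_max < 1,
            cfg$sparsity_min < cfg$sparsity_max, cfg$sparsity_step > 0,
            cfg$k_min >= 2, cfg$k_max >= cfg$k_min,
            cfg$kmeans_max_iter >= 1, cfg$kmeans_replicates >= 1,
            cfg$n_rand_static >= 1, cfg$n_rand_dynamic >= 1,
            cfg$q_fdr > 0, cfg$q_fdr < 1)
  invisible(cfg)
}

config_grid <- function(cfg) {
  seq(cfg$sparsity_min, cfg$sparsity_max, by = cfg$sparsity_step)
}

#' Write / read a run configuration as YAML
#' @param cfg a [run_config()].
#' @param path file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

# Per-stage seeds derived from the master seed via a recorded counter, so
# any stage can be rerun in isolation with the seed it had in run-all.
stage_seeds <- function(master_seed) {
  set.seed(master_seed)
  setNames(sample.int(.Machine$integer.max - 1L,
                      length(PIPELINE_STAGES)), PIPELINE_STAGES)
}

require_artifact <- function(path, producer) {
  if (!file.exists(path)) {
    stop("missing artifact ", path, "; run the `", producer,
         "` stage first", call. = FALSE)
  }
  path
}

log_event <- function(cfg, stage, event, subject = NA_character_) {
  line <- jsonlite::toJSON(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                                stage = stage, subject = subject,
                                event = event), auto_unbox = TRUE)
  cat(line, "\n", sep = "",
      file = file.path(cfg$output_dir, "log.jsonl"), append = TRUE)
}

cohort_spec_from_config <- function(cfg) {
  co <- cfg$cohort
  n_per_group <- c(HC = co$n_hc %||% 37L, LTLE = co$n_ltle %||% 22L,
                   RTLE = co$n_rtle %||% 31L)
  args <- list(n_per_group = n_per_group,
               n_components = co$n_components %||% 43L,
               n_timepoints = co$n_timepoints %||% 215L,
               tr_seconds = co$tr_seconds %||% 2,
               within_strength = co$within_strength %||% 0.45,
               between_strength = co$between_strength %||% 0.12,
               jitter_sd = co$jitter_sd %||% 0.02,
               noise_sd = co$noise_sd %||% 0.3,
               seed = stage_seeds(cfg$seed)[["simulate"]])
  if (isTRUE(co$null)) do.call(null_cohort_spec, args)
  else do.call(cohort_spec, args)
}

out_path <- function(cfg, ...) file.path(cfg$output_dir, ...)

#' Pipeline stages
#'
#' Each stage reads only the artifacts of its upstream stages from the
#' configured output directory and writes its own, so stages can be rerun
#' in isolation. [run_pipeline()] chains them and records provenance.
#'
#' @param cfg a [run_config()].
#' @return the config, invisibly.
#' @name pipeline-stages
NULL

#' @rdname pipeline-stages
#' @export
stage_simulate <- function(cfg) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- cohort_spec_from_config(cfg)
  cohort <- simulate_cohort(spec)
  cohort$truth$retained_trs <- TRUE  # generated post-discard
  write_cohort(cohort, out_path(cfg, "cohort"))
  log_event(cfg, "simulate", sprintf("wrote %d subjects",
                                     nrow(cohort$meta)))
  invisible(cfg)
}

cohort_dir <- function(cfg) {
  if (!is.null(cfg$input_dir)) cfg$input_dir
  else out_path(cfg, "cohort")
}

#' @rdname pipeline-stages
#' @export
stage_preprocess <- function(cfg) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  cdir <- cohort_dir(cfg)
  meta <- read_meta(require_artifact(file.path(cdir, "meta.tsv"),
                                     "simulate"))
  fd <- read_fd_traces(require_artifact(file.path(cdir, "fd_traces.tsv"),
                                        "simulate"))
  discard <- cfg$discard_volumes
  truth_path <- file.path(cdir, "truth.json")
  if (file.exists(truth_path) &&
      isTRUE(read_truth(truth_path)$retained_trs)) {
    discard <- 0L
  }
  qc <- lapply(meta$subject_id, function(sid) qc_subject(fd[[sid]]))
  names(qc) <- meta$subject_id
  jsonlite::write_json(
    lapply(qc, function(q) list(pass = q$pass, reasons = q$reasons)),
    out_path(cfg, "qc_report.json"), auto_unbox = TRUE)
  keep <- meta$subject_id[vapply(qc, `[[`, TRUE, "pass")]
  dir.create(out_path(cfg, "prep"), showWarnings = FALSE)
  for (sid in keep) {
    ts <- read_timecourses(file.path(cdir, "timecourses",
                                     paste0(sid, ".tsv")),
                           tr_seconds = cfg$tr_seconds,
                           subject_id = sid)
    ts <- condition_timecourses(ts, discard_volumes = discard)
    write_timecourses(ts, out_path(cfg, "prep", paste0(sid, ".tsv")))
  }
  write_meta(meta[meta$subject_id %in% keep, ],
             out_path(cfg, "meta_retained.tsv"))
  log_event(cfg, "preprocess",
            sprintf("retained %d/%d subjects (discard=%d)",
                    length(keep), nrow(meta), discard))
  invisible(cfg)
}

prep_subjects <- function(cfg) {
  meta <- read_meta(require_artifact(out_path(cfg, "meta_retained.tsv"),
                                     "preprocess"))
  meta
}

#' @rdname pipeline-stages
#' @export
stage_static <- function(cfg) {
  meta <- prep_subjects(cfg)
  dir.create(out_path(cfg, "static"), showWarnings = FALSE)
  for (sid in meta$subject_id) {
    ts <- read_timecourses(
      require_artifact(out_path(cfg, "prep", paste0(sid, ".tsv")),
                       "preprocess"),
      tr_seconds = cfg$tr_seconds, subject_id = sid)
    write_conn_matrix(static_fc(ts),
                      out_path(cfg, "static", paste0(sid, "_fc.tsv")))
  }
  log_event(cfg, "static", sprintf("wrote %d matrices", nrow(meta)))
  invisible(cfg)
}

#' @rdname pipeline-stages
#' @export
stage_dynamic <- function(cfg) {
  meta <- prep_subjects(cfg)
  dir.create(out_path(cfg, "dynamic"), showWarnings = FALSE)
  w <- make_window_weights(cfg$window_length, cfg$sigma)
  for (sid in meta$subject_id) {
    ts <- read_timecourses(
      require_artifact(out_path(cfg, "prep", paste0(sid, ".tsv")),
                       "preprocess"),
      tr_seconds = cfg$tr_seconds, subject_id = sid)
    stack <- windowed_fc(ts, w, step = cfg$step)
    write_window_stack(stack, out_path(cfg, "dynamic",
                                       paste0(sid, "_stack.rds")))
  }
  log_event(cfg, "dynamic", sprintf("wrote %d stacks", nrow(meta)))
  invisible(cfg)
}

read_stacks <- function(cfg) {
  meta <- prep_subjects(cfg)
  stacks <- lapply(meta$subject_id, function(sid) {
    read_window_stack(require_artifact(
      out_path(cfg, "dynamic", paste0(sid, "_stack.rds")), "dynamic"))
  })
  names(stacks) <- meta$subject_id
  stacks
}

#' @rdname pipeline-stages
#' @export
stage_states <- function(cfg) {
  stacks <- read_stacks(cfg)
  dir.create(out_path(cfg, "states"), showWarnings = FALSE)
  sel <- select_k(stacks, k_range = cfg$k_min:cfg$k_max,
                  seed = stage_seeds(cfg$seed)[["states"]],
                  n_replicates = cfg$kmeans_replicates,
                  max_iter = cfg$kmeans_max_iter,
                  max_silhouette_n = cfg$max_silhouette_n)
  model <- sel$models[[as.character(sel$k)]]
  saveRDS(model, out_path(cfg, "states", "state_model.rds"))
  jsonlite::write_json(list(k = sel$k,
                            silhouette_by_k = as.list(sel$silhouette_by_k)),
                       out_path(cfg, "states", "silhouette.json"),
                       auto_unbox = TRUE, digits = NA)
  tr <- stacks[[1]]$tr_seconds
  write.table(state_metrics_table(model, tr_seconds = tr, step = cfg$step),
              out_path(cfg, "states", "state_metrics.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  log_event(cfg, "states", sprintf("selected k=%d", sel$k))
  invisible(cfg)
}

#' @rdname pipeline-stages
#' @export
stage_graphs <- function(cfg) {
  meta <- prep_subjects(cfg)
  grid <- config_grid(cfg)
  seeds <- stage_seeds(cfg$seed)
  dir.create(out_path(cfg, "graphs"), showWarnings = FALSE)
  curves_rows <- list()
  auc_rows <- list()
  for (sid in meta$subject_id) {
    conn <- read_conn_matrix(require_artifact(
      out_path(cfg, "static", paste0(sid, "_fc.tsv")), "static"))
    mc <- metric_curves(conn, grid = grid, n_rand = cfg$n_rand_static,
                        seed = seeds[["graphs"]])
    for (m in colnames(mc$values)) {
      curves_rows[[length(curves_rows) + 1L]] <-
        data.frame(subject_id = sid, metric = m, sparsity = grid,
                   value = mc$values[, m])
    }
    auc_rows[[length(auc_rows) + 1L]] <-
      data.frame(subject_id = sid, metric = names(mc$auc),
                 auc = unname(mc$auc))
  }
  write.table(do.call(rbind, curves_rows),
              out_path(cfg, "graphs", "static_curves.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(do.call(rbind, auc_rows),
              out_path(cfg, "graphs", "static_auc.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  if (cfg$dynamic_graph_metrics) {
    var_rows <- list()
    for (sid in meta$subject_id) {
      stack <- read_window_stack(require_artifact(
        out_path(cfg, "dynamic", paste0(sid, "_stack.rds")), "dynamic"))
      dv <- dynamic_metric_variance(stack, grid = grid,
                                    n_rand = cfg$n_rand_dynamic,
                                    seed = seeds[["graphs"]],
                                    metrics = cfg$dynamic_metrics)
      var_rows[[length(var_rows) + 1L]] <-
        data.frame(subject_id = sid, metric = names(dv$variance),
                   variance_auc = unname(dv$variance))
    }
    write.table(do.call(rbind, var_rows),
                out_path(cfg, "graphs", "dynamic_variance.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  log_event(cfg, "graphs", "wrote metric curves and AUCs")
  invisible(cfg)
}

covars_from_meta <- function(meta) {
  meta[, c("age", "sex", "education", "mean_fd")]
}

#' @rdname pipeline-stages
#' @export
stage_stats <- function(cfg) {
  meta <- prep_subjects(cfg)
  dir.create(out_path(cfg, "stats"), showWarnings = FALSE)
  covars <- covars_from_meta(meta)
  group <- meta$group

  # static edge-wise group tests
  edges <- t(vapply(meta$subject_id, function(sid) {
    conn <- read_conn_matrix(require_artifact(
      out_path(cfg, "static", paste0(sid, "_fc.tsv")), "static"))
    upper_vec(conn$values)
  }, numeric(edge_count_from_static(cfg, meta))))
  colnames(edges) <- edge_names_from_static(cfg, meta)
  static_tests <- edge_group_ftests(edges, group, covars, q = cfg$q_fdr)
  write.table(static_tests, out_path(cfg, "stats", "static_edge_tests.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)

  # edge-variance (connectivity variability) group tests
  var_edges <- t(vapply(meta$subject_id, function(sid) {
    stack <- read_window_stack(require_artifact(
      out_path(cfg, "dynamic", paste0(sid, "_stack.rds")), "dynamic"))
    upper_vec(edge_variance(stack))
  }, numeric(ncol(edges))))
  colnames(var_edges) <- colnames(edges)
  var_tests <- edge_group_ftests(var_edges, group, covars, q = cfg$q_fdr)
  write.table(var_tests, out_path(cfg, "stats", "variance_edge_tests.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)

  # AUC group comparisons (five metrics)
  auc <- read.table(require_artifact(
    out_path(cfg, "graphs", "static_auc.tsv"), "graphs"), header = TRUE,
    sep = "\t", stringsAsFactors = FALSE)
  auc_tests <- do.call(rbind, lapply(unique(auc$metric), function(m) {
    sub <- auc[auc$metric == m, ]
    sub <- sub[match(meta$subject_id, sub$subject_id), ]
    r <- group_glm_ftest(sub$auc, group, covars, feature_id = m)
    data.frame(metric = m, statistic = r$statistic, p = r$p,
               stringsAsFactors = FALSE)
  }))
  auc_tests$q <- fdr_bh(auc_tests$p, cfg$q_fdr)$p_adjusted
  write.table(auc_tests, out_path(cfg, "stats", "auc_group_tests.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)

  # temporal state metrics: Kruskal-Wallis + Dunn post-hocs
  sm <- read.table(require_artifact(
    out_path(cfg, "states", "state_metrics.tsv"), "states"),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  sm <- sm[match(meta$subject_id, sm$subject_id), ]
  temporal_cols <- setdiff(names(sm), "subject_id")
  temporal_rows <- list()
  posthoc_rows <- list()
  for (v in temporal_cols) {
    yv <- sm[[v]]
    ok <- !is.na(yv)   # unvisited-state dwell times dropped listwise
    if (nlevels(droplevels(group[ok])) < 2L) {
      # metric defined in fewer than two groups: no test possible
      temporal_rows[[length(temporal_rows) + 1L]] <-
        data.frame(metric = v, H = NA_real_, p = NA_real_)
      next
    }
    kw <- kruskal_wallis(yv[ok], group[ok])
    temporal_rows[[length(temporal_rows) + 1L]] <-
      data.frame(metric = v, H = kw$H, p = kw$p)
    ph <- posthoc_dunn_bonferroni(yv[ok], group[ok])
    ph$metric <- v
    posthoc_rows[[length(posthoc_rows) + 1L]] <- ph
  }
  temporal_tests <- do.call(rbind, temporal_rows)
  write.table(temporal_tests,
              out_path(cfg, "stats", "temporal_tests.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  posthoc_tab <- if (length(posthoc_rows)) do.call(rbind, posthoc_rows)
                 else data.frame(group1 = character(), group2 = character(),
                                 z = numeric(), p_raw = numeric(),
                                 p_bonferroni = numeric(),
                                 metric = character())
  write.table(posthoc_tab,
              out_path(cfg, "stats", "temporal_posthoc.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)

  # partial correlations between dynamic properties and cognition
  moca_cols <- grep("^moca_", names(meta), value = TRUE)
  dyn_props <- sm[, grep("^(fraction|dwell)", temporal_cols, value = TRUE),
                  drop = FALSE]
  dyn_props$n_transitions <- sm$n_transitions
  dv_path <- out_path(cfg, "graphs", "dynamic_variance.tsv")
  if (file.exists(dv_path)) {
    dv <- read.table(dv_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    for (m in unique(dv$metric)) {
      sub <- dv[dv$metric == m, ]
      dyn_props[[paste0("variance_auc_", m)]] <-
        sub$variance_auc[match(meta$subject_id, sub$subject_id)]
    }
  }
  pc_rows <- list()
  for (p_name in names(dyn_props)) {
    for (m_name in moca_cols) {
      ok <- !is.na(dyn_props[[p_name]]) & !is.na(meta[[m_name]])
      if (sum(ok) < 7) next  # need positive residual df after 4 covariates
      pc <- partial_correlation(dyn_props[[p_name]][ok],
                                meta[[m_name]][ok], covars[ok, ],
                                x_name = p_name, y_name = m_name)
      pc_rows[[length(pc_rows) + 1L]] <-
        data.frame(property = p_name, moca = m_name, r = pc$r, p = pc$p,
                   df = pc$df)
    }
  }
  pc_tab <- if (length(pc_rows)) do.call(rbind, pc_rows)
            else data.frame(property = character(), moca = character(),
                            r = numeric(), p = numeric(), df = integer())
  pc_tab$q <- if (nrow(pc_tab)) fdr_bh(pc_tab$p, cfg$q_fdr)$p_adjusted
              else numeric()
  write.table(pc_tab, out_path(cfg, "stats", "moca_partial_corr.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)

  # demographics table
  demo <- demographics_table(meta)
  write.table(demo, out_path(cfg, "stats", "demographics.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)

  jsonlite::write_json(
    list(n_subjects = nrow(meta),
         n_static_edges_significant = sum(static_tests$significant),
         n_variance_edges_significant = sum(var_tests$significant),
         q_fdr = cfg$q_fdr),
    out_path(cfg, "stats", "summary.json"), auto_unbox = TRUE, digits = NA)
  log_event(cfg, "stats", "wrote group statistics")
  invisible(cfg)
}

edge_count_from_static <- function(cfg, meta) {
  conn <- read_conn_matrix(require_artifact(
    out_path(cfg, "static", paste0(meta$subject_id[1], "_fc.tsv")),
    "static"))
  nrow(conn$values) * (nrow(conn$values) - 1) / 2
}

edge_names_from_static <- function(cfg, meta) {
  conn <- read_conn_matrix(out_path(cfg, "static",
                                    paste0(meta$subject_id[1], "_fc.tsv")))
  idx <- edge_index(nrow(conn$values))
  paste0(conn$component_ids[idx[, 1]], "-", conn$component_ids[idx[, 2]])
}

#' @rdname pipeline-stages
#' @export
stage_report <- function(cfg) {
  read_tsv <- function(...) read.table(require_artifact(out_path(cfg, ...),
                                                        "stats"),
                                       header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE)
  report <- list(
    auc_group_tests = read_tsv("stats", "auc_group_tests.tsv"),
    temporal_tests = read_tsv("stats", "temporal_tests.tsv"),
    temporal_posthoc = read_tsv("stats", "temporal_posthoc.tsv"),
    moca_partial_corr = read_tsv("stats", "moca_partial_corr.tsv"),
    demographics = read_tsv("stats", "demographics.tsv"),
    selected_k = jsonlite::read_json(require_artifact(
      out_path(cfg, "states", "silhouette.json"), "states"))$k)
  jsonlite::write_json(report, out_path(cfg, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  log_event(cfg, "report", "wrote report.json")
  invisible(cfg)
}

#' Run the full pipeline
#'
#' Executes every stage in order (`simulate` only when no `input_dir` is
#' configured) and writes a provenance record (config hash, derived stage
#' seeds, package and R versions, per-stage wall time).
#'
#' @param cfg a [run_config()].
#' @return the config, invisibly.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- PIPELINE_STAGES
  if (!is.null(cfg$input_dir)) stages <- setdiff(stages, "simulate")
  timings <- numeric(0)
  for (st in stages) {
    fn <- get(paste0("stage_", st), mode = "function")
    timings[[st]] <- system.time(fn(cfg))[["elapsed"]]
  }
  prov <- list(config_hash = rlang::hash(unclass(cfg)),
               config = unclass(cfg),
               stage_seeds = as.list(stage_seeds(cfg$seed)),
               stage_seconds = as.list(round(timings, 3)),
               package_version = as.character(packageVersion("dynfc")),
               r_version = R.version.string)
  jsonlite::write_json(prov, out_path(cfg, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cfg)
}
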