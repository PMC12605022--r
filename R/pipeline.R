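#' Pipeline configuration
#'
#' Bundles everything [run_all()] needs: the cohort simulation settings,
#' the preprocessing settings, microstate options and connectivity /
#' statistics options. Can be built programmatically or loaded from a
#' YAML file with [read_pipeline_config()]; unspecified fields take the
#' defaults below.
#'
#' @param simulation a [simulation_config()].
#' @param preprocess a [preprocess_config()].
#' @param k_range K values to fit.
#' @param n_restarts k-means restarts per K.
#' @param forced_k force this K after fitting (NULL = CV argmin).
#' @param smooth_ms minimum segment duration for label smoothing (0 =
#'   off).
#' @param backfit_mode `"peaks"` or `"all"`.
#' @param connectivity_mode `"peaks"` or `"all"` (which samples feed the
#'   per-state connectivity).
#' @param alpha sLORETA regularisation.
#' @param edge_threshold |r| threshold for exported edge lists.
#' @param group_level `"pooled"` (concatenate GFP-peak maps across the
#'   group's subjects and cluster once per group) or `"two_level"`
#'   (cluster each subject, then cluster the subject templates).
#' @param out_dir output directory (created if missing); NULL disables
#'   file output.
#' @param seed master seed, recorded in every artifact.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            preprocess = preprocess_config(),
                            k_range = 2:8, n_restarts = 50, forced_k = NULL,
                            smooth_ms = 0,
                            backfit_mode = "peaks",
                            connectivity_mode = "peaks",
                            alpha = 1e-6, edge_threshold = 0.5,
                            group_level = c("pooled", "two_level"),
                            out_dir = NULL, seed = 1) {
  structure(list(simulation = simulation, preprocess = preprocess,
                 k_range = k_range, n_restarts = n_restarts,
                 forced_k = forced_k, smooth_ms = smooth_ms,
                 backfit_mode = backfit_mode,
                 connectivity_mode = connectivity_mode,
                 alpha = alpha, edge_threshold = edge_threshold,
                 group_level = match.arg(group_level),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `simulation`
#' and `preprocess` are nested maps passed to their constructors. Missing
#' keys default.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(simulation_config, y$simulation %||% list())
  pre <- do.call(preprocess_config, y$preprocess %||% list())
  rest <- y[setdiff(names(y), c("simulation", "preprocess"))]
  do.call(pipeline_config, c(list(simulation = sim, preprocess = pre), rest))
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

wrap_stage <- function(stage, subject = NULL, expr) {
  tryCatch(expr, error = function(e) {
    stopf("stage '%s'%s failed: %s", stage,
          if (is.null(subject)) "" else sprintf(" (subject %s)", subject),
          conditionMessage(e))
  })
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Simulate a two-group cohort, preprocess every recording, fit
#' group-level microstate templates (GFP-peak maps pooled within each
#' group), backfit each subject, compute temporal parameters, optionally
#' compute per-microstate sLORETA source connectivity, and run the group
#' comparisons. Every stage's outputs are written (as TSV/JSON) before
#' the next stage starts when `out_dir` is set, and a manifest with the
#' config, versions, warnings and output hashes is written last.
#'
#' @param config a [pipeline_config()].
#' @return list with `templates` (per group), `state_names`,
#'   `parameters` (tidy table, both groups), `parameter_stats`,
#'   `connectivity` (pooled summaries per group and state, or NULL),
#'   `connectivity_stats`, `manifest`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  warnings_log <- character(0)
  note <- function(w) warnings_log <<- c(warnings_log, w)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(df, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  sim <- config$simulation
  sim$seed <- config$seed
  log_stage("simulate", "cohort %d + %d subjects, %g s @ %g Hz",
            sim$group_sizes[1], sim$group_sizes[2], sim$record_s, sim$sfreq)
  cohort <- wrap_stage("simulate", NULL, generate_cohort(sim))

  log_stage("preprocess", "band %g-%g Hz, analysis rate %g Hz",
            config$preprocess$band_low, config$preprocess$band_high,
            config$preprocess$target_sfreq)
  prepped <- lapply(cohort$groups, function(grp) lapply(grp, function(subj) {
    pr <- wrap_stage("preprocess", subj$id,
                     preprocess_recording(subj$recording, config$preprocess))
    if (length(pr$report$bad_channels))
      note(sprintf("subject %s: bad channels %s", subj$id,
                   paste(pr$report$bad_channels, collapse = ",")))
    c(subj, list(clean = pr$recording, report = pr$report))
  }))
  if (!is.null(out_dir)) {
    reports <- lapply(unlist(prepped, recursive = FALSE), `[[`, "report")
    names(reports) <- vapply(unlist(prepped, recursive = FALSE), `[[`, "",
                             "id")
    jsonlite::write_json(reports, file.path(out_dir, "preprocess_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  log_stage("microstate", "group-level clustering, K in {%s}, %d restarts",
            paste(range(config$k_range), collapse = ".."), config$n_restarts)
  montage <- sim$montage
  group_fit <- lapply(names(prepped), function(gname) {
    grp <- prepped[[gname]]
    gfps <- lapply(grp, function(s) compute_gfp(s$clean))
    maps <- do.call(cbind, lapply(seq_along(grp), function(i)
      grp[[i]]$clean$data[, gfps[[i]]$peaks, drop = FALSE]))
    if (config$group_level == "two_level") {
      subj_templates <- do.call(cbind, lapply(seq_along(grp), function(i) {
        m <- modified_kmeans(grp[[i]]$clean$data[, gfps[[i]]$peaks, drop = FALSE],
                             k = max(config$k_range %||% 4),
                             n_restarts = config$n_restarts,
                             seed = config$seed + 700 + i)
        m$templates
      }))
      maps <- subj_templates
    }
    models <- wrap_stage(sprintf("microstate (%s)", gname), NULL,
                         fit_microstates(maps, config$k_range,
                                         config$n_restarts,
                                         seed = config$seed + 100 * match(gname, names(prepped))))
    model <- select_k(models, forced_k = config$forced_k)
    state_names <- name_states(model, montage)
    list(name = gname, model = model, models = models,
         state_names = state_names, gfps = gfps)
  })
  names(group_fit) <- names(prepped)
  # states are named against the canonical maps in the first group, then
  # carried to the second group by direct template matching, so that a
  # state label refers to the same topography in both groups
  if (length(group_fit) == 2 &&
      group_fit[[1]]$model$k == group_fit[[2]]$model$k) {
    mm <- match_templates(group_fit[[1]]$model, group_fit[[2]]$model)
    nm <- character(group_fit[[1]]$model$k)
    nm[mm$permutation] <- group_fit[[1]]$state_names
    group_fit[[2]]$state_names <- nm
  }
  for (gf in group_fit) {
    tdf <- data.frame(channel = montage$channel_names, gf$model$templates)
    names(tdf) <- c("channel", gf$state_names)
    emit(tdf, sprintf("templates_%s.tsv", gf$name))
  }

  log_stage("backfit", "per-subject backfit (%s mode) and parameters",
            config$backfit_mode)
  segs <- lapply(names(prepped), function(gname) {
    grp <- prepped[[gname]]
    gf <- group_fit[[gname]]
    lapply(seq_along(grp), function(i) {
      seg <- wrap_stage("backfit", grp[[i]]$id,
                        backfit(gf$model, grp[[i]]$clean, gf$gfps[[i]],
                                mode = config$backfit_mode))
      if (config$smooth_ms > 0)
        seg <- smooth_labels(seg, config$smooth_ms, grp[[i]]$clean, gf$model)
      seg
    })
  })
  names(segs) <- names(prepped)
  param_tables <- lapply(names(prepped), function(gname) {
    grp <- prepped[[gname]]
    gf <- group_fit[[gname]]
    do.call(rbind, lapply(seq_along(grp), function(i) {
      params <- wrap_stage("parameters", grp[[i]]$id,
                           compute_parameters(segs[[gname]][[i]]))
      parameters_tidy(params, grp[[i]]$id, gf$state_names)
    }))
  })
  names(param_tables) <- names(prepped)
  all_params <- rbind(cbind(group = "A", param_tables$A),
                      cbind(group = "B", param_tables$B))
  emit(all_params, "parameters.tsv")

  connectivity <- NULL
  connectivity_stats <- NULL
  if (!is.null(cohort$leadfield)) {
    log_stage("connectivity", "sLORETA (alpha = %g), %d regions, %s samples",
              config$alpha, length(cohort$parcellation$region_names),
              config$connectivity_mode)
    inv <- build_sloreta_inverse(cohort$leadfield, alpha = config$alpha)
    state_set <- sort(unique(group_fit$A$state_names))
    per_group <- lapply(names(prepped), function(gname) {
      grp <- prepped[[gname]]
      gf <- group_fit[[gname]]
      per_state <- lapply(seq_len(gf$model$k), function(s) {
        cms <- list()
        for (i in seq_along(grp)) {
          subj <- grp[[i]]
          seg <- segs[[gname]][[i]]
          sd_ <- extract_state_data(subj$clean, seg, s,
                                    mode = config$connectivity_mode,
                                    gfp = gf$gfps[[i]], align_to = gf$model,
                                    remove_span = TRUE)
          if (sd_$n < 10) {
            note(sprintf("subject %s state %s: only %d samples, skipped",
                         subj$id, gf$state_names[s], sd_$n))
            next
          }
          src <- apply_inverse(inv, sd_$data)
          reg <- parcellate(src, cohort$parcellation)
          cms[[length(cms) + 1L]] <- pearson_connectivity(reg, gf$state_names[s])
        }
        wrap_stage("connectivity", gname, summarize_connectivity(cms))
      })
      names(per_state) <- gf$state_names
      per_state[order(names(per_state))]
    })
    names(per_group) <- names(prepped)
    connectivity <- per_group
    conn_df <- do.call(rbind, lapply(names(per_group), function(g)
      do.call(rbind, lapply(per_group[[g]], function(s)
        data.frame(group = g, state = s$state, mean = s$mean, sd = s$sd,
                   n = s$n)))))
    emit(conn_df, "connectivity_summary.tsv")
    connectivity_stats <- compare_connectivity_tables(per_group$A, per_group$B)
    emit(connectivity_stats, "stats_connectivity.tsv")
  }

  log_stage("stats", "Mann-Whitney per state x metric")
  parameter_stats <- wrap_stage("stats", NULL,
                                compare_parameter_tables(param_tables$A,
                                                         param_tables$B))
  emit(parameter_stats, "stats_parameters.tsv")

  cfg_snapshot <- config
  cfg_snapshot$simulation$montage <-
    paste(config$simulation$montage$channel_names, collapse = ",")
  cfg_snapshot$preprocess$ica <- NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("eegmicrostates")),
    config = lapply(unclass(cfg_snapshot), function(x)
      if (inherits(x, c("simulation_config", "preprocess_config")))
        unclass(x) else x),
    seed = config$seed,
    k_selected = group_fit$A$model$k,
    selection = attr(group_fit$A$model, "selection"),
    group_level = config$group_level,
    state_match = if (group_fit$A$model$k == group_fit$B$model$k)
      match_templates(group_fit$A$model, group_fit$B$model)$correlations
    else NULL,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    warnings = warnings_log)
  if (!is.null(out_dir)) {
    files <- setdiff(list.files(out_dir, full.names = TRUE),
                     file.path(out_dir, "manifest.json"))
    manifest$output_hashes <- as.list(tools::md5sum(files))
    names(manifest$output_hashes) <- basename(files)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  log_stage("done", "%.1f s elapsed", manifest$elapsed_s)
  list(templates = lapply(group_fit, function(g) g$model),
       state_names = lapply(group_fit, function(g) g$state_names),
       parameters = all_params,
       parameter_stats = parameter_stats,
       connectivity = connectivity,
       connectivity_stats = connectivity_stats,
       manifest = manifest)
}
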