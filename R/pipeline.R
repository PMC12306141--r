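#' Build and validate a pipeline configuration
#'
#' Assembles the full configuration for a single-participant run, applying
#' the documented defaults for every choice the analysis leaves open
#' (day-boundary policy, EBIC gamma, centrality conventions, nomination
#' statistics). The configuration is validated against the schema below
#' before any computation; [read_pipeline_config()] /
#' [write_pipeline_config()] round-trip it through YAML.
#'
#' Schema (all keys optional unless noted):
#' \describe{
#'   \item{data}{path to the EMA score CSV (required for [run_pipeline()]).}
#'   \item{manifest}{path to the manifest CSV; default: bundled manifest.}
#'   \item{registry}{path to an intervention-registry CSV; default: bundled.}
#'   \item{schedule}{list `n_days`, `beeps_per_day`, `beep_interval`,
#'     `response_window` (defaults 21, 5, 2.5, 2).}
#'   \item{k_per_community}{nodes kept per community (default 4).}
#'   \item{skip_zero_variance}{skip sd = 0 items in selection (default TRUE).}
#'   \item{day_boundary_policy}{"within_day" (default) or "across_all".}
#'   \item{detrend}{remove a per-item linear day trend before estimation
#'     (default FALSE).}
#'   \item{grid}{list `n_lambda` (10), `lambda_min_ratio` (0.01).}
#'   \item{gamma}{EBIC hyperparameter (default 0.5).}
#'   \item{centrality}{list `signed` (FALSE), `include_self_loops` (FALSE).}
#'   \item{nomination}{list `statistics` (the four defaults), `k` (2).}
#'   \item{output_dir}{directory for artifacts (required for [run_pipeline()]).}
#'   \item{seed}{integer seed recorded in the manifest (default 1).}
#' }
#'
#' @param ... configuration keys overriding the defaults.
#' @return A validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    data = NULL,
    manifest = NULL,
    registry = NULL,
    schedule = list(n_days = 21L, beeps_per_day = 5L, beep_interval = 2.5,
                    response_window = 2),
    k_per_community = 4L,
    skip_zero_variance = TRUE,
    day_boundary_policy = "within_day",
    detrend = FALSE,
    grid = list(n_lambda = 10L, lambda_min_ratio = 0.01),
    gamma = 0.5,
    centrality = list(signed = FALSE, include_self_loops = FALSE),
    nomination = list(statistics = nomination_statistics(), k = 2L),
    output_dir = NULL,
    seed = 1L)
  override <- list(...)
  if (length(override) == 1 && is.null(names(override)) &&
      is.list(override[[1]])) {
    override <- override[[1]]
  }
  unknown <- setdiff(names(override), names(defaults))
  assert_that(length(unknown) == 0,
              sprintf("unknown config key(s): %s",
                      paste(unknown, collapse = ", ")))
  config <- merge_config(defaults, override)
  validate_pipeline_config(config)
}

# like modifyList(), but an explicit NULL in `override` keeps the key
# (paths legitimately default to NULL and must survive YAML round-trips)
merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[nm] <- list(override[[nm]])
    }
  }
  base
}

#' Validate a pipeline configuration list
#'
#' @param config a configuration list (see [pipeline_config()]).
#' @return The validated config, classed `pipeline_config`.
#' @export
validate_pipeline_config <- function(config) {
  assert_that(is.list(config), "config must be a list")
  sch <- config$schedule
  assert_that(is.list(sch), "config$schedule must be a list")
  # constructing the schedule performs its own validation
  ema_schedule(sch$n_days %||% 21L, sch$beeps_per_day %||% 5L,
               sch$beep_interval %||% 2.5, sch$response_window %||% 2)
  assert_that(is.numeric(config$k_per_community) && config$k_per_community >= 1,
              "config$k_per_community must be >= 1")
  assert_that(isTRUE(config$skip_zero_variance) ||
                isFALSE(config$skip_zero_variance),
              "config$skip_zero_variance must be TRUE/FALSE")
  assert_that(config$day_boundary_policy %in% c("within_day", "across_all"),
              "config$day_boundary_policy must be 'within_day' or 'across_all'")
  assert_that(isTRUE(config$detrend) || isFALSE(config$detrend),
              "config$detrend must be TRUE/FALSE")
  assert_that(is.numeric(config$gamma) && config$gamma >= 0,
              "config$gamma must be >= 0")
  g <- config$grid
  assert_that(is.numeric(g$n_lambda) && g$n_lambda >= 1,
              "config$grid$n_lambda must be >= 1")
  assert_that(is.numeric(g$lambda_min_ratio) && g$lambda_min_ratio > 0 &&
                g$lambda_min_ratio <= 1,
              "config$grid$lambda_min_ratio must lie in (0, 1]")
  assert_that(isTRUE(config$centrality$signed) ||
                isFALSE(config$centrality$signed),
              "config$centrality$signed must be TRUE/FALSE")
  assert_that(isTRUE(config$centrality$include_self_loops) ||
                isFALSE(config$centrality$include_self_loops),
              "config$centrality$include_self_loops must be TRUE/FALSE")
  assert_that(is.character(config$nomination$statistics) &&
                length(config$nomination$statistics) >= 1,
              "config$nomination$statistics must name >= 1 statistic")
  assert_that(is.numeric(config$nomination$k) && config$nomination$k >= 1,
              "config$nomination$k must be >= 1")
  assert_that(is.numeric(config$seed) && abs(config$seed) < 2^31,
              "config$seed must be a 32-bit integer")
  structure(config, class = c("pipeline_config", "list"))
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_pipeline_config()`, a validated `pipeline_config`;
#'   for `write_pipeline_config()`, `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# remove a linear day trend per item, preserving the item mean
detrend_dataset <- function(dataset) {
  m <- score_matrix(dataset)
  day <- dataset$scores$day
  for (it in colnames(m)) {
    obs <- !is.na(m[, it])
    if (sum(obs) >= 3 && stats::sd(day[obs]) > 0) {
      fit <- stats::lm(m[obs, it] ~ day[obs])
      m[obs, it] <- mean(m[obs, it]) + stats::residuals(fit)
    }
  }
  # detrended residuals can stray marginally outside the slider bounds
  m <- pmin(pmax(m, 0), 100)
  dataset$scores[, colnames(m)] <- m
  dataset
}

#' Run the full idiographic network pipeline for one participant
#'
#' Executes every stage in order: load and validate the EMA table,
#' summarize completeness and item means, select the highest-mean nodes per
#' community, build complete lagged pairs, estimate the sparse graphical
#' VAR with EBIC penalty selection, compute the centrality table, and build
#' the treatment-target report. All artifacts are written to
#' `config$output_dir`; every tie-break, convergence issue and low-data
#' condition is recorded in the returned run manifest (also written as
#' JSON) rather than silently dropped.
#'
#' @param config a `pipeline_config` (or list coercible to one) with at
#'   least `data` and `output_dir` set. `data` may also be an `ema_dataset`
#'   object directly.
#' @return The run manifest (list) invisibly: config snapshot, package
#'   version, timestamps, per-stage diagnostics, and the output inventory.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  assert_that(!is.null(config$output_dir), "config$output_dir is required")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  notes <- character(0)
  note <- function(...) notes <<- c(notes, sprintf(...))
  stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE)
      }),
      warning = function(w) {
        note("[%s] warning: %s", name, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        note("[%s] %s", name, trimws(conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
  }
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  set.seed(config$seed)

  sch <- config$schedule
  schedule <- ema_schedule(sch$n_days, sch$beeps_per_day, sch$beep_interval,
                           sch$response_window)
  manifest <- stage("load", {
    if (is.null(config$manifest)) default_manifest()
    else read_manifest(config$manifest)
  })
  dataset <- stage("load", {
    if (inherits(config$data, "ema_dataset")) config$data
    else {
      assert_that(!is.null(config$data), "config$data is required")
      load_ema_table(config$data, manifest, schedule)
    }
  })
  manifest <- dataset$manifest
  if (config$detrend) dataset <- stage("detrend", detrend_dataset(dataset))

  outputs <- character(0)
  emit <- function(name, writer) {
    path <- file.path(config$output_dir, name)
    writer(path)
    outputs <<- c(outputs, path)
    path
  }

  completeness <- stage("summarize", completeness_summary(dataset))
  summaries <- stage("summarize", item_summaries(dataset))
  emit("completeness.csv",
       function(p) utils::write.csv(completeness, p, row.names = FALSE))
  emit("item_summaries.csv",
       function(p) utils::write.csv(summaries, p, row.names = FALSE))

  partition <- community_partition(manifest)
  node_set <- stage("select", select_top_k_per_community(
    summaries, partition, k = config$k_per_community,
    skip_zero_variance = config$skip_zero_variance))
  if (node_set$ties) note("[select] tie at the selection boundary")

  pairs <- stage("lag", to_lagged_pairs(dataset, node_set$nodes,
                                        config$day_boundary_policy))
  p <- length(node_set$nodes)
  if (pairs$n_pairs < p + 1) {
    note("[lag] low data: only %d lagged pairs for %d nodes", pairs$n_pairs, p)
  }

  selection <- stage("fit", {
    std <- standardize_pairs(pairs)
    grid <- penalty_grid(std$pairs, n_lambda = config$grid$n_lambda,
                         lambda_min_ratio = config$grid$lambda_min_ratio,
                         gamma = config$gamma)
    select_model(pairs, grid = grid, gamma = config$gamma)
  })
  if (!all(selection$table$converged)) {
    note("[fit] %d of %d grid fits did not converge",
         sum(!selection$table$converged), nrow(selection$table))
  }
  emit("ebic_table.csv",
       function(p) utils::write.csv(selection$table, p, row.names = FALSE))
  emit("fit_diagnostics.json", function(pth) {
    jsonlite::write_json(list(
      lambda_beta = selection$fit$lambda_beta,
      lambda_kappa = selection$fit$lambda_kappa,
      gamma = selection$gamma, ebic = ebic_score(selection$fit, selection$gamma),
      n_pairs = selection$fit$n_pairs, converged = selection$fit$converged,
      n_iter = selection$fit$n_iter), pth, auto_unbox = TRUE, digits = NA)
  })

  networks <- stage("networks", extract_networks(selection$fit))
  emit("edge_list.csv", function(p) export_edge_list(networks, p))
  emit("network_contemporaneous.graphml", function(p) {
    export_graphml(networks, p, "contemporaneous", partition)
  })
  emit("network_temporal.graphml", function(p) {
    export_graphml(networks, p, "temporal", partition)
  })

  centrality <- stage("centrality", centrality_table(
    networks, partition, signed = config$centrality$signed,
    include_self_loops = config$centrality$include_self_loops))
  emit("centrality.csv",
       function(p) utils::write.csv(centrality, p, row.names = FALSE))

  registry <- stage("targets", {
    if (is.null(config$registry)) default_intervention_registry()
    else read_intervention_registry(config$registry)
  })
  rankings <- stage("targets", top_k_per_statistic(
    centrality, statistics = config$nomination$statistics,
    k = config$nomination$k))
  report <- stage("targets", build_target_report(rankings, registry))
  if (any(report$ties)) note("[targets] nomination tie(s) broken deterministically")
  emit("target_report.json", function(p) export_target_report(report, p, "json"))
  emit("target_report.md",
       function(p) export_target_report(report, p, "markdown"))

  manifest_out <- list(
    package_version = as.character(utils::packageVersion("idionet")),
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config)[setdiff(names(config), "data")],
    participant_id = dataset$participant_id,
    diagnostics = list(
      n_observed_beeps = n_observed_beeps(dataset),
      schedule_size = schedule_size(schedule),
      n_pairs = pairs$n_pairs,
      nodes = node_set$nodes,
      selection_ties = node_set$ties,
      skipped_zero_variance = node_set$skipped,
      lambda_beta = selection$fit$lambda_beta,
      lambda_kappa = selection$fit$lambda_kappa,
      converged = selection$fit$converged,
      notes = notes),
    outputs = basename(outputs))
  path <- file.path(config$output_dir, "run_manifest.json")
  jsonlite::write_json(manifest_out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  manifest_out$outputs <- c(manifest_out$outputs, "run_manifest.json")
  invisible(manifest_out)
}

#' Simulate and write a synthetic dataset (or cohort) to disk
#'
#' Wraps the synthetic generator for demos and tests: emits the dataset(s)
#' as long-format CSV next to a JSON description of the generating truth.
#' With `preset = "three_patients"` a trio spanning high/moderate/low
#' compliance (96, 75 and 45 completed beeps of 105) is produced.
#'
#' @param out_dir output directory (created if needed).
#' @param schedule an [ema_schedule()].
#' @param missing_rate beep-deletion probability in \[0, 1).
#' @param seed integer seed.
#' @param truth optional `synthetic_truth`; default [make_truth()].
#' @param preset `NULL` or `"three_patients"`.
#' @return Character vector of files written, invisibly.
#' @export
simulate_command <- function(out_dir, schedule = ema_schedule(),
                             missing_rate = 0, seed = 1L, truth = NULL,
                             preset = NULL) {
  assert_that(is.numeric(missing_rate) && missing_rate >= 0 && missing_rate < 1,
              "`missing_rate` must lie in [0, 1)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  write_truth <- function(tr, path) {
    jsonlite::write_json(list(nodes = tr$nodes,
                              communities = as.list(tr$communities),
                              B = tr$B, K = tr$K,
                              location = as.list(tr$location),
                              scale = as.list(tr$scale)),
                         path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  }
  if (identical(preset, "three_patients")) {
    cohort <- simulate_patients(schedule = schedule, seed = seed)
    for (nm in names(cohort)) {
      f <- file.path(out_dir, paste0(nm, ".csv"))
      write_ema_table(cohort[[nm]], f, "long")
      tf <- file.path(out_dir, paste0(nm, "_truth.json"))
      write_truth(attr(cohort[[nm]], "truth"), tf)
      files <- c(files, f, tf)
    }
  } else {
    set.seed(seed)
    tr <- truth %||% make_truth(seed = seed)
    ds <- simulate_ema(tr, schedule, missing_rate = missing_rate,
                       participant_id = "synthetic")
    f <- file.path(out_dir, "synthetic_patient.csv")
    write_ema_table(ds, f, "long")
    tf <- file.path(out_dir, "synthetic_truth.json")
    write_truth(tr, tf)
    files <- c(files, f, tf)
  }
  invisible(files)
}
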