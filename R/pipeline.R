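# End-to-end pipeline: generate (or load) -> ETL -> networks -> metrics ->
# null tests -> graphlets, from a single config, writing a CSV report bundle.

#' Build a normalized pipeline run configuration
#'
#' Either `input_dir` (tables in the [write_cohort()] schema) or `generator`
#' (arguments for [cohort_config()]) must be given, not both. All unspecified
#' settings are filled with defaults: a 5-year sliding window stepping yearly,
#' 1000 null replicates, graphlet windows of 5 years over all three scopes.
#'
#' @param input_dir Directory with `patients.csv` / `episodes.csv`, or `NULL`.
#' @param generator Named list of [cohort_config()] arguments, or `NULL`.
#' @param exclude_mental Drop F-prefixed codes in the ETL. Default `FALSE`.
#' @param window_years ETL event window half-width in years. Default `Inf`.
#' @param censor_date Administrative censoring date.
#' @param delta_t Snapshot window length in years. Default 5.
#' @param step Snapshot step in years. Default 1.
#' @param snapshot_mode `"sliding"` or `"cumulative"`.
#' @param n_replicates Null-model replicates. Default 1000.
#' @param n_swaps Accepted swaps per replicate, or `NULL` for `10 * n_edges`.
#' @param graphlet_delta_t Numeric vector of graphlet windows (years).
#' @param graphlet_scopes Subset of `c("all", "pre", "post")`.
#' @param seed Master seed; expanded into per-stage streams.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, generator = NULL,
                            exclude_mental = FALSE, window_years = Inf,
                            censor_date = as.Date("2018-03-31"),
                            delta_t = 5, step = 1,
                            snapshot_mode = "sliding",
                            n_replicates = 1000, n_swaps = NULL,
                            graphlet_delta_t = 5,
                            graphlet_scopes = c("all", "pre", "post"),
                            seed = 1L) {
  cfg <- list(input_dir = input_dir, generator = generator,
              exclude_mental = isTRUE(exclude_mental),
              window_years = window_years,
              censor_date = as.Date(censor_date),
              delta_t = delta_t, step = step, snapshot_mode = snapshot_mode,
              n_replicates = n_replicates, n_swaps = n_swaps,
              graphlet_delta_t = graphlet_delta_t,
              graphlet_scopes = graphlet_scopes, seed = as.integer(seed))
  errs <- character(0)
  if (is.null(cfg$input_dir) && is.null(cfg$generator)) {
    errs <- c(errs, "one of input_dir or generator must be given")
  }
  if (!is.null(cfg$input_dir) && !is.null(cfg$generator)) {
    errs <- c(errs, "input_dir and generator are mutually exclusive")
  }
  if (!is.null(cfg$input_dir) && !dir.exists(cfg$input_dir)) {
    errs <- c(errs, paste0("input_dir does not exist: ", cfg$input_dir))
  }
  if (!is.numeric(cfg$delta_t) || cfg$delta_t <= 0) {
    errs <- c(errs, "delta_t must be > 0")
  }
  if (!is.numeric(cfg$step) || cfg$step <= 0) {
    errs <- c(errs, "step must be > 0")
  }
  if (!cfg$snapshot_mode %in% c("sliding", "cumulative")) {
    errs <- c(errs, "snapshot_mode must be 'sliding' or 'cumulative'")
  }
  if (!is.numeric(cfg$n_replicates) || cfg$n_replicates < 1) {
    errs <- c(errs, "n_replicates must be a positive integer")
  }
  if (any(cfg$graphlet_delta_t < 0)) {
    errs <- c(errs, "graphlet_delta_t must be nonnegative")
  }
  if (!all(cfg$graphlet_scopes %in% c("all", "pre", "post"))) {
    errs <- c(errs, "graphlet_scopes must be within all/pre/post")
  }
  if (length(errs)) {
    stop("invalid pipeline config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load and validate a pipeline configuration file
#'
#' Reads a YAML (or JSON) config file and normalizes it through
#' [pipeline_config()], filling every default and reporting all violations at
#' once.
#'
#' @param path Config file path.
#' @return A `pipeline_config`.
#' @export
validate_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$censor_date)) raw$censor_date <- as.Date(raw$censor_date)
  if (!is.null(raw$window_years) && is.character(raw$window_years)) {
    raw$window_years <- as.numeric(raw$window_years)
  }
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Stages: cohort (generate or load), ETL (event stream + condition splits),
#' networks (pre/post/all summaries, snapshots), metrics (degree profiles,
#' new-condition ratios, new-per-year, chapter lift, mixing / second-order /
#' peer-attribute with null tests, efficiency-vs-window series with null
#' references and empirical/random ratios), and graphlet fractions per scope.
#' All outputs are written as CSV files under `out_dir`; the run is
#' deterministic given the config seed.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory for the report bundle.
#' @return Invisibly, a list with the in-memory artefacts (`patients`,
#'   `events`, `splits`, `networks`, `summaries`, `null_tests`,
#'   `efficiency_series`, `graphlets`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- sprintf(...)
    cat(format(Sys.time(), "%H:%M:%S "), msg, "\n", sep = "", file = log_path,
        append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    logf("stage %s: start", name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  logf("comorbnet %s, seed %d",
       as.character(utils::packageVersion("comorbnet")), config$seed)

  cohort <- stage("cohort", {
    if (!is.null(config$generator)) {
      gen_args <- config$generator
      if (is.null(gen_args$seed)) gen_args$seed <- config$seed
      gcfg <- do.call(cohort_config, gen_args)
      patients <- generate_cohort(gcfg)
      model <- disease_model(gcfg)
      episodes <- generate_episodes(patients, gcfg, model)
      write_cohort(patients, episodes, out_dir)
      write_disease_model(model, file.path(out_dir, "ground_truth.json"))
      list(patients = patients, episodes = episodes)
    } else {
      read_cohort(config$input_dir)
    }
  })

  etl <- stage("etl", {
    events <- build_event_stream(cohort$episodes, cohort$patients,
                                 exclude_mental = config$exclude_mental,
                                 window_years = config$window_years)
    splits <- condition_splits(events, cohort$patients)
    utils::write.csv(events, file.path(out_dir, "events.csv"),
                     row.names = FALSE)
    flat <- data.frame(
      patient_id = splits$patient_id,
      pre_existing = vapply(splits$pre_existing, paste, "", collapse = ";"),
      post_set = vapply(splits$post_set, paste, "", collapse = ";"),
      new_conditions = vapply(splits$new_conditions, paste, "",
                              collapse = ";"),
      re_occurring = vapply(splits$re_occurring, paste, "", collapse = ";"),
      new_ratio = splits$new_ratio, stringsAsFactors = FALSE)
    utils::write.csv(flat, file.path(out_dir, "condition_splits.csv"),
                     row.names = FALSE)
    list(events = events, splits = splits)
  })

  networks <- stage("networks", {
    pp <- build_pre_post(etl$events, cohort$patients)
    all_net <- build_network(etl$events, cohort$patients, label = "ALL")
    summaries <- rbind(summary(pp$pre), summary(pp$post), summary(all_net))
    utils::write.csv(summaries, file.path(out_dir, "network_summaries.csv"),
                     row.names = FALSE)
    snaps <- build_snapshots(etl$events, cohort$patients,
                             delta_t = config$delta_t, step = config$step,
                             mode = config$snapshot_mode)
    list(pre = pp$pre, post = pp$post, all = all_net, snapshots = snaps,
         summaries = summaries)
  })

  metrics <- stage("metrics", {
    prof <- rbind(
      cbind(profile = "chapter", degree_profile(networks$all, "chapter")),
      cbind(profile = "age_band", degree_profile(networks$all, "age_band")),
      cbind(profile = "side", degree_profile(networks$all, "side")))
    utils::write.csv(prof, file.path(out_dir, "degree_profiles.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(patient_id = etl$splits$patient_id,
                 new_ratio = etl$splits$new_ratio),
      file.path(out_dir, "new_ratio.csv"), row.names = FALSE)
    npy <- new_per_year(etl$splits, cohort$patients, config$censor_date)
    utils::write.csv(npy, file.path(out_dir, "new_per_year.csv"),
                     row.names = FALSE)
    cl <- chapter_lift(etl$splits)
    utils::write.csv(as.data.frame(as.table(cl$lift)),
                     file.path(out_dir, "chapter_lift.csv"),
                     row.names = FALSE)
    list(profiles = prof, new_per_year = npy, chapter_lift = cl)
  })

  null_tests <- stage("nulls", {
    n_swaps <- config$n_swaps
    tests <- list(
      mixing_patients = null_test(
        networks$all, function(n) mixing_profile(n, "patients")$tau,
        n_replicates = config$n_replicates,
        n_swaps = if (is.null(n_swaps)) 10 * nrow(networks$all$edges)
                  else n_swaps,
        seed = config$seed + 101L, name = "tau(k,knn) patients"),
      second_order_diseases = null_test(
        networks$all,
        function(n) second_order_correlations(n, "diseases")$tau_k_nn,
        n_replicates = config$n_replicates,
        n_swaps = if (is.null(n_swaps)) 10 * nrow(networks$all$edges)
                  else n_swaps,
        seed = config$seed + 102L, name = "tau(k,|NN|) diseases"),
      peer_age = null_test(
        networks$all, function(n) peer_attribute(n, "age_at_smi")$tau,
        n_replicates = config$n_replicates,
        n_swaps = if (is.null(n_swaps)) 10 * nrow(networks$all$edges)
                  else n_swaps,
        seed = config$seed + 103L, name = "tau(age, peer age)"))
    tab <- do.call(rbind, lapply(tests, function(x)
      data.frame(statistic = x$statistic, observed = x$observed,
                 null_mean = x$null_mean, null_sd = x$null_sd, z = x$z,
                 p_two_tailed = x$p_two_tailed,
                 n_replicates = x$n_replicates, seed = x$seed)))
    utils::write.csv(tab, file.path(out_dir, "null_tests.csv"),
                     row.names = FALSE)
    tests
  })

  eff_series <- stage("efficiency", {
    rows <- list()
    set.seed(config$seed + 200L)
    for (sn in networks$snapshots$snapshots) {
      net <- sn$network
      if (nrow(net$edges) < 2) next
      for (subset in c("all", "patients", "diseases")) {
        obs <- efficiency(net, subset)$value
        nulls <- vapply(seq_len(min(config$n_replicates, 100L)),
                        function(i) {
                          r <- rewire_bipartite(net)
                          efficiency(r, subset)$value
                        }, numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          midpoint = sn$midpoint, subset = subset, efficiency = obs,
          null_mean = mean(nulls), null_sd = stats::sd(nulls),
          ratio = obs / mean(nulls))
      }
    }
    out <- do.call(rbind, rows)
    utils::write.csv(out, file.path(out_dir, "efficiency_series.csv"),
                     row.names = FALSE)
    out
  })

  graphlets <- stage("graphlets", {
    rows <- list()
    for (dt in config$graphlet_delta_t) {
      for (sc in config$graphlet_scopes) {
        gc <- count_graphlets(etl$events, dt, sc)
        rows[[length(rows) + 1L]] <- data.frame(
          scope = gc$scope, delta_t = dt,
          D1 = gc$counts[["D1"]], D2 = gc$counts[["D2"]],
          D3 = gc$counts[["D3"]],
          f_D1 = gc$fractions[["D1"]], f_D2 = gc$fractions[["D2"]],
          f_D3 = gc$fractions[["D3"]])
      }
    }
    out <- do.call(rbind, rows)
    utils::write.csv(out, file.path(out_dir, "graphlet_counts.csv"),
                     row.names = FALSE)
    out
  })

  logf("pipeline complete")
  invisible(list(patients = cohort$patients, events = etl$events,
                 splits = etl$splits, networks = networks,
                 metrics = metrics, null_tests = null_tests,
                 efficiency_series = eff_series, graphlets = graphlets))
}
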