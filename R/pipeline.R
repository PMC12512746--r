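#' Default pipeline configuration
#'
#' Every analysis parameter with its default: QC flags 1-2, 7-day/50-detection
#' track minimums, 5-minute deduplication, hours + natural log edge weights
#' floored at 5 minutes, departure-based period assignment, the 3-node rule
#' for individual networks, inverse-event-count betweenness lengths,
#' upper-quartile common pathways, a 300 m covariate radius and the 75/25
#' GBM protocol. A config is a plain named list so it round-trips losslessly
#' through YAML ([read_pipeline_config()]).
#'
#' @return A named list of defaults, overridable entry-wise in
#'   [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    input = NULL,  # list(detections=, stations=, tags=) to read CSVs instead
    simulate = list(duration_days = 30, dt_s = 60,
                    scene_args = list(), agent_args = list(),
                    detection_args = list()),
    filters = list(allowed_flags = c(1L, 2L), min_days = 7,
                   min_detections = 50L, window_s = 300L,
                   order = "qc_minimums_dedup"),
    network = list(dt_floor_h = 1 / 12, log_base = exp(1),
                   period_from = "depart", min_individual_nodes = 3L,
                   length_mode = "inverse_count"),
    pathways = list(quantile_q = 0.75),
    covariates = list(radius_m = 300),
    model = list(enabled = TRUE, response = "degree", train_fraction = 0.75,
                 cv_folds = 5L,
                 grid = list(interaction_depth = c(1L, 3L),
                             shrinkage = c(0.05, 0.1),
                             bag_fraction = c(0.5, 0.75),
                             n_trees = 400L))
  )
}

#' Read a pipeline configuration from YAML
#'
#' Entries present in the file override the defaults of
#' [default_pipeline_config()]; everything else keeps its default.
#'
#' @param path YAML file.
#' @return A merged config list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(default_pipeline_config(), user)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
          class = "reefnet_stage_error", parent = e)
  })
}

#' Run the end-to-end telemetry-to-connectivity pipeline
#'
#' Executes the full analysis in order — simulate (or read) telemetry,
#' filter detections, annotate diel periods, build every stratified movement
#' network, compute metrics and common pathways, extract habitat covariates
#' and fit the habitat-preference models — and writes all products plus a
#' run manifest (config, seed, per-stage row/edge counts and the
#' conservation identities) to `out_dir`. Rerunning with the same config and
#' seed reproduces the outputs byte-identically.
#'
#' @param config Named list of overrides merged over
#'   [default_pipeline_config()].
#' @param out_dir Output directory.
#' @param force Overwrite an existing non-empty `out_dir`.
#' @return The manifest list, invisibly; all products on disk under
#'   `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir, force = FALSE) {
  cfg <- modifyList(default_pipeline_config(), config)
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    abort(sprintf("output directory '%s' is not empty (use force = TRUE)", out_dir))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "networks"), showWarnings = FALSE)
  counts <- list()

  if (!is.null(cfg$input)) {
    inp <- stage("telemetry_io", {
      for (f in c("detections", "stations", "tags")) {
        if (is.null(cfg$input[[f]]) || !file.exists(cfg$input[[f]])) {
          abort(sprintf("missing %s file: %s", f, cfg$input[[f]] %||% "<unset>"))
        }
      }
      read_detections(cfg$input$detections, cfg$input$stations, cfg$input$tags)
    })
    detections <- inp$detections; stations <- inp$stations; tags <- inp$tags
    scene <- NULL
  } else {
    sim <- stage("synthetic_data", do.call(simulate_telemetry, c(
      list(seed = cfg$seed), cfg$simulate
    )))
    detections <- left_join(sim$detections,
                            select(sim$tags, "tag_id", "species", "sex"),
                            by = "tag_id")
    stations <- sim$stations; tags <- sim$tags; scene <- sim$scene
  }
  counts$detections_raw <- nrow(detections)

  filtered <- stage("telemetry_io", do.call(filter_detections, c(
    list(detections = detections), cfg$filters
  )))
  counts$detections_filtered <- nrow(filtered)
  if (nrow(filtered) == 0) warn("no detections survive the filters")

  annotated <- stage("solar_periods", annotate_periods(filtered, stations))
  write_telemetry_csv(annotated, file.path(out_dir, "detections_filtered.csv"))

  networks <- stage("network_builder", build_stratified_networks(
    annotated, tags, stations,
    min_individual_nodes = cfg$network$min_individual_nodes,
    dt_floor_h = cfg$network$dt_floor_h, log_base = cfg$network$log_base,
    period_from = cfg$network$period_from
  ))
  counts$n_networks <- nrow(networks)

  stage("network_metrics", {
    readr::write_csv(network_edge_list(networks, include_self_loops = TRUE),
                     file.path(out_dir, "networks", "edges.csv"), progress = FALSE)
    summaries <- networks %>%
      mutate(metrics = purrr::map(
        .data$network,
        ~ select(glance(.x), "order", "size", "n_components",
                 "n_events", "n_self_loop_events")
      )) %>%
      select(-"network", -"order", -"size") %>%
      tidyr::unnest("metrics")
    readr::write_csv(summaries, file.path(out_dir, "network_summaries.csv"),
                     progress = FALSE)
    node_metrics <- purrr::pmap(networks, function(species, reef_system,
                                                   stratum_type, stratum_value,
                                                   order, size, network) {
      mutate(degree_centrality(network), species = species,
             reef_system = reef_system, stratum_type = stratum_type,
             stratum_value = stratum_value, .before = 1)
    }) %>% bind_rows() %>% empty_fallback(c(
      "species", "reef_system", "stratum_type", "stratum_value",
      "station_id", "degree"))
    readr::write_csv(node_metrics, file.path(out_dir, "node_metrics.csv"),
                     progress = FALSE)
    edge_metrics <- purrr::pmap(networks, function(species, reef_system,
                                                   stratum_type, stratum_value,
                                                   order, size, network) {
      eb <- edge_betweenness(network, cfg$network$length_mode)
      if (nrow(eb) == 0) return(NULL)
      rng <- range(eb$betweenness)
      eb$betweenness_scaled <- if (diff(rng) > 0)
        (eb$betweenness - rng[1]) / diff(rng) else 1
      mutate(eb, species = species, reef_system = reef_system,
             stratum_type = stratum_type, stratum_value = stratum_value,
             .before = 1)
    }) %>% bind_rows() %>% empty_fallback(c(
      "species", "reef_system", "stratum_type", "stratum_value",
      "from", "to", "event_count", "weight", "betweenness",
      "betweenness_scaled"))
    readr::write_csv(edge_metrics, file.path(out_dir, "edge_metrics.csv"),
                     progress = FALSE)
    full_nets <- filter(networks, .data$stratum_type == "full")
    for (k in seq_len(nrow(full_nets))) {
      write_network_graphml(
        full_nets$network[[k]],
        file.path(out_dir, "networks",
                  sprintf("%s_%s_full.graphml", full_nets$species[k],
                          full_nets$reef_system[k])),
        cfg$network$length_mode
      )
    }
  })

  stage("network_metrics", {
    full_by_species <- networks %>% filter(.data$stratum_type == "full")
    if (nrow(full_by_species) >= 2) {
      nets <- setNames(full_by_species$network, full_by_species$species)
      cp <- common_pathways(nets, cfg$pathways$quantile_q,
                            cfg$network$length_mode)
      readr::write_csv(cp, file.path(out_dir, "common_pathways.csv"),
                       progress = FALSE)
    }
  })

  model_reports <- list()
  if (!is.null(scene) && isTRUE(cfg$model$enabled)) {
    covariates <- stage("habitat_covariates",
                        assemble_node_covariates(scene, stations,
                                                 cfg$covariates$radius_m))
    readr::write_csv(covariates, file.path(out_dir, "covariates.csv"),
                     progress = FALSE)
    model_reports <- stage("habitat_model", {
      grid <- do.call(settings_grid, cfg$model$grid)
      reports <- list()
      for (sp in unique(tags$species)) {
        design <- assemble_design(annotated, tags, covariates,
                                  cfg$network$min_individual_nodes,
                                  species = sp)
        if (nrow(design) < 8 || var(design$degree) == 0) next
        fit <- fit_habitat_model(
          select(design, -"tag_id", -"station_id"),
          response = cfg$model$response,
          train_fraction = cfg$model$train_fraction,
          grid = grid, cv_folds = cfg$model$cv_folds, seed = cfg$seed
        )
        reports[[sp]] <- list(
          species = sp, n_rows = nrow(design),
          best_settings = as.list(glance(fit)[1, 1:4]),
          r2_train = fit$r2_train, rho_test = fit$rho_test,
          importance = as.list(setNames(fit$importance$relative_influence,
                                        fit$importance$predictor)),
          seed = cfg$seed
        )
        readr::write_csv(tidy(fit),
                         file.path(out_dir, sprintf("importance_%s.csv", sp)),
                         progress = FALSE)
      }
      jsonlite::write_json(reports, file.path(out_dir, "habitat_model.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      reports
    })
  }

  # conservation identities on this run
  full_nets <- filter(networks, .data$stratum_type == "full")
  events_total <- sum(purrr::map_int(full_nets$network, network_event_count))
  n_minus_1 <- annotated %>%
    filter(.data$species != "unknown") %>%
    distinct(.data$tag_id, .data$timestamp) %>%  # same-instant tie-break
    count(.data$tag_id) %>%
    summarise(v = sum(pmax(.data$n - 1, 0))) %>% pull("v")
  period_events <- networks %>%
    filter(.data$stratum_type == "period") %>%
    summarise(v = sum(purrr::map_int(.data$network, network_event_count))) %>%
    pull("v")
  handshake_ok <- all(purrr::map_lgl(networks$network, function(nw) {
    sum(degree_centrality(nw)$degree) == 2 * nrow(nw$edges)
  }))
  manifest <- list(
    package_version = as.character(utils::packageVersion("reefnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "input")],
    counts = counts,
    conservation = list(
      events_total = events_total,
      sum_detections_minus_one = n_minus_1,
      events_match = events_total == n_minus_1,
      period_partition_events = period_events,
      period_partition_match = period_events == events_total,
      handshake_identity = handshake_ok
    ),
    models = lapply(model_reports, function(r) r[c("species", "rho_test")])
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
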