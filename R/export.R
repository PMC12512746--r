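#' Export a movement network as GraphML
#'
#' Nodes carry latitude/longitude/atoll (when known) and degree; edges carry
#' `event_count`, `weight` and betweenness. GraphML is readable by igraph,
#' networkx, Gephi and Cytoscape.
#'
#' @param net A `movement_network`.
#' @param path Output `.graphml` path.
#' @param length_mode Betweenness length mode (see [edge_betweenness()]).
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path, length_mode = "inverse_count") {
  eb <- edge_betweenness(net, length_mode)
  g <- igraph::graph_from_data_frame(
    eb, directed = TRUE,
    vertices = as.data.frame(net$nodes)
  )
  deg <- degree_centrality(net)
  igraph::V(g)$degree <- deg$degree[match(igraph::V(g)$name, deg$station_id)]
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Long-form edge list across strata
#'
#' Binds the edges (and optionally self-loops) of a stratified network
#' collection into one tidy table for CSV export.
#'
#' @param networks Tibble from [build_stratified_networks()].
#' @param include_self_loops Append self-loop rows with `from == to`.
#' @return A tibble: stratum descriptors + `from`, `to`, `event_count`,
#'   `weight`.
#' @export
network_edge_list <- function(networks, include_self_loops = FALSE) {
  purrr::pmap(networks, function(species, reef_system, stratum_type,
                                 stratum_value, order, size, network) {
    ed <- network$edges
    if (include_self_loops && nrow(network$self_loops) > 0) {
      ed <- bind_rows(ed, network$self_loops %>%
                        mutate(from = .data$station_id, to = .data$station_id) %>%
                        select("from", "to", "event_count", "weight"))
    }
    if (nrow(ed) == 0) return(NULL)
    mutate(ed, species = species, reef_system = reef_system,
           stratum_type = stratum_type, stratum_value = stratum_value,
           .before = 1)
  }) %>% bind_rows() %>% empty_fallback(c(
    "species", "reef_system", "stratum_type", "stratum_value",
    "from", "to", "event_count", "weight"
  ))
}

# bind_rows of nothing loses the schema; restore it for empty results
empty_fallback <- function(df, cols) {
  if (nrow(df) > 0 && ncol(df) > 0) return(df)
  as_tibble(stats::setNames(
    lapply(cols, function(x) if (x %in% c("event_count")) integer() else
      if (x %in% c("weight", "betweenness", "betweenness_scaled", "degree"))
        numeric() else character()),
    cols
  ))
}
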