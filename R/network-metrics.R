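# igraph view of a movement network: aggregated directed edges, self-loops
# excluded; isolated (self-loop-only) stations kept as vertices
as_igraph_net <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("from", "to", "event_count", "weight")],
    directed = TRUE,
    vertices = data.frame(name = net$nodes$station_id)
  )
}

#' Broad-scale diagnostics of a movement network
#'
#' Order is the number of receivers (nodes) with detections in the stratum;
#' size is the number of directed movement edges between distinct receivers
#' (self-loops excluded); components counts the weakly connected components
#' (direction ignored), an indication of fragmentation in the network and a
#' way to spot movement barriers.
#'
#' @param net A `movement_network`.
#' @return A one-row tibble: `order`, `size`, `n_components`.
#' @export
summarize_network <- function(net) {
  n_nodes <- nrow(net$nodes)
  if (n_nodes == 0) {
    return(tibble(order = 0L, size = 0L, n_components = 0L))
  }
  g <- as_igraph_net(net)
  tibble(
    order = n_nodes,
    size = nrow(net$edges),
    n_components = igraph::count_components(g, mode = "weak")
  )
}

#' Degree centrality of each receiver
#'
#' Degree `d` counts all in- and out-going aggregated directed edges adjoining
#' a node. Self-loops are residency rather than movement between habitats and
#' are excluded by default (a station visited by one animal only has
#' `d = 0`); set `count_self_loops = TRUE` to count each self-loop with
#' multiplicity two. The handshake identity `sum(d) = 2 * size` holds under
#' the default.
#'
#' @param net A `movement_network`.
#' @param count_self_loops Count self-loop edges into the degree (default
#'   `FALSE`).
#' @return A tibble `station_id`, `degree`, sorted by decreasing degree.
#' @export
degree_centrality <- function(net, count_self_loops = FALSE) {
  out_d <- table(factor(net$edges$from, levels = net$nodes$station_id))
  in_d <- table(factor(net$edges$to, levels = net$nodes$station_id))
  d <- as.integer(out_d) + as.integer(in_d)
  if (count_self_loops && nrow(net$self_loops) > 0) {
    i <- match(net$self_loops$station_id, net$nodes$station_id)
    d[i] <- d[i] + 2L
  }
  tibble(station_id = net$nodes$station_id, degree = d) %>%
    arrange(dplyr::desc(.data$degree), .data$station_id)
}

#' Edge betweenness centrality
#'
#' Betweenness `b` of a directed edge is the frequency of shortest paths in
#' the network that use that movement link: for every ordered reachable pair
#' (s, t), each edge on a shortest s-t path accrues the fraction of s-t
#' shortest paths passing through it (ties split fractionally, Brandes
#' accumulation). High-betweenness edges are system-wide movement corridors.
#'
#' Shortest paths need a positive length per edge. The log-inverse-time
#' weights can be negative, so the default length is `1/event_count`
#' (strongly used edges are "shorter"); `unit` treats every edge as length 1
#' and `inverse_weight` uses `1/weight` (rejected if any weight is not
#' positive).
#'
#' @param net A `movement_network`.
#' @param length_mode One of `"inverse_count"` (default), `"unit"`,
#'   `"inverse_weight"`.
#' @return A tibble `from`, `to`, `event_count`, `weight`, `betweenness`.
#' @export
edge_betweenness <- function(net, length_mode = c("inverse_count", "unit", "inverse_weight")) {
  length_mode <- match.arg(length_mode)
  edges <- net$edges
  if (nrow(edges) == 0) {
    return(mutate(edges, betweenness = numeric(0)))
  }
  len <- switch(length_mode,
    unit = rep(1, nrow(edges)),
    inverse_count = 1 / edges$event_count,
    inverse_weight = {
      if (any(edges$weight <= 0)) {
        abort(paste("inverse_weight needs strictly positive edge weights;",
                    "use length_mode 'unit' or 'inverse_count'"),
              class = "reefnet_length_mode_error")
      }
      1 / edges$weight
    }
  )
  g <- as_igraph_net(net)
  b <- igraph::edge_betweenness(g, directed = TRUE, weights = len)
  mutate(edges, betweenness = b)
}

#' Cross-species common pathways
#'
#' Identifies shared movement corridors: directed edges present in the
#' networks of two or more species whose betweenness is high (at or above the
#' `quantile_q` quantile of the positive betweenness values) within every
#' species' network sharing the edge. Betweenness is also min-max scaled to
#' [0, 1] within each network for display parity across species.
#'
#' @param networks Named list of `movement_network` objects, one per species.
#' @param quantile_q Within-network quantile defining "high" betweenness
#'   (default 0.75, the upper quartile of positive values).
#' @param length_mode Passed to [edge_betweenness()].
#' @return A tibble `from`, `to`, `n_species`, `species`, `betweenness`,
#'   `betweenness_scaled` (one row per qualifying edge and species; empty if
#'   no edge qualifies).
#' @export
common_pathways <- function(networks, quantile_q = 0.75,
                            length_mode = "inverse_count") {
  stopifnot(length(networks) >= 2, !is.null(names(networks)))
  per_sp <- purrr::imap(networks, function(net, sp) {
    eb <- edge_betweenness(net, length_mode)
    if (nrow(eb) == 0) {
      return(tibble(from = character(), to = character(), species = character(),
                    betweenness = numeric(), betweenness_scaled = numeric(),
                    .high = logical()))
    }
    pos <- eb$betweenness[eb$betweenness > 0]
    thresh <- if (length(pos) > 0) quantile(pos, quantile_q, names = FALSE) else Inf
    rng <- range(eb$betweenness)
    scaled <- if (diff(rng) > 0) (eb$betweenness - rng[1]) / diff(rng) else
      rep(1, nrow(eb))
    tibble(from = eb$from, to = eb$to, species = sp,
           betweenness = eb$betweenness, betweenness_scaled = scaled,
           .high = eb$betweenness >= thresh)
  })
  all_edges <- bind_rows(per_sp)
  if (nrow(all_edges) == 0) return(empty_pathways())
  qual <- all_edges %>%
    group_by(.data$from, .data$to) %>%
    filter(dplyr::n() >= 2, all(.data$.high)) %>%
    mutate(n_species = dplyr::n()) %>%
    ungroup() %>%
    select("from", "to", "n_species", "species", "betweenness",
           "betweenness_scaled") %>%
    arrange(.data$from, .data$to, .data$species)
  if (nrow(qual) == 0) empty_pathways() else qual
}

empty_pathways <- function() {
  tibble(from = character(), to = character(), n_species = integer(),
         species = character(), betweenness = numeric(),
         betweenness_scaled = numeric())
}
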