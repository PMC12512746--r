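# fixture builders and independent oracles shared across the test files

suppressPackageStartupMessages(library(dplyr))

utc <- function(x) as.POSIXct(x, tz = "UTC")

`%||%` <- function(x, y) if (is.null(x)) y else x

PERIOD_LEVELS_TEST <- c("dawn", "day", "dusk", "night")
period_factor <- function(x) factor(x, levels = PERIOD_LEVELS_TEST)

# quick detections constructor; times in seconds from a fixed origin
make_detections <- function(tag, station, t_s, qc = 1L,
                            origin = "2013-05-01 00:00:00") {
  tibble::tibble(
    tag_id = tag, station_id = station,
    timestamp = utc(origin) + t_s,
    qc_flag = as.integer(qc)
  )
}

# assemble a movement_network directly from an edge table (metric tests)
make_net <- function(edges, nodes = NULL, self_loops = NULL) {
  edges <- tibble::as_tibble(edges)
  if (!"event_count" %in% names(edges)) edges$event_count <- 1L
  if (!"weight" %in% names(edges)) edges$weight <- 1
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  if (is.null(self_loops)) {
    self_loops <- tibble::tibble(station_id = character(),
                                 event_count = integer(), weight = numeric())
  }
  structure(
    list(stratum = list(species = "test", sex = "all", period = "all",
                        tag_id = "all"),
         nodes = tibble::tibble(station_id = nodes),
         edges = edges[order(edges$from, edges$to), ],
         self_loops = self_loops),
    class = "movement_network"
  )
}

# exhaustive-enumeration edge betweenness: all simple s-t paths, shortest
# ones found by total length, fractional credit per edge. Independent of the
# package's implementation.
brute_edge_betweenness <- function(edges, lengths, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  key <- paste(edges$from, edges$to)
  b <- stats::setNames(numeric(nrow(edges)), key)
  adj <- split(seq_len(nrow(edges)), edges$from)
  all_paths <- function(s, t) {
    paths <- list()
    walk <- function(v, used_nodes, edge_idx, len) {
      if (v == t) {
        paths[[length(paths) + 1]] <<- list(edges = edge_idx, len = len)
        return()
      }
      for (e in adj[[v]] %||% integer()) {
        w <- edges$to[e]
        if (w %in% used_nodes) next
        walk(w, c(used_nodes, w), c(edge_idx, e), len + lengths[e])
      }
    }
    walk(s, s, integer(), 0)
    paths
  }
  for (s in nodes) for (t in nodes) {
    if (s == t) next
    paths <- all_paths(s, t)
    if (length(paths) == 0) next
    lens <- vapply(paths, `[[`, numeric(1), "len")
    shortest <- which(lens <= min(lens) + 1e-9 * max(1, abs(min(lens))))
    for (k in shortest) {
      b[paths[[k]]$edges] <- b[paths[[k]]$edges] + 1 / length(shortest)
    }
  }
  unname(b)
}

# random directed graph with <= n_max nodes and random positive lengths
random_digraph <- function(n_max = 6) {
  n <- sample(2:n_max, 1)
  nodes <- LETTERS[seq_len(n)]
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- runif(nrow(pairs)) < 0.45
  if (!any(keep)) keep[sample.int(nrow(pairs), 1)] <- TRUE
  edges <- tibble::as_tibble(pairs[keep, ])
  edges$length <- runif(nrow(edges), 0.2, 3)
  list(nodes = nodes, edges = edges)
}

# small simulated study reused by several files (cached per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_telemetry(seed = 11, duration_days = 10,
                                agent_args = list(n_sharks = 8, n_fish = 4))
      det <- dplyr::left_join(sim$detections,
                              dplyr::select(sim$tags, tag_id, species, sex),
                              by = "tag_id")
      filt <- filter_detections(det)
      ann <- annotate_periods(filt, sim$stations)
      cache <<- list(sim = sim, detections = det, annotated = ann)
    }
    cache
  }
})
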