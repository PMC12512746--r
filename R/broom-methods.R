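#' Tidy a movement network into its edge table
#'
#' @param x A `movement_network`.
#' @param self_loops Include self-loop rows (`from == to`).
#' @param ... Unused.
#' @return A tibble `from`, `to`, `event_count`, `weight`.
#' @method tidy movement_network
#' @export
tidy.movement_network <- function(x, self_loops = FALSE, ...) {
  out <- x$edges
  if (self_loops && nrow(x$self_loops) > 0) {
    out <- bind_rows(out, x$self_loops %>%
                       mutate(from = .data$station_id, to = .data$station_id) %>%
                       select("from", "to", "event_count", "weight"))
  }
  out
}

#' One-row summary of a movement network
#'
#' @param x A `movement_network`.
#' @param ... Unused.
#' @return A one-row tibble: stratum descriptors, `order`, `size`,
#'   `n_components`, `n_events` (self-loops included), `n_self_loop_events`.
#' @method glance movement_network
#' @export
glance.movement_network <- function(x, ...) {
  s <- summarize_network(x)
  tibble(
    species = x$stratum$species, sex = x$stratum$sex,
    period = x$stratum$period, tag_id = x$stratum$tag_id,
    order = s$order, size = s$size, n_components = s$n_components,
    n_events = network_event_count(x),
    n_self_loop_events = sum(x$self_loops$event_count)
  )
}

#' Tidy the fitted habitat model into its importance table
#'
#' @param x A `habitat_gbm`.
#' @param ... Unused.
#' @return A tibble `predictor`, `relative_influence` (summing to 100),
#'   descending.
#' @method tidy habitat_gbm
#' @export
tidy.habitat_gbm <- function(x, ...) x$importance

#' One-row summary of a fitted habitat model
#'
#' @param x A `habitat_gbm`.
#' @param ... Unused.
#' @return A one-row tibble with the selected settings, `r2_train` and
#'   `rho_test`.
#' @method glance habitat_gbm
#' @export
glance.habitat_gbm <- function(x, ...) {
  tibble(
    interaction_depth = x$settings$interaction_depth,
    shrinkage = x$settings$shrinkage,
    bag_fraction = x$settings$bag_fraction,
    n_trees = x$settings$n_trees,
    r2_train = x$r2_train,
    rho_test = x$rho_test
  )
}
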