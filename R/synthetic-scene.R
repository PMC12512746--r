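# habitat class codes used by the synthetic scene
SCENE_CLASSES <- c("1" = "open_water", "2" = "forereef", "3" = "reef_crest",
                   "4" = "passage", "5" = "sand", "6" = "coral")

#' Build a synthetic atoll reef scene and receiver array
#'
#' Generates a planar gridded seascape with one or more atolls, each a
#' concentric structure of lagoon (sand floor with coral patches), an
#' emergent reef-crest ring broken by one or more passages, and a forereef
#' apron sloping into open water, together with a receiver-station table
#' (stations inside the lagoon, at each passage mouth and along the
#' forereef). Deterministic given `seed`; the crest ring (passages excepted)
#' acts as the movement barrier for the track simulator.
#'
#' @param n_atolls Number of atolls, placed west to east (default 1).
#' @param atoll_spacing_m Centre-to-centre spacing (default 12000); must
#'   exceed twice `atoll_radius_m`.
#' @param atoll_radius_m Outer forereef radius (default 2500).
#' @param lagoon_radius_m Lagoon radius (default 1600).
#' @param crest_width_m Reef-crest ring width (default 200).
#' @param n_passages Passages per atoll (default 1).
#' @param passage_width_deg Angular width of each passage gap (default 25).
#' @param cell_size_m Grid resolution (default 50).
#' @param margin_m Open-water margin around the atolls (default 1500).
#' @param n_coral_patches Coral patches per lagoon (default 4).
#' @param n_lagoon_stations,n_forereef_stations Receivers per atoll in each
#'   zone (passage mouths always get one receiver just inside and one just
#'   outside each passage).
#' @param origin_lonlat Geographic anchor (lon, lat) of the planar origin.
#' @param seed Integer seed.
#' @return A list with `scene` (a [habitat_scene()] with `atolls` and
#'   `passages` tibbles attached) and `stations` (receiver table in both
#'   planar and geographic coordinates).
#' @export
build_reef_scene <- function(n_atolls = 1L, atoll_spacing_m = 12000,
                             atoll_radius_m = 2500, lagoon_radius_m = 1600,
                             crest_width_m = 200, n_passages = 1L,
                             passage_width_deg = 25, cell_size_m = 50,
                             margin_m = 1500, n_coral_patches = 4L,
                             n_lagoon_stations = 3L, n_forereef_stations = 6L,
                             origin_lonlat = c(121.8, -14.1), seed = 1L) {
  if (n_atolls > 1 && atoll_spacing_m <= 2 * atoll_radius_m) {
    abort("atolls overlap: atoll_spacing_m must exceed 2 * atoll_radius_m")
  }
  stopifnot(lagoon_radius_m + crest_width_m < atoll_radius_m)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  centres <- tibble(
    atoll = paste0("A", seq_len(n_atolls)),
    cx = (seq_len(n_atolls) - 1) * atoll_spacing_m,
    cy = 0
  )
  crest_outer <- lagoon_radius_m + crest_width_m

  x0 <- -atoll_radius_m - margin_m
  y0 <- -atoll_radius_m - margin_m
  x1 <- (n_atolls - 1) * atoll_spacing_m + atoll_radius_m + margin_m
  y1 <- atoll_radius_m + margin_m
  xs <- seq(x0, x1, by = cell_size_m)
  ys <- seq(y0, y1, by = cell_size_m)
  nc <- length(xs); nr <- length(ys)

  # nearest atoll assignment per cell
  gx <- matrix(xs, nr, nc, byrow = TRUE)
  gy <- matrix(ys, nr, nc)
  rmin <- matrix(Inf, nr, nc)
  theta <- matrix(0, nr, nc)
  for (k in seq_len(n_atolls)) {
    rk <- sqrt((gx - centres$cx[k])^2 + (gy - centres$cy[k])^2)
    upd <- rk < rmin
    theta[upd] <- atan2(gy[upd] - centres$cy[k], gx[upd] - centres$cx[k])
    rmin[upd] <- rk[upd]
  }

  pass_angles <- (pi / 4 + 2 * pi * (seq_len(n_passages) - 1) / n_passages) %% (2 * pi)
  half_w <- passage_width_deg / 2 * pi / 180
  ang_dist <- function(a, b) {
    d <- abs((a - b) %% (2 * pi))
    pmin(d, 2 * pi - d)
  }
  in_passage <- matrix(FALSE, nr, nc)
  for (a in pass_angles) in_passage <- in_passage | ang_dist(theta, a) <= half_w

  cls <- matrix(1L, nr, nc)  # open water
  cls[rmin <= atoll_radius_m] <- 2L  # forereef
  crest_band <- rmin > lagoon_radius_m & rmin <= crest_outer
  cls[crest_band & !in_passage] <- 3L
  cls[crest_band & in_passage] <- 4L
  cls[rmin <= lagoon_radius_m] <- 5L  # lagoon sand
  # coral patches inside lagoons
  for (k in seq_len(n_atolls)) {
    for (p in seq_len(n_coral_patches)) {
      pa <- runif(1, 0, 2 * pi)
      pr <- runif(1, 0.2, 0.8) * lagoon_radius_m
      px <- centres$cx[k] + pr * cos(pa)
      py <- centres$cy[k] + pr * sin(pa)
      prad <- runif(1, 120, 280)
      patch <- (gx - px)^2 + (gy - py)^2 <= prad^2 & cls == 5L
      cls[patch] <- 6L
    }
  }

  depth <- matrix(0, nr, nc)
  depth[cls == 5L] <- 4 + 8 * (rmin[cls == 5L] / lagoon_radius_m)
  depth[cls == 6L] <- 3
  depth[cls == 3L] <- 0.3
  depth[cls == 4L] <- 7
  fr <- cls == 2L
  depth[fr] <- 5 + 55 * pmax(rmin[fr] - crest_outer, 0) / (atoll_radius_m - crest_outer)
  ow <- cls == 1L
  depth[ow] <- pmin(80 + 0.05 * (rmin[ow] - atoll_radius_m), 300)

  scene <- habitat_scene(
    class_grid = cls, class_names = SCENE_CLASSES, depth = depth,
    crest_mask = cls == 3L, passage_cells = cls == 4L,
    cell_size_m = cell_size_m, origin = c(x0, y0),
    origin_lonlat = origin_lonlat
  )
  scene$atolls <- mutate(centres, radius_m = atoll_radius_m,
                         lagoon_radius_m = lagoon_radius_m,
                         crest_outer_m = crest_outer)
  scene$passages <- tidyr::expand_grid(centres, angle = pass_angles) %>%
    mutate(x = .data$cx + (lagoon_radius_m + crest_width_m / 2) * cos(.data$angle),
           y = .data$cy + (lagoon_radius_m + crest_width_m / 2) * sin(.data$angle)) %>%
    select("atoll", "angle", "x", "y")

  stations <- build_station_array(scene, n_lagoon_stations, n_forereef_stations)
  list(scene = scene, stations = stations)
}

build_station_array <- function(scene, n_lagoon, n_forereef) {
  at <- scene$atolls
  rows <- purrr::map(seq_len(nrow(at)), function(k) {
    cx <- at$cx[k]; cy <- at$cy[k]
    lag_r <- at$lagoon_radius_m[k]; crest_o <- at$crest_outer_m[k]
    fr_r <- (crest_o + at$radius_m[k]) / 2
    ps <- filter(scene$passages, .data$atoll == at$atoll[k])
    pass_pts <- bind_rows(purrr::map(seq_len(nrow(ps)), function(q) {
      a <- ps$angle[q]
      tibble(
        x_m = c(cx + (lag_r - 300) * cos(a), cx + (crest_o + 300) * cos(a)),
        y_m = c(cy + (lag_r - 300) * sin(a), cy + (crest_o + 300) * sin(a)),
        zone = "passage"
      )
    }))
    lag_a <- seq(0, 2 * pi, length.out = n_lagoon + 1)[-1] + pi / 6
    lag_pts <- tibble(x_m = cx + 0.55 * lag_r * cos(lag_a),
                      y_m = cy + 0.55 * lag_r * sin(lag_a), zone = "lagoon")
    fr_a <- seq(0, 2 * pi, length.out = n_forereef + 1)[-1]
    fr_pts <- tibble(x_m = cx + fr_r * cos(fr_a),
                     y_m = cy + fr_r * sin(fr_a), zone = "forereef")
    mutate(bind_rows(pass_pts, lag_pts, fr_pts), atoll = at$atoll[k])
  })
  st <- bind_rows(rows)
  lon0 <- scene$origin_lonlat[1]; lat0 <- scene$origin_lonlat[2]
  st %>%
    mutate(
      station_id = sprintf("ST%02d", row_number()),
      latitude = lat0 + .data$y_m / 111320,
      longitude = lon0 + .data$x_m / (111320 * cos(lat0 * pi / 180)),
      reef_system = "SynthReef",
      detection_range_m = 300
    ) %>%
    select("station_id", "latitude", "longitude", "reef_system", "atoll",
           "detection_range_m", "zone", "x_m", "y_m")
}

#' Write / read a habitat scene as a plain-text bundle
#'
#' Layers are stored as headerless CSV matrices next to a JSON sidecar
#' carrying the class names, cell size and placement, so a scene round-trips
#' through text files.
#'
#' @param scene A `habitat_scene`.
#' @param dir Directory for the bundle (created if needed).
#' @return `dir` (writer) or the restored `habitat_scene` (reader).
#' @export
write_habitat_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wmat <- function(m, f) utils::write.table(
    m, file.path(dir, f), sep = ",", row.names = FALSE, col.names = FALSE)
  wmat(scene$class_grid, "class_grid.csv")
  wmat(scene$depth, "depth.csv")
  wmat(scene$crest_mask * 1L, "crest_mask.csv")
  wmat(scene$passage_cells * 1L, "passage_cells.csv")
  jsonlite::write_json(
    list(class_names = as.list(scene$class_names),
         cell_size_m = scene$cell_size_m, origin = scene$origin,
         origin_lonlat = scene$origin_lonlat),
    file.path(dir, "scene.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_habitat_scene
#' @export
read_habitat_scene <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "scene.json"), simplifyVector = TRUE)
  rmat <- function(f, cast = identity) {
    m <- as.matrix(utils::read.table(file.path(dir, f), sep = ","))
    dimnames(m) <- NULL
    cast(m)
  }
  cls <- rmat("class_grid.csv", function(m) matrix(as.integer(m), nrow(m)))
  habitat_scene(
    class_grid = cls,
    class_names = unlist(meta$class_names),
    depth = rmat("depth.csv"),
    crest_mask = rmat("crest_mask.csv") == 1,
    passage_cells = rmat("passage_cells.csv") == 1,
    cell_size_m = meta$cell_size_m, origin = meta$origin,
    origin_lonlat = meta$origin_lonlat
  )
}
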