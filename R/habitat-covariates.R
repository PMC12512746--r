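#' Construct a habitat scene from raw layers
#'
#' A habitat scene is a planar gridded description of the seascape: a habitat
#' class grid, a depth grid (metres, positive down), a reef-crest mask and the
#' set of crest-passage cells, all sharing one shape and placement. Cell
#' `[i, j]` has its centre at planar coordinates
#' `(origin[1] + (j-1) * cell_size_m, origin[2] + (i-1) * cell_size_m)`,
#' rows increasing northwards. The planar approximation is appropriate at
#' atoll scale (tens of km).
#'
#' @param class_grid Integer matrix of habitat class codes.
#' @param class_names Named character vector mapping code (as name) to class
#'   label, e.g. `c("1" = "open_water", "2" = "sand")`.
#' @param depth Numeric matrix, metres positive down; same shape.
#' @param crest_mask Logical matrix marking reef-crest cells.
#' @param passage_cells Logical matrix marking crest-passage cells.
#' @param cell_size_m Cell edge length in metres.
#' @param origin Planar coordinates (x, y) of the centre of cell `[1, 1]`.
#' @param origin_lonlat Optional (lon, lat) anchoring the planar origin so
#'   stations given in geographic coordinates can be projected in.
#' @return A `habitat_scene` object.
#' @export
habitat_scene <- function(class_grid, class_names, depth, crest_mask,
                          passage_cells, cell_size_m, origin = c(0, 0),
                          origin_lonlat = NULL) {
  stopifnot(is.matrix(class_grid), cell_size_m > 0)
  for (layer in list(depth, crest_mask, passage_cells)) {
    if (!all(dim(layer) == dim(class_grid))) {
      abort("all scene layers must share one shape")
    }
  }
  codes <- unique(as.vector(class_grid))
  if (!all(as.character(codes) %in% names(class_names))) {
    abort("class_grid contains codes absent from class_names")
  }
  structure(
    list(class_grid = class_grid, class_names = class_names, depth = depth,
         crest_mask = crest_mask, passage_cells = passage_cells,
         cell_size_m = cell_size_m, origin = origin,
         origin_lonlat = origin_lonlat),
    class = "habitat_scene"
  )
}

#' @export
print.habitat_scene <- function(x, ...) {
  cat(sprintf("<habitat_scene> %d x %d cells @ %g m (%0.1f x %0.1f km)\n",
              nrow(x$class_grid), ncol(x$class_grid), x$cell_size_m,
              nrow(x$class_grid) * x$cell_size_m / 1000,
              ncol(x$class_grid) * x$cell_size_m / 1000))
  cat("  classes:", paste(x$class_names, collapse = ", "), "\n")
  invisible(x)
}

# planar coordinates of every cell centre (j -> x, i -> y)
cell_centres <- function(scene) {
  list(
    x = scene$origin[1] + (seq_len(ncol(scene$class_grid)) - 1) * scene$cell_size_m,
    y = scene$origin[2] + (seq_len(nrow(scene$class_grid)) - 1) * scene$cell_size_m
  )
}

# planar station coordinates; falls back to projecting lat/lon about the
# scene's geographic origin
station_xy <- function(scene, stations) {
  if (all(c("x_m", "y_m") %in% names(stations))) {
    return(cbind(stations$x_m, stations$y_m))
  }
  if (is.null(scene$origin_lonlat)) {
    abort("stations lack planar x_m/y_m and the scene has no origin_lonlat")
  }
  check_columns(stations, c("latitude", "longitude"), "station table")
  lon0 <- scene$origin_lonlat[1]; lat0 <- scene$origin_lonlat[2]
  cbind((stations$longitude - lon0) * 111320 * cos(lat0 * pi / 180),
        (stations$latitude - lat0) * 111320)
}

#' Habitat class proportions within a sampling disc
#'
#' Fraction of each habitat class among the cells whose centres lie within
#' `radius_m` of the station — the area a receiver effectively monitors
#' (default 300 m, the receiver range estimate). Cells falling outside the
#' grid are excluded and proportions are renormalised over the covered cells;
#' the covered fraction of the disc is reported as attribute `coverage`.
#'
#' @param scene A `habitat_scene`.
#' @param station_x,station_y Planar station coordinates in metres.
#' @param radius_m Sampling radius (default 300).
#' @return Named numeric vector of proportions (one entry per class present),
#'   with attribute `coverage`.
#' @export
habitat_proportions <- function(scene, station_x, station_y, radius_m = 300) {
  cc <- cell_centres(scene)
  cell <- scene$cell_size_m
  # candidate index range, deliberately including off-grid indices so the
  # covered fraction of the disc can be reported
  jr <- floor((station_x - radius_m - scene$origin[1]) / cell):ceiling((station_x + radius_m - scene$origin[1]) / cell) + 1
  ir <- floor((station_y - radius_m - scene$origin[2]) / cell):ceiling((station_y + radius_m - scene$origin[2]) / cell) + 1
  grid <- expand.grid(i = ir, j = jr)
  gx <- scene$origin[1] + (grid$j - 1) * cell
  gy <- scene$origin[2] + (grid$i - 1) * cell
  inside_disc <- (gx - station_x)^2 + (gy - station_y)^2 <= radius_m^2
  on_grid <- grid$i >= 1 & grid$i <= nrow(scene$class_grid) &
    grid$j >= 1 & grid$j <= ncol(scene$class_grid)
  n_disc <- sum(inside_disc)
  covered <- inside_disc & on_grid
  if (n_disc == 0) {
    # disc smaller than half a cell: fall back to the station's own cell
    i0 <- round((station_y - scene$origin[2]) / cell) + 1
    j0 <- round((station_x - scene$origin[1]) / cell) + 1
    if (i0 < 1 || i0 > nrow(scene$class_grid) || j0 < 1 || j0 > ncol(scene$class_grid)) {
      abort(sprintf("sampling disc at (%g, %g) lies entirely off the scene grid",
                    station_x, station_y))
    }
    code <- as.character(scene$class_grid[i0, j0])
    out <- stats::setNames(1, scene$class_names[[code]])
    attr(out, "coverage") <- 1
    return(out)
  }
  if (!any(covered)) {
    abort(sprintf("sampling disc at (%g, %g) lies entirely off the scene grid",
                  station_x, station_y))
  }
  codes <- scene$class_grid[cbind(grid$i[covered], grid$j[covered])]
  tab <- table(scene$class_names[as.character(codes)])
  out <- as.numeric(tab) / sum(tab)
  names(out) <- names(tab)
  attr(out, "coverage") <- sum(covered) / n_disc
  out
}

#' Euclidean distance from a station to the nearest seascape feature
#'
#' Distance in metres from the station to the nearest reef-crest or
#' crest-passage cell centre (an in-grid equivalent of a GIS Euclidean
#' distance surface). A station sitting on a feature cell has distance 0.
#'
#' @inheritParams habitat_proportions
#' @param feature `"crest"` (distance to nearest reef crest, dist.reef) or
#'   `"passage"` (distance to the main passage in the reef crest,
#'   dist.channel).
#' @return Distance in metres.
#' @export
distance_to_feature <- function(scene, station_x, station_y,
                                feature = c("crest", "passage")) {
  feature <- match.arg(feature)
  mask <- if (feature == "crest") scene$crest_mask else scene$passage_cells
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) abort(sprintf("scene has no %s cells", feature))
  cell <- scene$cell_size_m
  # on-feature stations are distance 0 by definition
  i0 <- round((station_y - scene$origin[2]) / cell) + 1
  j0 <- round((station_x - scene$origin[1]) / cell) + 1
  if (i0 >= 1 && i0 <= nrow(mask) && j0 >= 1 && j0 <= ncol(mask) && mask[i0, j0]) {
    return(0)
  }
  fx <- scene$origin[1] + (idx[, "col"] - 1) * cell
  fy <- scene$origin[2] + (idx[, "row"] - 1) * cell
  sqrt(min((fx - station_x)^2 + (fy - station_y)^2))
}

# bilinear sample of the depth layer at a planar point (clamped to the grid)
sample_depth <- function(scene, station_x, station_y) {
  cell <- scene$cell_size_m
  gx <- (station_x - scene$origin[1]) / cell + 1
  gy <- (station_y - scene$origin[2]) / cell + 1
  nr <- nrow(scene$depth); nc <- ncol(scene$depth)
  gx <- min(max(gx, 1), nc); gy <- min(max(gy, 1), nr)
  j0 <- floor(gx); i0 <- floor(gy)
  j1 <- min(j0 + 1, nc); i1 <- min(i0 + 1, nr)
  tx <- gx - j0; ty <- gy - i0
  (1 - ty) * ((1 - tx) * scene$depth[i0, j0] + tx * scene$depth[i0, j1]) +
    ty * ((1 - tx) * scene$depth[i1, j0] + tx * scene$depth[i1, j1])
}

#' Assemble habitat covariates for every receiver station
#'
#' One row per station: habitat class proportions within `radius_m`
#' (`prop_<class>` columns, summing to 1 at full disc coverage), bilinear
#' depth (`depth_m`), distance to the nearest reef crest (`dist_reef_m`) and
#' to the main crest passage (`dist_channel_m`). This is the design-matrix
#' contract of the habitat preference model.
#'
#' @param scene A `habitat_scene`.
#' @param stations Station tibble; planar `x_m`/`y_m` are used when present,
#'   otherwise `latitude`/`longitude` are projected about the scene origin.
#' @param radius_m Habitat sampling radius (default 300).
#' @return A tibble with one row per station.
#' @export
assemble_node_covariates <- function(scene, stations, radius_m = 300) {
  xy <- station_xy(scene, stations)
  classes <- sort(unique(unname(scene$class_names)))
  rows <- purrr::map(seq_len(nrow(stations)), function(k) {
    pr <- habitat_proportions(scene, xy[k, 1], xy[k, 2], radius_m)
    full <- stats::setNames(numeric(length(classes)), classes)
    full[names(pr)] <- pr
    out <- as_tibble(as.list(full))
    names(out) <- paste0("prop_", names(out))
    out$station_id <- stations$station_id[k]
    out$depth_m <- sample_depth(scene, xy[k, 1], xy[k, 2])
    out$dist_reef_m <- distance_to_feature(scene, xy[k, 1], xy[k, 2], "crest")
    out$dist_channel_m <- distance_to_feature(scene, xy[k, 1], xy[k, 2], "passage")
    out$coverage <- attr(pr, "coverage")
    out
  })
  bind_rows(rows) %>%
    select("station_id", dplyr::starts_with("prop_"), "depth_m",
           "dist_reef_m", "dist_channel_m", "coverage")
}
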