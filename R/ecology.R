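# Ecological summarisation of georeferenced detections: abundance in
# individuals per square metre, effective-species diversity, and gridded
# spatial density along the camera track.

#' Georeference images against a navigation track
#'
#' Assigns each image the position and altitude of the navigation fix
#' nearest in time (ties go to the earlier fix). Images farther than
#' `max_gap_s` from every fix are reported as unresolved rather than
#' silently dropped.
#'
#' @param images tibble with `scene_id` and `timestamp` (seconds).
#' @param track tibble `timestamp, lon, lat, altitude_m`, time-ordered.
#' @param max_gap_s maximum tolerated time gap, seconds.
#' @return tibble `scene_id, timestamp, lon, lat, altitude_m, resolved`.
#' @export
georeference <- function(images, track, max_gap_s = Inf) {
  if (!nrow(track)) stop("`track` must be non-empty", call. = FALSE)
  if (is.unsorted(track$timestamp, strictly = TRUE)) {
    stop("`track` timestamps must be strictly increasing", call. = FALSE)
  }
  ts <- track$timestamp
  pos <- findInterval(images$timestamp, ts)
  pick <- vapply(seq_along(images$timestamp), function(i) {
    t <- images$timestamp[i]
    lo <- pos[i]
    cand <- c(if (lo >= 1) lo, if (lo < length(ts)) lo + 1)
    gaps <- abs(ts[cand] - t)
    as.integer(cand[which.min(gaps)]) # first index = earlier fix on ties
  }, integer(1))
  gap <- abs(ts[pick] - images$timestamp)
  tibble::tibble(
    scene_id = images$scene_id,
    timestamp = images$timestamp,
    lon = ifelse(gap <= max_gap_s, track$lon[pick], NA_real_),
    lat = ifelse(gap <= max_gap_s, track$lat[pick], NA_real_),
    altitude_m = ifelse(gap <= max_gap_s, track$altitude_m[pick], NA_real_),
    resolved = gap <= max_gap_s)
}

#' Visual footprint of one image
#'
#' Seafloor area imaged from altitude `a` with a rectangular field of
#' view: `(2 a tan(fov_x/2)) * (2 a tan(fov_y/2))` square metres. The
#' default 64 x 64 degree field of view matches a typical towed-camera
#' video head; override per deployment.
#'
#' @param altitude_m altitude above seafloor, metres (> 0); vectorised.
#' @param fov_x_deg,fov_y_deg field of view, degrees in (0, 180).
#' @return footprint(s) in square metres.
#' @export
image_footprint <- function(altitude_m, fov_x_deg = 64, fov_y_deg = 64) {
  if (any(altitude_m <= 0)) stop("`altitude_m` must be > 0", call. = FALSE)
  check_number(fov_x_deg, "fov_x_deg", min = 0, max = 180,
               closed_min = FALSE, closed_max = FALSE)
  check_number(fov_y_deg, "fov_y_deg", min = 0, max = 180,
               closed_min = FALSE, closed_max = FALSE)
  (2 * altitude_m * tan(fov_x_deg / 2 * pi / 180)) *
    (2 * altitude_m * tan(fov_y_deg / 2 * pi / 180))
}

#' Megafauna abundance in individuals per square metre
#'
#' Total individuals divided by the summed visual footprint of *all*
#' surveyed images (not only those with detections), overall and per
#' morphotype. No overlap correction between consecutive images is
#' applied.
#'
#' @param detections tibble with a `label` column (one row per detected
#'   individual).
#' @param images tibble with a `footprint_m2` column, one row per
#'   surveyed image; total footprint must be positive.
#' @return tibble `label, n, abundance_ind_m2`, one row per morphotype
#'   plus a leading `(all)` row with the overall abundance.
#' @export
abundance <- function(detections, images) {
  if (!"footprint_m2" %in% names(images)) {
    stop("`images` must carry `footprint_m2`", call. = FALSE)
  }
  total_area <- sum(images$footprint_m2)
  if (!is.finite(total_area) || total_area <= 0) {
    stop("total surveyed footprint must be > 0", call. = FALSE)
  }
  per_class <- detections |>
    dplyr::count(.data$label) |>
    dplyr::mutate(abundance_ind_m2 = .data$n / total_area) |>
    dplyr::arrange(dplyr::desc(.data$n))
  dplyr::bind_rows(
    tibble::tibble(label = "(all)", n = nrow(detections),
                   abundance_ind_m2 = nrow(detections) / total_area),
    per_class)
}

#' Effective number of morphotypes (exponential Shannon diversity)
#'
#' `exp(-sum(p_i log p_i))` over classes with positive counts: the number
#' of equally common morphotypes that would give the observed entropy.
#' Equal counts over k classes give exactly k; a single class gives 1.
#' Invariant under rescaling all counts by a positive constant.
#'
#' @param counts non-negative counts per morphotype (named or not);
#'   total must be positive.
#' @return effective number of morphotypes (>= 1).
#' @export
shannon_effective <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || sum(counts) <= 0) {
    stop("`counts` must be non-negative with positive sum", call. = FALSE)
  }
  p <- counts[counts > 0] / sum(counts)
  exp(-sum(p * log(p)))
}

#' Project lon/lat to local planar metres
#'
#' Local equirectangular projection about the mean latitude:
#' `x = R dlon cos(lat_mean)`, `y = R dlat` (radians, R = 6371 km).
#' Adequate at survey scale (kilometres).
#'
#' @param lon,lat decimal degrees.
#' @param lon0,lat0 projection origin; defaults to the data means.
#' @return tibble `x, y` in metres.
#' @export
lonlat_to_local <- function(lon, lat, lon0 = mean(lon), lat0 = mean(lat)) {
  R <- 6371000
  tibble::tibble(
    x = R * (lon - lon0) * pi / 180 * cos(lat0 * pi / 180),
    y = R * (lat - lat0) * pi / 180)
}

#' Gridded spatial density of detections
#'
#' Bins detections into square blocks of `cell_size` metres (cell index
#' `(floor(x / cell), floor(y / cell))`, valid for negative coordinates
#' too) and normalises each block's count by the total visual footprint
#' of the images whose centres fall in it.
#'
#' @param detections tibble with planar metric coordinates `x, y` (one
#'   row per individual), e.g. from [lonlat_to_local()].
#' @param images tibble with `x, y` and `footprint_m2` for every
#'   surveyed image.
#' @param cell_size block side in metres (default 200).
#' @return tibble `cell_x, cell_y, count, footprint_m2,
#'   density_ind_m2` (density is `NA` where no image footprint fell in
#'   the cell).
#' @export
grid_density <- function(detections, images, cell_size = 200) {
  check_number(cell_size, "cell_size", min = 0, closed_min = FALSE)
  det_cells <- tibble::tibble(
    cell_x = floor(detections$x / cell_size),
    cell_y = floor(detections$y / cell_size)) |>
    dplyr::count(.data$cell_x, .data$cell_y, name = "count")
  img_cells <- tibble::tibble(
    cell_x = floor(images$x / cell_size),
    cell_y = floor(images$y / cell_size),
    footprint_m2 = images$footprint_m2) |>
    dplyr::group_by(.data$cell_x, .data$cell_y) |>
    dplyr::summarise(footprint_m2 = sum(.data$footprint_m2),
                     .groups = "drop")
  out <- dplyr::full_join(det_cells, img_cells,
                          by = c("cell_x", "cell_y")) |>
    dplyr::mutate(
      count = dplyr::coalesce(.data$count, 0L),
      footprint_m2 = dplyr::coalesce(.data$footprint_m2, 0),
      density_ind_m2 = ifelse(.data$footprint_m2 > 0,
                              .data$count / .data$footprint_m2, NA_real_))
  dplyr::arrange(out, .data$cell_x, .data$cell_y)
}
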