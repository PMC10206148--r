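#' Default morphotype palette
#'
#' Ten megafauna morphotypes rendered as parametric shapes on the synthetic
#' seafloor. Shapes are coarse archetypes: `disk_arms` (central disk with
#' radiating arms, ophiuroid/coral-like), `fan` (half-ellipse, sponge-like),
#' `star` (spiked radial outline, urchin/anemone-like), `blob` (elongated
#' ellipse, holothurian/fish-like) and `plume` (irregular low-harmonic
#' outline, xenophyophore-like). The xenophyophore entry is deliberately
#' low-contrast against the sediment (a hard-to-see morphotype); relative
#' weights follow the skewed frequency distribution typical of abyssal
#' nodule fields, where ophiuroids, sponges and xenophyophores dominate.
#'
#' @return tibble with columns `name`, `shape`, `r`, `g`, `b` (mean colour),
#'   `size_min`, `size_max` (radius range, pixels) and `weight`
#'   (relative sampling probability).
#' @export
default_morphotype_palette <- function() {
  tibble::tribble(
    ~name,            ~shape,      ~r,   ~g,   ~b,   ~size_min, ~size_max, ~weight,
    "ophiuroid",      "disk_arms", 0.62, 0.30, 0.24, 8,  13, 0.31,
    "sponge",         "fan",       0.88, 0.84, 0.72, 7,  12, 0.18,
    "xenophyophore",  "plume",     0.55, 0.50, 0.43, 7,  11, 0.17,
    "anemone",        "star",      0.82, 0.52, 0.58, 6,  10, 0.11,
    "coral",          "disk_arms", 0.86, 0.55, 0.30, 8,  13, 0.05,
    "gastropod",      "blob",      0.78, 0.68, 0.52, 7,  10, 0.05,
    "sea_urchin",     "star",      0.30, 0.20, 0.38, 6,  10, 0.05,
    "holothurian",    "blob",      0.52, 0.36, 0.58, 7,  12, 0.04,
    "fish",           "blob",      0.66, 0.72, 0.82, 7,  11, 0.02,
    "shrimp",         "blob",      0.82, 0.62, 0.56, 7,  10, 0.02
  )
}

#' Configuration for synthetic benthic scenes
#'
#' Defines the statistical structure of one synthetic seafloor photograph:
#' a quasi-homogeneous sediment background with manganese-nodule speckle,
#' rare planted fauna, and red laser-point / dark-patch distractors.
#' Defaults emulate a deep-sea nodule province: fauna are rare (Poisson
#' mean 2 per frame), nodules numerous, and well over 80% of the frame is
#' plain sediment.
#'
#' @param image_size integer `(width, height)` in pixels, each >= 64.
#' @param nodule_density expected nodules per image (Poisson mean, >= 0).
#' @param fauna_rate expected fauna per image (Poisson mean, >= 0).
#' @param morphotype_palette tibble as [default_morphotype_palette()].
#' @param laser_rate expected red laser-point pairs per image (>= 0).
#' @param dark_patch_rate expected dark water-column patches per image.
#' @param noise_sigma background pixel-noise standard deviation, in
#'   `[0, 1]` intensity units.
#' @param seed integer master seed; every scene derives its own stream
#'   from `(seed, scene_index)` so scenes are independently reproducible.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(image_size = c(256, 256),
                         nodule_density = 150,
                         fauna_rate = 2,
                         morphotype_palette = default_morphotype_palette(),
                         laser_rate = 0.5,
                         dark_patch_rate = 0.2,
                         noise_sigma = 0.02,
                         seed = 1) {
  if (!is.numeric(image_size) || length(image_size) != 2 ||
      any(image_size < 64) || any(image_size != floor(image_size))) {
    stop("`image_size` must be two integers >= 64 (width, height)",
         call. = FALSE)
  }
  check_number(nodule_density, "nodule_density", min = 0)
  check_number(fauna_rate, "fauna_rate", min = 0)
  check_number(laser_rate, "laser_rate", min = 0)
  check_number(dark_patch_rate, "dark_patch_rate", min = 0)
  check_number(noise_sigma, "noise_sigma", min = 0, max = 1)
  if (!is.data.frame(morphotype_palette) || nrow(morphotype_palette) == 0) {
    stop("`morphotype_palette` must be a non-empty data frame", call. = FALSE)
  }
  need <- c("name", "shape", "r", "g", "b", "size_min", "size_max", "weight")
  if (length(setdiff(need, names(morphotype_palette)))) {
    stop("`morphotype_palette` lacks column(s): ",
         paste(setdiff(need, names(morphotype_palette)), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(morphotype_palette$name)) {
    stop("`morphotype_palette` names must be unique", call. = FALSE)
  }
  if (any(morphotype_palette$weight < 0) ||
      sum(morphotype_palette$weight) <= 0) {
    stop("`morphotype_palette` weights must be >= 0 with positive sum",
         call. = FALSE)
  }
  structure(
    list(image_size = as.integer(image_size),
         nodule_density = nodule_density, fauna_rate = fauna_rate,
         morphotype_palette = tibble::as_tibble(morphotype_palette),
         laser_rate = laser_rate, dark_patch_rate = dark_patch_rate,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "scene_config"
  )
}

# Sediment base colour; fauna palette contrasts are defined against this.
SEDIMENT_RGB <- c(0.45, 0.40, 0.33)
LASER_RADIUS_PX <- 5
LASER_SEPARATION_PX <- 40

# --- shape rasterisers -------------------------------------------------
# Each returns a logical mask over the local pixel grid (rows ys, cols xs),
# where (dx, dy) are pixel offsets from the shape centre.

shape_mask <- function(shape, r0, xs, ys, cx, cy) {
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  rr <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  switch(
    shape,
    blob = {
      ang <- stats::runif(1, 0, pi)
      aspect <- stats::runif(1, 1.6, 2.4)
      u <- dx * cos(ang) + dy * sin(ang)
      v <- -dx * sin(ang) + dy * cos(ang)
      (u / r0)^2 + (v * aspect / r0)^2 <= 1
    },
    star = {
      k <- sample(7:11, 1)
      phi <- stats::runif(1, 0, 2 * pi)
      rr <= r0 * (0.75 + 0.3 * cos(k * th + phi)^2)
    },
    plume = {
      phi <- stats::runif(3, 0, 2 * pi)
      amp <- stats::runif(3, 0.05, 0.25)
      rad <- r0 * (0.85 + amp[1] * cos(2 * th + phi[1]) +
                     amp[2] * cos(3 * th + phi[2]) +
                     amp[3] * cos(4 * th + phi[3]))
      rr <= pmax(rad, r0 * 0.3)
    },
    fan = {
      ang <- stats::runif(1, 0, 2 * pi)
      u <- dx * cos(ang) + dy * sin(ang)
      v <- -dx * sin(ang) + dy * cos(ang)
      ((u / r0)^2 + (v / (0.6 * r0))^2 <= 1) & (u >= -0.15 * r0)
    },
    disk_arms = {
      n_arms <- 5
      phi <- stats::runif(1, 0, 2 * pi)
      curve <- stats::runif(n_arms, -0.04, 0.04)
      mask <- rr <= 0.35 * r0
      for (i in seq_len(n_arms)) {
        t <- seq(0, r0, by = 0.6)
        a <- phi + 2 * pi * (i - 1) / n_arms + curve[i] * t
        px <- cx + t * cos(a)
        py <- cy + t * sin(a)
        for (j in seq_along(t)) {
          d2 <- (dx - (px[j] - cx))^2 + (dy - (py[j] - cy))^2
          mask <- mask | (d2 <= 1.4^2)
        }
      }
      mask
    },
    stop("unknown shape: ", shape)
  )
}

# Paint `mask` (over rows ys, cols xs) in colour `col` onto image `img`.
paint <- function(img, ys, xs, mask, col) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(img)
  rows <- ys[idx[, 1]]
  cols <- xs[idx[, 2]]
  for (ch in 1:3) img[cbind(rows, cols, ch)] <- col[ch]
  img
}

render_ellipse <- function(img, cx, cy, rx, ry, ang, col, w, h) {
  x0 <- max(1, floor(cx - rx - ry)); x1 <- min(w, ceiling(cx + rx + ry))
  y0 <- max(1, floor(cy - rx - ry)); y1 <- min(h, ceiling(cy + rx + ry))
  if (x0 > x1 || y0 > y1) return(list(img = img, n = 0))
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- dx * cos(ang) + dy * sin(ang)
  v <- -dx * sin(ang) + dy * cos(ang)
  mask <- (u / rx)^2 + (v / ry)^2 <= 1
  list(img = paint(img, ys, xs, mask, col), n = sum(mask))
}

# Smooth low-frequency sediment field: bilinear interpolation of a coarse
# random control grid, one per channel, about the sediment base colour.
background_field <- function(w, h, amplitude = 0.035) {
  nc <- 5
  gx <- seq(1, w, length.out = nc)
  gy <- seq(1, h, length.out = nc)
  img <- array(0, dim = c(h, w, 3))
  fx <- findInterval(seq_len(w), gx, rightmost.closed = TRUE)
  fy <- findInterval(seq_len(h), gy, rightmost.closed = TRUE)
  tx <- (seq_len(w) - gx[fx]) / (gx[fx + 1] - gx[fx])
  ty <- (seq_len(h) - gy[fy]) / (gy[fy + 1] - gy[fy])
  for (ch in 1:3) {
    ctrl <- matrix(stats::runif(nc * nc, -amplitude, amplitude), nc, nc)
    f00 <- ctrl[fy, fx, drop = FALSE]
    f10 <- ctrl[fy, fx + 1, drop = FALSE]
    f01 <- ctrl[fy + 1, fx, drop = FALSE]
    f11 <- ctrl[fy + 1, fx + 1, drop = FALSE]
    wx <- matrix(tx, h, w, byrow = TRUE)
    wy <- matrix(ty, h, w)
    img[, , ch] <- SEDIMENT_RGB[ch] +
      f00 * (1 - wx) * (1 - wy) + f10 * wx * (1 - wy) +
      f01 * (1 - wx) * wy + f11 * wx * wy
  }
  img
}

#' Generate one synthetic seafloor scene
#'
#' Renders sediment background, nodule speckle, planted fauna (with tight
#' ground-truth boxes computed from the actually painted pixels), and
#' laser / dark-patch distractors. Fully reproducible: the random stream is
#' derived from `(config$seed, scene_index)`, so any scene of a survey can
#' be regenerated in isolation.
#'
#' @param config a [scene_config()].
#' @param scene_index non-negative integer identifying the scene.
#' @param timestamp acquisition time (seconds, UTC epoch); defaults to
#'   `scene_index * 10` (a 0.1 Hz still-camera cadence).
#' @param fauna_rate_override optional Poisson mean replacing
#'   `config$fauna_rate` for this scene (used when planting at a target
#'   density per square metre).
#' @param keep_mask if `TRUE`, attach the logical fauna pixel mask (for
#'   coverage bookkeeping in tests).
#' @return object of class `scene_record`: list with `scene_id`, `image`
#'   (`h x w x 3` array in `[0,1]`), `timestamp`, `ground_truth` and
#'   `distractors` tibbles (half-open 0-based boxes), and
#'   `foreground_area` (painted non-sediment pixels).
#' @export
generate_scene <- function(config, scene_index, timestamp = NULL,
                           fauna_rate_override = NULL, keep_mask = FALSE) {
  if (!inherits(config, "scene_config")) {
    stop("`config` must be created by scene_config()", call. = FALSE)
  }
  scene_index <- check_count(scene_index, "scene_index", min = 0)
  w <- config$image_size[1]
  h <- config$image_size[2]
  scene_id <- sprintf("scene_%05d", scene_index)
  if (is.null(timestamp)) timestamp <- scene_index * 10
  fauna_rate <- fauna_rate_override %||% config$fauna_rate

  with_seed(derive_seed(config$seed, scene_index), {
    img <- background_field(w, h)
    foreground <- 0

    # nodules: dark ellipses, ordinary superpixels downstream
    n_nod <- stats::rpois(1, config$nodule_density)
    for (i in seq_len(n_nod)) {
      cx <- stats::runif(1, 1, w); cy <- stats::runif(1, 1, h)
      rx <- stats::runif(1, 3.5, 6); ry <- rx * stats::runif(1, 0.75, 1)
      col <- clip01(SEDIMENT_RGB * stats::runif(1, 0.35, 0.55) +
                      stats::rnorm(3, 0, 0.02))
      res <- render_ellipse(img, cx, cy, rx, ry, stats::runif(1, 0, pi),
                            col, w, h)
      img <- res$img
      foreground <- foreground + res$n
    }

    distractors <- list()
    # dark water-column patches
    n_dark <- stats::rpois(1, config$dark_patch_rate)
    for (i in seq_len(n_dark)) {
      cx <- stats::runif(1, 15, w - 15); cy <- stats::runif(1, 15, h - 15)
      rx <- stats::runif(1, 6, 13); ry <- rx * stats::runif(1, 0.7, 1)
      res <- render_ellipse(img, cx, cy, rx, ry, stats::runif(1, 0, pi),
                            c(0.06, 0.06, 0.07), w, h)
      img <- res$img
      foreground <- foreground + res$n
      distractors[[length(distractors) + 1]] <- tibble::tibble(
        scene_id = scene_id,
        x_min = max(0, floor(cx - rx) - 1), y_min = max(0, floor(cy - rx) - 1),
        x_max = min(w, ceiling(cx + rx)), y_max = min(h, ceiling(cy + rx)),
        kind = "dark_patch")
    }

    # laser point pairs: saturated red disks at fixed separation
    n_laser <- stats::rpois(1, config$laser_rate)
    for (i in seq_len(n_laser)) {
      ang <- stats::runif(1, 0, 2 * pi)
      m <- LASER_SEPARATION_PX / 2 + LASER_RADIUS_PX + 1
      cx <- stats::runif(1, m, w - m); cy <- stats::runif(1, m, h - m)
      for (s in c(-1, 1)) {
        px <- cx + s * cos(ang) * LASER_SEPARATION_PX / 2
        py <- cy + s * sin(ang) * LASER_SEPARATION_PX / 2
        res <- render_ellipse(img, px, py, LASER_RADIUS_PX, LASER_RADIUS_PX,
                              0, c(1, 0.12, 0.10), w, h)
        img <- res$img
        foreground <- foreground + res$n
        distractors[[length(distractors) + 1]] <- tibble::tibble(
          scene_id = scene_id,
          x_min = floor(px - LASER_RADIUS_PX) - 1,
          y_min = floor(py - LASER_RADIUS_PX) - 1,
          x_max = ceiling(px + LASER_RADIUS_PX),
          y_max = ceiling(py + LASER_RADIUS_PX), kind = "laser")
      }
    }

    # planted fauna with tight boxes from the painted pixel set
    pal <- config$morphotype_palette
    n_fauna <- stats::rpois(1, fauna_rate)
    truth <- list()
    fauna_mask <- if (keep_mask) matrix(FALSE, h, w)
    for (i in seq_len(n_fauna)) {
      row <- pal[sample.int(nrow(pal), 1, prob = pal$weight), ]
      r0 <- stats::runif(1, row$size_min, row$size_max)
      margin <- r0 + 3
      cx <- stats::runif(1, margin, w - margin)
      cy <- stats::runif(1, margin, h - margin)
      x0 <- max(1, floor(cx - r0 - 3)); x1 <- min(w, ceiling(cx + r0 + 3))
      y0 <- max(1, floor(cy - r0 - 3)); y1 <- min(h, ceiling(cy + r0 + 3))
      xs <- x0:x1; ys <- y0:y1
      mask <- shape_mask(row$shape, r0, xs, ys, cx, cy)
      if (!any(mask)) next
      col <- clip01(c(row$r, row$g, row$b) + stats::rnorm(3, 0, 0.02))
      img <- paint(img, ys, xs, mask, col)
      foreground <- foreground + sum(mask)
      idx <- which(mask, arr.ind = TRUE)
      rows <- ys[idx[, 1]]; cols <- xs[idx[, 2]]
      if (keep_mask) fauna_mask[cbind(rows, cols)] <- TRUE
      truth[[length(truth) + 1]] <- tibble::tibble(
        scene_id = scene_id,
        x_min = min(cols) - 1, y_min = min(rows) - 1,
        x_max = max(cols), y_max = max(rows), label = row$name)
    }

    if (config$noise_sigma > 0) {
      img <- img + array(stats::rnorm(length(img), 0, config$noise_sigma),
                         dim = dim(img))
    }
    img <- clip01(img)

    empty_truth <- tibble::tibble(scene_id = character(), x_min = numeric(),
                                  y_min = numeric(), x_max = numeric(),
                                  y_max = numeric(), label = character())
    empty_dist <- tibble::tibble(scene_id = character(), x_min = numeric(),
                                 y_min = numeric(), x_max = numeric(),
                                 y_max = numeric(), kind = character())
    out <- structure(
      list(scene_id = scene_id, image = img, timestamp = timestamp,
           ground_truth = if (length(truth)) dplyr::bind_rows(truth)
                          else empty_truth,
           distractors = if (length(distractors))
                           dplyr::bind_rows(distractors) else empty_dist,
           foreground_area = foreground,
           width = w, height = h),
      class = "scene_record")
    if (keep_mask) out$fauna_mask <- fauna_mask
    out
  })
}

#' Track specification for a synthetic camera tow
#'
#' A locally straight tow line: the platform moves at `speed_ms` along a
#' fixed heading, photographing every `interval_s` seconds (default 10 s,
#' a 0.1 Hz still camera), with navigation fixes every `fix_interval_s`
#' and altitude oscillating smoothly inside `altitude_range` (metres above
#' seafloor, the 1--4 m envelope of a towed camera platform).
#'
#' @param start_lon,start_lat track origin, decimal degrees.
#' @param heading_deg course over ground, degrees clockwise from north.
#' @param speed_ms tow speed in m/s (default 0.26, about 0.5 knots).
#' @param interval_s seconds between consecutive photographs (> 0).
#' @param t0 timestamp of the first photograph (seconds, UTC epoch).
#' @param fix_interval_s seconds between navigation fixes.
#' @param altitude_range,altitude_period_s envelope and period of the
#'   altitude oscillation.
#' @return list of class `track_spec`.
#' @export
survey_track <- function(start_lon = -117.5, start_lat = 11.85,
                         heading_deg = 90, speed_ms = 0.26,
                         interval_s = 10, t0 = 0, fix_interval_s = 5,
                         altitude_range = c(1.5, 3.5),
                         altitude_period_s = 300) {
  check_number(interval_s, "interval_s", min = 0, closed_min = FALSE)
  check_number(speed_ms, "speed_ms", min = 0)
  if (length(altitude_range) != 2 || altitude_range[1] < 1 ||
      altitude_range[2] > 10 || diff(altitude_range) < 0) {
    stop("`altitude_range` must lie within [1, 10] metres", call. = FALSE)
  }
  structure(list(start_lon = start_lon, start_lat = start_lat,
                 heading_deg = heading_deg, speed_ms = speed_ms,
                 interval_s = interval_s, t0 = t0,
                 fix_interval_s = fix_interval_s,
                 altitude_range = altitude_range,
                 altitude_period_s = altitude_period_s),
            class = "track_spec")
}

track_position <- function(track, t) {
  R <- 6371000
  dt <- t - track$t0
  dist <- track$speed_ms * dt
  hd <- track$heading_deg * pi / 180
  de <- dist * sin(hd)
  dn <- dist * cos(hd)
  lat0 <- track$start_lat * pi / 180
  mid <- mean(track$altitude_range)
  amp <- diff(track$altitude_range) / 2
  tibble::tibble(
    timestamp = t,
    lon = track$start_lon + (de / (R * cos(lat0))) * 180 / pi,
    lat = track$start_lat + (dn / R) * 180 / pi,
    altitude_m = mid + amp * sin(2 * pi * dt / track$altitude_period_s))
}

#' Generate a synthetic benthic survey
#'
#' Produces `n_images` scenes photographed along a straight tow line, plus
#' the matching timestamped navigation track. Image timestamps follow the
#' arithmetic cadence `t0 + i * interval_s`; navigation fixes are at least
#' as frequent as the image cadence.
#'
#' @param config a [scene_config()].
#' @param n_images number of photographs (>= 1).
#' @param track a [survey_track()].
#' @param fauna_density_m2 optional target abundance (individuals per
#'   square metre). When given, each scene's Poisson mean is
#'   `density * visual footprint` at its altitude (64 degree x 64 degree
#'   field of view), overriding `config$fauna_rate`.
#' @return list with elements `scenes` (list of `scene_record`) and
#'   `track` (tibble `timestamp, lon, lat, altitude_m`, strictly
#'   increasing timestamps).
#' @export
generate_survey <- function(config, n_images, track = survey_track(),
                            fauna_density_m2 = NULL) {
  n_images <- check_count(n_images, "n_images", min = 1)
  if (!inherits(track, "track_spec")) {
    stop("`track` must be created by survey_track()", call. = FALSE)
  }
  t_img <- track$t0 + (seq_len(n_images) - 1) * track$interval_s
  t_fix <- seq(track$t0, max(t_img) + track$fix_interval_s,
               by = track$fix_interval_s)
  fixes <- track_position(track, t_fix)
  scenes <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    rate <- NULL
    if (!is.null(fauna_density_m2)) {
      alt <- track_position(track, t_img[i])$altitude_m
      rate <- fauna_density_m2 * image_footprint(alt)
    }
    scenes[[i]] <- generate_scene(config, i - 1, timestamp = t_img[i],
                                  fauna_rate_override = rate)
  }
  list(scenes = scenes, track = fixes)
}

#' Write a survey to disk
#'
#' Writes per-scene PNGs, ground truth as both CSV and COCO-style JSON
#' (with per-image timestamps), navigation as CSV, and a manifest listing
#' every file with its MD5 checksum.
#'
#' @param scenes list of `scene_record`.
#' @param track navigation tibble (`timestamp, lon, lat, altitude_m`).
#' @param out_dir output directory (created if needed).
#' @return path to the manifest JSON, invisibly usable as a survey handle.
#' @export
write_survey <- function(scenes, track, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0) {
    stop("cannot write to directory: ", out_dir, call. = FALSE)
  }
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, showWarnings = FALSE)

  image_files <- character(0)
  for (sc in scenes) {
    f <- file.path(img_dir, paste0(sc$scene_id, ".png"))
    png::writePNG(sc$image, f)
    image_files <- c(image_files, f)
  }
  truth <- dplyr::bind_rows(lapply(scenes, `[[`, "ground_truth"))
  dist <- dplyr::bind_rows(lapply(scenes, `[[`, "distractors"))
  gt_csv <- file.path(out_dir, "ground_truth.csv")
  utils::write.csv(truth, gt_csv, row.names = FALSE)
  nav_csv <- file.path(out_dir, "navigation.csv")
  utils::write.csv(
    data.frame(
      timestamp_iso = format(as.POSIXct(track$timestamp,
                                        origin = "1970-01-01", tz = "UTC"),
                             "%Y-%m-%dT%H:%M:%OS3Z"),
      lon = track$lon, lat = track$lat, altitude_m = track$altitude_m),
    nav_csv, row.names = FALSE)

  scene_meta <- tibble::tibble(
    scene_id = vapply(scenes, `[[`, character(1), "scene_id"),
    timestamp = vapply(scenes, `[[`, numeric(1), "timestamp"),
    width = vapply(scenes, `[[`, integer(1), "width"),
    height = vapply(scenes, `[[`, integer(1), "height"),
    file_name = file.path("images", paste0(
      vapply(scenes, `[[`, character(1), "scene_id"), ".png")))
  gt_json <- file.path(out_dir, "ground_truth.json")
  write_coco(truth, scene_meta, gt_json, distractors = dist)

  files <- c(image_files, gt_csv, gt_json, nav_csv)
  manifest <- list(
    n_scenes = length(scenes),
    files = data.frame(file = sub(paste0("^", out_dir, "/?"), "", files),
                       md5 = vapply(files, md5_file, character(1)),
                       bytes = file.size(files), row.names = NULL))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest_path
}

#' @rdname write_survey
#' @param path path to `ground_truth.csv` (or a survey directory).
#' @return `read_ground_truth_csv()`: tibble of ground-truth boxes.
#' @export
read_ground_truth_csv <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "ground_truth.csv")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname write_survey
#' @return `read_navigation_csv()`: tibble `timestamp, lon, lat,
#'   altitude_m` with numeric epoch timestamps.
#' @export
read_navigation_csv <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "navigation.csv")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::tibble(
    timestamp = as.numeric(as.POSIXct(df$timestamp_iso,
                                      format = "%Y-%m-%dT%H:%M:%OSZ",
                                      tz = "UTC")),
    lon = df$lon, lat = df$lat, altitude_m = df$altitude_m)
}
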