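test_that("zero-rate scenes are empty and generation is deterministic", {
  cfg <- scene_config(image_size = c(64, 64), nodule_density = 5,
                      fauna_rate = 0, laser_rate = 0, dark_patch_rate = 0,
                      seed = 7)
  sc <- generate_scene(cfg, 3)
  expect_equal(nrow(sc$ground_truth), 0)
  expect_equal(nrow(sc$distractors), 0)

  sc2 <- generate_scene(cfg, 3)
  expect_identical(sc$image, sc2$image)
  expect_identical(sc$ground_truth, sc2$ground_truth)

  # different scene index gives a different image
  sc3 <- generate_scene(cfg, 4)
  expect_false(identical(sc$image, sc3$image))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(scene_config(image_size = c(32, 64)), "image_size")
  expect_error(scene_config(fauna_rate = -1), "fauna_rate")
  expect_error(scene_config(noise_sigma = 2), "noise_sigma")
  expect_error(scene_config(morphotype_palette = data.frame()),
               "morphotype_palette")
})

test_that("fauna counts are Poisson with the configured mean", {
  cfg <- scene_config(image_size = c(64, 64), nodule_density = 3,
                      fauna_rate = 2, laser_rate = 0, dark_patch_rate = 0,
                      noise_sigma = 0, seed = 1)
  total <- 0
  for (i in seq_len(500)) {
    total <- total + nrow(generate_scene(cfg, i)$ground_truth)
  }
  # expectation 1000, Poisson sd sqrt(1000) ~ 31.6; 3 sigma band
  expect_gt(total, 1000 - 3 * sqrt(1000))
  expect_lt(total, 1000 + 3 * sqrt(1000))
})

test_that("ground-truth boxes tightly cover every rendered fauna pixel", {
  cfg <- scene_config(image_size = c(128, 128), nodule_density = 20,
                      fauna_rate = 5, seed = 3)
  for (i in 1:5) {
    sc <- generate_scene(cfg, i, keep_mask = TRUE)
    gt <- sc$ground_truth
    if (!nrow(gt)) next
    expect_true(all(gt$x_min >= 0 & gt$y_min >= 0 &
                      gt$x_max <= 128 & gt$y_max <= 128))
    expect_true(all((gt$x_max - gt$x_min) * (gt$y_max - gt$y_min) >= 1))
    px <- which(sc$fauna_mask, arr.ind = TRUE)
    x <- px[, 2] - 1
    y <- px[, 1] - 1
    inside <- vapply(seq_along(x), function(k) {
      any(x[k] >= gt$x_min & x[k] < gt$x_max &
            y[k] >= gt$y_min & y[k] < gt$y_max)
    }, logical(1))
    expect_true(all(inside))
  }
})

test_that("default scenes are dominated by background sediment", {
  cfg <- scene_config(seed = 9)
  for (i in 1:3) {
    sc <- generate_scene(cfg, i)
    expect_lt(sc$foreground_area / (256 * 256), 0.2)
  }
})

test_that("survey timestamps follow the image cadence and tow speed", {
  survey <- small_survey()
  ts <- vapply(survey$scenes, `[[`, numeric(1), "timestamp")
  expect_equal(ts, (seq_along(ts) - 1) * 10)

  # consecutive image positions ~ speed * interval = 2.6 m apart
  track <- survey_track(speed_ms = 0.26, interval_s = 10)
  pos <- faunadetect:::track_position(track, ts)
  xy <- lonlat_to_local(pos$lon, pos$lat)
  gaps <- sqrt(diff(xy$x)^2 + diff(xy$y)^2)
  expect_equal(gaps, rep(2.6, length(gaps)), tolerance = 1e-3)

  # navigation covers every image time, strictly increasing, altitude band
  expect_true(all(diff(survey$track$timestamp) > 0))
  expect_gte(max(survey$track$timestamp), max(ts))
  expect_true(all(survey$track$altitude_m >= 1 &
                    survey$track$altitude_m <= 10))

  # minimal survey still has a covering fix
  one <- generate_survey(scene_config(image_size = c(64, 64),
                                      nodule_density = 2, seed = 1), 1)
  expect_gte(nrow(one$track), 1)
  expect_error(generate_survey(scene_config(seed = 1), 0), "n_images")
})

test_that("write_survey produces the expected files and round-trips", {
  cfg <- scene_config(image_size = c(64, 64), nodule_density = 5,
                      fauna_rate = 3, seed = 11)
  survey <- generate_survey(cfg, 2)
  dir1 <- withr::local_tempdir()
  manifest <- write_survey(survey$scenes, survey$track, dir1)
  files <- list.files(dir1, recursive = TRUE)
  expect_length(grep("\\.png$", files), 2)
  expect_length(grep("\\.json$", files), 2) # ground truth + manifest
  expect_length(grep("\\.csv$", files), 2)  # ground truth + navigation

  truth_in <- dplyr::bind_rows(lapply(survey$scenes, `[[`, "ground_truth"))
  truth_out <- read_ground_truth_csv(dir1)
  expect_equal(as.data.frame(truth_out), as.data.frame(truth_in))

  nav <- read_navigation_csv(dir1)
  expect_equal(nav$timestamp, survey$track$timestamp)
  expect_equal(nav$altitude_m, survey$track$altitude_m, tolerance = 1e-9)

  # identical survey => identical manifest; changed image => changed entry
  dir2 <- withr::local_tempdir()
  write_survey(survey$scenes, survey$track, dir2)
  expect_identical(readLines(manifest),
                   readLines(file.path(dir2, "manifest.json")))
  survey$scenes[[1]]$image[1, 1, 1] <-
    1 - survey$scenes[[1]]$image[1, 1, 1]
  dir3 <- withr::local_tempdir()
  write_survey(survey$scenes, survey$track, dir3)
  m2 <- jsonlite::read_json(file.path(dir2, "manifest.json"))
  m3 <- jsonlite::read_json(file.path(dir3, "manifest.json"))
  md5 <- function(m, i) m$files[[i]]$md5
  expect_false(md5(m2, 1) == md5(m3, 1))
  expect_identical(vapply(m2$files[-1], `[[`, "", "md5"),
                   vapply(m3$files[-1], `[[`, "", "md5"))
})

test_that("fauna can be planted at a target density per square metre", {
  cfg <- scene_config(image_size = c(64, 64), nodule_density = 2,
                      laser_rate = 0, dark_patch_rate = 0, seed = 5)
  survey <- generate_survey(cfg, 40, fauna_density_m2 = 0.5)
  n <- sum(vapply(survey$scenes, function(s) nrow(s$ground_truth),
                  numeric(1)))
  geo <- georeference(
    tibble::tibble(scene_id = vapply(survey$scenes, `[[`, "", "scene_id"),
                   timestamp = vapply(survey$scenes, `[[`, 1, "timestamp")),
    survey$track)
  expected <- 0.5 * sum(image_footprint(geo$altitude_m))
  expect_gt(n, expected - 4 * sqrt(expected))
  expect_lt(n, expected + 4 * sqrt(expected))
})
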