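test_that("georeferencing picks the nearest fix with earlier-fix ties", {
  track <- tibble::tibble(timestamp = c(0, 10), lon = c(1, 2),
                          lat = c(5, 6), altitude_m = c(2, 3))
  imgs <- tibble::tibble(scene_id = c("a", "b", "c"),
                         timestamp = c(4, 5, 500))
  g <- georeference(imgs, track, max_gap_s = 60)
  expect_equal(g$lon[1], 1) # t=4 nearer to fix at 0
  expect_equal(g$lon[2], 1) # t=5 ties -> earlier fix
  expect_false(g$resolved[3]) # 490 s gap: unresolved, not dropped
  expect_true(is.na(g$lon[3]))
  expect_equal(nrow(g), 3)
  expect_error(georeference(imgs, track[0, ]), "non-empty")
  expect_error(georeference(imgs, track[c(2, 1), ]), "increasing")
})

test_that("the visual footprint follows the pinhole closed form", {
  expect_equal(image_footprint(1), 4 * tan(32 * pi / 180)^2,
               tolerance = 1e-12)
  expect_equal(image_footprint(1), 1.5618, tolerance = 1e-3)
  expect_equal(image_footprint(2), 4 * image_footprint(1),
               tolerance = 1e-12)
  expect_equal(image_footprint(2), 6.2474, tolerance = 1e-3)
  # monotone in fov, vanishing in the small-angle limit
  expect_lt(image_footprint(1, 1, 1), 1e-3)
  expect_gt(image_footprint(1, 90, 90), image_footprint(1, 64, 64))
  expect_error(image_footprint(0), "altitude")
  expect_error(image_footprint(1, fov_x_deg = 180), "fov_x_deg")
})

test_that("abundance divides counts by the whole surveyed footprint", {
  imgs <- tibble::tibble(scene_id = paste0("s", 1:5),
                         footprint_m2 = rep(5, 5))
  dets <- tibble::tibble(scene_id = c("s1", "s1", "s2", "s3", "s3"),
                         label = c("sponge", "sponge", "ophiuroid",
                                   "sponge", "anemone"))
  ab <- abundance(dets, imgs)
  expect_equal(ab$abundance_ind_m2[ab$label == "(all)"], 5 / 25)
  expect_equal(ab$abundance_ind_m2[ab$label == "sponge"], 3 / 25)
  # zero detections
  ab0 <- abundance(dets[0, ], imgs)
  expect_equal(ab0$abundance_ind_m2[1], 0)
  expect_error(abundance(dets, imgs[0, ]), "footprint")

  # pooling sub-surveys equals the footprint-weighted combination
  ab_a <- abundance(dets[dets$scene_id %in% c("s1", "s2"), ],
                    imgs[1:2, ])
  ab_b <- abundance(dets[!dets$scene_id %in% c("s1", "s2"), ],
                    imgs[3:5, ])
  pooled <- (ab_a$abundance_ind_m2[1] * 10 +
               ab_b$abundance_ind_m2[1] * 15) / 25
  expect_equal(ab$abundance_ind_m2[1], pooled)
})

test_that("exponential Shannon diversity counts effective morphotypes", {
  expect_identical(shannon_effective(c(10, 10, 10, 10)), 4)
  expect_identical(shannon_effective(100), 1)
  expect_equal(shannon_effective(c(3, 1)), 1.7548, tolerance = 1e-3)
  # scale invariance and the uniform maximum
  expect_equal(shannon_effective(c(3, 1)), shannon_effective(c(30, 10)))
  set.seed(1)
  for (k in c(2, 5, 8)) {
    skewed <- runif(k, 0.1, 1) * c(10, rep(1, k - 1))
    expect_lte(shannon_effective(skewed), k + 1e-12)
    expect_equal(shannon_effective(rep(7, k)), k)
  }
  expect_error(shannon_effective(c(0, 0)), "positive")
  expect_error(shannon_effective(-1), "non-negative")
})

test_that("grid density bins by floor division and conserves counts", {
  dets <- tibble::tibble(x = c(250, -1, 10, 399), y = c(450, 0, 10, 450),
                         label = "a")
  imgs <- tibble::tibble(x = c(250, -1, 10, 399), y = c(450, 0, 10, 450),
                         footprint_m2 = c(4, 4, 2, 4))
  g <- grid_density(dets, imgs, cell_size = 200)
  expect_equal(g$cell_x[g$count == 2], 1)
  expect_equal(g$cell_y[g$count == 2], 2) # (250,450) and (399,450)
  expect_true(any(g$cell_x == -1 & g$cell_y == 0))
  expect_equal(sum(g$count), nrow(dets))
  # density invariant = count / footprint where defined
  ok <- g$footprint_m2 > 0
  expect_equal(g$density_ind_m2[ok], g$count[ok] / g$footprint_m2[ok])

  # translating the origin by a multiple of the cell size only relabels
  shift <- function(df) { df$x <- df$x + 600; df$y <- df$y - 400; df }
  g2 <- grid_density(shift(dets), shift(imgs), cell_size = 200)
  expect_equal(g2$cell_x, g$cell_x + 3)
  expect_equal(g2$cell_y, g$cell_y - 2)
  expect_equal(g2$density_ind_m2, g$density_ind_m2)
})

test_that("planted density is recovered through the zero-noise detector", {
  cfg <- scene_config(image_size = c(64, 64), nodule_density = 2,
                      laser_rate = 0, dark_patch_rate = 0, seed = 21)
  density <- 0.25
  est <- vapply(1:3, function(s) {
    cfg$seed <- 21 + s
    survey <- generate_survey(cfg, 40, fauna_density_m2 = density)
    gt <- dplyr::bind_rows(lapply(survey$scenes, `[[`, "ground_truth"))
    dets <- oracle_detector(gt, seed = s, image_size = c(64, 64))
    imgs <- tibble::tibble(
      scene_id = vapply(survey$scenes, `[[`, "", "scene_id"),
      timestamp = vapply(survey$scenes, `[[`, 1, "timestamp"))
    geo <- georeference(imgs, survey$track)
    geo$footprint_m2 <- image_footprint(geo$altitude_m)
    abundance(dets, geo)$abundance_ind_m2[1]
  }, numeric(1))
  expect_lt(abs(mean(est) - density) / density, 0.1)
})
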