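box <- function(x0, y0, x1, y1) {
  data.frame(x_min = x0, y_min = y0, x_max = x1, y_max = y1)
}

det <- function(sc, x0, y0, x1, y1, label, conf) {
  data.frame(scene_id = sc, x_min = x0, y_min = y0, x_max = x1,
             y_max = y1, label = label, confidence = conf)
}

truth <- function(sc, x0, y0, x1, y1, label) {
  data.frame(scene_id = sc, x_min = x0, y_min = y0, x_max = x1,
             y_max = y1, label = label)
}

test_that("IoU matches hand geometry and the pixel-grid oracle", {
  expect_equal(iou(box(0, 0, 10, 10), box(0, 0, 10, 10)), 1)
  expect_equal(iou(box(0, 0, 10, 10), box(20, 20, 30, 30)), 0)
  expect_equal(iou(box(0, 0, 10, 10), box(5, 5, 15, 15)), 1 / 7)
  # symmetry
  expect_equal(iou(box(0, 0, 10, 10), box(5, 5, 15, 15)),
               iou(box(5, 5, 15, 15), box(0, 0, 10, 10)))
  # random integer boxes against exhaustive pixel counting
  set.seed(1)
  for (i in 1:25) {
    a <- sort(sample(0:60, 2)); b <- sort(sample(0:60, 2))
    c_ <- sort(sample(0:60, 2)); d <- sort(sample(0:60, 2))
    A <- box(a[1], b[1], a[2] + 1, b[2] + 1)
    B <- box(c_[1], d[1], c_[2] + 1, d[2] + 1)
    expect_equal(iou(A, B), grid_iou(as.list(A), as.list(B)))
  }
})

test_that("greedy NMS keeps the strongest of overlapping boxes", {
  d <- rbind(det("s", 0, 0, 10, 10, "a", 0.9),
             det("s", 1, 1, 11, 11, "a", 0.8))
  expect_equal(iou(d[1, ], d[2, ]), 81 / 119)
  kept <- greedy_nms(d, 0.5)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$confidence, 0.9)

  disjoint <- rbind(det("s", 0, 0, 5, 5, "a", 0.9),
                    det("s", 20, 20, 30, 30, "a", 0.3))
  expect_equal(nrow(greedy_nms(disjoint, 0.5)), 2)

  # equal confidence on identical boxes: exactly one survives (first id)
  twin <- rbind(det("s", 0, 0, 10, 10, "a", 0.7),
                det("s", 0, 0, 10, 10, "a", 0.7))
  expect_equal(nrow(greedy_nms(twin, 0.5)), 1)

  # different classes never suppress each other
  classes <- rbind(det("s", 0, 0, 10, 10, "a", 0.9),
                   det("s", 0, 0, 10, 10, "b", 0.1))
  expect_equal(nrow(greedy_nms(classes, 0.5)), 2)
})

test_that("NMS agrees with the O(n^2) brute-force reference", {
  for (seed in 1:12) {
    inst <- random_eval_instance(seed)
    got <- greedy_nms(inst$detections, 0.5)
    want <- brute_nms(inst$detections, 0.5)
    expect_equal(tibble::as_tibble(got), tibble::as_tibble(want))
  }
})

test_that("matching follows the COCO double-count convention", {
  t1 <- truth("s", 0, 0, 10, 10, "a")
  m <- match_detections(det("s", 0, 0, 10, 10, "a", 0.9), t1)
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 0))

  two <- rbind(det("s", 0, 0, 10, 10, "a", 0.9),
               det("s", 0, 0, 10, 10, "a", 0.8))
  m2 <- match_detections(two, t1)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(1, 1, 0))

  t3 <- rbind(truth("s", 0, 0, 10, 10, "a"),
              truth("s", 20, 20, 30, 30, "a"),
              truth("s", 40, 40, 50, 50, "a"))
  m3 <- match_detections(two[0, ], t3)
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(0, 0, 3))
})

test_that("hand-constructed AP cases reproduce exactly", {
  t1 <- truth("s", 0, 0, 10, 10, "a")
  tp_first <- rbind(det("s", 0, 0, 10, 10, "a", 0.9),
                    det("s", 50, 50, 60, 60, "a", 0.8))
  ap1 <- faunadetect:::pr_one_class(tp_first, t1, "a", 0.5)$ap
  expect_equal(ap1, 1.0)

  fp_first <- rbind(det("s", 50, 50, 60, 60, "a", 0.9),
                    det("s", 0, 0, 10, 10, "a", 0.8))
  ap2 <- faunadetect:::pr_one_class(fp_first, t1, "a", 0.5)$ap
  expect_equal(ap2, 0.5)

  ap0 <- faunadetect:::pr_one_class(tp_first[0, ], t1, "a", 0.5)$ap
  expect_equal(ap0, 0)
})

test_that("AP agrees with the exhaustive PR oracle on random instances", {
  for (seed in 1:22) {
    inst <- random_eval_instance(seed)
    for (cl in c("a", "b")) {
      if (!any(inst$truths$label == cl)) next
      got <- faunadetect:::pr_one_class(inst$detections, inst$truths,
                                        cl, 0.5)$ap
      want <- brute_ap(inst$detections, inst$truths, cl, 0.5)
      expect_equal(got, want, tolerance = 1e-6)
    }
  }
})

test_that("size strata and AR caps behave as contracted", {
  # all truths 10x10 (area 100 < 32^2): only the small stratum is defined
  t_small <- rbind(truth("s", 0, 0, 10, 10, "a"),
                   truth("s", 30, 30, 40, 40, "a"))
  d_perfect <- cbind(t_small, confidence = 1)
  ev <- evaluate_detections(d_perfect, t_small)
  expect_true(is.na(ev$metrics["AP_medium"]))
  expect_true(is.na(ev$metrics["AP_large"]))
  expect_false(is.na(ev$metrics["AP_small"]))
  expect_equal(unname(ev$metrics["AR_100"]), 100)
  expect_equal(unname(ev$metrics["AP50"]), 100)

  # AR monotone in the detection cap
  set.seed(7)
  inst <- random_eval_instance(3, n_scenes = 3)
  ev2 <- evaluate_detections(inst$detections, inst$truths)
  expect_lte(ev2$metrics["AR_1"], ev2$metrics["AR_10"] + 1e-9)
  expect_lte(ev2$metrics["AR_10"], ev2$metrics["AR_100"] + 1e-9)
})

test_that("metrics are invariant under global box translation", {
  inst <- random_eval_instance(5, n_scenes = 2)
  shift <- function(df) {
    df$x_min <- df$x_min + 137; df$x_max <- df$x_max + 137
    df$y_min <- df$y_min - 41; df$y_max <- df$y_max - 41
    df
  }
  ev1 <- evaluate_detections(inst$detections, inst$truths)
  ev2 <- evaluate_detections(shift(inst$detections), shift(inst$truths))
  expect_equal(ev1$metrics, ev2$metrics)
})

test_that("the confusion matrix counts label mix-ups and misses", {
  t1 <- rbind(truth("s", 0, 0, 10, 10, "a"),
              truth("s", 30, 30, 40, 40, "b"))
  d1 <- rbind(det("s", 0, 0, 10, 10, "b", 0.9), # right box, wrong label
              det("s", 70, 70, 80, 80, "a", 0.8)) # spurious
  cm <- confusion_matrix(d1, t1, label_set = c("a", "b"))
  expect_equal(cm["a", "b"], 1L)          # mislabel
  expect_equal(cm["b", "background"], 1L) # miss
  expect_equal(cm["background", "a"], 1L) # false positive
  # truth-side conservation: each truth lands in exactly one row cell
  expect_equal(unname(rowSums(cm)[c("a", "b")]), c(1L, 1L))
})

test_that("the zero-noise oracle detector is the identity detector", {
  survey <- small_survey()
  gt <- dplyr::bind_rows(lapply(survey$scenes, `[[`, "ground_truth"))
  d <- oracle_detector(gt, seed = 1, image_size = c(128, 128))
  expect_equal(nrow(d), nrow(gt))
  expect_true(all(d$confidence == 1))
  expect_equal(d$x_min, gt$x_min)
  ev <- evaluate_detections(d, gt)
  expect_equal(unname(ev$metrics["AP50"]), 100)

  none <- oracle_detector(gt, miss_rate = 1, seed = 1)
  expect_equal(nrow(none), 0)
  ev0 <- evaluate_detections(none, gt)
  expect_equal(unname(ev0$metrics["AR_100"]), 0)
})

test_that("oracle miss rate reproduces binomial recall", {
  gt <- do.call(rbind, lapply(1:50, function(s) {
    x0 <- seq(0, 190, by = 10)
    truth(paste0("s", s), x0, x0, x0 + 8, x0 + 8, "a")
  }))
  expect_equal(nrow(gt), 1000)
  d <- oracle_detector(gt, miss_rate = 0.2, seed = 4)
  kept <- nrow(d) / nrow(gt)
  sigma <- sqrt(0.2 * 0.8 / 1000)
  expect_lt(abs(kept - 0.8), 3 * sigma)
})
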