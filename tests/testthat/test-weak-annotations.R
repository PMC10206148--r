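test_that("percentile thresholding uses linear interpolation strictly", {
  res <- tibble::tibble(patch_id = c("a", "b", "c", "d"),
                        score = c(1, 2, 3, 4))
  # 75th percentile of {1,2,3,4} is 3.25 -> only the 4 survives
  expect_equal(threshold_filter(res, 75), "d")
  # just above zero: everything but the minimum
  expect_setequal(threshold_filter(res, 1e-6), c("b", "c", "d"))
  # equal scores: strict inequality retains nothing
  eq <- tibble::tibble(patch_id = letters[1:5], score = rep(2, 5))
  expect_length(threshold_filter(eq, 75), 0)
  expect_error(threshold_filter(res[0, ], 75), "non-empty")
  expect_error(threshold_filter(res, 100), "percentile")
})

test_that("the review queue sorts by score with id tie-breaks", {
  res <- tibble::tibble(patch_id = c("p1", "p2", "p3"),
                        score = c(0.2, 0.9, 0.5))
  expect_equal(review_queue(res), c("p2", "p3", "p1"))
  tie <- tibble::tibble(patch_id = c("z", "a", "m"), score = 1)
  expect_equal(review_queue(tie), c("a", "m", "z"))
  expect_setequal(review_queue(res), res$patch_id)
})

test_that("label assignment enforces the closed morphotype vocabulary", {
  rec <- tibble::tibble(patch_id = c("p1", "p2"), scene_id = "s",
                        x_min = 0, y_min = 0, x_max = 5, y_max = 5,
                        label = "UNLABELED", source = "weak",
                        anomaly_score = 0.7)
  out <- assign_labels(rec, c(p1 = "ophiuroid"))
  expect_equal(out$label, c("ophiuroid", "UNLABELED"))
  expect_equal(out$source, c("weak", "weak"))
  expect_error(assign_labels(rec, c(p1 = "kraken")), "kraken")
  expect_error(assign_labels(rec, c(p1 = "kraken")), "ophiuroid")
  dropped <- assign_labels(rec, c(p1 = "sponge"), drop_unlabeled = TRUE)
  expect_equal(nrow(dropped), 1)

  manual <- add_manual_annotation(out, "s",
                                  list(x_min = 1, y_min = 1, x_max = 9,
                                       y_max = 9), "anemone")
  expect_equal(manual$source[3], "manual")
  expect_error(add_manual_annotation(out, "s",
                                     list(x_min = 1, y_min = 1, x_max = 9,
                                          y_max = 9), "dragon"),
               "dragon")
})

test_that("train/validation split follows floor arithmetic and is grouped", {
  n <- 2118
  rec <- tibble::tibble(patch_id = sprintf("r%05d", 1:n),
                        scene_id = sprintf("s%05d", 1:n),
                        x_min = 0, y_min = 0, x_max = 5, y_max = 5,
                        label = "sponge", source = "weak",
                        anomaly_score = 0.5)
  sp <- split_annotations(rec, 0.9, seed = 1)
  expect_equal(nrow(sp$train), 1906)
  expect_equal(nrow(sp$validation), 212)
  expect_equal(sort(c(sp$train$patch_id, sp$validation$patch_id)),
               sort(rec$patch_id))
  expect_length(intersect(sp$train$patch_id, sp$validation$patch_id), 0)
  sp2 <- split_annotations(rec, 0.9, seed = 1)
  expect_identical(sp$train$patch_id, sp2$train$patch_id)

  # grouped: records of one scene never straddle the split
  grouped <- rec
  grouped$scene_id <- rep(sprintf("s%03d", 1:100), length.out = n)
  spg <- split_annotations(grouped, 0.9, seed = 2)
  expect_length(intersect(unique(spg$train$scene_id),
                          unique(spg$validation$scene_id)), 0)
  expect_equal(nrow(spg$train) + nrow(spg$validation), n)
  expect_lte(nrow(spg$train), 1906)

  expect_error(split_annotations(rec[1, ], 0.9), "at least 2")
  one_scene <- rec[1:5, ]
  one_scene$scene_id <- "s1"
  expect_error(split_annotations(one_scene, 0.9), "2 scenes")
})

test_that("the patch classifier separates an easy toy fixture", {
  pos <- lapply(1:64, function(i) disk_patch(seed = i))
  neg <- toy_patches(64, c(0.5, 0.5, 0.5), noise = 0.05, seed = 99)
  clf <- train_patch_classifier(pos[1:48], neg[1:48], epochs = 60,
                                seed = 1)
  p_pos <- predict(clf, pos[49:64])
  p_neg <- predict(clf, neg[49:64])
  expect_true(all(p_pos >= 0 & p_pos <= 1))
  expect_true(all(p_neg >= 0 & p_neg <= 1))
  acc <- mean(c(p_pos >= 0.5, p_neg < 0.5))
  expect_gte(acc, 0.95)

  # noisy labels: a duplicated patch in both classes must not break training
  dup <- c(pos[1:8], neg[1])
  expect_s3_class(train_patch_classifier(dup, c(neg[1:8], neg[1]),
                                         epochs = 2, seed = 1),
                  "patch_classifier")
  expect_error(train_patch_classifier(pos[1:4], neg, epochs = 1),
               "8 examples")
})

test_that("classifier_filter passes through or rejects wholesale", {
  patches <- tibble::tibble(
    patch_id = c("p1", "p2"), parent_id = c("s1", "s1"),
    x_min = c(0, 10), y_min = c(0, 10), x_max = c(5, 20),
    y_max = c(5, 20), area = c(25L, 100L), score = c(0.9, 0.8),
    patch = toy_patches(2, c(0.5, 0.5, 0.5)))
  pass_all <- structure(list(p = 1), class = "constant_clf")
  assign("predict.constant_clf",
         function(object, patches, ...) rep(object$p, nrow(patches)),
         envir = globalenv())
  on.exit(rm("predict.constant_clf", envir = globalenv()), add = TRUE)

  out <- classifier_filter(pass_all, patches)
  expect_equal(nrow(out), 2)
  expect_equal(out$label, rep("UNLABELED", 2))
  expect_equal(out$source, rep("weak", 2))
  expect_equal(out$anomaly_score, c(0.9, 0.8))
  # no box invention: every output bbox is an input bbox
  expect_true(all(paste(out$x_min, out$y_min, out$x_max, out$y_max) %in%
                    paste(patches$x_min, patches$y_min, patches$x_max,
                          patches$y_max)))

  reject_all <- structure(list(p = 0), class = "constant_clf")
  expect_equal(nrow(classifier_filter(reject_all, patches)), 0)
})

test_that("annotation CSV and COCO JSON round-trip the records", {
  rec <- tibble::tibble(scene_id = c("s1", "s1", "s2"),
                        x_min = c(0, 10, 3), y_min = c(1, 11, 4),
                        x_max = c(5, 20, 9), y_max = c(6, 21, 10),
                        label = c("sponge", "ophiuroid", "anemone"),
                        source = c("weak", "weak", "manual"),
                        anomaly_score = c(0.8, 0.7, NA))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_annotations_csv(rec, csv)
  expect_equal(as.data.frame(read_annotations_csv(csv)),
               as.data.frame(rec))

  meta <- tibble::tibble(scene_id = c("s1", "s2"), width = 64, height = 64,
                         file_name = c("s1.png", "s2.png"),
                         timestamp = c(0, 10))
  json <- withr::local_tempfile(fileext = ".json")
  write_coco(rec, meta, json, categories = default_label_set())
  back <- read_coco(json)
  expect_equal(back$annotations$x_min, rec$x_min)
  expect_equal(back$annotations$y_max, rec$y_max)
  expect_equal(back$annotations$label, rec$label)
  expect_equal(back$annotations$scene_id, rec$scene_id)
  expect_equal(back$images$timestamp, meta$timestamp)
  expect_equal(back$categories$name, default_label_set())
})
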