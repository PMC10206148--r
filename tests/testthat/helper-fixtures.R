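# Shared fixtures, built in code at test time.

# flat-colour square patch with optional pixel noise
toy_patch <- function(colour, side = 64, noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- array(rep(colour, each = side * side), dim = c(side, side, 3))
  if (noise > 0) p <- p + array(rnorm(length(p), 0, noise), dim = dim(p))
  p[p < 0] <- 0
  p[p > 1] <- 1
  p
}

toy_patches <- function(n, colour, side = 64, noise = 0.02, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) toy_patch(colour, side, noise))
}

# a red disk on grey background: the "obvious fauna" patch
disk_patch <- function(side = 64, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- toy_patch(c(0.5, 0.5, 0.5), side, noise = 0.02)
  cx <- side / 2 + runif(1, -3, 3)
  cy <- side / 2 + runif(1, -3, 3)
  r <- side / 4 + runif(1, -2, 2)
  for (i in seq_len(side)) {
    for (j in seq_len(side)) {
      if ((i - cy)^2 + (j - cx)^2 <= r^2) p[i, j, ] <- c(0.9, 0.1, 0.1)
    }
  }
  p
}

# lazily cached small survey shared across test files
.fixture_cache <- new.env(parent = emptyenv())

small_survey <- function() {
  if (is.null(.fixture_cache$survey)) {
    cfg <- scene_config(image_size = c(128, 128), nodule_density = 40,
                        fauna_rate = 2, laser_rate = 0.3,
                        dark_patch_rate = 0.1, seed = 42)
    .fixture_cache$survey <- generate_survey(cfg, 6)
  }
  .fixture_cache$survey
}

# rank-based AUROC (Mann-Whitney)
auroc <- function(score, is_pos) {
  r <- rank(score)
  (mean(r[is_pos]) - (sum(is_pos) + 1) / 2) / sum(!is_pos)
}

# random detection/truth instances for oracle-equivalence checks
random_eval_instance <- function(seed, n_scenes = 2, max_boxes = 10,
                                 classes = c("a", "b")) {
  set.seed(seed)
  mk <- function(n, sc, conf = FALSE) {
    if (n == 0) {
      out <- data.frame(scene_id = character(), x_min = numeric(),
                        y_min = numeric(), x_max = numeric(),
                        y_max = numeric(), label = character())
      if (conf) out$confidence <- numeric()
      return(out)
    }
    x0 <- runif(n, 0, 80); y0 <- runif(n, 0, 80)
    out <- data.frame(
      scene_id = sc, x_min = x0, y_min = y0,
      x_max = x0 + runif(n, 4, 30), y_max = y0 + runif(n, 4, 30),
      label = sample(classes, n, replace = TRUE))
    if (conf) out$confidence <- runif(n)
    out
  }
  truths <- do.call(rbind, lapply(seq_len(n_scenes), function(s) {
    mk(sample.int(max_boxes, 1), paste0("s", s))
  }))
  dets <- do.call(rbind, lapply(seq_len(n_scenes), function(s) {
    mk(sample.int(max_boxes, 1), paste0("s", s), conf = TRUE)
  }))
  list(detections = dets, truths = truths)
}
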