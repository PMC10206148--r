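#' Superpixel segmentation parameters
#'
#' Controls for graph-based over-segmentation with Gaussian pre-smoothing.
#' `scale` is the merging-threshold constant of the greedy graph algorithm
#' (larger values favour larger segments); `sigma` is the standard
#' deviation of the Gaussian filter applied before segmentation to damp
#' pixel noise; `min_size` is the minimum segment area enforced by a
#' post-merging pass; `max_area_fraction` excludes near-background
#' segments (on a quasi-homogeneous seafloor the sediment collapses into
#' one dominant superpixel, which is not a candidate object). Defaults
#' give on the order of 10^2--10^3 superpixels on default synthetic
#' scenes; segmentation hyperparameters must be re-tuned for other image
#' sources.
#'
#' @param scale merging-threshold constant (> 0).
#' @param sigma Gaussian pre-smoothing std in pixels (>= 0; 0 disables).
#' @param min_size minimum segment area in pixels (>= 1).
#' @param max_area_fraction exclude segments larger than this fraction of
#'   the image, in (0, 1].
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(scale = 100, sigma = 1.0, min_size = 50,
                                max_area_fraction = 0.25) {
  check_number(scale, "scale", min = 0, closed_min = FALSE)
  check_number(sigma, "sigma", min = 0)
  min_size <- check_count(min_size, "min_size", min = 1)
  check_number(max_area_fraction, "max_area_fraction", min = 0, max = 1,
               closed_min = FALSE)
  structure(list(scale = scale, sigma = sigma, min_size = min_size,
                 max_area_fraction = max_area_fraction),
            class = "segmentation_params")
}

#' Segment an image into superpixels
#'
#' Graph-based segmentation: pixels are nodes of an 8-connected graph with
#' RGB Euclidean edge weights; greedy merging over weight-sorted edges
#' groups perceptually similar neighbourhoods into superpixels. The image
#' is first smoothed channel-wise with a Gaussian filter (`params$sigma`)
#' so isolated noisy pixels do not seed spurious segments.
#'
#' @param image `h x w x 3` numeric array in `[0, 1]`.
#' @param params a [segmentation_params()].
#' @return integer label matrix (`h x w`); labels `1..K` tile the image
#'   exactly and every segment has at least `min_size` pixels.
#' @export
segment_image <- function(image, params = segmentation_params()) {
  assert_image(image)
  if (!inherits(params, "segmentation_params")) {
    stop("`params` must be created by segmentation_params()", call. = FALSE)
  }
  smoothed <- image
  if (params$sigma > 0) {
    for (ch in 1:3) {
      smoothed[, , ch] <- EBImage::gblur(image[, , ch], sigma = params$sigma)
    }
  }
  # Edge weights are Euclidean RGB distances on the 0-255 intensity scale,
  # the convention of the reference implementations of this algorithm, so
  # `scale` keeps its customary magnitude (~100).
  .felzenszwalb_cpp(smoothed[, , 1] * 255, smoothed[, , 2] * 255,
                    smoothed[, , 3] * 255, params$scale, params$min_size)
}

#' Crop superpixels into square patches
#'
#' One patch per segment small enough to be an object candidate (area at
#' most `max_area_fraction` of the image; the dominant sediment segment is
#' excluded here). Each patch is the square crop of side
#' `max(box width, box height)` centred on the segment's bounding-box
#' centre, clipped to image bounds, replicate-padded back to square, and
#' bilinearly resampled to `patch_size x patch_size`.
#'
#' @param image `h x w x 3` array.
#' @param label_map integer matrix from [segment_image()] of equal shape.
#' @param params a [segmentation_params()].
#' @param patch_size output patch side in pixels.
#' @param parent_id scene identifier recorded on each patch.
#' @return tibble with columns `patch_id`, `parent_id`, `segment_id`,
#'   `x_min, y_min, x_max, y_max` (segment bounding box, half-open
#'   0-based), `area` (segment pixel count) and `patch` (list-column of
#'   `patch_size x patch_size x 3` arrays).
#' @export
extract_patches <- function(image, label_map, params = segmentation_params(),
                            patch_size = 64, parent_id = "scene") {
  assert_image(image)
  if (!all(dim(label_map) == dim(image)[1:2])) {
    stop("`label_map` shape does not match `image`", call. = FALSE)
  }
  patch_size <- check_count(patch_size, "patch_size", min = 2)
  h <- dim(image)[1]; w <- dim(image)[2]
  areas <- tabulate(label_map)
  keep <- which(areas > 0 & areas <= params$max_area_fraction * h * w)
  if (!length(keep)) {
    return(tibble::tibble(patch_id = character(), parent_id = character(),
                          segment_id = integer(), x_min = numeric(),
                          y_min = numeric(), x_max = numeric(),
                          y_max = numeric(), area = integer(),
                          patch = list()))
  }
  # bounding boxes per label, via one pass over the label map
  row_idx <- rep.int(seq_len(h), w)
  col_idx <- rep(seq_len(w), each = h)
  lab <- as.integer(label_map)
  rows_min <- tapply(row_idx, lab, min)
  rows_max <- tapply(row_idx, lab, max)
  cols_min <- tapply(col_idx, lab, min)
  cols_max <- tapply(col_idx, lab, max)
  lab_levels <- as.integer(names(rows_min))

  li <- match(keep, lab_levels)
  bx_min <- unname(cols_min[li]) - 1; bx_max <- unname(cols_max[li])
  by_min <- unname(rows_min[li]) - 1; by_max <- unname(rows_max[li])
  crops <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    side <- max(bx_max[k] - bx_min[k], by_max[k] - by_min[k])
    cx <- (bx_min[k] + bx_max[k]) / 2; cy <- (by_min[k] + by_max[k]) / 2
    x0 <- round(cx - side / 2); y0 <- round(cy - side / 2)
    # clip to image, remember how much padding each border needs
    cx0 <- max(0, x0); cx1 <- min(w, x0 + side)
    cy0 <- max(0, y0); cy1 <- min(h, y0 + side)
    crop <- image[(cy0 + 1):cy1, (cx0 + 1):cx1, , drop = FALSE]
    crop <- pad_replicate(crop, top = cy0 - y0, bottom = (y0 + side) - cy1,
                          left = cx0 - x0, right = (x0 + side) - cx1)
    crops[[k]] <- resize_patch(crop, patch_size)
  }
  tibble::tibble(
    patch_id = sprintf("%s_seg%05d", parent_id, keep),
    parent_id = parent_id, segment_id = keep,
    x_min = bx_min, y_min = by_min, x_max = bx_max, y_max = by_max,
    area = areas[keep], patch = crops)
}

# Replicate-pad an [h, w, 3] array on each border.
pad_replicate <- function(x, top = 0, bottom = 0, left = 0, right = 0) {
  if (top <= 0 && bottom <= 0 && left <= 0 && right <= 0) return(x)
  h <- dim(x)[1]; w <- dim(x)[2]
  rows <- c(rep(1, max(0, top)), seq_len(h), rep(h, max(0, bottom)))
  cols <- c(rep(1, max(0, left)), seq_len(w), rep(w, max(0, right)))
  x[rows, cols, , drop = FALSE]
}

#' Sample scene ids without replacement
#'
#' Uniform random subsample of a survey's scenes, used to cap the memory
#' and compute cost of feature learning (a few hundred images suffice to
#' characterise the background).
#'
#' @param scene_ids character vector of available ids (or a survey
#'   manifest path whose ground truth lists them).
#' @param n sample size (`n <= length(scene_ids)`).
#' @param seed integer seed; the sample is reproducible.
#' @return character vector of `n` ids.
#' @export
sample_images <- function(scene_ids, n, seed = 1) {
  if (length(scene_ids) == 1 && file.exists(scene_ids) &&
      !dir.exists(scene_ids)) {
    manifest <- jsonlite::read_json(scene_ids)
    files <- vapply(manifest$files, `[[`, character(1), "file")
    scene_ids <- sub("\\.png$", "", basename(grep("\\.png$", files,
                                                  value = TRUE)))
  }
  scene_ids <- unique(as.character(scene_ids))
  n <- check_count(n, "n", min = 1)
  if (n > length(scene_ids)) {
    stop(sprintf("`n` (%d) exceeds the number of scenes (%d)", n,
                 length(scene_ids)), call. = FALSE)
  }
  with_seed(derive_seed(seed, "sample_images"),
            sample(scene_ids, n, replace = FALSE))
}
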