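#' COCO-style annotation JSON I/O
#'
#' Export/import of the interchange format used by detector training
#' pipelines: top-level `images` (id, file_name, width, height, plus
#' `scene_id` and acquisition `timestamp`), `annotations` (bbox as
#' `[x, y, width, height]` in pixels, category_id, area) and
#' `categories`. Boxes convert losslessly to and from this package's
#' half-open `x_min/y_min/x_max/y_max` convention.
#'
#' @param records annotation tibble (`scene_id`, box columns, `label`).
#' @param scene_meta tibble `scene_id, width, height, file_name` and
#'   optionally `timestamp`.
#' @param path output JSON path.
#' @param categories optional character vector fixing category order;
#'   defaults to the labels present.
#' @param distractors optional distractor tibble stored under a
#'   `distractors` key.
#' @return `write_coco()`: `path`, invisibly.
#' @export
write_coco <- function(records, scene_meta, path, categories = NULL,
                       distractors = NULL) {
  categories <- categories %||% sort(unique(records$label))
  cat_df <- data.frame(id = seq_along(categories), name = categories)
  images <- data.frame(
    id = seq_len(nrow(scene_meta)),
    scene_id = scene_meta$scene_id,
    file_name = scene_meta$file_name,
    width = scene_meta$width, height = scene_meta$height)
  if ("timestamp" %in% names(scene_meta)) {
    images$timestamp <- scene_meta$timestamp
  }
  ann <- NULL
  if (nrow(records)) {
    ann <- data.frame(
      id = seq_len(nrow(records)),
      image_id = images$id[match(records$scene_id, images$scene_id)],
      category_id = cat_df$id[match(records$label, cat_df$name)],
      area = (records$x_max - records$x_min) *
        (records$y_max - records$y_min))
    ann$bbox <- lapply(seq_len(nrow(records)), function(i) {
      c(records$x_min[i], records$y_min[i],
        records$x_max[i] - records$x_min[i],
        records$y_max[i] - records$y_min[i])
    })
  }
  payload <- list(images = images,
                  annotations = ann %||% list(),
                  categories = cat_df)
  if (!is.null(distractors)) payload$distractors <- distractors
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname write_coco
#' @return `read_coco()`: list of tibbles `images`, `annotations`
#'   (boxes back in `x_min/.../x_max` form), `categories`.
#' @export
read_coco <- function(path) {
  x <- jsonlite::read_json(path)
  images <- dplyr::bind_rows(lapply(x$images, tibble::as_tibble))
  cats <- dplyr::bind_rows(lapply(x$categories, tibble::as_tibble))
  ann <- NULL
  if (length(x$annotations)) {
    ann <- dplyr::bind_rows(lapply(x$annotations, function(a) {
      bb <- as.numeric(unlist(a$bbox))
      tibble::tibble(
        id = a$id,
        scene_id = images$scene_id[match(a$image_id, images$id)],
        label = cats$name[match(a$category_id, cats$id)],
        x_min = bb[1], y_min = bb[2],
        x_max = bb[1] + bb[3], y_max = bb[2] + bb[4])
    }))
  } else {
    ann <- tibble::tibble(id = integer(), scene_id = character(),
                          label = character(), x_min = numeric(),
                          y_min = numeric(), x_max = numeric(),
                          y_max = numeric())
  }
  list(images = images, annotations = ann, categories = cats)
}
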