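#' Default morphotype label set
#'
#' The ten megafauna morphotype classes used for semantic labelling of
#' weak annotations.
#'
#' @return character vector of unique morphotype names.
#' @export
default_label_set <- function() {
  c("anemone", "coral", "fish", "gastropod", "holothurian", "ophiuroid",
    "sea_urchin", "shrimp", "sponge", "xenophyophore")
}

UNLABELED <- "UNLABELED"

#' Retain patches above an anomaly-score percentile
#'
#' The simpler of the two false-positive removal strategies: keep patches
#' whose anomaly score is *strictly greater* than the linear-interpolation
#' percentile of the score vector. With all-equal scores nothing is
#' retained (strict inequality); the threshold has no principled value,
#' which is why the trainable classifier filter exists as well.
#'
#' @param results non-empty tibble with `patch_id` and `score`.
#' @param percentile percentile in (0, 100), default 75.
#' @return character vector of retained patch ids.
#' @export
threshold_filter <- function(results, percentile = 75) {
  if (!is.data.frame(results) || nrow(results) == 0) {
    stop("`results` must be a non-empty data frame", call. = FALSE)
  }
  check_number(percentile, "percentile", min = 0, max = 100,
               closed_min = FALSE, closed_max = FALSE)
  thr <- stats::quantile(results$score, percentile / 100, type = 7,
                         names = FALSE)
  results$patch_id[results$score > thr]
}

#' Train a binary patch classifier
#'
#' Learns to separate truly anomalous patches (fauna) from false-positive
#' anomalies (lasers, dark patches, odd nodules). A small dense network
#' over pooled patch pixels behind a generic patch-to-probability
#' interface: any model with a `predict(model, patches)` returning
#' probabilities can replace it.
#'
#' @param positives,negatives tibbles from [extract_patches()] or lists
#'   of patch arrays; at least 8 examples per class. Duplicated or
#'   contradictory examples are tolerated (labels are noisy by nature).
#' @param epochs,learning_rate,hidden_dim,input_side,seed training
#'   controls.
#' @return object of class `patch_classifier`.
#' @export
train_patch_classifier <- function(positives, negatives, epochs = 40,
                                   learning_rate = 5e-3, hidden_dim = 32,
                                   input_side = 16, seed = 1) {
  np <- if (is.data.frame(positives)) nrow(positives) else length(positives)
  nn <- if (is.data.frame(negatives)) nrow(negatives) else length(negatives)
  if (np < 8 || nn < 8) {
    stop("need at least 8 examples per class (got ", np, " positive, ",
         nn, " negative)", call. = FALSE)
  }
  Xp <- patches_to_matrix(positives, input_side)
  Xn <- patches_to_matrix(negatives, input_side)
  X <- rbind(Xp, Xn)
  y <- c(rep(1, nrow(Xp)), rep(0, nrow(Xn)))
  D <- ncol(X); H <- hidden_dim; n <- nrow(X)

  with_seed(derive_seed(seed, "patch_classifier"), {
    params <- list(W1 = nn_init_matrix(D, H), b1 = numeric(H),
                   W2 = nn_init_matrix(H, 1), b2 = numeric(1))
    state <- adam_init(params)
    batch_size <- min(64, n)
    for (epoch in seq_len(epochs)) {
      idx <- sample.int(n)
      for (s in seq(1, n, by = batch_size)) {
        batch <- idx[s:min(s + batch_size - 1, n)]
        xb <- X[batch, , drop = FALSE]; yb <- y[batch]
        nb <- nrow(xb)
        a1 <- sweep_add(xb %*% params$W1, params$b1); h1 <- relu(a1)
        p <- sigmoid(as.numeric(h1 %*% params$W2 + params$b2[1]))
        dlogit <- matrix((p - yb) / nb, ncol = 1)
        gW2 <- crossprod(h1, dlogit); gb2 <- sum(dlogit)
        da1 <- (dlogit %*% t(params$W2)) * (a1 > 0)
        gW1 <- crossprod(xb, da1); gb1 <- colSums(da1)
        upd <- adam_step(params, list(W1 = gW1, b1 = gb1, W2 = gW2,
                                      b2 = gb2), state, learning_rate)
        params <- upd$params; state <- upd$state
      }
    }
    structure(list(params = params, input_side = input_side),
              class = "patch_classifier")
  })
}

#' @rdname train_patch_classifier
#' @param object a `patch_classifier`.
#' @param patches patches to score.
#' @param ... unused.
#' @return `predict()`: numeric vector of fauna probabilities in `[0, 1]`.
#' @export
predict.patch_classifier <- function(object, patches, ...) {
  X <- patches_to_matrix(patches, object$input_side)
  h1 <- relu(sweep_add(X %*% object$params$W1, object$params$b1))
  as.numeric(sigmoid(h1 %*% object$params$W2 + object$params$b2[1]))
}

empty_annotations <- function() {
  tibble::tibble(scene_id = character(), x_min = numeric(),
                 y_min = numeric(), x_max = numeric(), y_max = numeric(),
                 label = character(), source = character(),
                 anomaly_score = numeric())
}

#' Turn classifier-approved patches into weak annotations
#'
#' One weak annotation per flagged patch whose fauna probability reaches
#' `prob_cutoff`; the bounding box is the superpixel's own box (never an
#' invented one) and the anomaly score is carried through. Labels start
#' as `UNLABELED` and `source` is `"weak"`.
#'
#' @param classifier a [train_patch_classifier()] model (or any object
#'   with a compatible `predict` method).
#' @param flagged_patches tibble of flagged patches: `patch_id`,
#'   `parent_id`, box columns, `patch` list-column, and optionally
#'   `score` (anomaly score).
#' @param prob_cutoff retain patches with probability >= cutoff.
#' @return annotation tibble (`scene_id, x_min, y_min, x_max, y_max,
#'   label, source, anomaly_score`, plus `patch_id, probability`).
#' @export
classifier_filter <- function(classifier, flagged_patches,
                              prob_cutoff = 0.5) {
  if (!is.data.frame(flagged_patches)) {
    stop("`flagged_patches` must be a data frame of patches", call. = FALSE)
  }
  if (nrow(flagged_patches) == 0) return(empty_annotations())
  prob <- predict(classifier, flagged_patches)
  keep <- prob >= prob_cutoff
  out <- tibble::tibble(
    scene_id = flagged_patches$parent_id[keep],
    x_min = flagged_patches$x_min[keep],
    y_min = flagged_patches$y_min[keep],
    x_max = flagged_patches$x_max[keep],
    y_max = flagged_patches$y_max[keep],
    label = UNLABELED, source = "weak",
    anomaly_score = if ("score" %in% names(flagged_patches))
      flagged_patches$score[keep] else NA_real_,
    patch_id = flagged_patches$patch_id[keep],
    probability = prob[keep])
  out
}

#' Order patches for manual review
#'
#' Sorting by descending anomaly score floats most truly anomalous
#' superpixels to the top, so a reviewer can pick classifier training
#' examples quickly.
#'
#' @param results non-empty tibble with `patch_id` and `score`.
#' @return character vector: all patch ids, descending score, ties broken
#'   by id.
#' @export
review_queue <- function(results) {
  if (!is.data.frame(results) || nrow(results) == 0) {
    stop("`results` must be a non-empty data frame", call. = FALSE)
  }
  results$patch_id[order(-results$score, results$patch_id)]
}

#' Assign morphotype labels to annotations
#'
#' Attaches labels from a lookup of record ids to morphotype names; every
#' label must come from the configured label set. Records that stay
#' unlabeled can be kept or dropped.
#'
#' @param records annotation tibble with a `patch_id` (or `record_id`)
#'   column.
#' @param labels named character vector or two-column data frame mapping
#'   record id to morphotype.
#' @param label_set allowed morphotype names.
#' @param drop_unlabeled drop records that end up `UNLABELED`?
#' @return labelled annotation tibble (`source` is preserved).
#' @export
assign_labels <- function(records, labels, label_set = default_label_set(),
                          drop_unlabeled = FALSE) {
  if (is.data.frame(labels)) {
    labels <- stats::setNames(as.character(labels[[2]]),
                              as.character(labels[[1]]))
  }
  bad <- setdiff(unique(labels), label_set)
  if (length(bad)) {
    stop("unknown morphotype label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(label_set, collapse = ", "), call. = FALSE)
  }
  id_col <- if ("patch_id" %in% names(records)) "patch_id" else "record_id"
  hit <- match(records[[id_col]], names(labels))
  records$label <- ifelse(is.na(hit), records$label, labels[hit])
  if (drop_unlabeled) records <- records[records$label != UNLABELED, ]
  tibble::as_tibble(records)
}

#' Add a manually drawn annotation
#'
#' Appends an expert-drawn box (fauna visible in the image but missing
#' from the weak set) with `source = "manual"`.
#'
#' @param records annotation tibble.
#' @param scene_id parent scene.
#' @param box named list/vector with `x_min, y_min, x_max, y_max`.
#' @param label morphotype name from `label_set`.
#' @param label_set allowed names.
#' @return extended annotation tibble.
#' @export
add_manual_annotation <- function(records, scene_id, box, label,
                                  label_set = default_label_set()) {
  if (!label %in% label_set) {
    stop("unknown morphotype label: ", label, "; allowed: ",
         paste(label_set, collapse = ", "), call. = FALSE)
  }
  box <- as.list(box)
  new <- tibble::tibble(scene_id = scene_id, x_min = box$x_min,
                        y_min = box$y_min, x_max = box$x_max,
                        y_max = box$y_max, label = label,
                        source = "manual", anomaly_score = NA_real_)
  dplyr::bind_rows(tibble::as_tibble(records), new)
}

#' Split annotations into training and validation sets
#'
#' Scene-grouped split: whole scenes are assigned to one side so near-
#' duplicate superpixels of one image can never leak across the split
#' (stricter than a per-record split). Scenes are shuffled under `seed`
#' and accumulated into the training side while it holds at most
#' `floor(train_fraction * n)` records; with one record per scene this
#' reproduces exact floor arithmetic.
#'
#' @param records annotation tibble (>= 2 records over >= 2 scenes).
#' @param train_fraction fraction of records targeted for training.
#' @param seed integer seed.
#' @return list with tibbles `train` and `validation`; disjoint and
#'   exhaustive.
#' @export
split_annotations <- function(records, train_fraction = 0.9, seed = 1) {
  if (!is.data.frame(records) || nrow(records) < 2) {
    stop("`records` needs at least 2 annotations", call. = FALSE)
  }
  check_number(train_fraction, "train_fraction", min = 0, max = 1,
               closed_min = FALSE, closed_max = FALSE)
  scenes <- unique(records$scene_id)
  if (length(scenes) < 2) {
    stop("need annotations from at least 2 scenes to split", call. = FALSE)
  }
  target <- floor(train_fraction * nrow(records))
  with_seed(derive_seed(seed, "split_annotations"), {
    scenes <- sample(scenes)
    counts <- table(records$scene_id)[scenes]
    train_scenes <- scenes[cumsum(counts) <= target]
    if (!length(train_scenes)) train_scenes <- scenes[1]
    if (length(train_scenes) == length(scenes)) {
      train_scenes <- train_scenes[-length(train_scenes)]
    }
    list(train = tibble::as_tibble(
           records[records$scene_id %in% train_scenes, ]),
         validation = tibble::as_tibble(
           records[!records$scene_id %in% train_scenes, ]))
  })
}

#' Annotation CSV I/O
#'
#' Writes/reads the flat annotation table
#' (`scene_id, x_min, y_min, x_max, y_max, label, source, anomaly_score`).
#'
#' @param records annotation tibble.
#' @param path CSV path.
#' @return `write_annotations_csv()` returns `path` invisibly;
#'   `read_annotations_csv()` returns the tibble.
#' @export
write_annotations_csv <- function(records, path) {
  cols <- c("scene_id", "x_min", "y_min", "x_max", "y_max", "label",
            "source", "anomaly_score")
  present <- intersect(cols, names(records))
  utils::write.csv(records[, present, drop = FALSE], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations_csv
#' @export
read_annotations_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
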