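# Detector-agnostic COCO-style evaluation: greedy NMS, detection-truth
# matching with ignore semantics, 101-point interpolated AP, size-stratified
# AP/AR, confusion matrix, and a configurable noisy oracle detector.

COCO_IOU_THRESHOLDS <- seq(0.5, 0.95, by = 0.05)
AREA_SMALL_MAX <- 32^2
AREA_LARGE_MIN <- 96^2

#' Greedy non-maximum suppression
#'
#' Iterates detections of one class within one scene by descending
#' confidence and drops any box whose IoU with an already retained box of
#' the same class exceeds `iou_threshold`. Confidence ties are broken by
#' input order (earliest row wins).
#'
#' @param detections tibble with `scene_id`, box columns, `label`,
#'   `confidence`.
#' @param iou_threshold suppression threshold, default 0.5.
#' @return the retained detections (original row order preserved).
#' @export
greedy_nms <- function(detections, iou_threshold = 0.5) {
  if (!nrow(detections)) return(tibble::as_tibble(detections))
  if (!"confidence" %in% names(detections)) {
    stop("`detections` must carry a `confidence` column", call. = FALSE)
  }
  detections <- tibble::as_tibble(detections)
  keep_idx <- integer(0)
  groups <- split(seq_len(nrow(detections)),
                  paste(detections$scene_id, detections$label, sep = "\r"))
  for (g in groups) {
    ord <- g[order(-detections$confidence[g], g)]
    kept <- integer(0)
    for (i in ord) {
      if (!length(kept)) {
        kept <- i
      } else {
        ious <- iou(detections[rep(i, length(kept)), ],
                    detections[kept, ])
        if (all(ious <= iou_threshold)) kept <- c(kept, i)
      }
    }
    keep_idx <- c(keep_idx, kept)
  }
  detections[sort(keep_idx), ]
}

# Greedy confidence-ordered matching within one scene (one class if the
# caller pre-filtered). Truths may carry a logical `ignore` column; a
# detection prefers the best non-ignored truth with IoU >= threshold and
# falls back to an ignored one (the detection is then ignored, not a FP).
match_one_scene <- function(dets, truths, iou_threshold) {
  nd <- nrow(dets); nt <- nrow(truths)
  det_tp <- logical(nd); det_ign <- logical(nd)
  det_match <- rep(NA_integer_, nd)
  truth_matched <- logical(nt)
  ignore <- if ("ignore" %in% names(truths)) truths$ignore else
    rep(FALSE, nt)
  if (nd && nt) M <- iou_matrix(dets, truths)
  for (i in seq_len(nd)) {
    if (!nt) break
    best <- 0L; best_iou <- iou_threshold - 1e-12; best_ign <- TRUE
    for (j in seq_len(nt)) {
      if (truth_matched[j] && !ignore[j]) next
      if (M[i, j] < iou_threshold) next
      # prefer any non-ignored truth over any ignored one
      if (best && !best_ign && ignore[j]) next
      if (best && best_ign == ignore[j] && M[i, j] <= best_iou) next
      best <- j; best_iou <- M[i, j]; best_ign <- ignore[j]
    }
    if (best) {
      det_match[i] <- best
      if (ignore[best]) {
        det_ign[i] <- TRUE
      } else {
        det_tp[i] <- TRUE
        truth_matched[best] <- TRUE
      }
    }
  }
  list(det_tp = det_tp, det_ignored = det_ign, det_match = det_match,
       truth_matched = truth_matched)
}

#' Match detections to ground truth
#'
#' COCO-convention greedy matching: within each scene (and class, when
#' `by_class`), detections sorted by descending confidence each claim the
#' unmatched truth with the highest IoU at or above `iou_threshold`; at
#' most `max_dets` detections per scene (and class) are considered.
#' Surplus detections of an already matched truth are false positives.
#'
#' @param detections tibble `scene_id`, boxes, `label`, `confidence`.
#' @param truths tibble `scene_id`, boxes, `label` (optional logical
#'   `ignore`).
#' @param iou_threshold match threshold.
#' @param max_dets per-scene cap on detections considered.
#' @param by_class match only within identical labels?
#' @return list: `detections` (with `is_tp`, `ignored`, `rank`),
#'   `truths` (with `matched`), and counts `tp`, `fp`, `fn`.
#' @export
match_detections <- function(detections, truths, iou_threshold = 0.5,
                             max_dets = 100, by_class = TRUE) {
  detections <- tibble::as_tibble(detections)
  truths <- tibble::as_tibble(truths)
  nd <- nrow(detections)
  detections$is_tp <- logical(nd)
  detections$ignored <- logical(nd)
  detections$considered <- logical(nd)
  truths$matched <- logical(nrow(truths))
  key <- function(df) {
    if (by_class) paste(df$scene_id, df$label, sep = "\r") else df$scene_id
  }
  det_groups <- split(seq_len(nd), key(detections))
  truth_groups <- split(seq_len(nrow(truths)), key(truths))
  all_keys <- union(names(det_groups), names(truth_groups))
  for (k in all_keys) {
    di <- det_groups[[k]] %||% integer(0)
    ti <- truth_groups[[k]] %||% integer(0)
    ord <- di[order(-detections$confidence[di], di)]
    ord <- ord[seq_len(min(length(ord), max_dets))]
    res <- match_one_scene(detections[ord, ], truths[ti, ], iou_threshold)
    detections$is_tp[ord] <- res$det_tp
    detections$ignored[ord] <- res$det_ignored
    detections$considered[ord] <- TRUE
    truths$matched[ti] <- res$truth_matched
  }
  ignore_t <- if ("ignore" %in% names(truths)) truths$ignore else
    rep(FALSE, nrow(truths))
  list(detections = detections, truths = truths,
       tp = sum(detections$is_tp),
       fp = sum(detections$considered & !detections$is_tp &
                  !detections$ignored),
       fn = sum(!truths$matched & !ignore_t))
}

# Per-class AP (101-point interpolation) and recall at one IoU threshold,
# optionally restricted to truths in an area stratum [lo, hi).
pr_one_class <- function(detections, truths, class, iou_threshold,
                         area_range = NULL, max_dets = 100) {
  truths_c <- truths[truths$label == class, , drop = FALSE]
  dets_c <- detections[detections$label == class, , drop = FALSE]
  if (!is.null(area_range)) {
    a <- box_area(truths_c)
    truths_c$ignore <- a < area_range[1] | a >= area_range[2]
  } else {
    truths_c$ignore <- FALSE
  }
  npos <- sum(!truths_c$ignore)
  if (npos == 0) return(list(ap = NA_real_, recall = NA_real_))
  m <- match_detections(dets_c, truths_c, iou_threshold,
                        max_dets = max_dets, by_class = TRUE)
  d <- m$detections[m$detections$considered & !m$detections$ignored, ,
                    drop = FALSE]
  d <- d[order(-d$confidence), , drop = FALSE]
  tp <- cumsum(d$is_tp)
  fp <- cumsum(!d$is_tp)
  rec <- if (nrow(d)) tp / npos else numeric(0)
  prec <- if (nrow(d)) tp / (tp + fp) else numeric(0)
  # precision envelope, then 101-point sampling
  ap <- 0
  if (length(rec)) {
    for (i in rev(seq_along(prec))[-1]) {
      prec[i] <- max(prec[i], prec[i + 1])
    }
    recall_pts <- seq(0, 1, by = 0.01)
    idx <- findInterval(recall_pts, rec, left.open = TRUE) + 1
    p_at <- ifelse(idx <= length(prec), prec[idx], 0)
    ap <- mean(p_at)
  }
  list(ap = ap, recall = if (length(rec)) max(rec) else 0)
}

mean_defined <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) NA_real_ else mean(x)
}

#' COCO-style evaluation summary
#'
#' Computes the standard detection metric family: `AP50` (mean average
#' precision at IoU 0.5), `AP50_95` (averaged over IoU 0.50:0.95 in steps
#' of 0.05), size-stratified `AP_small/medium/large` (truth box area
#' `< 32^2`, `[32^2, 96^2)`, `>= 96^2` pixels), `AR_1/10/100` (average
#' recall with at most 1/10/100 detections per scene) and size-stratified
#' AR. All values are percentages; strata with no ground truth are `NA`
#' (skipped by the means, never silently counted as 0).
#'
#' @param detections tibble `scene_id`, boxes, `label`, `confidence`.
#' @param truths tibble `scene_id`, boxes, `label`.
#' @param label_set classes to evaluate; defaults to classes present in
#'   the truths.
#' @return object of class `detection_eval`: list with `metrics` (named
#'   numeric vector), `per_class` (tibble of per-class AP50 / AP50_95),
#'   and the inputs' class list.
#' @export
evaluate_detections <- function(detections, truths,
                                label_set = NULL) {
  detections <- tibble::as_tibble(detections)
  truths <- tibble::as_tibble(truths)
  label_set <- label_set %||% sort(unique(truths$label))
  strata <- list(all = NULL, small = c(0, AREA_SMALL_MAX),
                 medium = c(AREA_SMALL_MAX, AREA_LARGE_MIN),
                 large = c(AREA_LARGE_MIN, Inf))

  ap_tab <- array(NA_real_,
                  dim = c(length(label_set), length(COCO_IOU_THRESHOLDS),
                          length(strata)),
                  dimnames = list(label_set, NULL, names(strata)))
  rec_tab <- ap_tab
  for (ci in seq_along(label_set)) {
    for (ti in seq_along(COCO_IOU_THRESHOLDS)) {
      for (si in seq_along(strata)) {
        r <- pr_one_class(detections, truths, label_set[ci],
                          COCO_IOU_THRESHOLDS[ti], strata[[si]],
                          max_dets = 100)
        ap_tab[ci, ti, si] <- r$ap
        rec_tab[ci, ti, si] <- r$recall
      }
    }
  }
  ar_k <- vapply(c(1, 10, 100), function(k) {
    vals <- vapply(label_set, function(cl) {
      mean_defined(vapply(COCO_IOU_THRESHOLDS, function(t) {
        pr_one_class(detections, truths, cl, t, NULL, max_dets = k)$recall
      }, numeric(1)))
    }, numeric(1))
    mean_defined(vals)
  }, numeric(1))

  per_class <- tibble::tibble(
    label = label_set,
    ap50 = 100 * ap_tab[, 1, "all"],
    ap50_95 = 100 * apply(ap_tab[, , "all", drop = FALSE], 1,
                          mean_defined))
  metrics <- c(
    AP50 = 100 * mean_defined(ap_tab[, 1, "all"]),
    AP50_95 = 100 * mean_defined(apply(
      ap_tab[, , "all", drop = FALSE], 1, mean_defined)),
    AP_small = 100 * mean_defined(ap_tab[, , "small"]),
    AP_medium = 100 * mean_defined(ap_tab[, , "medium"]),
    AP_large = 100 * mean_defined(ap_tab[, , "large"]),
    AR_1 = 100 * ar_k[1], AR_10 = 100 * ar_k[2], AR_100 = 100 * ar_k[3],
    AR_small = 100 * mean_defined(rec_tab[, , "small"]),
    AR_medium = 100 * mean_defined(rec_tab[, , "medium"]),
    AR_large = 100 * mean_defined(rec_tab[, , "large"]))
  structure(list(metrics = metrics, per_class = per_class,
                 label_set = label_set),
            class = "detection_eval")
}

#' @export
print.detection_eval <- function(x, ...) {
  cat("COCO-style detection evaluation (percent; NA = empty stratum)\n")
  print(round(x$metrics, 1))
  invisible(x)
}

#' Detection-truth confusion matrix
#'
#' Matches detections to truths class-agnostically (IoU only), then
#' compares labels. Rows are true classes, columns predicted classes; the
#' extra `background` row collects false positives (unmatched detections)
#' and the `background` column false negatives (unmatched truths).
#'
#' @param detections,truths tibbles as in [evaluate_detections()].
#' @param iou_threshold class-agnostic match threshold.
#' @param label_set classes; defaults to union of labels present.
#' @return integer matrix `(classes + background) x (classes +
#'   background)`.
#' @export
confusion_matrix <- function(detections, truths, iou_threshold = 0.5,
                             label_set = NULL) {
  label_set <- label_set %||%
    sort(union(unique(truths$label), unique(detections$label)))
  dims <- c(label_set, "background")
  cm <- matrix(0L, length(dims), length(dims),
               dimnames = list(truth = dims, predicted = dims))
  m <- match_detections(detections, truths, iou_threshold,
                        max_dets = Inf, by_class = FALSE)
  d <- m$detections
  t <- m$truths
  for (i in seq_len(nrow(d))) {
    if (!d$considered[i]) next
    if (d$is_tp[i]) next # counted from the truth side below
    cm["background", d$label[i]] <- cm["background", d$label[i]] + 1L
  }
  # matched pairs: recover via re-match to get pairing
  pairs <- match_pairs(detections, truths, iou_threshold)
  for (p in seq_len(nrow(pairs))) {
    cm[pairs$truth_label[p], pairs$det_label[p]] <-
      cm[pairs$truth_label[p], pairs$det_label[p]] + 1L
  }
  unmatched_truth <- t$label[!t$matched]
  for (lbl in unmatched_truth) {
    cm[lbl, "background"] <- cm[lbl, "background"] + 1L
  }
  cm
}

# class-agnostic matched (truth_label, det_label) pairs per scene
match_pairs <- function(detections, truths, iou_threshold) {
  out <- list()
  for (sc in unique(truths$scene_id)) {
    di <- which(detections$scene_id == sc)
    ti <- which(truths$scene_id == sc)
    if (!length(di) || !length(ti)) next
    ord <- di[order(-detections$confidence[di], di)]
    res <- match_one_scene(detections[ord, ], truths[ti, ], iou_threshold)
    hit <- which(!is.na(res$det_match) & res$det_tp)
    if (length(hit)) {
      out[[length(out) + 1]] <- tibble::tibble(
        det_label = detections$label[ord[hit]],
        truth_label = truths$label[ti[res$det_match[hit]]])
    }
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(det_label = character(), truth_label = character())
}

#' Noisy oracle detector
#'
#' A stand-in for a trained object detector, so evaluation and ecology
#' can be exercised end-to-end with controllable error modes: each truth
#' is dropped with probability `miss_rate`, surviving boxes get uniform
#' corner jitter of up to `jitter_px`, labels are optionally resampled
#' from a row-stochastic confusion matrix, and `Poisson(fp_rate)` random
#' false boxes are added per scene. True boxes receive higher confidence
#' than false ones; with every noise source at zero the output is exactly
#' the ground truth at confidence 1.
#'
#' @param truths tibble `scene_id`, boxes, `label`.
#' @param miss_rate,fp_rate,jitter_px noise controls (`rates in [0, 1]`,
#'   `fp_rate >= 0` per image).
#' @param label_confusion optional row-stochastic matrix with
#'   row/col names = labels.
#' @param seed integer seed.
#' @param image_size `(width, height)` for jitter clipping and false-box
#'   placement.
#' @param scene_ids scenes to emit false positives for; defaults to the
#'   scenes present in `truths`.
#' @return detection tibble `scene_id, x_min, y_min, x_max, y_max, label,
#'   confidence`.
#' @export
oracle_detector <- function(truths, miss_rate = 0, fp_rate = 0,
                            jitter_px = 0, label_confusion = NULL,
                            seed = 1, image_size = c(256, 256),
                            scene_ids = NULL) {
  check_number(miss_rate, "miss_rate", min = 0, max = 1)
  check_number(fp_rate, "fp_rate", min = 0)
  check_number(jitter_px, "jitter_px", min = 0)
  truths <- tibble::as_tibble(truths)
  scene_ids <- scene_ids %||% unique(truths$scene_id)
  w <- image_size[1]; h <- image_size[2]
  noiseless <- miss_rate == 0 && fp_rate == 0 && jitter_px == 0 &&
    is.null(label_confusion)
  labels <- sort(unique(truths$label))

  with_seed(derive_seed(seed, "oracle_detector"), {
    keep <- stats::runif(nrow(truths)) >= miss_rate
    d <- truths[keep, , drop = FALSE]
    n <- nrow(d)
    if (jitter_px > 0 && n) {
      jit <- matrix(stats::runif(4 * n, -jitter_px, jitter_px), n, 4)
      d$x_min <- pmin(pmax(d$x_min + jit[, 1], 0), w - 1)
      d$y_min <- pmin(pmax(d$y_min + jit[, 2], 0), h - 1)
      d$x_max <- pmax(pmin(d$x_max + jit[, 3], w), d$x_min + 1)
      d$y_max <- pmax(pmin(d$y_max + jit[, 4], h), d$y_min + 1)
    }
    if (!is.null(label_confusion) && n) {
      d$label <- vapply(d$label, function(l) {
        p <- label_confusion[l, ]
        sample(colnames(label_confusion), 1, prob = p)
      }, character(1))
    }
    d <- d[, c("scene_id", "x_min", "y_min", "x_max", "y_max", "label")]
    d$confidence <- if (noiseless) 1.0 else stats::runif(n, 0.7, 1.0)

    fps <- list()
    if (fp_rate > 0) {
      for (sc in scene_ids) {
        nfp <- stats::rpois(1, fp_rate)
        for (i in seq_len(nfp)) {
          bw <- stats::runif(1, 8, 40); bh <- stats::runif(1, 8, 40)
          x0 <- stats::runif(1, 0, w - bw); y0 <- stats::runif(1, 0, h - bh)
          fps[[length(fps) + 1]] <- tibble::tibble(
            scene_id = sc, x_min = x0, y_min = y0, x_max = x0 + bw,
            y_max = y0 + bh,
            label = sample(labels, 1),
            confidence = stats::runif(1, 0.3, 0.7))
        }
      }
    }
    dplyr::bind_rows(c(list(d), fps))
  })
}
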