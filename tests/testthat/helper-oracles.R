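# Independent brute-force oracles for the evaluation suite.

# Anomaly scores from scikit-learn's IsolationForest (independent
# reference implementation), run through the python interpreter on PATH.
# Returns scores oriented so that larger = more anomalous.
sklearn_iforest_scores <- function(x, n_trees = 100, psi = 256, seed = 0) {
  infile <- tempfile(fileext = ".csv")
  outfile <- tempfile(fileext = ".csv")
  utils::write.table(x, infile, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  code <- paste(
    "import sys, numpy as np",
    "from sklearn.ensemble import IsolationForest",
    "x = np.loadtxt(sys.argv[1], delimiter=',')",
    sprintf(paste0("m = IsolationForest(n_estimators=%d, max_samples=%d,",
                   " random_state=%d).fit(x)"), n_trees, psi, seed),
    "np.savetxt(sys.argv[2], -m.score_samples(x))",
    sep = "; ")
  status <- system2("python", c("-c", shQuote(code), infile, outfile))
  stopifnot(status == 0)
  as.numeric(readLines(outfile))
}

# O(n^2) reference NMS: repeatedly take the highest-confidence remaining
# box (earliest index on ties) and delete same-class boxes in the same
# scene with IoU above the threshold.
brute_nms <- function(detections, iou_threshold = 0.5) {
  remaining <- seq_len(nrow(detections))
  kept <- integer(0)
  while (length(remaining)) {
    conf <- detections$confidence[remaining]
    i <- remaining[which.max(conf)] # which.max: earliest index on ties
    kept <- c(kept, i)
    remaining <- setdiff(remaining, i)
    if (length(remaining)) {
      same <- detections$scene_id[remaining] == detections$scene_id[i] &
        detections$label[remaining] == detections$label[i]
      ious <- iou(detections[remaining, ], detections[rep(i, length(remaining)), ])
      remaining <- remaining[!(same & ious > iou_threshold)]
    }
  }
  detections[sort(kept), ]
}

# pixel-grid IoU oracle for integer boxes: count covered unit cells
grid_iou <- function(a, b, extent = 200) {
  cover <- function(box) {
    m <- matrix(FALSE, extent, extent)
    if (box$x_max > box$x_min && box$y_max > box$y_min) {
      m[(box$y_min + 1):box$y_max, (box$x_min + 1):box$x_max] <- TRUE
    }
    m
  }
  ma <- cover(a); mb <- cover(b)
  inter <- sum(ma & mb); un <- sum(ma | mb)
  if (un == 0) 0 else inter / un
}

# Exhaustive PR construction for one class at one IoU threshold: rebuild
# the matching from scratch at every confidence cutoff, then integrate
# max-precision over the 101 recall points. Independent of the package's
# cumulative-flag implementation.
brute_ap <- function(detections, truths, class, iou_threshold) {
  truths_c <- truths[truths$label == class, , drop = FALSE]
  dets_c <- detections[detections$label == class, , drop = FALSE]
  npos <- nrow(truths_c)
  if (npos == 0) return(NA_real_)
  match_at_cutoff <- function(cut) {
    d <- dets_c[dets_c$confidence >= cut, , drop = FALSE]
    d <- d[order(-d$confidence), , drop = FALSE]
    tp <- 0
    used <- rep(FALSE, nrow(truths_c))
    for (i in seq_len(nrow(d))) {
      cand <- which(!used & truths_c$scene_id == d$scene_id[i])
      if (!length(cand)) next
      ious <- iou(d[rep(i, length(cand)), ], truths_c[cand, ])
      j <- which.max(ious)
      if (ious[j] >= iou_threshold) {
        tp <- tp + 1
        used[cand[j]] <- TRUE
      }
    }
    c(tp = tp, n = nrow(d))
  }
  cuts <- sort(unique(dets_c$confidence))
  pr <- t(vapply(cuts, match_at_cutoff, numeric(2)))
  rec <- pr[, "tp"] / npos
  prec <- ifelse(pr[, "n"] > 0, pr[, "tp"] / pr[, "n"], 0)
  ap_points <- vapply(seq(0, 1, by = 0.01), function(r) {
    ok <- rec >= r
    if (!any(ok)) 0 else max(prec[ok])
  }, numeric(1))
  mean(ap_points)
}
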