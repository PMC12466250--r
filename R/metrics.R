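# Segmentation, detection and temporal evaluation metrics: Dice/IoU,
# confusion-count scores, motion-compensated temporal consistency, and
# partition concordance via optimal cluster matching.

#' @noRd
.same_shape <- function(a, b) {
  identical(dim(a), dim(b)) && length(a) == length(b)
}

#' @noRd
.check_binary <- function(m, what) {
  if (is.logical(m)) return(m)
  if (!all(m %in% c(0, 1))) stop(sprintf("%s must be binary", what))
  m == 1
}

#' Dice coefficient and intersection-over-union of binary masks
#'
#' `Dice = 2|A & B| / (|A| + |B|)`; `IoU = |A & B| / (|A | B|)`. When both
#' masks are empty both scores are 1 by convention. The identity
#' `IoU = Dice / (2 - Dice)` holds exactly.
#'
#' @param pred,truth Equal-shape binary (logical or 0/1) masks.
#' @return A scalar in `[0, 1]`.
#' @export
dice <- function(pred, truth) {
  pred <- .check_binary(pred, "pred"); truth <- .check_binary(truth, "truth")
  if (!.same_shape(pred, truth)) stop("masks must have the same shape")
  s <- sum(pred) + sum(truth)
  if (s == 0) return(1)
  2 * sum(pred & truth) / s
}

#' @rdname dice
#' @export
iou <- function(pred, truth) {
  pred <- .check_binary(pred, "pred"); truth <- .check_binary(truth, "truth")
  if (!.same_shape(pred, truth)) stop("masks must have the same shape")
  u <- sum(pred | truth)
  if (u == 0) return(1)
  sum(pred & truth) / u
}

#' Confusion counts
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(v < 0)) stop("confusion counts must be non-negative")
  structure(as.list(v), class = "confusion_counts")
}

#' Detection scores from confusion counts
#'
#' Sensitivity and accuracy as percentages, precision and F1 as
#' fractions. A zero denominator yields `NA` with a warning.
#'
#' @param counts A [confusion_counts()].
#' @return `list(sensitivity =, precision =, f1 =, accuracy =)`.
#' @export
detection_scores <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator)", what))
      return(NA_real_)
    }
    num / den
  }
  with(counts, {
    sens <- safe(tp, tp + fn, "sensitivity")
    prec <- safe(tp, tp + fp, "precision")
    f1 <- if (is.na(sens) || is.na(prec) || (prec + sens) == 0) {
      warning("f1 undefined")
      NA_real_
    } else 2 * prec * sens / (prec + sens)
    acc <- safe(tp + tn, tp + fp + fn + tn, "accuracy")
    list(sensitivity = 100 * sens, precision = prec, f1 = f1,
         accuracy = 100 * acc)
  })
}

#' Motion-compensated temporal segmentation consistency
#'
#' For every consecutive frame pair, warps `mask[t]` onto the grid of
#' frame `t + 1` along the flow (bilinear interpolation, threshold 0.5, or
#' nearest-neighbour with `method = "nearest"`) and computes the Dice
#' overlap with `mask[t + 1]`; returns the mean over pairs. Temporally
#' coherent segmentations score near 1.
#'
#' @param masks `T x H x W` binary array.
#' @param flow A [flow_field()] with `T - 1` pairs on the same grid.
#' @param method Mask interpolation, `"bilinear"` (default) or
#'   `"nearest"`.
#' @return A scalar in `[0, 1]`.
#' @export
temporal_consistency <- function(masks, flow,
                                 method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(is.array(masks), length(dim(masks)) == 3,
            inherits(flow, "flow_field"))
  d <- dim(masks)
  if (d[1] < 2) stop("need at least 2 frames")
  stopifnot(all(dim(flow$vectors)[1:3] == c(d[1] - 1, d[2], d[3])))
  if (sum(masks) == 0) {
    warning("all masks empty; temporal consistency is 1 by convention")
    return(1)
  }
  scores <- numeric(d[1] - 1)
  rows <- matrix(seq_len(d[2]), d[2], d[3])
  cols <- matrix(seq_len(d[3]), d[2], d[3], byrow = TRUE)
  for (t in seq_len(d[1] - 1)) {
    m <- masks[t, , ] * 1
    sr <- as.vector(rows + flow$vectors[t, , , 1])
    sc <- as.vector(cols + flow$vectors[t, , , 2])
    wm <- if (method == "bilinear") {
      matrix(.bilinear_sample(m, sr, sc), d[2], d[3]) >= 0.5
    } else {
      matrix(.nearest_sample(m, sr, sc), d[2], d[3]) >= 0.5
    }
    scores[t] <- dice(wm, masks[t + 1, , ] == 1)
  }
  mean(scores)
}

#' Concordance between two partitions
#'
#' Optimally matches the clusters of two label maps one-to-one
#' (maximum-weight assignment on the contingency table) and returns the
#' matched overlap divided by the number of shared non-noise pixels. The
#' score is invariant to cluster relabelling; identical partitions score
#' 1.
#'
#' @param labels_a,labels_b Equal-shape integer label maps; negative
#'   labels and `NA` are treated as noise and excluded.
#' @return A scalar in `[0, 1]`.
#' @export
partition_concordance <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label maps must have the same support")
  a <- as.vector(labels_a); b <- as.vector(labels_b)
  keep <- !is.na(a) & !is.na(b) & a >= 0 & b >= 0
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0) stop("no shared non-noise pixels")
  tab <- table(a, b)
  ka <- nrow(tab); kb <- ncol(tab)
  # maximum-weight bipartite matching on the contingency table
  g <- igraph::make_empty_graph(ka + kb, directed = FALSE)
  edges <- as.vector(t(cbind(rep(seq_len(ka), each = kb),
                             ka + rep(seq_len(kb), times = ka))))
  g <- igraph::add_edges(g, edges)
  igraph::V(g)$type <- c(rep(FALSE, ka), rep(TRUE, kb))
  wts <- as.vector(t(tab))
  m <- igraph::max_bipartite_match(g, weights = wts + 1e-9)
  matched <- 0
  for (i in seq_len(ka)) {
    j <- m$matching[i]
    if (!is.na(j)) matched <- matched + tab[i, j - ka]
  }
  matched / length(a)
}
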