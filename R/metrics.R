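#' Pairwise IoU matrix between ground-truth and predicted instances
#'
#' IoU(g, s) = |g intersect s| / |g union s| for every overlapping pair of
#' a ground-truth and a predicted label; non-overlapping pairs are 0.
#'
#' @param gt,pred Integer label arrays of identical shape.
#' @return Numeric matrix (GT labels x predicted labels) with dimnames the
#'   label values. 0 x 0 when either volume is empty.
#' @export
instance_iou_matrix <- function(gt, pred) {
  if (!identical(dim(gt), dim(pred)))
    stop("shape mismatch between volumes", call. = FALSE)
  glab <- sort(unique(as.vector(gt[gt != 0L])))
  plab <- sort(unique(as.vector(pred[pred != 0L])))
  iou <- matrix(0, length(glab), length(plab),
                dimnames = list(glab, plab))
  if (length(glab) == 0L || length(plab) == 0L) return(iou)
  gsz <- tabulate(gt[gt != 0L], nbins = max(glab))
  psz <- tabulate(pred[pred != 0L], nbins = max(plab))
  both <- gt != 0L & pred != 0L
  if (any(both)) {
    tab <- table(g = gt[both], p = pred[both])
    for (i in seq_len(nrow(tab))) {
      gl <- as.integer(rownames(tab)[i])
      for (j in seq_len(ncol(tab))) {
        inter <- tab[i, j]
        if (inter == 0) next
        pl <- as.integer(colnames(tab)[j])
        iou[as.character(gl), as.character(pl)] <-
          inter / (gsz[gl] + psz[pl] - inter)
      }
    }
  }
  iou
}

#' One-to-one instance matching at an IoU threshold
#'
#' Greedy matching in descending IoU order among pairs with IoU >= t; each
#' ground-truth and each predicted instance is used at most once.
#'
#' @param iou IoU matrix from [instance_iou_matrix()].
#' @param t Threshold in (0, 1).
#' @param method `"greedy"` (default) or `"optimal"` (exhaustive best
#'   one-to-one assignment maximizing the number of matches, then total
#'   IoU; intended for small fixtures).
#' @return List with `threshold`, `pairs` (data frame gt/pred/iou),
#'   and counts `tp`, `fp`, `fn`.
#' @export
match_at_threshold <- function(iou, t, method = c("greedy", "optimal")) {
  method <- match.arg(method)
  n_gt <- nrow(iou); n_pred <- ncol(iou)
  cand <- which(iou >= t, arr.ind = TRUE)
  pairs <- data.frame(gt = integer(0), pred = integer(0), iou = numeric(0))
  if (nrow(cand) > 0) {
    if (method == "greedy") {
      ord <- order(iou[cand], -cand[, 1], -cand[, 2], decreasing = TRUE)
      cand <- cand[ord, , drop = FALSE]
      used_g <- logical(n_gt); used_p <- logical(n_pred)
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (used_g[i] || used_p[j]) next
        used_g[i] <- TRUE; used_p[j] <- TRUE
        pairs <- rbind(pairs, data.frame(
          gt = as.integer(rownames(iou)[i]),
          pred = as.integer(colnames(iou)[j]), iou = iou[i, j]))
      }
    } else {
      pairs <- .optimal_assignment(iou, t)
    }
  }
  tp <- nrow(pairs)
  list(threshold = t, pairs = pairs,
       tp = tp, fp = n_pred - tp, fn = n_gt - tp)
}

# Exhaustive one-to-one assignment maximizing (#matches, total IoU) over
# pairs with IoU >= t. Recursion over GT rows; small inputs only.
.optimal_assignment <- function(iou, t) {
  n_gt <- nrow(iou); n_pred <- ncol(iou)
  best <- list(count = -1, total = -Inf, sel = NULL)
  rec <- function(i, used_p, sel, count, total) {
    if (i > n_gt) {
      if (count > best$count ||
          (count == best$count && total > best$total)) {
        best <<- list(count = count, total = total, sel = sel)
      }
      return(invisible())
    }
    rec(i + 1L, used_p, sel, count, total)  # leave GT i unmatched
    for (j in seq_len(n_pred)) {
      if (!used_p[j] && iou[i, j] >= t) {
        used_p[j] <- TRUE
        rec(i + 1L, used_p, rbind(sel, c(i, j)), count + 1L,
            total + iou[i, j])
        used_p[j] <- FALSE
      }
    }
  }
  rec(1L, logical(n_pred), NULL, 0L, 0)
  sel <- best$sel
  if (is.null(sel))
    return(data.frame(gt = integer(0), pred = integer(0), iou = numeric(0)))
  data.frame(gt = as.integer(rownames(iou)[sel[, 1]]),
             pred = as.integer(colnames(iou)[sel[, 2]]),
             iou = iou[sel])
}

#' Object-level detection metrics over a set of IoU thresholds
#'
#' Per threshold t: precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, their
#' harmonic mean F1, and average precision `AP_t = TP/(TP+FP+FN)`. The
#' aggregates mP, mR, mF1 and mAP are arithmetic means over the threshold
#' set, reported on the 0-100 scale. With an empty prediction, precision
#' (and F1) guard to 0; an empty prediction against an empty ground truth
#' scores 100 everywhere.
#'
#' @param gt,pred Integer label arrays of identical shape.
#' @param thresholds IoU thresholds (default `seq(0.25, 0.45, by = 0.05)`;
#'   `seq(0.5, 0.75, by = 0.05)` is the conventional set for easier data).
#' @param method Matching rule, see [match_at_threshold()].
#' @return List of class `metrics_report`: `per_threshold` data frame and
#'   scalars `mP`, `mR`, `mF1`, `mAP`.
#' @export
detection_metrics <- function(gt, pred,
                              thresholds = seq(0.25, 0.45, by = 0.05),
                              method = "greedy") {
  stopifnot(length(thresholds) >= 1)
  iou <- instance_iou_matrix(gt, pred)
  if (nrow(iou) == 0L && ncol(iou) == 0L) {
    message("both volumes are empty; metrics defined as perfect agreement")
    per <- data.frame(threshold = thresholds, tp = 0L, fp = 0L, fn = 0L,
                      precision = 100, recall = 100, f1 = 100, ap = 100)
    return(structure(list(per_threshold = per, mP = 100, mR = 100,
                          mF1 = 100, mAP = 100), class = "metrics_report"))
  }
  per <- do.call(rbind, lapply(thresholds, function(t) {
    m <- match_at_threshold(iou, t, method)
    prec <- if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else 0
    rec <- if (m$tp + m$fn > 0) m$tp / (m$tp + m$fn) else 0
    f1 <- if (2 * m$tp + m$fp + m$fn > 0)
      2 * m$tp / (2 * m$tp + m$fp + m$fn) else 0
    ap <- if (m$tp + m$fp + m$fn > 0) m$tp / (m$tp + m$fp + m$fn) else 0
    data.frame(threshold = t, tp = m$tp, fp = m$fp, fn = m$fn,
               precision = 100 * prec, recall = 100 * rec,
               f1 = 100 * f1, ap = 100 * ap)
  }))
  structure(list(per_threshold = per,
                 mP = mean(per$precision), mR = mean(per$recall),
                 mF1 = mean(per$f1), mAP = mean(per$ap)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Instance detection metrics over",
      nrow(x$per_threshold), "IoU thresholds\n")
  print(x$per_threshold, row.names = FALSE, digits = 4)
  cat(sprintf("mP = %.2f  mR = %.2f  mF1 = %.2f  mAP = %.2f\n",
              x$mP, x$mR, x$mF1, x$mAP))
  if (!is.null(x$aji)) cat(sprintf("AJI = %.4f\n", x$aji))
  invisible(x)
}

#' Aggregated Jaccard Index
#'
#' For each ground-truth instance (in label order) the as-yet-unused
#' predicted instance with the largest Jaccard similarity is selected; the
#' AJI is the ratio of summed matched intersections to summed matched
#' unions plus the total volume of unmatched predictions. 1 for a perfect
#' segmentation, 0 for an empty one.
#'
#' @param gt,pred Integer label arrays of identical shape.
#' @return Scalar in \[0, 1\].
#' @export
aji <- function(gt, pred) {
  if (!identical(dim(gt), dim(pred)))
    stop("shape mismatch between volumes", call. = FALSE)
  glab <- sort(unique(as.vector(gt[gt != 0L])))
  plab <- sort(unique(as.vector(pred[pred != 0L])))
  if (length(glab) == 0L) return(0)
  if (length(plab) == 0L) return(0)
  gsz <- tabulate(gt[gt != 0L], nbins = max(glab))
  psz <- tabulate(pred[pred != 0L], nbins = max(plab))
  both <- gt != 0L & pred != 0L
  inter <- if (any(both))
    as.matrix(unclass(table(g = gt[both], p = pred[both]))) else NULL
  used <- stats::setNames(logical(length(plab)), plab)
  num <- 0; den <- 0
  for (gl in glab) {
    bi <- 0; bu <- gsz[gl]; bp <- NA
    if (!is.null(inter) && as.character(gl) %in% rownames(inter)) {
      for (pn in colnames(inter)) {
        i <- inter[as.character(gl), pn]
        if (i == 0 || used[[pn]]) next
        u <- gsz[gl] + psz[as.integer(pn)] - i
        if (bi == 0 || i / u > bi / bu) { bi <- i; bu <- u; bp <- pn }
      }
    }
    num <- num + bi
    den <- den + bu
    if (!is.na(bp)) used[[bp]] <- TRUE
  }
  den <- den + sum(psz[as.integer(names(used)[!used])])
  num / den
}

#' Full instance-segmentation evaluation report
#'
#' Detection metrics plus the Aggregated Jaccard Index and voxel-level
#' (semantic) precision/recall/F1.
#'
#' @inheritParams detection_metrics
#' @return A `metrics_report` with additional fields `aji` and `voxel`.
#' @export
evaluate_instances <- function(gt, pred,
                               thresholds = seq(0.25, 0.45, by = 0.05),
                               method = "greedy") {
  rep <- detection_metrics(gt, pred, thresholds, method)
  rep$aji <- aji(gt, pred)
  tp <- sum(gt != 0L & pred != 0L)
  fp <- sum(gt == 0L & pred != 0L)
  fn <- sum(gt != 0L & pred == 0L)
  vp <- if (tp + fp > 0) tp / (tp + fp) else 0
  vr <- if (tp + fn > 0) tp / (tp + fn) else 0
  rep$voxel <- c(precision = 100 * vp, recall = 100 * vr,
                 f1 = if (2 * tp + fp + fn > 0)
                   100 * 2 * tp / (2 * tp + fp + fn) else 0)
  rep
}
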