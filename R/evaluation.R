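#' Pixel confusion counts
#'
#' Tallies true/false positives/negatives between a binary prediction and a
#' binary ground truth, optionally restricted to FOV pixels.
#'
#' @param pred_binary binary matrix/array of predictions.
#' @param gt binary ground truth, same shape.
#' @param fov_mask optional binary mask; pixels where it is 0 are ignored.
#' @return A \code{confusion_counts} list with \code{TP}, \code{TN},
#'   \code{FP}, \code{FN}.
#' @export
confusion <- function(pred_binary, gt, fov_mask = NULL) {
  p <- as.vector(unclass(pred_binary))
  g <- as.vector(unclass(gt))
  if (length(p) != length(g)) stop("shape mismatch")
  if (any(p != 0 & p != 1) || any(g != 0 & g != 1))
    stop("confusion() expects binary inputs")
  if (!is.null(fov_mask)) {
    keep <- as.vector(unclass(fov_mask)) == 1
    p <- p[keep]
    g <- g[keep]
  }
  structure(list(TP = sum(p == 1 & g == 1), TN = sum(p == 0 & g == 0),
                 FP = sum(p == 1 & g == 0), FN = sum(p == 0 & g == 1)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion: TP %d  TN %d  FP %d  FN %d>\n", x$TP, x$TN, x$FP,
              x$FN))
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity (recall), specificity, precision and F1:
#' \deqn{ACC = (TP+TN)/(TP+TN+FP+FN)}
#' \deqn{SE = TP/(TP+FN), \quad SP = TN/(TN+FP)}
#' \deqn{Precision = TP/(TP+FP), \quad F1 = TP/(TP + (FP+FN)/2)}
#' A metric whose denominator is zero is reported as \code{NA} rather than 0.
#'
#' @param cc a \code{\link{confusion}} result or list with TP/TN/FP/FN.
#' @return Named list with \code{acc}, \code{sensitivity},
#'   \code{specificity}, \code{precision}, \code{f1}.
#' @export
seg_metrics <- function(cc) {
  rat <- function(a, b) if (b == 0) NA_real_ else a / b
  with(cc, list(
    acc = rat(TP + TN, TP + TN + FP + FN),
    sensitivity = rat(TP, TP + FN),
    specificity = rat(TN, TN + FP),
    precision = rat(TP, TP + FP),
    f1 = rat(TP, TP + (FP + FN) / 2)))
}

#' Mean intersection-over-union
#'
#' Mean over the k+1 classes of \code{TP_c / (TP_c + FP_c + FN_c)}, the
#' per-class Jaccard index. Classes with an empty union (absent from both
#' prediction and truth) are skipped rather than counted as zero.
#'
#' @param pred_binary,gt binary matrices (two classes: background 0 and
#'   vessel 1), or a list of per-class \code{c(TP, FP, FN)} triplets.
#' @param fov_mask optional binary mask.
#' @return Mean IoU in \code{[0, 1]}.
#' @export
miou <- function(pred_binary, gt = NULL, fov_mask = NULL) {
  if (is.list(pred_binary) && is.null(gt)) {
    counts <- pred_binary
  } else {
    cc <- confusion(pred_binary, gt, fov_mask)
    counts <- list(vessel = c(TP = cc$TP, FP = cc$FP, FN = cc$FN),
                   background = c(TP = cc$TN, FP = cc$FN, FN = cc$FP))
  }
  ious <- vapply(counts, function(k) {
    u <- k[["TP"]] + k[["FP"]] + k[["FN"]]
    if (u == 0) NA_real_ else k[["TP"]] / u
  }, numeric(1))
  mean(ious, na.rm = TRUE)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over every distinct score, tracing the true
#' positive rate against the false positive rate from (0,0) to (1,1); the
#' area under the curve is computed by trapezoidal integration, which for a
#' step ROC equals the probability that a random positive outscores a random
#' negative (ties counting one half).
#'
#' @param scores numeric scores (higher = more vessel-like).
#' @param labels binary labels, same length.
#' @param fov_mask optional binary mask.
#' @return A list of class \code{roc_curve}: \code{fpr}, \code{tpr},
#'   \code{thresholds} and \code{auc}.
#' @export
roc_auc <- function(scores, labels, fov_mask = NULL) {
  s <- as.vector(unclass(scores))
  y <- as.vector(unclass(labels))
  if (length(s) != length(y)) stop("shape mismatch")
  if (!is.null(fov_mask)) {
    keep <- as.vector(unclass(fov_mask)) == 1
    s <- s[keep]
    y <- y[keep]
  }
  np <- sum(y == 1)
  nn <- sum(y == 0)
  if (np == 0 || nn == 0)
    stop("AUC is undefined when only one class is present")
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]
  y <- y[ord]
  grp <- cumsum(!duplicated(s))        # ties share a threshold
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, s[last]), auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve: %d points, AUC %.4f>\n", length(x$fpr), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlab = "False positive rate",
                 ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.4f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Threshold a probability map
#'
#' @param prob_map numeric map in \code{[0, 1]}.
#' @param threshold decision threshold; pixels with value \code{>=}
#'   threshold become 1 (default 0.5).
#' @return Binary map of the same shape.
#' @export
binarize <- function(prob_map, threshold = 0.5) {
  v <- unclass(prob_map)
  attr(v, "range_tag") <- NULL
  (v >= threshold) * 1
}

#' Segment and score one full image
#'
#' Covers the preprocessed plane with a stride grid of patches, runs the
#' model on every patch, reconstructs the full probability map by averaging
#' overlaps, and scores it against the ground truth: threshold-free AUC on
#' the probabilities plus threshold metrics and mean IoU on the binarised
#' map, restricted to the FOV when a mask is given.
#'
#' @param model a fitted \code{vesselnet}, or a function mapping a patch
#'   array \code{(ps, ps, 1, N)} to predictions of the same shape.
#' @param plane preprocessed unit-range \code{gray_plane}.
#' @param gt binary vessel ground truth.
#' @param fov optional binary FOV mask.
#' @param stride patch-grid stride (default half a patch).
#' @param threshold binarisation threshold (default 0.5).
#' @param patch_size patch side; defaults to the model input size.
#' @return A \code{metrics_report} list: \code{acc}, \code{sensitivity},
#'   \code{specificity}, \code{precision}, \code{f1}, \code{miou},
#'   \code{auc}, plus the \code{prob_map} and \code{roc} curve.
#' @export
evaluate_image <- function(model, plane, gt, fov = NULL, stride = NULL,
                           threshold = 0.5, patch_size = NULL) {
  if (inherits(model, "vesselnet")) {
    ps <- patch_size %||% model$config$input_size[1]
    predict_fun <- function(x) net_predict(model, x)
  } else {
    if (is.null(patch_size)) stop("patch_size is required for a function model")
    ps <- patch_size
    predict_fun <- model
  }
  stride <- stride %||% max(1L, ps %/% 2L)
  v <- unclass(plane)
  attr(v, "range_tag") <- NULL
  grid <- patch_grid(dim(v), ps, stride)
  patches <- cpp_crop_patches(v, grid$row, grid$col, ps)
  preds <- predict_fun(patches)
  prob <- reconstruct_from_patches(preds, grid, dim(v))
  roc <- roc_auc(prob, gt, fov)
  bin <- binarize(prob, threshold)
  cc <- confusion(bin, gt, fov)
  m <- seg_metrics(cc)
  structure(c(m, list(miou = miou(bin, gt, fov), auc = roc$auc,
                      counts = cc, prob_map = prob, roc = roc)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics: ACC %.4f  SE %.4f  SP %.4f  P %.4f  ",
                     "F1 %.4f  MIOU %.4f  AUC %.4f>\n"),
              x$acc, x$sensitivity, x$specificity, x$precision, x$f1,
              x$miou, x$auc))
  invisible(x)
}

#' Write per-image metric rows as CSV
#'
#' @param reports named list of \code{metrics_report}s (names = image ids).
#' @param path output CSV path.
#' @return The data frame written, invisibly.
#' @export
metrics_csv <- function(reports, path) {
  df <- do.call(rbind, lapply(names(reports), function(id) {
    r <- reports[[id]]
    data.frame(image_id = id, ACC = r$acc, SE = r$sensitivity,
               SP = r$specificity, precision = r$precision, F1 = r$f1,
               MIOU = r$miou, AUC = r$auc)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Export a ROC curve as a two-column CSV
#'
#' @param roc a \code{roc_curve} from \code{\link{roc_auc}}.
#' @param path output CSV path (columns \code{fpr}, \code{tpr}).
#' @return \code{path}, invisibly.
#' @export
write_roc_csv <- function(roc, path) {
  write.csv(data.frame(fpr = roc$fpr, tpr = roc$tpr), path,
            row.names = FALSE)
  invisible(path)
}

#' Matched-filter vessel score (baseline)
#'
#' Simple non-learned baseline: a difference-of-Gaussians band-pass tuned to
#' dark curvilinear structures. The local background estimate (wide blur)
#' minus the vessel-scale blur is large where the intensity dips over a few
#' pixels, which ranks vessel pixels above background while cancelling
#' smooth illumination gradients. Used as a fixed yardstick for synthetic
#' benchmark difficulty.
#'
#' @param plane unit-range \code{gray_plane}.
#' @param sigma vessel-scale Gaussian radius in pixels (default 1.5); the
#'   background scale is \code{6 * sigma}.
#' @return Score matrix in \code{[0, 1]}.
#' @export
vessel_filter_score <- function(plane, sigma = 1.5) {
  v <- unclass(plane)
  attr(v, "range_tag") <- NULL
  blur <- function(s) t(EBImage::imageData(
    EBImage::gblur(EBImage::Image(t(v)), s)))
  sc <- blur(6 * sigma) - blur(sigma)
  rg <- range(sc)
  if (rg[2] > rg[1]) (sc - rg[1]) / (rg[2] - rg[1]) else sc * 0
}
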