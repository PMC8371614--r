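#' @export
print.vesselnet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Vessel segmentation network (variant '%s')\n", cfg$variant))
  cat(sprintf("  input %dx%dx1, widths %s, t = %d, SE reduction r = %d\n",
              cfg$input_size[1], cfg$input_size[2],
              paste(cfg$widths, collapse = "/"), cfg$recurrence_steps,
              cfg$se_reduction))
  cat(sprintf("  parameters: %s   upsampling: %s\n",
              format(count_parameters(x), big.mark = ","),
              cfg$upsample_mode))
  if (isTRUE(x$fitted)) {
    h <- x$history
    cat(sprintf("  fitted: %d epochs, best val Dice loss %.4f\n",
                nrow(h), min(h$val_loss, na.rm = TRUE)))
  } else {
    cat("  fitted: no (initial weights)\n")
  }
  invisible(x)
}

#' Layer-by-layer model summary
#'
#' Prints a layer listing with output sizes and per-layer parameter counts,
#' and the grand total.
#'
#' @param object a \code{vesselnet}.
#' @param ... unused.
#' @return The layer table, invisibly.
#' @export
summary.vesselnet <- function(object, ...) {
  tab <- layer_table(object)
  print.data.frame(tab, row.names = FALSE)
  cat(sprintf("Total parameters: %s\n",
              format(attr(tab, "total"), big.mark = ",")))
  if (isTRUE(object$fitted)) {
    cat("\nTraining history (last epochs):\n")
    print.data.frame(utils::tail(object$history, 3), row.names = FALSE)
  }
  invisible(tab)
}

#' @export
coef.vesselnet <- function(object, ...) object$params

#' Predict vessel probabilities
#'
#' For a patch array or \code{patch_set}, returns per-patch probability
#' maps. For a full preprocessed plane (\code{gray_plane}/matrix), covers it
#' with a stride grid, predicts every patch and reconstructs the full map by
#' overlap averaging. A raw \code{fundus_image} is first run through
#' \code{\link{preprocess_pipeline}} with default settings.
#'
#' @param object a fitted \code{vesselnet}.
#' @param newdata patches, plane or \code{fundus_image}.
#' @param type \code{"prob"} (default) or \code{"class"} (thresholded).
#' @param threshold threshold for \code{type = "class"} (default 0.5).
#' @param stride grid stride for full-plane prediction (default half patch).
#' @param ... passed to \code{\link{preprocess_pipeline}} for raw images.
#' @return Probability (or binary) array shaped like the input.
#' @export
predict.vesselnet <- function(object, newdata, type = c("prob", "class"),
                              threshold = 0.5, stride = NULL, ...) {
  type <- match.arg(type)
  ps <- object$config$input_size[1]
  if (inherits(newdata, "fundus_image"))
    newdata <- preprocess_pipeline(newdata, ...)
  if (inherits(newdata, "patch_set")) newdata <- newdata$inputs
  if (length(dim(newdata)) == 4L) {
    out <- net_predict(object, newdata)
  } else {
    v <- unclass(newdata)
    attr(v, "range_tag") <- NULL
    stride <- stride %||% max(1L, ps %/% 2L)
    grid <- patch_grid(dim(v), ps, stride)
    patches <- cpp_crop_patches(v, grid$row, grid$col, ps)
    preds <- net_predict(object, patches)
    out <- reconstruct_from_patches(preds, grid, dim(v))
  }
  if (type == "class") binarize(out, threshold) else out
}

#' Plot training history
#'
#' Loss and pixel-accuracy curves per epoch for training and validation.
#'
#' @param x a fitted \code{vesselnet}.
#' @param ... further graphical parameters.
#' @return \code{x}, invisibly.
#' @export
plot.vesselnet <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history to plot")
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op), add = TRUE)
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "b",
                    pch = c(1, 2), lty = 1, xlab = "epoch", ylab = "Dice loss",
                    main = "Loss", ...)
  graphics::legend("topright", c("train", "validation"), pch = c(1, 2),
                   col = 1:2, bty = "n")
  graphics::matplot(h$epoch, cbind(h$train_acc, h$val_acc), type = "b",
                    pch = c(1, 2), lty = 1, xlab = "epoch",
                    ylab = "pixel accuracy", main = "Accuracy", ...)
  invisible(x)
}

#' Residuals of a fitted segmentation model
#'
#' Signed per-pixel residuals (probability minus label) on a patch set.
#'
#' @param object a fitted \code{vesselnet}.
#' @param patches a \code{patch_set} with labels.
#' @param ... unused.
#' @return Array of residuals shaped like the patch inputs.
#' @export
residuals.vesselnet <- function(object, patches, ...) {
  if (!inherits(patches, "patch_set")) stop("patches must be a patch_set")
  net_predict(object, patches$inputs) - patches$labels
}

#' Simulate segmentations from predicted probabilities
#'
#' Draws Bernoulli pixel labels from the model's predicted probabilities,
#' giving stochastic segmentations consistent with the fitted per-pixel
#' posterior.
#'
#' @param object a fitted \code{vesselnet}.
#' @param nsim number of draws (default 1).
#' @param seed integer seed.
#' @param newdata patches or plane (see \code{\link{predict.vesselnet}}).
#' @param ... passed to \code{predict}.
#' @return A list of \code{nsim} binary arrays.
#' @export
simulate.vesselnet <- function(object, nsim = 1, seed = 1L, newdata, ...) {
  prob <- predict(object, newdata, type = "prob", ...)
  v <- unclass(prob)
  attr(v, "range_tag") <- NULL
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    out <- (runif(length(v)) <= as.vector(v)) * 1
    dim(out) <- dim(v)
    out
  }))
}

#' Save / load model weights
#'
#' Weights go to a raw double container with a YAML manifest carrying the
#' configuration and parameter shapes, so a checkpoint is a pair of small
#' files reconstructable anywhere.
#'
#' @param model a \code{vesselnet}.
#' @param dir checkpoint directory.
#' @return \code{dir} (save) or the restored \code{vesselnet} (load).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeBin(unlist(model$params, use.names = FALSE),
           file.path(dir, "weights.f64"))
  cfg <- model$config
  yaml::write_yaml(list(
    config = list(input_size = cfg$input_size, widths = cfg$widths,
                  recurrence_steps = cfg$recurrence_steps,
                  se_reduction = cfg$se_reduction, variant = cfg$variant,
                  upsample_mode = cfg$upsample_mode, seed = cfg$seed),
    shapes = lapply(model$params, function(p) dim(p) %||% length(p)),
    fitted = isTRUE(model$fitted)), file.path(dir, "manifest.yaml"))
  if (!is.null(model$history))
    write.csv(model$history, file.path(dir, "history.csv"),
              row.names = FALSE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  cfg <- do.call(network_config, man$config)
  model <- build_model(cfg)
  vals <- readBin(file.path(dir, "weights.f64"), "double",
                  n = sum(vapply(man$shapes, function(s) prod(unlist(s)), 1)))
  at <- 0L
  for (nm in names(man$shapes)) {
    sh <- unlist(man$shapes[[nm]])
    n <- prod(sh)
    p <- vals[at + seq_len(n)]
    if (length(sh) > 1L) dim(p) <- sh
    model$params[[nm]] <- p
    at <- at + n
  }
  model$fitted <- isTRUE(man$fitted)
  hp <- file.path(dir, "history.csv")
  if (file.exists(hp)) model$history <- read.csv(hp)
  model
}
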