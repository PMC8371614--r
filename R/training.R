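#' Soft Dice loss
#'
#' Differentiable Dice loss for binary segmentation,
#' \code{1 - 2*sum(p*g) / (sum(p^2) + sum(g^2))}, with a small smoothing
#' constant added to numerator and denominator so that two empty masks score
#' a perfect 0 instead of 0/0. Dice is preferred over cross-entropy here
#' because vessel pixels are only about a tenth of a fundus image: a
#' background-biased classifier gets little credit under Dice.
#'
#' @param p numeric vector/array of predictions in \code{[0, 1]}.
#' @param g binary ground truth, same length.
#' @param smooth smoothing constant (default \code{1e-7}).
#' @return Loss in \code{[0, 1]}.
#' @export
dice_loss <- function(p, g, smooth = 1e-7) {
  if (length(p) != length(g)) stop("p and g must have equal length")
  if (any(g != 0 & g != 1)) stop("ground truth must be binary")
  if (any(p < -1e-9 | p > 1 + 1e-9)) stop("predictions must lie in [0, 1]")
  num <- 2 * sum(p * g) + smooth
  den <- sum(p * p) + sum(g * g) + smooth
  1 - num / den
}

# gradient of dice_loss w.r.t. p
dice_loss_grad <- function(p, g, smooth = 1e-7) {
  num <- 2 * sum(p * g) + smooth
  den <- sum(p * p) + sum(g * g) + smooth
  2 * (num * p - den * g) / den^2
}

#' L2-regularised objective
#'
#' Adds the squared L2 norm of the weights, scaled by \code{lambda}, to a
#' base loss value: \code{loss + lambda * sum(w^2)}.
#'
#' @param loss base loss (e.g. a Dice loss).
#' @param weights numeric vector/list of weight arrays.
#' @param lambda nonnegative regularisation strength.
#' @return Penalised objective value.
#' @export
l2_objective <- function(loss, weights, lambda) {
  if (lambda < 0) stop("lambda must be >= 0")
  if (is.list(weights)) weights <- unlist(weights, use.names = FALSE)
  loss + lambda * sum(weights^2)
}

#' Training configuration
#'
#' @param lambda_l2 L2 weight-decay strength (default \code{1e-4}).
#' @param learning_rate Adam step size (default 0.001).
#' @param batch_size mini-batch size (default 25).
#' @param epochs training epochs (default 20).
#' @param learning_step epochs between learning-rate halvings (default 5);
#'   set \code{lr_decay = FALSE} to keep the rate constant.
#' @param lr_decay logical, halve the rate every \code{learning_step} epochs.
#' @param seed integer seed controlling shuffling.
#' @return An \code{objective_config} list.
#' @export
objective_config <- function(lambda_l2 = 1e-4, learning_rate = 0.001,
                             batch_size = 25L, epochs = 20L,
                             learning_step = 5L, lr_decay = TRUE, seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be positive")
  batch_size <- as.integer(batch_size)
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (lambda_l2 < 0) stop("lambda_l2 must be >= 0")
  structure(list(lambda_l2 = lambda_l2, learning_rate = learning_rate,
                 batch_size = batch_size, epochs = as.integer(epochs),
                 learning_step = as.integer(learning_step),
                 lr_decay = isTRUE(lr_decay), seed = as.integer(seed)),
            class = "objective_config")
}

weight_param_names <- function(P)
  grep("\\.(conv_w|proj_w|se_w1|se_w2|up_w)$", names(P), value = TRUE)

weight_sq_norm <- function(P) {
  sum(vapply(weight_param_names(P),
             function(nm) sum(P[[nm]]^2), numeric(1)))
}

eval_loss_acc <- function(model, patches, batch = 64L) {
  probs <- net_predict(model, patches$inputs, batch = batch)
  c(loss = dice_loss(probs, patches$labels),
    acc = mean((probs >= 0.5) == (patches$labels >= 0.5)))
}

#' Train a segmentation model
#'
#' Minimises the Dice loss plus L2 weight decay with Adam over shuffled
#' mini-batches. Validation loss and pixel accuracy are computed after each
#' epoch and the weights with the lowest validation Dice loss are kept.
#'
#' @param model a \code{vesselnet} from \code{\link{build_model}}.
#' @param train_patches,val_patches \code{patch_set}s matching the model
#'   input size.
#' @param cfg an \code{\link{objective_config}}.
#' @param verbose print one line per epoch.
#' @return The model with trained parameters and a \code{history} data frame
#'   (epoch, train_loss, val_loss, train_acc, val_acc, lr).
#' @export
train_model <- function(model, train_patches, val_patches,
                        cfg = objective_config(), verbose = FALSE) {
  n <- n_patches(train_patches)
  if (n == 0L) stop("empty training patch set")
  ps <- dim(train_patches$inputs)[1]
  if (ps != model$config$input_size[1])
    stop("patch size ", ps, " does not match network input ",
         model$config$input_size[1])
  P <- model$params
  opt <- adam_state(P)
  wnames <- weight_param_names(P)
  history <- NULL
  best <- list(val = Inf, params = P)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cfg$learning_rate *
      if (cfg$lr_decay) 0.5^((epoch - 1L) %/% cfg$learning_step) else 1
    ord <- with_seed(cfg$seed + epoch, sample.int(n))
    ep_loss <- 0; ep_acc <- 0; nb <- 0L
    for (at in seq(1L, n, by = cfg$batch_size)) {
      sel <- ord[at:min(at + cfg$batch_size - 1L, n)]
      xb <- train_patches$inputs[, , , sel, drop = FALSE]
      yb <- train_patches$labels[, , , sel, drop = FALSE]
      fw <- net_forward(P, model$config, xb, training = TRUE)
      loss <- dice_loss(fw$prob, yb)
      gprob <- dice_loss_grad(fw$prob, yb)
      dim(gprob) <- dim(fw$prob)
      grads <- net_backward(P, model$config, fw$caches, gprob)
      if (cfg$lambda_l2 > 0)
        for (nm in wnames)
          grads[[nm]] <- grads[[nm]] + 2 * cfg$lambda_l2 * P[[nm]]
      st <- adam_step(P, grads, opt, lr)
      P <- st$params
      opt <- st$state
      for (nm in names(fw$bn_updates)) {
        P[[paste0(nm, ".bn_rmean")]] <- fw$bn_updates[[nm]]$rmean
        P[[paste0(nm, ".bn_rvar")]] <- fw$bn_updates[[nm]]$rvar
      }
      ep_loss <- ep_loss + l2_objective(loss, P[wnames], cfg$lambda_l2)
      ep_acc <- ep_acc + mean((fw$prob >= 0.5) == (yb >= 0.5))
      nb <- nb + 1L
    }
    mtmp <- model; mtmp$params <- P
    va <- if (!is.null(val_patches) && n_patches(val_patches) > 0)
      eval_loss_acc(mtmp, val_patches) else c(loss = NA_real_, acc = NA_real_)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss / nb, val_loss = va[["loss"]],
      train_acc = ep_acc / nb, val_acc = va[["acc"]], lr = lr))
    if (verbose)
      message(sprintf(
        "epoch %2d  train %.4f  val %.4f  acc %.4f  val_acc %.4f  lr %.2g",
        epoch, ep_loss / nb, va[["loss"]], ep_acc / nb, va[["acc"]], lr))
    if (!is.na(va[["loss"]]) && va[["loss"]] < best$val)
      best <- list(val = va[["loss"]], params = P)
  }
  model$params <- if (is.finite(best$val)) best$params else P
  model$final_params <- P
  model$history <- history
  model$fitted <- TRUE
  model
}

#' Fit a vessel-segmentation network
#'
#' One-stop fitting front end: builds the network described by
#' \code{network} and trains it on a patch set. When no validation set is
#' given, a fraction of the training patches is held out (deterministically
#' in the objective seed).
#'
#' @param patches training \code{patch_set}.
#' @param val_patches optional validation \code{patch_set}.
#' @param val_fraction fraction of \code{patches} held out when
#'   \code{val_patches} is missing (default 0.1).
#' @param network a \code{\link{network_config}}.
#' @param objective an \code{\link{objective_config}}.
#' @param verbose print per-epoch progress.
#' @return A fitted \code{vesselnet}.
#' @export
fit_vesselnet <- function(patches, val_patches = NULL, val_fraction = 0.1,
                          network = network_config(),
                          objective = objective_config(), verbose = FALSE) {
  if (is.null(val_patches) && val_fraction > 0) {
    n <- n_patches(patches)
    idx <- with_seed(objective$seed,
                     sample.int(n, max(1L, round(val_fraction * n))))
    val_patches <- subset_patch_set(patches, idx)
    patches <- subset_patch_set(patches, setdiff(seq_len(n), idx))
  }
  model <- build_model(network)
  train_model(model, patches, val_patches, cfg = objective, verbose = verbose)
}

#' Subset a patch set by index
#' @param x a \code{patch_set}.
#' @param idx integer indices.
#' @return A \code{patch_set} with the selected patches.
#' @export
subset_patch_set <- function(x, idx) {
  new_patch_set(x$inputs[, , , idx, drop = FALSE],
                x$labels[, , , idx, drop = FALSE],
                x$coords[idx, , drop = FALSE], x$seed)
}

#' Export a training history as CSV
#' @param model a fitted \code{vesselnet}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
export_history <- function(model, path) {
  if (is.null(model$history)) stop("model has no training history")
  write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}
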