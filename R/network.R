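#' Network architecture configuration
#'
#' Describes the U-shaped segmentation network: four encoder stages with
#' 2x max-pooling between them, a bottom bridge at the deepest width, and a
#' mirrored decoder whose features are fused with the encoder skips by
#' elementwise summation. Each stage is a recurrent convolution unit
#' optionally wrapped in a residual skip and a squeeze-and-excitation (SE)
#' channel gate; the \code{variant} flag selects which of the three
#' ingredients are active, giving the ablation family:
#' \describe{
#'   \item{unet}{plain conv + BN + ReLU blocks}
#'   \item{recurrent}{adds recurrence (\code{recurrence_steps} shared steps)}
#'   \item{se_resnet}{adds SE gates and residual skips, no recurrence}
#'   \item{r2}{recurrence + residual skips, no SE}
#'   \item{serr}{all three (the full model)}
#' }
#'
#' @param input_size integer triple \code{c(h, w, 1)}; h and w must be
#'   divisible by \code{2^(length(widths) - 1)}.
#' @param widths channel widths per encoder stage, strictly increasing
#'   (default \code{c(16, 32, 64, 128)}).
#' @param recurrence_steps shared recurrence steps t >= 1 (default 2).
#' @param se_reduction SE bottleneck reduction r (default 4); must divide
#'   every width.
#' @param variant one of \code{"unet"}, \code{"recurrent"},
#'   \code{"se_resnet"}, \code{"r2"}, \code{"serr"}.
#' @param upsample_mode \code{"transposed_conv"} (2x2 stride-2 transposed
#'   convolution, the default) or \code{"nearest_up"} (nearest-neighbour
#'   upsampling followed by a 1x1 convolution).
#' @param seed integer seed for weight initialisation.
#' @return A \code{network_config} list.
#' @export
network_config <- function(input_size = c(48L, 48L, 1L),
                           widths = c(16L, 32L, 64L, 128L),
                           recurrence_steps = 2L, se_reduction = 4L,
                           variant = c("serr", "unet", "recurrent",
                                       "se_resnet", "r2"),
                           upsample_mode = c("transposed_conv", "nearest_up"),
                           seed = 42L) {
  variant <- match.arg(variant)
  upsample_mode <- match.arg(upsample_mode)
  widths <- as.integer(widths)
  if (length(widths) < 2L || any(diff(widths) <= 0L))
    stop("widths must be a strictly increasing vector of length >= 2")
  recurrence_steps <- as.integer(recurrence_steps)
  if (recurrence_steps < 1L) stop("recurrence_steps must be >= 1")
  se_reduction <- as.integer(se_reduction)
  if (se_reduction < 1L || any(widths %% se_reduction != 0L))
    stop("se_reduction must divide every stage width")
  input_size <- as.integer(input_size)
  if (length(input_size) == 2L) input_size <- c(input_size, 1L)
  if (input_size[3] != 1L) stop("the network takes single-channel input")
  div <- 2L^(length(widths) - 1L)
  if (any(input_size[1:2] %% div != 0L))
    stop("input height/width must be divisible by ", div)
  structure(list(input_size = input_size, widths = widths,
                 recurrence_steps = recurrence_steps,
                 se_reduction = se_reduction, variant = variant,
                 upsample_mode = upsample_mode, seed = as.integer(seed)),
            class = "network_config")
}

variant_flags <- function(variant) {
  list(se = variant %in% c("se_resnet", "serr"),
       resid = variant %in% c("se_resnet", "r2", "serr"),
       recur = variant %in% c("recurrent", "r2", "serr"))
}

# static block plan: list of blocks with role, name, ci, co
block_plan <- function(cfg) {
  w <- cfg$widths
  ns <- length(w)
  plan <- list()
  ci <- 1L
  for (k in seq_len(ns)) {
    plan[[length(plan) + 1L]] <- list(name = paste0("enc", k), role = "enc",
                                      ci = ci, co = w[k])
    ci <- w[k]
  }
  plan[[length(plan) + 1L]] <- list(name = "bridge", role = "bridge",
                                    ci = w[ns], co = w[ns])
  for (k in rev(seq_len(ns - 1L))) {
    plan[[length(plan) + 1L]] <- list(name = paste0("dec", ns - k),
                                      role = "dec", ci = ci, co = w[k])
    ci <- w[k]
  }
  plan
}

init_block_params <- function(blk, cfg, fl) {
  ci <- blk$ci; co <- blk$co
  p <- list()
  if (blk$role == "dec") {
    if (cfg$upsample_mode == "transposed_conv") {
      p$up_w <- array(rnorm(4 * ci * co, sd = sqrt(2 / ci)), c(2, 2, ci, co))
    } else {
      p$up_w <- matrix(rnorm(ci * co, sd = sqrt(2 / ci)), ci, co)
    }
    p$up_b <- numeric(co)
    ci <- co  # block conv runs on the fused, already-reduced map
  }
  p$conv_w <- matrix(rnorm(9 * ci * co, sd = sqrt(2 / (9 * ci))), 9 * ci, co)
  p$conv_b <- numeric(co)
  p$bn_gamma <- rep(1, co)
  p$bn_beta <- numeric(co)
  p$bn_rmean <- numeric(co)
  p$bn_rvar <- rep(1, co)
  if (fl$resid && blk$role == "enc" && blk$ci != blk$co)
    p$proj_w <- matrix(rnorm(blk$ci * co, sd = sqrt(2 / blk$ci)), blk$ci, co)
  if (fl$se) {
    h <- co %/% cfg$se_reduction
    p$se_w1 <- matrix(rnorm(co * h, sd = sqrt(2 / co)), co, h)
    p$se_w2 <- matrix(rnorm(h * co, sd = sqrt(1 / h)), h, co)
  }
  p
}

#' Build an (untrained) segmentation model
#'
#' Assembles the network described by a \code{\link{network_config}} and
#' initialises its weights (He-scaled Gaussians, deterministic in
#' \code{cfg$seed}). The result is a \code{vesselnet} object; training it is
#' the job of \code{\link{fit_vesselnet}} / \code{\link{train_model}}.
#'
#' @param cfg a \code{\link{network_config}}.
#' @return An object of class \code{vesselnet} with \code{fitted = FALSE}.
#' @export
build_model <- function(cfg = network_config()) {
  if (!inherits(cfg, "network_config")) stop("cfg must be a network_config")
  fl <- variant_flags(cfg$variant)
  plan <- block_plan(cfg)
  params <- with_seed(cfg$seed, {
    P <- list()
    for (blk in plan) {
      bp <- init_block_params(blk, cfg, fl)
      names(bp) <- paste0(blk$name, ".", names(bp))
      P <- c(P, bp)
    }
    P[["head.conv_w"]] <- matrix(rnorm(cfg$widths[1],
                                       sd = sqrt(2 / cfg$widths[1])),
                                 cfg$widths[1], 1)
    P[["head.conv_b"]] <- numeric(1)
    P
  })
  structure(list(config = cfg, params = params, plan = plan, fitted = FALSE,
                 history = NULL), class = "vesselnet")
}

# ---- forward / backward ----------------------------------------------------

# one SE-residual-recurrent unit; x is the stage input (already fused and
# width-reduced for decoder blocks)
block_fwd <- function(P, pfx, x, blk, fl, t, training) {
  g <- function(s) P[[paste0(pfx, ".", s)]]
  z <- conv_fwd(x, g("conv_w"), g("conv_b"), 3L)
  rmean <- g("bn_rmean"); rvar <- g("bn_rvar")
  steps <- vector("list", t)
  o <- NULL
  for (k in seq_len(t)) {
    s <- if (k == 1L) z else z + o
    bn <- bnrelu_fwd(s, g("bn_gamma"), g("bn_beta"), rmean, rvar, training)
    rmean <- bn$rmean; rvar <- bn$rvar
    o <- bn$o
    steps[[k]] <- list(s = s, o = o, mu = bn$mu, invsd = bn$invsd)
  }
  se <- NULL
  y <- o
  if (fl$se) {
    se <- se_fwd(o, g("se_w1"), g("se_w2"))
    y <- se$y
  }
  if (fl$resid) {
    r <- if (blk$ci == blk$co || blk$role != "enc") x
         else conv_fwd(x, g("proj_w"), numeric(blk$co), 1L)
    out <- cpp_add_relu(r, y)
  } else {
    out <- y
  }
  list(out = out, cache = list(x = x, steps = steps, se = se, o_t = o,
                               training = training),
       bn_stats = list(rmean = rmean, rvar = rvar))
}

# full network forward; returns probability map and (optionally) caches
net_forward <- function(P, cfg, x, training = FALSE) {
  fl <- variant_flags(cfg$variant)
  t <- if (fl$recur) cfg$recurrence_steps else 1L
  plan <- block_plan(cfg)
  byname <- stats::setNames(plan, vapply(plan, `[[`, "", "name"))
  ns <- length(cfg$widths)
  caches <- list()
  bn_updates <- list()
  enc_out <- vector("list", ns)
  h <- x
  for (k in seq_len(ns)) {
    nmk <- paste0("enc", k)
    bf <- block_fwd(P, nmk, h, byname[[nmk]], fl, t, training)
    caches[[nmk]] <- bf$cache
    caches[[nmk]]$out <- bf$out
    bn_updates[[nmk]] <- bf$bn_stats
    enc_out[[k]] <- bf$out
    if (k < ns) {
      mp <- cpp_maxpool2_fwd(bf$out)
      caches[[paste0("pool", k)]] <- list(idx = mp$idx, d = dim(bf$out))
      h <- mp$y
    } else {
      h <- bf$out
    }
  }
  bf <- block_fwd(P, "bridge", h, byname[["bridge"]], fl, t, training)
  caches[["bridge"]] <- bf$cache
  caches[["bridge"]]$out <- bf$out
  bn_updates[["bridge"]] <- bf$bn_stats
  h <- bf$out
  for (k in seq_len(ns - 1L)) {
    nmk <- paste0("dec", k)
    blk <- byname[[nmk]]
    if (cfg$upsample_mode == "transposed_conv") {
      u <- cpp_upconv2_fwd(h, P[[paste0(nmk, ".up_w")]],
                           P[[paste0(nmk, ".up_b")]])
      up_cache <- list(xin = h)
    } else {
      u0 <- nearest_up_fwd(h)
      u <- conv_fwd(u0, P[[paste0(nmk, ".up_w")]],
                    P[[paste0(nmk, ".up_b")]], 1L)
      up_cache <- list(xin = h, u0 = u0)
    }
    skip <- enc_out[[ns - k]]
    f <- u + skip
    bf <- block_fwd(P, nmk, f, blk, fl, t, training)
    caches[[nmk]] <- bf$cache
    caches[[nmk]]$out <- bf$out
    caches[[nmk]]$up <- up_cache
    bn_updates[[nmk]] <- bf$bn_stats
    h <- bf$out
  }
  logits <- conv_fwd(h, P[["head.conv_w"]], P[["head.conv_b"]], 1L)
  prob <- sigmoid_fwd(logits)
  caches[["head"]] <- list(x = h, prob = prob)
  list(prob = prob, caches = caches, bn_updates = bn_updates)
}

# backward through one block given upstream grad; fills grads (an env-like
# list returned), returns grad w.r.t. block input
block_backward <- function(P, pfx, g_out, cache, blk, fl, t, grads) {
  g <- function(s) P[[paste0(pfx, ".", s)]]
  nm <- function(s) paste0(pfx, ".", s)
  if (fl$resid) {
    g_sum <- cpp_mask_mul(g_out, cache$out)
    g_y <- g_sum
    if (blk$ci == blk$co || blk$role != "enc") {
      gx_res <- g_sum
    } else {
      cb <- conv_bwd(cache$x, g("proj_w"), g_sum, 1L)
      grads[[nm("proj_w")]] <- (grads[[nm("proj_w")]] %||% 0) + cb$gw
      gx_res <- cb$gx
    }
  } else {
    g_y <- g_out
    gx_res <- 0
  }
  if (fl$se) {
    sb <- se_bwd(g_y, cache$o_t, g("se_w1"), g("se_w2"), cache$se)
    grads[[nm("se_w1")]] <- (grads[[nm("se_w1")]] %||% 0) + sb$gw1
    grads[[nm("se_w2")]] <- (grads[[nm("se_w2")]] %||% 0) + sb$gw2
    g_o <- sb$gx
  } else {
    g_o <- g_y
  }
  g_z <- 0
  dgam <- 0; dbet <- 0
  for (k in rev(seq_len(t))) {
    st <- cache$steps[[k]]
    bb <- cpp_bnrelu_bwd(g_o, st$o, st$s, g("bn_gamma"), st$mu, st$invsd,
                         cache$training)
    dgam <- dgam + bb$dgamma
    dbet <- dbet + bb$dbeta
    g_z <- g_z + bb$gx
    g_o <- bb$gx  # gradient w.r.t. previous step's output
  }
  grads[[nm("bn_gamma")]] <- (grads[[nm("bn_gamma")]] %||% 0) + dgam
  grads[[nm("bn_beta")]] <- (grads[[nm("bn_beta")]] %||% 0) + dbet
  cb <- conv_bwd(cache$x, g("conv_w"), g_z, 3L)
  grads[[nm("conv_w")]] <- (grads[[nm("conv_w")]] %||% 0) + cb$gw
  grads[[nm("conv_b")]] <- (grads[[nm("conv_b")]] %||% 0) + cb$gb
  list(gx = cb$gx + gx_res, grads = grads)
}

net_backward <- function(P, cfg, caches, gprob) {
  fl <- variant_flags(cfg$variant)
  t <- if (fl$recur) cfg$recurrence_steps else 1L
  plan <- block_plan(cfg)
  byname <- stats::setNames(plan, vapply(plan, `[[`, "", "name"))
  ns <- length(cfg$widths)
  grads <- list()
  prob <- caches$head$prob
  glogits <- gprob * prob * (1 - prob)
  cb <- conv_bwd(caches$head$x, P[["head.conv_w"]], glogits, 1L)
  grads[["head.conv_w"]] <- cb$gw
  grads[["head.conv_b"]] <- cb$gb
  gh <- cb$gx
  g_enc <- vector("list", ns)   # grads flowing into encoder outputs via skips
  for (k in rev(seq_len(ns - 1L))) {
    nmk <- paste0("dec", k)
    bb <- block_backward(P, nmk, gh, caches[[nmk]], byname[[nmk]], fl, t,
                         grads)
    grads <- bb$grads
    g_f <- bb$gx
    g_enc[[ns - k]] <- g_f   # summation fusion: same grad to the skip
    up <- caches[[nmk]]$up
    if (cfg$upsample_mode == "transposed_conv") {
      ub <- cpp_upconv2_bwd(up$xin, P[[paste0(nmk, ".up_w")]], g_f)
      grads[[paste0(nmk, ".up_w")]] <- ub$gw
      grads[[paste0(nmk, ".up_b")]] <- ub$gb
      gh <- ub$gx
    } else {
      ub <- conv_bwd(up$u0, P[[paste0(nmk, ".up_w")]], g_f, 1L)
      grads[[paste0(nmk, ".up_w")]] <- ub$gw
      grads[[paste0(nmk, ".up_b")]] <- ub$gb
      gh <- nearest_up_bwd(ub$gx)
    }
  }
  bb <- block_backward(P, "bridge", gh, caches[["bridge"]],
                       byname[["bridge"]], fl, t, grads)
  grads <- bb$grads
  gh <- bb$gx
  for (k in rev(seq_len(ns))) {
    nmk <- paste0("enc", k)
    if (k < ns) {
      pc <- caches[[paste0("pool", k)]]
      gh <- cpp_maxpool2_bwd(pc$idx, gh, pc$d[1], pc$d[2])
    }
    if (!is.null(g_enc[[k]])) gh <- gh + g_enc[[k]]
    bb <- block_backward(P, nmk, gh, caches[[nmk]], byname[[nmk]], fl, t,
                         grads)
    grads <- bb$grads
    gh <- bb$gx
  }
  grads
}

# forward pass in inference mode over patch batches
net_predict <- function(model, patches, batch = 64L) {
  d <- dim(patches)
  out <- array(0, d)
  for (at in seq(1L, d[4], by = batch)) {
    sel <- at:min(at + batch - 1L, d[4])
    fw <- net_forward(model$params, model$config,
                      patches[, , , sel, drop = FALSE], training = FALSE)
    out[, , , sel] <- fw$prob
  }
  out
}

# ---- parameter accounting --------------------------------------------------

#' Count model parameters
#'
#' Total of every stored per-layer quantity: convolution and fully-connected
#' weights and biases, and all four per-channel batch-normalisation
#' quantities (scale, offset, running mean, running variance).
#'
#' @param model a \code{vesselnet} (or a \code{network_config}, which is
#'   built first).
#' @param by_block return the per-block breakdown instead of the total.
#' @return Integer total, or a named numeric vector of per-block subtotals.
#' @export
count_parameters <- function(model, by_block = FALSE) {
  if (inherits(model, "network_config")) model <- build_model(model)
  if (length(model$params) == 0L) return(0L)
  sizes <- vapply(model$params, length, 1L)
  if (!by_block) return(sum(sizes))
  blocks <- sub("\\..*$", "", names(sizes))
  tapply(sizes, factor(blocks, unique(blocks)), sum)
}

#' Analytic parameter count of a conv + BN + ReLU unit
#'
#' For a same-padded \code{k x k} convolution from \code{ci} to \code{co}
#' channels with bias, followed by batch normalisation over \code{co}
#' channels: \code{k^2 * ci * co + co} convolution parameters and
#' \code{4 * co} BN quantities.
#'
#' @param ci,co input/output channel counts.
#' @param k kernel side (default 3).
#' @param bn include the BN quantities (default FALSE: convolution only).
#' @return Integer parameter count.
#' @export
conv_unit_params <- function(ci, co, k = 3L, bn = FALSE) {
  as.integer(k * k * ci * co + co + if (bn) 4L * co else 0L)
}

#' Layer-by-layer summary table
#'
#' @param model a \code{vesselnet} or \code{network_config}.
#' @return Data frame with block, layer, output size and parameter count per
#'   layer, plus a grand total attribute.
#' @export
layer_table <- function(model) {
  if (inherits(model, "network_config")) model <- build_model(model)
  cfg <- model$config
  fl <- variant_flags(cfg$variant)
  hw <- cfg$input_size[1:2]
  ns <- length(cfg$widths)
  rows <- list()
  add <- function(block, layer, size, params) {
    rows[[length(rows) + 1L]] <<- data.frame(
      block = block, layer = layer,
      output_size = paste0("(", size[1], ", ", size[2], ", ", size[3], ")"),
      params = params, stringsAsFactors = FALSE)
  }
  add("", "input", c(hw, 1L), 0L)
  pl <- function(pfx, s) length(model$params[[paste0(pfx, ".", s)]] %||% numeric(0))
  blkrows <- function(nmk, lab, size) {
    add(lab, paste0(nmk, ".conv 3x3"), size, pl(nmk, "conv_w") + pl(nmk, "conv_b"))
    add(lab, "batch_norm", size,
        pl(nmk, "bn_gamma") + pl(nmk, "bn_beta") + pl(nmk, "bn_rmean") +
          pl(nmk, "bn_rvar"))
    if (fl$resid && pl(nmk, "proj_w") > 0)
      add(lab, "residual proj 1x1", size, pl(nmk, "proj_w"))
    if (fl$se)
      add(lab, paste0("SE gate (r=", cfg$se_reduction, ")"), size,
          pl(nmk, "se_w1") + pl(nmk, "se_w2"))
  }
  for (k in seq_len(ns)) {
    sz <- c(hw %/% 2L^(k - 1L), cfg$widths[k])
    blkrows(paste0("enc", k), paste0("Encoder block (", k, ")"), sz)
    if (k < ns) add(paste0("Encoder block (", k, ")"), "max_pool 2x2",
                    c(hw %/% 2L^k, cfg$widths[k]), 0L)
  }
  blkrows("bridge", "Bridge", c(hw %/% 2L^(ns - 1L), cfg$widths[ns]))
  for (k in seq_len(ns - 1L)) {
    nmk <- paste0("dec", k)
    sz <- c(hw %/% 2L^(ns - 1L - k), cfg$widths[ns - k])
    add(paste0("Decoder block (", k, ")"),
        if (cfg$upsample_mode == "transposed_conv") "up_conv 2x2 (transposed)"
        else "nearest up + conv 1x1", sz, pl(nmk, "up_w") + pl(nmk, "up_b"))
    blkrows(nmk, paste0("Decoder block (", k, ")"), sz)
  }
  add("", "head conv 1x1 + sigmoid", c(hw, 1L),
      pl("head", "conv_w") + pl("head", "conv_b"))
  out <- do.call(rbind, rows)
  attr(out, "total") <- count_parameters(model)
  out
}
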