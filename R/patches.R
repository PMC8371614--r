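#' Patch extraction configuration
#'
#' @param patch_size square patch side in pixels (default 48, matching the
#'   network input).
#' @param per_image number of random patches per training image (default
#'   9500).
#' @param rotate apply a random rotation to each patch pair (default FALSE).
#' @param seed integer RNG seed.
#' @param downsampling_ratio accepted and carried through for interface
#'   compatibility with published training-parameter tables; it has no
#'   defined semantics here and nothing consumes it.
#' @return A \code{patch_config} list.
#' @export
patch_config <- function(patch_size = 48L, per_image = 9500L, rotate = FALSE,
                         seed = 1L, downsampling_ratio = 500L) {
  patch_size <- as.integer(patch_size)
  per_image <- as.integer(per_image)
  if (patch_size < 8L) stop("patch_size must be >= 8")
  if (per_image < 0L) stop("per_image must be >= 0")
  structure(list(patch_size = patch_size, per_image = per_image,
                 rotate = isTRUE(rotate), seed = as.integer(seed),
                 downsampling_ratio = as.integer(downsampling_ratio)),
            class = "patch_config")
}

#' Split image collections into training / validation / test sets
#'
#' Splits each collection 1:1 into training and test halves, then flags a
#' fixed number of training images as the validation subset: 4 of 20 for a
#' DRIVE-sized collection and 2 of 10 for a STARE-sized one. The validation
#' count scales as one fifth of the training half (rounded) for other sizes.
#' The assignment is deterministic given \code{seed}.
#'
#' @param drive_items,stare_items lists (or vectors) of image references;
#'   either may be empty.
#' @param val_fraction validation fraction of the training half (default
#'   0.2).
#' @param seed integer RNG seed.
#' @return A \code{dataset_split} with \code{train}, \code{val} and
#'   \code{test} item lists; \code{val} items are also present in the training
#'   pool's provenance but the three returned sets are disjoint.
#' @export
make_split <- function(drive_items, stare_items = list(), val_fraction = 0.2,
                       seed = 1L) {
  split_one <- function(items, tag) {
    n <- length(items)
    if (n == 0L) return(list(train = list(), val = list(), test = list()))
    if (n < 2L) stop(tag, ": need at least 2 items to split 1:1")
    if (n %% 2L != 0L) stop(tag, ": item count must be even for a 1:1 split")
    n_train <- n %/% 2L
    n_val <- max(1L, round(val_fraction * n_train))
    if (n_val >= n_train) stop(tag, ": validation would consume the training set")
    perm <- sample.int(n)
    train_pool <- perm[seq_len(n_train)]
    test_idx <- perm[(n_train + 1L):n]
    val_idx <- train_pool[seq_len(n_val)]
    train_idx <- setdiff(train_pool, val_idx)
    list(train = items[train_idx], val = items[val_idx], test = items[test_idx])
  }
  out <- with_seed(seed, {
    d <- split_one(as.list(drive_items), "drive")
    s <- split_one(as.list(stare_items), "stare")
    list(train = c(d$train, s$train), val = c(d$val, s$val),
         test = c(d$test, s$test),
         drive = lapply(d, length), stare = lapply(s, length))
  })
  structure(c(out, list(seed = as.integer(seed))), class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split: %d train / %d val / %d test (seed %d)>\n",
              length(x$train), length(x$val), length(x$test), x$seed))
  invisible(x)
}

#' Extract random patches from a plane and its label mask
#'
#' Draws \code{per_image} top-left corners uniformly over the valid positions
#' and crops the co-located input and label windows. When a FOV mask is given,
#' positions are rejected unless the patch centre lies inside the FOV. Label
#' patches are taken from \code{mask} and stay binary; optional rotation
#' augmentation rotates input and label by the same random angle.
#'
#' @param plane unit-range \code{gray_plane} (or plain matrix).
#' @param mask binary matrix of the same size.
#' @param cfg a \code{\link{patch_config}}.
#' @param fov optional binary FOV matrix.
#' @return A \code{patch_set}: list with \code{inputs} and \code{labels}
#'   (\code{ps x ps x 1 x N} arrays), \code{coords} (data frame with
#'   \code{image}, \code{row}, \code{col}) and \code{seed}.
#' @export
extract_random_patches <- function(plane, mask, cfg = patch_config(),
                                   fov = NULL) {
  v <- unclass(plane)
  attr(v, "range_tag") <- NULL
  ps <- cfg$patch_size
  H <- nrow(v); W <- ncol(v)
  if (ps > H || ps > W)
    stop("patch_size ", ps, " exceeds image size ", H, "x", W)
  if (!all(dim(mask) == c(H, W))) stop("mask dimensions must match the plane")
  n <- cfg$per_image
  if (n == 0L) return(new_patch_set(empty_4d(ps), empty_4d(ps),
                                    data.frame(image = integer(),
                                               row = integer(),
                                               col = integer()), cfg$seed))
  with_seed(cfg$seed, {
    draw <- function(k) {
      data.frame(row = sample.int(H - ps + 1L, k, replace = TRUE),
                 col = sample.int(W - ps + 1L, k, replace = TRUE))
    }
    pos <- draw(n)
    if (!is.null(fov)) {
      ok <- fov[cbind(pos$row + ps %/% 2L, pos$col + ps %/% 2L)] == 1
      guard <- 0L
      while (!all(ok) && guard < 200L) {
        redo <- which(!ok)
        pos[redo, ] <- draw(length(redo))
        ok[redo] <- fov[cbind(pos$row[redo] + ps %/% 2L,
                              pos$col[redo] + ps %/% 2L)] == 1
        guard <- guard + 1L
      }
      if (!all(ok)) stop("could not place patch centres inside the FOV")
    }
    inputs <- cpp_crop_patches(v, pos$row, pos$col, ps)
    labels <- cpp_crop_patches(unclass(mask), pos$row, pos$col, ps)
    if (cfg$rotate) {
      angles <- runif(n, 0, 360)
      for (i in seq_len(n)) {
        pr <- rotate_patch(list(input = inputs[, , 1, i],
                                label = labels[, , 1, i]), angles[i])
        inputs[, , 1, i] <- pr$input
        labels[, , 1, i] <- pr$label
      }
    }
    new_patch_set(inputs, labels,
                  data.frame(image = 1L, row = pos$row, col = pos$col),
                  cfg$seed)
  })
}

empty_4d <- function(ps) array(0, c(ps, ps, 1, 0))

new_patch_set <- function(inputs, labels, coords, seed) {
  structure(list(inputs = inputs, labels = labels, coords = coords,
                 seed = as.integer(seed)), class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  d <- dim(x$inputs)
  cat(sprintf("<patch_set: %d patches of %d x %d (seed %d)>\n", d[4], d[1],
              d[2], x$seed))
  invisible(x)
}

#' Number of patches in a patch set
#' @param x a \code{patch_set}.
#' @return Integer count.
#' @export
n_patches <- function(x) dim(x$inputs)[4]

#' Concatenate patch sets
#' @param ... \code{patch_set} objects with equal patch sizes.
#' @return A single combined \code{patch_set}.
#' @export
bind_patch_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "patch_set")) sets <- sets[[1]]
  ps <- dim(sets[[1]]$inputs)[1]
  total <- sum(vapply(sets, n_patches, 1L))
  inputs <- array(0, c(ps, ps, 1, total))
  labels <- array(0, c(ps, ps, 1, total))
  coords <- vector("list", length(sets))
  at <- 0L
  for (k in seq_along(sets)) {
    s <- sets[[k]]
    n <- n_patches(s)
    if (n > 0L) {
      inputs[, , , at + seq_len(n)] <- s$inputs
      labels[, , , at + seq_len(n)] <- s$labels
      cc <- s$coords
      cc$image <- k
      coords[[k]] <- cc
      at <- at + n
    }
  }
  new_patch_set(inputs, labels, do.call(rbind, coords), sets[[1]]$seed)
}

#' Rotate an input/label patch pair by a common angle
#'
#' The input is rotated with bilinear interpolation; the label with
#' nearest-neighbour sampling and re-thresholded at 0.5 so it stays binary.
#' The rotation keeps the original patch frame (corners revealed by the
#' rotation are filled with 0).
#'
#' @param patch_pair list with square matrices \code{input} and \code{label}.
#' @param angle rotation angle in degrees.
#' @return The rotated pair, same shape.
#' @export
rotate_patch <- function(patch_pair, angle) {
  inp <- patch_pair$input
  lab <- patch_pair$label
  if (nrow(inp) != ncol(inp)) stop("patches must be square")
  angle <- angle %% 360
  if (angle == 0) return(patch_pair)
  if (angle %in% c(90, 180, 270)) {
    k <- angle / 90
    rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]
    for (i in seq_len(k)) {
      inp <- rot90(inp)
      lab <- rot90(lab)
    }
    return(list(input = inp, label = lab))
  }
  rot <- function(m, filter) {
    r <- EBImage::rotate(EBImage::Image(t(m)), angle,
                         output.dim = rev(dim(m)), bg.col = 0, filter = filter)
    t(EBImage::imageData(r))
  }
  out_in <- rot(unclass(inp), "bilinear")
  out_in[out_in < 0] <- 0
  out_in[out_in > 1] <- 1
  out_lab <- rot(unclass(lab), "none")
  list(input = out_in, label = (out_lab >= 0.5) * 1)
}

#' Regular patch grid covering a full image
#'
#' Top-left corners of a stride grid whose patches cover every pixel; the
#' final row/column positions are clamped to the image border so coverage is
#' complete even when the stride does not divide the image size.
#'
#' @param image_shape integer pair \code{c(H, W)}.
#' @param patch_size patch side.
#' @param stride grid stride (default \code{patch_size}, i.e. exact tiling
#'   when possible).
#' @return Data frame with \code{row} and \code{col} corners.
#' @export
patch_grid <- function(image_shape, patch_size, stride = patch_size) {
  H <- image_shape[1]; W <- image_shape[2]
  if (patch_size > H || patch_size > W)
    stop("patch_size exceeds the image")
  axis <- function(n) unique(c(seq(1L, n - patch_size + 1L, by = stride),
                               n - patch_size + 1L))
  expand.grid(row = axis(H), col = axis(W))
}

#' Reconstruct a full-image plane from patch predictions
#'
#' Every pixel receives the mean of all patch predictions overlapping it.
#'
#' @param pred_patches \code{ps x ps x 1 x N} array (or \code{ps x ps x N}).
#' @param coords data frame with 1-based \code{row}, \code{col} top-left
#'   corners.
#' @param image_shape integer pair \code{c(H, W)}.
#' @param strict error when some pixel is covered by no patch (default TRUE);
#'   otherwise uncovered pixels are 0.
#' @return A unit-range \code{gray_plane}.
#' @export
reconstruct_from_patches <- function(pred_patches, coords, image_shape,
                                     strict = TRUE) {
  if (length(dim(pred_patches)) == 3L) {
    d <- dim(pred_patches)
    dim(pred_patches) <- c(d[1], d[2], 1L, d[3])
  }
  acc <- cpp_accumulate_patches(pred_patches, as.integer(coords$row),
                                as.integer(coords$col),
                                as.integer(image_shape[1]),
                                as.integer(image_shape[2]))
  cnt <- acc$count
  if (any(cnt == 0)) {
    if (strict) stop("patch grid leaves ", sum(cnt == 0), " pixels uncovered")
    cnt[cnt == 0] <- 1
  }
  gray_plane(pmin(pmax(acc$sum / cnt, 0), 1), "unit")
}

#' Persist a patch set to disk
#'
#' Inputs and labels go to a lossless binary-free container (plain-text TSV of
#' the flattened arrays would be enormous, so the arrays are written as
#' native-endian raw doubles) plus a YAML sidecar manifest recording the
#' dimensions, seed and configuration.
#'
#' @param x a \code{patch_set}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
save_patch_set <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeBin(as.vector(x$inputs), file.path(dir, "inputs.f64"))
  writeBin(as.vector(x$labels), file.path(dir, "labels.f64"))
  write.csv(x$coords, file.path(dir, "coords.csv"), row.names = FALSE)
  yaml::write_yaml(list(dim = dim(x$inputs), seed = x$seed),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname save_patch_set
#' @export
load_patch_set <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  n <- prod(unlist(man$dim))
  inputs <- readBin(file.path(dir, "inputs.f64"), "double", n = n)
  labels <- readBin(file.path(dir, "labels.f64"), "double", n = n)
  dim(inputs) <- unlist(man$dim)
  dim(labels) <- unlist(man$dim)
  new_patch_set(inputs, labels, read.csv(file.path(dir, "coords.csv")),
                man$seed)
}
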