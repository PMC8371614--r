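#' Synthetic fundus configuration
#'
#' Parameters of the synthetic fundus generator: a circular field of view on
#' a dark background, a branching vessel tree darker than its surround in
#' the green channel, radial illumination falloff and additive Gaussian
#' noise. Defaults aim for vessels covering roughly a tenth of the FOV, the
#' class balance typical of real fundus photographs.
#'
#' @param image_size integer pair \code{c(H, W)} (default 128 x 128).
#' @param n_trees minimum number of vessel trees grown from the disc region
#'   (default 6; more are added until \code{target_vessel_fraction} is
#'   approached).
#' @param branch_prob probability a segment bifurcates (default 0.35).
#' @param vessel_width_range pixel pair: terminal and root vessel widths
#'   (default \code{c(1.5, 4)}).
#' @param target_vessel_fraction desired vessel share of FOV pixels
#'   (default 0.10; must be in (0, 0.5)).
#' @param noise_sd additive Gaussian noise sd on the unit intensity scale
#'   (default 0.03).
#' @param illumination_gradient strength of the radial illumination falloff
#'   (default 0.25; 0 disables it).
#' @param vessel_contrast how much darker the vessel core is than the local
#'   background (default 0.35).
#' @param seed integer seed; generation is bitwise deterministic in it.
#' @return A \code{synth_config} list.
#' @export
synth_config <- function(image_size = c(128L, 128L), n_trees = 6L,
                         branch_prob = 0.35,
                         vessel_width_range = c(1.5, 4),
                         target_vessel_fraction = 0.10, noise_sd = 0.03,
                         illumination_gradient = 0.25,
                         vessel_contrast = 0.35, seed = 1L) {
  if (target_vessel_fraction <= 0 || target_vessel_fraction >= 0.5)
    stop("target_vessel_fraction must be in (0, 0.5)")
  if (any(vessel_width_range < 1)) stop("vessel widths must be >= 1 pixel")
  structure(list(image_size = as.integer(image_size),
                 n_trees = as.integer(n_trees), branch_prob = branch_prob,
                 vessel_width_range = vessel_width_range,
                 target_vessel_fraction = target_vessel_fraction,
                 noise_sd = noise_sd,
                 illumination_gradient = illumination_gradient,
                 vessel_contrast = vessel_contrast,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# grow one vessel tree; stamps Gaussian cross-sections along quadratic
# Bezier segments (max-composited in C++ so crossings do not thicken)
grow_tree <- function(D, p0, ang0, wid0, cfg, centre, R) {
  wmin <- cfg$vessel_width_range[1]
  stack <- list(list(p = p0, ang = ang0, wid = wid0, depth = 0L))
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (nd$wid < wmin || nd$depth > 9L) next
    len <- runif(1, 0.12, 0.25) * R
    p2 <- nd$p + len * c(cos(nd$ang), sin(nd$ang))
    mid <- (nd$p + p2) / 2 +
      runif(1, -0.25, 0.25) * len * c(-sin(nd$ang), cos(nd$ang))
    ts <- seq(0, 1, length.out = max(4L, ceiling(2 * len)))
    qy <- (1 - ts)^2 * nd$p[1] + 2 * ts * (1 - ts) * mid[1] + ts^2 * p2[1]
    qx <- (1 - ts)^2 * nd$p[2] + 2 * ts * (1 - ts) * mid[2] + ts^2 * p2[2]
    inside <- (qy - centre[1])^2 + (qx - centre[2])^2 <= (1.02 * R)^2
    ncut <- if (all(inside)) length(ts) else which(!inside)[1] - 1L
    if (ncut > 0L) {
      keep <- seq_len(ncut)
      cpp_stamp_curve(D, qy[keep], qx[keep],
                      nd$wid * (1 - 0.2 * ts[keep]))
    }
    if (ncut < length(ts)) next   # left the FOV: stop this branch
    if (runif(1) < cfg$branch_prob) {
      split <- runif(1, 15, 40) * pi / 180
      for (s in c(-1, 1))
        stack[[length(stack) + 1L]] <-
          list(p = p2, ang = nd$ang + s * split,
               wid = nd$wid * runif(1, 0.6, 0.85), depth = nd$depth + 1L)
    } else {
      stack[[length(stack) + 1L]] <-
        list(p = p2, ang = nd$ang + runif(1, -0.35, 0.35),
             wid = nd$wid * 0.92, depth = nd$depth + 1L)
    }
  }
  D
}

#' Generate one synthetic fundus image with ground truth
#'
#' Draws a circular FOV disc, grows branching vessel trees as quadratic
#' Bezier curves with Gaussian cross-sections and tapering width, and
#' composes RGB channels in which the green plane carries the strongest
#' vessel contrast (dark vessels on a brighter, radially shaded background
#' with additive noise). The vessel mask is the exact rasterised tree.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @return A list with \code{image} (a \code{\link{fundus_image}}),
#'   \code{mask} (binary vessel ground truth) and \code{fov} (binary FOV
#'   disc).
#' @export
generate_fundus <- function(cfg = synth_config()) {
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  centre <- c(H, W) / 2
  R <- 0.47 * min(H, W)
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  r2 <- (yy - centre[1])^2 + (xx - centre[2])^2
  fov <- (r2 <= R^2) * 1
  with_seed(cfg$seed, {
    D <- matrix(0, H, W)
    if (cfg$n_trees > 0L) {
      frac <- function() sum((D > 0.5) & (fov == 1)) / sum(fov == 1)
      disc <- centre + c(0, 0.55 * R)   # optic-disc-like origin, right of centre
      k <- 0L
      while (k < cfg$n_trees ||
             (frac() < 0.85 * cfg$target_vessel_fraction && k < 6L * cfg$n_trees)) {
        k <- k + 1L
        root_ang <- runif(1, 0, 2 * pi)
        p0 <- disc + 0.08 * R * c(cos(root_ang), sin(root_ang))
        aim <- atan2(centre[1] - p0[1] + runif(1, -0.6, 0.6) * R,
                     centre[2] - p0[2] + runif(1, -0.6, 0.6) * R)
        ang <- atan2(sin(aim), cos(aim))
        ang <- runif(1, 0, 2 * pi) * 0.3 + ang * 0.7
        wid <- runif(1, 0.7, 1) * cfg$vessel_width_range[2]
        D <- grow_tree(D, p0, ang, wid, cfg, centre, R)
      }
    }
    mask <- ((D > 0.5) & (fov == 1)) * 1
    shade <- 1 - cfg$illumination_gradient * (r2 / R^2)
    noise <- if (cfg$noise_sd > 0) matrix(rnorm(H * W), H, W) else
      matrix(0, H, W)
    clip01 <- function(m) pmin(pmax(m, 0), 1)
    green <- clip01((0.55 * shade - cfg$vessel_contrast * D +
                       cfg$noise_sd * noise) * fov + 0.02 * (1 - fov))
    red <- clip01((0.80 * shade - 0.12 * D + 0.7 * cfg$noise_sd * noise) *
                    fov + 0.02 * (1 - fov))
    blue <- clip01((0.20 * shade - 0.05 * D + 0.5 * cfg$noise_sd * noise) *
                     fov + 0.02 * (1 - fov))
    px <- array(0, c(H, W, 3))
    px[, , 1] <- round(255 * red)
    px[, , 2] <- round(255 * green)
    px[, , 3] <- round(255 * blue)
    list(image = fundus_image(px, fov_mask = fov,
                              source_id = paste0("synth-", cfg$seed)),
         mask = mask, fov = fov)
  })
}

#' Generate a synthetic two-collection dataset
#'
#' Produces \code{n_drive_like} images at DRIVE-like resolution (584 x 565)
#' and \code{n_stare_like} at STARE-like resolution (605 x 700), or at a
#' common scaled-down size for fast pipelines.
#'
#' @param n_drive_like,n_stare_like item counts (either may be 0).
#' @param cfg base \code{\link{synth_config}}; item i uses seed
#'   \code{cfg$seed + i}.
#' @param sizes list with \code{drive} and \code{stare} \code{c(H, W)}
#'   pairs; pass e.g. \code{list(drive = c(96, 96), stare = c(96, 96))} for
#'   quick mode.
#' @return A list of items, each with \code{image}, \code{mask}, \code{fov},
#'   \code{id} and \code{dataset}.
#' @export
generate_dataset <- function(n_drive_like, n_stare_like,
                             cfg = synth_config(),
                             sizes = list(drive = c(584L, 565L),
                                          stare = c(605L, 700L))) {
  items <- list()
  mk <- function(i, ds, size) {
    ci <- cfg
    ci$image_size <- as.integer(size)
    ci$seed <- cfg$seed + i
    out <- generate_fundus(ci)
    out$id <- sprintf("%s_%02d", ds, i)
    out$dataset <- ds
    out
  }
  for (i in seq_len(n_drive_like))
    items[[length(items) + 1L]] <- mk(i, "drive", sizes$drive)
  for (i in seq_len(n_stare_like))
    items[[length(items) + 1L]] <- mk(n_drive_like + i, "stare", sizes$stare)
  items
}

#' Write a synthetic dataset to disk as PNG triplets
#'
#' @param items result of \code{\link{generate_dataset}}.
#' @param dir output directory.
#' @return The manifest data frame, invisibly.
#' @export
write_dataset <- function(items, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(items, function(it) {
    base <- file.path(dir, it$id)
    write_image_png(it$image$pixels / 255, paste0(base, "_image.png"))
    write_image_png(it$mask, paste0(base, "_mask.png"))
    write_image_png(it$fov, paste0(base, "_fov.png"))
    data.frame(id = it$id, dataset = it$dataset,
               H = nrow(it$mask), W = ncol(it$mask))
  })
  man <- do.call(rbind, rows)
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
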