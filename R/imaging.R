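#' Construct a fundus image object
#'
#' Bundles an RGB fundus photograph with an optional binary field-of-view
#' (FOV) mask and a source label. Pixel intensities are integers in
#' \code{[0, 255]}; the FOV mask marks the circular camera aperture.
#'
#' @param pixels numeric \code{H x W x 3} array of intensities in
#'   \code{[0, 255]}.
#' @param fov_mask optional \code{H x W} matrix with values in \code{{0, 1}}.
#' @param source_id character label identifying the image.
#' @return An object of class \code{fundus_image}.
#' @export
fundus_image <- function(pixels, fov_mask = NULL, source_id = "image") {
  pixels <- unclass(pixels)
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("fundus images must have exactly 3 channels (got ",
         paste(dim(pixels), collapse = "x"), ")")
  d <- dim(pixels)
  if (d[1] < 48L || d[2] < 48L)
    stop("fundus images must be at least 48x48 pixels")
  if (any(pixels < 0 | pixels > 255))
    stop("pixel intensities must lie in [0, 255]")
  if (!is.null(fov_mask)) {
    fov_mask <- unclass(fov_mask)
    if (!all(dim(fov_mask) == d[1:2]))
      stop("fov_mask dimensions must match the image")
    if (!all(fov_mask %in% c(0, 1))) stop("fov_mask must be binary")
    storage.mode(fov_mask) <- "double"
  }
  structure(list(pixels = pixels, fov_mask = fov_mask,
                 source_id = as.character(source_id)),
            class = "fundus_image")
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fundus_image '%s': %d x %d, %s FOV mask>\n", x$source_id,
              d[1], d[2], if (is.null(x$fov_mask)) "no" else "with"))
  invisible(x)
}

#' Split an RGB fundus image into colour planes
#'
#' The green channel shows the strongest vessel/background contrast in fundus
#' photography and is the designated input for the rest of the pipeline.
#'
#' @param img a \code{\link{fundus_image}}.
#' @return A list with elements \code{red}, \code{green}, \code{blue}, each a
#'   \code{gray_plane} in the raw \code{[0, 255]} range.
#' @export
split_channels <- function(img) {
  if (!inherits(img, "fundus_image")) img <- fundus_image(img)
  list(red   = gray_plane(img$pixels[, , 1], "raw"),
       green = gray_plane(img$pixels[, , 2], "raw"),
       blue  = gray_plane(img$pixels[, , 3], "raw"))
}

#' Single-channel intensity plane
#'
#' @param values numeric matrix of intensities.
#' @param range_tag \code{"raw"} for \code{[0, 255]} data or \code{"unit"} for
#'   \code{[0, 1]} data.
#' @return A \code{gray_plane}: the matrix with a \code{range_tag} attribute.
#' @export
gray_plane <- function(values, range_tag = c("raw", "unit")) {
  range_tag <- match.arg(range_tag)
  values <- as.matrix(unclass(values))
  if (range_tag == "unit" && length(values) &&
      (min(values) < -1e-9 || max(values) > 1 + 1e-9))
    stop("unit-range plane has values outside [0, 1]")
  structure(values, range_tag = range_tag, class = c("gray_plane", "matrix"))
}

#' @export
print.gray_plane <- function(x, ...) {
  cat(sprintf("<gray_plane %d x %d (%s), range [%.4g, %.4g]>\n", nrow(x),
              ncol(x), attr(x, "range_tag"), min(x), max(x)))
  invisible(x)
}

#' Standardise then min-max normalise an intensity plane
#'
#' Centres and scales the plane to zero mean and unit variance, then linearly
#' maps it onto \code{[0, 1]}. The composition is a monotone map that is
#' invariant to any affine rescaling of the input. A constant plane carries no
#' contrast; it is returned as all zeros with a warning so that batch
#' pipelines survive blank border images.
#'
#' @param p a \code{gray_plane}.
#' @param fov optional binary matrix; when supplied the statistics are
#'   computed over FOV pixels only (the whole plane is still transformed).
#' @return A unit-range \code{gray_plane} with minimum 0 and maximum 1.
#' @export
standardize_normalize <- function(p, fov = NULL) {
  v <- unclass(p)
  attr(v, "range_tag") <- NULL
  sel <- if (is.null(fov)) v else v[fov == 1]
  if (length(unique(as.vector(sel))) < 2L) {
    warning("constant intensity plane: returning all zeros")
    return(gray_plane(array(0, dim(v)), "unit"))
  }
  z <- (v - mean(sel)) / sd(sel)
  zr <- if (is.null(fov)) range(z) else range(z[fov == 1])
  out <- (z - zr[1]) / (zr[2] - zr[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  gray_plane(out, "unit")
}

#' Gamma (power-law) intensity transform
#'
#' Applies \code{V_out = A * V_in^gamma} elementwise. With \code{A = 1} the
#' transform maps \code{[0, 1]} onto itself monotonically; \code{gamma < 1}
#' brightens mid-tones, \code{gamma > 1} darkens them.
#'
#' @param p unit-range \code{gray_plane}.
#' @param gamma positive grayscale scaling exponent.
#' @param A positive scale constant (default 1).
#' @return A \code{gray_plane}; unit-tagged when \code{A = 1}.
#' @export
gamma_transform <- function(p, gamma = 1.2, A = 1) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("gamma must be a positive scalar")
  if (!is.numeric(A) || length(A) != 1L || A <= 0)
    stop("A must be a positive scalar")
  v <- unclass(p)
  attr(v, "range_tag") <- NULL
  out <- A * v^gamma
  gray_plane(out, if (A == 1) "unit" else "raw")
}

#' Contrast-limited adaptive histogram equalisation
#'
#' Local contrast enhancement on a tile grid with a clip limit that caps how
#' far any local histogram may be flattened, preventing noise amplification.
#' Delegates to \code{EBImage::clahe}.
#'
#' @param p unit-range \code{gray_plane}.
#' @param clip_limit positive clipping factor (default 2).
#' @param tile_grid integer pair: number of tiles in x and y (default
#'   \code{c(8, 8)}).
#' @return A unit-range \code{gray_plane}.
#' @export
clahe_enhance <- function(p, clip_limit = 2, tile_grid = c(8, 8)) {
  if (clip_limit <= 0) stop("clip_limit must be positive")
  tile_grid <- rep_len(as.integer(tile_grid), 2L)
  if (any(tile_grid < 1L)) stop("tile_grid entries must be >= 1")
  v <- unclass(p)
  attr(v, "range_tag") <- NULL
  if (any(dim(v) < tile_grid))
    stop("tile grid is finer than the image itself")
  # EBImage stores x (width) first; transpose so nx tiles run along columns
  out <- EBImage::clahe(EBImage::Image(t(v)), nx = tile_grid[1],
                        ny = tile_grid[2], limit = clip_limit)
  out <- t(EBImage::imageData(out))
  out[out < 0] <- 0
  out[out > 1] <- 1
  gray_plane(out, "unit")
}

#' Green-channel preprocessing pipeline
#'
#' Runs the full intensity pipeline on a fundus image: optional external
#' pre-enhancement hook, green-channel extraction, standardise/normalise,
#' gamma correction and CLAHE (in that order by default).
#'
#' @param img a \code{\link{fundus_image}}.
#' @param gamma,A gamma-transform parameters (see
#'   \code{\link{gamma_transform}}).
#' @param clip_limit,tile_grid CLAHE parameters; set
#'   \code{clahe = FALSE} to skip the CLAHE stage.
#' @param clahe logical: apply CLAHE? (default \code{TRUE}).
#' @param clahe_first logical: apply CLAHE before the gamma transform instead
#'   of after it.
#' @param fov_restrict logical: compute normalisation statistics over FOV
#'   pixels only.
#' @param enhance_hook optional function or external command (see
#'   \code{\link{apply_enhance_hook}}); \code{NULL} disables it.
#' @return A unit-range \code{gray_plane}.
#' @export
preprocess_pipeline <- function(img, gamma = 1.2, A = 1, clip_limit = 2,
                                tile_grid = c(8, 8), clahe = TRUE,
                                clahe_first = FALSE, fov_restrict = FALSE,
                                enhance_hook = NULL) {
  if (!inherits(img, "fundus_image")) img <- fundus_image(img)
  if (!is.null(enhance_hook)) img <- apply_enhance_hook(img, enhance_hook)
  g <- split_channels(img)$green
  fov <- if (fov_restrict) img$fov_mask else NULL
  p <- standardize_normalize(g, fov = fov)
  if (clahe && clahe_first)
    p <- clahe_enhance(p, clip_limit = clip_limit, tile_grid = tile_grid)
  p <- gamma_transform(p, gamma = gamma, A = A)
  if (clahe && !clahe_first)
    p <- clahe_enhance(p, clip_limit = clip_limit, tile_grid = tile_grid)
  p
}

#' Optional pre-enhancement hook
#'
#' Plug-in point for an external detail-enhancement step (for instance a
#' super-resolution tool) run before the intensity pipeline. A function hook
#' receives and returns a \code{fundus_image}; a character hook is treated as
#' a shell command template containing \code{\%in\%} and \code{\%out\%}
#' placeholders for PNG paths.
#'
#' @param img a \code{fundus_image}.
#' @param hook function or command template.
#' @return The enhanced \code{fundus_image}.
#' @export
apply_enhance_hook <- function(img, hook) {
  if (is.function(hook)) return(hook(img))
  if (!is.character(hook)) stop("hook must be a function or command string")
  fin <- tempfile(fileext = ".png")
  fout <- tempfile(fileext = ".png")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  write_image_png(img$pixels / 255, fin)
  cmd <- gsub("%out%", shQuote(fout), gsub("%in%", shQuote(fin), hook,
                                           fixed = TRUE), fixed = TRUE)
  status <- system(cmd)
  if (status != 0 || !file.exists(fout))
    stop("enhancement hook failed (exit status ", status, ")")
  px <- read_image_any(fout)
  fundus_image(px * 255, fov_mask = img$fov_mask, source_id = img$source_id)
}

# ---- image file IO ---------------------------------------------------------

#' Read an image file
#'
#' Reads PNG, TIFF or JPEG via EBImage and PPM/PGM (P2/P3/P5/P6) via a small
#' built-in parser. Returns intensities in \code{[0, 1]} as a matrix
#' (grayscale) or \code{H x W x C} array.
#'
#' @param path file path.
#' @return Numeric matrix or array in \code{[0, 1]}.
#' @export
read_image_any <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ppm", "pgm")) return(read_ppm(path))
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  # EBImage stores x (width) as the first dimension; convert to row = y
  if (length(dim(dat)) == 2L) t(dat) else aperm(dat, c(2, 1, 3))[, , 1:min(3, dim(dat)[3]), drop = FALSE]
}

#' Read a PPM/PGM image
#'
#' Minimal reader for the netpbm formats P2/P3 (ASCII) and P5/P6 (binary),
#' the container used by classic retinal-image collections.
#'
#' @param path file path.
#' @return Numeric matrix (PGM) or \code{H x W x 3} array (PPM) in
#'   \code{[0, 1]}.
#' @export
read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  tok <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (!length(ch)) stop("unexpected end of PPM header")
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (!length(ch) || ch == "\n") break
        }
      } else if (!grepl("[ \t\r\n]", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (!length(ch) || grepl("[ \t\r\n]", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  magic <- tok()
  if (!magic %in% c("P2", "P3", "P5", "P6")) stop("unsupported netpbm type: ", magic)
  w <- as.integer(tok()); h <- as.integer(tok()); maxv <- as.integer(tok())
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  vals <- if (magic %in% c("P5", "P6")) {
    as.numeric(readBin(con, "integer", n = n, size = if (maxv < 256) 1 else 2,
                       signed = FALSE, endian = "big"))
  } else {
    out <- numeric(0)
    while (length(out) < n) {
      line <- readLines(con, n = 1L)
      if (!length(line)) break
      out <- c(out, as.numeric(strsplit(trimws(line), "[ \t]+")[[1]]))
    }
    out
  }
  if (length(vals) < n) stop("truncated PPM payload")
  vals <- vals[seq_len(n)] / maxv
  if (nch == 1L) {
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else {
    a <- array(0, c(h, w, 3))
    for (c in 1:3) a[, , c] <- matrix(vals[seq(c, n, by = 3)], nrow = h,
                                      ncol = w, byrow = TRUE)
    a
  }
}

#' Write a plane or RGB array as 8-bit PNG
#'
#' @param x matrix or \code{H x W x 3} array in \code{[0, 1]}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_image_png <- function(x, path) {
  x <- unclass(x)
  attr(x, "range_tag") <- NULL
  x[x < 0] <- 0
  x[x > 1] <- 1
  png::writePNG(x, path)
  invisible(path)
}

#' Write a numeric plane losslessly
#'
#' Stores a floating-point plane as a plain-text TSV with full precision, for
#' interchange of preprocessed planes and probability maps.
#'
#' @param p matrix (e.g. a \code{gray_plane}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_plane_tsv <- function(p, path) {
  write.table(format(unclass(p), digits = 17, trim = TRUE, scientific = TRUE),
              path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_plane_tsv
#' @export
read_plane_tsv <- function(path) {
  gray_plane_guess(as.matrix(read.table(path, sep = "\t")))
}

gray_plane_guess <- function(m) {
  dimnames(m) <- NULL
  gray_plane(m, if (max(m) <= 1 + 1e-9) "unit" else "raw")
}
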