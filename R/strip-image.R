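# Synthetic strip-image generation and the classical processing chain that
# extracts a mean RGB per reagent pad.
#
# Images are plain numeric arrays, height x width x 3, 8-bit channel values
# (0-255), row-major with the origin at the top-left. The processing chain is:
# Gaussian smoothing -> highlight suppression (weighted superposition with a
# blurred copy) -> grayscale -> Otsu binarization -> morphological opening and
# closing -> Canny edge extraction -> connected pad regions -> mean RGB over a
# 15 x 15 patch at each pad center, computed on the pre-binarization color
# image. Standard morphology and labelling are delegated to EBImage; Otsu and
# Canny are implemented here.

#' Describe a synthetic strip layout
#'
#' Defaults emulate a common urinalysis strip: 11 square reagent pads in a
#' horizontal row on a light plastic carrier.
#'
#' @param n_pads number of reagent pads (>= 1); default 11.
#' @param pad_size pad side length in pixels; default 40.
#' @param spacing gap between adjacent pads in pixels; default 24.
#' @param margin left/right margin in pixels; default 30.
#' @param height image height in pixels; default 120.
#' @param background carrier gray level (0-255); default 230 (light plastic).
#' @return an object of class `strip_layout` with the derived image `width`.
#' @export
strip_layout <- function(n_pads = 11, pad_size = 40, spacing = 24,
                         margin = 30, height = 120, background = 230) {
  n_pads <- as.integer(n_pads)
  if (n_pads < 1L) stop("n_pads must be >= 1", call. = FALSE)
  width <- 2L * margin + n_pads * pad_size + (n_pads - 1L) * spacing
  if (pad_size > height)
    stop("pads overflow the image height", call. = FALSE)
  if (height < 64L || width < 64L)
    stop("image must be at least 64 x 64 for processing", call. = FALSE)
  structure(list(n_pads = n_pads, pad_size = as.integer(pad_size),
                 spacing = as.integer(spacing), margin = as.integer(margin),
                 height = as.integer(height), width = as.integer(width),
                 background = background),
            class = "strip_layout")
}

# Pad top-left corners (row, col), 1-based
.pad_positions <- function(layout) {
  top <- as.integer((layout$height - layout$pad_size) %/% 2) + 1L
  lefts <- layout$margin + 1L +
    (seq_len(layout$n_pads) - 1L) * (layout$pad_size + layout$spacing)
  list(top = top, lefts = lefts)
}

#' Generate a synthetic test-strip image
#'
#' Renders uniform colored reagent pads on a light carrier, then adds i.i.d.
#' Gaussian sensor noise and, optionally, one localized elliptical specular
#' highlight. Reagent pads are matte, so the default highlight sits on the
#' glossy plastic carrier between the strip edge and the pad row. The result
#' is quantized to 8 bits and fully reproducible from `seed`.
#'
#' @param layout a [strip_layout()].
#' @param pad_colors matrix (n_pads x 3) or list of RGB triples, 0-255.
#' @param noise_sd Gaussian sensor noise standard deviation; default 5.
#' @param highlight `"auto"` (default) for one specular glint on the carrier,
#'   `NULL` for none, or a list with `center = c(row, col)`,
#'   `radii = c(row_radius, col_radius)` and `amplitude` for an explicit
#'   additive elliptical-Gaussian highlight.
#' @param seed integer RNG seed.
#' @return a height x width x 3 numeric array (0-255 integers) of class
#'   `strip_image`, with the layout stored as attribute `layout`.
#' @export
generate_strip_image <- function(layout, pad_colors, noise_sd = 5,
                                 highlight = "auto", seed = 1) {
  stopifnot(inherits(layout, "strip_layout"))
  if (is.list(pad_colors) && !is.data.frame(pad_colors))
    pad_colors <- do.call(rbind, pad_colors)
  pad_colors <- as_color_matrix(pad_colors, "pad color")
  if (nrow(pad_colors) != layout$n_pads)
    stop("need exactly ", layout$n_pads, " pad colors", call. = FALSE)
  if (any(pad_colors < 0 | pad_colors > 255))
    stop("pad colors must be in [0, 255]", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  h <- layout$height; w <- layout$width
  pos <- .pad_positions(layout)
  if (max(pos$lefts) + layout$pad_size - 1L > w)
    stop("pads overflow the image width", call. = FALSE)

  img <- with_seed(seed, {
    a <- array(layout$background, dim = c(h, w, 3))
    rows <- pos$top:(pos$top + layout$pad_size - 1L)
    for (i in seq_len(layout$n_pads)) {
      cols <- pos$lefts[i]:(pos$lefts[i] + layout$pad_size - 1L)
      for (ch in 1:3) a[rows, cols, ch] <- pad_colors[i, ch]
    }
    if (identical(highlight, "auto")) {
      highlight <- list(
        center = c(max(1, (pos$top - 1) %/% 2),
                   round(stats::runif(1, layout$margin, w - layout$margin))),
        radii = c(6, 12), amplitude = 80)
    }
    if (!is.null(highlight)) {
      r0 <- highlight$center[1]; c0 <- highlight$center[2]
      ry <- highlight$radii[1]; rx <- highlight$radii[2]
      bump <- highlight$amplitude *
        exp(-(outer(((1:h - r0) / ry)^2, ((1:w - c0) / rx)^2, `+`)) / 2)
      for (ch in 1:3) a[, , ch] <- a[, , ch] + bump
    }
    if (noise_sd > 0) a <- a + array(stats::rnorm(h * w * 3, sd = noise_sd),
                                     dim = c(h, w, 3))
    a
  })
  img <- round(pmin(pmax(img, 0), 255))
  attr(img, "layout") <- layout
  class(img) <- c("strip_image", class(img))
  img
}

#' Strip image PNG I/O
#'
#' @param img a height x width x 3 array, 0-255.
#' @param path PNG file path.
#' @return `read_strip_image` returns the 0-255 array.
#' @export
write_strip_image <- function(img, path) {
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}

#' @rdname write_strip_image
#' @export
read_strip_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]
  round(a * 255)
}

# ---- small convolution helpers (replicate-padded, separable) ----------------

.gauss_kernel <- function(size, sigma) {
  r <- (size - 1) / 2
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# 1-D convolution of a matrix along rows (margin = 1) or columns (margin = 2),
# replicating edge values.
.conv1 <- function(mat, kernel, margin) {
  r <- (length(kernel) - 1L) %/% 2L
  n <- if (margin == 1L) nrow(mat) else ncol(mat)
  out <- 0
  for (j in seq_along(kernel)) {
    off <- j - r - 1L
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    out <- out + kernel[j] * (if (margin == 1L) mat[idx, , drop = FALSE]
                              else mat[, idx, drop = FALSE])
  }
  out
}

.sep_conv <- function(mat, krow, kcol = krow) {
  .conv1(.conv1(mat, krow, 1L), kcol, 2L)
}

#' Gaussian-smooth an image
#'
#' Separable Gaussian filter with replicate edge padding, applied per channel.
#'
#' @param img height x width x 3 array (or a single matrix).
#' @param sigma Gaussian standard deviation in pixels; default 1.
#' @param size odd kernel side length; default 5.
#' @return smoothed array of the same shape (not re-quantized).
#' @export
gaussian_smooth <- function(img, sigma = 1, size = 5) {
  if (size %% 2 != 1) stop("kernel size must be odd", call. = FALSE)
  k <- .gauss_kernel(size, sigma)
  if (length(dim(img)) == 2L) return(.sep_conv(img, k))
  out <- unclass(img)
  for (ch in seq_len(dim(img)[3])) out[, , ch] <- .sep_conv(img[, , ch], k)
  out
}

#' Suppress specular highlights
#'
#' Linear weighting of the image with its Gaussian-blurred version:
#' `out = weight * img + (1 - weight) * blur(img)`, clipped to \[0, 255\].
#' Localized bright spots are attenuated while flat regions are unchanged.
#'
#' @param img height x width x 3 array (or matrix), 0-255.
#' @param weight weight of the original image, in (0, 1]; default 0.6.
#' @param blur_sigma sigma of the smooth version; default 5.
#' @return the blended image, same shape.
#' @export
suppress_highlights <- function(img, weight = 0.6, blur_sigma = 5) {
  if (!is.numeric(weight) || length(weight) != 1 || weight <= 0 || weight > 1)
    stop("weight must lie in (0, 1]", call. = FALSE)
  size <- 2L * ceiling(3 * blur_sigma) + 1L
  sm <- gaussian_smooth(img, sigma = blur_sigma, size = size)
  pmin(pmax(weight * unclass(img) + (1 - weight) * sm, 0), 255)
}

#' Convert an RGB image to grayscale
#'
#' Standard luma weights 0.299 R + 0.587 G + 0.114 B.
#'
#' @param img height x width x 3 array, 0-255.
#' @return a height x width matrix of gray values (continuous, 0-255).
#' @export
to_gray <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Gray-level histogram
#'
#' Counts and probabilities over the 256 8-bit gray levels (values are
#' rounded to the nearest level first).
#'
#' @param gray a matrix (or vector) of gray values in \[0, 255\].
#' @return an object of class `gray_histogram`: list with integer `counts`
#'   (length 256, levels 0-255) and `p` (probabilities summing to 1).
#' @export
gray_histogram <- function(gray) {
  g <- round(as.numeric(gray))
  if (any(!is.finite(g)) || any(g < 0 | g > 255))
    stop("gray values must lie in [0, 255]", call. = FALSE)
  counts <- tabulate(g + 1L, nbins = 256L)
  structure(list(counts = counts, p = counts / sum(counts)),
            class = "gray_histogram")
}

#' Otsu's threshold from a gray-level histogram
#'
#' Finds the threshold T (1..255) maximizing the inter-class variance
#' `sigma_b^2 = w0 w1 (mu0 - mu1)^2`, where class 0 holds levels \[0, T-1\]
#' and class 1 holds levels \[T, 255\], with class probabilities w0, w1 and
#' class mean gray levels mu0, mu1. All candidate thresholds are traversed;
#' ties take the smallest T.
#'
#' @param hist a [gray_histogram()], a raw count vector of length 256, or a
#'   gray matrix (converted internally).
#' @return an object of class `otsu_result`: list with `threshold`, `omega0`,
#'   `omega1`, `mu0`, `mu1`, `sigma_b2`.
#' @export
otsu_threshold <- function(hist) {
  if (is.matrix(hist) || (is.numeric(hist) && length(hist) != 256L))
    hist <- gray_histogram(hist)
  if (is.numeric(hist) && length(hist) == 256L)
    hist <- structure(list(counts = hist, p = hist / sum(hist)),
                      class = "gray_histogram")
  stopifnot(inherits(hist, "gray_histogram"))
  p <- hist$p
  if (sum(p > 0) < 2L)
    stop("degenerate histogram: fewer than two distinct gray levels",
         call. = FALSE)
  lev <- 0:255
  mu_total <- sum(lev * p)
  # cumulative class-0 mass and first moment for T = 1..255
  w0 <- cumsum(p)[1:255]
  m0 <- cumsum(lev * p)[1:255]
  w1 <- 1 - w0
  sigma <- ifelse(w0 > 0 & w1 > 0,
                  (mu_total * w0 - m0)^2 / (w0 * w1), 0)
  T <- which.max(sigma)  # smallest maximizer (which.max is first-on-ties)
  w0T <- w0[T]; w1T <- w1[T]
  mu0 <- m0[T] / w0T
  mu1 <- (mu_total - m0[T]) / w1T
  structure(list(threshold = T, omega0 = w0T, omega1 = w1T,
                 mu0 = mu0, mu1 = mu1,
                 sigma_b2 = w0T * w1T * (mu0 - mu1)^2),
            class = "otsu_result")
}

#' Canny edge detection
#'
#' Sobel gradients, gradient-direction quantized non-maximum suppression, and
#' two-threshold hysteresis (weak edges are kept only when 8-connected to a
#' strong edge).
#'
#' @param gray matrix of gray values, 0-255.
#' @param low,high hysteresis thresholds on the gradient magnitude
#'   (defaults 50 and 150).
#' @return a logical edge matrix of the same dimensions.
#' @export
canny_edges <- function(gray, low = 50, high = 150) {
  if (low <= 0 || high <= low)
    stop("need 0 < low < high", call. = FALSE)
  sm <- c(1, 2, 1) / 4
  dv <- c(1, 0, -1)  # derivative kernel; sign irrelevant for magnitude
  gx <- .conv1(.conv1(gray, sm, 1L), dv, 2L)
  gy <- .conv1(.conv1(gray, dv, 1L), sm, 2L)
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx)
  sector <- (round(ang / (pi / 4)) %% 4)  # 0:E-W, 1:NE-SW, 2:N-S, 3:NW-SE
  h <- nrow(gray); w <- ncol(gray)
  shift <- function(m, dr, dc) {
    ri <- pmin(pmax(seq_len(h) + dr, 1L), h)
    ci <- pmin(pmax(seq_len(w) + dc, 1L), w)
    m[ri, ci, drop = FALSE]
  }
  keep <- matrix(FALSE, h, w)
  nbr <- list(`0` = c(0, 1), `1` = c(-1, 1), `2` = c(-1, 0), `3` = c(-1, -1))
  for (s in 0:3) {
    d <- nbr[[as.character(s)]]
    ok <- (sector == s) &
      mag >= shift(mag, d[1], d[2]) & mag >= shift(mag, -d[1], -d[2])
    keep <- keep | ok
  }
  thin <- mag * keep
  strong <- thin >= high
  weak <- thin >= low
  if (!any(strong)) return(matrix(FALSE, h, w))
  lab <- matrix(as.numeric(EBImage::bwlabel(weak * 1)), h, w)
  good <- setdiff(unique(lab[strong]), 0)
  weak & matrix(lab %in% good, h, w)
}

#' Processing-chain configuration
#'
#' @param smooth_sigma,smooth_size Gaussian pre-filter (default 1.0, 5 x 5).
#' @param highlight_weight weight of the original image in highlight
#'   suppression (default 0.6).
#' @param highlight_blur_sigma sigma of the smooth version used for
#'   suppression (default 5).
#' @param canny_low,canny_high Canny hysteresis thresholds (50 / 150).
#' @param morph_size side of the elliptical structuring element (default 3).
#' @param patch_size side of the square color-sampling patch (default 15).
#' @param min_area smallest connected-component area accepted as a pad,
#'   in pixels (default 64).
#' @return a list of class `strip_config`.
#' @export
strip_config <- function(smooth_sigma = 1, smooth_size = 5,
                         highlight_weight = 0.6, highlight_blur_sigma = 5,
                         canny_low = 50, canny_high = 150,
                         morph_size = 3, patch_size = 15, min_area = 64) {
  structure(list(smooth_sigma = smooth_sigma, smooth_size = smooth_size,
                 highlight_weight = highlight_weight,
                 highlight_blur_sigma = highlight_blur_sigma,
                 canny_low = canny_low, canny_high = canny_high,
                 morph_size = morph_size, patch_size = patch_size,
                 min_area = min_area),
            class = "strip_config")
}

#' Read a processing configuration from YAML
#'
#' Any subset of the [strip_config()] arguments may appear as top-level keys;
#' the rest keep their defaults.
#'
#' @param path YAML file path.
#' @return a `strip_config`.
#' @export
read_strip_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configs", call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(strip_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(strip_config, vals)
}

#' Extract per-pad mean colors from a strip image
#'
#' Runs the full classical chain: Gaussian smoothing, highlight suppression,
#' grayscale conversion, Otsu binarization (the carrier is identified as the
#' gray class dominating the image border), morphological opening then
#' closing (3 x 3 elliptical element via EBImage), Canny edge extraction,
#' connected pad regions, and finally the mean RGB over a `patch_size` square
#' patch at each pad center, computed on the pre-binarization color image.
#' Pads are reported left to right.
#'
#' @param img a height x width x 3 array (0-255), e.g. from
#'   [generate_strip_image()] or [read_strip_image()].
#' @param config a [strip_config()].
#' @return a data frame of class `pad_readings` with columns
#'   `pad`, `row`, `col`, `R`, `G`, `B` (one row per detected pad; empty,
#'   with a warning, when nothing is detected).
#' @export
process_strip <- function(img, config = strip_config()) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  h <- dim(img)[1]; w <- dim(img)[2]
  if (h < 64L || w < 64L)
    stop("image must be at least 64 x 64", call. = FALSE)
  empty <- data.frame(pad = integer(), row = integer(), col = integer(),
                      R = numeric(), G = numeric(), B = numeric())
  class(empty) <- c("pad_readings", "data.frame")

  sm <- gaussian_smooth(unclass(img), config$smooth_sigma, config$smooth_size)
  color <- suppress_highlights(sm, config$highlight_weight,
                               config$highlight_blur_sigma)
  gray <- to_gray(color)
  ot <- tryCatch(otsu_threshold(gray), error = function(e) NULL)
  if (is.null(ot)) {
    warning("degenerate gray histogram; no pads detected", call. = FALSE)
    return(empty)
  }
  dark <- round(gray) < ot$threshold
  # the carrier (background) is whichever class dominates the image border
  border <- c(dark[1, ], dark[h, ], dark[, 1], dark[, w])
  fg <- if (mean(border) > 0.5) !dark else dark

  kern <- EBImage::makeBrush(config$morph_size, shape = "disc")
  fg <- EBImage::closing(EBImage::opening(fg * 1, kern), kern)
  edges <- canny_edges(gray, config$canny_low, config$canny_high)

  lab <- EBImage::bwlabel(fg)
  lab_m <- matrix(as.numeric(lab), h, w)
  areas <- tabulate(lab_m[lab_m > 0])
  ids <- which(areas >= config$min_area)
  if (length(ids) == 0L) {
    warning("no pad regions detected", call. = FALSE)
    return(empty)
  }
  centers <- t(vapply(ids, function(id) {
    px <- which(lab_m == id, arr.ind = TRUE)
    epx <- px[edges[px], , drop = FALSE]  # the region's edge pixels
    if (nrow(epx) == 0L) epx <- px
    c(round((min(epx[, 1]) + max(epx[, 1])) / 2),
      round((min(epx[, 2]) + max(epx[, 2])) / 2))
  }, numeric(2)))
  ord <- order(centers[, 2])
  centers <- centers[ord, , drop = FALSE]

  half <- (config$patch_size - 1L) %/% 2L
  out <- list()
  for (i in seq_len(nrow(centers))) {
    r0 <- centers[i, 1]; c0 <- centers[i, 2]
    if (r0 - half < 1 || r0 + half > h || c0 - half < 1 || c0 + half > w) {
      warning("pad ", i, ": sampling patch exceeds image bounds; skipped",
              call. = FALSE)
      next
    }
    rows <- (r0 - half):(r0 + half); cols <- (c0 - half):(c0 + half)
    out[[length(out) + 1L]] <- data.frame(
      pad = NA_integer_, row = r0, col = c0,
      R = mean(color[rows, cols, 1]),
      G = mean(color[rows, cols, 2]),
      B = mean(color[rows, cols, 3]))
  }
  if (length(out) == 0L) {
    warning("no pad regions detected", call. = FALSE)
    return(empty)
  }
  res <- do.call(rbind, out)
  res$pad <- seq_len(nrow(res))
  class(res) <- c("pad_readings", "data.frame")
  res
}

#' Pad readings CSV export
#'
#' Columns `pad_index,row,col,R,G,B`.
#'
#' @param readings a `pad_readings` data frame; @param path file path.
#' @export
write_pad_readings <- function(readings, path) {
  df <- as.data.frame(readings)
  names(df)[names(df) == "pad"] <- "pad_index"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
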