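# Device RGB <-> CIELab conversion, CIE76 color difference and
# semi-quantitative level matching against a colorimetric card.
#
# The conversion pipeline is the standard sRGB (D65) one: channels are
# normalized to [0,1], gamma-expanded, mapped to XYZ tristimulus values by the
# sRGB matrix, divided by the reference white, and passed through the CIE
# cube-root compression f(t).

# Reference white (D65, 2 degree observer), Y normalized to 1
.white_d65 <- c(X = 0.95047, Y = 1.0, Z = 1.08883)

# sRGB linear-RGB -> XYZ matrix (D65). Rows are rescaled (by < 1e-7 relative)
# to sum exactly to the reference white, so achromatic RGB maps to x = y = z
# and hence to a* = b* = 0 exactly.
.rgb2xyz <- local({
  m <- matrix(c(
    0.4124564, 0.3575761, 0.1804375,
    0.2126729, 0.7151522, 0.0721750,
    0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE)
  m * (.white_d65 / rowSums(m))
})

# CIE constants: threshold for the cube-root branch and the low-t slope
.cie_eps   <- 0.008856
.cie_kappa <- 903.3

.cie_f <- function(t) {
  ifelse(t > .cie_eps, t^(1 / 3), (.cie_kappa * t + 16) / 116)
}

.cie_f_inv <- function(ft) {
  t3 <- ft^3
  ifelse(t3 > .cie_eps, t3, (116 * ft - 16) / .cie_kappa)
}

#' Convert device RGB to CIELab
#'
#' Applies the standard sRGB (D65) pipeline: normalization of 8-bit channels
#' to \[0,1\], per-channel gamma expansion (linear below 0.04045, exponent 2.4
#' above), the sRGB RGB-to-XYZ matrix, division by the reference white
#' (Xn, Yn, Zn) = (0.95047, 1, 1.08883), and the CIE compression
#' f(t) = t^(1/3) for t > 0.008856 and (903.3 t + 16)/116 otherwise.
#'
#' @param rgb a numeric vector of length 3 (R, G, B on the 0-255 device
#'   scale; fractional values such as patch means are allowed) or an n x 3
#'   matrix of such rows.
#' @return a vector (L, a, b) or an n x 3 matrix of Lab rows. L is in
#'   \[0, 100\] for valid inputs; a and b are signed chromatic coordinates.
#' @examples
#' rgb_to_lab(c(255, 255, 255))  # ~ (100, 0, 0)
#' rgb_to_lab(c(128, 128, 128))  # achromatic: a = b = 0
#' @seealso [lab_to_rgb()], [delta_e()]
#' @export
rgb_to_lab <- function(rgb) {
  m <- as_color_matrix(rgb, "RGB")
  wv <- attr(m, "was_vector")
  bad <- which(m < 0 | m > 255, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    ch <- c("R", "G", "B")[bad[1, 2]]
    stop("RGB channel ", ch, " out of range [0, 255]: ",
         format(m[bad[1, 1], bad[1, 2]]), call. = FALSE)
  }
  srgb <- m / 255
  lin <- ifelse(srgb <= 0.04045, srgb / 12.92, ((srgb + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.rgb2xyz)
  xyz <- sweep(xyz, 2, .white_d65, "/")
  fx <- .cie_f(xyz[, 1]); fy <- .cie_f(xyz[, 2]); fz <- .cie_f(xyz[, 3])
  lab <- cbind(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
  drop_color_matrix(lab, wv, c("L", "a", "b"))
}

#' Convert CIELab back to device RGB
#'
#' Exact algebraic inverse of [rgb_to_lab()] on its range. Out-of-gamut
#' results are clipped to \[0, 255\]; when any channel was clipped the result
#' carries attribute `clipped = TRUE`.
#'
#' @param lab a numeric vector (L, a, b) or an n x 3 matrix of Lab rows.
#' @return RGB values on the 0-255 scale, same shape as the input, with a
#'   logical `clipped` attribute.
#' @export
lab_to_rgb <- function(lab) {
  m <- as_color_matrix(lab, "Lab")
  wv <- attr(m, "was_vector")
  fy <- (m[, 1] + 16) / 116
  fx <- fy + m[, 2] / 500
  fz <- fy - m[, 3] / 200
  xyz <- cbind(.cie_f_inv(fx), .cie_f_inv(fy), .cie_f_inv(fz))
  xyz <- sweep(xyz, 2, .white_d65, "*")
  lin <- xyz %*% t(solve(.rgb2xyz))
  srgb <- ifelse(lin <= 0.04045 / 12.92,
                 lin * 12.92,
                 1.055 * pmax(lin, 0)^(1 / 2.4) - 0.055)
  out <- srgb * 255
  clipped <- any(out < -1e-9 | out > 255 + 1e-9)
  out <- pmin(pmax(out, 0), 255)
  out <- drop_color_matrix(out, wv, c("R", "G", "B"))
  attr(out, "clipped") <- clipped
  out
}

#' CIE76 color difference
#'
#' Euclidean distance between two CIELab colors,
#' `dE = sqrt((L1-L2)^2 + (a1-a2)^2 + (b1-b2)^2)`.
#'
#' @param lab1,lab2 Lab vectors of length 3, or conformable n x 3 matrices
#'   (rows paired; one may be a single color recycled against the other).
#' @return non-negative scalar distance(s).
#' @export
delta_e <- function(lab1, lab2) {
  m1 <- as_color_matrix(lab1, "Lab")
  m2 <- as_color_matrix(lab2, "Lab")
  if (nrow(m1) == 1L && nrow(m2) > 1L) m1 <- m1[rep(1L, nrow(m2)), , drop = FALSE]
  if (nrow(m2) == 1L && nrow(m1) > 1L) m2 <- m2[rep(1L, nrow(m1)), , drop = FALSE]
  if (nrow(m1) != nrow(m2))
    stop("lab1 and lab2 must have the same number of rows", call. = FALSE)
  sqrt(rowSums((m1 - m2)^2))
}

#' Construct a colorimetric card
#'
#' A colorimetric card is an ordered set of reference colors, one per
#' semi-quantitative concentration level (conventionally labelled
#' `-`, `-+`, `+`, `++`, `+++`, `++++`), each given in CIELab.
#'
#' @param levels character vector of unique level labels, in card order
#'   (lowest concentration first).
#' @param lab an n x 3 matrix (or data frame) of Lab rows, one per level.
#' @return an object of class `color_card`: a data frame with columns
#'   `level`, `L`, `a`, `b`.
#' @export
color_card <- function(levels, lab) {
  lab <- as_color_matrix(lab, "Lab")
  levels <- as.character(levels)
  if (length(levels) < 2L)
    stop("a color card needs at least 2 entries", call. = FALSE)
  if (anyDuplicated(levels))
    stop("card level labels must be unique", call. = FALSE)
  if (length(levels) != nrow(lab))
    stop("one Lab row per level required", call. = FALSE)
  card <- data.frame(level = levels, L = lab[, 1], a = lab[, 2], b = lab[, 3],
                     stringsAsFactors = FALSE)
  class(card) <- c("color_card", "data.frame")
  card
}

#' Match a measured color to the nearest card level
#'
#' Computes the CIE76 distance from `lab` to every card entry and returns the
#' level label of the nearest one. Ties are broken in favour of the earliest
#' (lowest) level in card order, which is the clinically conservative choice.
#'
#' @param lab a Lab vector of length 3.
#' @param card a [color_card()].
#' @return the matched level label (character scalar) with attribute
#'   `delta_e` giving the full distance vector, named by level.
#' @export
match_level <- function(lab, card) {
  if (!inherits(card, "color_card"))
    stop("`card` must be a color_card", call. = FALSE)
  if (nrow(card) == 0L) stop("empty color card", call. = FALSE)
  d <- delta_e(lab, as.matrix(card[, c("L", "a", "b")]))
  best <- which.min(d)  # which.min takes the first index on ties
  out <- card$level[best]
  names(d) <- card$level
  attr(out, "delta_e") <- d
  out
}

#' Read or write a colorimetric card as CSV
#'
#' The on-disk format has a header row and columns `level,L,a,b` (UTF-8).
#'
#' @param path file path.
#' @param card a [color_card()] (for writing).
#' @return `read_color_card` returns a [color_card()]; `write_color_card`
#'   returns `path` invisibly.
#' @export
read_color_card <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("level", "L", "a", "b")
  if (!all(need %in% names(df)))
    stop("color card CSV must have columns level,L,a,b", call. = FALSE)
  color_card(df$level, as.matrix(df[, c("L", "a", "b")]))
}

#' @rdname read_color_card
#' @export
write_color_card <- function(card, path) {
  stopifnot(inherits(card, "color_card"))
  utils::write.csv(as.data.frame(card), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
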