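# Device color correction: per-channel polynomial regression in CIELab,
# fitted by least squares against a standard colorimetric chart.
#
# Each channel c in {L, a, b} gets its own model
#   x_ref = a0 + a1 * x_meas + ... + an * x_meas^n
# so a corrector is three independent univariate polynomials. Cross-channel
# (3x3 / 3D LUT) correction is deliberately out of scope.

#' Fit a single-channel correction polynomial
#'
#' Least-squares fit of `reference ~ poly(measured, degree)` with raw
#' (untransformed) polynomial terms, intercept first.
#'
#' @param measured numeric vector of device-measured channel values.
#' @param reference numeric vector of the corresponding standard values.
#' @param degree polynomial order n >= 1 (default 2).
#' @return an object of class `channel_poly`: list with `degree`,
#'   `coefficients` (a0 ... an), `rms` (fit residual RMS) and the measured
#'   range used for the fit.
#' @export
fit_channel <- function(measured, reference, degree = 2) {
  measured <- as.numeric(measured); reference <- as.numeric(reference)
  if (length(measured) != length(reference))
    stop("measured and reference must have equal length", call. = FALSE)
  if (!all(is.finite(measured)) || !all(is.finite(reference)))
    stop("non-finite values in chart data", call. = FALSE)
  degree <- as.integer(degree)
  if (degree < 1L) stop("degree must be >= 1", call. = FALSE)
  m <- length(measured)
  if (m < degree + 1L)
    stop("underdetermined fit: ", m, " points for degree ", degree,
         " (need >= ", degree + 1L, ")", call. = FALSE)
  if (length(unique(measured)) < degree + 1L)
    stop("rank-deficient fit: measured values do not span degree ", degree,
         call. = FALSE)
  fit <- stats::lm(reference ~ stats::poly(measured, degree, raw = TRUE))
  cf <- unname(stats::coef(fit))
  if (any(!is.finite(cf)))
    stop("rank-deficient fit: could not estimate all coefficients",
         call. = FALSE)
  structure(list(degree = degree, coefficients = cf,
                 rms = sqrt(mean(stats::residuals(fit)^2)),
                 range = range(measured)),
            class = "channel_poly")
}

#' Evaluate a channel polynomial
#'
#' @param poly a `channel_poly` from [fit_channel()].
#' @param x channel values to correct.
#' @return corrected channel values.
#' @export
eval_channel <- function(poly, x) {
  stopifnot(inherits(poly, "channel_poly"))
  drop(outer(as.numeric(x), 0:poly$degree, `^`) %*% poly$coefficients)
}

#' Fit a three-channel CIELab color corrector
#'
#' Fits one polynomial per channel (L, a, b) from measured/reference chart
#' pairs, each by least squares at the same degree.
#'
#' @param measured n x 3 matrix (or data frame) of device-measured Lab rows.
#' @param reference n x 3 matrix of the corresponding standard Lab rows.
#' @param degree polynomial order, default 2 (supported 1-4).
#' @return an object of class `color_corrector`: list of three
#'   `channel_poly` models plus per-channel residual RMS.
#' @export
fit_corrector <- function(measured, reference, degree = 2) {
  m <- as_color_matrix(measured, "measured Lab")
  r <- as_color_matrix(reference, "reference Lab")
  if (nrow(m) != nrow(r))
    stop("measured and reference charts must pair row-for-row", call. = FALSE)
  if (degree < 1 || degree > 4)
    stop("degree must be between 1 and 4", call. = FALSE)
  ch <- c("L", "a", "b")
  models <- lapply(1:3, function(i) {
    tryCatch(fit_channel(m[, i], r[, i], degree),
             error = function(e) stop("channel ", ch[i], ": ",
                                      conditionMessage(e), call. = FALSE))
  })
  names(models) <- ch
  structure(list(degree = degree, channels = models,
                 rms = vapply(models, `[[`, numeric(1), "rms")),
            class = "color_corrector")
}

#' Apply a fitted color correction
#'
#' Evaluates each channel's polynomial at the corresponding measured channel
#' value. Inputs outside the chart's fitted range are extrapolated; a warning
#' notes this, since polynomials diverge outside the fit range.
#'
#' @param corrector a [fit_corrector()] result.
#' @param lab a Lab vector or n x 3 matrix of measured colors.
#' @return corrected Lab values, same shape as the input.
#' @export
apply_correction <- function(corrector, lab) {
  stopifnot(inherits(corrector, "color_corrector"))
  m <- as_color_matrix(lab, "Lab")
  wv <- attr(m, "was_vector")
  out <- m
  extrap <- FALSE
  for (i in 1:3) {
    cp <- corrector$channels[[i]]
    tol <- 1e-8 * (diff(cp$range) + 1)   # serialization-safe boundary slack
    if (any(m[, i] < cp$range[1] - tol | m[, i] > cp$range[2] + tol))
      extrap <- TRUE
    out[, i] <- eval_channel(cp, m[, i])
  }
  if (extrap)
    warning("input outside the chart's fitted range; polynomial extrapolation",
            call. = FALSE)
  drop_color_matrix(out, wv, c("L", "a", "b"))
}

#' @export
print.color_corrector <- function(x, ...) {
  cat("CIELab polynomial color corrector (degree ", x$degree, ")\n", sep = "")
  for (ch in names(x$channels)) {
    cat(sprintf("  %s: [%s]  residual RMS %.4g\n", ch,
                paste(signif(x$channels[[ch]]$coefficients, 5),
                      collapse = ", "), x$channels[[ch]]$rms))
  }
  invisible(x)
}

#' Chart and corrector I/O
#'
#' Charts are CSVs with header
#' `patch_id,L_meas,a_meas,b_meas,L_ref,a_ref,b_ref`; correctors are JSON
#' files holding the degree and the three coefficient vectors.
#'
#' @param path file path.
#' @param corrector a `color_corrector` (for writing).
#' @return `read_chart` returns a data frame; `read_corrector` a
#'   `color_corrector`.
#' @export
read_chart <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patch_id", "L_meas", "a_meas", "b_meas", "L_ref", "a_ref", "b_ref")
  if (!all(need %in% names(df)))
    stop("chart CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  df
}

#' @rdname read_chart
#' @export
write_corrector <- function(corrector, path) {
  stopifnot(inherits(corrector, "color_corrector"))
  obj <- list(degree = corrector$degree,
              coefficients = lapply(corrector$channels, `[[`, "coefficients"),
              range = lapply(corrector$channels, `[[`, "range"),
              rms = as.list(corrector$rms))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_chart
#' @export
read_corrector <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ch <- lapply(c("L", "a", "b"), function(nm) {
    structure(list(degree = obj$degree,
                   coefficients = as.numeric(obj$coefficients[[nm]]),
                   rms = as.numeric(obj$rms[[nm]]),
                   range = as.numeric(obj$range[[nm]])),
              class = "channel_poly")
  })
  names(ch) <- c("L", "a", "b")
  structure(list(degree = obj$degree, channels = ch,
                 rms = vapply(ch, `[[`, numeric(1), "rms")),
            class = "color_corrector")
}
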