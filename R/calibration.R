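# Concentration -> RGB calibration curves and synthetic dataset construction.
#
# The built-in curve sets are the published least-squares fits relating each
# color channel of the reacted reagent pad to analyte concentration C:
# double-exponential-with-offset forms for urinary protein, and
# logistic / Hill forms for leukocytes. They are treated as printed constants;
# refitting from raw card measurements is out of scope.

.curve_forms <- c("double_exp_offset", "logistic", "hill")

#' Construct a calibration curve
#'
#' Supported functional forms (x = concentration C >= 0):
#' \describe{
#'   \item{double_exp_offset}{`y = A1 exp(-x/t1) + A2 exp(-x/t2) + y0`,
#'     coefficients `(A1, t1, A2, t2, y0)`}
#'   \item{logistic}{`y = y0 + A / (1 + exp((x - x0)/k))`,
#'     coefficients `(y0, A, x0, k)`}
#'   \item{hill}{`y = y0 + A / (1 + (x/x0)^p)`, coefficients `(y0, A, x0, p)`}
#' }
#'
#' @param channel one of "R", "G", "B".
#' @param form functional form identifier.
#' @param coefficients named or ordered numeric vector as documented above.
#' @return an object of class `calibration_curve`.
#' @export
calibration_curve <- function(channel, form, coefficients) {
  channel <- match.arg(channel, c("R", "G", "B"))
  form <- match.arg(form, .curve_forms)
  coefficients <- as.numeric(coefficients)
  n_need <- if (form == "double_exp_offset") 5L else 4L
  if (length(coefficients) != n_need || any(!is.finite(coefficients)))
    stop(form, " curve needs ", n_need, " finite coefficients", call. = FALSE)
  structure(list(channel = channel, form = form, coefficients = coefficients),
            class = "calibration_curve")
}

#' Evaluate a calibration curve
#'
#' @param curve a [calibration_curve()].
#' @param C concentration(s), >= 0.
#' @return the modelled channel value (not clipped; the printed protein C-B
#'   curve leaves \[0, 255\] away from C = 0).
#' @export
evaluate_curve <- function(curve, C) {
  stopifnot(inherits(curve, "calibration_curve"))
  C <- as.numeric(C)
  if (any(!is.finite(C)) || any(C < 0))
    stop("concentration must be finite and >= 0", call. = FALSE)
  k <- curve$coefficients
  switch(curve$form,
    double_exp_offset = k[1] * exp(-C / k[2]) + k[3] * exp(-C / k[4]) + k[5],
    logistic = k[1] + k[2] / (1 + exp((C - k[3]) / k[4])),
    hill = k[1] + k[2] / (1 + (C / k[3])^k[4]))
}

#' Built-in analyte curve sets
#'
#' Returns the published concentration-to-channel regression fits for a urine
#' analyte, together with its valid concentration range.
#'
#' Protein (range 0-500 mg/dL), double-exponential-with-offset per channel:
#' \itemize{
#'   \item R: 45.17 exp(-C/15.67) + 170.50 exp(-C/345.99) + 12.55
#'   \item G: 27.86 exp(-C/24.47) + 53.51 exp(-C/484.70) + 158.29
#'   \item B: -23.29 exp(-C/23.61) - 707813.13 exp(-C/1.39) + 707957.78
#' }
#' Leukocyte (curve-domain units; no physical units were published for the
#' leukocyte fits, and the default range \[0, 500\] mirrors the protein span):
#' \itemize{
#'   \item R: 180.69 + 74.17 / (1 + exp((C - 112.27)/38.33))
#'   \item G: 77.88 + 174.77 / (1 + (C/83.35)^0.77)
#'   \item B: 143.66 + 87.49 / (1 + (C/105.65)^1.02)
#' }
#'
#' @param analyte "protein" or "leukocyte".
#' @return an object of class `curve_set`: list with `analyte`, `range`,
#'   `units`, and curves `R`, `G`, `B`.
#' @export
builtin_curves <- function(analyte = c("protein", "leukocyte")) {
  if (length(analyte) == 1L && !analyte %in% c("protein", "leukocyte"))
    stop("unknown analyte: ", analyte,
         " (built-in sets: protein, leukocyte)", call. = FALSE)
  analyte <- match.arg(analyte)
  if (analyte == "protein") {
    curves <- list(
      R = calibration_curve("R", "double_exp_offset",
                            c(45.17, 15.67, 170.50, 345.99, 12.55)),
      G = calibration_curve("G", "double_exp_offset",
                            c(27.86, 24.47, 53.51, 484.70, 158.29)),
      B = calibration_curve("B", "double_exp_offset",
                            c(-23.29, 23.61, -707813.13, 1.39, 707957.78)))
    units <- "mg/dL"
  } else {
    curves <- list(
      R = calibration_curve("R", "logistic", c(180.69, 74.17, 112.27, 38.33)),
      G = calibration_curve("G", "hill",     c(77.88, 174.77, 83.35, 0.77)),
      B = calibration_curve("B", "hill",     c(143.66, 87.49, 105.65, 1.02)))
    units <- "curve units"
  }
  structure(list(analyte = analyte, range = c(0, 500), units = units,
                 curves = curves),
            class = "curve_set")
}

#' Evaluate a curve set at concentrations
#'
#' @param curves a `curve_set`.
#' @param C concentration vector.
#' @param clip clip channel values into \[0, 255\] (default TRUE).
#' @return an n x 3 matrix with columns R, G, B.
#' @export
evaluate_curve_set <- function(curves, C, clip = TRUE) {
  stopifnot(inherits(curves, "curve_set"))
  rgb <- cbind(R = evaluate_curve(curves$curves$R, C),
               G = evaluate_curve(curves$curves$G, C),
               B = evaluate_curve(curves$curves$B, C))
  if (clip) rgb <- pmin(pmax(rgb, 0), 255)
  rgb
}

#' Generate a regression dataset from a curve set
#'
#' Samples concentrations uniformly over the curve set's valid range,
#' evaluates all three channel curves at each concentration, optionally adds
#' i.i.d. Gaussian channel noise, clips features to \[0, 255\], and splits the
#' rows into a training and a test set (default 500/70) after a seeded
#' shuffle.
#'
#' @param curves a `curve_set` from [builtin_curves()].
#' @param n_train,n_test split sizes (defaults 500 and 70).
#' @param noise_sd Gaussian channel noise standard deviation (default 0:
#'   the curves are deterministic; noise is exposed for robustness studies).
#' @param seed integer RNG seed; the dataset is fully reproducible from it.
#' @return an object of class `regression_dataset`: a data frame with
#'   columns `R`, `G`, `B`, `C`, `split`, plus metadata attributes.
#' @export
generate_dataset <- function(curves, n_train = 500, n_test = 70,
                             noise_sd = 0, seed = 1) {
  stopifnot(inherits(curves, "curve_set"))
  n_train <- as.integer(n_train); n_test <- as.integer(n_test)
  if (n_train < 1L || n_test < 1L)
    stop("n_train and n_test must both be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  n <- n_train + n_test
  df <- with_seed(seed, {
    C <- stats::runif(n, curves$range[1], curves$range[2])
    rgb <- evaluate_curve_set(curves, C, clip = FALSE)
    if (noise_sd > 0)
      rgb <- rgb + matrix(stats::rnorm(3 * n, sd = noise_sd), ncol = 3)
    rgb <- pmin(pmax(rgb, 0), 255)
    ord <- sample.int(n)
    data.frame(R = rgb[ord, 1], G = rgb[ord, 2], B = rgb[ord, 3], C = C[ord],
               split = rep(c("train", "test"), c(n_train, n_test)),
               stringsAsFactors = FALSE)
  })
  attr(df, "analyte") <- curves$analyte
  attr(df, "range") <- curves$range
  attr(df, "units") <- curves$units
  attr(df, "noise_sd") <- noise_sd
  attr(df, "seed") <- seed
  class(df) <- c("regression_dataset", "data.frame")
  df
}

#' Dataset I/O
#'
#' Datasets are CSVs with header `R,G,B,C,split`.
#'
#' @param dataset a `regression_dataset` (for writing).
#' @param path file path.
#' @param range,units,analyte metadata restored on read (optional).
#' @return `read_dataset` returns a `regression_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(is.data.frame(dataset),
            all(c("R", "G", "B", "C", "split") %in% names(dataset)))
  utils::write.csv(as.data.frame(dataset)[, c("R", "G", "B", "C", "split")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path, range = c(0, 500), units = "mg/dL",
                         analyte = "protein") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("R", "G", "B", "C", "split")
  if (!all(need %in% names(df)))
    stop("dataset CSV must have columns R,G,B,C,split", call. = FALSE)
  attr(df, "analyte") <- analyte
  attr(df, "range") <- range
  attr(df, "units") <- units
  class(df) <- c("regression_dataset", "data.frame")
  df
}

#' Serialize a curve set to JSON
#'
#' @param curves a `curve_set`; @param path file path.
#' @return `read_curve_set` returns a `curve_set`.
#' @export
write_curve_set <- function(curves, path) {
  stopifnot(inherits(curves, "curve_set"))
  obj <- list(analyte = curves$analyte, range = curves$range,
              units = curves$units,
              curves = lapply(curves$curves, function(cv)
                list(channel = cv$channel, form = cv$form,
                     coefficients = cv$coefficients)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_curve_set
#' @export
read_curve_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  curves <- lapply(obj$curves, function(cv)
    calibration_curve(cv$channel, cv$form, as.numeric(cv$coefficients)))
  structure(list(analyte = obj$analyte, range = as.numeric(obj$range),
                 units = obj$units, curves = curves),
            class = "curve_set")
}
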