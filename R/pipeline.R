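# End-to-end WOA-BP training and prediction, plus evaluation metrics.
#
# The training procedure mirrors the construction steps: normalize the data
# (min-max, fitted on the training split only), pick a topology, build a
# fitness function mapping a flat weight/threshold vector to the network's
# training MSE, run a metaheuristic (WOA by default; PSO/GA/none available as
# baselines) to find a good starting vector, then refine with full-batch
# backpropagation, and finally predict by inverse-scaling the network output.

#' Fitness function over flat network parameter vectors
#'
#' Returns a closure mapping a flat parameter vector (length
#' `topology$n_params`) to the network's mean squared error on the supplied
#' scaled training data — the objective the metaheuristics minimize.
#'
#' @param x n x input matrix of scaled training features.
#' @param y length-n vector of scaled training targets.
#' @param topology an [mlp_topology()].
#' @return a function `numeric(n_params) -> scalar MSE`, with the expected
#'   vector length in attribute `n_params`.
#' @export
make_fitness <- function(x, y, topology) {
  stopifnot(inherits(topology, "mlp_topology"))
  if (is.null(dim(x))) x <- matrix(x, ncol = topology$input)
  if (nrow(x) == 0L) stop("empty training split", call. = FALSE)
  force(y)
  fn <- function(vec) mse_loss(unflatten_params(vec, topology), x, y)
  attr(fn, "n_params") <- topology$n_params
  fn
}

#' Train a WOA-BP concentration model
#'
#' Full training pipeline on a [generate_dataset()] result (or any data frame
#' with columns `R`, `G`, `B`, `C`, `split`): min-max scalers are fitted on
#' the training split, the chosen metaheuristic searches the flat
#' weight/threshold space for the initialization minimizing training MSE, and
#' full-batch gradient descent refines it. Everything is reproducible from
#' the seeds in the configs.
#'
#' @param dataset a `regression_dataset` (needs >= 50 training rows).
#' @param topology an [mlp_topology()]; default 3-10-1.
#' @param optimizer one of "woa" (default), "pso", "ga", or "none" (plain
#'   BP from random initialization).
#' @param opt_config an [optimizer_config()] for the metaheuristic.
#' @param lr,epochs gradient-descent refinement settings (see [train_gd()]).
#' @param seed seed for the random initialization used when
#'   `optimizer = "none"`.
#' @return an object of class `woabp_model`: the trained parameters, the
#'   fitted scalers, the optimizer run (NULL for "none"), the gradient
#'   descent loss history, and the analyte range used for clipping.
#' @export
train_woabp <- function(dataset, topology = mlp_topology(),
                        optimizer = c("woa", "pso", "ga", "none"),
                        opt_config = optimizer_config(),
                        lr = 0.1, epochs = 4000, seed = 1) {
  optimizer <- match.arg(optimizer)
  stopifnot(is.data.frame(dataset),
            all(c("R", "G", "B", "C", "split") %in% names(dataset)))
  tr <- dataset[dataset$split == "train", ]
  if (nrow(tr) < 50L)
    stop("training split has ", nrow(tr), " rows; need >= 50", call. = FALSE)
  x_raw <- as.matrix(tr[, c("R", "G", "B")])
  scaler_x <- scaler_fit(x_raw)
  scaler_y <- scaler_fit(tr$C)
  x <- scaler_apply(scaler_x, x_raw)
  y <- scaler_apply(scaler_y, tr$C)

  run <- NULL
  if (optimizer == "none") {
    params0 <- init_network(topology, seed = seed)
  } else {
    fitness <- make_fitness(x, y, topology)
    run <- switch(optimizer,
                  woa = woa_optimize(fitness, topology$n_params, opt_config),
                  pso = pso_optimize(fitness, topology$n_params, opt_config),
                  ga  = ga_optimize(fitness, topology$n_params, opt_config))
    params0 <- unflatten_params(run$best, topology)
  }
  params <- train_gd(params0, x, y, lr = lr, epochs = epochs)
  structure(list(topology = topology, params = params,
                 scaler_x = scaler_x, scaler_y = scaler_y,
                 optimizer = optimizer, run = run,
                 gd_history = attr(params, "loss_history"),
                 analyte = attr(dataset, "analyte"),
                 range = attr(dataset, "range") %||% c(0, 500),
                 units = attr(dataset, "units") %||% ""),
            class = "woabp_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict concentration from a pad color
#'
#' Scales the RGB features, runs the forward pass, and inverse-scales the
#' output back to concentration units. Predictions outside the analyte range
#' are clipped, with attribute `clipped = TRUE` flagging it.
#'
#' @param model a [train_woabp()] result.
#' @param rgb an RGB vector (0-255) or an n x 3 matrix of pad colors.
#' @return predicted concentration(s) in original units.
#' @export
predict_concentration <- function(model, rgb) {
  if (!inherits(model, "woabp_model"))
    stop("`model` must be a fitted woabp_model", call. = FALSE)
  m <- as_color_matrix(rgb, "RGB")
  x <- scaler_apply(model$scaler_x, m)
  pred <- scaler_invert(model$scaler_y, mlp_forward(model$params, x))
  clipped <- any(pred < model$range[1] | pred > model$range[2])
  pred <- pmin(pmax(pred, model$range[1]), model$range[2])
  attr(pred, "clipped") <- clipped
  pred
}

#' @export
print.woabp_model <- function(x, ...) {
  cat(sprintf("WOA-BP concentration model (%s, optimizer = %s)\n",
              x$analyte %||% "unknown analyte", x$optimizer))
  cat(sprintf("  topology %s, %d parameters\n",
              paste(x$topology$sizes, collapse = "-"), x$topology$n_params))
  if (!is.null(x$run))
    cat(sprintf("  optimizer best fitness %.6g\n", x$run$best_fitness))
  cat(sprintf("  final training MSE (scaled) %.6g\n",
              x$gd_history[length(x$gd_history)]))
  invisible(x)
}

#' Regression evaluation metrics
#'
#' Computes the mean absolute error, root mean squared error, coefficient of
#' determination `R2 = 1 - sum((pred-true)^2) / sum((true-mean(true))^2)`,
#' and per-sample relative errors `100 (pred - true) / true` (NA where the
#' true value is 0).
#'
#' @param true,predicted equal-length numeric vectors.
#' @return an object of class `metric_report`: list with `mae`, `rmse`,
#'   `r2`, `relative_errors`, `n`.
#' @export
compute_metrics <- function(true, predicted) {
  true <- as.numeric(true); predicted <- as.numeric(predicted)
  if (length(true) == 0L || length(true) != length(predicted))
    stop("true and predicted must be equal-length, non-empty", call. = FALSE)
  err <- predicted - true
  rel <- ifelse(true == 0, NA_real_, 100 * err / true)
  structure(list(mae = mean(abs(err)),
                 rmse = sqrt(mean(err^2)),
                 r2 = 1 - sum(err^2) / sum((true - mean(true))^2),
                 relative_errors = rel,
                 n = length(true)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("n = %d   MAE = %.4f   RMSE = %.4f   R2 = %.5f\n",
              x$n, x$mae, x$rmse, x$r2))
  invisible(x)
}

#' Export a metric report as JSON
#'
#' @param report a `metric_report`; @param path file path.
#' @export
write_metrics <- function(report, path) {
  stopifnot(inherits(report, "metric_report"))
  jsonlite::write_json(list(mae = report$mae, rmse = report$rmse,
                            r2 = report$r2, n = report$n,
                            relative_errors = report$relative_errors),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Model JSON serialization
#'
#' Persists topology, flat parameters, scalers and metadata; `read_model`
#' restores a usable `woabp_model` (without the optimizer history).
#'
#' @param model a `woabp_model`; @param path file path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "woabp_model"))
  obj <- list(topology = model$topology$sizes,
              parameters = flatten_params(model$params),
              scaler_x = unclass(model$scaler_x),
              scaler_y = unclass(model$scaler_y),
              optimizer = model$optimizer,
              analyte = model$analyte, range = model$range,
              units = model$units)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  s <- as.integer(obj$topology)
  topo <- mlp_topology(s[1], s[-c(1, length(s))], s[length(s)])
  as_scaler <- function(s) {
    lo <- as.numeric(s$min); hi <- as.numeric(s$max)
    span <- if (!is.null(s$span)) as.numeric(s$span) else
      ifelse(hi > lo, hi - lo, 1)
    deg <- if (!is.null(s$degenerate)) as.logical(s$degenerate) else hi <= lo
    structure(list(min = lo, max = hi, span = span, degenerate = deg),
              class = "minmax_scaler")
  }
  sx <- as_scaler(obj$scaler_x)
  sy <- as_scaler(obj$scaler_y)
  structure(list(topology = topo,
                 params = unflatten_params(as.numeric(obj$parameters), topo),
                 scaler_x = sx, scaler_y = sy,
                 optimizer = obj$optimizer, run = NULL, gd_history = NULL,
                 analyte = obj$analyte, range = as.numeric(obj$range),
                 units = obj$units),
            class = "woabp_model")
}

#' Published protein validation table
#'
#' Loads the packaged validation table for urinary protein: 14 samples with
#' the true concentration (mg/dL), the measured pad RGB fed to the network,
#' and the model's predicted concentration. [compute_metrics()] on its
#' true/predicted columns is the package's primary regression check.
#'
#' @return a data frame with columns `serial`, `true`, `R`, `G`, `B`,
#'   `predicted`.
#' @export
protein_validation_table <- function() {
  path <- system.file("extdata", "protein_predictions.csv",
                      package = "uriquant", mustWork = TRUE)
  utils::read.csv(path)
}
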