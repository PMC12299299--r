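#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm coef predict runif rnorm sd
#' @importFrom utils read.csv write.csv
NULL

# Run code with a private RNG stream so package functions are reproducible by
# `seed` without clobbering the caller's .Random.seed.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Coerce a color argument to an n x 3 numeric matrix; remembers whether the
# input was a bare length-3 vector so results can be returned in kind.
as_color_matrix <- function(x, what = "color") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) != 3L)
      stop(what, " must have exactly 3 channels", call. = FALSE)
    x <- matrix(as.numeric(x), nrow = 1L)
    attr(x, "was_vector") <- TRUE
  } else {
    if (ncol(x) != 3L)
      stop(what, " matrix must have 3 columns", call. = FALSE)
    x <- matrix(as.numeric(x), ncol = 3L, dimnames = NULL)
  }
  if (!all(is.finite(x)))
    stop(what, " contains non-finite values", call. = FALSE)
  x
}

drop_color_matrix <- function(m, was_vector, names3) {
  colnames(m) <- names3
  if (isTRUE(was_vector)) {
    v <- m[1L, ]
    names(v) <- names3
    return(v)
  }
  m
}
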