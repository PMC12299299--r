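# Independent oracles, written as literal scalar transcriptions separate from
# the production (vectorized) code paths they check.

# RGB -> CIELab, one color at a time, straight off the defining equations.
lab_oracle <- function(R, G, B) {
  gam <- function(u) {
    u <- u / 255
    if (u <= 0.04045) u / 12.92 else ((u + 0.055) / 1.055)^2.4
  }
  r <- gam(R); g <- gam(G); b <- gam(B)
  X <- 0.4124564 * r + 0.3575761 * g + 0.1804375 * b
  Y <- 0.2126729 * r + 0.7151522 * g + 0.0721750 * b
  Z <- 0.0193339 * r + 0.1191920 * g + 0.9503041 * b
  x <- X / 0.95047; y <- Y / 1.0; z <- Z / 1.08883
  f <- function(t) if (t > 0.008856) t^(1 / 3) else (903.3 * t + 16) / 116
  c(L = 116 * f(y) - 16,
    a = 500 * (f(x) - f(y)),
    b = 200 * (f(y) - f(z)))
}

# Exhaustive between-class-variance search over all 255 candidate thresholds;
# class 0 holds levels [0, T-1], class 1 holds [T, 255]; smallest T on ties.
otsu_oracle <- function(counts) {
  p <- counts / sum(counts)
  lev <- 0:255
  best_T <- NA_integer_; best_s <- -Inf
  for (T in 1:255) {
    w0 <- sum(p[1:T])          # levels 0 .. T-1
    w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum(lev[1:T] * p[1:T]) / w0
    mu1 <- sum(lev[(T + 1):256] * p[(T + 1):256]) / w1
    s <- w0 * w1 * (mu0 - mu1)^2
    if (s > best_s + 1e-12) { best_s <- s; best_T <- T }
  }
  list(threshold = best_T, sigma_b2 = best_s)
}

# Polynomial least squares by explicit normal equations.
polyfit_oracle <- function(x, y, degree) {
  V <- outer(x, 0:degree, `^`)
  drop(solve(t(V) %*% V, t(V) %*% y))
}

# A reproducible set of plausible reacted reagent-pad colors: mid-tone
# (channels 40-160), so every pad is distinctly darker than the light plastic
# carrier — the operating assumption of a single global Otsu threshold.
random_pad_colors <- function(n, seed) {
  set.seed(seed)
  matrix(round(runif(3 * n, 40, 160)), ncol = 3)
}
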