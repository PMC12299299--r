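test_that("noiseless generated pads are rendered exactly", {
  lay <- strip_layout(n_pads = 4)
  cols <- random_pad_colors(4, seed = 1)
  img <- generate_strip_image(lay, cols, noise_sd = 0, highlight = NULL,
                              seed = 1)
  expect_equal(dim(img), c(lay$height, lay$width, 3))
  # every pad-interior pixel equals its pad color exactly
  top <- (lay$height - lay$pad_size) %/% 2 + 1
  for (i in 1:4) {
    left <- lay$margin + 1 + (i - 1) * (lay$pad_size + lay$spacing)
    block <- img[top:(top + lay$pad_size - 1),
                 left:(left + lay$pad_size - 1), , drop = FALSE]
    for (ch in 1:3) expect_true(all(block[, , ch] == cols[i, ch]))
  }
})

test_that("generation is deterministic in the seed", {
  lay <- strip_layout(n_pads = 3)
  cols <- random_pad_colors(3, seed = 2)
  a <- generate_strip_image(lay, cols, noise_sd = 5, seed = 9)
  b <- generate_strip_image(lay, cols, noise_sd = 5, seed = 9)
  c <- generate_strip_image(lay, cols, noise_sd = 5, seed = 10)
  expect_identical(unclass(a), unclass(b))
  expect_false(identical(unclass(a), unclass(c)))
})

test_that("noisy pad interiors average close to the nominal color", {
  lay <- strip_layout(n_pads = 2, pad_size = 50, height = 130)
  cols <- rbind(c(80, 120, 160), c(150, 90, 60))
  img <- generate_strip_image(lay, cols, noise_sd = 5, highlight = NULL,
                              seed = 4)
  top <- (lay$height - 50) %/% 2 + 1
  for (i in 1:2) {
    left <- lay$margin + 1 + (i - 1) * (50 + lay$spacing)
    block <- img[top:(top + 49), left:(left + 49), ]
    means <- apply(block, 3, mean)
    expect_true(all(abs(means - cols[i, ]) < 1.0))
  }
})

test_that("pad colors and layout are validated", {
  lay <- strip_layout(n_pads = 2)
  expect_error(generate_strip_image(lay, rbind(c(1, 2, 3))), "2 pad colors")
  expect_error(strip_layout(n_pads = 0), "n_pads")
  expect_error(strip_layout(pad_size = 200, height = 100), "overflow")
})

test_that("otsu_threshold matches the two-level closed form", {
  h <- gray_histogram(c(rep(50, 100), rep(200, 100)))
  expect_equal(sum(h$p), 1, tolerance = 1e-9)
  res <- otsu_threshold(h)
  expect_identical(res$threshold, 51L)
  expect_equal(res$sigma_b2, 5625)
  expect_equal(res$omega0 + res$omega1, 1, tolerance = 1e-9)
  expect_equal(res$mu0, 50)
  expect_equal(res$mu1, 200)
})

test_that("constant images are a degenerate input for Otsu", {
  expect_error(otsu_threshold(matrix(77, 10, 10)), "degenerate")
})

test_that("otsu_threshold equals the exhaustive search on random histograms", {
  set.seed(21)
  for (i in 1:200) {
    counts <- rpois(256, lambda = rexp(256, 1 / 20))
    if (sum(counts > 0) < 2) counts[c(10, 200)] <- c(5, 5)
    res <- otsu_threshold(structure(list(counts = counts,
                                         p = counts / sum(counts)),
                                    class = "gray_histogram"))
    ref <- otsu_oracle(counts)
    expect_identical(res$threshold, as.integer(ref$threshold))
    expect_equal(res$sigma_b2, ref$sigma_b2, tolerance = 1e-9)
  }
})

test_that("otsu on a two-Gaussian mixture matches the brute-force maximizer", {
  set.seed(8)
  g <- round(c(rnorm(4000, 60, 10), rnorm(4000, 180, 10)))
  g <- pmin(pmax(g, 0), 255)
  res <- otsu_threshold(gray_histogram(g))
  ref <- otsu_oracle(gray_histogram(g)$counts)
  expect_identical(res$threshold, as.integer(ref$threshold))
})

test_that("the attained variance matches EBImage's Otsu (independent check)", {
  # EBImage may settle elsewhere on a flat sigma_b^2 plateau (e.g. an empty
  # gray gap between classes), so equivalence is on the attained criterion,
  # not the threshold index.
  sigma_at <- function(counts, T) {
    p <- counts / sum(counts); lev <- 0:255
    w0 <- sum(p[1:T]); w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) return(0)
    mu0 <- sum(lev[1:T] * p[1:T]) / w0
    mu1 <- sum(lev[(T + 1):256] * p[(T + 1):256]) / w1
    w0 * w1 * (mu0 - mu1)^2
  }
  set.seed(18)
  for (i in 1:10) {
    g <- round(c(rnorm(3000, runif(1, 40, 90), 12),
                 rnorm(3000, runif(1, 150, 210), 12)))
    g <- pmin(pmax(g, 0), 255)
    m <- matrix(g, 60, 100)
    counts <- gray_histogram(m)$counts
    mine <- otsu_threshold(gray_histogram(m))
    eb <- EBImage::otsu(m / 255, range = c(0, 1), levels = 256) * 255
    s_eb <- max(sapply(unique(pmin(pmax(round(eb) + c(0, 1), 1), 255)),
                       function(T) sigma_at(counts, T)))
    expect_equal(mine$sigma_b2, s_eb, tolerance = 1e-9)
  }
})

test_that("class masses conserve the global histogram mean", {
  set.seed(22)
  for (i in 1:20) {
    counts <- rpois(256, 10)
    res <- otsu_threshold(structure(list(counts = counts,
                                         p = counts / sum(counts)),
                                    class = "gray_histogram"))
    total <- sum((0:255) * counts) / sum(counts)
    expect_equal(res$omega0 * res$mu0 + res$omega1 * res$mu1, total,
                 tolerance = 1e-9)
  }
})

test_that("highlight suppression is identity at weight 1 and on constants", {
  img <- array(120, dim = c(70, 70, 3))
  expect_equal(suppress_highlights(img, weight = 1), unclass(img))
  expect_equal(suppress_highlights(img, weight = 0.3), unclass(img),
               tolerance = 1e-9)
  expect_error(suppress_highlights(img, weight = 0), "weight")
  expect_error(suppress_highlights(img, weight = 1.2), "weight")
})

test_that("highlight suppression strictly reduces a specular peak", {
  lay <- strip_layout(n_pads = 3)
  cols <- random_pad_colors(3, seed = 5)
  # +80 glint on the carrier above the pad row
  hl <- list(center = c(15, 100), radii = c(5, 8), amplitude = 80)
  img <- generate_strip_image(lay, cols, noise_sd = 0, highlight = hl,
                              seed = 1)
  clean <- generate_strip_image(lay, cols, noise_sd = 0, highlight = NULL,
                                seed = 1)
  out <- suppress_highlights(img, weight = 0.6)
  # deviation from the clean image inside the highlight neighbourhood
  win_r <- 5:25; win_c <- 80:120
  dev_before <- max(abs(unclass(img)[win_r, win_c, ] -
                          unclass(clean)[win_r, win_c, ]))
  dev_after <- max(abs(out[win_r, win_c, ] -
                         unclass(clean)[win_r, win_c, ]))
  expect_lt(dev_after, dev_before)
})

test_that("process_strip recovers a noiseless strip exactly", {
  lay <- strip_layout(n_pads = 4)
  cols <- random_pad_colors(4, seed = 6)
  img <- generate_strip_image(lay, cols, noise_sd = 0, highlight = NULL,
                              seed = 1)
  pr <- process_strip(img)
  expect_equal(nrow(pr), 4)
  expect_true(all(abs(as.matrix(pr[, c("R", "G", "B")]) - cols) < 1))
  expect_identical(pr$pad, 1:4)          # left-to-right
  expect_false(is.unsorted(pr$col))
})

test_that("process_strip handles noise and a highlight on an 11-pad strip", {
  lay <- strip_layout()
  cols <- random_pad_colors(11, seed = 7)
  img <- generate_strip_image(lay, cols, noise_sd = 5, highlight = "auto",
                              seed = 13)
  pr <- process_strip(img)
  expect_equal(nrow(pr), 11)
  expect_true(all(abs(as.matrix(pr[, c("R", "G", "B")]) - cols) < 3))
})

test_that("pad counts are recovered across random layouts (noiseless)", {
  set.seed(30)
  for (i in 1:50) {
    n <- sample(3:11, 1)
    lay <- strip_layout(n_pads = n, pad_size = sample(c(36, 40, 44), 1),
                        spacing = sample(c(20, 24, 30), 1))
    cols <- random_pad_colors(n, seed = 1000 + i)
    img <- generate_strip_image(lay, cols, noise_sd = 0, highlight = NULL,
                                seed = i)
    pr <- process_strip(img)
    expect_equal(nrow(pr), n)
  }
})

test_that("a blank background image yields an empty result with a warning", {
  img <- array(230, dim = c(80, 200, 3))
  expect_warning(pr <- process_strip(img), "degenerate|no pad")
  expect_equal(nrow(pr), 0)
})

test_that("strip images survive the PNG round trip", {
  lay <- strip_layout(n_pads = 2)
  cols <- random_pad_colors(2, seed = 3)
  img <- generate_strip_image(lay, cols, noise_sd = 3, seed = 2)
  path <- withr::local_tempfile(fileext = ".png")
  write_strip_image(img, path)
  expect_equal(read_strip_image(path), unclass(img), ignore_attr = TRUE)
})
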