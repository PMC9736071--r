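gaussian_window <- function(center, k_umb, n, beta = 1, seed = 1L) {
  set.seed(seed)
  umbrella_window(center, k_umb, rnorm(n, center, sqrt(1 / (beta * k_umb))))
}

test_that("umbrella schedules step by the gap and end exactly at N", {
  p5 <- straight_path_1d(0, 2, 5L)
  expect_equal(build_schedule(p5, 0.5), seq(1, 5, by = 0.5))
  expect_length(build_schedule(p5, 0.5), 9L)
  expect_equal(build_schedule(2L, 0.5), c(1, 1.5, 2))
  expect_equal(build_schedule(5L, 0.75), c(seq(1, 5, by = 0.75), 5))
  expect_error(build_schedule(5L, 10), "too coarse")
  expect_error(build_schedule(5L, 0), "positive")
})

test_that("umbrella windows validate their series and discard", {
  expect_error(umbrella_window(1, 10, c(1, 2, NA)), "non-finite")
  expect_error(umbrella_window(1, 10, 1:5, n_equil_discard = 5L),
               "whole series")
  w <- umbrella_window(1, 10, 1:10, n_equil_discard = 3L)
  expect_equal(w$s_series, 4:10)
})

test_that("overlap is 1 for identical windows, 0 for disjoint ones", {
  a <- umbrella_window(1, 10, seq(0, 1, length.out = 50))
  b <- umbrella_window(1.1, 10, seq(0, 1, length.out = 50))
  rep <- check_overlap(list(a, b))
  expect_equal(rep$pairs$overlap, 1, tolerance = 1e-12)
  far <- umbrella_window(5.5, 10, seq(5, 6, length.out = 50))
  rep <- check_overlap(list(a, far))
  expect_equal(rep$pairs$overlap, 0)
  expect_false(rep$pass)
  expect_equal(rep$proposed_centers, (1 + 5.5) / 2)
})

test_that("overlap of offset Gaussians matches the analytic intersection", {
  # equal-width Gaussians offset by delta share 2*Phi(-delta/(2*sigma))
  sigma <- 0.3
  delta <- 0.5
  k <- 1 / sigma^2
  a <- gaussian_window(0, k, 40000L, seed = 11L)
  b <- gaussian_window(delta, k, 40000L, seed = 12L)
  rep <- check_overlap(list(a, b), n_bins = 60L)
  expect_equal(rep$pairs$overlap, 2 * pnorm(-delta / (2 * sigma)),
               tolerance = 0.05)
})

test_that("single unbiased window reduces WHAM to the plain histogram", {
  set.seed(31)
  s <- rnorm(20000, 1.7, 0.4)
  w <- umbrella_window(1.7, 0, s)   # zero stiffness: no bias
  prof <- wham(list(w), beta = 1, n_bins = 30L)
  breaks <- seq(min(s) - 1e-9, max(s) + 1e-9, length.out = 31L)
  h <- tabulate(findInterval(s, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), 30L)
  keep <- h > 0
  ref <- -log(h[keep] / sum(h) / diff(breaks)[1])
  ref <- ref - min(ref)
  expect_equal(prof$f, ref, tolerance = 1e-8)
})

test_that("WHAM recovers a flat profile from exact Gaussian windows", {
  centers <- seq(1, 5, by = 0.5)
  wins <- lapply(seq_along(centers), function(i)
    gaussian_window(centers[i], 16, 8000L, seed = 100L + i))
  prof <- wham(wins, beta = 1)
  mid <- prof$s_grid > 1.2 & prof$s_grid < 4.8
  expect_lt(max(prof$f[mid]) - min(prof$f[mid]), 0.2)
  # probability normalises to 1 over the grid
  expect_equal(sum(prof$p * prof$bin_width), 1, tolerance = 1e-6)
})

test_that("WHAM is invariant to window order and redundant windows", {
  centers <- seq(1, 4, by = 0.5)
  wins <- lapply(seq_along(centers), function(i)
    gaussian_window(centers[i], 16, 4000L, seed = 200L + i))
  prof <- wham(wins, beta = 1, n_bins = 40L)
  set.seed(1)
  perm <- sample(length(wins))
  prof2 <- wham(wins[perm], beta = 1, n_bins = 40L)
  expect_equal(prof$f, prof2$f, tolerance = 1e-6)
  # adding a duplicate-center window barely moves the estimate
  wins3 <- c(wins, list(gaussian_window(2.5, 16, 4000L, seed = 999L)))
  prof3 <- wham(wins3, beta = 1, n_bins = 40L)
  expect_lt(max(abs(prof3$f - prof$f)), 0.1)
})

test_that("disconnected window sets abort with the gap location", {
  a <- gaussian_window(1, 25, 2000L, seed = 1L)
  b <- gaussian_window(8, 25, 2000L, seed = 2L)
  expect_error(wham(list(a, b)), "disconnected")
})

test_that("non-convergent WHAM reports the residual", {
  a <- gaussian_window(1, 16, 2000L, seed = 5L)
  b <- gaussian_window(1.5, 16, 2000L, seed = 6L)
  expect_error(wham(list(a, b), tol = 1e-16, max_iter = 3L), "residual")
})

test_that("state finding handles the enumerable example", {
  prof <- structure(list(s_grid = 1:5, f = c(0, 1, 0.2, 2, 0),
                         p = rep(0.2, 5), counts = rep(100L, 5),
                         bin_width = 1, beta = 1, minima = NULL,
                         maxima = NULL), class = "fes_profile")
  out <- find_states(prof, prominence = 0.1)
  expect_equal(out$minima$s, c(1, 3, 5))
  expect_equal(out$maxima$s, c(2, 4))
  # alternation: min, max, min, max, min
  all_s <- sort(c(out$minima$s, out$maxima$s))
  expect_equal(all_s, 1:5)
})

test_that("monotone profiles yield endpoint states only", {
  prof <- structure(list(s_grid = 1:6, f = c(0, 0.5, 1.1, 1.9, 2.4, 3),
                         p = rep(1 / 6, 6), counts = rep(10L, 6),
                         bin_width = 1, beta = 1, minima = NULL,
                         maxima = NULL), class = "fes_profile")
  out <- find_states(prof, prominence = 0.2)
  expect_equal(out$minima$s, c(1, 6))
  expect_equal(nrow(out$maxima), 0L)
})

test_that("prominence above the noise floor suppresses spurious states", {
  set.seed(77)
  noise_q <- stats::quantile(replicate(1000, {
    y <- rnorm(40, sd = 0.05)
    max(y) - min(y)
  }), 0.99)
  y <- rnorm(40, sd = 0.05)
  prof <- structure(list(s_grid = seq(1, 5, length.out = 40), f = y - min(y),
                         p = rep(1, 40), counts = rep(50L, 40),
                         bin_width = 0.1, beta = 1, minima = NULL,
                         maxima = NULL), class = "fes_profile")
  out <- find_states(prof, prominence = 2 * noise_q)
  expect_equal(nrow(out$maxima), 0L)
  expect_equal(nrow(out$minima), 2L)   # the two endpoints
})

test_that("free-energy differences read off identified minima", {
  s <- seq(-1.6, 1.6, length.out = 80)
  f <- 3 * (s^2 - 1)^2 + s           # tilted double well
  prof <- structure(list(s_grid = s, f = f - min(f), p = exp(-f),
                         counts = rep(1000L, 80),
                         bin_width = diff(s)[1], beta = 1, minima = NULL,
                         maxima = NULL), class = "fes_profile")
  prof <- find_states(prof, prominence = 0.5)
  expect_equal(nrow(prof$minima), 4L)   # two wells + the two grid endpoints
  wells <- prof$minima[abs(prof$minima$s) < 1.3 & abs(prof$minima$s) > 0.7, ]
  expect_equal(nrow(wells), 2L)
  dg <- delta_g(prof, wells$s[1], wells$s[2])
  # grid minima of the tilted quartic sit near -1.04 and +0.96
  xa <- optimize(function(x) 3 * (x^2 - 1)^2 + x, c(-1.5, 0))$minimum
  xb <- optimize(function(x) 3 * (x^2 - 1)^2 + x, c(0, 1.5))$minimum
  ref <- (3 * (xb^2 - 1)^2 + xb) - (3 * (xa^2 - 1)^2 + xa)
  expect_equal(dg, ref, tolerance = 0.1)
  expect_equal(delta_g(prof, wells$s[1], wells$s[1]), 0)
  expect_error(delta_g(prof, wells$s[1], 0.1), "minimum")
})

test_that("symmetric double-well profiles give zero delta G", {
  s <- seq(-1.5, 1.5, length.out = 61)
  f <- 2 * (s^2 - 1)^2
  prof <- structure(list(s_grid = s, f = f - min(f), p = exp(-f),
                         counts = rep(1000L, 61), bin_width = diff(s)[1],
                         beta = 1, minima = NULL, maxima = NULL),
                    class = "fes_profile")
  prof <- find_states(prof, prominence = 0.5)
  wells <- prof$minima[abs(abs(prof$minima$s) - 1) < 0.2, ]
  expect_equal(delta_g(prof, wells$s[1], wells$s[2]), 0,
               tolerance = 1e-10)
})
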