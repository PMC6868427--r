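test_that("peak-volume populations reproduce known splits and propagate errors", {
  pt <- function(v1, v2) tibble::tibble(condition = "c", fold = c("1B", "2B"),
                                        volume = c(v1, v2))
  expect_equal(estimate_populations(pt(50, 50))$p_1B, 0.5)
  res <- estimate_populations(pt(60, 40))
  expect_equal(res$p_1B, 0.60)
  expect_equal(res$p_2B, 0.40)
  res_b <- estimate_populations(pt(10, 90))
  expect_equal(res_b$p_1B, 0.10)
  expect_equal(res_b$p_2B, 0.90)

  # invariance under uniform volume scaling; populations sum to 1
  for (sc in c(0.01, 1, 250)) {
    r <- estimate_populations(pt(60 * sc, 40 * sc))
    expect_equal(r$p_1B, 0.6)
    expect_equal(r$p_1B + r$p_2B, 1)
  }

  # first-order error propagation
  with_err <- tibble::tibble(condition = "c", fold = c("1B", "2B"),
                             volume = c(60, 40), volume_err = c(3, 2))
  r <- estimate_populations(with_err)
  expect_equal(r$err_1B, sqrt(40^2 * 9 + 60^2 * 4) / 100^2)
  expect_identical(r$err_1B, r$err_2B)

  expect_error(estimate_populations(pt(0, 0)), "zero total")
  expect_error(
    estimate_populations(tibble::tibble(condition = "c", fold = "1B", volume = 5)),
    "one volume per fold"
  )
})

test_that("two-Lorentzian fit recovers noiseless parameters and closed-form areas", {
  x <- seq(0, 10, length.out = 400)
  a <- c(2, 1); x0 <- c(4, 6.5); w <- c(0.4, 0.6); off <- 0.05
  y <- a[1] / (1 + ((x - x0[1]) / (w[1] / 2))^2) +
    a[2] / (1 + ((x - x0[2]) / (w[2] / 2))^2) + off
  fit <- fit_two_lorentzians(tibble::tibble(ppm = x, intensity = y), c(3.8, 6.8))
  pk <- fit$peaks
  expect_lt(max(abs(pk$position - x0) / x0), 1e-6)
  expect_lt(max(abs(pk$fwhm - w) / w), 1e-6)
  expect_lt(max(abs(pk$amplitude - a) / a), 1e-6)
  expect_equal(pk$area, a * pi * w / 2, tolerance = 1e-6)

  # closed-form area equals numerical integration over +/- 50 FWHM
  for (i in 1:2) {
    num <- stats::integrate(function(z) pk$amplitude[i] /
                              (1 + ((z - pk$position[i]) / (pk$fwhm[i] / 2))^2),
                            pk$position[i] - 50 * pk$fwhm[i],
                            pk$position[i] + 50 * pk$fwhm[i])$value
    expect_equal(pk$area[i], num, tolerance = 2e-2)  # tails beyond +/-50 FWHM
    num_wide <- stats::integrate(function(z) pk$amplitude[i] /
                                   (1 + ((z - pk$position[i]) / (pk$fwhm[i] / 2))^2),
                                 -Inf, Inf)$value
    expect_equal(pk$area[i], num_wide, tolerance = 1e-6)
  }
})

test_that("population recovery from noisy traces is accurate and unbiased", {
  # 30:70 split, 1% noise: mean recovery within 2 points, low bias
  p1 <- vapply(1:20, function(s) {
    tr <- lorentzian_trace(0.30, seed = s)
    populations_from_trace(tr, c(12.24, 12.56))$p_1B
  }, numeric(1))
  expect_lt(abs(mean(p1) - 0.30), 0.02)
  expect_lt(abs(mean(p1) - 0.30), 0.01)  # unbiasedness at this separation/SNR
})

test_that("overlapping peaks raise the merged-peak warning", {
  x <- seq(0, 10, length.out = 300)
  y <- 1 / (1 + ((x - 5) / 0.5)^2)
  expect_warning(
    fit_two_lorentzians(tibble::tibble(ppm = x, intensity = y), c(4.9, 5.1)),
    "merged"
  )
})

test_that("trace input validation catches bad axes and positions", {
  x <- seq(0, 10, length.out = 100)
  y <- stats::dnorm(x, 5)
  expect_error(fit_two_lorentzians(tibble::tibble(ppm = x[1:20], intensity = y[1:20]),
                                   c(0.2, 0.8)), ">= 32")
  expect_error(fit_two_lorentzians(tibble::tibble(ppm = sample(x), intensity = y),
                                   c(3, 7)), "monotone")
  expect_error(fit_two_lorentzians(tibble::tibble(ppm = x, intensity = y),
                                   c(3, 30)), "inside the axis")
  expect_error(fit_two_lorentzians(tibble::tibble(ppm = x, intensity = y),
                                   c(5, 5.01)), "separated")
})

test_that("titration summary orders conditions and reports the p_2B trend", {
  mk <- function(p1_vec, labels) {
    purrr::map2_dfr(p1_vec, labels, function(p, lab) {
      tibble::tibble(condition = lab, fold = c("1B", "2B"),
                     volume = c(p, 1 - p) * 100)
    })
  }
  up <- titration_summary(mk(seq(0.6, 0.3, length.out = 5),
                             paste0("mg_", 0:4)))
  expect_identical(attr(up, "direction"), "p_2B increasing")
  expect_equal(up$p_2B, seq(0.4, 0.7, length.out = 5))

  down <- titration_summary(mk(c(0.6, 0.75), c("apo", "edta")))
  expect_identical(attr(down, "direction"), "p_2B decreasing")

  flat <- titration_summary(mk(c(0.5, 0.5, 0.5), c("a", "b", "c")))
  expect_identical(attr(flat, "direction"), "no change")

  expect_error(titration_summary(mk(0.5, "only")), ">= 2 conditions")
})
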