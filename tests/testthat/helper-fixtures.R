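# shared fixtures: everything is generated in code, no files on disk

MIX_TIMES_S <- c(5, 10, 20, 30, 40, 50, 60, 70, 80, 90, 100) / 1000

# U24-like two-state parameters: k_ex 20.89 s^-1 split 60/40 by detailed balance
u24_params <- function() exchange_params(k_f = 20.89 * 0.4, k_b = 20.89 * 0.6,
                                         r1_a = 2.5, r1_b = 2.5)

noisy_decay <- function(params, seed, snr = 100, times = MIX_TIMES_S) {
  d <- decay_curves(params, times)
  withr::with_seed(seed, {
    d$intensity <- d$intensity + stats::rnorm(nrow(d), 0, 1 / snr)
  })
  d
}

random_valid_params <- function(n, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      k_f = stats::runif(n, 0.01, 30),
      k_b = stats::runif(n, 0.01, 30),
      r1_a = stats::runif(n, 0.3, 6),
      r1_b = stats::runif(n, 0.3, 6)
    )
  })
}

lorentzian_trace <- function(p_1B, seed = 1, noise_frac = 0.01,
                             positions = c(12.25, 12.55), fwhm = 0.03,
                             n_points = 256) {
  x <- seq(min(positions) - 8 * fwhm, max(positions) + 8 * fwhm,
           length.out = n_points)
  lor <- function(a, x0) a / (1 + ((x - x0) / (fwhm / 2))^2)
  y <- lor(1 - p_1B, positions[1]) + lor(p_1B, positions[2])
  if (noise_frac > 0) {
    withr::with_seed(seed, {
      y <- y + stats::rnorm(n_points, 0, noise_frac * max(1 - p_1B, p_1B))
    })
  }
  tibble::tibble(ppm = x, intensity = y)
}

synthetic_melt <- function(dH = -200, dS = -0.6, noise_sd = 0,
                           slopes = c(5e-4, 8e-4), seed = 1,
                           t_range = c(283, 383), n = 150) {
  tt <- seq(t_range[1], t_range[2], length.out = n)
  alpha <- 1 / (1 + exp((dH - tt * dS) / (8.314e-3 * tt)))
  a_low <- 0.50 + slopes[1] * (tt - t_range[1])
  a_high <- 0.65 + slopes[2] * (tt - t_range[1])
  a <- a_low * alpha + a_high * (1 - alpha)
  if (noise_sd > 0) {
    withr::with_seed(seed, a <- a + stats::rnorm(n, 0, noise_sd))
  }
  tibble::tibble(temperature = tt, absorbance = a)
}
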