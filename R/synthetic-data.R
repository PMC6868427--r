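#' Scenario configuration for the synthetic-data generators
#'
#' Defines the conditions every generator draws from: the mixing-time
#' grid, signal-to-noise ratio, per-residue exchange parameters,
#' per-condition fold populations, sugar-pucker cases and melting cases.
#' A fixed seed makes every generated table reproducible bit for bit.
#'
#' The default residue set carries the exchange rates characteristic of
#' the D56 two-fold equilibrium in the resting (apo) state — k_ex of
#' 20.89 (U24), 15.24 (A23), 10.11 (U22) and 7.88 s^-1 (C19) split into
#' forward/backward rates by detailed balance at 60/40 populations, with
#' R1 = 2.5 s^-1 in both folds (a typical ribose C1' value at 14.1 T).
#' The default mixing-time grid is 5, 10, 20, ..., 100 ms (11 points) and
#' the default SNR is 100.
#'
#' @param seed Integer seed.
#' @param mixing_times_ms Mixing times in milliseconds.
#' @param snr Signal-to-noise ratio; intensity noise sd is 1/snr.
#' @param residues Data frame with columns `residue_id`, `k_f`, `k_b`,
#'   `r1_a`, `r1_b`.
#' @param conditions Data frame with columns `condition`, `p_1B`.
#' @param pucker_cases Data frame with columns `residue_id`, `j_hz`
#'   (NA = no detectable cross peak), optionally `fold`.
#' @param melt_cases Data frame with columns `dH` (kJ/mol), `dS`
#'   (kJ/mol/K), `base_low_slope`, `base_high_slope` (AU/K),
#'   `noise_sd` (AU).
#' @param volume_cv Lognormal coefficient of variation of peak volumes.
#' @return Object of class `scenario_config` (named list).
#' @export
scenario_config <- function(seed = 1L,
                            mixing_times_ms = c(5, 10, 20, 30, 40, 50, 60, 70, 80, 90, 100),
                            snr = 100,
                            residues = default_residues(),
                            conditions = default_conditions(),
                            pucker_cases = default_pucker_cases(),
                            melt_cases = default_melt_cases(),
                            volume_cv = 0.05) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            all(mixing_times_ms > 0), !is.unsorted(mixing_times_ms, strictly = TRUE),
            snr > 0, volume_cv >= 0)
  stopifnot(all(c("residue_id", "k_f", "k_b", "r1_a", "r1_b") %in% names(residues)))
  stopifnot(all(c("condition", "p_1B") %in% names(conditions)),
            all(conditions$p_1B > 0 & conditions$p_1B < 1))
  structure(
    list(seed = as.integer(seed), mixing_times_ms = mixing_times_ms, snr = snr,
         residues = tibble::as_tibble(residues),
         conditions = tibble::as_tibble(conditions),
         pucker_cases = tibble::as_tibble(pucker_cases),
         melt_cases = tibble::as_tibble(melt_cases),
         volume_cv = volume_cv),
    class = "scenario_config"
  )
}

#' Detailed-balance split of an exchange rate into forward/backward rates
#'
#' Given k_ex = k_f + k_b and the equilibrium 1B population,
#' k_f = k_ex (1 - p_1B) and k_b = k_ex p_1B.
#'
#' @param k_ex Exchange rate constant, s^-1.
#' @param p_1B Equilibrium population of fold 1B.
#' @return Tibble with `k_f`, `k_b`.
#' @export
split_rates <- function(k_ex, p_1B) {
  stopifnot(k_ex > 0, p_1B > 0, p_1B < 1)
  tibble::tibble(k_f = k_ex * (1 - p_1B), k_b = k_ex * p_1B)
}

#' @rdname scenario_config
#' @export
default_residues <- function() {
  k_ex <- c(U24 = 20.89, A23 = 15.24, U22 = 10.11, C19 = 7.88)
  tibble::tibble(
    residue_id = names(k_ex),
    k_f = unname(k_ex) * 0.40,   # detailed balance at 60/40 (1B/2B)
    k_b = unname(k_ex) * 0.60,
    r1_a = 2.5,
    r1_b = 2.5
  )
}

#' @rdname scenario_config
#' @export
default_conditions <- function() {
  tibble::tibble(
    condition = c("apo", "mg_25eq", "edta_24eq", "branched", "branched_mg"),
    p_1B = c(0.60, 0.30, 0.75, 0.25, 0.10)
  )
}

#' @rdname scenario_config
#' @export
default_pucker_cases <- function() {
  tibble::tibble(
    residue_id = c("U12_1B", "A23_1B", "U12_2B", "A23_2B"),
    j_hz = c(8.8, 4.6, 8.8, NA_real_)
  )
}

#' @rdname scenario_config
#' @export
default_melt_cases <- function() {
  tibble::tibble(
    case = c("fold_1B", "fold_2B"),
    dH = c(-200, -190),
    dS = c(-0.60, -0.57),
    base_low_slope = 0.0005,
    base_high_slope = 0.0008,
    noise_sd = 0.002
  )
}

#' Condition presets mirroring the titration series
#'
#' `"mg_titration"` is a five-step series from the apo equilibrium
#' (p_1B = 0.60) to the magnesium-saturated one (p_1B = 0.30);
#' `"branched_mg"` pairs the branched RNA with and without Mg2+.
#'
#' @param name Preset name.
#' @return A conditions tibble usable in [scenario_config()].
#' @export
condition_preset <- function(name = c("mg_titration", "edta_series", "branched_mg")) {
  name <- match.arg(name)
  switch(name,
    mg_titration = tibble::tibble(
      condition = c("apo", "mg_5eq", "mg_10eq", "mg_15eq", "mg_25eq"),
      p_1B = seq(0.60, 0.30, length.out = 5)
    ),
    edta_series = tibble::tibble(
      condition = c("apo", "edta_24eq"),
      p_1B = c(0.60, 0.75)
    ),
    branched_mg = tibble::tibble(
      condition = c("branched", "branched_mg"),
      p_1B = c(0.25, 0.10)
    )
  )
}

#' Synthetic decay data set (ZZ auto-peaks + T1 channels)
#'
#' Evaluates the closed-form exchange model for every configured residue
#' on the configured mixing-time grid and adds i.i.d. Gaussian noise of
#' sd 1/snr to the normalized intensities. Fully deterministic given the
#' config seed.
#'
#' @param cfg A [scenario_config()].
#' @return Tibble with columns `residue_id`, `experiment`, `channel`,
#'   `mixing_time_ms`, `intensity`, `intensity_err`.
#' @export
gen_exchange_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  times <- cfg$mixing_times_ms / 1000
  noise_sd <- 1 / cfg$snr
  withr::with_seed(cfg$seed, {
    purrr::pmap_dfr(cfg$residues, function(residue_id, k_f, k_b, r1_a, r1_b, ...) {
      p <- exchange_params(k_f, k_b, r1_a, r1_b)
      d <- decay_curves(p, times)
      d$intensity <- d$intensity + stats::rnorm(nrow(d), 0, noise_sd)
      tibble::tibble(
        residue_id = residue_id,
        experiment = ifelse(d$channel %in% c("AA", "BB"), "ZZ", "T1"),
        channel = d$channel,
        mixing_time_ms = d$mixing_time * 1000,
        intensity = d$intensity,
        intensity_err = noise_sd
      )
    })
  })
}

#' Synthetic peak-volume tables per condition
#'
#' Draws one volume per fold and condition lognormally around
#' p_fold * V_total with coefficient of variation `cfg$volume_cv`.
#'
#' @param cfg A [scenario_config()].
#' @param probe Probe label stamped on every row.
#' @param v_total Total volume scale (arbitrary units).
#' @return Tibble with columns `condition`, `probe`, `fold`, `volume`,
#'   `volume_err`.
#' @export
gen_peak_tables <- function(cfg, probe = "A4_H8C8", v_total = 100) {
  stopifnot(inherits(cfg, "scenario_config"))
  cv <- cfg$volume_cv
  sdlog <- sqrt(log(1 + cv^2))
  withr::with_seed(cfg$seed + 1L, {
    purrr::pmap_dfr(cfg$conditions, function(condition, p_1B, ...) {
      mu <- c(`1B` = p_1B, `2B` = 1 - p_1B) * v_total
      vol <- if (cv > 0) {
        stats::rlnorm(2, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
      } else mu
      tibble::tibble(
        condition = condition, probe = probe,
        fold = c("1B", "2B"), volume = unname(vol), volume_err = unname(mu) * cv
      )
    })
  })
}

#' Synthetic 1D traces of two Lorentzian peaks per condition
#'
#' Builds, per condition, a 1D slice of two Lorentzian lines whose areas
#' are proportional to the fold populations, plus additive Gaussian noise
#' expressed as a fraction of the taller peak amplitude. The 2B peak sits
#' at the lower chemical shift.
#'
#' @param cfg A [scenario_config()].
#' @param positions Peak positions in ppm `(2B, 1B)`.
#' @param fwhm Linewidth (ppm) of both peaks.
#' @param noise_frac Noise sd as a fraction of the maximum amplitude.
#' @param n_points Grid points across the window.
#' @return Tibble with columns `condition`, `ppm`, `intensity`.
#' @export
gen_traces <- function(cfg, positions = c(12.25, 12.55), fwhm = 0.03,
                       noise_frac = 0.01, n_points = 256) {
  stopifnot(inherits(cfg, "scenario_config"), length(positions) == 2L,
            abs(diff(positions)) > 2 * fwhm)
  window <- range(positions) + c(-1, 1) * 8 * fwhm
  x <- seq(window[1], window[2], length.out = n_points)
  lor <- function(a, x0, w) a / (1 + ((x - x0) / (w / 2))^2)
  withr::with_seed(cfg$seed + 2L, {
    purrr::pmap_dfr(cfg$conditions, function(condition, p_1B, ...) {
      # equal widths: amplitudes proportional to areas hence to populations
      amp <- c(1 - p_1B, p_1B)  # (2B at positions[1], 1B at positions[2])
      y <- lor(amp[1], positions[1], fwhm) + lor(amp[2], positions[2], fwhm)
      y <- y + stats::rnorm(n_points, 0, noise_frac * max(amp))
      tibble::tibble(condition = condition, ppm = x, intensity = y)
    })
  })
}

#' Synthetic quantitative-J coupling tables
#'
#' Emits cross/diagonal intensities obeying the tangent law
#' S_cross/S_diag = -tan^2(2 pi J zeta) with relative Gaussian noise on
#' both intensities; a case with `j_hz = NA` emits a below-threshold
#' cross peak (no detectable coupling).
#'
#' @param cfg A [scenario_config()].
#' @param zeta Evolution delay, seconds.
#' @param noise_frac Relative noise on the intensities (0 = exact).
#' @return Tibble with columns `residue_id`, `s_cross`, `s_diag`, `zeta`,
#'   `detected`.
#' @export
gen_coupling_table <- function(cfg, zeta = 0.01305, noise_frac = 0) {
  stopifnot(inherits(cfg, "scenario_config"))
  withr::with_seed(cfg$seed + 3L, {
    purrr::pmap_dfr(cfg$pucker_cases, function(residue_id, j_hz, ...) {
      s_diag <- 1
      if (is.na(j_hz)) {
        s_cross <- -1e-4  # below any sensible detection threshold
        detected <- FALSE
      } else {
        s_cross <- ratio_from_j(j_hz, zeta) * s_diag
        detected <- TRUE
      }
      if (noise_frac > 0) {
        s_diag <- s_diag * (1 + stats::rnorm(1, 0, noise_frac))
        s_cross <- s_cross * (1 + stats::rnorm(1, 0, noise_frac))
        s_cross <- min(s_cross, 0)
      }
      tibble::tibble(residue_id = residue_id, s_cross = s_cross,
                     s_diag = s_diag, zeta = zeta, detected = detected)
    })
  })
}

#' Synthetic absorbance melting curves
#'
#' Forward two-state model: alpha(T) from the configured (dH, dS), folded
#' and unfolded linear baselines, absorbance
#' A(T) = A_low(T) alpha + A_high(T) (1 - alpha) + noise, five
#' heating-cooling cycles per case by default.
#'
#' @param cfg A [scenario_config()].
#' @param t_range Temperature range in Kelvin.
#' @param n_points Points per cycle.
#' @param n_cycles Cycles per melt case.
#' @param wavelength_nm Wavelength label (250 or 260).
#' @return Tibble with columns `case`, `cycle_id`, `temperature`
#'   (Kelvin), `absorbance`, `wavelength_nm`.
#' @export
gen_melt_curves <- function(cfg, t_range = c(283, 383), n_points = 150,
                            n_cycles = 5, wavelength_nm = 260) {
  stopifnot(inherits(cfg, "scenario_config"), n_points >= 20)
  tt <- seq(t_range[1], t_range[2], length.out = n_points)
  withr::with_seed(cfg$seed + 4L, {
    purrr::pmap_dfr(cfg$melt_cases, function(case, dH, dS, base_low_slope,
                                             base_high_slope, noise_sd, ...) {
      alpha <- 1 / (1 + exp((dH - tt * dS) / (.R_GAS * tt)))
      a_low <- 0.50 + base_low_slope * (tt - t_range[1])
      a_high <- 0.65 + base_high_slope * (tt - t_range[1])
      purrr::map_dfr(seq_len(n_cycles), function(cy) {
        a <- a_low * alpha + a_high * (1 - alpha) +
          stats::rnorm(n_points, 0, noise_sd)
        tibble::tibble(case = case, cycle_id = paste0(case, "_c", cy),
                       temperature = tt, absorbance = a,
                       wavelength_nm = wavelength_nm)
      })
    })
  })
}

#' Write a complete synthetic scenario to disk
#'
#' Generates every input table of the pipeline under one directory
#' (exchange.csv, peaks.csv, traces.csv, couplings.csv, melt.csv) plus a
#' manifest.json recording the configuration, seed and per-file MD5
#' checksums. Identical seeds yield identical files.
#'
#' @param cfg A [scenario_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest as a list.
#' @export
generate_scenario <- function(cfg, dir) {
  stopifnot(inherits(cfg, "scenario_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list(
    exchange.csv = gen_exchange_dataset(cfg),
    peaks.csv = gen_peak_tables(cfg),
    traces.csv = gen_traces(cfg),
    couplings.csv = gen_coupling_table(cfg),
    melt.csv = gen_melt_curves(cfg)
  )
  for (nm in names(files)) {
    readr::write_csv(files[[nm]], file.path(dir, nm))
  }
  manifest <- list(
    seed = cfg$seed,
    snr = cfg$snr,
    mixing_times_ms = cfg$mixing_times_ms,
    residues = cfg$residues,
    conditions = cfg$conditions,
    checksums = as.list(tools::md5sum(file.path(dir, names(files))))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
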