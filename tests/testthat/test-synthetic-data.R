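test_that("generators are deterministic under a fixed seed", {
  cfg <- scenario_config(seed = 42)
  expect_identical(gen_exchange_dataset(cfg), gen_exchange_dataset(cfg))
  expect_identical(gen_peak_tables(cfg), gen_peak_tables(cfg))
  expect_identical(gen_traces(cfg), gen_traces(cfg))
  expect_identical(gen_coupling_table(cfg), gen_coupling_table(cfg))
  expect_identical(gen_melt_curves(cfg), gen_melt_curves(cfg))
  # a different seed changes the noise
  cfg2 <- scenario_config(seed = 43)
  expect_false(identical(gen_exchange_dataset(cfg), gen_exchange_dataset(cfg2)))
})

test_that("noise-free settings reproduce the forward models exactly", {
  cfg <- scenario_config(seed = 1, snr = 1e12, volume_cv = 0)
  d <- gen_exchange_dataset(cfg)
  u24 <- dplyr::filter(d, residue_id == "U24")
  clean <- decay_curves(exchange_params(20.89 * 0.4, 20.89 * 0.6, 2.5, 2.5),
                        MIX_TIMES_S)
  expect_identical(u24$channel, clean$channel)
  expect_equal(u24$intensity, clean$intensity, tolerance = 1e-9)

  pops <- estimate_populations(gen_peak_tables(cfg))
  expect_equal(sort(pops$p_1B), sort(cfg$conditions$p_1B), tolerance = 1e-12)

  cp <- gen_coupling_table(cfg, noise_frac = 0)
  res <- analyze_coupling(cp)
  expect_equal(res$j_hz[res$residue_id == "U12_1B"], 8.8, tolerance = 1e-9)
  expect_equal(res$j_hz[res$residue_id == "A23_1B"], 4.6, tolerance = 1e-9)
  expect_match(res$status[res$residue_id == "A23_2B"], "no detectable")
})

test_that("default conditions mirror the titration states and validate downstream", {
  cfg <- scenario_config(seed = 7)
  expect_equal(cfg$mixing_times_ms, c(5, 10, 20, 30, 40, 50, 60, 70, 80, 90, 100))
  expect_equal(default_conditions()$p_1B, c(0.60, 0.30, 0.75, 0.25, 0.10))
  expect_equal(default_residues()$k_f + default_residues()$k_b,
               c(20.89, 15.24, 10.11, 7.88))
  # detailed balance at 60/40 holds for every preset residue
  for (i in seq_len(nrow(cfg$residues))) {
    pops <- populations_from_rates(as.numeric(cfg$residues[i, -1]))
    expect_equal(pops$p_1B, 0.60, tolerance = 1e-12)
  }
})

test_that("rate splitting obeys detailed balance", {
  s <- split_rates(20.89, 0.6)
  expect_equal(s$k_f + s$k_b, 20.89)
  expect_equal(s$k_b / (s$k_f + s$k_b), 0.6)
  expect_error(split_rates(10, 1.2), "p_1B")
})

test_that("exchange fits recover each preset k_ex from generated data within 5%", {
  k_true <- c(U24 = 20.89, A23 = 15.24, U22 = 10.11, C19 = 7.88)
  rel_err <- sapply(1:5, function(s) {
    d <- gen_exchange_dataset(scenario_config(seed = s))
    d$mixing_time <- d$mixing_time_ms / 1000
    sapply(names(k_true), function(rid) {
      f <- fit_exchange(dplyr::filter(d, residue_id == rid))
      abs(f$k_ex - k_true[[rid]]) / k_true[[rid]]
    })
  })
  expect_lt(max(rowMeans(rel_err)), 0.05)
})

test_that("mg titration preset drives p_2B upward through the analysis", {
  cfg <- scenario_config(seed = 11, conditions = condition_preset("mg_titration"))
  ts <- titration_summary(gen_peak_tables(cfg))
  expect_identical(attr(ts, "direction"), "p_2B increasing")
})

test_that("branched+Mg preset lands near the 10/90 split", {
  p1 <- vapply(1:20, function(s) {
    cfg <- scenario_config(seed = s, conditions = condition_preset("branched_mg"))
    pops <- estimate_populations(gen_peak_tables(cfg))
    pops$p_1B[pops$condition == "branched_mg"]
  }, numeric(1))
  expect_equal(mean(p1), 0.10, tolerance = 0.02 / 0.10)
})

test_that("melt generator round-trips its thermodynamics and wavelength labels", {
  cfg <- scenario_config(seed = 3, melt_cases = tibble::tibble(
    case = "m", dH = -200, dS = -0.6, base_low_slope = 5e-4,
    base_high_slope = 8e-4, noise_sd = 0
  ))
  m <- gen_melt_curves(cfg, n_cycles = 2)
  one <- dplyr::filter(m, cycle_id == "m_c1")
  fit <- fit_vant_hoff(association_degree(one), n_boot = 0)
  expect_equal(fit$tm, 200 / 0.6, tolerance = 0.3 / 333)
  expect_equal(fit$dH, -200, tolerance = 0.05)
  expect_equal(fit$dS, -0.6, tolerance = 0.05)

  for (wl in c(250, 260)) {
    expect_equal(unique(gen_melt_curves(cfg, wavelength_nm = wl)$wavelength_nm), wl)
  }

  noisy <- gen_melt_curves(scenario_config(seed = 3), n_cycles = 5)
  res <- cycle_average(dplyr::filter(noisy, case == "fold_1B"))
  expect_gt(res$tm_sd, 0)
  expect_equal(res$tm_mean, 333.33, tolerance = 1 / 333)
})

test_that("a written scenario validates against every reader and is seed-stable", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- scenario_config(seed = 21)
  m1 <- generate_scenario(cfg, dir1)
  m2 <- generate_scenario(cfg, dir2)
  expect_identical(unname(unlist(m1$checksums)), unname(unlist(m2$checksums)))

  expect_no_warning({
    d <- read_decay_table(file.path(dir1, "exchange.csv"))
    pk <- read_peak_table(file.path(dir1, "peaks.csv"))
    tr <- read_trace(file.path(dir1, "traces.csv"))
    cp <- read_coupling_table(file.path(dir1, "couplings.csv"))
    ml <- read_melt_table(file.path(dir1, "melt.csv"))
  })
  expect_setequal(unique(d$channel), c("AA", "BB", "A", "B"))
  expect_equal(nrow(pk), 10)
  expect_true(all(c("ppm", "intensity") %in% names(tr)))
  expect_true(all(ml$temperature > 273))
})
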