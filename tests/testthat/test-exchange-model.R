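test_that("rate matrix reproduces the two-site exchange convention", {
  # no exchange: eigenvalues are just the negated relaxation rates
  rm0 <- rate_matrix(exchange_params(0, 0, 2, 3))
  expect_equal(sort(c(rm0$lambda1, rm0$lambda2)), c(-3, -2))

  # symmetric exchange: lambda = -(k + R) +/- k
  rms <- rate_matrix(exchange_params(5, 5, 2, 2))
  expect_equal(rms$lambda1, -2)
  expect_equal(rms$lambda2, -12)

  # asymmetric rates, equal R1: frozen values from a generic eigen-solver
  rma <- rate_matrix(exchange_params(8.356, 12.534, 2.5, 2.5))
  expect_equal(rma$lambda1, -2.5, tolerance = 1e-10)
  expect_equal(rma$lambda2, -23.39, tolerance = 1e-10)
  expect_equal(rma$a11, 8.356 + 2.5)
  expect_equal(rma$a22, 12.534 + 2.5)
  expect_equal(rma$a12, -12.534)
  expect_equal(rma$a21, -8.356)

  # trace and determinant identities hold for random parameter sets
  grid <- random_valid_params(50, seed = 7)
  for (i in seq_len(nrow(grid))) {
    rm <- rate_matrix(as.numeric(grid[i, ]))
    expect_equal(rm$lambda1 + rm$lambda2, -(rm$a11 + rm$a22))
    expect_equal(rm$lambda1 * rm$lambda2, rm$a11 * rm$a22 - rm$a12 * rm$a21)
    expect_true(rm$lambda1 >= rm$lambda2)
    expect_lte(rm$lambda1, 0)
  }
})

test_that("parameter validation rejects negative rates", {
  expect_error(exchange_params(-1, 1, 2, 2), "k_f and k_b")
  expect_error(exchange_params(1, 1, 0, 2), "r1_a and r1_b")
})

test_that("ZZ auto-peak curves match trivial limits and the frozen oracle value", {
  # normalization at zero mixing time, arbitrary parameters
  zz0 <- zz_auto_curves(exchange_params(3, 7, 1.2, 4.1), 0)
  expect_identical(zz0$M_AA, 1)
  expect_identical(zz0$M_BB, 1)

  # pure relaxation when exchange is off
  t <- seq(0, 0.1, by = 0.01)
  zz <- zz_auto_curves(exchange_params(0, 0, 2, 3), t)
  expect_equal(zz$M_AA, exp(-2 * t))
  expect_equal(zz$M_BB, exp(-3 * t))

  # frozen value from the matrix-exponential oracle (initial vector (1,0))
  zz5 <- zz_auto_curves(exchange_params(8.356, 12.534, 2.5, 2.5), 0.05)
  expect_equal(zz5$M_AA, 0.653707006966, tolerance = 1e-10)
  expect_equal(zz5$M_BB, 0.539312059157, tolerance = 1e-10)
})

test_that("T1 curves match trivial limits and the frozen oracle value", {
  t <- seq(0, 0.1, by = 0.01)
  # symmetric exchange starting from equilibrium is invisible to T1
  t1s <- t1_curves(exchange_params(6, 6, 2, 2), t)
  expect_equal(t1s$M_A, exp(-2 * t))
  expect_equal(t1s$M_B, exp(-2 * t))

  # k_ex = 0 reduces to independent single exponentials
  t10 <- t1_curves(exchange_params(0, 0, 2, 3), t)
  expect_equal(t10$M_A, exp(-2 * t))
  expect_equal(t10$M_B, exp(-3 * t))

  # frozen values from the matrix-exponential oracle with equilibrium start
  t15 <- t1_curves(exchange_params(8.356, 12.534, 2.0, 3.0), 0.05)
  expect_equal(t15$M_A, 0.898075857114, tolerance = 1e-10)
  expect_equal(t15$M_B, 0.870669325022, tolerance = 1e-10)
})

test_that("closed forms agree with the matrix-exponential propagator over a random grid", {
  grid <- random_valid_params(1000, seed = 11)
  tt <- withr::with_seed(13, stats::runif(nrow(grid), 0, 0.2))
  worst <- 0
  for (i in seq_len(nrow(grid))) {
    p <- exchange_params(grid$k_f[i], grid$k_b[i], grid$r1_a[i], grid$r1_b[i])
    t <- tt[i]
    zz <- zz_auto_curves(p, t)
    t1 <- t1_curves(p, t)
    o_aa <- exchange_propagator(p, t, c(1, 0))[1]
    o_bb <- exchange_propagator(p, t, c(0, 1))[2]
    pa <- p$k_b / p$k_ex
    o_eq <- exchange_propagator(p, t, c(pa, 1 - pa))
    worst <- max(worst,
                 abs(zz$M_AA - o_aa), abs(zz$M_BB - o_bb),
                 abs(t1$M_A - o_eq[1] / pa), abs(t1$M_B - o_eq[2] / (1 - pa)))
  }
  expect_lt(worst, 1e-9)
})

test_that("propagator is the identity at t = 0 and diagonal when exchange is off", {
  p <- exchange_params(4, 9, 1.5, 2.5)
  expect_equal(exchange_propagator(p, 0, c(0.3, 0.7)), c(0.3, 0.7))
  p0 <- exchange_params(0, 0, 2, 3)
  expect_equal(exchange_propagator(p0, 0.1, c(1, 1)),
               c(exp(-0.2), exp(-0.3)))
})

test_that("swapping folds swaps the curves (relabelling symmetry)", {
  t <- seq(0.005, 0.1, length.out = 11)
  p <- exchange_params(3.7, 9.1, 1.8, 3.3)
  ps <- exchange_params(9.1, 3.7, 3.3, 1.8)
  expect_equal(zz_auto_curves(p, t)$M_AA, zz_auto_curves(ps, t)$M_BB)
  expect_equal(t1_curves(p, t)$M_A, t1_curves(ps, t)$M_B)
})

test_that("degenerate eigenvalues fall back to the limiting expression", {
  # k_f = k_b = 0 with equal R1: both eigenvalues equal -R1
  p <- exchange_params(0, 0, 2, 2)
  rm <- rate_matrix(p)
  expect_true(rm$degenerate)
  t <- c(0, 0.02, 0.1)
  zz <- zz_auto_curves(p, t)
  expect_equal(zz$M_AA, exp(-2 * t), tolerance = 1e-12)
  expect_equal(zz$M_BB, exp(-2 * t), tolerance = 1e-12)
})

test_that("populations from rates follow detailed balance and sum to one", {
  expect_equal(as.numeric(populations_from_rates(exchange_params(5, 5, 1, 1))),
               c(0.5, 0.5))
  pops <- populations_from_rates(exchange_params(8.356, 12.534, 2.5, 2.5))
  expect_equal(pops$p_1B, 0.6, tolerance = 1e-4)
  expect_equal(pops$p_2B, 0.4, tolerance = 1e-4)
  expect_identical(pops$p_1B + pops$p_2B, 1)
  expect_error(populations_from_rates(exchange_params(0, 0, 2, 2)), "undefined")

  grid <- random_valid_params(100, seed = 3)
  sums <- vapply(seq_len(nrow(grid)), function(i) {
    sum(populations_from_rates(as.numeric(grid[i, ])))
  }, numeric(1))
  expect_true(all(sums == 1))
})
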