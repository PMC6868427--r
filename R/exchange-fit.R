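#' Joint fit of ZZ-exchange and T1 decay curves
#'
#' Fits the four shared parameters (k_f, k_b, R1 of each fold) of the
#' two-site longitudinal exchange model to all supplied decay channels of
#' one residue simultaneously, by bounded Levenberg-Marquardt least
#' squares. Either the two ZZ auto-peak channels (AA, BB) alone or all
#' four channels (plus T1 channels A, B) may be supplied; every channel
#' contributes residuals against its closed-form curve with the same
#' parameter vector. When `intensity_err` is present residuals are
#' weighted 1/err; otherwise the fit is unweighted.
#'
#' Starting values, when not supplied, are derived from the data: R1 seeds
#' from log-linear decay of the T1 (or auto-peak) channels and the k_ex
#' seed from the excess decay of AA relative to A. Up to five bounded
#' multi-start restarts are attempted before the fit is declared failed.
#'
#' @param data A data frame with columns `channel` (values among
#'   "AA", "BB", "A", "B"), `mixing_time` (seconds), `intensity`
#'   (normalized, 1 at zero mixing time) and optionally `intensity_err`.
#'   A `residue_id` column, if present, must hold a single residue.
#' @param init Optional [exchange_params()] starting values.
#' @return An object of class `exchange_fit`: list with `params`
#'   ([exchange_params()] best fit), `k_ex`, `populations` (tibble),
#'   `rss`, `converged`, `data` (the input), `residual_sd`, and `mc`
#'   (NULL until [monte_carlo_errors()] is run).
#' @examples
#' truth <- exchange_params(8.356, 12.534, 2.5, 2.5)
#' d <- decay_curves(truth, seq(0.005, 0.1, length.out = 11))
#' fit <- fit_exchange(d)
#' glance(fit)
#' @export
fit_exchange <- function(data, init = NULL) {
  data <- .validate_decay_data(data)
  channels <- unique(data$channel)
  has_t1 <- all(c("A", "B") %in% channels)
  if (!all(c("AA", "BB") %in% channels) && !has_t1) {
    stop("need at least the AA and BB channels (or all four)", call. = FALSE)
  }
  n_per <- table(data$channel)
  if (any(n_per < 4)) {
    stop("each channel needs >= 4 distinct mixing times", call. = FALSE)
  }

  wt <- if ("intensity_err" %in% names(data) && all(is.finite(data$intensity_err)) &&
             all(data$intensity_err > 0)) 1 / data$intensity_err else rep(1, nrow(data))

  predictor <- .make_predictor(data)
  y <- data$intensity
  resid_fun <- function(theta) wt * (y - predictor(theta))

  starts <- .exchange_starts(data, init)
  lower <- c(0, 0, 1e-6, 1e-6)
  upper <- rep(Inf, 4)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = pmax(s, lower), fn = resid_fun, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12, maxiter = 500)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12 * max(1, best$rss)) {
      best <- list(fit = fit, rss = rss)
    }
    # informative convergence: stop restarting once a good solution is found
    if (!is.null(best) && best$fit$info %in% 1:3) break
  }
  if (is.null(best)) {
    stop("exchange fit failed to converge after bounded restarts", call. = FALSE)
  }

  theta <- best$fit$par
  params <- exchange_params(theta[1], theta[2], max(theta[3], 1e-6), max(theta[4], 1e-6))
  pops <- if (params$k_ex > 0) populations_from_rates(params) else
    tibble::tibble(p_1B = NA_real_, p_2B = NA_real_)
  n_par <- 4L
  dof <- max(nrow(data) - n_par, 1L)
  # residual_sd is on the raw intensity scale (it seeds the Monte-Carlo
  # noise); rss stays the minimized, possibly weighted, objective
  raw_resid <- y - predictor(theta)
  structure(
    list(
      params = params,
      k_ex = params$k_ex,
      populations = pops,
      rss = best$rss,
      residual_sd = sqrt(sum(raw_resid^2) / dof),
      converged = best$fit$info %in% 1:3,
      info = best$fit$info,
      message = best$fit$message,
      data = data,
      mc = NULL
    ),
    class = "exchange_fit"
  )
}

.validate_decay_data <- function(data) {
  stopifnot(is.data.frame(data))
  req <- c("channel", "mixing_time", "intensity")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop("decay data lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if ("residue_id" %in% names(data) && length(unique(data$residue_id)) > 1L) {
    stop("fit_exchange() handles one residue at a time; got several residue_id values",
         call. = FALSE)
  }
  bad <- setdiff(unique(data$channel), c("AA", "BB", "A", "B"))
  if (length(bad)) stop("unknown channel label(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (any(data$mixing_time <= 0)) {
    stop("mixing times must be strictly positive (zero-time point is the normalization)",
         call. = FALSE)
  }
  dplyr::arrange(tibble::as_tibble(data), .data$channel, .data$mixing_time)
}

.predict_channels <- function(params, data) {
  .make_predictor(data)(c(params$k_f, params$k_b, params$r1_a, params$r1_b))
}

# closure evaluating all channels of `data` directly from a parameter vector
# (k_f, k_b, r1_a, r1_b); hot path of the fitter and Monte-Carlo loop
.make_predictor <- function(data) {
  chs <- unique(data$channel)
  idx <- lapply(chs, function(ch) which(data$channel == ch))
  tms <- lapply(idx, function(i) data$mixing_time[i])
  n <- nrow(data)
  function(theta) {
    a11 <- theta[1] + theta[3]; a22 <- theta[2] + theta[4]
    disc <- sqrt((a11 - a22)^2 + 4 * theta[1] * theta[2])
    l1 <- 0.5 * (-(a11 + a22) + disc)
    l2 <- 0.5 * (-(a11 + a22) - disc)
    pred <- numeric(n)
    for (k in seq_along(chs)) {
      cc <- switch(chs[[k]], AA = a22, BB = a11,
                   A = a22 + theta[1], B = a11 + theta[2])
      tt <- tms[[k]]
      pred[idx[[k]]] <- if (disc < .DEGENERATE_TOL) {
        exp(l1 * tt) * (1 + (cc + l1) * tt)
      } else {
        ((cc + l1) * exp(l1 * tt) - (cc + l2) * exp(l2 * tt)) / disc
      }
    }
    pred
  }
}

# data-driven starting values plus bounded multi-start perturbations
.exchange_starts <- function(data, init) {
  if (!is.null(init)) {
    p <- as_exchange_params(init)
    base <- c(p$k_f, p$k_b, p$r1_a, p$r1_b)
  } else {
    slope_of <- function(ch) {
      idx <- data$channel == ch
      if (!any(idx)) return(NA_real_)
      y <- pmax(data$intensity[idx], 1e-6)
      -stats::coef(stats::lm(log(y) ~ data$mixing_time[idx]))[[2]]
    }
    s_A <- slope_of("A"); s_B <- slope_of("B")
    s_AA <- slope_of("AA"); s_BB <- slope_of("BB")
    r1_a0 <- if (is.finite(s_A)) s_A else s_AA / 2
    r1_b0 <- if (is.finite(s_B)) s_B else s_BB / 2
    # AA decays with ~ k_f + r1_a at short times; excess over T1 decay seeds k
    k_f0 <- max(s_AA - r1_a0, 0.5, na.rm = TRUE)
    k_b0 <- max(s_BB - r1_b0, 0.5, na.rm = TRUE)
    base <- c(k_f0, k_b0, max(r1_a0, 0.1), max(r1_b0, 0.1))
  }
  scales <- list(1, 0.3, 3, c(0.3, 3, 1, 1), c(3, 0.3, 1, 1), 0.1)
  lapply(scales[1:6], function(sc) base * sc)
}

#' Monte-Carlo parameter uncertainties for an exchange fit
#'
#' Propagates intensity noise into parameter uncertainties by parametric
#' bootstrap: synthetic data sets are generated from the best-fit curves
#' plus independent Gaussian noise, each is refit, and the standard
#' deviation of every parameter across runs is reported. The noise
#' standard deviation defaults to the residual standard deviation of the
#' fit. Deterministic for a fixed seed.
#'
#' @param fit An `exchange_fit` from [fit_exchange()].
#' @param n_runs Number of Monte-Carlo replicates (>= 2; 1000 for
#'   publication-grade errors).
#' @param noise_sd Gaussian noise standard deviation on normalized
#'   intensities; default `fit$residual_sd`.
#' @param seed Integer RNG seed.
#' @return The fit with `mc` filled in: a list with `errors` (tibble of
#'   per-parameter sd, including `k_ex`), `n_runs`, `n_converged`, `seed`.
#' @export
monte_carlo_errors <- function(fit, n_runs = 1000, noise_sd = NULL, seed = 1L) {
  stopifnot(inherits(fit, "exchange_fit"), n_runs >= 2)
  if (!fit$converged) stop("refusing Monte-Carlo on a non-converged fit", call. = FALSE)
  if (is.null(noise_sd)) noise_sd <- fit$residual_sd
  stopifnot(noise_sd >= 0)

  base <- fit$data
  predictor <- .make_predictor(base)
  par0 <- c(fit$params$k_f, fit$params$k_b, fit$params$r1_a, fit$params$r1_b)
  clean <- predictor(par0)
  draws <- withr::with_seed(seed, {
    lapply(seq_len(n_runs), function(i) clean + stats::rnorm(length(clean), 0, noise_sd))
  })
  lower <- c(0, 0, 1e-6, 1e-6)
  refit_one <- function(y) {
    f <- tryCatch(
      minpack.lm::nls.lm(
        par = par0, fn = function(th) y - predictor(th), lower = lower,
        control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10, maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(f) || !f$info %in% 1:3) return(NULL)
    c(k_f = f$par[1], k_b = f$par[2], r1_a = f$par[3], r1_b = f$par[4],
      k_ex = f$par[1] + f$par[2])
  }
  res <- purrr::compact(lapply(draws, refit_one))
  if (length(res) < 0.8 * n_runs) {
    stop(sprintf("Monte-Carlo unstable: only %d/%d runs converged",
                 length(res), n_runs), call. = FALSE)
  }
  mat <- do.call(rbind, res)
  sds <- apply(mat, 2, stats::sd)
  fit$mc <- list(
    errors = tibble::as_tibble(as.list(sds)),
    n_runs = n_runs,
    n_converged = length(res),
    noise_sd = noise_sd,
    seed = seed
  )
  fit
}

#' @export
print.exchange_fit <- function(x, ...) {
  cat("<exchange_fit>\n")
  cat(sprintf("  k_f = %.4g, k_b = %.4g, r1_a = %.4g, r1_b = %.4g s^-1\n",
              x$params$k_f, x$params$k_b, x$params$r1_a, x$params$r1_b))
  cat(sprintf("  k_ex = %.4g s^-1, populations (1B/2B) = %.3f/%.3f\n",
              x$k_ex, x$populations$p_1B, x$populations$p_2B))
  cat(sprintf("  rss = %.4g over %d points, %sconverged\n",
              x$rss, nrow(x$data), if (x$converged) "" else "NOT "))
  if (!is.null(x$mc)) {
    cat(sprintf("  Monte-Carlo (n = %d): k_ex sd = %.3g s^-1\n",
                x$mc$n_runs, x$mc$errors$k_ex))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an exchange fit into one row per parameter
#'
#' @param x An `exchange_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` and, after
#'   [monte_carlo_errors()], `std.error`.
#' @export
tidy.exchange_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = c("k_f", "k_b", "r1_a", "r1_b", "k_ex"),
    estimate = c(x$params$k_f, x$params$k_b, x$params$r1_a, x$params$r1_b, x$k_ex)
  )
  if (!is.null(x$mc)) {
    err <- x$mc$errors
    out$std.error <- as.numeric(err[1, out$term])
  }
  out
}

#' One-row model summary of an exchange fit
#'
#' @param x An `exchange_fit`.
#' @param ... Unused.
#' @return One-row tibble with `k_ex`, `p_1B`, `p_2B`, `rss`,
#'   `residual_sd`, `converged`, `n_points`, `n_mc`.
#' @export
glance.exchange_fit <- function(x, ...) {
  tibble::tibble(
    k_ex = x$k_ex,
    p_1B = x$populations$p_1B,
    p_2B = x$populations$p_2B,
    rss = x$rss,
    residual_sd = x$residual_sd,
    converged = x$converged,
    n_points = nrow(x$data),
    n_mc = if (is.null(x$mc)) 0L else x$mc$n_runs
  )
}

#' Plot an exchange fit: data points and fitted curves per channel
#'
#' @param object An `exchange_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.exchange_fit <- function(object, ...) {
  d <- object$data
  grid <- seq(0, max(d$mixing_time), length.out = 100)
  fitted <- decay_curves(object$params, grid)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mixing_time, y = .data$intensity,
                                  colour = .data$channel)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = fitted) +
    ggplot2::labs(x = "mixing time (s)", y = "normalized intensity",
                  colour = "channel") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
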