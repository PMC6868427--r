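# gas constant in kJ mol^-1 K^-1 (thermodynamics kept in kJ throughout)
.R_GAS <- 8.314e-3

#' Association degree from an absorbance melting curve
#'
#' Standard UV-melting baseline treatment: straight lines are fitted to
#' the absorbance in a low-temperature (folded) and a high-temperature
#' (unfolded) window, and the association degree is
#' alpha(T) = (A_high(T) - A(T)) / (A_high(T) - A_low(T)).
#' alpha is 1 on the folded baseline, 0 on the unfolded baseline, and
#' dimensionless — invariant under affine rescaling of the absorbance.
#' Values escaping [0, 1] through noise are clipped to [-0.05, 1.05] with
#' a warning. Default windows are the lowest and highest 15% of the
#' temperature range.
#'
#' @param curve Data frame with columns `temperature` (Kelvin, strictly
#'   increasing) and `absorbance`. Use [read_melt_table()] for Celsius
#'   input.
#' @param low_window,high_window Length-2 numeric temperature ranges (K)
#'   for the folded / unfolded baselines; each must contain >= 5 points.
#' @return Tibble with columns `temperature`, `alpha`.
#' @export
association_degree <- function(curve, low_window = NULL, high_window = NULL) {
  stopifnot(is.data.frame(curve),
            all(c("temperature", "absorbance") %in% names(curve)))
  tt <- curve$temperature; a <- curve$absorbance
  if (length(tt) < 20) stop("melting curve needs >= 20 points", call. = FALSE)
  if (any(diff(tt) <= 0)) stop("temperature must be strictly increasing", call. = FALSE)
  rng <- range(tt); span <- diff(rng)
  low_window <- low_window %||% c(rng[1], rng[1] + 0.15 * span)
  high_window <- high_window %||% c(rng[2] - 0.15 * span, rng[2])
  if (low_window[2] >= high_window[1]) stop("baseline windows overlap", call. = FALSE)
  in_low <- tt >= low_window[1] & tt <= low_window[2]
  in_high <- tt >= high_window[1] & tt <= high_window[2]
  if (sum(in_low) < 5 || sum(in_high) < 5) {
    stop("each baseline window must contain >= 5 points", call. = FALSE)
  }
  fit_low <- stats::lm(a[in_low] ~ tt[in_low])
  fit_high <- stats::lm(a[in_high] ~ tt[in_high])
  base_low <- stats::coef(fit_low)[1] + stats::coef(fit_low)[2] * tt
  base_high <- stats::coef(fit_high)[1] + stats::coef(fit_high)[2] * tt
  alpha <- (base_high - a) / (base_high - base_low)
  if (any(alpha < -0.05 | alpha > 1.05)) {
    warning("association degree outside [-0.05, 1.05]; clipped", call. = FALSE)
    alpha <- pmin(pmax(alpha, -0.05), 1.05)
  }
  tibble::tibble(temperature = tt, alpha = alpha)
}

#' Van't Hoff fit of a two-state monomolecular melting transition
#'
#' Fits alpha(T) = 1 / (1 + exp((dH - T dS) / (R T))) for the enthalpy
#' dH (kJ/mol) and entropy dS (kJ/mol/K) of association, both expected
#' negative for a folding transition; the melting temperature follows as
#' Tm = dH / dS, at which alpha = 1/2 exactly. Parameter uncertainties
#' come from Monte-Carlo residual resampling (refit after adding
#' resampled residuals to the fitted curve).
#'
#' @param alpha Data frame with columns `temperature` (K) and `alpha`;
#'   the transition should span at least [0.2, 0.8].
#' @param n_boot Monte-Carlo resampling runs for errors (0 to skip).
#' @param seed RNG seed for the resampling.
#' @return Object of class `vant_hoff_fit`: list with `dH`, `dS` (kJ),
#'   `tm` (K), `rss`, `param_errors` (tibble or NULL), `data`.
#' @examples
#' tt <- seq(293, 373, length.out = 60)
#' a <- 1 / (1 + exp((-200 + tt * 0.6) / (8.314e-3 * tt)))
#' fit_vant_hoff(data.frame(temperature = tt, alpha = a), n_boot = 0)
#' @export
fit_vant_hoff <- function(alpha, n_boot = 200, seed = 1L) {
  stopifnot(is.data.frame(alpha),
            all(c("temperature", "alpha") %in% names(alpha)))
  tt <- alpha$temperature; y <- alpha$alpha
  if (min(y) > 0.2 || max(y) < 0.8) {
    stop("alpha must span at least [0.2, 0.8] for a stable two-parameter fit",
         call. = FALSE)
  }
  model <- function(th, x) 1 / (1 + exp((th[1] - x * th[2]) / (.R_GAS * x)))
  fit_once <- function(yy) {
    # seed Tm from alpha = 0.5 crossing; slope from logit-linearization
    tm0 <- tt[which.min(abs(yy - 0.5))]
    dh0 <- -300
    th0 <- c(dh0, dh0 / tm0)
    f <- minpack.lm::nls.lm(
      par = th0, fn = function(th) yy - model(th, tt),
      control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12, maxiter = 500)
    )
    if (!f$info %in% 1:3) return(NULL)
    f
  }
  fit <- fit_once(y)
  if (is.null(fit)) stop("van't Hoff fit failed to converge", call. = FALSE)
  th <- fit$par
  if (th[2] >= 0) stop("fit gave dS >= 0: not a two-state folding transition", call. = FALSE)
  resid <- fit$fvec
  fitted <- y - resid

  errors <- NULL
  if (n_boot > 0) {
    boot <- withr::with_seed(seed, {
      purrr::map(seq_len(n_boot), function(i) {
        f <- fit_once(fitted + sample(resid, replace = TRUE))
        if (is.null(f)) return(NULL)
        c(dH = f$par[1], dS = f$par[2], tm = f$par[1] / f$par[2])
      })
    })
    mat <- do.call(rbind, purrr::compact(boot))
    if (!is.null(mat) && nrow(mat) >= 2) {
      sds <- apply(mat, 2, stats::sd)
      errors <- tibble::tibble(dH = sds[["dH"]], dS = sds[["dS"]], tm = sds[["tm"]])
    }
  }
  structure(
    list(dH = th[1], dS = th[2], tm = th[1] / th[2],
         rss = sum(resid^2), param_errors = errors,
         data = tibble::as_tibble(alpha)),
    class = "vant_hoff_fit"
  )
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat(sprintf("<vant_hoff_fit> dH = %.1f kJ/mol, dS = %.4f kJ/(mol K), Tm = %.2f K\n",
              x$dH, x$dS, x$tm))
  if (!is.null(x$param_errors)) {
    cat(sprintf("  sd(dH) = %.2f, sd(dS) = %.5f, sd(Tm) = %.3f\n",
                x$param_errors$dH, x$param_errors$dS, x$param_errors$tm))
  }
  invisible(x)
}

#' @rdname fit_vant_hoff
#' @param x A `vant_hoff_fit`.
#' @param ... Unused.
#' @export
tidy.vant_hoff_fit <- function(x, ...) {
  out <- tibble::tibble(term = c("dH", "dS", "tm"),
                        estimate = c(x$dH, x$dS, x$tm))
  if (!is.null(x$param_errors)) {
    out$std.error <- c(x$param_errors$dH, x$param_errors$dS, x$param_errors$tm)
  }
  out
}

#' @rdname fit_vant_hoff
#' @export
glance.vant_hoff_fit <- function(x, ...) {
  tibble::tibble(dH = x$dH, dS = x$dS, tm = x$tm, rss = x$rss,
                 n_points = nrow(x$data))
}

#' Plot a van't Hoff fit over the transformed data
#' @param object A `vant_hoff_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vant_hoff_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(
    temperature = seq(min(d$temperature), max(d$temperature), length.out = 200)
  )
  grid$alpha <- 1 / (1 + exp((object$dH - grid$temperature * object$dS) /
                               (.R_GAS * grid$temperature)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$temperature, y = .data$alpha)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = object$tm, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "temperature (K)", y = "association degree") +
    ggplot2::theme_minimal()
}

#' Average melting temperature over heating-cooling cycles
#'
#' Transforms and fits each cycle of a multi-cycle melting data set
#' independently and reports the per-cycle thermodynamics together with
#' the mean and standard deviation of Tm. Cycles whose fit fails are
#' excluded with a warning; all cycles failing is an error.
#'
#' @param curves Data frame with columns `temperature` (K), `absorbance`,
#'   `cycle_id` (>= 2 cycles).
#' @param low_window,high_window Baseline windows passed to
#'   [association_degree()].
#' @param n_boot Per-cycle bootstrap runs (0 skips per-cycle errors).
#' @param seed RNG seed.
#' @return List with `cycles` (tibble: cycle_id, dH, dS, tm), `tm_mean`,
#'   `tm_sd`, `n_cycles`.
#' @export
cycle_average <- function(curves, low_window = NULL, high_window = NULL,
                          n_boot = 0, seed = 1L) {
  stopifnot(is.data.frame(curves),
            all(c("temperature", "absorbance", "cycle_id") %in% names(curves)))
  ids <- unique(curves$cycle_id)
  if (length(ids) < 2) stop("need >= 2 cycles", call. = FALSE)
  rows <- purrr::map(ids, function(id) {
    cyc <- dplyr::filter(curves, .data$cycle_id == id) |>
      dplyr::arrange(.data$temperature)
    out <- tryCatch({
      a <- suppressWarnings(association_degree(cyc, low_window, high_window))
      f <- fit_vant_hoff(a, n_boot = n_boot, seed = seed)
      tibble::tibble(cycle_id = id, dH = f$dH, dS = f$dS, tm = f$tm)
    }, error = function(e) {
      warning(sprintf("cycle '%s' excluded: %s", id, conditionMessage(e)), call. = FALSE)
      NULL
    })
    out
  })
  cycles <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(cycles) == 0) stop("all cycles failed to fit", call. = FALSE)
  list(
    cycles = cycles,
    tm_mean = mean(cycles$tm),
    tm_sd = stats::sd(cycles$tm),
    n_cycles = nrow(cycles)
  )
}
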