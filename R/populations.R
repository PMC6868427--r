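#' Fold populations from per-fold peak volumes
#'
#' For each (condition, probe) group with one volume per fold,
#' p_1B = V_1B / (V_1B + V_2B) and p_2B its complement; the populations
#' are invariant under uniform scaling of the volumes. When `volume_err`
#' is supplied the uncertainty is propagated to first order:
#' sd(p_1B) = sqrt(V_2B^2 e_1^2 + V_1B^2 e_2^2) / (V_1B + V_2B)^2.
#'
#' @param table Data frame with columns `condition`, `fold` ("1B"/"2B"),
#'   `volume`, optionally `probe` and `volume_err`.
#' @return Tibble with one row per (condition, probe): `p_1B`, `p_2B` and,
#'   when errors were given, `err_1B`, `err_2B`.
#' @examples
#' estimate_populations(data.frame(condition = "apo", fold = c("1B", "2B"),
#'                                 volume = c(60, 40)))
#' @export
estimate_populations <- function(table) {
  stopifnot(is.data.frame(table))
  req <- c("condition", "fold", "volume")
  if (!all(req %in% names(table))) {
    stop("peak table needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (!"probe" %in% names(table)) table$probe <- "default"
  has_err <- "volume_err" %in% names(table)
  if (any(table$volume < 0)) stop("volumes must be >= 0", call. = FALSE)

  table |>
    dplyr::group_by(.data$condition, .data$probe) |>
    dplyr::group_modify(function(g, key) {
      v1 <- unname(g$volume[g$fold == "1B"])
      v2 <- unname(g$volume[g$fold == "2B"])
      if (length(v1) != 1L || length(v2) != 1L) {
        stop(sprintf("condition '%s': need exactly one volume per fold", key$condition),
             call. = FALSE)
      }
      tot <- v1 + v2
      if (tot <= 0) stop(sprintf("condition '%s': zero total volume", key$condition),
                         call. = FALSE)
      out <- tibble::tibble(p_1B = v1 / tot, p_2B = v2 / tot)
      if (has_err) {
        e1 <- g$volume_err[g$fold == "1B"]
        e2 <- g$volume_err[g$fold == "2B"]
        sd1 <- sqrt(v2^2 * e1^2 + v1^2 * e2^2) / tot^2
        out$err_1B <- sd1
        out$err_2B <- sd1  # complementary fractions share the same sd
      }
      out
    }) |>
    dplyr::ungroup()
}

#' Fit two Lorentzian lines plus a baseline to a 1D trace
#'
#' Models a 1D slice as
#' I(x) = sum_i A_i / (1 + ((x - x0_i)/(w_i/2))^2) + baseline,
#' with a constant (default) or linear baseline, by Levenberg-Marquardt
#' least squares. The area of each component is the closed form
#' A_i * pi * w_i / 2. Fits whose centres end up closer than a quarter of
#' the wider line width are flagged as merged.
#'
#' @param trace Data frame with columns `ppm` (strictly monotone, >= 32
#'   points) and `intensity`.
#' @param init_positions Two starting peak positions (ppm), inside the
#'   axis range and separated by more than one grid step.
#' @param baseline "constant" or "linear".
#' @return An object of class `lorentzian_fit`: list with `peaks` (tibble:
#'   `position`, `fwhm`, `amplitude`, `area`), `baseline` coefficients,
#'   `rss`, `converged`, `merged` flag and the input `trace`.
#' @export
fit_two_lorentzians <- function(trace, init_positions, baseline = c("constant", "linear")) {
  baseline <- match.arg(baseline)
  stopifnot(is.data.frame(trace), all(c("ppm", "intensity") %in% names(trace)))
  x <- trace$ppm; y <- trace$intensity
  if (length(x) < 32) stop("trace needs >= 32 points", call. = FALSE)
  dx <- diff(x)
  if (!(all(dx > 0) || all(dx < 0))) stop("ppm axis must be strictly monotone", call. = FALSE)
  stopifnot(length(init_positions) == 2L)
  rng <- range(x)
  if (any(init_positions < rng[1] | init_positions > rng[2])) {
    stop("initial positions must lie inside the axis range", call. = FALSE)
  }
  step <- stats::median(abs(dx))
  if (abs(diff(init_positions)) <= step) {
    stop("initial positions must be separated by more than one grid step", call. = FALSE)
  }

  amp0 <- vapply(init_positions, function(p) y[which.min(abs(x - p))], numeric(1))
  off0 <- stats::quantile(y, 0.1, names = FALSE)
  w0 <- max(4 * step, diff(rng) / 50)
  # theta: x01, x02, log w1, log w2, A1, A2, c0 [, c1]
  theta0 <- c(init_positions, log(w0), log(w0), pmax(amp0 - off0, 1e-3), off0)
  if (baseline == "linear") theta0 <- c(theta0, 0)

  model <- function(theta) {
    l1 <- theta[5] / (1 + ((x - theta[1]) / (exp(theta[3]) / 2))^2)
    l2 <- theta[6] / (1 + ((x - theta[2]) / (exp(theta[4]) / 2))^2)
    base <- theta[7]
    if (baseline == "linear") base <- base + theta[8] * (x - mean(x))
    l1 + l2 + base
  }
  fit <- minpack.lm::nls.lm(
    par = theta0, fn = function(th) y - model(th),
    control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12, maxiter = 500)
  )
  if (!fit$info %in% 1:3) {
    stop("two-Lorentzian fit failed to converge (info = ", fit$info, ")", call. = FALSE)
  }
  th <- fit$par
  w <- exp(th[3:4])
  peaks <- tibble::tibble(
    peak = 1:2,
    position = th[1:2],
    fwhm = w,
    amplitude = th[5:6],
    area = th[5:6] * pi * w / 2
  ) |> dplyr::arrange(.data$position)
  merged <- abs(diff(th[1:2])) < max(w) / 4
  if (merged) warning("fitted peaks overlap strongly (merged-peak flag set)", call. = FALSE)
  structure(
    list(
      peaks = peaks,
      baseline = if (baseline == "linear") th[7:8] else th[7],
      baseline_type = baseline,
      rss = sum(fit$fvec^2),
      converged = TRUE,
      merged = merged,
      trace = tibble::as_tibble(trace),
      .model = model, .par = th
    ),
    class = "lorentzian_fit"
  )
}

#' @export
print.lorentzian_fit <- function(x, ...) {
  cat("<lorentzian_fit>\n")
  print(x$peaks)
  cat(sprintf("  rss = %.4g%s\n", x$rss, if (x$merged) " [merged peaks]" else ""))
  invisible(x)
}

#' @rdname fit_two_lorentzians
#' @param x A `lorentzian_fit`.
#' @param ... Unused.
#' @export
tidy.lorentzian_fit <- function(x, ...) x$peaks

#' Plot a two-Lorentzian fit over its trace
#' @param object A `lorentzian_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lorentzian_fit <- function(object, ...) {
  d <- object$trace
  d$fitted <- object$.model(object$.par)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ppm)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$intensity), size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "intensity") +
    ggplot2::theme_minimal()
}

#' Fold populations from a 1D trace by lineshape integration
#'
#' Convenience wrapper: fits two Lorentzians to the trace and converts the
#' component areas to fold populations. Peak order along the axis maps to
#' folds via `fold_order` (first = lower ppm after sorting).
#'
#' @inheritParams fit_two_lorentzians
#' @param fold_order Character length-2: folds assigned to the two peaks
#'   in order of increasing position.
#' @param condition Label carried into the output.
#' @return Tibble with `condition`, `p_1B`, `p_2B`, `merged`.
#' @export
populations_from_trace <- function(trace, init_positions,
                                   fold_order = c("2B", "1B"),
                                   condition = "trace", baseline = "constant") {
  stopifnot(length(fold_order) == 2L, setequal(fold_order, c("1B", "2B")))
  fit <- fit_two_lorentzians(trace, init_positions, baseline = baseline)
  areas <- stats::setNames(fit$peaks$area, fold_order)
  tot <- sum(areas)
  tibble::tibble(
    condition = condition,
    p_1B = unname(areas["1B"]) / tot,
    p_2B = unname(areas["2B"]) / tot,
    merged = fit$merged
  )
}

#' Population trend across ordered experimental conditions
#'
#' Estimates fold populations for every condition of a peak table (in the
#' order the conditions first appear, or an explicit `condition_order`)
#' and reports the direction of change of the 2B population along that
#' order: "p_2B increasing", "p_2B decreasing", "no change", or
#' "non-monotonic".
#'
#' @param table Peak table as for [estimate_populations()], >= 2 conditions.
#' @param condition_order Optional explicit condition ordering.
#' @return Tibble of per-condition populations (class `titration_summary`)
#'   with the trend in `attr(, "direction")`.
#' @export
titration_summary <- function(table, condition_order = NULL) {
  stopifnot(is.data.frame(table))
  ord <- condition_order %||% unique(table$condition)
  if (length(ord) < 2) stop("need >= 2 conditions", call. = FALSE)
  pops <- estimate_populations(table) |>
    dplyr::mutate(condition = factor(.data$condition, levels = ord)) |>
    dplyr::arrange(.data$condition) |>
    dplyr::mutate(condition = as.character(.data$condition))
  d <- diff(pops$p_2B)
  eps <- 1e-9
  direction <- if (all(abs(d) < eps)) "no change"
    else if (all(d > -eps)) "p_2B increasing"
    else if (all(d < eps)) "p_2B decreasing"
    else "non-monotonic"
  structure(pops, direction = direction, class = c("titration_summary", class(pops)))
}

#' @export
print.titration_summary <- function(x, ...) {
  NextMethod()
  cat("trend:", attr(x, "direction"), "\n")
  invisible(x)
}

#' Bar plot of fold populations across conditions
#' @param object A `titration_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.titration_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("p_1B", "p_2B"),
                              names_to = "fold", values_to = "population") |>
    dplyr::mutate(fold = sub("p_", "", .data$fold),
                  condition = factor(.data$condition, levels = unique(.data$condition)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$population,
                                     fill = .data$fold)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(`1B` = "firebrick", `2B` = "steelblue")) +
    ggplot2::labs(x = NULL, y = "equilibrium population", fill = "fold") +
    ggplot2::theme_minimal()
}
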