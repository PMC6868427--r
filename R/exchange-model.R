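#' Two-site exchange parameter set
#'
#' Bundles the four kinetic/relaxation parameters of one residue exchanging
#' slowly between two folds, here labelled 1B (state A) and 2B (state B):
#' the refolding rate constants and the longitudinal relaxation rate of each
#' fold. All rates are in s^-1.
#'
#' @param k_f Rate constant for the 1B -> 2B transition, s^-1 (>= 0).
#' @param k_b Rate constant for the 2B -> 1B transition, s^-1 (>= 0).
#' @param r1_a Longitudinal relaxation rate R1 of fold 1B, s^-1 (> 0).
#' @param r1_b Longitudinal relaxation rate R1 of fold 2B, s^-1 (> 0).
#' @return An object of class `exchange_params`: a named list with the four
#'   rates plus derived `k_ex = k_f + k_b`.
#' @examples
#' p <- exchange_params(k_f = 8.356, k_b = 12.534, r1_a = 2.5, r1_b = 2.5)
#' p$k_ex
#' @export
exchange_params <- function(k_f, k_b, r1_a, r1_b) {
  stopifnot(
    is.numeric(k_f), length(k_f) == 1L, is.finite(k_f),
    is.numeric(k_b), length(k_b) == 1L, is.finite(k_b),
    is.numeric(r1_a), length(r1_a) == 1L, is.finite(r1_a),
    is.numeric(r1_b), length(r1_b) == 1L, is.finite(r1_b)
  )
  if (k_f < 0 || k_b < 0) stop("rate constants k_f and k_b must be >= 0", call. = FALSE)
  if (r1_a <= 0 || r1_b <= 0) stop("relaxation rates r1_a and r1_b must be > 0", call. = FALSE)
  structure(
    list(k_f = k_f, k_b = k_b, r1_a = r1_a, r1_b = r1_b, k_ex = k_f + k_b),
    class = "exchange_params"
  )
}

#' @export
print.exchange_params <- function(x, ...) {
  cat(sprintf(
    "<exchange_params> k_f = %.4g, k_b = %.4g, r1_a = %.4g, r1_b = %.4g (k_ex = %.4g s^-1)\n",
    x$k_f, x$k_b, x$r1_a, x$r1_b, x$k_ex
  ))
  invisible(x)
}

as_exchange_params <- function(x) {
  if (inherits(x, "exchange_params")) return(x)
  if (is.numeric(x) && length(x) == 4L) {
    nm <- names(x)
    if (!is.null(nm) && all(c("k_f", "k_b", "r1_a", "r1_b") %in% nm)) {
      return(exchange_params(x[["k_f"]], x[["k_b"]], x[["r1_a"]], x[["r1_b"]]))
    }
    return(exchange_params(x[1], x[2], x[3], x[4]))
  }
  if (is.list(x)) return(exchange_params(x$k_f, x$k_b, x$r1_a, x$r1_b))
  stop("cannot interpret input as exchange parameters", call. = FALSE)
}

# threshold below which the eigenvalues are treated as degenerate and the
# limiting (t * exp(lambda t)) form replaces the 0/0 two-exponential form
.DEGENERATE_TOL <- 1e-10

#' Exchange rate matrix and its eigenvalues
#'
#' Constructs the 2x2 evolution matrix of longitudinal magnetization under
#' slow two-site exchange, dM/dt = -A M, with
#' a11 = k_f + r1_a, a22 = k_b + r1_b, a12 = -k_b, a21 = -k_f,
#' and the eigenvalues of -A,
#' lambda_{1,2} = (1/2) [ -(a11 + a22) +/- sqrt((a11 - a22)^2 + 4 a12 a21) ],
#' ordered lambda1 >= lambda2. Both eigenvalues are <= 0 for valid
#' parameters; they coincide only when k_f * k_b = 0 and a11 = a22, which is
#' flagged so the closed-form curves switch to the limiting expression.
#'
#' @param params An [exchange_params()] object (or coercible).
#' @return An object of class `rate_matrix`: list with `a11`, `a12`, `a21`,
#'   `a22`, `lambda1`, `lambda2`, and logical `degenerate`.
#' @examples
#' rate_matrix(exchange_params(5, 5, 2, 2))$lambda2  # -12
#' @export
rate_matrix <- function(params) {
  p <- as_exchange_params(params)
  a11 <- p$k_f + p$r1_a
  a22 <- p$k_b + p$r1_b
  a12 <- -p$k_b
  a21 <- -p$k_f
  disc <- sqrt((a11 - a22)^2 + 4 * a12 * a21)  # a12*a21 = k_f*k_b >= 0
  lambda1 <- 0.5 * (-(a11 + a22) + disc)
  lambda2 <- 0.5 * (-(a11 + a22) - disc)
  structure(
    list(
      a11 = a11, a12 = a12, a21 = a21, a22 = a22,
      lambda1 = lambda1, lambda2 = lambda2,
      degenerate = abs(lambda1 - lambda2) < .DEGENERATE_TOL
    ),
    class = "rate_matrix"
  )
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat(sprintf(
    "<rate_matrix> a11 = %.4g, a12 = %.4g, a21 = %.4g, a22 = %.4g\n  lambda1 = %.6g, lambda2 = %.6g%s\n",
    x$a11, x$a12, x$a21, x$a22, x$lambda1, x$lambda2,
    if (x$degenerate) " (degenerate)" else ""
  ))
  invisible(x)
}

# shared two-exponential kernel of all four closed forms:
#   1/(l1 - l2) [ (c + l1) e^{l1 t} - (c + l2) e^{l2 t} ]
# with c = a22 (AA), a11 (BB), a22 - a21 (A), a11 - a12 (B).
# Degenerate eigenvalues take the l'Hopital limit e^{l t} (1 + (c + l) t).
.biexp <- function(rm, c1, t) {
  out <- if (rm$degenerate) {
    l <- 0.5 * (rm$lambda1 + rm$lambda2)
    exp(l * t) * (1 + (c1 + l) * t)
  } else {
    d <- rm$lambda1 - rm$lambda2
    ((c1 + rm$lambda1) * exp(rm$lambda1 * t) -
       (c1 + rm$lambda2) * exp(rm$lambda2 * t)) / d
  }
  out[t == 0] <- 1  # normalization at zero mixing time is exact by contract
  out
}

#' ZZ-exchange auto-peak decay curves
#'
#' Closed-form normalized auto-peak intensities of the ZZ-exchange
#' experiment, in which only one fold's magnetization is selected at zero
#' mixing time:
#' M_AA(t)/M_AA(0) = [(a22 + lambda1) e^{lambda1 t} - (a22 + lambda2)
#' e^{lambda2 t}] / (lambda1 - lambda2), and symmetrically for M_BB with
#' a11 in place of a22 (the (1,1) and (2,2) elements of the matrix
#' exponential of -A t). Equals 1 at t = 0 and decays monotonically for
#' valid parameters.
#'
#' @param params An [exchange_params()] object.
#' @param times Mixing times in seconds (>= 0).
#' @return A tibble with columns `time`, `M_AA`, `M_BB`.
#' @seealso [t1_curves()], [exchange_propagator()]
#' @export
zz_auto_curves <- function(params, times) {
  p <- as_exchange_params(params)
  stopifnot(is.numeric(times), all(times >= 0))
  rm <- rate_matrix(p)
  tibble::tibble(
    time = as.numeric(times),
    M_AA = .biexp(rm, rm$a22, times),
    M_BB = .biexp(rm, rm$a11, times)
  )
}

#' T1 decay curves under exchange
#'
#' Closed-form normalized intensities of the T1 experiment, in which both
#' folds start at their equilibrium magnetization (p_a, p_b) =
#' (k_b, k_f) / (k_f + k_b) and each channel is normalized by its own
#' zero-time intensity:
#' M_A(t)/M_A(0) = [(a22 - a21 + lambda1) e^{lambda1 t} -
#' (a22 - a21 + lambda2) e^{lambda2 t}] / (lambda1 - lambda2),
#' and M_B likewise with a11 - a12. These expressions are exactly the
#' equilibrium-weighted solution of dM/dt = -A M (detailed balance); the
#' matrix-exponential oracle [exchange_propagator()] is the independent
#' check. With k_ex = 0 they reduce to pure single exponentials.
#'
#' @inheritParams zz_auto_curves
#' @return A tibble with columns `time`, `M_A`, `M_B`.
#' @export
t1_curves <- function(params, times) {
  p <- as_exchange_params(params)
  stopifnot(is.numeric(times), all(times >= 0))
  rm <- rate_matrix(p)
  if (p$k_ex == 0) {
    return(tibble::tibble(
      time = as.numeric(times),
      M_A = exp(-p$r1_a * times),
      M_B = exp(-p$r1_b * times)
    ))
  }
  tibble::tibble(
    time = as.numeric(times),
    M_A = .biexp(rm, rm$a22 - rm$a21, times),
    M_B = .biexp(rm, rm$a11 - rm$a12, times)
  )
}

#' All four decay channels in long format
#'
#' Convenience wrapper evaluating [zz_auto_curves()] and [t1_curves()] on a
#' common time grid and stacking them in the long layout used by
#' [fit_exchange()] and the synthetic-data generator.
#'
#' @inheritParams zz_auto_curves
#' @return A tibble with columns `channel` (AA, BB, A, B), `mixing_time`
#'   (seconds), `intensity`.
#' @export
decay_curves <- function(params, times) {
  zz <- zz_auto_curves(params, times)
  t1 <- t1_curves(params, times)
  dplyr::bind_rows(
    tibble::tibble(channel = "AA", mixing_time = zz$time, intensity = zz$M_AA),
    tibble::tibble(channel = "BB", mixing_time = zz$time, intensity = zz$M_BB),
    tibble::tibble(channel = "A", mixing_time = t1$time, intensity = t1$M_A),
    tibble::tibble(channel = "B", mixing_time = t1$time, intensity = t1$M_B)
  )
}

#' Matrix-exponential propagator (brute-force oracle)
#'
#' Propagates an arbitrary initial magnetization vector under
#' dM/dt = -A M by a generic matrix exponential, M(t) = expm(-A t) m0,
#' making no use of the closed-form two-exponential expressions. Serves as
#' the independent oracle against which [zz_auto_curves()] and
#' [t1_curves()] are validated.
#'
#' @param params An [exchange_params()] object.
#' @param t A single time in seconds (>= 0).
#' @param m0 Initial magnetization, numeric length-2 vector (fold A, fold B).
#' @return Numeric length-2 vector M(t).
#' @export
exchange_propagator <- function(params, t, m0) {
  p <- as_exchange_params(params)
  stopifnot(is.numeric(t), length(t) == 1L, t >= 0,
            is.numeric(m0), length(m0) == 2L)
  A <- matrix(c(p$k_f + p$r1_a, -p$k_b,
                -p$k_f,         p$k_b + p$r1_b),
              nrow = 2, byrow = TRUE)
  as.numeric(Matrix::expm(-A * t) %*% m0)
}

#' Equilibrium fold populations from rate constants
#'
#' Detailed balance links the refolding rate constants to the equilibrium
#' occupancies: p_1B = k_b / (k_f + k_b), p_2B = k_f / (k_f + k_b). The
#' populations sum to 1 exactly and are defined only when k_ex > 0.
#'
#' @param params An [exchange_params()] object (or coercible).
#' @return A tibble with one row: columns `p_1B`, `p_2B`.
#' @examples
#' populations_from_rates(exchange_params(8.356, 12.534, 2.5, 2.5))
#' @export
populations_from_rates <- function(params) {
  p <- as_exchange_params(params)
  if (p$k_ex <= 0) {
    stop("equilibrium populations are undefined when k_ex = 0", call. = FALSE)
  }
  p_1B <- p$k_b / p$k_ex
  tibble::tibble(p_1B = p_1B, p_2B = 1 - p_1B)
}
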