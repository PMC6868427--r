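#' Cross/diagonal intensity ratio expected for a given 3J(H1'H2')
#'
#' The quantitative-J H1'(C1')H2' experiment yields a cross/diagonal peak
#' ratio S_cross/S_diag = -tan^2(2 pi J zeta) for evolution delay zeta.
#' The ratio is <= 0 (cross peak opposite in sign to the diagonal) and
#' diverges at J = 1/(4 zeta) (19.157 Hz at the default zeta).
#'
#' @param j Scalar coupling 3J(H1'H2') in Hz, `0 <= j < 1/(4 zeta)`.
#' @param zeta Evolution delay in seconds (default 0.01305, i.e. 13.05 ms).
#' @return The dimensionless ratio, in (-Inf, 0].
#' @examples
#' ratio_from_j(8.8)   # about -0.777
#' @export
ratio_from_j <- function(j, zeta = 0.01305) {
  stopifnot(is.numeric(j), is.numeric(zeta), zeta > 0)
  bound <- 1 / (4 * zeta)
  if (any(j < 0) || any(j >= bound)) {
    stop(sprintf("j must lie in [0, %.3f) Hz (tangent singularity at the bound)", bound),
         call. = FALSE)
  }
  -tan(2 * pi * j * zeta)^2
}

#' Invert the tangent relation: 3J(H1'H2') from the intensity ratio
#'
#' Inverts S_cross/S_diag = -tan^2(2 pi J zeta) on the principal
#' arctangent branch, giving the unique J in [0, 1/(4 zeta)). Round-trips
#' with [ratio_from_j()] to machine precision.
#'
#' @param ratio Cross/diagonal intensity ratio, must be <= 0.
#' @inheritParams ratio_from_j
#' @return Coupling in Hz.
#' @examples
#' j_from_ratio(ratio_from_j(4.6))  # 4.6
#' @export
j_from_ratio <- function(ratio, zeta = 0.01305) {
  stopifnot(is.numeric(ratio), is.numeric(zeta), zeta > 0)
  if (any(ratio > 0)) {
    stop("ratio must be <= 0 (cross peak is opposite in sign to the diagonal)",
         call. = FALSE)
  }
  atan(sqrt(-ratio)) / (2 * pi * zeta)
}

#' South (C2'-endo) population from a 3J(H1'H2') coupling
#'
#' Two-state north/south model: the observed coupling is the population-
#' weighted average of the limiting couplings of the pure C3'-endo (north,
#' small J) and C2'-endo (south, large J) conformers, so
#' f_south = (J - J_north) / (J_south - J_north). Values outside the
#' limits are clamped to [0, 1] with a warning. The default limits
#' (1.0 and 8.8 Hz) treat a fully south-puckered reference ribose as the
#' south limit; both are configurable.
#'
#' @param j Observed coupling, Hz.
#' @param j_north Limiting coupling of the pure north conformer, Hz.
#' @param j_south Limiting coupling of the pure south conformer, Hz.
#' @return South-conformer fraction in [0, 1].
#' @examples
#' south_fraction(4.6)  # 0.4615... ~ 46% C2'-endo
#' @export
south_fraction <- function(j, j_north = 1.0, j_south = 8.8) {
  stopifnot(is.numeric(j), is.numeric(j_north), is.numeric(j_south))
  if (j_north >= j_south) stop("j_north must be < j_south", call. = FALSE)
  f <- (j - j_north) / (j_south - j_north)
  tol <- 1e-6  # absorb representation error (e.g. text round-trips), not real excursions
  if (any(f < -tol | f > 1 + tol)) {
    warning("coupling outside [j_north, j_south]; fraction clamped to [0, 1]",
            call. = FALSE)
  }
  pmin(pmax(f, 0), 1)
}

#' Sugar-pucker analysis of quantitative-J measurements
#'
#' For each row of a coupling table, derives the 3J(H1'H2') coupling from
#' the cross/diagonal ratio and converts it to a C2'-endo (south)
#' population under the two-state model. A measurement whose
#' |S_cross/S_diag| falls below `detection_threshold` (or whose `detected`
#' flag is FALSE) is treated as "no detectable cross peak": the coupling
#' is reported as NA, the south fraction as 0, and the status marks a
#' pure C3'-endo pucker — non-detection reflects the noise floor, not a
#' true zero coupling.
#'
#' @param data Data frame with columns `residue_id`, `s_cross`, `s_diag`,
#'   optionally `zeta` (seconds, default 0.01305) and `detected` (logical).
#' @param j_north,j_south Limiting couplings, Hz (see [south_fraction()]).
#' @param detection_threshold Minimum |ratio| counted as a detected cross
#'   peak (default 0.01).
#' @return Tibble with columns `residue_id`, `j_hz`, `south_fraction`,
#'   `status`.
#' @export
analyze_coupling <- function(data, j_north = 1.0, j_south = 8.8,
                             detection_threshold = 0.01) {
  stopifnot(is.data.frame(data))
  req <- c("residue_id", "s_cross", "s_diag")
  if (!all(req %in% names(data))) {
    stop("coupling table needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(data$s_diag <= 0)) stop("s_diag must be > 0", call. = FALSE)
  zeta <- if ("zeta" %in% names(data)) data$zeta else rep(0.01305, nrow(data))
  detected <- if ("detected" %in% names(data)) data$detected else rep(TRUE, nrow(data))

  purrr::pmap_dfr(
    list(data$residue_id, data$s_cross, data$s_diag, zeta, detected),
    function(rid, s_cross, s_diag, z, det) {
      ratio <- s_cross / s_diag
      if (ratio > 0) {
        stop(sprintf("residue %s: positive cross/diagonal ratio violates the sign convention",
                     rid), call. = FALSE)
      }
      if (!det || abs(ratio) < detection_threshold) {
        return(tibble::tibble(
          residue_id = rid, j_hz = NA_real_, south_fraction = 0,
          status = "C3'-endo (no detectable cross peak)"
        ))
      }
      j <- j_from_ratio(ratio, z)
      tibble::tibble(
        residue_id = rid, j_hz = j,
        south_fraction = south_fraction(j, j_north, j_south),
        status = "detected"
      )
    }
  )
}
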