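#' Derive true stress and stretch from engineering measures
#'
#' For an incompressible uniaxial specimen the stretch ratio is
#' \eqn{\lambda = 1 + \epsilon_{Eng}} and the true (Cauchy) stress is
#' \eqn{\sigma = \lambda \, \sigma_{Eng}}: the cross-section shrinks by
#' \eqn{1/\lambda} under volume conservation, so the force acts on a smaller
#' current area. (The opposite convention \eqn{\sigma_{Eng}/\lambda} would
#' violate incompressibility.)
#'
#' @param curve a [uniaxial_curve()].
#' @return The curve with `stretch` and `stress_true` filled in.
#' @examples
#' cv <- to_true(uniaxial_curve(c(0, 0.5, 1), c(0, 0.8, 2)))
#' cv$stress_true  # c(0, 1.2, 4)
#' @export
to_true <- function(curve) {
  if (!inherits(curve, "uniaxial_curve")) {
    stop_pugraft("`curve` must be a uniaxial_curve", "pugraft_value_error")
  }
  curve$stretch <- 1 + curve$strain_eng
  curve$stress_true <- curve$stretch * curve$stress_eng
  curve
}

#' Average replicate tensile curves on a common stretch grid
#'
#' Replicate specimens of one material rarely share strain sampling or break
#' at the same elongation, so curves are linearly interpolated onto a common
#' uniform stretch grid spanning `[1, min(max stretch)]` (truncated to the
#' shortest replicate) and averaged pointwise in true stress.
#'
#' @param curves list of [uniaxial_curve()] of the same composition and
#'   hydration state.
#' @param n_grid number of grid points (default 200).
#' @return Object of class `averaged_curve`: `composition_label`,
#'   `hydration_state`, `stretch_grid`, `stress_true_mean`,
#'   `stress_true_sd` (0 when a single replicate), `n_replicates`.
#' @examples
#' cv <- uniaxial_curve(c(0, 0.5, 1), c(0, 0.8, 1.6))
#' avg <- average_curves(list(cv, cv), n_grid = 20)
#' max(avg$stress_true_sd)  # 0
#' @export
average_curves <- function(curves, n_grid = 200) {
  if (!is.list(curves) || length(curves) == 0L) {
    stop_pugraft("`curves` must be a non-empty list of uniaxial_curve",
                 "pugraft_value_error")
  }
  if (!all(vapply(curves, inherits, logical(1), "uniaxial_curve"))) {
    stop_pugraft("all elements must be uniaxial_curve objects", "pugraft_value_error")
  }
  labels <- unique(vapply(curves, `[[`, character(1), "composition_label"))
  states <- unique(vapply(curves, `[[`, character(1), "hydration_state"))
  if (length(labels) > 1L || length(states) > 1L) {
    stop_pugraft("curves mix composition labels or hydration states",
                 "pugraft_data_error")
  }
  check_scalar_number(n_grid, "n_grid", positive = TRUE)
  curves <- lapply(curves, to_true)

  lo <- max(1, max(vapply(curves, function(cv) min(cv$stretch), numeric(1))))
  hi <- min(vapply(curves, function(cv) max(cv$stretch), numeric(1)))
  if (!(hi > lo)) {
    stop_pugraft("overlapping stretch range of the replicates is degenerate",
                 "pugraft_data_error")
  }
  grid <- seq(lo, hi, length.out = n_grid)

  mat <- vapply(curves, function(cv) {
    approx(cv$stretch, cv$stress_true, xout = grid, method = "linear",
           ties = "ordered")$y
  }, numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))

  n <- length(curves)
  structure(
    list(
      composition_label = labels,
      hydration_state = states,
      stretch_grid = grid,
      stress_true_mean = rowMeans(mat),
      stress_true_sd = if (n > 1L) apply(mat, 1L, sd) else rep(0, length(grid)),
      n_replicates = n
    ),
    class = "averaged_curve"
  )
}

#' @export
print.averaged_curve <- function(x, ...) {
  cat(sprintf(
    "<averaged_curve> %s [%s], %d replicates, %d grid points on stretch %.3g..%.3g\n",
    x$composition_label, x$hydration_state, x$n_replicates,
    length(x$stretch_grid), min(x$stretch_grid), max(x$stretch_grid)
  ))
  invisible(x)
}

#' Storage and loss modulus from an oscillatory measurement
#'
#' For a sinusoidal strain of amplitude \eqn{\epsilon} producing a stress of
#' amplitude \eqn{\sigma} with phase lag \eqn{\delta}:
#' \eqn{E' = (\sigma/\epsilon)\cos\delta} (storage, elastic) and
#' \eqn{E'' = (\sigma/\epsilon)\sin\delta} (loss, viscous).
#'
#' @param stress_amplitude MPa.
#' @param strain_amplitude dimensionless, > 0.
#' @param delta phase angle in radians, in \eqn{[0, \pi/2]}.
#' @return Object of class `dynamic_point` with `storage_modulus`,
#'   `loss_modulus` (MPa) and the three inputs.
#' @examples
#' dynamic_moduli(1, 0.5, 0)  # purely elastic: E' = 2, E'' = 0
#' @export
dynamic_moduli <- function(stress_amplitude, strain_amplitude, delta) {
  check_scalar_number(stress_amplitude, "stress_amplitude")
  check_scalar_number(strain_amplitude, "strain_amplitude", positive = TRUE)
  check_scalar_number(delta, "delta")
  if (delta < 0 || delta > pi / 2) {
    stop_pugraft("`delta` must lie in [0, pi/2]", "pugraft_value_error")
  }
  ratio <- stress_amplitude / strain_amplitude
  structure(
    list(
      stress_amplitude = stress_amplitude,
      strain_amplitude = strain_amplitude,
      phase_angle_delta = delta,
      storage_modulus = ratio * cos(delta),
      loss_modulus = ratio * sin(delta)
    ),
    class = "dynamic_point"
  )
}
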