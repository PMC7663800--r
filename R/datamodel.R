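#' One specimen's uniaxial tensile record
#'
#' Container for an engineering stress-strain curve of a single tensile
#' specimen. The stretch ratio \eqn{\lambda = 1 + \epsilon_{Eng}} is derived
#' on construction; the true (Cauchy) stress is filled in by [to_true()].
#'
#' @param strain_eng engineering strain, dimensionless fraction, strictly
#'   increasing, first value >= 0.
#' @param stress_eng engineering stress in MPa, non-negative, same length as
#'   `strain_eng` (length >= 3).
#' @param specimen_id identifier string.
#' @param composition_label opaque material label (e.g. a PEG-PCL-PE weight
#'   ratio such as `"5-90-5"`); never parsed.
#' @param hydration_state `"non_hydrated"` or `"hydrated"`.
#' @return An object of class `uniaxial_curve`: a list with fields
#'   `specimen_id`, `composition_label`, `hydration_state`, `strain_eng`,
#'   `stress_eng`, `stretch` and (after [to_true()]) `stress_true`.
#' @examples
#' cv <- uniaxial_curve(c(0, 0.5, 1), c(0, 0.8, 1.6))
#' cv$stretch
#' @export
uniaxial_curve <- function(strain_eng, stress_eng,
                           specimen_id = "specimen",
                           composition_label = "",
                           hydration_state = c("non_hydrated", "hydrated")) {
  hydration_state <- match.arg(hydration_state)
  strain_eng <- as.numeric(strain_eng)
  stress_eng <- as.numeric(stress_eng)
  if (length(strain_eng) != length(stress_eng)) {
    stop_pugraft("strain and stress must have the same length", "pugraft_data_error")
  }
  if (length(strain_eng) < 3L) {
    stop_pugraft("a curve needs at least 3 points", "pugraft_data_error")
  }
  if (anyNA(strain_eng) || anyNA(stress_eng) ||
      any(!is.finite(strain_eng)) || any(!is.finite(stress_eng))) {
    stop_pugraft("strain and stress must be finite", "pugraft_data_error")
  }
  bad <- which(diff(strain_eng) <= 0)
  if (length(bad)) {
    stop_pugraft(
      sprintf("strain must be strictly increasing; first violation at row %d",
              bad[1L] + 1L),
      "pugraft_data_error"
    )
  }
  if (strain_eng[1L] < 0) {
    stop_pugraft("first strain value must be >= 0", "pugraft_data_error")
  }
  if (any(stress_eng < 0)) {
    stop_pugraft("engineering stress must be non-negative", "pugraft_data_error")
  }
  structure(
    list(
      specimen_id = as.character(specimen_id),
      composition_label = as.character(composition_label),
      hydration_state = hydration_state,
      strain_eng = strain_eng,
      stress_eng = stress_eng,
      stretch = 1 + strain_eng,
      stress_true = NULL
    ),
    class = "uniaxial_curve"
  )
}

#' @export
print.uniaxial_curve <- function(x, ...) {
  cat(sprintf(
    "<uniaxial_curve> %s%s [%s], %d points, strain %.3g..%.3g, stress %.3g..%.3g MPa\n",
    x$specimen_id,
    if (nzchar(x$composition_label)) paste0(" (", x$composition_label, ")") else "",
    x$hydration_state, length(x$strain_eng),
    min(x$strain_eng), max(x$strain_eng),
    min(x$stress_eng), max(x$stress_eng)
  ))
  invisible(x)
}

#' @export
length.uniaxial_curve <- function(x) length(x$strain_eng)

#' Mooney-Rivlin coefficient triple
#'
#' The three-parameter Mooney-Rivlin material: strain-energy density
#' \eqn{W = C_{10}(I_1-3) + C_{01}(I_2-3) + C_{11}(I_1-3)(I_2-3)} in MPa.
#' No sign constraint is imposed on any coefficient: physically admissible
#' fits to PU elastomers routinely have negative C10 or C01, and only the
#' monotonicity of the resulting stress-stretch curve matters downstream
#' (checked by the simulator).
#'
#' @param c10,c01,c11 coefficients in MPa; finite.
#' @param temperature temperature context in kelvin (default body
#'   temperature, 310.15 K), used for crosslink density.
#' @return An object of class `mooney_rivlin`.
#' @examples
#' mooney_rivlin(0.589, -0.416, -0.0399)
#' @export
mooney_rivlin <- function(c10, c01, c11, temperature = 310.15) {
  check_scalar_number(c10, "c10")
  check_scalar_number(c01, "c01")
  check_scalar_number(c11, "c11")
  check_scalar_number(temperature, "temperature", positive = TRUE)
  structure(
    list(c10 = as.numeric(c10), c01 = as.numeric(c01), c11 = as.numeric(c11),
         temperature = as.numeric(temperature)),
    class = "mooney_rivlin"
  )
}

#' @export
print.mooney_rivlin <- function(x, ...) {
  cat(sprintf(
    "<mooney_rivlin> C10 = %.4g, C01 = %.4g, C11 = %.4g MPa (T = %.2f K)\n",
    x$c10, x$c01, x$c11, x$temperature
  ))
  invisible(x)
}

#' Sinusoidal physiological pressure waveform
#'
#' Pressure model \eqn{P(t) = P_m (1 + \epsilon \sin(2\pi f t))} with mean
#' pressure \eqn{P_m = \frac{1}{3} P_{max} + \frac{2}{3} P_{min}} and
#' relative amplitude \eqn{\epsilon = P_s / P_m}. The frequency `freq` is a
#' cardiac frequency in Hz, so one waveform period is one cardiac cycle.
#'
#' @param p_max,p_min systolic and diastolic pressure, mmHg.
#' @param ps sinusoidal pressure amplitude in mmHg (default 10).
#' @param freq frequency in Hz (> 0).
#' @return Object of class `pressure_waveform` with fields `p_max`, `p_min`,
#'   `p_mean`, `ps`, `epsilon`, `freq`.
#' @examples
#' wf <- pressure_waveform(180, 40)
#' wf$p_mean  # 86.67 mmHg
#' @export
pressure_waveform <- function(p_max = 180, p_min = 40, ps = 10, freq = 1) {
  check_scalar_number(p_max, "p_max")
  check_scalar_number(p_min, "p_min")
  check_scalar_number(ps, "ps", positive = TRUE)
  check_scalar_number(freq, "freq", positive = TRUE)
  if (p_min >= p_max) {
    stop_pugraft("p_min must be < p_max", "pugraft_value_error")
  }
  pm <- mean_pressure(p_max, p_min)
  structure(
    list(p_max = p_max, p_min = p_min, p_mean = pm, ps = ps,
         epsilon = ps / pm, freq = freq),
    class = "pressure_waveform"
  )
}

#' @export
print.pressure_waveform <- function(x, ...) {
  cat(sprintf(
    "<pressure_waveform> Pm = %.2f mmHg (Pmax %.4g / Pmin %.4g), Ps = %.4g mmHg, eps = %.4f, f = %.3g Hz\n",
    x$p_mean, x$p_max, x$p_min, x$ps, x$epsilon, x$freq
  ))
  invisible(x)
}

#' Cylindrical graft geometry
#'
#' @param r0 undeformed inner radius, mm (> 0).
#' @param h wall thickness, mm (> 0).
#' @return Object of class `graft_geometry`.
#' @examples
#' graft_geometry(2, 0.4)
#' @export
graft_geometry <- function(r0, h) {
  check_scalar_number(r0, "r0", positive = TRUE)
  check_scalar_number(h, "h", positive = TRUE)
  structure(list(r0 = r0, h = h), class = "graft_geometry")
}

#' @export
print.graft_geometry <- function(x, ...) {
  cat(sprintf("<graft_geometry> r0 = %.3g mm, h = %.3g mm\n", x$r0, x$h))
  invisible(x)
}

#' Reference Mooney-Rivlin coefficient sets for PEG-PCL-PE polyurethanes
#'
#' Coefficient triples for four hydrated polyurethane blends (labelled by
#' their PEG-PCL-PE weight ratio) fitted at body temperature. They are
#' bundled as realistic inputs for examples, synthetic-data generation and
#' the simulation sweeps; `"45-45-10"` is the stiffest composition and
#' `"5-90-5"` the most compliant.
#'
#' @return A data.frame with columns `label`, `c10`, `c01`, `c11` (MPa).
#' @examples
#' pu_reference_params()
#' @export
pu_reference_params <- function() {
  data.frame(
    label = c("5-90-5", "45-45-10", "46.3-46.3-7.5", "47.5-47.5-5"),
    c10 = c(0.589, -1.41, -0.854, -0.812),
    c01 = c(-0.416, 3.03, 1.82, 1.66),
    c11 = c(-0.0399, 0.223, 0.132, 0.101),
    stringsAsFactors = FALSE
  )
}
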