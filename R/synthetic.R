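#' Specification for synthetic tensile curves
#'
#' Describes a family of synthetic uniaxial tensile records generated from a
#' known Mooney-Rivlin material: a uniform stretch grid, additive Gaussian
#' measurement noise on the engineering stress (the quantity an instrument
#' actually records), multiplicative lognormal replicate-to-replicate jitter
#' on the coefficients, and an optional uniform hydration-softening scaling.
#'
#' The lognormal jitter is parameterised by its coefficient of variation and
#' has unit mean, so coefficients stay sign-stable across replicates and
#' replicate averages are centred on the truth. Hydration softening is
#' modelled as a single factor in (0, 1] multiplying all three coefficients,
#' the minimal mechanism for the plasticising effect of absorbed water.
#'
#' @param params true [mooney_rivlin()] coefficients.
#' @param lambda_max maximum stretch, > 1 (default 2.5).
#' @param n_points points per curve, >= 10 (default 100).
#' @param n_replicates replicates per material (default 5, the usual number
#'   of tensile specimens per blend).
#' @param noise_sd additive Gaussian noise sd on engineering stress, MPa,
#'   >= 0 (default 0.02; no instrument figure exists, this is an assumed
#'   magnitude of ~1% of typical ultimate strength).
#' @param replicate_jitter_cv coefficient of variation of the per-replicate
#'   lognormal multiplier on each coefficient (default 0.05).
#' @param hydration_state `"non_hydrated"` (default) or `"hydrated"`; the
#'   softening factor is applied only in the hydrated state.
#' @param hydration_softening_factor scaling in (0, 1] applied to all three
#'   coefficients when hydrated (default 0.6).
#' @param seed integer RNG seed or `NULL`.
#' @param composition_label label carried onto generated curves.
#' @return Object of class `synthetic_spec`.
#' @examples
#' sp <- synthetic_spec(mooney_rivlin(1, 0, 0), lambda_max = 2, seed = 1)
#' generate_curve(sp)
#' @export
synthetic_spec <- function(params,
                           lambda_max = 2.5,
                           n_points = 100,
                           n_replicates = 5,
                           noise_sd = 0.02,
                           replicate_jitter_cv = 0.05,
                           hydration_state = c("non_hydrated", "hydrated"),
                           hydration_softening_factor = 0.6,
                           seed = NULL,
                           composition_label = "synthetic") {
  if (!inherits(params, "mooney_rivlin")) {
    stop_pugraft("`params` must be a mooney_rivlin object", "pugraft_value_error")
  }
  hydration_state <- match.arg(hydration_state)
  check_scalar_number(lambda_max, "lambda_max")
  if (lambda_max <= 1) {
    stop_pugraft("`lambda_max` must be > 1", "pugraft_value_error")
  }
  check_scalar_number(n_points, "n_points")
  if (n_points < 10) {
    stop_pugraft("`n_points` must be >= 10", "pugraft_value_error")
  }
  check_scalar_number(n_replicates, "n_replicates", positive = TRUE)
  check_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) {
    stop_pugraft("`noise_sd` must be >= 0", "pugraft_value_error")
  }
  check_scalar_number(replicate_jitter_cv, "replicate_jitter_cv")
  if (replicate_jitter_cv < 0) {
    stop_pugraft("`replicate_jitter_cv` must be >= 0", "pugraft_value_error")
  }
  check_scalar_number(hydration_softening_factor, "hydration_softening_factor")
  if (hydration_softening_factor <= 0 || hydration_softening_factor > 1) {
    stop_pugraft("`hydration_softening_factor` must be in (0, 1]",
                 "pugraft_value_error")
  }
  structure(
    list(
      true_params = params,
      lambda_max = lambda_max,
      n_points = as.integer(n_points),
      n_replicates = as.integer(n_replicates),
      noise_sd = noise_sd,
      replicate_jitter_cv = replicate_jitter_cv,
      hydration_state = hydration_state,
      hydration_softening_factor = hydration_softening_factor,
      seed = if (is.null(seed)) NULL else as.integer(seed),
      composition_label = composition_label
    ),
    class = "synthetic_spec"
  )
}

# coefficients actually driving the generator (softening applied if hydrated)
effective_params <- function(spec) {
  p <- spec$true_params
  if (spec$hydration_state == "hydrated") {
    f <- spec$hydration_softening_factor
    p <- mooney_rivlin(p$c10 * f, p$c01 * f, p$c11 * f,
                       temperature = p$temperature)
  }
  p
}

# forward-evaluate one curve on the uniform stretch grid; consumes RNG
generate_curve_impl <- function(params, spec, specimen_id) {
  lambda <- seq(1, spec$lambda_max, length.out = spec$n_points)
  stress_true <- uniaxial_stress(lambda, params)
  if (min(stress_true) < -1e-12) {
    stop_pugraft(
      paste0("model stress is negative within [1, lambda_max] for these ",
             "coefficients; choose a smaller lambda_max or different parameters"),
      "pugraft_parameter_error"
    )
  }
  stress_eng <- stress_true / lambda
  if (spec$noise_sd > 0) {
    stress_eng <- stress_eng + rnorm(length(lambda), sd = spec$noise_sd)
    stress_eng <- pmax(stress_eng, 0)
  }
  stress_eng[1L] <- 0  # undeformed point recorded exactly
  uniaxial_curve(
    strain_eng = lambda - 1,
    stress_eng = stress_eng,
    specimen_id = specimen_id,
    composition_label = spec$composition_label,
    hydration_state = spec$hydration_state
  )
}

#' Generate one synthetic tensile curve
#'
#' Evaluates the Mooney-Rivlin uniaxial stress on a uniform stretch grid
#' over `[1, lambda_max]`, converts to engineering stress
#' (\eqn{\sigma_{Eng} = \sigma_1/\lambda}), adds Gaussian noise on the
#' engineering stress (clipped at zero), and records the undeformed point
#' exactly as (strain 0, stress 0). Deterministic under a fixed seed.
#'
#' @param spec a [synthetic_spec()].
#' @return A [uniaxial_curve()].
#' @examples
#' sp <- synthetic_spec(mooney_rivlin(1, 0, 0), lambda_max = 2,
#'                      n_points = 11, noise_sd = 0)
#' cv <- generate_curve(sp)
#' tail(cv$stress_eng, 1)  # 3.5 MPa at stretch 2
#' @export
generate_curve <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    stop_pugraft("`spec` must be a synthetic_spec", "pugraft_value_error")
  }
  with_seed(spec$seed,
            generate_curve_impl(effective_params(spec), spec, "rep1"))
}

#' Generate a replicate set of synthetic tensile curves
#'
#' Produces `n_replicates` curves whose coefficients are independently
#' perturbed by unit-mean lognormal multipliers of coefficient of variation
#' `replicate_jitter_cv` (one multiplier per coefficient per replicate),
#' each then sampled with measurement noise as in [generate_curve()].
#'
#' @param spec a [synthetic_spec()].
#' @return List of [uniaxial_curve()] of length `n_replicates`.
#' @examples
#' sp <- synthetic_spec(mooney_rivlin(1, 0.2, 0.05), seed = 7)
#' length(generate_replicates(sp))
#' @export
generate_replicates <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    stop_pugraft("`spec` must be a synthetic_spec", "pugraft_value_error")
  }
  base <- effective_params(spec)
  cv <- spec$replicate_jitter_cv
  with_seed(spec$seed, {
    mult <- if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      matrix(stats::rlnorm(3L * spec$n_replicates,
                           meanlog = -sdlog^2 / 2, sdlog = sdlog),
             nrow = spec$n_replicates)
    } else {
      matrix(1, nrow = spec$n_replicates, ncol = 3L)
    }
    lapply(seq_len(spec$n_replicates), function(i) {
      p <- mooney_rivlin(base$c10 * mult[i, 1L],
                         base$c01 * mult[i, 2L],
                         base$c11 * mult[i, 3L],
                         temperature = base$temperature)
      generate_curve_impl(p, spec, sprintf("rep%d", i))
    })
  })
}
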