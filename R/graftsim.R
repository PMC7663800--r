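#' Mean arterial pressure from systolic and diastolic pressure
#'
#' \eqn{P_m = \frac{1}{3} P_{max} + \frac{2}{3} P_{min}}, the usual
#' diastole-weighted estimate (diastole occupies roughly two thirds of the
#' cardiac cycle).
#'
#' @param p_max,p_min systolic and diastolic pressure, mmHg, with
#'   `p_max >= p_min`.
#' @return Mean pressure in mmHg.
#' @examples
#' mean_pressure(180, 40)  # 86.67 mmHg
#' @export
mean_pressure <- function(p_max, p_min) {
  check_scalar_number(p_max, "p_max")
  check_scalar_number(p_min, "p_min")
  if (p_max < p_min) {
    stop_pugraft("`p_max` must be >= `p_min`", "pugraft_value_error")
  }
  p_max / 3 + 2 * p_min / 3
}

#' Evaluate the sinusoidal pressure waveform
#'
#' \eqn{P(t) = P_m (1 + \epsilon \sin(2\pi f t))} with `f` in Hz, so the
#' waveform period is one cardiac cycle `1/f`. Bounded in
#' \eqn{[P_m(1-\epsilon), P_m(1+\epsilon)]}.
#'
#' @param t time in seconds; vectorised.
#' @param wf a [pressure_waveform()].
#' @return Pressure in mmHg.
#' @examples
#' wf <- pressure_waveform(180, 40, ps = 10, freq = 1)
#' pressure_at(0, wf)     # Pm
#' pressure_at(0.25, wf)  # Pm + Ps
#' @export
pressure_at <- function(t, wf) {
  if (!inherits(wf, "pressure_waveform")) {
    stop_pugraft("`wf` must be a pressure_waveform", "pugraft_value_error")
  }
  wf$p_mean * (1 + wf$epsilon * sin(2 * pi * wf$freq * t))
}

#' Circumferential (hoop) wall stress of a pressurised thick-wall tube
#'
#' \deqn{\sigma_{\theta\theta} = P \frac{r_0^2}{(r_0+h)^2}
#'   \left(1 + \frac{(r_0+h)^2}{r_0^2}\right)
#'   = P \left(1 + \frac{r_0^2}{(r_0+h)^2}\right)}
#'
#' The bracketed factor depends on geometry only through the ratio
#' \eqn{h/r_0}, which is why compliance turns out to be invariant under a
#' uniform geometric scaling. In the thin-wall limit \eqn{h \to 0} the
#' factor tends to 2.
#'
#' @param pressure transmural pressure in mmHg; vectorised.
#' @param geom a [graft_geometry()].
#' @return Hoop stress in MPa.
#' @examples
#' hoop_stress(86.67, graft_geometry(2, 0.4))
#' @export
hoop_stress <- function(pressure, geom) {
  if (!inherits(geom, "graft_geometry")) {
    stop_pugraft("`geom` must be a graft_geometry", "pugraft_value_error")
  }
  if (!is.numeric(pressure) || any(!is.finite(pressure))) {
    stop_pugraft("`pressure` must be finite", "pugraft_value_error")
  }
  ratio <- (geom$r0 / (geom$r0 + geom$h))^2
  mmhg_to_mpa(pressure) * (1 + ratio)
}

# Vectorised inversion of the stress-stretch curve by bisection on
# [1, hi]. Assumes sigma1 is strictly increasing on the bracket and
# sigma1(hi) >= max(target) (checked by callers). Bisection is iterated
# until the bracket collapses to adjacent doubles, so the result is the
# floating-point root: deterministic, and identical targets give
# bit-identical stretches.
invert_stretch_vec <- function(targets, params, hi) {
  lo <- rep(1, length(targets))
  up <- rep(hi, length(targets))
  zero <- targets == 0
  for (iter in seq_len(200L)) {
    mid <- (lo + up) / 2
    f <- drop(mr_basis(mid) %*% c(params$c10, params$c01, params$c11))
    below <- f < targets
    lo[below] <- mid[below]
    up[!below] <- mid[!below]
    if (all(up - lo <= 2 * .Machine$double.eps * up)) break
  }
  out <- (lo + up) / 2
  out[zero] <- 1
  out
}

check_monotone_stress <- function(params, hi, label = "") {
  grid <- seq(1, hi, length.out = 512L)
  s <- uniaxial_stress(grid, params)
  if (any(diff(s) <= 0)) {
    stop_pugraft(
      sprintf(paste0("stress-stretch curve%s is not strictly increasing on ",
                     "[1, %.3g]; material is unstable in this range"),
              if (nzchar(label)) paste0(" of ", label) else "", hi),
      "pugraft_stability_error"
    )
  }
  invisible(s)
}

#' Invert the uniaxial stress-stretch relation
#'
#' Finds the stretch \eqn{\lambda^*} at which the Mooney-Rivlin uniaxial
#' Cauchy stress equals a target wall stress, by bracketed bisection run to
#' floating-point collapse; the residual \eqn{|\sigma_1(\lambda^*) - target|}
#' is below 1e-10 MPa for physiological stress levels. A target of exactly 0
#' returns \eqn{\lambda = 1}.
#'
#' @param target_stress Cauchy stress in MPa, >= 0; vectorised.
#' @param params a [mooney_rivlin()] object.
#' @param bracket stretch search interval, default `c(1, 3)`; the stress
#'   must be strictly increasing on it.
#' @return Stretch ratio(s).
#' @examples
#' invert_stretch(7, mooney_rivlin(1, 0, 0))  # 2
#' @export
invert_stretch <- function(target_stress, params, bracket = c(1, 3)) {
  if (!is.numeric(target_stress) || any(!is.finite(target_stress)) ||
      any(target_stress < 0)) {
    stop_pugraft("`target_stress` must be finite and >= 0", "pugraft_value_error")
  }
  if (length(bracket) != 2L || bracket[1L] != 1 || bracket[2L] <= 1) {
    stop_pugraft("`bracket` must be c(1, hi) with hi > 1", "pugraft_value_error")
  }
  hi <- bracket[2L]
  s <- check_monotone_stress(params, hi)
  if (max(target_stress) > s[length(s)]) {
    stop_pugraft(
      sprintf("target stress %.4g MPa exceeds sigma1(%.3g) = %.4g MPa",
              max(target_stress), hi, s[length(s)]),
      "pugraft_range_error"
    )
  }
  invert_stretch_vec(target_stress, params, hi)
}

#' Simulate a graft tube under pulsatile pressure
#'
#' Drives a Mooney-Rivlin wall with the sinusoidal waveform on a uniform
#' time grid of `samples_per_cycle` samples per cycle over `n_cycles`
#' cycles. Per sample: pressure, thick-wall hoop stress, stretch (by
#' inverting the constitutive law), radius \eqn{r = r_0 \lambda}; then the
#' pointwise compliance between consecutive samples
#' \deqn{C_i = \frac{r_{i+1} - r_i}{r_i (P_{i+1} - P_i)}}
#' in 1/mmHg. Samples at pressure turning points (\eqn{|\Delta P|} below
#' `gap_dp`) are reported as `NA` gaps, not zeros or infinities, because the
#' forward difference is undefined there; summaries skip them.
#'
#' The waveform is evaluated at exact sample phases (`sin(2*pi*(i %% N)/N)`)
#' rather than at accumulated times, so the sampled pressure — and hence the
#' whole series — is exactly periodic across cycles.
#'
#' @param params a [mooney_rivlin()] object.
#' @param wf a [pressure_waveform()].
#' @param geom a [graft_geometry()].
#' @param n_cycles number of pressure cycles (default 3).
#' @param samples_per_cycle samples per cycle, >= 16 (default 256).
#' @param bracket_hi upper stretch bound for the inversion (default 3).
#' @param gap_dp pressure-difference threshold in mmHg below which the
#'   compliance sample is a gap (default 1e-6).
#' @return Object of class `compliance_series`: vectors `time` (s),
#'   `pressure` (mmHg), `hoop_stress` (MPa), `stretch`, `radius` (mm) of
#'   length `n_cycles * samples_per_cycle + 1`, and `compliance` (1/mmHg)
#'   one element shorter, plus the inputs.
#' @examples
#' fit <- pu_reference_params()
#' p <- mooney_rivlin(fit$c10[1], fit$c01[1], fit$c11[1])
#' sim <- simulate_graft(p, pressure_waveform(180, 40),
#'                       graft_geometry(2, 0.4), n_cycles = 2,
#'                       samples_per_cycle = 64)
#' range(sim$compliance, na.rm = TRUE) * 1e4  # mmHg^-1 x 10^4
#' @export
simulate_graft <- function(params, wf, geom, n_cycles = 3,
                           samples_per_cycle = 256, bracket_hi = 3,
                           gap_dp = 1e-6) {
  if (!inherits(params, "mooney_rivlin")) {
    stop_pugraft("`params` must be a mooney_rivlin object", "pugraft_value_error")
  }
  if (!inherits(wf, "pressure_waveform")) {
    stop_pugraft("`wf` must be a pressure_waveform", "pugraft_value_error")
  }
  if (!inherits(geom, "graft_geometry")) {
    stop_pugraft("`geom` must be a graft_geometry", "pugraft_value_error")
  }
  check_scalar_number(n_cycles, "n_cycles", positive = TRUE)
  check_scalar_number(samples_per_cycle, "samples_per_cycle", positive = TRUE)
  if (samples_per_cycle < 16) {
    stop_pugraft("`samples_per_cycle` must be >= 16", "pugraft_value_error")
  }
  n_cycles <- as.integer(n_cycles)
  nps <- as.integer(samples_per_cycle)

  idx <- 0:(n_cycles * nps)
  time <- idx / (nps * wf$freq)
  phase <- (idx %% nps) / nps
  pressure <- wf$p_mean * (1 + wf$epsilon * sin(2 * pi * phase))
  sigma <- hoop_stress(pressure, geom)

  s <- check_monotone_stress(params, bracket_hi)
  if (max(sigma) > s[length(s)]) {
    stop_pugraft(
      sprintf("peak hoop stress %.4g MPa exceeds sigma1(%.3g) = %.4g MPa",
              max(sigma), bracket_hi, s[length(s)]),
      "pugraft_range_error"
    )
  }

  # phases repeat every cycle, so only the unique stress targets need a
  # root solve; this also makes cross-cycle samples bit-identical
  uniq <- unique(sigma)
  lam_u <- invert_stretch_vec(uniq, params, bracket_hi)
  stretch <- lam_u[match(sigma, uniq)]
  radius <- geom$r0 * stretch

  dp <- diff(pressure)
  compliance <- diff(radius) / (radius[-length(radius)] * dp)
  compliance[abs(dp) < gap_dp] <- NA_real_

  structure(
    list(
      time = time, pressure = pressure, hoop_stress = sigma,
      stretch = stretch, radius = radius, compliance = compliance,
      params = params, waveform = wf, geometry = geom,
      samples_per_cycle = nps, n_cycles = n_cycles
    ),
    class = "compliance_series"
  )
}

#' @export
print.compliance_series <- function(x, ...) {
  cat(sprintf(
    paste0("<compliance_series> %d cycles x %d samples at f = %.3g Hz, ",
           "r0 = %.3g mm, h = %.3g mm\n",
           "  stretch %.6f..%.6f, compliance %.4g..%.4g mmHg^-1 (gaps: %d)\n"),
    x$n_cycles, x$samples_per_cycle, x$waveform$freq,
    x$geometry$r0, x$geometry$h,
    min(x$stretch), max(x$stretch),
    min(x$compliance, na.rm = TRUE), max(x$compliance, na.rm = TRUE),
    sum(is.na(x$compliance))
  ))
  invisible(x)
}

#' @export
as.data.frame.compliance_series <- function(x, ...) {
  data.frame(
    time = x$time,
    pressure = x$pressure,
    hoop_stress = x$hoop_stress,
    stretch = x$stretch,
    radius = x$radius,
    compliance = c(x$compliance, NA_real_)
  )
}

#' Sweep compliance over frequency and geometry grids
#'
#' Runs [simulate_graft()] for every combination of frequency, inner radius
#' and thickness, and summarises each cell's compliance (minimum, maximum,
#' mean in 1/mmHg, plus the same scaled by 1e4 for readability). The first
#' cycle of each run and gap samples are excluded from summaries. Failing
#' cells are collected and reported, not fatal.
#'
#' @param params a [mooney_rivlin()] object.
#' @param wf a [pressure_waveform()] (its `freq` is overridden per cell).
#' @param omega_grid frequencies in Hz.
#' @param r0_grid inner radii in mm.
#' @param h_grid wall thicknesses in mm.
#' @param label material label carried into the summary.
#' @inheritParams simulate_graft
#' @return Object of class `sweep_result`: `series` (list of
#'   `compliance_series`, one per cell, `NULL` on failure), `summary`
#'   (data.frame with columns `label`, `omega`, `r0`, `h`, `c_min`, `c_max`,
#'   `c_mean`, `c_min_e4`, `c_max_e4`, `c_mean_e4`), `errors` (named
#'   character vector of per-cell failures).
#' @examples
#' p <- mooney_rivlin(-0.854, 1.82, 0.132)
#' sw <- sweep_compliance(p, pressure_waveform(180, 40), omega_grid = 1,
#'                        r0_grid = 2, h_grid = 0.4,
#'                        samples_per_cycle = 64, n_cycles = 2)
#' sw$summary
#' @export
sweep_compliance <- function(params, wf,
                             omega_grid = c(1, 1.5, 2),
                             r0_grid = c(1.5, 2, 3),
                             h_grid = c(0.3, 0.4, 0.5),
                             n_cycles = 3, samples_per_cycle = 256,
                             bracket_hi = 3, label = "") {
  if (length(omega_grid) == 0L || length(r0_grid) == 0L || length(h_grid) == 0L) {
    stop_pugraft("sweep grids must be non-empty", "pugraft_value_error")
  }
  cells <- expand.grid(omega = omega_grid, r0 = r0_grid, h = h_grid,
                       KEEP.OUT.ATTRS = FALSE)
  series <- vector("list", nrow(cells))
  errors <- character(0)
  summ <- cells
  summ$label <- if (nzchar(label)) label else "material"
  summ <- summ[, c("label", "omega", "r0", "h")]
  summ$c_min <- summ$c_max <- summ$c_mean <- NA_real_

  for (i in seq_len(nrow(cells))) {
    wf_i <- pressure_waveform(wf$p_max, wf$p_min, ps = wf$ps,
                              freq = cells$omega[i])
    res <- tryCatch(
      simulate_graft(params, wf_i, graft_geometry(cells$r0[i], cells$h[i]),
                     n_cycles = n_cycles,
                     samples_per_cycle = samples_per_cycle,
                     bracket_hi = bracket_hi),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      errors[sprintf("omega=%g,r0=%g,h=%g", cells$omega[i], cells$r0[i],
                     cells$h[i])] <- conditionMessage(res)
      next
    }
    series[[i]] <- res
    # skip the first cycle (guard against any start-up artefact) and gaps
    keep <- seq_along(res$compliance) > res$samples_per_cycle
    cc <- res$compliance[keep]
    cc <- cc[is.finite(cc)]
    summ$c_min[i] <- min(cc)
    summ$c_max[i] <- max(cc)
    summ$c_mean[i] <- mean(cc)
  }
  summ$c_min_e4 <- summ$c_min * 1e4
  summ$c_max_e4 <- summ$c_max * 1e4
  summ$c_mean_e4 <- summ$c_mean * 1e4

  structure(
    list(series = series, summary = summ, errors = errors,
         cells = cells, label = label),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result>%s %d cells (%d failed)\n",
              if (nzchar(x$label)) paste0(" ", x$label, ":") else "",
              nrow(x$summary), length(x$errors)))
  print(utils::head(x$summary, 10))
  if (nrow(x$summary) > 10) cat("  ...\n")
  invisible(x)
}
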