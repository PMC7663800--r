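#' Fit the three-parameter Mooney-Rivlin model to a tensile curve
#'
#' Estimates \eqn{(C_{10}, C_{01}, C_{11})} from true stress vs stretch by
#' least squares. Although coefficient estimation for hyperelastic models is
#' conventionally posed as nonlinear regression, the uniaxial Mooney-Rivlin
#' stress is linear in its coefficients, so the least-squares problem has an
#' exact global optimum which is solved here by QR factorisation of the
#' three basis functions. An optional Levenberg-Marquardt path
#' (`method = "nonlinear"`, via \pkg{minpack.lm}) exists purely as a
#' cross-check and must agree with the linear solution.
#'
#' @param x a [uniaxial_curve()] (true stress derived via [to_true()] if
#'   absent), an `averaged_curve` from [average_curves()], or a numeric
#'   vector of stretch ratios (with `stress` supplied).
#' @param stress true (Cauchy) stress in MPa, for the default method only.
#' @param temperature temperature in kelvin for crosslink density
#'   (default 310.15).
#' @param method `"linear"` (exact QR solution, default) or `"nonlinear"`
#'   (Levenberg-Marquardt cross-check).
#' @param label material label carried into the result.
#' @param ... passed between methods.
#' @return Object of class `mr_fit`: `params` ([mooney_rivlin()]), `rmse`
#'   (MPa), `ccc` (Lin's concordance, dimensionless), `crosslink_density`
#'   (kmol/m^3), `n_points`, `initial_slope` (\eqn{6(C_{10}+C_{01})}, MPa),
#'   `fitted`, `residuals`, `label`.
#' @examples
#' lam <- seq(1, 2.5, length.out = 50)
#' truth <- mooney_rivlin(-0.854, 1.82, 0.132)
#' fit <- fit_mooney_rivlin(lam, uniaxial_stress(lam, truth))
#' fit$params
#' @export
fit_mooney_rivlin <- function(x, ...) UseMethod("fit_mooney_rivlin")

#' @rdname fit_mooney_rivlin
#' @export
fit_mooney_rivlin.uniaxial_curve <- function(x, temperature = 310.15,
                                             method = c("linear", "nonlinear"),
                                             ...) {
  x <- to_true(x)
  fit_mr_core(x$stretch, x$stress_true, temperature, match.arg(method),
              label = x$composition_label)
}

#' @rdname fit_mooney_rivlin
#' @export
fit_mooney_rivlin.averaged_curve <- function(x, temperature = 310.15,
                                             method = c("linear", "nonlinear"),
                                             ...) {
  fit_mr_core(x$stretch_grid, x$stress_true_mean, temperature,
              match.arg(method), label = x$composition_label)
}

#' @rdname fit_mooney_rivlin
#' @export
fit_mooney_rivlin.default <- function(x, stress, temperature = 310.15,
                                      method = c("linear", "nonlinear"),
                                      label = "", ...) {
  fit_mr_core(x, stress, temperature, match.arg(method), label = label)
}

fit_mr_core <- function(lambda, stress, temperature, method, label = "") {
  lambda <- as.numeric(lambda)
  stress <- as.numeric(stress)
  if (anyNA(lambda) || anyNA(stress) ||
      any(!is.finite(lambda)) || any(!is.finite(stress))) {
    stop_pugraft("NaN or non-finite values in fit input", "pugraft_data_error")
  }
  if (length(lambda) != length(stress)) {
    stop_pugraft("stretch and stress must have the same length", "pugraft_data_error")
  }
  if (length(lambda) < 3L) {
    stop_pugraft("need at least 3 points to identify 3 coefficients",
                 "pugraft_data_error")
  }
  if (any(lambda <= 0)) {
    stop_pugraft("stretch values must be > 0", "pugraft_data_error")
  }
  check_scalar_number(temperature, "temperature", positive = TRUE)

  X <- mr_basis(lambda)
  dec <- qr(X, tol = 1e-10)
  if (dec$rank < 3L) {
    stop_pugraft(
      "rank-deficient design: stretch values do not identify all three coefficients",
      "pugraft_fit_error"
    )
  }
  coefs <- as.numeric(qr.coef(dec, stress))

  if (method == "nonlinear") {
    df <- data.frame(l = lambda, y = stress)
    nl <- minpack.lm::nlsLM(
      y ~ 2 * C10 * (l^2 - 1 / l) + 2 * C01 * (l - 1 / l^2) +
        6 * C11 * (l^3 - l^2 - l + 1 / l + 1 / l^2 - 1 / l^3),
      data = df,
      start = list(C10 = 0.1, C01 = 0.1, C11 = 0.1),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)
    )
    coefs <- as.numeric(stats::coef(nl))
  }

  params <- mooney_rivlin(coefs[1L], coefs[2L], coefs[3L],
                          temperature = temperature)
  fitted <- drop(X %*% coefs)
  res <- stress - fitted
  structure(
    list(
      params = params,
      rmse = sqrt(mean(res^2)),
      ccc = concordance_ccc(stress, fitted),
      crosslink_density = crosslink_density(params),
      n_points = length(lambda),
      initial_slope = 6 * (params$c10 + params$c01),
      fitted = fitted,
      residuals = res,
      label = label,
      method = method
    ),
    class = "mr_fit"
  )
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<mr_fit>%s C10 = %.4g, C01 = %.4g, C11 = %.4g MPa\n",
           "  RMSE = %.3g MPa, CCC = %.6f, v = %.3g kmol/m^3, ",
           "initial slope = %.3g MPa (n = %d)\n"),
    if (nzchar(x$label)) paste0(" ", x$label, ":") else "",
    x$params$c10, x$params$c01, x$params$c11,
    x$rmse, x$ccc, x$crosslink_density, x$initial_slope, x$n_points
  ))
  invisible(x)
}

#' Lin's concordance correlation coefficient
#'
#' Measures agreement between two series against the 45-degree identity
#' line: \deqn{CCC = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}}
#' with population (1/n) moments, following Lin's original estimator.
#' Unlike Pearson correlation it penalises both location and scale shifts,
#' so \eqn{|CCC| \le |r|} always.
#'
#' @param observed,predicted numeric vectors of equal length >= 2.
#' @return Concordance in \eqn{[-1, 1]}.
#' @examples
#' concordance_ccc(c(1, 2, 3), c(1, 2, 4))  # 6/7
#' @export
concordance_ccc <- function(observed, predicted) {
  x <- as.numeric(observed)
  y <- as.numeric(predicted)
  if (length(x) != length(y)) {
    stop_pugraft("observed and predicted must have the same length",
                 "pugraft_value_error")
  }
  if (length(x) < 2L || anyNA(x) || anyNA(y)) {
    stop_pugraft("need >= 2 finite paired values", "pugraft_value_error")
  }
  n <- length(x)
  mx <- mean(x)
  my <- mean(y)
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) {
    stop_pugraft("CCC undefined: both series are constant and equal",
                 "pugraft_value_error")
  }
  2 * sxy / denom
}

#' Crosslink density from the C10 coefficient
#'
#' Rubber-elasticity theory relates the leading Mooney-Rivlin coefficient to
#' the density of effective network chains, \eqn{\nu = C_{10} / (R T)}.
#' The magnitude of C10 is used: three-parameter fits to strongly nonlinear
#' elastomer curves can return a negative C10 while the material's network
#' density is of course positive, and the magnitude convention reproduces
#' the reported densities of the bundled PU reference materials.
#'
#' @param params a [mooney_rivlin()] object (C10 in MPa).
#' @param temperature kelvin; defaults to the temperature stored in
#'   `params`.
#' @return Crosslink density in kmol/m^3 (C10 converted to Pa,
#'   R = 8314 J kmol^-1 K^-1).
#' @examples
#' crosslink_density(mooney_rivlin(0.589, 0, 0), 310.15)  # ~0.23 kmol/m^3
#' @export
crosslink_density <- function(params, temperature = params$temperature) {
  check_scalar_number(temperature, "temperature", positive = TRUE)
  abs(params$c10) * 1e6 / (.GAS_CONSTANT * temperature)
}
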