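test_that("uniaxial kinematics give unit third invariant", {
  st <- uniaxial_state(1)
  expect_equal(c(st$i1, st$i2, st$i3), c(3, 3, 1))

  st2 <- uniaxial_state(2)
  expect_equal(st2$i1, 5)
  expect_equal(st2$i2, 4.25)
  expect_equal(st2$i3, 1, tolerance = 1e-12)

  for (lam in runif(20, 0.3, 4)) {
    expect_equal(uniaxial_state(lam)$i3, 1, tolerance = 1e-12)
  }
  expect_error(uniaxial_state(0), class = "pugraft_value_error")
})

test_that("strain energy vanishes when undeformed and matches hand values", {
  expect_equal(strain_energy(1, mooney_rivlin(3, -2, 5)), 0)
  expect_equal(strain_energy(2, mooney_rivlin(1, 0, 0)), 2)     # I1 - 3
  expect_equal(strain_energy(2, mooney_rivlin(0, 0, 1)), 2.5)   # (I1-3)(I2-3)
})

test_that("uniaxial stress matches per-coefficient hand evaluation at stretch 2", {
  expect_equal(uniaxial_stress(2, mooney_rivlin(1, 0, 0)), 7)
  expect_equal(uniaxial_stress(2, mooney_rivlin(0, 1, 0)), 3.5)
  expect_equal(uniaxial_stress(2, mooney_rivlin(0, 0, 1)), 15.75)
  # stress is exactly zero at lambda = 1 for any coefficients
  for (i in 1:10) {
    p <- mooney_rivlin(rnorm(1), rnorm(1), rnorm(1))
    expect_identical(uniaxial_stress(1, p), 0)
  }
})

test_that("stress equals lambda dW/dlambda along the uniaxial path", {
  set.seed(4)
  h <- 1e-6
  for (i in 1:100) {
    p <- mooney_rivlin(runif(1, -2, 2), runif(1, -2, 3), runif(1, -0.5, 0.5))
    lam <- runif(1, 0.5, 3)
    dW <- (strain_energy(lam + h, p) - strain_energy(lam - h, p)) / (2 * h)
    sig <- uniaxial_stress(lam, p)
    # relative to the MPa stress scale; the identity is ill-conditioned for
    # a finite-difference check where sigma itself crosses zero
    expect_lt(abs(sig - lam * dW), 1e-6 * max(1, abs(sig)))
  }
})

test_that("stress equals the invariant-derivative closed form", {
  # sigma = 2 (lambda^2 - 1/lambda) (dW/dI1 + dW/dI2 / lambda)
  set.seed(5)
  for (i in 1:100) {
    p <- mooney_rivlin(runif(1, -2, 2), runif(1, -2, 3), runif(1, -0.5, 0.5))
    lam <- runif(1, 0.5, 3)
    st <- uniaxial_state(lam)
    w1 <- p$c10 + p$c11 * (st$i2 - 3)
    w2 <- p$c01 + p$c11 * (st$i1 - 3)
    closed <- 2 * (lam^2 - 1 / lam) * (w1 + w2 / lam)
    expect_equal(uniaxial_stress(lam, p), closed, tolerance = 1e-10)
  }
})

test_that("analytic slope matches finite differences and 6(C10+C01) at rest", {
  p <- mooney_rivlin(0.6, -0.4, 0.1)
  expect_equal(uniaxial_stress_deriv(1, p), 6 * (p$c10 + p$c01))
  h <- 1e-6
  for (lam in c(1.1, 1.5, 2.3)) {
    fd <- (uniaxial_stress(lam + h, p) - uniaxial_stress(lam - h, p)) / (2 * h)
    expect_equal(uniaxial_stress_deriv(lam, p), fd, tolerance = 1e-6)
  }
})

test_that("three points at distinct stretches are interpolated exactly", {
  p <- mooney_rivlin(0.7, 0.2, -0.05)
  lam <- c(1.2, 1.7, 2.4)
  fit <- fit_mooney_rivlin(lam, uniaxial_stress(lam, p))
  expect_equal(fit$rmse, 0, tolerance = 1e-12)
  expect_equal(fit$params$c10, p$c10, tolerance = 1e-9)
  expect_equal(fit$params$c01, p$c01, tolerance = 1e-9)
  expect_equal(fit$params$c11, p$c11, tolerance = 1e-9)
})

test_that("fit is idempotent and linear in the data", {
  lam <- seq(1, 2.5, length.out = 60)
  p <- mooney_rivlin(-1.41, 3.03, 0.223)
  noisy <- uniaxial_stress(lam, p) + rnorm(60, sd = 0.05)
  noisy <- pmax(noisy, 0) * (lam / lam)  # keep as-is; fit takes any stress
  f1 <- fit_mooney_rivlin(lam, noisy)
  # refitting the model's own prediction returns the same coefficients
  f2 <- fit_mooney_rivlin(lam, f1$fitted)
  expect_equal(f2$params$c10, f1$params$c10, tolerance = 1e-10)
  expect_equal(f2$params$c01, f1$params$c01, tolerance = 1e-10)
  expect_equal(f2$params$c11, f1$params$c11, tolerance = 1e-10)
  expect_lt(f2$rmse, 1e-12)

  # scaling the curve scales the coefficients
  f3 <- fit_mooney_rivlin(lam, 2.5 * noisy)
  expect_equal(f3$params$c10, 2.5 * f1$params$c10, tolerance = 1e-9)
  expect_equal(f3$params$c01, 2.5 * f1$params$c01, tolerance = 1e-9)
  expect_equal(f3$params$c11, 2.5 * f1$params$c11, tolerance = 1e-9)
})

test_that("linear and Levenberg-Marquardt paths agree", {
  lam <- seq(1, 2.5, length.out = 80)
  set.seed(8)
  y <- uniaxial_stress(lam, mooney_rivlin(-0.854, 1.82, 0.132)) +
    rnorm(80, sd = 0.02)
  fl <- fit_mooney_rivlin(lam, y, method = "linear")
  fn <- fit_mooney_rivlin(lam, y, method = "nonlinear")
  expect_equal(fn$params$c10, fl$params$c10, tolerance = 1e-8)
  expect_equal(fn$params$c01, fl$params$c01, tolerance = 1e-8)
  expect_equal(fn$params$c11, fl$params$c11, tolerance = 1e-8)
})

test_that("degenerate fit inputs raise typed errors", {
  expect_error(fit_mooney_rivlin(rep(1.5, 10), rep(2, 10)),
               class = "pugraft_fit_error")
  expect_error(fit_mooney_rivlin(c(1, 1.5, 2), c(0, NaN, 1)),
               class = "pugraft_data_error")
  expect_error(fit_mooney_rivlin(c(1, 1.5), c(0, 1)),
               class = "pugraft_data_error")
})

test_that("concordance matches its defining formula and limiting cases", {
  x <- c(1, 5, 3, 8, 2)
  expect_equal(concordance_ccc(x, x), 1)
  xc <- x - mean(x)
  expect_equal(concordance_ccc(xc, -xc), -1)

  # brute-force arithmetic oracle, population moments
  obs <- c(1, 2, 3); pred <- c(1, 2, 4)
  n <- 3
  sxy <- sum((obs - mean(obs)) * (pred - mean(pred))) / n
  sx2 <- sum((obs - mean(obs))^2) / n
  sy2 <- sum((pred - mean(pred))^2) / n
  brute <- 2 * sxy / (sx2 + sy2 + (mean(obs) - mean(pred))^2)
  expect_equal(concordance_ccc(obs, pred), brute)
  expect_equal(brute, 6 / 7)

  expect_error(concordance_ccc(1:3, 1:4), class = "pugraft_value_error")
  expect_error(concordance_ccc(rep(2, 5), rep(2, 5)),
               class = "pugraft_value_error")
})

test_that("|CCC| never exceeds |Pearson| and both live in [-1, 1]", {
  set.seed(12)
  for (i in 1:50) {
    x <- rnorm(30)
    y <- 0.5 * x + rnorm(30, sd = runif(1, 0.1, 2)) + runif(1, -1, 1)
    ccc <- concordance_ccc(x, y)
    expect_lte(abs(ccc), abs(cor(x, y)) + 1e-12)
    expect_lte(abs(ccc), 1)
  }
})

test_that("crosslink density uses |C10|/(RT) in kmol/m^3", {
  expect_equal(signif(crosslink_density(mooney_rivlin(0.589, 0, 0), 310.15), 2),
               0.23)
  expect_equal(signif(crosslink_density(mooney_rivlin(-1.41, 0, 0), 310.15), 2),
               0.55)
  expect_equal(crosslink_density(mooney_rivlin(0, 1, 1), 300), 0)
  # magnitude convention: sign of C10 is irrelevant
  expect_equal(crosslink_density(mooney_rivlin(-0.5, 0, 0), 310.15),
               crosslink_density(mooney_rivlin(0.5, 0, 0), 310.15))
})
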