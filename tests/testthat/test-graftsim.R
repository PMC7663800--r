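test_that("mean pressure is the diastole-weighted average", {
  expect_equal(mean_pressure(180, 40), 260 / 3)
  expect_equal(round(mean_pressure(180, 40), 2), 86.67)
  expect_equal(mean_pressure(120, 80), 280 / 3)   # 93.33
  expect_equal(mean_pressure(100, 100), 100)      # degenerate equality
  expect_error(mean_pressure(40, 180), class = "pugraft_value_error")
})

test_that("waveform evaluation hits its anchors and is periodic and bounded", {
  wf <- pressure_waveform(180, 40, ps = 10, freq = 1.25)
  expect_equal(pressure_at(0, wf), wf$p_mean)
  expect_equal(pressure_at(1 / (4 * wf$freq), wf), wf$p_mean + 10)
  expect_equal(pressure_at(3 / (4 * wf$freq), wf), wf$p_mean - 10)

  t <- runif(50, 0, 10)
  expect_equal(pressure_at(t, wf), pressure_at(t + 1 / wf$freq, wf),
               tolerance = 1e-9)
  p <- pressure_at(seq(0, 2, by = 1e-3), wf)
  expect_true(all(p >= wf$p_mean * (1 - wf$epsilon) - 1e-12))
  expect_true(all(p <= wf$p_mean * (1 + wf$epsilon) + 1e-12))
  expect_equal(wf$epsilon, 10 / wf$p_mean)
})

test_that("hoop stress is linear in pressure, thin-wall limited, scale-free", {
  geom <- graft_geometry(2, 0.4)
  expect_equal(hoop_stress(0, geom), 0)
  expect_equal(hoop_stress(100, geom), 2 * hoop_stress(50, geom))

  # h -> 0: bracketed factor tends to 2
  thin <- hoop_stress(100, graft_geometry(2, 1e-9))
  expect_equal(thin, mmhg_to_mpa(100) * 2, tolerance = 1e-8)

  # homogeneity degree 0 in (r0, h)
  for (k in c(0.5, 2, 7)) {
    expect_equal(hoop_stress(90, graft_geometry(2 * k, 0.4 * k)),
                 hoop_stress(90, geom), tolerance = 1e-15)
  }
})

test_that("stretch inversion recovers known roots and round-trips", {
  p <- mooney_rivlin(1, 0, 0)
  expect_identical(invert_stretch(0, p), 1)
  expect_equal(invert_stretch(7, p), 2, tolerance = 1e-12)

  set.seed(31)
  q <- mooney_rivlin(-0.854, 1.82, 0.132)
  smax <- uniaxial_stress(3, q)
  s <- runif(100, 0, smax)
  lam <- invert_stretch(s, q)
  expect_equal(uniaxial_stress(lam, q), s, tolerance = 1e-9)
  expect_true(all(abs(uniaxial_stress(lam, q) - s) <= 1e-10 * pmax(1, s)))
})

test_that("stretch inversion rejects unstable materials and out-of-range targets", {
  # C10 < 0 alone gives a decreasing stress curve
  expect_error(invert_stretch(0.5, mooney_rivlin(-1, 0, 0)),
               class = "pugraft_stability_error")
  p <- mooney_rivlin(1, 0, 0)
  expect_error(invert_stretch(1e6, p), class = "pugraft_range_error")
  expect_error(invert_stretch(-1, p), class = "pugraft_value_error")
})

test_that("constant pressure gives constant radius and all-gap compliance", {
  # epsilon = 0 is outside the waveform constructor's contract (ps > 0), so
  # emulate it with a degenerate-amplitude waveform built directly
  wf <- pressure_waveform(180, 40, ps = 1e-12, freq = 1)
  sim <- simulate_graft(mooney_rivlin(1, 0.5, 0), wf, graft_geometry(2, 0.4),
                        n_cycles = 1, samples_per_cycle = 32)
  expect_equal(diff(range(sim$radius)), 0, tolerance = 1e-12)
  expect_true(all(is.na(sim$compliance)))
})

test_that("radius is r0 times stretch and grows with pressure", {
  p <- mooney_rivlin(-0.854, 1.82, 0.132)
  sim <- simulate_graft(p, default_waveform(), graft_geometry(2, 0.4),
                        n_cycles = 2, samples_per_cycle = 64)
  expect_equal(sim$radius / sim$geometry$r0, sim$stretch)
  expect_true(all(sim$stretch >= 1))
  # sample-to-sample: radius moves with pressure
  dp <- diff(sim$pressure)
  dr <- diff(sim$radius)
  expect_true(all(sign(dr[dp != 0]) == sign(dp[dp != 0])))
})

test_that("compliance series is exactly periodic and geometry-scale invariant", {
  p <- mooney_rivlin(0.589, -0.416, -0.0399)
  sim <- simulate_graft(p, default_waveform(), graft_geometry(1.5, 0.3),
                        n_cycles = 3, samples_per_cycle = 128)
  N <- sim$samples_per_cycle
  c2 <- sim$compliance[(N + 1):(2 * N)]
  c3 <- sim$compliance[(2 * N + 1):(3 * N)]
  expect_identical(c2, c3)

  sim2 <- simulate_graft(p, default_waveform(), graft_geometry(3, 0.6),
                         n_cycles = 3, samples_per_cycle = 128)
  expect_identical(sim$compliance, sim2$compliance)
  expect_equal(sim2$radius, 2 * sim$radius, tolerance = 1e-15)
  expect_identical(sim$stretch, sim2$stretch)
})

test_that("physiological stretches stay modest for all reference materials", {
  for (m in reference_materials()) {
    sim <- simulate_graft(m, default_waveform(), graft_geometry(2, 0.4),
                          n_cycles = 1, samples_per_cycle = 64)
    expect_lt(max(sim$stretch), 1.5)
  }
})

test_that("uniformly stiffer coefficients give pointwise smaller compliance", {
  p <- mooney_rivlin(-0.854, 1.82, 0.132)
  stiff <- mooney_rivlin(2 * p$c10, 2 * p$c01, 2 * p$c11)
  a <- simulate_graft(p, default_waveform(), graft_geometry(2, 0.4),
                      n_cycles = 1, samples_per_cycle = 64)
  b <- simulate_graft(stiff, default_waveform(), graft_geometry(2, 0.4),
                      n_cycles = 1, samples_per_cycle = 64)
  keep <- !is.na(a$compliance) & !is.na(b$compliance)
  expect_true(all(b$compliance[keep] <= a$compliance[keep]))
})

test_that("sweep wraps single cells, reports per-cell summaries, collects errors", {
  p <- mooney_rivlin(-0.854, 1.82, 0.132)
  wf <- default_waveform()
  sw <- sweep_compliance(p, wf, omega_grid = 1, r0_grid = 2, h_grid = 0.4,
                         n_cycles = 3, samples_per_cycle = 64, label = "m")
  expect_equal(nrow(sw$summary), 1L)
  sim <- simulate_graft(p, wf, graft_geometry(2, 0.4), n_cycles = 3,
                        samples_per_cycle = 64)
  keep <- seq_along(sim$compliance) > 64
  cc <- sim$compliance[keep]; cc <- cc[is.finite(cc)]
  expect_equal(sw$summary$c_min, min(cc))
  expect_equal(sw$summary$c_max, max(cc))
  expect_equal(sw$summary$c_max_e4, max(cc) * 1e4)

  # frequency shifts timing, not amplitude: identical per-cycle extrema
  sw2 <- sweep_compliance(p, wf, omega_grid = c(1, 1.5, 2), r0_grid = 2,
                          h_grid = 0.4, n_cycles = 2,
                          samples_per_cycle = 64, label = "m")
  expect_equal(length(unique(sw2$summary$c_min)), 1L)
  expect_equal(length(unique(sw2$summary$c_max)), 1L)

  # a failing cell is collected, not fatal
  unstable <- mooney_rivlin(-1, 0, 0)
  sw3 <- sweep_compliance(unstable, wf, omega_grid = 1, r0_grid = 2,
                          h_grid = 0.4, samples_per_cycle = 64, label = "bad")
  expect_length(sw3$errors, 1L)
  expect_true(is.na(sw3$summary$c_min))

  expect_error(sweep_compliance(p, wf, omega_grid = numeric(0)),
               class = "pugraft_value_error")
})
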