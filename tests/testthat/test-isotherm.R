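test_that("compression law evaluates and behaves asymptotically", {
  m <- compression_model(59.8, 49.3, 8.1)
  expect_equal(area_model(0, m), 109.1)
  expect_equal(area_model(8.1, m), 59.8 + 49.3 / exp(1))
  expect_equal(area_model(1e6, m), 59.8, tolerance = 1e-10)
  expect_error(area_model(-1, m), "non-negative")
  expect_error(compression_model(-1, 49, 8), "positive")
  # strictly decreasing and convex in P
  P <- seq(0, 40, by = 0.5)
  A <- area_model(P, m)
  expect_true(all(diff(A) < 0))
  expect_true(all(diff(diff(A)) > 0))
})

test_that("noiseless isotherms are recovered to 4 significant digits", {
  ref <- dmps_isotherm_params()
  for (i in which(ref$phase == "LE")) {
    m <- compression_model(ref$A0[i], ref$Ae[i], ref$KP[i])
    fit <- fit_compression(gen_isotherm(m, noise_sd = 0))
    expect_equal(unname(fit$par["A0"]), ref$A0[i], tolerance = 1e-4)
    expect_equal(unname(fit$par["Ae"]), ref$Ae[i], tolerance = 1e-4)
    expect_equal(unname(fit$par["KP"]), ref$KP[i], tolerance = 1e-4)
    expect_lt(fit$t0, 1e-6)
  }
})

test_that("noisy LE isotherms recover KP within 5%", {
  m <- compression_model(60.8, 48.9, 13.6)
  fit <- fit_compression(gen_isotherm(m, noise_sd = 0.5, seed = 5))
  expect_lt(abs(fit$par[["KP"]] / 13.6 - 1), 0.05)
})

test_that("recovered KP tracks the generating KP monotonically", {
  kps <- c(4, 8, 16)
  rec <- vapply(seq_along(kps), function(i) {
    m <- compression_model(59.8, 49.3, kps[i])
    fit_compression(gen_isotherm(m, noise_sd = 0.3, seed = 20 + i))$par[["KP"]]
  }, numeric(1))
  expect_true(all(diff(rec) > 0))
})

test_that("degenerate constant-area input is rejected", {
  flat <- isotherm_curve(P = seq(1, 10, by = 0.5),
                         A = rep(70, 19))
  expect_error(fit_compression(flat), "degenerate")
})

test_that("fits need enough points and warn across the plateau", {
  m <- compression_model(59.8, 49.3, 8.1)
  short <- gen_isotherm(m, P = seq(1, 3, by = 0.5), noise_sd = 0)
  expect_error(fit_compression(short), "at least 10")
})

test_that("compression energy is zero at the reference and additive", {
  m <- compression_model(59.8, 49.3, 8.1)
  iso <- gen_isotherm(m, P = seq(1, 22, by = 0.25), noise_sd = 0)
  en <- compression_energy(iso, P_ref = 1)
  expect_equal(en$W[1], 0)
  expect_true(all(diff(en$W) > 0))     # monotone along compression
  # additivity over adjacent intervals: recompute from an interior reference
  en5 <- compression_energy(iso, P_ref = 5)
  W_at5 <- approx(en$P, en$W, xout = 5)$y
  joined <- approx(en5$P, en5$W + W_at5, xout = en$P[en$P > 5.1])$y
  direct <- en$W[en$P > 5.1]
  expect_equal(joined, direct, tolerance = 1e-3)
  expect_error(compression_energy(iso, P_ref = 0.1), "outside")
})

test_that("trapezoidal quadrature is exact for pressure linear in area", {
  A <- seq(110, 70, by = -1)
  P <- 1 + (110 - A) * 0.2                 # P rises linearly from 1 to 9
  en <- compression_energy(isotherm_curve(P, A), P_ref = 1)
  # closed form: mean pressure times the swept area
  expect_equal(en$W[nrow(en)], (1 + 9) / 2 * 40)
})

test_that("Volta slope recovers exact and noisy proportionality", {
  W <- seq(0, 400, by = 5)
  expect_equal(volta_slope(W, 0.132 * W)$S, 0.132)
  vd <- gen_volta(0.132, W, noise_sd = 2, seed = 9)
  s <- volta_slope(vd$W, vd$dV)
  expect_lt(abs(s$S / 0.132 - 1), 0.10)
  # potential unrelated to W: slope CI covers zero
  v0 <- gen_volta(0, W, noise_sd = 2, seed = 10)
  s0 <- volta_slope(v0$W, v0$dV)
  expect_lt(abs(s0$S), 2 * s0$se)
  expect_error(volta_slope(rep(0, 10), rnorm(10)), "degenerate")
})

test_that("volta series pairs energy with the zero-referenced potential", {
  m <- compression_model(59.8, 49.3, 8.1)
  iso <- gen_isotherm(m, P = seq(1, 20, by = 0.25), noise_sd = 0)
  W <- compression_energy(iso)$W
  iso$V <- 50 + 0.132 * W          # offset trace; zero-ref must remove 50
  wv <- compression_volta(iso)
  expect_equal(wv$dV[1], 0)
  expect_equal(volta_slope(wv$W, wv$dV)$S, 0.132, tolerance = 1e-10)
})
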