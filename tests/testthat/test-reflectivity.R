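optics <- subphase_optics()
qc <- optics$qc

test_that("critical wavevector follows 4*sqrt(pi*r_e*rho)", {
  expect_equal(critical_qc(0.333), 0.0217, tolerance = 2e-3)
  expect_equal(critical_qc(4 * 0.333), 2 * critical_qc(0.333))
  expect_error(critical_qc(0), "positive")
  expect_error(critical_qc(-1), "positive")
})

test_that("critical angle is linear in wavelength and ~0.017 degrees", {
  a1 <- critical_angle(0.333, 0.175)
  expect_equal(a1, 3.022e-4, tolerance = 1e-3)
  expect_equal(a1 * 180 / pi, 0.0173, tolerance = 1e-3)
  expect_equal(critical_angle(0.333, 1.54), a1 * 1.54 / 0.175)
  expect_equal(critical_angle(0.333, 0), 0)
  expect_error(critical_angle(-0.3, 0.175), "positive")
})

test_that("qzt takes the real branch above qc, positive-imaginary below", {
  expect_equal(qzt(qc, qc), 0 + 0i)
  expect_equal(qzt(2 * qc, qc), complex(real = sqrt(3) * qc))
  expect_equal(qzt(qc / 2, qc), complex(imaginary = sqrt(3) / 2 * qc))
  expect_error(qzt(-0.1, qc), "non-negative")
})

test_that("Fresnel reflectivity: total reflection, exact value, asymptote", {
  expect_equal(fresnel(qc, qc), 1)
  expect_equal(fresnel(qc / 3, qc), 1)
  expect_equal(fresnel(2 * qc, qc), ((2 - sqrt(3)) / (2 + sqrt(3)))^2)
  expect_equal(fresnel(10 * qc, qc), (1 / 20)^4, tolerance = 0.02)
})

test_that("zero-roughness bare interface reproduces Fresnel exactly", {
  m <- bare_surface(0)
  qz <- c(qc / 2, qz_coarse())
  expect_equal(reflectivity(qz, m, optics)$R, fresnel(qz, qc),
               tolerance = 1e-15)
})

test_that("rough bare interface matches the Nevot-Croce closed form", {
  for (s in c(1, 3, 5)) {
    m <- bare_surface(s)
    qz <- qz_coarse()
    qt <- sqrt(qz^2 - qc^2)
    expect_equal(reflectivity(qz, m, optics)$R,
                 fresnel(qz, qc) * exp(-s^2 * qz * qt),
                 tolerance = 1e-12)
  }
})

test_that("slab sum agrees with the gradient-integral oracle", {
  # reference two- and three-slab films
  for (key in list(c("LC", "water"), c("LE", "water"), c("LC", "PL-5"))) {
    m <- dmps_interface_model(key[1], key[2])
    smax <- max(c(m$slabs$sigma, m$sigma_bottom))
    qz <- seq(1.3 * qc, max(0.06, min(0.5, 1 / smax)), length.out = 25)
    expect_lt(max(abs(refl_oracle(m, qz, optics) /
                        reflectivity(qz, m, optics)$R - 1)), 0.005)
  }
  # random models within the sigma*qz <= 1 validity band
  set.seed(303)
  for (i in 1:8) {
    m <- random_model(smax = 6)
    smax <- max(c(m$slabs$sigma, m$sigma_bottom))
    qz <- seq(1.3 * qc, min(0.8, 1 / smax), length.out = 20)
    expect_lt(max(abs(refl_oracle(m, qz, optics) /
                        reflectivity(qz, m, optics)$R - 1)), 0.01)
  }
})

test_that("reflectivity stays within (0, 1] for arbitrary valid models", {
  set.seed(404)
  qz <- c(seq(0.001, 0.03, by = 0.002), qz_coarse(100))
  for (i in 1:25) {
    R <- reflectivity(sort(unique(qz)), random_model(), optics)$R
    expect_true(all(R > 0 & R <= 1))
  }
})

test_that("tied roughness damps reflectivity monotonically", {
  qz <- qz_coarse()
  base <- clean_lc()
  prev <- rep(Inf, length(qz))
  for (s in c(1, 2, 3.6, 5, 8)) {
    m <- interface_model(data.frame(L = base$slabs$L, rho = base$slabs$rho,
                                    sigma = s), sigma_bottom = s)
    R <- reflectivity(qz, m, optics)$R
    expect_true(all(R <= prev + 1e-14))
    prev <- R
  }
  # growing a single interface width must not raise R beyond the small
  # interference scale
  for (j in 1:3) {
    sig <- c(base$slabs$sigma, base$sigma_bottom)
    sig[j] <- sig[j] * 1.5
    m <- interface_model(data.frame(L = base$slabs$L, rho = base$slabs$rho,
                                    sigma = sig[1:2]), sigma_bottom = sig[3])
    expect_true(all(reflectivity(qz, m, optics)$R <=
                      reflectivity(qz, base, optics)$R + 1e-3))
  }
})

test_that("the slab sum is invariant under rigid translation of the stack", {
  # prepending a zero-density (air) slab shifts every interface depth by a
  # constant; |amplitude|^2 must be unchanged
  qz <- qz_coarse()
  m <- clean_lc()
  shifted <- interface_model(rbind(data.frame(L = 7, rho = 0, sigma = 3.6),
                                   m$slabs),
                             sigma_bottom = m$sigma_bottom)
  expect_equal(reflectivity(qz, shifted, optics)$R,
               reflectivity(qz, m, optics)$R, tolerance = 1e-12)
})

test_that("capillary width follows the thermal log-cutoff formula", {
  # water at room temperature, a = 10 A, qz_max = 0.8 1/A, 0.023 deg
  expect_equal(capillary_width(72, T_K = 293), 2.60, tolerance = 0.005)
  # stiff-surface limit
  expect_lt(capillary_width(1e9), 1e-3)
  # ln = 1 case: sigma0^2 = kB T / (2 pi gamma)
  a <- 10; Qmax <- 2 * pi / a
  db <- Qmax / (0.8 * exp(1))
  s0 <- capillary_width(72, T_K = 293, a = a, qz_max = 0.8, delta_beta = db)
  expect_equal(s0^2, 1.380649e-23 * 293 / (2 * pi * 0.072) * 1e20,
               tolerance = 1e-10)
  expect_error(capillary_width(72, a = 1e6), "Qmax > Qmin")
  expect_error(capillary_width(-5), "positive")
})
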