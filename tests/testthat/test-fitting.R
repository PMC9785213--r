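optics <- subphase_optics()

test_that("noiseless forward data is a fixed point of the fit", {
  for (key in list(c("LC", "water"), c("LE", "water"))) {
    truth <- dmps_interface_model(key[1], key[2])
    cur <- gen_reflectivity(truth, level = 0)
    fit <- suppressMessages(
      fit_reflectivity(cur, truth, constraint_scheme("tie_all"),
                       n_restarts = 0, ci = "none"))
    expect_lt(fit$chi2, 1e-6)
    expect_equal(fit$model$slabs$L, truth$slabs$L, tolerance = 1e-5)
    expect_equal(fit$model$slabs$rho, truth$slabs$rho, tolerance = 1e-5)
  }
})

test_that("noiseless self-consistency holds for all reference films", {
  p <- dmps_reference_params()
  for (i in seq_len(nrow(p))) {
    truth <- dmps_interface_model(p$phase[i], p$film[i])
    scheme <- constraint_scheme("tie_all", fixed_tail = p$film[i] != "water")
    cur <- gen_reflectivity(truth, level = 0)
    fit <- suppressMessages(
      fit_reflectivity(cur, truth, scheme, n_restarts = 0, ci = "none"))
    got <- fit$model$slabs
    expect_equal(got$L, truth$slabs$L, tolerance = 1e-4,
                 label = sprintf("%s/%s L", p$phase[i], p$film[i]))
    expect_equal(got$rho, truth$slabs$rho, tolerance = 1e-4,
                 label = sprintf("%s/%s rho", p$phase[i], p$film[i]))
  }
})

test_that("tie and fix constraints are honored exactly", {
  truth <- clean_lc()
  cur <- gen_reflectivity(truth, level = 0.05, seed = 31)
  init <- interface_model(list(c(14, 1.1, 3), c(8, 1.4, 3)),
                          sigma_bottom = 3)
  fit <- fit_reflectivity(cur, init, constraint_scheme("tie_all"),
                          n_restarts = 1, ci = "none")
  sig <- c(fit$model$slabs$sigma, fit$model$sigma_bottom)
  expect_identical(sig[1], sig[2])
  expect_identical(sig[2], sig[3])

  truth3 <- dmps_interface_model("LC", "PL-5")
  cur3 <- gen_reflectivity(truth3, level = 0.05, seed = 32)
  init3 <- interface_model(list(c(16.1, 1.02, 3.5), c(7, 1.8, 3.5),
                                c(120, 1.25, 3.5)), sigma_bottom = 30)
  fit3 <- fit_reflectivity(cur3, init3,
                           constraint_scheme("tie_all", fixed_tail = TRUE),
                           n_restarts = 1, ci = "none")
  expect_identical(fit3$model$slabs$L[1], 16.1)
  expect_identical(fit3$model$slabs$rho[1], 1.02)
  expect_false("L1" %in% names(fit3$par))
})

test_that("two-slab recovery from 5% noise lands within 1 A on L2", {
  truth <- clean_lc()
  cur <- gen_reflectivity(truth, level = 0.05, seed = 8)
  init <- interface_model(list(c(14, 1.1, 3), c(8, 1.4, 3)),
                          sigma_bottom = 3)
  fit <- fit_reflectivity(cur, init, constraint_scheme("tie_all"),
                          n_restarts = 3)
  expect_lt(abs(fit$par[["L2"]] - 9.5), 1)
  expect_gt(fit$s2, 0.5); expect_lt(fit$s2, 2)  # consistent weighting
})

test_that("three-slab fixed-tail recovery lands within 0.05 on rho3", {
  truth <- dmps_interface_model("LC", "PL-5")
  cur <- gen_reflectivity(truth, level = 0.05, seed = 12)
  init <- interface_model(list(c(16.1, 1.02, 3.5), c(7, 1.8, 3.5),
                               c(120, 1.2, 3.5)), sigma_bottom = 30)
  fit <- fit_reflectivity(cur, init,
                          constraint_scheme("tie_all", fixed_tail = TRUE),
                          n_restarts = 3)
  expect_lt(abs(fit$par[["rho3"]] - 1.29), 0.05)
})

test_that("profile and Wald confidence intervals agree near the optimum", {
  truth <- clean_lc()
  cur <- gen_reflectivity(truth, level = 0.05, seed = 21)
  init <- interface_model(list(c(15, 1.0, 3.2), c(9, 1.5, 3.2)),
                          sigma_bottom = 3.2)
  fw <- fit_reflectivity(cur, init, constraint_scheme("tie_all"),
                         n_restarts = 0, ci = "wald")
  fp <- fit_reflectivity(cur, init, constraint_scheme("tie_all"),
                         n_restarts = 0, ci = "profile")
  expect_equal(unname(fp$ci95), unname(fw$ci95), tolerance = 0.25)
})

test_that("fit report flags Born-validity violations and tight windows", {
  truth <- dmps_interface_model("LC", "PL-5")   # sigma3 = 40 A
  cur <- gen_reflectivity(truth, level = 0.05, seed = 13)
  init <- truth
  fit <- fit_reflectivity(cur, init,
                          constraint_scheme("tie_all", fixed_tail = TRUE),
                          n_restarts = 0, ci = "none")
  # nearly every point has sigma3 * qz > 1 for a 40 A diffuse interface
  expect_gt(fit$sqz_flagged_frac, 0.9)
  # too few points for the parameter count is an error
  tiny <- cur[seq(1, 40, by = 4), ]
  expect_error(fit_reflectivity(reflectivity_curve(tiny$qz, tiny$R,
                                                   tiny$sigma_R),
                                init, constraint_scheme("free")),
               "3 datapoints per free parameter")
})

test_that("scheme comparison resolves intrinsic headgroup structure", {
  # generated with a wider inner width than the film-air width
  gen <- interface_model(list(c(16.1, 1.02, 4), c(9.5, 1.56, 6)),
                         sigma_bottom = 6)
  cur <- gen_reflectivity(gen, level = 0.05, seed = 17)
  init <- interface_model(list(c(15, 1.0, 4), c(9, 1.5, 4)),
                          sigma_bottom = 4)
  cmp <- compare_schemes(cur, init, n_restarts = 1)
  expect_lt(cmp$chi2_hi_inner, cmp$chi2_hi_all)
  expect_true(cmp$distinguishable)
  expect_equal(cmp$intrinsic_width, sqrt(36 - 16), tolerance = 0.25)

  # generated under the strict tie: schemes statistically indistinguishable
  cur0 <- gen_reflectivity(clean_lc(), level = 0.05, seed = 18)
  cmp0 <- compare_schemes(cur0, init, n_restarts = 1)
  expect_false(cmp0$distinguishable)
})
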