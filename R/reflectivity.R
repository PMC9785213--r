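#' Critical wavevector of total external reflection
#'
#' `qc = 4 sqrt(pi r_e rho)` for a subphase of electron density `rho`
#' (e-/A^3). Wavelength-independent. For water (0.333 e-/A^3) this is
#' 0.0217 1/A.
#'
#' @param rho_w_abs absolute electron density of the subphase (e-/A^3).
#' @param r_e classical electron radius (Angstrom).
#' @return critical wavevector in 1/Angstrom.
#' @export
critical_qc <- function(rho_w_abs, r_e = .xrr_const$r_e) {
  if (!is.numeric(rho_w_abs) || any(rho_w_abs <= 0))
    stop("subphase electron density must be positive")
  4 * sqrt(pi * r_e * rho_w_abs)
}

#' Critical glancing angle of total external reflection
#'
#' `alpha_c = lambda * sqrt(r_e rho / pi)` in radians; linear in the
#' wavelength. At lambda = 0.175 A on water this is 3.02e-4 rad = 0.0173
#' degrees.
#'
#' @inheritParams critical_qc
#' @param lambda X-ray wavelength (Angstrom, >= 0).
#' @return critical angle in radians.
#' @export
critical_angle <- function(rho_w_abs, lambda, r_e = .xrr_const$r_e) {
  if (!is.numeric(rho_w_abs) || any(rho_w_abs <= 0))
    stop("subphase electron density must be positive")
  if (!is.numeric(lambda) || any(lambda < 0))
    stop("wavelength must be non-negative")
  lambda * sqrt(r_e * rho_w_abs / pi)
}

#' Subphase optical constants
#'
#' Bundles the absolute subphase electron density, the classical electron
#' radius and the derived critical wavevector used by the forward model and
#' the fitting routines.
#'
#' @inheritParams critical_qc
#' @return list of class `subphase_optics` with fields `rho_w_abs`, `r_e`,
#'   `qc`.
#' @export
subphase_optics <- function(rho_w_abs = .xrr_const$rho_w,
                            r_e = .xrr_const$r_e) {
  structure(list(rho_w_abs = rho_w_abs, r_e = r_e,
                 qc = critical_qc(rho_w_abs, r_e)),
            class = "subphase_optics")
}

#' Beam geometry constants
#'
#' @param lambda X-ray wavelength (Angstrom).
#' @param delta_beta_deg detector angular resolution (degrees).
#' @return list with `lambda`, `k0 = 2*pi/lambda`, `delta_beta` (radians).
#' @export
beam_geometry <- function(lambda = 0.175, delta_beta_deg = 0.023) {
  stopifnot(lambda > 0, delta_beta_deg > 0)
  list(lambda = lambda, k0 = 2 * pi / lambda,
       delta_beta = delta_beta_deg * pi / 180)
}

#' Wavevector transfer inside the subphase
#'
#' `qzt = sqrt(qz^2 - qc^2)`: real above the critical wavevector, and on the
#' positive-imaginary branch `i*sqrt(qc^2 - qz^2)` below it (evanescent
#' regime).
#'
#' @param qz scattering vector(s), 1/Angstrom, >= 0.
#' @param qc critical wavevector, 1/Angstrom.
#' @return complex vector.
#' @export
qzt <- function(qz, qc) {
  if (any(qz < 0)) stop("qz must be non-negative")
  ifelse(qz >= qc,
         complex(real = sqrt(pmax(qz^2 - qc^2, 0))),
         complex(imaginary = sqrt(pmax(qc^2 - qz^2, 0))))
}

#' Fresnel reflectivity of an ideally sharp interface
#'
#' `R_F = |(qz - qzt)/(qz + qzt)|^2`; identically 1 in the total-reflection
#' region `qz <= qc` and decaying as `(qc/2qz)^4` far above it.
#'
#' @inheritParams qzt
#' @return numeric vector in (0, 1].
#' @export
fresnel <- function(qz, qc) {
  qt <- qzt(qz, qc)
  Mod((qz - qt) / (qz + qt))^2
}

# Forward model: numeric R(qz) for an interface model. Slab sum in the
# distorted-wave Born approximation with Nevot-Croce roughness damping:
#   R = R_F * | sum_j (rho_{j+1}-rho_j) exp(-i sqrt(qz qzt) z_j)
#                                       exp(-sigma_j^2 qz qzt / 2) |^2
# with normalized densities (the 1/rho_w^2 prefactor cancels). R is clamped
# to 1 in the total-reflection region qz <= qc, where the Born sum is not
# trusted, and capped at 1 above it.
refl_forward <- function(qz, model, optics = subphase_optics()) {
  stopifnot(inherits(model, "interface_model"))
  if (any(qz < 0)) stop("qz must be non-negative")
  qc <- optics$qc
  zj   <- interface_depths(model)
  sj   <- interface_widths(model)
  drho <- diff(interface_densities(model))
  R <- rep(1, length(qz))
  i <- which(qz > qc)
  if (length(i)) {
    q  <- qz[i]
    qt <- sqrt(q^2 - qc^2)
    qq <- q * qt                      # qz * qzt (real above qc)
    qe <- sqrt(qq)                    # effective phase wavevector
    amp <- complex(real = numeric(length(q)))
    for (j in seq_along(zj))
      amp <- amp + drho[j] * exp(-1i * qe * zj[j]) * exp(-0.5 * sj[j]^2 * qq)
    RF <- ((q - qt) / (q + qt))^2
    R[i] <- pmin(RF * Mod(amp)^2, 1)
  }
  R
}

#' Specular reflectivity of a slab-stack interface model
#'
#' Computes `R(qz)` for an [interface_model()] via the slab sum in the
#' distorted-wave Born approximation with Nevot--Croce roughness damping,
#' using normalized electron densities. For the bare interface with zero
#' roughness this reduces exactly to the Fresnel curve; with roughness
#' `sigma` it equals `R_F * exp(-sigma^2 qz qzt)`. `R` is fixed at 1 in the
#' total-reflection region `qz <= qc`. The approximation is reliable where
#' `sigma * qz <= 1`.
#'
#' @param qz scattering vector grid (1/Angstrom), strictly increasing.
#' @param model an [interface_model()].
#' @param optics a [subphase_optics()].
#' @return A [reflectivity_curve()] with `sigma_R = 0` (noise-free model
#'   curve).
#' @export
reflectivity <- function(qz, model, optics = subphase_optics()) {
  R <- refl_forward(qz, model, optics)
  reflectivity_curve(qz, R, sigma_R = rep(0, length(qz)))
}

#' Reflectivity curve container
#'
#' Model curves satisfy `R <= 1` exactly; measured (noisy) points may
#' scatter slightly above 1 near total reflection, so the container only
#' enforces positivity.
#'
#' @param qz scattering vector values (1/Angstrom), strictly increasing.
#' @param R reflectivity, > 0 (model curves lie in (0, 1]).
#' @param sigma_R absolute 1-sigma uncertainty per point (0 for model
#'   curves).
#' @return data frame of class `reflectivity_curve`.
#' @export
reflectivity_curve <- function(qz, R, sigma_R = NULL) {
  stopifnot(is.numeric(qz), is.numeric(R), length(qz) == length(R))
  if (any(diff(qz) <= 0)) stop("qz must be strictly increasing")
  if (any(R <= 0)) stop("reflectivity values must be positive")
  if (is.null(sigma_R)) sigma_R <- rep(0, length(qz))
  if (any(sigma_R < 0)) stop("sigma_R must be non-negative")
  structure(data.frame(qz = qz, R = R, sigma_R = sigma_R),
            class = c("reflectivity_curve", "data.frame"))
}

as_reflectivity_curve <- function(x) {
  if (inherits(x, "reflectivity_curve")) return(x)
  stopifnot(is.data.frame(x), all(c("qz", "R") %in% names(x)))
  reflectivity_curve(x$qz, x$R, if ("sigma_R" %in% names(x)) x$sigma_R)
}

#' Capillary-wave roughness of a liquid surface
#'
#' Thermal capillary waves give the surface an irreducible width
#' \deqn{\sigma_0^2 = \frac{k_B T}{2\pi\gamma}\,
#'   \ln\frac{Q_{max}}{Q_{min}},}
#' with the short-wavelength cutoff `Qmax = 2*pi/a` set by the
#' intermolecular distance `a` and the long-wavelength (resolution) cutoff
#' `Qmin = qz_max * delta_beta` set by the detector acceptance. For water
#' (gamma = 72 mN/m) at 293 K with a = 10 A, qz_max = 0.8 1/A and
#' delta_beta = 0.023 deg, sigma_0 is about 2.6 A.
#'
#' @param gamma surface tension in mN/m (> 0).
#' @param T_K temperature in kelvin.
#' @param a intermolecular cutoff length (Angstrom).
#' @param qz_max maximum scattering vector of the measurement (1/Angstrom).
#' @param delta_beta detector angular resolution in radians.
#' @return capillary width sigma_0 in Angstrom.
#' @export
capillary_width <- function(gamma, T_K = 293, a = 10, qz_max = 0.8,
                            delta_beta = 0.023 * pi / 180) {
  if (!is.numeric(gamma) || any(gamma <= 0))
    stop("surface tension must be positive")
  if (T_K <= 0) stop("temperature must be positive")
  Qmax <- 2 * pi / a
  Qmin <- qz_max * delta_beta
  if (any(Qmax <= Qmin) || any(Qmin <= 0))
    stop("cutoffs must satisfy Qmax > Qmin > 0")
  # k_B T / (2 pi gamma) in m^2 -> A^2 (gamma mN/m = 1e-3 N/m)
  pref_A2 <- .xrr_const$k_B * T_K / (2 * pi * gamma * 1e-3) * 1e20
  sqrt(pref_A2 * log(Qmax / Qmin))
}
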