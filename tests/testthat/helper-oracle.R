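# Independent numerical oracle for the specular reflectivity: the
# gradient-integral master formula
#   R = R_F * | (1/Drho) Int drho/dz exp(i sqrt(qz qzt) z) dz |^2
# evaluated by finite differences + trapezoidal quadrature on the rendered
# erf profile. Shares no code with the slab-sum forward model beyond the
# profile itself.
refl_oracle <- function(model, qz, optics = subphase_optics(), dz = 0.02) {
  zj <- cumsum(c(0, model$slabs$L))
  sj <- c(model$slabs$sigma, model$sigma_bottom)
  pad <- 8 * max(sj, 1)
  z <- seq(min(zj) - pad, max(zj) + pad, by = dz)
  rho <- density_profile(model, z)$rho
  n <- length(z)
  dr <- (rho[-(1:2)] - rho[1:(n - 2)]) / (2 * dz)  # central differences
  zi <- z[-c(1, n)]
  vapply(qz, function(q) {
    qt <- sqrt(q^2 - optics$qc^2)
    qe <- sqrt(q * qt)
    f <- dr * exp(1i * qe * zi)
    I <- dz * (sum(f) - (f[1] + f[length(f)]) / 2)
    fresnel(q, optics$qc) * Mod(I)^2
  }, numeric(1))
}
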