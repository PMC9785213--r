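#' Plot a reflectivity curve
#'
#' Log-scale reflectivity vs qz; with `fresnel_scale = TRUE` the curve is
#' shown divided by the Fresnel reflectivity of the bare subphase, which
#' flattens the steep `qz^-4` decay and emphasizes film interference.
#'
#' @param x a [reflectivity_curve()].
#' @param fresnel_scale divide by the Fresnel curve.
#' @param optics a [subphase_optics()] (needed for `fresnel_scale`).
#' @param ... passed to [graphics::plot()].
#' @export
plot.reflectivity_curve <- function(x, fresnel_scale = FALSE,
                                    optics = subphase_optics(), ...) {
  y <- x$R
  ylab <- "R"
  if (fresnel_scale) {
    y <- x$R / fresnel(x$qz, optics$qc)
    ylab <- "R / R_F"
  }
  graphics::plot(x$qz, y, log = "y", xlab = "qz (1/A)", ylab = ylab, ...)
  invisible(x)
}

#' Plot an electron-density profile
#'
#' Normalized density vs depth; the air side is at negative z, bulk water
#' at large positive z.
#'
#' @param x a [density_profile()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.density_profile <- function(x, ...) {
  graphics::plot(x$z, x$rho, type = "l", xlab = "z (A)",
                 ylab = "rho / rho_w", ...)
  invisible(x)
}
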