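#' Reference slab parameters for DMPS monolayers with adsorbed polylysine
#'
#' Bundled reference parameter sets for a DMPS Langmuir monolayer on a
#' 10 mM KCl subphase, clean and under maximal coverage by poly-D-lysine of
#' three chain lengths (PL-5, PL-12, PL-200), in the liquid-expanded state
#' (LE, area per molecule about 70 A^2) and the liquid-condensed state (LC,
#' about 40 A^2). The clean monolayer is a two-slab model (acyl tails +
#' headgroups); films with polymer add a third, thick, diffuse polymer
#' slab. Tail packing (`L1`, `rho1`) under polymer is that of the clean
#' monolayer in the same state. These parameter sets drive the synthetic
#' data generators, examples and recovery benchmarks.
#'
#' @return data frame with columns `phase` (LE/LC), `film` (water, PL-5,
#'   PL-12, PL-200), `A` (A^2), `L1`, `rho1`, `sigma0`, `L2`, `rho2`, `L3`,
#'   `rho3`, `sigma3` (lengths in Angstrom, densities normalized to water;
#'   polymer columns are `NA` for the clean monolayer).
#' @export
dmps_reference_params <- function() {
  data.frame(
    phase  = c("LC", "LC", "LC", "LC", "LE", "LE", "LE", "LE"),
    film   = c("water", "PL-5", "PL-12", "PL-200",
               "water", "PL-5", "PL-12", "PL-200"),
    A      = c(40, 40, 40, 40, 70, 70, 70, 70),
    L1     = c(16.1, 16.1, 16.1, 16.1, 12, 12, 12, 12),
    rho1   = c(1.02, 1.02, 1.02, 1.02, 0.90, 0.90, 0.90, 0.90),
    sigma0 = c(3.6, 4.6, 5.0, 4.9, 3.0, 3.9, 3.6, 3.9),
    L2     = c(9.5, 6.0, 6.0, 6.9, 11, 2.5, 5.2, 3.4),
    rho2   = c(1.56, 2.1, 2.1, 2.0, 1.25, 2.5, 1.5, 2.1),
    L3     = c(NA, 144, 112, 103, NA, 167, 165, 115),
    rho3   = c(NA, 1.29, 1.29, 1.27, NA, 1.21, 1.18, 1.09),
    sigma3 = c(NA, 40, 25, 33, NA, 29, 19, 41),
    stringsAsFactors = FALSE
  )
}

#' Interface model for a reference DMPS film condition
#'
#' Builds the [interface_model()] for one row of
#' [dmps_reference_params()]: a two-slab model for the clean monolayer
#' (all lipid interface widths tied to `sigma0`, including the
#' headgroup--water interface) or a three-slab model with the polymer layer
#' (lipid interfaces at `sigma0`, polymer--water interface at `sigma3`).
#'
#' @param phase `"LE"` or `"LC"`.
#' @param film `"water"`, `"PL-5"`, `"PL-12"` or `"PL-200"`.
#' @return an [interface_model()].
#' @examples
#' dmps_interface_model("LC", "water")
#' dmps_interface_model("LE", "PL-12")
#' @export
dmps_interface_model <- function(phase = c("LC", "LE"),
                                 film = c("water", "PL-5", "PL-12",
                                          "PL-200")) {
  phase <- match.arg(phase)
  film <- match.arg(film)
  tab <- dmps_reference_params()
  p <- tab[tab$phase == phase & tab$film == film, ]
  stopifnot(nrow(p) == 1L)
  if (film == "water") {
    interface_model(list(c(p$L1, p$rho1, p$sigma0),
                         c(p$L2, p$rho2, p$sigma0)),
                    sigma_bottom = p$sigma0)
  } else {
    interface_model(list(c(p$L1, p$rho1, p$sigma0),
                         c(p$L2, p$rho2, p$sigma0),
                         c(p$L3, p$rho3, p$sigma0)),
                    sigma_bottom = p$sigma3)
  }
}

#' Reference compression-law parameters for DMPS isotherms
#'
#' Parameters of the empirical elastic-shell compression law
#' `A(P) = A0 + Ae * exp(-P/KP)` for DMPS monolayers, clean and with
#' PL-200 at maximal coverage, fitted separately in the liquid-expanded
#' (LE) and condensed (LC) branches, together with the pressure-residual
#' scale `t0` and the Volta-potential/compression-energy slope `S`
#' (LE branch only; `S` relates potential in mV to two-dimensional
#' compression energy in mN/m A^2 per molecule).
#'
#' @return data frame with columns `system`, `phase`, `A0` (A^2), `Ae`
#'   (A^2), `KP` (mN/m), `t0` (mN/m), `S`.
#' @export
dmps_isotherm_params <- function() {
  data.frame(
    system = c("DMPS", "DMPS+PL-200", "DMPS", "DMPS+PL-200"),
    phase  = c("LE", "LE", "LC", "LC"),
    A0     = c(59.8, 60.8, 46, 49),
    Ae     = c(49.3, 48.9, 30.6, 24.4),
    KP     = c(8.1, 13.6, 5.2, 7.0),
    t0     = c(0.08, 0.07, NA, NA),
    S      = c(0.132, 0.057, NA, NA),
    stringsAsFactors = FALSE
  )
}
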