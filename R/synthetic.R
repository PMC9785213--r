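#' Default scattering-vector grid
#'
#' 200 log-spaced points over 0.02--0.8 1/A, the range over which monolayer
#' reflectivity is informative (from just below the critical wavevector up
#' to where roughness damping kills the signal).
#'
#' @param n number of points.
#' @param qz_range length-2 range (1/Angstrom).
#' @return numeric vector.
#' @export
default_qz_grid <- function(n = 200, qz_range = c(0.02, 0.8)) {
  stopifnot(n >= 2, qz_range[1] > 0, qz_range[2] > qz_range[1])
  exp(seq(log(qz_range[1]), log(qz_range[2]), length.out = n))
}

#' Simulate a noisy specular reflectivity measurement
#'
#' Forward-computes `R(qz)` for a slab model and applies multiplicative
#' Gaussian noise, `R_obs = R * (1 + eps)`, `eps ~ N(0, level)`, emulating
#' counting statistics with a fractional error band (3--10% in practice;
#' default 5%). Draws with `1 + eps <= 0` are redrawn so that `R_obs > 0`.
#' The per-point uncertainty `sigma_R = level * R` is recorded. The
#' generator is a pure function of (model, grid, level, seed): the caller's
#' RNG state is untouched and the same seed reproduces the same dataset.
#'
#' @param model an [interface_model()].
#' @param qz scattering-vector grid (1/Angstrom); default
#'   [default_qz_grid()].
#' @param level relative noise level, in `[0, 0.2]`.
#' @param seed integer seed (`NULL` = use current RNG stream).
#' @param optics a [subphase_optics()].
#' @return a [reflectivity_curve()].
#' @export
gen_reflectivity <- function(model, qz = default_qz_grid(), level = 0.05,
                             seed = NULL, optics = subphase_optics()) {
  if (!is.numeric(level) || level < 0 || level > 0.2)
    stop("noise level must lie in [0, 0.2]")
  R <- refl_forward(qz, model, optics)
  if (level == 0) return(reflectivity_curve(qz, R, rep(0, length(qz))))
  eps <- with_seed(seed, {
    e <- rnorm(length(qz), 0, level)
    while (any(bad <- (1 + e <= 0)))
      e[bad] <- rnorm(sum(bad), 0, level)
    e
  })
  reflectivity_curve(qz, R * (1 + eps), sigma_R = level * R)
}

#' Simulate a noisy pressure--area isotherm
#'
#' Evaluates the elastic-shell compression law on a pressure grid and adds
#' additive Gaussian area noise (instrumental scatter, default 0.5 A^2).
#'
#' @param model a [compression_model()].
#' @param P pressure grid (mN/m), within `[0, 45]`.
#' @param noise_sd additive area noise (A^2, >= 0).
#' @param seed integer seed.
#' @return an [isotherm_curve()].
#' @export
gen_isotherm <- function(model, P = seq(1, 22, by = 0.25), noise_sd = 0.5,
                         seed = NULL) {
  if (!length(P)) stop("pressure grid is empty")
  if (any(P < 0) || any(P > 45)) stop("pressure grid must lie in [0, 45] mN/m")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  A <- area_model(P, model)
  if (noise_sd > 0)
    A <- A + with_seed(seed, rnorm(length(P), 0, noise_sd))
  isotherm_curve(P, A)
}

#' Simulate a Volta-potential vs compression-energy series
#'
#' The liquid-expanded regime shows a linear relation `dV = S * W`; this
#' generator adds Gaussian potential noise (default 2 mV) to that line.
#'
#' @param S slope (mV per mN/m A^2).
#' @param W compression-energy grid (mN/m A^2, >= 0).
#' @param noise_sd additive potential noise (mV).
#' @param seed integer seed.
#' @return data frame with columns `W`, `dV`.
#' @export
gen_volta <- function(S, W, noise_sd = 2, seed = NULL) {
  if (any(W < 0)) stop("compression energies must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  dV <- S * W
  if (noise_sd > 0)
    dV <- dV + with_seed(seed, rnorm(length(W), 0, noise_sd))
  data.frame(W = W, dV = dV)
}

#' Materialize the full battery of reference synthetic datasets
#'
#' Writes, under `dir`, a noisy reflectivity curve for each of the eight
#' reference film conditions ([dmps_reference_params()]) and a noisy LE
#' isotherm plus Volta series for each reference compression-law row that
#' has one, using documented per-file seeds derived from `seed`. Files are
#' the same delimited-text formats the readers accept.
#'
#' @param dir output directory (created if needed).
#' @param seed base integer seed.
#' @param level reflectivity noise level.
#' @param noise_sd isotherm area noise (A^2).
#' @return invisibly, a data frame manifest (file, kind, seed).
#' @export
write_reference_fixtures <- function(dir, seed = 1L, level = 0.05,
                                     noise_sd = 0.5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  tab <- dmps_reference_params()
  for (i in seq_len(nrow(tab))) {
    p <- tab[i, ]
    s <- seed + i
    m <- dmps_interface_model(p$phase, p$film)
    cur <- gen_reflectivity(m, level = level, seed = s)
    f <- file.path(dir, sprintf("refl_%s_%s.dat", p$phase,
                                gsub("[^A-Za-z0-9]", "", p$film)))
    write_reflectivity(cur, f, meta = sprintf("seed %d, noise %.2g", s, level))
    manifest[[length(manifest) + 1L]] <-
      data.frame(file = f, kind = "reflectivity", seed = s)
  }
  iso <- dmps_isotherm_params()
  le <- iso[iso$phase == "LE", ]
  for (i in seq_len(nrow(le))) {
    p <- le[i, ]
    s <- seed + 100 + i
    cm <- compression_model(p$A0, p$Ae, p$KP)
    cur <- gen_isotherm(cm, noise_sd = noise_sd, seed = s)
    # P grid starts at the 1 mN/m reference, so W aligns point-for-point
    W <- compression_energy(cur)$W
    vd <- gen_volta(p$S, W, seed = s + 1000)
    cur$V <- vd$dV  # potential trace, already zero at the reference point
    f <- file.path(dir, sprintf("isotherm_%s.dat",
                                gsub("[^A-Za-z0-9]", "", p$system)))
    write_isotherm(cur, f, meta = sprintf("seed %d, area noise %.2g A^2",
                                          s, noise_sd))
    manifest[[length(manifest) + 1L]] <-
      data.frame(file = f, kind = "isotherm", seed = s)
  }
  invisible(do.call(rbind, manifest))
}
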