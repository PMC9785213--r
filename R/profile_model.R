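#' Build a slab-stack interface model
#'
#' Represents the air--film--water interface as an ordered stack of `N`
#' homogeneous slabs between air (normalized density 0) and bulk water
#' (normalized density 1). Each slab carries a thickness `L` (Angstrom), an
#' electron density `rho` normalized to the bulk water value
#' (0.333 e-/A^3), and the Gaussian width `sigma` (Angstrom) of the
#' interface at its *upper* (air-side) boundary. `sigma_bottom` is the width
#' of the deepest slab--subphase interface. Interface `j` sits at depth
#' `z_j = sum(L_1..L_j)` with `z = 0` at the tail--air boundary and `z`
#' increasing into the subphase.
#'
#' An empty stack (`N = 0`) describes the bare water surface, a single
#' erf-smeared air--water interface of width `sigma_bottom`.
#'
#' @param slabs list of numeric triples `c(L, rho, sigma)` (or a data frame
#'   with columns `L`, `rho`, `sigma`), ordered from the air side to the
#'   water side.
#' @param sigma_bottom width (Angstrom, >= 0) of the deepest interface.
#' @param rho_air normalized electron density of air (must be ~0).
#' @param rho_bulk normalized density of the subphase (must be exactly 1;
#'   densities are stored relative to bulk water).
#' @return An object of class `interface_model`.
#' @examples
#' # clean DMPS monolayer in the LC state: acyl tails + headgroups
#' m <- interface_model(list(c(16.1, 1.02, 3.6), c(9.5, 1.56, 3.6)),
#'                      sigma_bottom = 3.6)
#' m
#' @export
interface_model <- function(slabs = list(), sigma_bottom, rho_air = 0,
                            rho_bulk = 1) {
  if (is.data.frame(slabs)) {
    stopifnot(all(c("L", "rho", "sigma") %in% names(slabs)))
    df <- slabs[c("L", "rho", "sigma")]
  } else {
    if (length(slabs) && !all(vapply(slabs, length, 1L) == 3L))
      stop("each slab must be a numeric triple c(L, rho, sigma)")
    df <- as.data.frame(do.call(rbind, slabs))
    if (!nrow(df)) df <- data.frame(L = numeric(), rho = numeric(),
                                    sigma = numeric())
    names(df) <- c("L", "rho", "sigma")
  }
  if (!is.numeric(sigma_bottom) || length(sigma_bottom) != 1L ||
      !is.finite(sigma_bottom) || sigma_bottom < 0)
    stop("sigma_bottom must be a single non-negative width in Angstrom")
  if (nrow(df)) {
    if (any(!is.finite(as.matrix(df))))
      stop("slab parameters must be finite")
    if (any(df$L <= 0))
      stop("slab thicknesses must be positive")
    if (any(df$rho < 0))
      stop("slab densities must be non-negative")
    if (any(df$sigma < 0))
      stop("slab roughnesses must be non-negative")
  }
  if (abs(rho_air) > 1e-6)
    stop("rho_air must be 0 within tolerance (densities are normalized)")
  if (rho_bulk != 1)
    stop("rho_bulk must be exactly 1 (densities are normalized to water)")
  structure(list(slabs = df, sigma_bottom = sigma_bottom,
                 rho_air = rho_air, rho_bulk = rho_bulk, N = nrow(df)),
            class = "interface_model")
}

#' @export
print.interface_model <- function(x, ...) {
  cat(sprintf("<interface_model> %d slab(s), sigma_bottom = %g A\n",
              x$N, x$sigma_bottom))
  if (x$N) {
    df <- x$slabs
    df$z_lower <- cumsum(df$L)
    print(df, row.names = TRUE)
  } else {
    cat("  bare air-water interface\n")
  }
  invisible(x)
}

# Interface depths z_j, j = 0..N (z_0 = 0 at the tail--air boundary).
interface_depths <- function(model) cumsum(c(0, model$slabs$L))

# Interface widths sigma_j, j = 0..N (slab j carries sigma_{j-1}).
interface_widths <- function(model) c(model$slabs$sigma, model$sigma_bottom)

# Densities rho_j, j = 0..N+1, normalized (air, slabs..., bulk).
interface_densities <- function(model)
  c(model$rho_air, model$slabs$rho, model$rho_bulk)

#' Render an interface model as a continuous electron-density profile
#'
#' Evaluates the erf-smeared profile
#' \deqn{\rho(z) = \rho_{air} + \tfrac12 \sum_{j=0}^{N}
#'   (\rho_{j+1}-\rho_j)\,[1 + \mathrm{erf}((z - z_j)/(\sigma_j\sqrt2))]}
#' on a depth grid (z positive into the subphase). The asymptotes are exactly
#' `rho_air` on the air side and 1 (bulk water) at depth. With all
#' `sigma -> 0` the profile converges to the ideal step profile.
#'
#' @param model an [interface_model()].
#' @param z depth grid in Angstrom, strictly increasing. If `NULL`, a default
#'   grid with step `dz` padded by `8 * max(sigma)` beyond the outermost
#'   interfaces is used.
#' @param dz grid step (Angstrom) for the default grid.
#' @return A data frame of class `density_profile` with columns `z` and
#'   `rho` (normalized to bulk water).
#' @export
density_profile <- function(model, z = NULL, dz = 0.1) {
  stopifnot(inherits(model, "interface_model"))
  zj  <- interface_depths(model)
  sj  <- interface_widths(model)
  if (is.null(z)) {
    pad <- 8 * max(sj, 1)
    z <- seq(min(zj) - pad, max(zj) + pad, by = dz)
  }
  if (any(diff(z) <= 0)) stop("z grid must be strictly increasing")
  rho_all <- interface_densities(model)
  drho <- diff(rho_all)                      # rho_{j+1} - rho_j, j = 0..N
  rho <- rep(model$rho_air, length(z))
  for (j in seq_along(zj)) {
    if (sj[j] > 0) {
      step <- pnorm((z - zj[j]) / sj[j])     # = (1 + erf(x/(s*sqrt2)))/2
    } else {
      step <- as.numeric(z > zj[j]) + 0.5 * (z == zj[j])
    }
    rho <- rho + drho[j] * step
  }
  structure(data.frame(z = z, rho = rho),
            class = c("density_profile", "data.frame"))
}

#' Write a density profile as two-column delimited text
#'
#' Columns are depth z (Angstrom) and normalized density rho/rho_w.
#'
#' @param profile a `density_profile`.
#' @param path output file path.
#' @param meta optional character vector written as `#`-prefixed header lines.
#' @export
write_profile <- function(profile, path, meta = NULL) {
  stopifnot(inherits(profile, "density_profile"))
  lines <- c(if (length(meta)) paste("#", meta),
             "# z_angstrom rho_over_rhow",
             sprintf("%.17g %.17g", profile$z, profile$rho))
  writeLines(lines, path)
  invisible(path)
}
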