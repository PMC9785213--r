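#' Isotherm curve container
#'
#' A pressure--area isotherm, optionally with the simultaneously recorded
#' Volta potential. Points are stored sorted by increasing pressure.
#'
#' @param P lateral pressure (mN/m, >= 0).
#' @param A area per molecule (A^2, > 0).
#' @param V optional Volta potential (mV, raw trace; zero-referencing to
#'   P = 1 mN/m happens in [compression_volta()]).
#' @return data frame of class `isotherm_curve`.
#' @export
isotherm_curve <- function(P, A, V = NULL) {
  stopifnot(is.numeric(P), is.numeric(A), length(P) == length(A))
  if (any(P < 0)) stop("pressure must be non-negative")
  if (any(A <= 0)) stop("area per molecule must be positive")
  o <- order(P)
  df <- data.frame(P = P[o], A = A[o])
  if (!is.null(V)) {
    stopifnot(length(V) == length(P))
    df$V <- V[o]
  }
  structure(df, class = c("isotherm_curve", "data.frame"))
}

as_isotherm_curve <- function(x) {
  if (inherits(x, "isotherm_curve")) return(x)
  stopifnot(is.data.frame(x), all(c("P", "A") %in% names(x)))
  isotherm_curve(x$P, x$A, if ("V" %in% names(x)) x$V)
}

#' Elastic-shell compression law
#'
#' The empirical law `A(P) = A0 + Ae * exp(-P/KP)`: each molecule occupies
#' a rigid core of area `A0` plus an elastic shell of area `Ae` that yields
#' under lateral pressure with softness `KP` (smaller `KP` = stiffer
#' monolayer).
#'
#' @param A0 rigid-core area (A^2, > 0).
#' @param Ae elastic-shell area (A^2, > 0).
#' @param KP elasticity parameter (mN/m, > 0).
#' @param t0 optional goodness-of-fit scale (mN/m), RMS pressure residual.
#' @param branch optional phase label ("LE" or "LC").
#' @return list of class `compression_model`.
#' @export
compression_model <- function(A0, Ae, KP, t0 = NA_real_,
                              branch = NA_character_) {
  if (any(c(A0, Ae, KP) <= 0)) stop("A0, Ae and KP must be positive")
  structure(list(A0 = A0, Ae = Ae, KP = KP, t0 = t0, branch = branch),
            class = "compression_model")
}

#' @export
print.compression_model <- function(x, ...) {
  cat(sprintf("compression law: A(P) = %.4g + %.4g exp(-P/%.4g) A^2",
              x$A0, x$Ae, x$KP))
  if (is.finite(x$t0)) cat(sprintf("   [t0 = %.3g mN/m]", x$t0))
  cat("\n")
  invisible(x)
}

#' Area per molecule under the compression law
#'
#' @param P lateral pressure (mN/m, >= 0).
#' @param model a [compression_model()].
#' @return area per molecule (A^2).
#' @export
area_model <- function(P, model) {
  stopifnot(inherits(model, "compression_model"))
  if (any(P < 0)) stop("pressure must be non-negative")
  model$A0 + model$Ae * exp(-P / model$KP)
}

#' Detect the LE--LC coexistence plateau of an isotherm
#'
#' Flags the pressure range where the local |dP/dA| falls below a fraction
#' of its median over the low-pressure (LE) half of the curve -- the nearly
#' horizontal coexistence plateau. Heuristic; used only to warn when a fit
#' window straddles the phase transition.
#'
#' @param curve an [isotherm_curve()].
#' @param frac slope threshold as a fraction of the LE median slope.
#' @return numeric length-2 pressure range of the plateau, or `NULL`.
#' @export
detect_plateau <- function(curve, frac = 0.1) {
  curve <- as_isotherm_curve(curve)
  if (nrow(curve) < 8) return(NULL)
  dP <- diff(curve$P); dA <- diff(curve$A)
  ok <- abs(dA) > 1e-12
  slope <- abs(dP[ok] / dA[ok])
  Pm <- (curve$P[-1] + curve$P[-nrow(curve)])[ok] / 2
  le <- Pm <= median(curve$P)
  if (!any(le)) return(NULL)
  ref <- median(slope[le])
  flat <- slope < frac * ref
  if (!any(flat)) return(NULL)
  range(Pm[flat])
}

#' Fit the compression law to a pressure--area isotherm
#'
#' Least-squares fit of `A(P) = A0 + Ae exp(-P/KP)` in area space
#' (minimizing the sum of squared area residuals), restricted to a single
#' phase branch. The window must exclude the LE--LC coexistence plateau; a
#' warning is issued if the detected plateau overlaps it. The
#' goodness-of-fit scale `t0` is the RMS pressure residual after inverting
#' the fitted law, `P(A) = -KP log((A - A0)/Ae)`, which has pressure units
#' and vanishes for a perfect fit.
#'
#' @param curve an [isotherm_curve()] (or data frame with `P`, `A`).
#' @param window optional pressure range `c(Pmin, Pmax)` selecting the
#'   branch (e.g. the LE region below the plateau onset).
#' @param start optional named start values `c(A0=, Ae=, KP=)`.
#' @return list of class `compression_fit` with the fitted
#'   [compression_model()], standard errors, residuals and convergence
#'   info.
#' @export
fit_compression <- function(curve, window = NULL, start = NULL) {
  curve <- as_isotherm_curve(curve)
  plateau <- detect_plateau(curve)
  d <- curve
  if (!is.null(window)) {
    stopifnot(length(window) == 2L)
    d <- curve[curve$P >= window[1] & curve$P <= window[2], ]
    if (!is.null(plateau) && plateau[1] < window[2] && plateau[2] > window[1])
      warning("fit window overlaps the detected LE-LC coexistence plateau")
  }
  if (nrow(d) < 10) stop("need at least 10 points in the fit window")
  if (diff(range(d$A)) < 1e-6)
    stop("degenerate isotherm: area does not vary over the window")
  if (is.null(start)) {
    A0s <- max(min(d$A) * 0.95, 1)
    start <- c(A0 = A0s, Ae = max(d$A) - A0s, KP = max(median(d$P), 1))
  }
  resfn <- function(th) d$A - (th[1] + th[2] * exp(-d$P / th[3]))
  fit <- minpack.lm::nls.lm(
    par = unname(start), fn = resfn,
    lower = c(1e-6, 1e-6, 1e-3), upper = c(Inf, Inf, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!(fit$info %in% 1:4))
    stop("compression-law fit did not converge: ", fit$message)
  th <- fit$par
  names(th) <- c("A0", "Ae", "KP")
  if (th["Ae"] < 1e-3)
    warning("Ae collapsed to ~0: data carry no compression signal")
  # t0: RMS pressure residual through the inverted law
  r <- (d$A - th["A0"]) / th["Ae"]
  ok <- r > 1e-10
  t0 <- if (any(ok)) {
    Pinv <- -th["KP"] * log(r[ok])
    sqrt(mean((d$P[ok] - Pinv)^2))
  } else NA_real_
  se <- tryCatch({
    s2 <- fit$deviance / (nrow(d) - 3L)
    sqrt(diag(s2 * solve(fit$hessian)))
  }, error = function(e) rep(NA_real_, 3))
  names(se) <- names(th)
  structure(list(model = compression_model(th["A0"], th["Ae"], th["KP"],
                                           t0 = unname(t0)),
                 par = th, se = se, t0 = unname(t0),
                 deviance = fit$deviance, n = nrow(d),
                 converged = TRUE, plateau = plateau),
            class = "compression_fit")
}

#' @export
print.compression_fit <- function(x, ...) {
  print(x$model)
  cat(sprintf("  n = %d, RSS(A) = %.4g A^4, se: A0 %.2g, Ae %.2g, KP %.2g\n",
              x$n, x$deviance, x$se["A0"], x$se["Ae"], x$se["KP"]))
  invisible(x)
}

#' Two-dimensional compression energy along an isotherm
#'
#' The work per molecule done compressing the film from the reference point
#' `A(P_ref)` down to area `A`:
#' \deqn{W(A) = \int_A^{A(P_{ref})} P\,dA'}
#' computed by trapezoidal quadrature along the measured curve, zero at the
#' reference point (P_ref = 1 mN/m by convention). Units: mN/m A^2 per
#' molecule.
#'
#' @param curve an [isotherm_curve()].
#' @param P_ref reference pressure (mN/m); must lie within the data range.
#' @return data frame of class `compression_energy` with columns `P`, `A`,
#'   `W`, restricted to the compression branch `P >= P_ref` (first row is
#'   the interpolated reference point with `W = 0`).
#' @export
compression_energy <- function(curve, P_ref = 1) {
  curve <- as_isotherm_curve(curve)
  if (P_ref < min(curve$P) || P_ref > max(curve$P))
    stop("P_ref lies outside the pressure range of the data")
  A_ref <- approx(curve$P, curve$A, xout = P_ref, ties = mean)$y
  d <- curve[curve$P > P_ref, ]
  P <- c(P_ref, d$P)
  A <- c(A_ref, d$A)
  # W_k = sum of trapezoids of P dA from the reference down to point k
  W <- cumsum(c(0, 0.5 * (P[-1] + P[-length(P)]) * (-diff(A))))
  structure(data.frame(P = P, A = A, W = W),
            class = c("compression_energy", "data.frame"))
}

#' Volta potential vs compression energy series
#'
#' Zero-references the measured Volta potential at the `P_ref` point
#' (potential taken as zero at 1 mN/m) and pairs it with the
#' two-dimensional compression energy [compression_energy()] at the same
#' pressures.
#'
#' @param curve an [isotherm_curve()] carrying a `V` column (mV).
#' @param P_ref reference pressure (mN/m).
#' @return data frame with columns `P`, `A`, `W`, `dV`.
#' @export
compression_volta <- function(curve, P_ref = 1) {
  curve <- as_isotherm_curve(curve)
  if (is.null(curve$V)) stop("isotherm carries no Volta potential column")
  en <- compression_energy(curve, P_ref)
  V_ref <- approx(curve$P, curve$V, xout = P_ref, ties = mean)$y
  dV <- approx(curve$P, curve$V, xout = en$P, ties = mean)$y - V_ref
  cbind(en, dV = dV)
}

#' Slope of the Volta potential vs compression energy
#'
#' In the liquid-expanded regime the Volta potential change is directly
#' proportional to the two-dimensional compression energy; `S` is the slope
#' of the least-squares line through the origin (both series are
#' zero-referenced at the same P = 1 mN/m point). Units: mV per
#' (mN/m A^2); values are comparable only within this fixed unit system.
#'
#' @param W compression energy series (mN/m A^2 per molecule, >= 0).
#' @param dV Volta potential change series (mV), matched to `W`.
#' @return list of class `volta_slope` with `S`, its standard error `se`,
#'   and `n`.
#' @export
volta_slope <- function(W, dV) {
  stopifnot(length(W) == length(dV))
  ok <- is.finite(W) & is.finite(dV)
  W <- W[ok]; dV <- dV[ok]
  if (length(W) < 5) stop("need at least 5 matched (W, dV) points")
  if (any(W < 0)) stop("compression energy must be non-negative")
  sw2 <- sum(W^2)
  if (sw2 <= 0) stop("degenerate series: all compression energies are zero")
  S <- sum(W * dV) / sw2
  se <- sqrt(sum((dV - S * W)^2) / (length(W) - 1) / sw2)
  structure(list(S = S, se = se, n = length(W)), class = "volta_slope")
}

#' @export
print.volta_slope <- function(x, ...) {
  cat(sprintf("Volta/energy slope S = %.4g +/- %.2g (n = %d)\n",
              x$S, x$se, x$n))
  invisible(x)
}
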