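# Parse a delimited numeric text file, tracking original line numbers for
# error messages. Accepts whitespace- and/or comma-separated columns and
# "#"-prefixed comment lines.
parse_numeric_table <- function(path, comment = "#") {
  lines <- readLines(path)
  idx <- which(!grepl(sprintf("^\\s*(%s|$)", comment), lines))
  if (!length(idx)) stop("no data rows in '", path, "'")
  rows <- lapply(idx, function(i) {
    toks <- strsplit(trimws(gsub(",", " ", lines[i])), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals))
      stop(sprintf("non-numeric value on line %d of '%s'", i, path))
    vals
  })
  ncols <- unique(vapply(rows, length, 1L))
  if (length(ncols) != 1L)
    stop("inconsistent column counts in '", path, "'")
  mat <- do.call(rbind, rows)
  attr(mat, "lines") <- idx
  mat
}

#' Read a reflectivity curve from delimited text
#'
#' Expects 2 or 3 numeric columns: qz (1/Angstrom), R, and optionally the
#' absolute uncertainty sigma_R. `#`-prefixed lines are comments. Rows are
#' sorted by qz. A missing uncertainty column defaults to 5% relative
#' errors, with a warning.
#'
#' @param path file path.
#' @param default_rel_err relative error assumed when no third column is
#'   present.
#' @return a [reflectivity_curve()].
#' @export
read_reflectivity <- function(path, default_rel_err = 0.05) {
  mat <- parse_numeric_table(path)
  if (!ncol(mat) %in% 2:3)
    stop("expected 2 or 3 columns (qz, R[, sigma_R]) in '", path, "'")
  lineno <- attr(mat, "lines")
  if (any(mat[, 2] <= 0))
    stop(sprintf("non-positive reflectivity on line %d of '%s'",
                 lineno[which(mat[, 2] <= 0)[1]], path))
  o <- order(mat[, 1])
  qz <- mat[o, 1]; R <- mat[o, 2]
  if (ncol(mat) == 3) {
    sR <- mat[o, 3]
  } else {
    warning("no uncertainty column in '", path, "'; assuming ",
            default_rel_err * 100, "% relative errors")
    sR <- default_rel_err * R
  }
  reflectivity_curve(qz, R, sR)
}

#' Write a reflectivity curve as delimited text
#'
#' Three columns (qz, R, sigma_R) at full double precision, so that a
#' write/read round trip is lossless.
#'
#' @param curve a [reflectivity_curve()].
#' @param path output file path.
#' @param meta optional character vector of `#`-prefixed header lines.
#' @export
write_reflectivity <- function(curve, path, meta = NULL) {
  curve <- as_reflectivity_curve(curve)
  writeLines(c(if (length(meta)) paste("#", meta),
               "# qz_invA R sigma_R",
               sprintf("%.17g %.17g %.17g", curve$qz, curve$R,
                       curve$sigma_R)),
             path)
  invisible(path)
}

#' Read a pressure--area isotherm from delimited text
#'
#' Expects 2 or 3 numeric columns: A (A^2), P (mN/m), and optionally the
#' Volta potential V (mV).
#'
#' @param path file path.
#' @return an [isotherm_curve()].
#' @export
read_isotherm <- function(path) {
  mat <- parse_numeric_table(path)
  if (!ncol(mat) %in% 2:3)
    stop("expected 2 or 3 columns (A, P[, V]) in '", path, "'")
  isotherm_curve(P = mat[, 2], A = mat[, 1],
                 V = if (ncol(mat) == 3) mat[, 3])
}

#' Write an isotherm as delimited text (A, P[, V])
#'
#' @param curve an [isotherm_curve()].
#' @param path output file path.
#' @param meta optional `#`-prefixed header lines.
#' @export
write_isotherm <- function(curve, path, meta = NULL) {
  curve <- as_isotherm_curve(curve)
  hasV <- !is.null(curve$V)
  body <- if (hasV)
    sprintf("%.17g %.17g %.17g", curve$A, curve$P, curve$V)
  else sprintf("%.17g %.17g", curve$A, curve$P)
  writeLines(c(if (length(meta)) paste("#", meta),
               paste("# A_A2 P_mNm", if (hasV) "V_mV"),
               body),
             path)
  invisible(path)
}

# Build an interface model from a config-style list:
# list(layers = list(list(L=, rho=, sigma=), ...), sigma_bottom = )
model_from_config <- function(mc) {
  if (is.null(mc)) stop("config is missing a 'model' block")
  layers <- lapply(mc$layers, function(l) {
    if (is.null(l$L) || is.null(l$rho) || is.null(l$sigma))
      stop("each layer needs L, rho and sigma")
    c(l$L, l$rho, l$sigma)
  })
  sb <- mc$sigma_bottom
  if (is.null(sb)) stop("model block needs sigma_bottom")
  interface_model(layers, sigma_bottom = sb)
}

scheme_from_config <- function(sc) {
  if (is.null(sc)) return(constraint_scheme())
  constraint_scheme(mode = sc$mode %||% "tie_all",
                    fixed_tail = isTRUE(sc$fixed_tail),
                    bounds = sc$bounds %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and validate a pipeline run configuration
#'
#' YAML configuration with a top-level `mode` (one of `simulate`,
#' `fit-refl`, `fit-isotherm`, `hydration`, `profile`, `fixtures`) plus
#' mode-specific blocks (`model`, `scheme`, `noise`, `grid`, `input`,
#' `output`, `constants`). Validation happens before any computation:
#' referenced input paths must exist, slab models must be physically valid
#' (positive thicknesses, non-negative densities and roughnesses), and
#' constants must be positive.
#'
#' @param path YAML file path.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  modes <- c("simulate", "fit-refl", "fit-isotherm", "hydration",
             "profile", "fixtures")
  if (is.null(cfg$mode) || !cfg$mode %in% modes)
    stop("config mode must be one of: ", paste(modes, collapse = ", "))
  if (cfg$mode %in% c("fit-refl", "fit-isotherm", "hydration")) {
    if (is.null(cfg$input) || !file.exists(cfg$input))
      stop("config input path does not exist: ", cfg$input %||% "<missing>")
  }
  if (!is.null(cfg$model)) model_from_config(cfg$model)  # validates
  for (k in names(cfg$constants %||% list())) {
    v <- cfg$constants[[k]]
    if (!is.numeric(v) || v <= 0)
      stop("constant '", k, "' must be a positive number")
  }
  structure(cfg, class = "run_config")
}

optics_from_config <- function(cfg) {
  cc <- cfg$constants %||% list()
  subphase_optics(rho_w_abs = cc$rho_w %||% .xrr_const$rho_w)
}

# Header lines embedded in every written report: exact config + versions,
# enough to regenerate the output.
report_header <- function(cfg) {
  c(sprintf("xrrfit %s | R %s.%s",
            as.character(utils::packageVersion("xrrfit")),
            R.version$major, R.version$minor),
    "config:",
    strsplit(yaml::as.yaml(unclass(cfg)), "\n")[[1]])
}

#' Run a simulate / fit / report pipeline stage
#'
#' Dispatches on `config$mode`:
#' * `simulate` -- generate a synthetic reflectivity curve or isotherm
#'   (blocks: `model` or `compression`, `grid`, `noise`) and write it.
#' * `fit-refl` -- read a reflectivity file, fit the configured slab model
#'   under the configured [constraint_scheme()], write a parameter report,
#'   the model curve and the density profile.
#' * `fit-isotherm` -- read an isotherm, fit the compression law in the
#'   configured pressure `window`; if a Volta column is present also
#'   report the energy--potential slope S.
#' * `hydration` -- read a slab-parameter table (header: label A L1 rho1
#'   L2 rho2) and write the hydration report.
#' * `profile` -- render the configured model as a density profile.
#' * `fixtures` -- materialize the reference synthetic dataset battery.
#'
#' Every written report embeds the configuration and seeds needed to
#' regenerate it.
#'
#' @param config a `run_config` (or path to one).
#' @return invisibly, a list with the stage's in-memory results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- switch(config$mode,
    "simulate"     = pipe_simulate(config),
    "fit-refl"     = pipe_fit_refl(config),
    "fit-isotherm" = pipe_fit_isotherm(config),
    "hydration"    = pipe_hydration(config),
    "profile"      = pipe_profile(config),
    "fixtures"     = list(manifest = write_reference_fixtures(
      config$output$dir %||% ".", seed = config$seed %||% 1L)))
  invisible(out)
}

pipe_simulate <- function(cfg) {
  kind <- cfg$simulate$kind %||% "reflectivity"
  seed <- cfg$seed %||% 1L
  if (kind == "reflectivity") {
    m <- model_from_config(cfg$model)
    g <- cfg$grid %||% list()
    qz <- default_qz_grid(g$n %||% 200,
                          c(g$qz_min %||% 0.02, g$qz_max %||% 0.8))
    cur <- gen_reflectivity(m, qz, level = cfg$noise$level %||% 0.05,
                            seed = seed, optics = optics_from_config(cfg))
    if (!is.null(cfg$output$data))
      write_reflectivity(cur, cfg$output$data, meta = report_header(cfg))
    list(curve = cur, model = m)
  } else if (kind == "isotherm") {
    cc <- cfg$compression
    cm <- compression_model(cc$A0, cc$Ae, cc$KP)
    g <- cfg$grid %||% list()
    P <- seq(g$P_min %||% 1, g$P_max %||% 22, by = g$P_by %||% 0.25)
    cur <- gen_isotherm(cm, P, noise_sd = cfg$noise$sd %||% 0.5,
                        seed = seed)
    if (!is.null(cfg$output$data))
      write_isotherm(cur, cfg$output$data, meta = report_header(cfg))
    list(curve = cur, model = cm)
  } else stop("unknown simulate kind: ", kind)
}

pipe_fit_refl <- function(cfg) {
  cur <- read_reflectivity(cfg$input)
  init <- model_from_config(cfg$model)
  scheme <- scheme_from_config(cfg$scheme)
  optics <- optics_from_config(cfg)
  fit <- fit_reflectivity(cur, init, scheme, optics,
                          n_restarts = cfg$fit$n_restarts %||% 5,
                          restart_seed = cfg$seed %||% 1L)
  if (!is.null(cfg$output$report)) {
    tab <- data.frame(parameter = names(fit$par), estimate = fit$par,
                      ci95 = fit$ci95, at_bound = fit$at_bound)
    writeLines(c(paste("#", report_header(cfg)),
                 sprintf("# chi2 %.6g dof %d flagged_sqz_frac %.3f",
                         fit$chi2, fit$dof, fit$sqz_flagged_frac),
                 paste(tab$parameter,
                       sprintf("%.6g %.3g %s", tab$estimate, tab$ci95,
                               tab$at_bound))),
               cfg$output$report)
  }
  if (!is.null(cfg$output$model_curve))
    write_reflectivity(reflectivity(cur$qz, fit$model, optics),
                       cfg$output$model_curve, meta = report_header(cfg))
  if (!is.null(cfg$output$profile))
    write_profile(density_profile(fit$model), cfg$output$profile,
                  meta = report_header(cfg))
  list(fit = fit, curve = cur)
}

pipe_fit_isotherm <- function(cfg) {
  cur <- read_isotherm(cfg$input)
  window <- if (!is.null(cfg$window)) unlist(cfg$window)
  fit <- fit_compression(cur, window = window)
  S <- NULL
  if (!is.null(cur$V)) {
    wv <- compression_volta(cur, P_ref = cfg$P_ref %||% 1)
    S <- volta_slope(wv$W, wv$dV)
  }
  if (!is.null(cfg$output$report)) {
    writeLines(c(paste("#", report_header(cfg)),
                 "# A0_A2 Ae_A2 KP_mNm t0_mNm S",
                 sprintf("%.6g %.6g %.6g %.4g %s",
                         fit$par["A0"], fit$par["Ae"], fit$par["KP"],
                         fit$t0,
                         if (is.null(S)) "NA" else sprintf("%.4g", S$S))),
               cfg$output$report)
  }
  list(fit = fit, volta = S, curve = cur)
}

pipe_hydration <- function(cfg) {
  params <- read.table(cfg$input, header = TRUE,
                       stringsAsFactors = FALSE, comment.char = "#")
  rep <- hydration_report(params,
                          Gamma = cfg$constants$Gamma %||% 391,
                          Gamma_w = cfg$constants$Gamma_w %||% 10)
  if (!is.null(cfg$output$report)) {
    con <- file(cfg$output$report, "w")
    writeLines(paste("#", report_header(cfg)), con)
    utils::write.table(rep, con, row.names = FALSE, quote = FALSE)
    close(con)
  }
  list(report = rep)
}

pipe_profile <- function(cfg) {
  m <- model_from_config(cfg$model)
  prof <- density_profile(m, dz = cfg$grid$dz %||% 0.1)
  if (!is.null(cfg$output$profile))
    write_profile(prof, cfg$output$profile, meta = report_header(cfg))
  list(profile = prof, model = m)
}
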