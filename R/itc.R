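# One-site ITC binding isotherm: forward simulation of injection heats
# under the standard total-heat (Wiseman) model with cell dilution, and
# nonlinear least-squares recovery of (n, K, dH) with exact thermodynamic
# identities dG = -RT ln K, -TdS = dG - dH, Kd = 1e6/K (uM).

.R_KCAL <- 1.987e-3  # gas constant, kcal mol^-1 K^-1

#' Titration protocol description
#'
#' Defaults mirror a standard cell-instrument setup: 1.4 mL cell, 10 uM
#' macromolecule in the cell, 100 uM ligand in the syringe, twenty 14 uL
#' injections, 283.15 K. The dilution model is "perfusion" (injected
#' volume displaces cell contents, the convention for overflow cells);
#' "no_displacement" switches to simple volume addition.
#'
#' @param cell_volume Cell volume, liters.
#' @param cell_conc Macromolecule concentration in the cell, mol/L.
#' @param syringe_conc Ligand concentration in the syringe, mol/L.
#' @param injection_volumes Per-injection volumes, liters.
#' @param temperature Kelvin.
#' @param dilution_model "perfusion" or "no_displacement".
#' @return A `titration_protocol` list.
#' @export
titration_protocol <- function(cell_volume = 1.4e-3,
                               cell_conc = 1e-5,
                               syringe_conc = 1e-4,
                               injection_volumes = rep(14e-6, 20),
                               temperature = 283.15,
                               dilution_model = c("perfusion",
                                                  "no_displacement")) {
  stopifnot(cell_volume > 0, cell_conc > 0, syringe_conc > 0,
            length(injection_volumes) >= 1, all(injection_volumes > 0),
            temperature > 0)
  structure(list(
    cell_volume = cell_volume, cell_conc = cell_conc,
    syringe_conc = syringe_conc,
    injection_volumes = injection_volumes,
    temperature = temperature,
    dilution_model = match.arg(dilution_model)),
    class = "titration_protocol")
}

# total and ligand concentrations in the cell after each injection
.cell_concentrations <- function(protocol) {
  v <- cumsum(protocol$injection_volumes)
  V0 <- protocol$cell_volume
  if (protocol$dilution_model == "perfusion") {
    Mt <- protocol$cell_conc * (1 - v / (2 * V0)) / (1 + v / (2 * V0))
    Xt <- protocol$syringe_conc * (v / V0) / (1 + v / (2 * V0))
  } else {
    Mt <- protocol$cell_conc * V0 / (V0 + v)
    Xt <- protocol$syringe_conc * v / (V0 + v)
  }
  list(Mt = Mt, Xt = Xt, v = v)
}

# fraction of sites occupied: smaller root of the binding quadratic
.site_occupancy <- function(Mt, Xt, n, K) {
  b <- 1 + Xt / (n * Mt) + 1 / (n * K * Mt)
  (b - sqrt(pmax(b^2 - 4 * Xt / (n * Mt), 0))) / 2
}

#' Predict injection heats for a one-site titration
#'
#' Cumulative heat after injection `i` is
#' `Q_i = n * theta_i * Mt_i * dH * V0`, with `theta` the smaller root of
#' the single-site binding quadratic at the diluted cell concentrations;
#' per-injection heat is the difference of cumulative heats with the
#' standard displaced-volume correction under the perfusion model.
#'
#' @param protocol A [titration_protocol()].
#' @param n Stoichiometry (sites per macromolecule).
#' @param K Association constant, 1/M.
#' @param dH Molar binding enthalpy, kcal/mol (any sign).
#' @return A tibble of class `thermogram`: `injection`, `volume` (L),
#'   `heat` (ucal); the protocol is attached as attribute `protocol`.
#' @export
predict_heats <- function(protocol, n, K, dH) {
  stopifnot(inherits(protocol, "titration_protocol"), n > 0, K > 0)
  cc <- .cell_concentrations(protocol)
  V0 <- protocol$cell_volume
  theta <- .site_occupancy(cc$Mt, cc$Xt, n, K)
  Q <- n * theta * cc$Mt * dH * V0 * 1e9  # kcal -> ucal
  Qprev <- c(0, head(Q, -1))
  dV <- protocol$injection_volumes
  dQ <- if (protocol$dilution_model == "perfusion") {
    Q - Qprev + (dV / V0) * (Q + Qprev) / 2
  } else {
    Q - Qprev
  }
  out <- tibble(injection = seq_along(dQ), volume = dV, heat = dQ)
  attr(out, "protocol") <- protocol
  class(out) <- c("thermogram", class(out))
  out
}

#' Derived binding thermodynamics
#'
#' Exact identities connecting an association constant and enthalpy to the
#' remaining state functions: `dG = -R T ln K` with
#' `R = 1.987e-3 kcal/mol/K`, `-TdS = dG - dH`, `Kd = 1e6 / K` in uM.
#'
#' @param K Association constant, 1/M.
#' @param dH Molar enthalpy, kcal/mol.
#' @param temperature Kelvin.
#' @return One-row tibble: `K`, `Kd_uM`, `dG`, `dH`, `TdS_neg`,
#'   `temperature`.
#' @examples
#' thermo_derive(2.0e6, 8.8, 283.15)  # dG ~ -8.2, -TdS ~ -17.0
#' @export
thermo_derive <- function(K, dH, temperature) {
  if (any(K <= 0)) abort("K must be positive")
  stopifnot(all(temperature > 0))
  dG <- -.R_KCAL * temperature * log(K)
  tibble(K = K, Kd_uM = 1e6 / K, dG = dG, dH = dH,
         TdS_neg = dG - dH, temperature = temperature)
}

#' Fit a one-site binding model to a thermogram
#'
#' Least-squares estimation of `(n, K, dH)` from per-injection heats by
#' Levenberg-Marquardt (via \pkg{minpack.lm}), fitting `log10 K` with
#' bounds `K` in `[1e2, 1e12]`. Initialization: `dH0` from the
#' first-injection heat per mole of injected ligand, `n0 = 1`, and the
#' best of a coarse `log10 K` grid. A thermogram with essentially no heat
#' (all |heat| below `flat_tol`) returns a flagged no-fit outcome, the
#' representation of a "no binding detected" titration.
#'
#' @param thermogram A `thermogram` (tibble with `heat` in ucal and a
#'   `protocol` attribute, or supply `protocol`).
#' @param protocol Optional [titration_protocol()] overriding the
#'   attribute.
#' @param flat_tol Flat-signal tolerance, ucal; default 1e-3.
#' @return A `binding_fit` object with elements `n`, `K`, `dH`, `Kd_uM`,
#'   `dG`, `TdS_neg`, `temperature`, `converged`, `no_binding`,
#'   `residual_norm`, `fitted` (tibble), `fit` (the nls object or NULL).
#' @export
fit_one_site <- function(thermogram, protocol = NULL, flat_tol = 1e-3) {
  protocol <- protocol %||% attr(thermogram, "protocol")
  if (is.null(protocol)) abort("no titration protocol available")
  q <- thermogram$heat
  if (length(q) < 5) abort("need at least 5 injections")
  if (max(abs(q)) < flat_tol) {
    return(new_binding_fit(protocol, converged = FALSE,
                           no_binding = TRUE, q = q))
  }
  dV1 <- protocol$injection_volumes[1]
  dH0 <- (q[1] * 1e-9) / (protocol$syringe_conc * dV1)
  model_fun <- function(n, lk, dh) {
    predict_heats(protocol, n, 10^lk, dh)$heat
  }
  dat <- data.frame(q = q)
  best <- NULL
  for (lk0 in 3:9) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        q ~ model_fun(n, lk, dh), data = dat,
        start = list(n = 1, lk = lk0, dh = dH0),
        lower = c(n = 0.05, lk = 2, dh = -1e4),
        upper = c(n = 20, lk = 12, dh = 1e4),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      if (is.null(best) || deviance(fit) < deviance(best)) best <- fit
    }
  }
  if (is.null(best)) {
    return(new_binding_fit(protocol, converged = FALSE,
                           no_binding = FALSE, q = q))
  }
  cf <- stats::coef(best)
  new_binding_fit(protocol, converged = TRUE, no_binding = FALSE,
                  q = q, n = unname(cf["n"]), K = 10^unname(cf["lk"]),
                  dH = unname(cf["dh"]), fit = best)
}

new_binding_fit <- function(protocol, converged, no_binding, q,
                            n = NA_real_, K = NA_real_, dH = NA_real_,
                            fit = NULL) {
  derived <- if (is.finite(K)) {
    thermo_derive(K, dH, protocol$temperature)
  } else {
    tibble(K = NA_real_, Kd_uM = NA_real_, dG = NA_real_, dH = NA_real_,
           TdS_neg = NA_real_, temperature = protocol$temperature)
  }
  fitted <- if (!is.null(fit)) {
    tibble(injection = seq_along(q), heat = q,
           fitted = predict_heats(protocol, n, K, dH)$heat)
  } else {
    tibble(injection = seq_along(q), heat = q, fitted = NA_real_)
  }
  structure(list(
    n = n, K = K, dH = dH,
    Kd_uM = derived$Kd_uM, dG = derived$dG, TdS_neg = derived$TdS_neg,
    temperature = protocol$temperature,
    converged = converged, no_binding = no_binding,
    residual_norm = if (!is.null(fit)) sqrt(deviance(fit)) else NA_real_,
    fitted = fitted, fit = fit, protocol = protocol),
    class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("<binding_fit>\n")
  if (x$no_binding) {
    cat("  no binding detected (flat thermogram)\n")
  } else if (!x$converged) {
    cat("  fit did not converge\n")
  } else {
    cat(sprintf("  n = %.3f, K = %.3g 1/M (Kd = %.3g uM)\n",
                x$n, x$K, x$Kd_uM))
    cat(sprintf(
      "  dH = %.2f, dG = %.2f, -TdS = %.2f kcal/mol at %.2f K\n",
      x$dH, x$dG, x$TdS_neg, x$temperature))
  }
  invisible(x)
}

#' @export
tidy.binding_fit <- function(x, ...) {
  est <- tibble(
    term = c("n", "K", "dH", "Kd_uM", "dG", "TdS_neg"),
    estimate = c(x$n, x$K, x$dH, x$Kd_uM, x$dG, x$TdS_neg))
  if (!is.null(x$fit)) {
    se <- tryCatch(sqrt(diag(stats::vcov(x$fit))),
                   error = function(e) rep(NA_real_, 3))
    scale <- c(1, x$K * log(10), 1)  # lk -> K via delta method
    est$std.error <- c(se * scale, rep(NA_real_, 3))
  }
  est
}

#' @export
glance.binding_fit <- function(x, ...) {
  tibble(converged = x$converged, no_binding = x$no_binding,
         residual_norm = x$residual_norm,
         nobs = nrow(x$fitted), temperature = x$temperature)
}

#' Write a thermogram as tab-separated text with a protocol header
#' @param thermogram A `thermogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_thermogram <- function(thermogram, path) {
  pr <- attr(thermogram, "protocol")
  hdr <- c(
    sprintf("# cell_volume_L\t%g", pr$cell_volume),
    sprintf("# cell_conc_M\t%g", pr$cell_conc),
    sprintf("# syringe_conc_M\t%g", pr$syringe_conc),
    sprintf("# temperature_K\t%g", pr$temperature),
    sprintf("# dilution_model\t%s", pr$dilution_model),
    sprintf("# injection_volumes_L\t%s",
            paste(pr$injection_volumes, collapse = ",")))
  readr::write_lines(hdr, path)
  readr::write_tsv(as_tibble(thermogram)[, c("injection", "heat")],
                   path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a thermogram written by [write_thermogram()]
#' @param path Input path.
#' @return A `thermogram` tibble with its protocol attached.
#' @export
read_thermogram <- function(path) {
  lines <- readr::read_lines(path)
  hdr <- lines[startsWith(lines, "#")]
  kv <- strsplit(sub("^# ", "", hdr), "\t")
  vals <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  protocol <- titration_protocol(
    cell_volume = as.numeric(vals["cell_volume_L"]),
    cell_conc = as.numeric(vals["cell_conc_M"]),
    syringe_conc = as.numeric(vals["syringe_conc_M"]),
    injection_volumes = as.numeric(strsplit(
      vals[["injection_volumes_L"]], ",")[[1]]),
    temperature = as.numeric(vals["temperature_K"]),
    dilution_model = vals[["dilution_model"]])
  body <- readr::read_tsv(I(lines[!startsWith(lines, "#")]),
                          show_col_types = FALSE)
  out <- tibble(injection = body$injection,
                volume = protocol$injection_volumes,
                heat = body$heat)
  attr(out, "protocol") <- protocol
  class(out) <- c("thermogram", class(out))
  out
}
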