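#' Titration protocol for an ITC experiment
#'
#' Describes the cell and syringe contents of an isothermal titration
#' calorimetry run with a perfusion (constant-volume, displacement) cell.
#' Defaults describe 25 injections of 4 ul of 30 mM titrant into 1.5 mM
#' macromolecule in a 1 ml cell at 298 K.
#'
#' @param V0_ml Cell volume, ml.
#' @param M0_mM Initial macromolecule concentration in the cell, mM.
#' @param X0_mM Syringe titrant concentration, mM.
#' @param injections_ul Vector of injection volumes, ul.
#' @param T Temperature, K.
#' @return A list of class `"titration_protocol"`.
#' @export
titration_protocol <- function(V0_ml = 1, M0_mM = 1.5, X0_mM = 30,
                               injections_ul = rep(4, 25), T = 298) {
  stopifnot(V0_ml > 0, M0_mM > 0, X0_mM > 0, T > 0,
            length(injections_ul) >= 1L, all(injections_ul > 0))
  structure(list(V0_ml = V0_ml, M0_mM = M0_mM, X0_mM = X0_mM,
                 injections_ul = as.numeric(injections_ul), T = T),
            class = "titration_protocol")
}

#' @export
print.titration_protocol <- function(x, ...) {
  cat("ITC protocol: ", length(x$injections_ul), " injections (",
      paste(unique(x$injections_ul), collapse = "/"), " ul) of ",
      x$X0_mM, " mM titrant into ", x$M0_mM, " mM in a ",
      x$V0_ml, " ml cell at ", x$T, " K\n", sep = "")
  invisible(x)
}

# per-injection cell concentrations under the multiplicative displacement
# model: each injection expels dV/V0 of the (instantly mixed) cell contents
.itc_concentrations <- function(protocol) {
  dV <- protocol$injections_ul * 1e-6 / (protocol$V0_ml * 1e-3)  # dV/V0
  n_inj <- length(dV)
  Mt <- Xt <- numeric(n_inj)
  M <- protocol$M0_mM * 1e-3                                     # mol/L
  X <- 0
  for (i in seq_len(n_inj)) {
    M <- M * (1 - dV[i])
    X <- X * (1 - dV[i]) + protocol$X0_mM * 1e-3 * dV[i]
    Mt[i] <- M
    Xt[i] <- X
  }
  list(Mt = Mt, Xt = Xt, dV = dV)
}

#' Simulate per-injection heats for a 1:1 binding isotherm
#'
#' Forward model for a single-site titration in a displacement cell
#' (Wiseman isotherm). After injection i the cumulative heat is
#' \deqn{Q_i = \frac{n M_i \Delta H_b V_0}{2}\left[1 + \frac{X_i}{n M_i}
#'   + \frac{1}{n K_a M_i} - \sqrt{\left(1 + \frac{X_i}{n M_i} +
#'   \frac{1}{n K_a M_i}\right)^2 - \frac{4 X_i}{n M_i}}\right]}
#' with running cell concentrations \eqn{M_i, X_i} diluted multiplicatively
#' by each injection; the observed heat of injection i is
#' \eqn{q_i = Q_i - Q_{i-1} + (dV_i/V_0)(Q_i + Q_{i-1})/2}, the standard
#' displaced-volume correction.
#'
#' @param protocol A [titration_protocol()].
#' @param Ka Association constant, M^-1.
#' @param dHb Binding enthalpy, kJ mol^-1.
#' @param n_sites Stoichiometry (sites per macromolecule).
#' @param noise_sd Additive Gaussian noise on each heat, uJ (0 = none).
#' @return Numeric vector of injection heats in uJ, with attributes `Mt`,
#'   `Xt` (cell concentrations, M) and `Q` (cumulative heats, uJ).
#' @examples
#' q <- simulate_injection_heats(titration_protocol(), Ka = 6.6e3, dHb = -6.7)
#' round(q[1:3], 1)
#' @export
simulate_injection_heats <- function(protocol, Ka, dHb, n_sites = 1,
                                     noise_sd = 0) {
  stopifnot(inherits(protocol, "titration_protocol"))
  if (Ka <= 0) stop("'Ka' must be positive", call. = FALSE)
  if (n_sites <= 0) stop("'n_sites' must be positive", call. = FALSE)

  cc <- .itc_concentrations(protocol)
  V0 <- protocol$V0_ml * 1e-3                        # L
  dH_J <- dHb * 1000                                 # J/mol

  r <- cc$Xt / (n_sites * cc$Mt)
  u <- 1 / (n_sites * Ka * cc$Mt)
  disc <- (1 + r + u)^2 - 4 * r
  stopifnot(all(disc >= 0))                          # true by construction
  Q <- n_sites * cc$Mt * dH_J * V0 / 2 * (1 + r + u - sqrt(disc))  # J
  Q <- Q * 1e6                                       # uJ

  Qprev <- c(0, Q[-length(Q)])
  q <- Q - Qprev + cc$dV * (Q + Qprev) / 2
  if (noise_sd > 0) q <- q + stats::rnorm(length(q), 0, noise_sd)
  attr(q, "Mt") <- cc$Mt
  attr(q, "Xt") <- cc$Xt
  attr(q, "Q") <- Q
  q
}

#' Fit a single-site binding model to ITC injection heats
#'
#' Levenberg-Marquardt least squares of (Ka, dHb, n) through the forward
#' model of [simulate_injection_heats()], parameterised internally in
#' (ln Ka, dHb, n) for conditioning. Starting values come from the data:
#' dHb from the early near-stoichiometric heats, Ka from a small grid of
#' trial affinities.
#'
#' @param protocol The [titration_protocol()] used to collect the heats.
#' @param heats Observed injection heats, uJ.
#' @param fix_n Fix the stoichiometry at `n_start` instead of floating it.
#' @param n_start Starting (or fixed) stoichiometry.
#' @param drop_first Discard the first injection before fitting (common
#'   practice for diffusion-spoiled first injections; off by default).
#' @return An object of class `"binding_fit"`: quantities `Ka` (M^-1),
#'   `dHb` (kJ mol^-1), `n_sites`, plus `rss`, `c_value` and the protocol.
#'   A c-value `n*Ka*M0` outside \[1, 1000\] triggers a warning that the
#'   isotherm shape poorly determines Ka.
#' @examples
#' p <- titration_protocol()
#' fit_single_site(p, simulate_injection_heats(p, 6.6e3, -6.7))
#' @export
fit_single_site <- function(protocol, heats, fix_n = FALSE, n_start = 1,
                            drop_first = FALSE) {
  stopifnot(inherits(protocol, "titration_protocol"))
  heats <- as.numeric(heats)
  if (length(heats) != length(protocol$injections_ul))
    stop("length(heats) must match the number of injections", call. = FALSE)
  if (length(heats) < 10L)
    stop("need at least 10 injections for a stable fit", call. = FALSE)
  if (!all(is.finite(heats))) stop("heats must be finite", call. = FALSE)

  keep <- if (drop_first) -1L else seq_along(heats)

  # crude dHb start: early injections are near-stoichiometric at high c
  mol_inj1 <- protocol$injections_ul[1L] * 1e-6 * protocol$X0_mM * 1e-3  # mol
  dHb0 <- heats[1L] * 1e-6 / mol_inj1 / 1000                            # kJ/mol
  if (!is.finite(dHb0) || dHb0 == 0) dHb0 <- sum(heats) * 1e-6 / 1000 /
      (sum(protocol$injections_ul) * 1e-6 * protocol$X0_mM * 1e-3)

  resid_fun <- function(p) {
    q <- simulate_injection_heats(protocol, Ka = exp(p[["lnKa"]]),
                                  dHb = p[["dHb"]],
                                  n_sites = if (fix_n) n_start else p[["n"]])
    (heats - q)[keep]
  }

  best <- NULL
  for (lnKa0 in log(c(1e3, 1e4, 1e5))) {
    p0 <- c(lnKa = lnKa0, dHb = dHb0)
    if (!fix_n) p0 <- c(p0, n = n_start)
    f <- try(minpack.lm::nls.lm(
      par = p0, fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
    if (inherits(f, "try-error")) next
    if (is.null(best) || f$deviance < best$deviance) best <- f
  }
  if (is.null(best)) stop("single-site fit failed to converge", call. = FALSE)

  p <- best$par
  sm <- .quiet_summary(best)
  se <- sm$coefficients[, "Std. Error"]
  Ka <- exp(p[["lnKa"]])
  nfit <- if (fix_n) n_start else p[["n"]]
  cval <- nfit * Ka * protocol$M0_mM * 1e-3
  if (cval < 1 || cval > 1000)
    warning("c-value ", signif(cval, 3),
            " outside [1, 1000]: isotherm poorly determines Ka",
            call. = FALSE)

  structure(list(
    Ka = quantity(Ka, Ka * se[["lnKa"]]),
    dHb = quantity(p[["dHb"]], se[["dHb"]]),
    n_sites = if (fix_n) quantity(n_start, 0) else
      quantity(p[["n"]], se[["n"]]),
    rss = best$deviance,
    c_value = cval,
    protocol = protocol,
    fit = best
  ), class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("Single-site ITC fit (c = ", signif(x$c_value, 3), ")\n", sep = "")
  cat("  Ka : ", format(x$Ka), " M^-1\n", sep = "")
  cat("  dHb: ", format(x$dHb), " kJ/mol\n", sep = "")
  cat("  n  : ", format(x$n_sites), "\n", sep = "")
  invisible(x)
}

#' Thermodynamic decomposition of a binding constant
#'
#' Converts an association constant and binding enthalpy into the full
#' binding thermodynamics at temperature T:
#' \eqn{\Delta G_b = -RT\ln K_a}, \eqn{T\Delta S_b = \Delta H_b - \Delta
#' G_b}, \eqn{\Delta S_b = 1000\,T\Delta S_b/T}. Standard errors are
#' first-order and combined in quadrature.
#'
#' @param Ka Association constant, M^-1 ([quantity()] or numeric,
#'   optionally `c(value, se)`).
#' @param dHb Binding enthalpy, kJ mol^-1.
#' @param T Temperature, K.
#' @return An object of class `"binding_thermo"` with quantities `Ka`,
#'   `dGb`, `dHb`, `TdSb` (kJ mol^-1) and `dSb` (J mol^-1 K^-1), plus `T`.
#' @examples
#' binding_decompose(c(6.6e3, 0.4e3), c(-6.7, 0.4))
#' @export
binding_decompose <- function(Ka, dHb, T = 298) {
  Ka <- as_quantity(Ka); dHb <- as_quantity(dHb)
  if (Ka$value <= 0) stop("'Ka' must be positive", call. = FALSE)
  stopifnot(T > 0)
  RT_kJ <- .const$R * T / 1000
  dGb <- -RT_kJ * log(Ka$value)
  dGb_se <- if (is.na(Ka$se)) NA_real_ else RT_kJ * Ka$se / Ka$value
  TdSb <- dHb$value - dGb
  TdSb_se <- quad_se(dHb$se, dGb_se)
  structure(list(
    Ka = Ka, T = T,
    dGb = quantity(dGb, dGb_se),
    dHb = dHb,
    TdSb = quantity(TdSb, TdSb_se),
    dSb = quantity(1000 * TdSb / T,
                   if (is.na(TdSb_se)) NA_real_ else 1000 * TdSb_se / T)
  ), class = "binding_thermo")
}

#' @export
print.binding_thermo <- function(x, ...) {
  cat("Binding thermodynamics at ", x$T, " K\n", sep = "")
  cat("  Ka  : ", format(x$Ka), " M^-1\n", sep = "")
  cat("  dGb : ", format(x$dGb), " kJ/mol\n", sep = "")
  cat("  dHb : ", format(x$dHb), " kJ/mol\n", sep = "")
  cat("  TdSb: ", format(x$TdSb), " kJ/mol\n", sep = "")
  cat("  dSb : ", format(x$dSb), " J/mol/K\n", sep = "")
  invisible(x)
}

#' Paired difference of binding thermodynamics
#'
#' Same convention as [delta_delta()]: first argument the variant without
#' the salt-bridge, second the variant with it; quadrature errors.
#'
#' @param a,b `"binding_thermo"` objects at the same temperature.
#' @param label_a,label_b Optional variant names.
#' @return A `"delta_delta"` object (fields `ddG`, `ddH`, `TddS`, `ddS`
#'   refer to the binding quantities).
#' @export
binding_delta_delta <- function(a, b, label_a = "a", label_b = "b") {
  stopifnot(inherits(a, "binding_thermo"), inherits(b, "binding_thermo"))
  if (!isTRUE(all.equal(a$T, b$T)))
    stop("temperatures differ: ", a$T, " vs ", b$T, call. = FALSE)
  diff_q <- function(x, y) quantity(x$value - y$value, quad_se(x$se, y$se))
  structure(list(
    label_a = label_a, label_b = label_b, T_ref = a$T,
    ddG = diff_q(a$dGb, b$dGb),
    ddH = diff_q(a$dHb, b$dHb),
    TddS = diff_q(a$TdSb, b$TdSb),
    ddS = diff_q(a$dSb, b$dSb)
  ), class = "delta_delta")
}
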