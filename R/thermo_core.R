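#' Transition-state decomposition of a turnover number
#'
#' Decomposes a turnover number and Arrhenius activation energy into the
#' activation free energy, enthalpy and entropy at a reference temperature,
#' using transition-state theory with transmission coefficient 1:
#' \deqn{\Delta G^\# = RT(\ln(k_B T/h) - \ln k_{cat}),\quad
#'       \Delta H^\# = E_a - RT,\quad
#'       T\Delta S^\# = \Delta H^\# - \Delta G^\#.}
#'
#' Uncertainties are first-order: the standard error of \eqn{\Delta G^\#}
#' is \eqn{RT\,\mathrm{se}(k_{cat})/k_{cat}}, that of \eqn{\Delta H^\#}
#' equals the activation-energy error, and the entropic term combines the
#' two in quadrature (errors assumed uncorrelated).
#'
#' @param kcat Turnover number in s^-1; a [quantity()] or numeric
#'   (optionally `c(value, se)`). Must be positive.
#' @param Ea Arrhenius activation energy in kJ mol^-1 ([quantity()] or
#'   numeric).
#' @param T_ref Reference temperature in K (default 298).
#' @return An object of class `"activation_thermo"`: a list with the
#'   reference temperature `T_ref` and quantities `kcat` (s^-1), `Ea`,
#'   `dG`, `dH`, `TdS` (kJ mol^-1) and `dS` (J mol^-1 K^-1).
#' @examples
#' eyring_decompose(c(228, 15), c(49.1, 1.4))
#' @seealso [delta_delta()], [compensation_curve()]
#' @export
eyring_decompose <- function(kcat, Ea, T_ref = 298) {
  kcat <- as_quantity(kcat)
  Ea <- as_quantity(Ea)
  if (!is.numeric(T_ref) || length(T_ref) != 1L || T_ref <= 0)
    stop("'T_ref' must be a positive temperature in K", call. = FALSE)
  if (kcat$value <= 0)
    stop("'kcat' must be positive", call. = FALSE)

  RT_kJ <- .const$R * T_ref / 1000                    # kJ mol^-1
  dG <- RT_kJ * (log(.const$kB * T_ref / .const$h) - log(kcat$value))
  dH <- Ea$value - RT_kJ
  TdS <- dH - dG

  dG_se <- if (is.na(kcat$se)) NA_real_ else RT_kJ * kcat$se / kcat$value
  TdS_se <- quad_se(Ea$se, dG_se)

  structure(list(
    T_ref = T_ref,
    kcat = kcat,
    Ea = Ea,
    dG = quantity(dG, dG_se),
    dH = quantity(dH, Ea$se),
    TdS = quantity(TdS, TdS_se),
    dS = quantity(1000 * TdS / T_ref,
                  if (is.na(TdS_se)) NA_real_ else 1000 * TdS_se / T_ref)
  ), class = "activation_thermo")
}

#' @export
print.activation_thermo <- function(x, ...) {
  cat("Activation thermodynamics at ", x$T_ref, " K\n", sep = "")
  cat("  kcat : ", format(x$kcat), " s^-1\n", sep = "")
  cat("  Ea   : ", format(x$Ea), " kJ/mol\n", sep = "")
  cat("  dG#  : ", format(x$dG), " kJ/mol\n", sep = "")
  cat("  dH#  : ", format(x$dH), " kJ/mol\n", sep = "")
  cat("  TdS# : ", format(x$TdS), " kJ/mol\n", sep = "")
  cat("  dS#  : ", format(x$dS), " J/mol/K\n", sep = "")
  invisible(x)
}

#' Paired difference of activation thermodynamics
#'
#' Forms the change in activation parameters between two variants measured
#' at the same reference temperature. By convention the first argument is
#' the variant *without* the salt-bridge and the second the variant *with*
#' it, so that e.g. `ddH = a$dH - b$dH` is the change upon removing the
#' bridge. Standard errors combine in quadrature.
#'
#' @param a,b `"activation_thermo"` objects sharing `T_ref`.
#' @param label_a,label_b Optional variant names carried into the result.
#' @return An object of class `"delta_delta"` with quantities `ddG`, `ddH`,
#'   `TddS` (kJ mol^-1) and `ddS` (J mol^-1 K^-1), plus `T_ref` and labels.
#' @examples
#' wt <- eyring_decompose(c(228, 15), c(49.1, 1.4))
#' mut <- eyring_decompose(c(211, 25), c(32.1, 1.7))
#' delta_delta(mut, wt, "PhG91A", "PhWT")
#' @export
delta_delta <- function(a, b, label_a = "a", label_b = "b") {
  stopifnot(inherits(a, "activation_thermo"), inherits(b, "activation_thermo"))
  if (!isTRUE(all.equal(a$T_ref, b$T_ref)))
    stop("reference temperatures differ: ", a$T_ref, " vs ", b$T_ref,
         call. = FALSE)
  diff_q <- function(x, y) quantity(x$value - y$value, quad_se(x$se, y$se))
  structure(list(
    label_a = label_a, label_b = label_b, T_ref = a$T_ref,
    ddG = diff_q(a$dG, b$dG),
    ddH = diff_q(a$dH, b$dH),
    TddS = diff_q(a$TdS, b$TdS),
    ddS = diff_q(a$dS, b$dS)
  ), class = "delta_delta")
}

#' @export
print.delta_delta <- function(x, ...) {
  cat("Paired difference ", x$label_a, " - ", x$label_b,
      " at ", x$T_ref, " K\n", sep = "")
  cat("  ddG  : ", format(x$ddG), " kJ/mol\n", sep = "")
  cat("  ddH  : ", format(x$ddH), " kJ/mol\n", sep = "")
  cat("  TddS : ", format(x$TddS), " kJ/mol\n", sep = "")
  cat("  ddS  : ", format(x$ddS), " J/mol/K\n", sep = "")
  invisible(x)
}

#' Enthalpy-entropy compensation curve
#'
#' Propagates a paired activation difference across temperature assuming
#' temperature-independent \eqn{\Delta\Delta H} and \eqn{\Delta\Delta S}
#' (straight Arrhenius lines): \eqn{\Delta\Delta G(T) = \Delta\Delta H -
#' T\,\Delta\Delta S}. The compensation temperature
#' \eqn{T_c = \Delta\Delta H/\Delta\Delta S} is where the free-energy
#' difference crosses zero, i.e. where the two variants are equally active.
#'
#' @param dd A [delta_delta()] object defined at its `T_ref`.
#' @param T_grid Temperatures (K) at which to evaluate the curve.
#' @return A list with `curve`, a data frame of columns `T`, `ddG`, `ddH`,
#'   `TddS` (kJ mol^-1), and `Tc`, the compensation temperature in K
#'   (`NA` when `ddS` is zero and the lines never cross).
#' @examples
#' wt <- eyring_decompose(c(228, 15), c(49.1, 1.4))
#' mut <- eyring_decompose(c(211, 25), c(32.1, 1.7))
#' compensation_curve(delta_delta(mut, wt))$Tc
#' @export
compensation_curve <- function(dd, T_grid = seq(273, 323, by = 1)) {
  stopifnot(inherits(dd, "delta_delta"))
  ddH <- dd$ddH$value
  ddS <- 1000 * dd$TddS$value / dd$T_ref     # J/mol/K, T-independent
  ddG <- ddH - T_grid * ddS / 1000
  Tc <- if (ddS == 0) NA_real_ else 1000 * ddH / ddS
  list(
    curve = data.frame(T = T_grid, ddG = ddG, ddH = ddH,
                       TddS = T_grid * ddS / 1000),
    Tc = Tc
  )
}

#' Rate fold-change implied by an activation-entropy change
#'
#' At constant activation enthalpy, a change `TddS` (kJ mol^-1) in the
#' entropic term multiplies the turnover number by
#' \eqn{\exp(T\Delta\Delta S^\#/(RT))}. A ~20 kJ mol^-1 entropic advantage
#' at 298 K corresponds to a more than 3000-fold rate increase.
#'
#' @param TddS Entropic term change, kJ mol^-1.
#' @param T Temperature in K.
#' @return The implied kcat ratio (dimensionless).
#' @examples
#' entropic_fold_change(20, 298)  # about 3.2e3
#' @export
entropic_fold_change <- function(TddS, T = 298) {
  if (!is.numeric(T) || any(T <= 0))
    stop("'T' must be positive", call. = FALSE)
  exp(1000 * TddS / (.const$R * T))
}
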