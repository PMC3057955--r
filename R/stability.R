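#' Two-state linear-extrapolation denaturation model
#'
#' Signal of a two-state unfolder in denaturant, with sloped native and
#' unfolded baselines. The unfolded fraction follows the linear
#' extrapolation model \eqn{\Delta G(D) = \Delta G_u - m D}:
#' \deqn{f_U(D) = \frac{e^{-(\Delta G_u - mD)/RT}}{1 + e^{-(\Delta G_u -
#'   mD)/RT}},\qquad y = (1-f_U)(y_N + s_N D) + f_U (y_U + s_U D).}
#'
#' @param D Denaturant concentrations, M.
#' @param dGu Free energy of unfolding in water, kJ mol^-1.
#' @param m m-value, kJ mol^-1 M^-1.
#' @param yN,slope_N Native baseline intercept and slope.
#' @param yU,slope_U Unfolded baseline intercept and slope.
#' @param T Temperature, K.
#' @return Predicted signal, same length as `D`.
#' @examples
#' lem_model(5.30, dGu = 58, m = 10.9)  # near the midpoint
#' @export
lem_model <- function(D, dGu, m, yN = 1, slope_N = 0, yU = 0, slope_U = 0,
                      T = 298) {
  z <- -(dGu - m * D) * 1000 / (.const$R * T)
  fU <- stats::plogis(z)                      # exp(z)/(1+exp(z)), overflow-safe
  (1 - fU) * (yN + slope_N * D) + fU * (yU + slope_U * D)
}

# unfolded fraction alone (used by the fit diagnostics)
.lem_fu <- function(D, dGu, m, T = 298) {
  stats::plogis(-(dGu - m * D) * 1000 / (.const$R * T))
}

#' Fit the two-state linear-extrapolation model to a denaturation curve
#'
#' Six-parameter (dGu, m, two baseline intercepts and slopes) nonlinear
#' least squares by Levenberg-Marquardt. The midpoint is reported as
#' \eqn{C_m = \Delta G_u / m} with its standard error propagated from the
#' full (dGu, m) covariance, including their correlation.
#'
#' Starting values are data-driven: baselines from the curve ends, the
#' midpoint from where the signal crosses halfway, and m from a default
#' cooperative slope. A warning is issued when fewer than 3 points fall
#' in the fitted transition (0.1 < fU < 0.9), where dGu and m are poorly
#' constrained.
#'
#' @param D Denaturant concentrations, M (nonnegative).
#' @param y Observed signal, arbitrary units.
#' @param T Temperature, K.
#' @param m_start Starting m-value, kJ mol^-1 M^-1.
#' @return An object of class `"lem_fit"`: quantities `dGu` (kJ mol^-1),
#'   `m_value` (kJ mol^-1 M^-1) and `Cm` (M); `baselines` (yN, slope_N,
#'   yU, slope_U); `rss`; and the parameter covariance `cov`.
#' @examples
#' D <- seq(0, 7, by = 0.25)
#' fit_lem(D, lem_model(D, 58, 10.9))
#' @export
fit_lem <- function(D, y, T = 298, m_start = 10) {
  D <- as.numeric(D); y <- as.numeric(y)
  stopifnot(length(D) == length(y), length(D) >= 8L)
  if (any(D < 0)) stop("denaturant concentrations must be nonnegative",
                       call. = FALSE)
  o <- order(D); D <- D[o]; y <- y[o]

  k <- max(2L, length(D) %/% 5L)
  yN0 <- mean(y[seq_len(k)])
  yU0 <- mean(y[seq(length(y) - k + 1L, length(y))])
  mid <- (yN0 + yU0) / 2
  Cm0 <- D[which.min(abs(y - mid))]
  if (Cm0 <= 0) Cm0 <- stats::median(D)
  p0 <- c(dGu = m_start * Cm0, m = m_start, yN = yN0, sN = 0, yU = yU0, sU = 0)

  resid_fun <- function(p)
    y - lem_model(D, p[["dGu"]], p[["m"]], p[["yN"]], p[["sN"]],
                  p[["yU"]], p[["sU"]], T = T)
  fit <- minpack.lm::nls.lm(par = p0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info %in% c(0, 9))
    stop("LEM fit did not converge (", fit$message, ")", call. = FALSE)

  p <- fit$par
  sm <- .quiet_summary(fit)
  se <- sm$coefficients[, "Std. Error"]
  # full parameter covariance sigma^2 (J'J)^-1, for the Cm error
  V <- tryCatch({
    Vi <- sm$sigma^2 * solve(fit$hessian)
    dimnames(Vi) <- list(names(p), names(p))
    Vi
  }, error = function(e) NULL)
  Cm <- p[["dGu"]] / p[["m"]]
  Cm_se <- if (!is.null(V)) {
    g <- c(1 / p[["m"]], -p[["dGu"]] / p[["m"]]^2)
    sqrt(drop(t(g) %*% V[c("dGu", "m"), c("dGu", "m")] %*% g))
  } else NA_real_

  fU <- .lem_fu(D, p[["dGu"]], p[["m"]], T = T)
  if (sum(fU > 0.1 & fU < 0.9) < 3L)
    warning("fewer than 3 points inside the unfolding transition; ",
            "dGu and m are poorly constrained", call. = FALSE)

  structure(list(
    dGu = quantity(p[["dGu"]], se[["dGu"]]),
    m_value = quantity(p[["m"]], se[["m"]]),
    Cm = quantity(Cm, Cm_se),
    baselines = c(yN = p[["yN"]], slope_N = p[["sN"]],
                  yU = p[["yU"]], slope_U = p[["sU"]]),
    rss = fit$deviance,
    cov = V,
    T = T,
    fit = fit
  ), class = "lem_fit")
}

#' @export
print.lem_fit <- function(x, ...) {
  cat("Two-state LEM fit at ", x$T, " K\n", sep = "")
  cat("  dGu: ", format(x$dGu), " kJ/mol\n", sep = "")
  cat("  m  : ", format(x$m_value), " kJ/mol/M\n", sep = "")
  cat("  Cm : ", format(x$Cm), " M\n", sep = "")
  invisible(x)
}
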