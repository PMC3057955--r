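#' Fit the Michaelis-Menten equation to initial-rate assay data
#'
#' Nonlinear least-squares fit of \eqn{v = k_{cat} E_0 S/(K_m + S)} to
#' initial rates measured at a single temperature. Enzyme concentrations
#' are supplied in nM and converted internally to mM so that `kcat` comes
#' out in s^-1 when rates are in mM s^-1 and substrate in mM.
#'
#' Starting values are taken from the data: `kcat` from the largest
#' observed rate over its enzyme concentration, `Km` from the substrate
#' concentration nearest half-maximal rate.
#'
#' @param data Data frame with columns `S` (substrate, mM), `v` (initial
#'   rate, mM s^-1) and `E0` (enzyme, nM). Additional columns are ignored.
#' @param T Optional assay temperature in K, stored in the result.
#' @return An object of class `"mm_fit"`: quantities `kcat` (s^-1) and
#'   `Km` (mM), plus `T`, `n_points`, `rss` and the `minpack.lm` fit.
#' @examples
#' S <- c(0.05, 0.1, 0.2, 0.4, 0.7, 1, 1.5, 2)
#' d <- data.frame(S = S, v = 228 * 1e-6 * S / (0.10 + S), E0 = 1)
#' fit_michaelis_menten(d)
#' @export
fit_michaelis_menten <- function(data, T = NA_real_) {
  req <- c("S", "v", "E0")
  if (!all(req %in% names(data)))
    stop("'data' needs columns S, v, E0", call. = FALSE)
  S <- as.numeric(data$S); v <- as.numeric(data$v)
  E0 <- as.numeric(data$E0) * 1e-6                     # nM -> mM
  if (any(S <= 0)) stop("substrate concentrations 'S' must be positive",
                        call. = FALSE)
  if (any(E0 <= 0)) stop("enzyme concentrations 'E0' must be positive",
                         call. = FALSE)
  if (length(unique(S)) < 4L)
    stop("need at least 4 distinct substrate concentrations", call. = FALSE)

  imax <- which.max(v / E0)
  kcat0 <- v[imax] / E0[imax]
  Km0 <- S[which.min(abs(v / E0 - kcat0 / 2))]
  if (Km0 <= 0 || !is.finite(Km0)) Km0 <- stats::median(S)

  fit <- minpack.lm::nlsLM(
    v ~ kcat * E0 * S / (Km + S),
    data = data.frame(S = S, v = v, E0 = E0),
    start = list(kcat = kcat0, Km = Km0),
    lower = c(kcat = 1e-12, Km = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- stats::coef(fit)
  se <- .quiet_summary(fit)$coefficients[, "Std. Error"]
  structure(list(
    kcat = quantity(est[["kcat"]], se[["kcat"]]),
    Km = quantity(est[["Km"]], se[["Km"]]),
    T = T,
    n_points = length(v),
    rss = sum(stats::resid(fit)^2),
    fit = fit
  ), class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten fit",
      if (!is.na(x$T)) paste0(" at ", x$T, " K"), "\n", sep = "")
  cat("  kcat: ", format(x$kcat), " s^-1\n", sep = "")
  cat("  Km  : ", format(x$Km), " mM   (n = ", x$n_points, ")\n", sep = "")
  invisible(x)
}

#' Arrhenius regression of turnover numbers
#'
#' Ordinary least squares of `ln kcat` on `1/T`. The activation energy is
#' `-slope * R` (reported in kJ mol^-1) and the intercept is `ln A`. The
#' regression is unweighted by default; supply `weights` to down-weight
#' noisy temperatures.
#'
#' @param T Temperatures in K (>= 3 values).
#' @param kcat Positive turnover numbers in s^-1, same length as `T`.
#' @param kcat_se Optional per-point standard errors, stored with the
#'   points but not used in the fit unless `weights` is given.
#' @param weights Optional OLS weights on the log scale.
#' @return An object of class `"arrhenius_fit"`: quantities `Ea`
#'   (kJ mol^-1) and `lnA`, the 2x2 covariance `cov` of (intercept, slope)
#'   on the regression scale, the data `points` and `r_squared`.
#' @examples
#' T <- seq(283, 318, by = 5)
#' k <- 228 * exp(-(49.1e3 / 8.31446) * (1 / T - 1 / 298))
#' fit_arrhenius(T, k)
#' @export
fit_arrhenius <- function(T, kcat, kcat_se = NULL, weights = NULL) {
  T <- as.numeric(T); kcat <- as.numeric(kcat)
  if (length(T) != length(kcat))
    stop("'T' and 'kcat' lengths differ", call. = FALSE)
  if (length(T) < 3L)
    stop("need at least 3 temperatures for an Arrhenius fit", call. = FALSE)
  if (any(kcat <= 0)) stop("'kcat' must be positive", call. = FALSE)
  if (any(T <= 0)) stop("'T' must be positive", call. = FALSE)

  x <- 1 / T; y <- log(kcat)
  lmfit <- if (is.null(weights)) stats::lm(y ~ x) else
    stats::lm(y ~ x, weights = weights)
  co <- stats::coef(lmfit)
  V <- .quietly(stats::vcov(lmfit))
  slope_se <- sqrt(V["x", "x"])

  structure(list(
    Ea = quantity(-co[["x"]] * .const$R / 1000, slope_se * .const$R / 1000),
    lnA = quantity(co[["(Intercept)"]], sqrt(V["(Intercept)", "(Intercept)"])),
    cov = V,
    points = data.frame(T = T, kcat = kcat,
                        se = if (is.null(kcat_se)) NA_real_ else kcat_se),
    r_squared = .quiet_summary(lmfit)$r.squared,
    lm = lmfit
  ), class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat("Arrhenius fit (ln kcat vs 1/T), ", nrow(x$points), " points\n",
      sep = "")
  cat("  Ea : ", format(x$Ea), " kJ/mol\n", sep = "")
  cat("  lnA: ", format(x$lnA), "   R^2 = ",
      signif(x$r_squared, 4), "\n", sep = "")
  invisible(x)
}

#' Build an Arrhenius line from a single anchor point
#'
#' Constructs an exact (zero-covariance) `"arrhenius_fit"` from a turnover
#' number at one temperature and an activation energy, for closed-form
#' extrapolation and crossover work when only summary parameters are known.
#'
#' @param kcat_ref Turnover number (s^-1) at `T_ref`.
#' @param Ea Activation energy, kJ mol^-1.
#' @param T_ref Anchor temperature, K.
#' @return An `"arrhenius_fit"` with deterministic coefficients.
#' @examples
#' arrhenius_line(228, 49.1, 298)
#' @export
arrhenius_line <- function(kcat_ref, Ea, T_ref = 298) {
  stopifnot(kcat_ref > 0, T_ref > 0)
  lnA <- log(kcat_ref) + 1000 * Ea / (.const$R * T_ref)
  V <- matrix(0, 2, 2, dimnames = list(c("(Intercept)", "x"),
                                       c("(Intercept)", "x")))
  structure(list(
    Ea = quantity(Ea), lnA = quantity(lnA), cov = V,
    points = data.frame(T = T_ref, kcat = kcat_ref, se = NA_real_),
    r_squared = NA_real_, lm = NULL
  ), class = "arrhenius_fit")
}

#' Extrapolate a turnover number along an Arrhenius line
#'
#' Evaluates \eqn{k_{cat}(T) = \exp(\ln A - E_a/(RT))} with a standard
#' error propagated from the regression covariance of (intercept, slope).
#'
#' @param fit An `"arrhenius_fit"`.
#' @param T Target temperature in K.
#' @return A [quantity()] in s^-1.
#' @examples
#' extrapolate_kcat(arrhenius_line(228, 49.1, 298), 318)  # ~793 s^-1
#' @export
extrapolate_kcat <- function(fit, T) {
  stopifnot(inherits(fit, "arrhenius_fit"))
  if (!is.numeric(T) || length(T) != 1L || T <= 0)
    stop("'T' must be a positive temperature in K", call. = FALSE)
  x <- 1 / T
  lnk <- fit$lnA$value - 1000 * fit$Ea$value / (.const$R * T)
  V <- fit$cov
  var_lnk <- V[1, 1] + x^2 * V[2, 2] + 2 * x * V[1, 2]
  k <- exp(lnk)
  quantity(k, if (var_lnk > 0) k * sqrt(var_lnk) else NA_real_)
}

#' Temperature at which two Arrhenius lines cross
#'
#' Solves \eqn{\ln A_a - E_{a,a}/(RT) = \ln A_b - E_{a,b}/(RT)} for T.
#' Variants with and without the active-site salt-bridge have different
#' slopes, and the crossing temperature marks where the rank order of
#' their activities flips.
#'
#' @param fit_a,fit_b `"arrhenius_fit"` objects.
#' @param tol Relative slope-difference threshold below which the lines
#'   are treated as parallel.
#' @return Crossing temperature in K, or `NA` for parallel lines. The
#'   result is symmetric in its arguments.
#' @examples
#' crossover_temperature(arrhenius_line(228, 49.1), arrhenius_line(211, 32.1))
#' @export
crossover_temperature <- function(fit_a, fit_b, tol = 1e-10) {
  stopifnot(inherits(fit_a, "arrhenius_fit"), inherits(fit_b, "arrhenius_fit"))
  dEa <- fit_a$Ea$value - fit_b$Ea$value
  dlnA <- fit_a$lnA$value - fit_b$lnA$value
  scale <- max(abs(fit_a$Ea$value), abs(fit_b$Ea$value), 1)
  if (abs(dEa) < tol * scale && abs(dlnA) < tol) return(NA_real_)  # same line
  if (abs(dlnA) < tol) return(NA_real_)                            # parallel
  1000 * dEa / (.const$R * dlnA)
}

#' Assemble a kcat(T) series from per-temperature assay data
#'
#' Convenience wrapper: splits an assay table by temperature, fits the
#' Michaelis-Menten model at each, and returns the per-temperature `kcat`
#' and `Km` estimates ready for [fit_arrhenius()].
#'
#' @param data Assay data frame with columns `T`, `S`, `v`, `E0`.
#' @return Data frame with one row per temperature: `T`, `kcat`,
#'   `kcat_se`, `Km`, `Km_se`, `n`.
#' @export
kcat_series <- function(data) {
  stopifnot(all(c("T", "S", "v", "E0") %in% names(data)))
  out <- lapply(split(data, data$T), function(d) {
    f <- fit_michaelis_menten(d, T = d$T[[1L]])
    data.frame(T = d$T[[1L]], kcat = f$kcat$value, kcat_se = f$kcat$se,
               Km = f$Km$value, Km_se = f$Km$se, n = f$n_points)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$T), , drop = FALSE]
}
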