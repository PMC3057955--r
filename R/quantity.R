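#' Physical constants
#'
#' CODATA 2018 values of the gas constant, the Boltzmann constant and the
#' Planck constant, the only physical constants used by the package.
#'
#' @return A named list with elements `R` (gas constant, J mol^-1 K^-1),
#'   `kB` (Boltzmann constant, J K^-1) and `h` (Planck constant, J s).
#' @examples
#' physical_constants()$R  # 8.31446
#' @export
physical_constants <- function() {
  list(R = 8.31446, kB = 1.380649e-23, h = 6.62607015e-34)
}

# internal shorthand; never modified
.const <- list(R = 8.31446, kB = 1.380649e-23, h = 6.62607015e-34)

#' Scalar measurement with a standard error
#'
#' Lightweight container for a measured or derived value together with its
#' one-sigma uncertainty. Units are carried contextually by the field that
#' holds the quantity (e.g. kJ mol^-1 for activation energies).
#'
#' @param value Numeric scalar.
#' @param se Nonnegative standard error, or `NA` when unknown.
#' @return An object of class `"quantity"`: a list with elements `value`
#'   and `se`.
#' @examples
#' quantity(228, 15)
#' @export
quantity <- function(value, se = NA_real_) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("'value' must be a finite numeric scalar", call. = FALSE)
  se <- as.numeric(se)
  if (length(se) != 1L) stop("'se' must be a scalar", call. = FALSE)
  if (!is.na(se) && se < 0) stop("'se' must be nonnegative", call. = FALSE)
  structure(list(value = as.numeric(value), se = se), class = "quantity")
}

#' Coerce to a quantity
#'
#' @param x A `quantity`, or a numeric scalar (taken as a value with
#'   unknown uncertainty), or a length-2 numeric vector `(value, se)`.
#' @return A `quantity`.
#' @export
as_quantity <- function(x) {
  if (inherits(x, "quantity")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(quantity(x[[1L]], x[[2L]]))
  quantity(x)
}

#' @export
format.quantity <- function(x, ..., digits = 4L) {
  v <- signif(x$value, digits)
  if (is.na(x$se)) as.character(v) else
    paste0(v, " ± ", signif(x$se, max(2L, digits - 2L)))
}

#' @export
print.quantity <- function(x, ...) {
  cat("<quantity> ", format(x, ...), "\n", sep = "")
  invisible(x)
}

# value / se extractors tolerant of plain numerics
q_val <- function(x) if (inherits(x, "quantity")) x$value else as.numeric(x)
q_se <- function(x) if (inherits(x, "quantity")) x$se else NA_real_

# first-order, uncorrelated error combination
quad_se <- function(...) {
  ses <- c(...)
  if (any(is.na(ses))) return(NA_real_)
  sqrt(sum(ses^2))
}

# evaluate a fit-summary expression, muffling the advisory emitted when
# the residuals are numerically zero (routine for noiseless synthetic data)
.quietly <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}
.quiet_summary <- function(fit) .quietly(summary(fit))
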