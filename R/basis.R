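#' Legendre basis over the parity gradient
#'
#' Defines the polynomial basis used for the fixed and random regressions on
#' parity (lactation number). Parity is linearly rescaled to `x` in
#' \eqn{[-1, 1]} via `x = 2 (t - t_min) / (t_max - t_min) - 1`, and the basis
#' functions are the (optionally normalized) Legendre polynomials of order 0
#' and 1: with normalization \eqn{\phi_0 = \sqrt{1/2}},
#' \eqn{\phi_1 = \sqrt{3/2}\,x}; without, \eqn{(1, x)}.
#'
#' @param t_min,t_max Integer parity bounds of the trajectory (e.g. 0 and 6
#'   for a trait recorded from the heifer insemination onwards, 1 and 6 for
#'   cow-only traits).
#' @param normalized Use the orthonormal scaling (default) or the raw
#'   `(1, x)` polynomials.
#' @param order Polynomial order: 1 (intercept + slope, the default) or 0
#'   (intercept only, useful for single-parity reductions).
#' @return An object of class `rr_basis`.
#' @examples
#' b <- legendre_basis(1, 6)
#' eval_basis(b, c(1, 3.5, 6))
#' @export
legendre_basis <- function(t_min, t_max, normalized = TRUE, order = 1) {
  if (order == 1 && !(t_min < t_max)) {
    abort("`t_min` must be strictly less than `t_max` for a slope basis.")
  }
  if (!order %in% c(0, 1)) abort("`order` must be 0 or 1.")
  structure(
    list(t_min = t_min, t_max = t_max, normalized = isTRUE(normalized),
         order = order),
    class = "rr_basis"
  )
}

#' Evaluate a Legendre basis at given parities
#'
#' @param basis An [legendre_basis()] object.
#' @param parity Numeric vector of parities; must lie within
#'   `[t_min, t_max]`.
#' @return A numeric matrix with one row per parity and `order + 1` columns
#'   (`phi0`, and `phi1` for order-1 bases).
#' @export
eval_basis <- function(basis, parity) {
  stopifnot(inherits(basis, "rr_basis"))
  if (any(parity < basis$t_min | parity > basis$t_max)) {
    abort(sprintf("parity outside basis range [%s, %s]",
                  basis$t_min, basis$t_max))
  }
  if (basis$order == 0) {
    phi <- matrix(if (basis$normalized) sqrt(1 / 2) else 1,
                  nrow = length(parity), ncol = 1)
    colnames(phi) <- "phi0"
    return(phi)
  }
  x <- 2 * (parity - basis$t_min) / (basis$t_max - basis$t_min) - 1
  phi <- if (basis$normalized) {
    cbind(phi0 = rep(sqrt(1 / 2), length(x)), phi1 = sqrt(3 / 2) * x)
  } else {
    cbind(phi0 = rep(1, length(x)), phi1 = x)
  }
  phi
}

#' @export
print.rr_basis <- function(x, ...) {
  cat(sprintf("<rr_basis> order %d, parity %s..%s, %s\n", x$order,
              x$t_min, x$t_max,
              if (x$normalized) "normalized" else "raw (1, x)"))
  invisible(x)
}

n_coef <- function(basis) basis$order + 1L
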