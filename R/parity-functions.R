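#' Heritability and genetic-correlation functions across parities
#'
#' From fitted (or true) covariance components, computes the additive
#' genetic variance `var_a(t) = phi(t)' G_a phi(t)`, the analogous
#' permanent-environment variance, the heritability
#' `h2(t) = var_a(t) / (var_a(t) + var_p(t) + var_s + var_e)` and the
#' genetic correlation between parities
#' `r_g(t, t') = phi(t)' G_a phi(t') / sqrt(var_a(t) var_a(t'))`.
#'
#' @param vc An `rr_reml` fit, or a list with `G_a`, `P_pe`, `var_s`,
#'   `var_e`.
#' @param basis Basis used to evaluate the trajectories; defaults to the
#'   fit's own basis.
#' @param parities Parities at which to evaluate; defaults to the integer
#'   parities of the basis range.
#' @return A list of class `rr_parity_fns`: `h2` (tibble with `parity`,
#'   `var_a`, `var_p`, `h2`, and `h2_se` when the fit carries a parameter
#'   covariance for delta-method propagation) and `genetic_correlation`
#'   (matrix; unit diagonal; `NA` where `var_a(t) = 0`).
#' @export
parity_functions <- function(vc, basis = NULL, parities = NULL) {
  basis <- basis %||% vc$basis
  if (is.null(basis)) abort("a `basis` is required.")
  parities <- parities %||% seq(basis$t_min, basis$t_max)
  Phi <- eval_basis(basis, parities)
  var_a <- rowSums((Phi %*% vc$G_a) * Phi)
  var_p <- rowSums((Phi %*% vc$P_pe) * Phi)
  var_s <- vc$var_s %||% 0
  denom <- var_a + var_p + var_s + vc$var_e
  h2 <- var_a / denom

  Cg <- Phi %*% vc$G_a %*% t(Phi)
  sdv <- sqrt(var_a)
  rg <- Cg / outer(sdv, sdv)
  rg[var_a == 0, ] <- NA_real_
  rg[, var_a == 0] <- NA_real_
  diag(rg)[var_a > 0] <- 1
  dimnames(rg) <- list(parities, parities)

  h2_se <- rep(NA_real_, length(parities))
  if (!is.null(vc$cov_params) && inherits(vc, "rr_reml")) {
    h2_se <- h2_delta_se(vc, Phi)
  }

  structure(
    list(h2 = tibble(parity = parities, var_a = var_a, var_p = var_p,
                     h2 = h2, h2_se = h2_se),
         genetic_correlation = rg),
    class = "rr_parity_fns"
  )
}

#' @export
print.rr_parity_fns <- function(x, ...) {
  cat("<rr_parity_fns>\n")
  print(as.data.frame(x$h2), row.names = FALSE, digits = 4)
  cat("genetic correlations:\n")
  print(round(x$genetic_correlation, 3))
  invisible(x)
}

## delta-method SE of h2(t) through the raw-parameter covariance
h2_delta_se <- function(vc, Phi) {
  nm <- colnames(vc$cov_params)
  theta <- c(var_a1 = vc$G_a[1, 1],
             cov_a = if (ncol(vc$G_a) > 1) vc$G_a[1, 2] else NULL,
             var_a2 = if (ncol(vc$G_a) > 1) vc$G_a[2, 2] else NULL,
             var_p1 = vc$P_pe[1, 1],
             cov_p = if (ncol(vc$P_pe) > 1) vc$P_pe[1, 2] else NULL,
             var_p2 = if (ncol(vc$P_pe) > 1) vc$P_pe[2, 2] else NULL,
             var_s = vc$var_s, var_e = vc$var_e)
  theta <- theta[nm]
  h2_of <- function(th, phi) {
    nc <- ncol(Phi)
    G <- matrix(0, nc, nc); P <- matrix(0, nc, nc)
    G[1, 1] <- th["var_a1"]; P[1, 1] <- th["var_p1"]
    if (nc > 1) {
      G[1, 2] <- G[2, 1] <- th["cov_a"]; G[2, 2] <- th["var_a2"]
      P[1, 2] <- P[2, 1] <- th["cov_p"]; P[2, 2] <- th["var_p2"]
    }
    va <- drop(phi %*% G %*% phi)
    vp <- drop(phi %*% P %*% phi)
    vs <- if ("var_s" %in% names(th)) th["var_s"] else 0
    unname(va / (va + vp + vs + th["var_e"]))
  }
  vapply(seq_len(nrow(Phi)), function(i) {
    phi <- Phi[i, ]
    grad <- vapply(seq_along(theta), function(j) {
      h <- max(abs(theta[j]) * 1e-5, 1e-10)
      tp <- theta; tp[j] <- tp[j] + h
      tm <- theta; tm[j] <- tm[j] - h
      (h2_of(tp, phi) - h2_of(tm, phi)) / (2 * h)
    }, 0)
    sqrt(max(drop(t(grad) %*% vc$cov_params %*% grad), 0))
  }, 0)
}
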