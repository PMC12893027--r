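#' Tidy a REML fit into the standard component layout
#'
#' One row per (co)variance component (`var_a1`, `cov_a`, `var_a2`,
#' `var_p1`, `cov_p`, `var_p2`, `var_s`, `var_e`) with asymptotic standard
#' errors when available.
#'
#' @param x An `rr_reml` object.
#' @param ... Unused.
#' @return A tibble with columns `component`, `estimate`, `std_error`.
#' @method tidy rr_reml
#' @export
tidy.rr_reml <- function(x, ...) {
  nc <- ncol(x$G_a)
  est <- c(sym_vec(x$G_a),
           if (x$spec$include_pe) sym_vec(x$P_pe),
           if (x$n_sires) x$var_s,
           x$var_e)
  nm <- param_names(nc, x$spec$include_pe, x$n_sires)
  se <- if (!is.null(x$se)) unname(x$se[nm]) else rep(NA_real_, length(nm))
  tibble(component = nm, estimate = unname(est), std_error = se)
}

#' One-line model summary of a REML fit
#'
#' @param x An `rr_reml` object.
#' @param ... Unused.
#' @return A one-row tibble: `loglik`, `converged`, `n_iter`, `n_records`,
#'   `n_animals`, `trait`.
#' @method glance rr_reml
#' @export
glance.rr_reml <- function(x, ...) {
  tibble(loglik = x$loglik, converged = x$converged, n_iter = x$n_iter,
         n_records = x$n_records, n_animals = x$n_animals,
         trait = x$spec$trait)
}

#' Tidy a GWAS result (already tabular; returns its tibble)
#'
#' @param x An `rr_gwas` object.
#' @param ... Unused.
#' @method tidy rr_gwas
#' @export
tidy.rr_gwas <- function(x, ...) {
  as_tibble(x)
}

#' Scan-level summary of a GWAS result
#'
#' @param x An `rr_gwas` object.
#' @param ... Unused.
#' @return A one-row tibble with SNP counts and the genomic inflation
#'   factor per layer.
#' @method glance rr_gwas
#' @export
glance.rr_gwas <- function(x, ...) {
  s <- gwas_summaries(x)
  tibble(n_snps = nrow(x),
         n_tested = sum(!is.na(x$p_joint)),
         lambda_intercept = s$lambda_per_layer[["intercept"]],
         lambda_slope = s$lambda_per_layer[["slope"]],
         lambda_joint = s$lambda_per_layer[["joint"]],
         r_intercept_slope = s$r_intercept_slope)
}
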