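#' Options for the REML fit
#'
#' @param max_iter Maximum number of iterations.
#' @param tol_loglik Convergence tolerance on the restricted log-likelihood
#'   change.
#' @param tol_param Convergence tolerance on the maximum relative parameter
#'   change.
#' @param n_em Number of initial expectation-maximization iterations before
#'   switching to average-information updates.
#' @param step_halvings Maximum halvings of a rejected AI step before
#'   falling back to an EM update.
#' @param freeze_tol Variance components that collapse below this fraction
#'   of the phenotypic variance are frozen at their current value (their
#'   updates stop), which avoids an indefinite expectation-maximization
#'   creep toward a zero boundary.
#' @param ridge Optional ridge added to the relationship diagonal (fraction
#'   of its mean diagonal) for near-singular matrices.
#' @param verbose Print per-iteration progress?
#' @export
reml_options <- function(max_iter = 200, tol_loglik = 1e-6, tol_param = 1e-5,
                         n_em = 2, step_halvings = 8, ridge = 0,
                         freeze_tol = 1e-5, verbose = FALSE) {
  structure(as.list(environment()), class = "rr_reml_options")
}

#' REML estimation of random-regression (co)variance components
#'
#' Maximizes the restricted likelihood of the single-trait random-regression
#' model over the additive-genetic coefficient covariance `G_a`, the
#' permanent-environment coefficient covariance `P_pe`, the service-sire
#' variance and the residual variance. Updates are average-information (AI)
#' steps on a log-Cholesky parameterization (which keeps the 2x2 blocks
#' positive semi-definite by construction), with step halving and an
#' expectation-maximization fallback whenever an AI step would decrease the
#' restricted log-likelihood; accepted iterations therefore never decrease
#' it. The likelihood is evaluated through dense mixed-model equations in
#' which the permanent-environment effect is absorbed into a per-animal
#' block-diagonal residual covariance, an exactly equivalent formulation
#' that keeps the system at (fixed effects + 2 x animals + sires) order.
#'
#' @param phenotypes Phenotype tibble (`animal_id`, `trait`, `parity`,
#'   `value`, fixed-effect factors, `service_sire_id`).
#' @param relationship Relationship matrix (A, G or H) covering all
#'   phenotyped animals; `NULL` fits an identity relationship.
#' @param spec An [rr_model_spec()].
#' @param options An [reml_options()] list.
#' @param start Optional list with starting values (`G_a`, `P_pe`, `var_s`,
#'   `var_e`); defaults split the phenotypic variance 10/10/5/75% over
#'   genetic, permanent-environment, service-sire and residual parts.
#' @return An object of class `rr_reml` with components `G_a`, `P_pe`,
#'   `var_s`, `var_e`, `loglik`, `loglik_trace`, `converged`, `n_iter`,
#'   `se` (asymptotic standard errors from the inverse AI matrix) and
#'   bookkeeping fields. Non-convergence within `max_iter` is flagged via
#'   `converged = FALSE` and a warning, never silently.
#' @seealso [parity_functions()], [tidy.rr_reml()]
#' @export
reml_rrm <- function(phenotypes, relationship, spec,
                     options = reml_options(), start = NULL) {
  des <- rr_design(phenotypes, spec, relationship)
  nc <- des$nc
  n <- des$n_anim
  ns <- if (spec$service_sire) length(des$sire_levels) else 0L
  use_pe <- spec$include_pe

  ## relationship over the phenotyped animals (marginalizing unphenotyped
  ## relatives out of a MVN prior is exact)
  if (is.null(relationship)) {
    K <- diag(n)
    dimnames(K) <- list(des$animals, des$animals)
  } else {
    K <- relationship[des$animals, des$animals]
  }
  if (options$ridge > 0) {
    diag(K) <- diag(K) + options$ridge * mean(diag(K))
  }
  cK <- tryCatch(chol(K), error = function(e) {
    abort("relationship matrix is not positive definite over the phenotyped animals; consider `ridge`.")
  })
  Kinv <- chol2inv(cK)
  logdetK <- 2 * sum(log(diag(cK)))

  eng <- reml_engine(des, Kinv, logdetK, ns, use_pe)

  ## starting values
  vy <- var(des$y)
  mphi2 <- colMeans(des$phi_rec^2)
  if (is.null(start)) start <- list()
  G0 <- start$G_a %||% diag(c(0.10, 0.05)[seq_len(nc)] * vy / mphi2, nc)
  P0 <- if (use_pe) {
    start$P_pe %||% diag(c(0.10, 0.05)[seq_len(nc)] * vy / mphi2, nc)
  } else {
    NULL
  }
  sigs <- if (ns) start$var_s %||% (0.05 * vy) else NULL
  sige <- start$var_e %||% (0.75 * vy)
  eta <- par_pack(G0, P0, sigs, sige, nc)

  state <- eng$evaluate(eta)
  trace <- state$loglik
  converged <- FALSE
  iter <- 0L
  frozen <- rep(FALSE, length(eta))
  prev_step <- NULL
  repeat {
    iter <- iter + 1L
    if (iter > options$max_iter) break
    full <- eng$derivatives(state)
    frozen <- frozen | frozen_params(state$eta, nc, use_pe, ns,
                                     options$freeze_tol * vy)
    active <- which(!frozen)
    proposal <- NULL
    if (iter > options$n_em && length(active)) {
      AIa <- full$AI_eta[active, active, drop = FALSE]
      mdiag <- mean(diag(AIa))
      for (damp in c(1e-8, 1e-4, 1e-2) * mdiag) {
        stepa <- tryCatch(
          solve(AIa + diag(damp, nrow(AIa)), full$score_eta[active]),
          error = function(e) NULL)
        if (is.null(stepa)) next
        step <- numeric(length(eta))
        step[active] <- stepa
        ## damp period-2 oscillation along soft likelihood ridges
        fac <- 1
        if (!is.null(prev_step)) {
          cs <- sum(step * prev_step) /
            sqrt(sum(step^2) * sum(prev_step^2) + 1e-300)
          if (is.finite(cs) && cs < -0.3) fac <- 0.5
        }
        for (h in seq_len(min(4, options$step_halvings))) {
          cand <- state$eta + fac * step
          cand_state <- tryCatch(eng$evaluate(cand), error = function(e) NULL)
          if (!is.null(cand_state) && is.finite(cand_state$loglik) &&
              cand_state$loglik >= state$loglik - 1e-8) {
            proposal <- cand_state
            prev_step <- fac * step
            break
          }
          fac <- fac / 2
        }
        if (!is.null(proposal)) break
      }
    }
    step_kind <- if (!is.null(proposal)) "AI" else "EM"
    if (is.null(proposal)) {
      cand <- eng$em_update(full)
      cand[frozen] <- state$eta[frozen]
      proposal <- eng$evaluate(cand)
      if (!is.finite(proposal$loglik)) {
        abort("REML likelihood became non-finite; check the inputs for degenerate structure.")
      }
      if (proposal$loglik < state$loglik - 1e-8) {
        ## EM with frozen coordinates can stall; keep the better state
        proposal <- state
        converged <- TRUE
      }
    }
    dll <- proposal$loglik - state$loglik
    old_par <- par_unpack_vec(state$eta, nc, use_pe, ns)
    new_par <- par_unpack_vec(proposal$eta, nc, use_pe, ns)
    ## components that have collapsed to < 1e-4 of the phenotypic variance
    ## no longer gate convergence on their relative change
    relpar <- max(abs(new_par - old_par) / pmax(abs(old_par), 1e-4 * vy))
    if (options$verbose) {
      inform(sprintf("iter %3d [%s] loglik %.6f (delta %.3g) par %s", iter,
                     step_kind, proposal$loglik, dll,
                     paste(signif(new_par, 3), collapse = " ")))
    }
    state <- proposal
    trace <- c(trace, state$loglik)
    if (abs(dll) < options$tol_loglik && relpar < options$tol_param) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("REML did not converge in %d iterations; returning flagged estimates.",
                 options$max_iter))
  }

  full <- eng$derivatives(state)
  pars <- par_unpack(state$eta, nc, use_pe, ns)
  cov_raw <- tryCatch(solve(full$AI_raw), error = function(e) NULL)
  se <- if (!is.null(cov_raw)) sqrt(pmax(diag(cov_raw), 0)) else NULL
  nm <- param_names(nc, use_pe, ns)
  if (!is.null(se)) names(se) <- nm
  if (!is.null(cov_raw)) dimnames(cov_raw) <- list(nm, nm)

  coef_names <- c("intercept", "slope")[seq_len(nc)]
  dimnames(pars$G0) <- list(coef_names, coef_names)
  if (use_pe) dimnames(pars$P0) <- list(coef_names, coef_names)
  structure(
    list(G_a = pars$G0,
         P_pe = if (use_pe) pars$P0 else matrix(0, nc, nc,
                                                dimnames = list(coef_names, coef_names)),
         var_s = if (ns) pars$sigs else 0,
         var_e = pars$sige,
         loglik = state$loglik, loglik_trace = trace,
         converged = converged, n_iter = iter,
         se = se, cov_params = cov_raw,
         basis = des$basis, spec = spec,
         n_records = des$n_rec, n_animals = n, n_sires = ns),
    class = "rr_reml"
  )
}

#' @export
print.rr_reml <- function(x, ...) {
  cat(sprintf("<rr_reml> %s: %d records, %d animals%s\n", x$spec$trait,
              x$n_records, x$n_animals,
              if (x$n_sires) sprintf(", %d service sires", x$n_sires) else ""))
  cat(sprintf("  loglik %.4f after %d iterations (%s)\n", x$loglik, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  print(as.data.frame(tidy(x)), row.names = FALSE, digits = 4)
  invisible(x)
}

## eta indices whose component has collapsed below `thresh` (absolute,
## on the variance scale); they stop being updated
frozen_params <- function(eta, nc, use_pe, ns, thresh) {
  p <- par_unpack(eta, nc, use_pe, ns)
  ng <- nc * (nc + 1) / 2
  block_frz <- function(M) {
    if (nc == 1) return(M[1, 1] < thresh)
    g1 <- M[1, 1] < thresh
    g2 <- M[2, 2] < thresh
    if (g1 && g2) c(TRUE, TRUE, TRUE)
    else if (g2) c(FALSE, TRUE, TRUE)
    else if (g1) c(TRUE, TRUE, FALSE)
    else c(FALSE, FALSE, FALSE)
  }
  frz <- block_frz(p$G0)
  if (use_pe) frz <- c(frz, block_frz(p$P0))
  if (ns) frz <- c(frz, p$sigs < thresh)
  c(frz, p$sige < thresh)
}

param_names <- function(nc, use_pe, ns) {
  g <- if (nc == 2) c("var_a1", "cov_a", "var_a2") else "var_a1"
  p <- if (use_pe) {
    if (nc == 2) c("var_p1", "cov_p", "var_p2") else "var_p1"
  } else {
    character()
  }
  c(g, p, if (ns) "var_s" else character(), "var_e")
}

## --- log-Cholesky packing -------------------------------------------------

chol_to_eta <- function(M) {
  if (nrow(M) == 1) return(0.5 * log(M[1, 1]))
  L <- t(chol(M + diag(1e-12 * max(diag(M), 1e-300), nrow(M))))
  c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
}

eta_to_mat <- function(eta) {
  if (length(eta) == 1) return(matrix(exp(2 * eta), 1, 1))
  L <- matrix(c(exp(eta[1]), eta[2], 0, exp(eta[3])), 2, 2)
  tcrossprod(L)
}

par_pack <- function(G0, P0, sigs, sige, nc) {
  c(chol_to_eta(G0),
    if (!is.null(P0)) chol_to_eta(P0),
    if (!is.null(sigs)) 0.5 * log(max(sigs, 1e-12)),
    0.5 * log(sige))
}

par_unpack <- function(eta, nc, use_pe, ns) {
  ng <- nc * (nc + 1) / 2
  off <- 0
  G0 <- eta_to_mat(eta[off + seq_len(ng)]); off <- off + ng
  P0 <- NULL
  if (use_pe) { P0 <- eta_to_mat(eta[off + seq_len(ng)]); off <- off + ng }
  sigs <- NULL
  if (ns) { sigs <- exp(2 * eta[off + 1]); off <- off + 1 }
  sige <- exp(2 * eta[off + 1])
  list(G0 = G0, P0 = P0, sigs = sigs, sige = sige)
}

par_unpack_vec <- function(eta, nc, use_pe, ns) {
  p <- par_unpack(eta, nc, use_pe, ns)
  c(sym_vec(p$G0), if (use_pe) sym_vec(p$P0), p$sigs, p$sige)
}

sym_vec <- function(M) {
  if (nrow(M) == 1) return(M[1, 1])
  c(M[1, 1], M[1, 2], M[2, 2])
}

## Jacobian d(raw)/d(eta) for one log-Cholesky block.
chol_block_jac <- function(eta) {
  if (length(eta) == 1) {
    return(matrix(2 * exp(2 * eta), 1, 1))
  }
  l11 <- exp(eta[1]); l21 <- eta[2]; l22 <- exp(eta[3])
  ## rows: g11, g12, g22; cols: eta1, eta2, eta3
  matrix(c(2 * l11^2, 0, 0,
           l11 * l21, l11, 0,
           0, 2 * l21, 2 * l22^2),
         3, 3, byrow = TRUE)
}

sym_basis <- function(nc) {
  if (nc == 1) return(list(matrix(1, 1, 1)))
  list(matrix(c(1, 0, 0, 0), 2, 2),
       matrix(c(0, 1, 1, 0), 2, 2),
       matrix(c(0, 0, 0, 1), 2, 2))
}
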