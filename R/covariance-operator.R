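#' Phenotypic covariance operator for the longitudinal GWAS
#'
#' Builds a factorization of the record covariance
#' `V = Q (K x G_a) Q' + Z (I x P_pe) Z' + S S' var_s + I var_e`
#' with the step-1 components held fixed. Two modes:
#'
#' * `direct` — a dense Cholesky of `V`, computed once and reused across
#'   SNPs; works for any record pattern.
#' * `eigen` — requires every analyzed animal to carry the identical parity
#'   set (a balanced design). The relationship `K = U D U'` is
#'   eigen-decomposed and records are rotated animal-wise by `U'`, turning
#'   the genetic plus residual part block-diagonal with per-animal blocks
#'   `d_i Phi G_a Phi' + Phi P_pe Phi' + var_e I`; the service-sire term is
#'   handled as a low-rank Woodbury correction on those blocks.
#'
#' Fixed-effect and SNP covariates must be passed through `transform()`
#' before `vsolve()` so both modes expose identical generalized least
#' squares inner products.
#'
#' @param phenotypes Phenotype tibble restricted to the analyzed animals.
#' @param vc Variance components (an `rr_reml` fit or a compatible list).
#' @param relationship Relationship matrix covering the analyzed animals.
#' @param spec An [rr_model_spec()].
#' @param mode `"direct"` or `"eigen"`.
#' @return An object of class `rr_covop`.
#' @export
assemble_covariance <- function(phenotypes, vc, relationship, spec,
                                mode = c("direct", "eigen")) {
  mode <- match.arg(mode)
  des <- rr_design(phenotypes, spec, relationship)
  covop_build(des, vc, relationship, spec, mode)
}

covop_build <- function(des, vc, relationship, spec, mode) {
  nc <- des$nc
  n <- des$n_anim
  if (is.null(relationship)) {
    K <- diag(n); dimnames(K) <- list(des$animals, des$animals)
  } else {
    K <- relationship[des$animals, des$animals]
  }
  G0 <- unname(vc$G_a)
  P0 <- if (spec$include_pe) unname(vc$P_pe) else matrix(0, nc, nc)
  sigs <- if (spec$service_sire) vc$var_s else 0
  sige <- vc$var_e
  ns <- if (spec$service_sire) length(des$sire_levels) else 0L
  phi <- des$phi_rec
  N <- des$n_rec

  if (mode == "direct") {
    same_anim <- outer(des$anim_idx, des$anim_idx, "==")
    V <- (phi %*% G0 %*% t(phi)) * K[des$anim_idx, des$anim_idx] +
      (phi %*% P0 %*% t(phi)) * same_anim +
      diag(sige, N)
    if (ns) {
      V <- V + sigs * outer(des$sire_idx, des$sire_idx, "==")
    }
    cV <- chol(V)
    op <- list(
      mode = "direct",
      transform = function(M) as.matrix(M),
      vsolve = function(M) {
        backsolve(cV, backsolve(cV, as.matrix(M), transpose = TRUE))
      },
      vmul = function(M) V %*% as.matrix(M),
      logdet = 2 * sum(log(diag(cV)))
    )
  } else {
    if (length(des$groups) != 1) {
      abort(paste("eigen mode requires a balanced design (identical parity",
                  "set for every animal); use mode = \"direct\"."),
            class = "rrgwas_unbalanced")
    }
    g <- des$groups[[1]]
    m <- g$m
    Phi <- g$Phi
    ed <- eigen(K, symmetric = TRUE)
    U <- ed$vectors
    lam <- ed$values
    GP <- Phi %*% G0 %*% t(Phi)
    PP <- Phi %*% P0 %*% t(Phi) + diag(sige, m)
    Binv <- array(0, c(m, m, n))
    logdet <- 0
    for (j in seq_len(n)) {
      Bj <- lam[j] * GP + PP
      cB <- chol(Bj)
      Binv[, , j] <- chol2inv(cB)
      logdet <- logdet + 2 * sum(log(diag(cB)))
    }
    rotate <- function(M, Umat) {
      M <- as.matrix(M)
      Karr <- ncol(M)
      A <- array(M, c(m, n, Karr))
      Am <- matrix(aperm(A, c(2, 1, 3)), n, m * Karr)
      Bm <- crossprod(Umat, Am)
      Barr <- array(Bm, c(n, m, Karr))
      matrix(aperm(Barr, c(2, 1, 3)), n * m, Karr)
    }
    bsolve <- function(M) {
      M <- as.matrix(M)
      Karr <- ncol(M)
      A <- array(M, c(m, n, Karr))
      out <- array(0, c(m, n, Karr))
      for (r1 in seq_len(m)) {
        for (r2 in seq_len(m)) {
          out[r1, , ] <- out[r1, , ] + Binv[r1, r2, ] * A[r2, , ]
        }
      }
      matrix(out, n * m, Karr)
    }
    cap_chol <- NULL
    Srot <- NULL
    if (ns) {
      S <- matrix(0, N, ns)
      S[cbind(seq_len(N), des$sire_idx)] <- 1
      Srot <- rotate(S, U)
      BiS <- bsolve(Srot)
      cap <- diag(1 / sigs, ns) + crossprod(Srot, BiS)
      cap_chol <- chol(cap)
      logdet <- logdet + 2 * sum(log(diag(cap_chol))) + ns * log(sigs)
    }
    op <- list(
      mode = "eigen",
      transform = function(M) rotate(M, U),
      vsolve = function(M) {
        g1 <- bsolve(M)
        if (ns) {
          w <- crossprod(Srot, g1)
          z <- backsolve(cap_chol, backsolve(cap_chol, w, transpose = TRUE))
          g1 <- g1 - bsolve(Srot %*% z)
        }
        g1
      },
      vmul = function(M) {
        M <- as.matrix(M)
        Karr <- ncol(M)
        A <- array(M, c(m, n, Karr))
        out <- array(0, c(m, n, Karr))
        for (r1 in seq_len(m)) {
          for (r2 in seq_len(m)) {
            Bvals <- lam * GP[r1, r2] + PP[r1, r2]
            out[r1, , ] <- out[r1, , ] + Bvals * A[r2, , ]
          }
        }
        out <- matrix(out, n * m, Karr)
        if (ns) out <- out + sigs * (Srot %*% crossprod(Srot, M))
        out
      },
      logdet = logdet
    )
  }
  op$rec <- des$rec[, c("animal_id", "parity")]
  op$animals <- des$animals
  op$anim_idx <- des$anim_idx
  op$phi_rec <- phi
  op$X <- des$X
  op$y <- des$y
  op$n_rec <- N
  op$basis <- des$basis
  op$vc <- list(G_a = G0, P_pe = P0, var_s = sigs, var_e = sige)
  class(op) <- "rr_covop"
  op
}

#' @export
print.rr_covop <- function(x, ...) {
  cat(sprintf("<rr_covop> mode %s, %d records, %d animals\n",
              x$mode, x$n_rec, length(x$animals)))
  invisible(x)
}
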