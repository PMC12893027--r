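## Independent oracles used across tests. These deliberately avoid the
## package's MME/operator code paths: dense covariance matrices are
## assembled brute-force from the model definition.

## Dense record covariance assembled directly from the generative model.
dense_v <- function(phenotypes, vc, relationship, spec) {
  des <- rrgwas:::rr_design(phenotypes, spec, relationship)
  K <- if (is.null(relationship)) {
    diag(des$n_anim)
  } else {
    relationship[des$animals, des$animals]
  }
  phi <- des$phi_rec
  same <- outer(des$anim_idx, des$anim_idx, "==")
  V <- (phi %*% vc$G_a %*% t(phi)) * K[des$anim_idx, des$anim_idx] +
    diag(vc$var_e, des$n_rec)
  if (spec$include_pe) {
    V <- V + (phi %*% vc$P_pe %*% t(phi)) * same
  }
  if (spec$service_sire) {
    V <- V + vc$var_s * outer(des$sire_idx, des$sire_idx, "==")
  }
  list(V = V, des = des)
}

## Restricted log-likelihood through the direct dense-V route.
direct_reml_loglik <- function(vc, phenotypes, relationship, spec) {
  dv <- dense_v(phenotypes, vc, relationship, spec)
  V <- dv$V
  X <- dv$des$X
  y <- dv$des$y
  cV <- chol(V)
  ViX <- backsolve(cV, backsolve(cV, X, transpose = TRUE))
  Viy <- backsolve(cV, backsolve(cV, y, transpose = TRUE))
  XtViX <- crossprod(X, ViX)
  beta <- solve(XtViX, crossprod(X, Viy))
  yPy <- sum(y * Viy) - sum(crossprod(X, Viy) * beta)
  -0.5 * (2 * sum(log(diag(cV))) +
            as.numeric(determinant(XtViX)$modulus) + yPy +
            (length(y) - ncol(X)) * log(2 * pi))
}

## Plain single-trait animal-model REML (y = Xb + u + e, u ~ N(0, A s2a))
## by 1-D profile optimization over the variance ratio on the eigenbasis
## of A. Independent of the package's MME machinery.
animal_model_reml <- function(y, X, A) {
  n <- length(y)
  ed <- eigen(A, symmetric = TRUE)
  profile_m2l <- function(log_gamma) {
    gamma <- exp(log_gamma)            # s2a / s2e
    d <- gamma * ed$values + 1
    U <- ed$vectors
    yt <- crossprod(U, y)
    Xt <- crossprod(U, X)
    w <- 1 / d
    XtWX <- crossprod(Xt, Xt * w)
    XtWy <- crossprod(Xt, yt * w)
    beta <- solve(XtWX, XtWy)
    rss <- sum(yt^2 * w) - sum(XtWy * beta)
    p <- ncol(X)
    s2e <- rss / (n - p)
    sum(log(d)) + as.numeric(determinant(XtWX)$modulus) +
      (n - p) * log(s2e)
  }
  opt <- stats::optimize(profile_m2l, c(-12, 8))
  gamma <- exp(opt$minimum)
  d <- gamma * ed$values + 1
  U <- ed$vectors
  yt <- crossprod(U, y); Xt <- crossprod(U, X)
  w <- 1 / d
  XtWX <- crossprod(Xt, Xt * w)
  XtWy <- crossprod(Xt, yt * w)
  beta <- solve(XtWX, XtWy)
  rss <- sum(yt^2 * w) - sum(XtWy * beta)
  s2e <- rss / (n - ncol(X))
  list(var_a = gamma * s2e, var_e = s2e)
}

## Small standard datasets reused across GWAS tests.
make_balanced_sim <- function(n_founders = 30, n_generations = 1,
                              trait = "DO", seed = 1,
                              with_sire = TRUE, n_service_sires = 8,
                              G_a = matrix(c(40, 10, 10, 20), 2),
                              P_pe = matrix(c(30, 5, 5, 15), 2),
                              var_s = 8, var_e = 100) {
  ped <- simulate_pedigree(n_founders, n_generations,
                           offspring_per_mating = 2, seed = seed)
  arch <- trait_architecture(
    trait, G_a = G_a, P_pe = P_pe,
    var_s = if (with_sire) var_s else 0, var_e = var_e,
    parity_survival = rep(1, if (trait == "NRR56") 6 else 5),
    binary = FALSE, n_hys = 4, n_age_classes = 3,
    n_service_sires = n_service_sires)
  sim <- simulate_phenotypes(ped, arch = arch, seed = seed + 100)
  ## restrict to 3 parities for small balanced designs
  sim$phenotypes <- sim$phenotypes[sim$phenotypes$parity <= 3, ]
  list(ped = ped, arch = arch, sim = sim,
       A = a_matrix(ped))
}
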