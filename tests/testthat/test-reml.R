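test_that("MME likelihood equals the direct dense-V evaluation", {
  bs <- make_balanced_sim(n_founders = 24, seed = 3)
  spec <- rr_model_spec("DO")
  fit <- suppressWarnings(
    reml_rrm(bs$sim$phenotypes, bs$A, spec,
             reml_options(max_iter = 15, tol_loglik = 1e-4)))
  ll_direct <- direct_reml_loglik(fit, bs$sim$phenotypes, bs$A, spec)
  expect_equal(fit$loglik, ll_direct, tolerance = 1e-8)
})

test_that("single-parity intercept model matches an independent animal-model REML", {
  ped <- simulate_pedigree(80, 2, 2, prop_male = 0.2, seed = 17)
  ## one record per animal at parity 1; intercept-only (raw) basis
  arch2 <- trait_architecture(
    "CTFS", G_a = matrix(c(30, 0, 0, 1e-9), 2), P_pe = diag(1e-9, 2),
    var_s = 0, var_e = 60, n_hys = 3, n_age_classes = 2,
    parity_survival = rep(1, 5))
  sim <- simulate_phenotypes(ped, arch = arch2, seed = 18)
  ph <- sim$phenotypes[sim$phenotypes$parity == 1, ]
  A <- a_matrix(ped)
  basis0 <- legendre_basis(1, 6, normalized = FALSE, order = 0)
  spec0 <- rr_model_spec("CTFS", basis = basis0, include_pe = FALSE,
                         service_sire = FALSE)
  fit <- suppressWarnings(reml_rrm(ph, A, spec0))
  ## oracle: eigen-decomposition profile REML of the plain animal model
  des <- rrgwas:::rr_design(ph, spec0, A)
  oracle <- animal_model_reml(des$y, des$X, A[des$animals, des$animals])
  expect_equal(fit$G_a[1, 1], oracle$var_a, tolerance = 1e-3)
  expect_equal(fit$var_e, oracle$var_e, tolerance = 1e-3)
})

test_that("balanced random intercept+slope fit matches lme4", {
  ped <- simulate_pedigree(120, 1, 1, seed = 21)
  arch <- trait_architecture(
    "DO", G_a = matrix(c(40, 15, 15, 25), 2), P_pe = diag(1e-9, 2),
    var_s = 0, var_e = 50, n_hys = 1, n_age_classes = 1, sd_hys = 0,
    sd_age = 0, parity_survival = rep(1, 5))
  sim <- simulate_phenotypes(ped, arch = arch, seed = 22)
  ph <- sim$phenotypes
  basis <- legendre_basis(1, 6, normalized = FALSE)
  spec <- rr_model_spec("DO", basis = basis, fixed = character(),
                        include_pe = FALSE, service_sire = FALSE)
  fit <- reml_rrm(ph, NULL, spec, reml_options(tol_loglik = 1e-8))
  x <- 2 * (ph$parity - 1) / 5 - 1
  lfit <- lme4::lmer(value ~ x + (1 + x | animal_id), data = ph, REML = TRUE)
  vcv <- lme4::VarCorr(lfit)$animal_id
  expect_equal(fit$G_a[1, 1], vcv[1, 1], tolerance = 1e-3)
  expect_equal(fit$G_a[1, 2], vcv[1, 2], tolerance = 5e-3)
  expect_equal(fit$G_a[2, 2], vcv[2, 2], tolerance = 1e-3)
  expect_equal(fit$var_e, stats::sigma(lfit)^2, tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lfit)), tolerance = 1e-4)
})

test_that("accepted REML iterations never decrease the log-likelihood", {
  bs <- make_balanced_sim(n_founders = 30, seed = 9)
  fit <- suppressWarnings(
    reml_rrm(bs$sim$phenotypes, bs$A, rr_model_spec("DO"),
             reml_options(max_iter = 30, tol_loglik = 1e-5)))
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
})

test_that("a zero-genetic-variance simulation yields collapsed var_a estimates", {
  ped <- simulate_pedigree(200, 1, 2, prop_male = 0.1, seed = 31)
  arch <- trait_architecture(
    "DO", G_a = diag(1e-12, 2), P_pe = matrix(c(60, 20, 20, 40), 2),
    var_s = 10, var_e = 1000, parity_survival = rep(1, 5))
  est <- sapply(1:3, function(r) {
    sim <- simulate_phenotypes(ped, arch = arch, seed = 40 + r)
    fit <- suppressWarnings(
      reml_rrm(sim$phenotypes, a_matrix(ped), rr_model_spec("DO"),
               reml_options(max_iter = 25, tol_loglik = 1e-4)))
    fit$G_a[1, 1]
  })
  expect_lt(median(est), 0.2 * 1000)
})

test_that("non-convergence is flagged, not silent", {
  bs <- make_balanced_sim(n_founders = 20, seed = 5)
  expect_warning(
    fit <- reml_rrm(bs$sim$phenotypes, bs$A, rr_model_spec("DO"),
                    reml_options(max_iter = 2)),
    "did not converge")
  expect_false(fit$converged)
})

test_that("parity functions obey their analytic identities", {
  vc <- list(G_a = matrix(c(4, 1, 1, 2), 2,
                          dimnames = list(c("intercept", "slope"),
                                          c("intercept", "slope"))),
             P_pe = matrix(c(3, 0.5, 0.5, 1), 2), var_s = 0.5, var_e = 10)
  basis <- legendre_basis(1, 6)
  pf <- parity_functions(vc, basis)
  ## unit diagonal and bounded correlations
  expect_equal(unname(diag(pf$genetic_correlation)), rep(1, 6))
  expect_true(all(abs(pf$genetic_correlation) <= 1 + 1e-12))
  expect_true(all(pf$h2$h2 >= 0 & pf$h2$h2 <= 1))
  ## var_a(t) = phi' G phi by hand at parity 6
  phi <- drop(eval_basis(basis, 6))
  expect_equal(pf$h2$var_a[6], drop(phi %*% vc$G_a %*% phi))

  ## c*I coefficient covariance: var_a symmetric in x <-> -x
  vc2 <- list(G_a = diag(2, 2), P_pe = diag(1, 2), var_s = 0, var_e = 5)
  pf2 <- parity_functions(vc2, basis, parities = c(1, 6))
  expect_equal(pf2$h2$var_a[1], pf2$h2$var_a[2])
  expect_equal(pf2$h2$var_a[1], 2 * (0.5 + 1.5))

  ## rank-1 G_a: all genetic correlations are +/-1
  g <- c(1, 0.5)
  vc3 <- list(G_a = 3 * outer(g, g), P_pe = diag(1, 2), var_s = 0, var_e = 5)
  pf3 <- parity_functions(vc3, basis)
  expect_true(all(abs(abs(pf3$genetic_correlation) - 1) < 1e-10,
                  na.rm = TRUE))
})

test_that("h2 trajectory from a converged fit tracks the simulated truth", {
  bs <- make_balanced_sim(n_founders = 60, seed = 51)
  fit <- suppressWarnings(
    reml_rrm(bs$sim$phenotypes, bs$A, rr_model_spec("DO"),
             reml_options(max_iter = 30, tol_loglik = 1e-4)))
  pf <- parity_functions(fit, parities = 1:3)
  truth_vc <- list(G_a = bs$arch$G_a, P_pe = bs$arch$P_pe,
                   var_s = bs$arch$var_s, var_e = bs$arch$var_e)
  pf0 <- parity_functions(truth_vc, basis = fit$basis, parities = 1:3)
  ## Monte-Carlo tolerance: small design, generous band
  expect_true(all(abs(pf$h2$h2 - pf0$h2$h2) < 0.25))
  expect_true(all(is.finite(pf$h2$h2_se)))
})

test_that("tidy and glance return the standard layouts", {
  bs <- make_balanced_sim(n_founders = 20, seed = 61)
  fit <- suppressWarnings(
    reml_rrm(bs$sim$phenotypes, bs$A, rr_model_spec("DO"),
             reml_options(max_iter = 10, tol_loglik = 1e-3)))
  td <- tidy(fit)
  expect_identical(td$component,
                   c("var_a1", "cov_a", "var_a2", "var_p1", "cov_p",
                     "var_p2", "var_s", "var_e"))
  expect_true(all(c("loglik", "converged", "n_iter") %in% names(glance(fit))))
})
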