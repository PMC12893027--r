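## shared balanced toy with service sire: 20 animals x 3 parities
toy <- local({
  bs <- make_balanced_sim(n_founders = 20, seed = 2)
  vc <- list(G_a = bs$arch$G_a, P_pe = bs$arch$P_pe, var_s = bs$arch$var_s,
             var_e = bs$arch$var_e)
  g <- simulate_genotypes(bs$ped, n_snps = 40, seed = 3)
  list(ph = bs$sim$phenotypes, A = bs$A, vc = vc, g = g,
       spec = rr_model_spec("DO"))
})

test_that("a components-free operator is white noise scaled by var_e", {
  vc0 <- list(G_a = matrix(0, 2, 2), P_pe = matrix(0, 2, 2),
              var_s = 0, var_e = 2.5)
  spec0 <- rr_model_spec("DO", include_pe = FALSE, service_sire = FALSE)
  op <- assemble_covariance(toy$ph, vc0, toy$A, spec0, "direct")
  x <- rnorm(op$n_rec)
  expect_equal(drop(op$vsolve(matrix(x))), x / 2.5, tolerance = 1e-10)
})

test_that("eigen-mode statistics equal direct dense-V statistics", {
  for (with_sire in c(TRUE, FALSE)) {
    spec <- rr_model_spec("DO", service_sire = with_sire)
    op_d <- assemble_covariance(toy$ph, toy$vc, toy$A, spec, "direct")
    op_e <- assemble_covariance(toy$ph, toy$vc, toy$A, spec, "eigen")
    for (j in c(1, 7, 25)) {
      r1 <- snp_layer_tests(cov_op = op_d, dosage = toy$g$dosage[, j])
      r2 <- snp_layer_tests(cov_op = op_e, dosage = toy$g$dosage[, j])
      for (cl in c("beta0", "beta1", "chisq_intercept", "chisq_slope",
                   "chisq_joint")) {
        expect_equal(r1[[cl]], r2[[cl]], tolerance = 1e-8)
      }
    }
  }
})

test_that("eigen mode refuses unbalanced designs with advice", {
  ph_unbal <- toy$ph[-1, ]
  expect_error(
    assemble_covariance(ph_unbal, toy$vc, toy$A, toy$spec, "eigen"),
    "direct")
})

test_that("GLS with identity covariance reduces to ordinary least squares", {
  vc0 <- list(G_a = matrix(0, 2, 2), P_pe = matrix(0, 2, 2),
              var_s = 0, var_e = 1)
  spec0 <- rr_model_spec("DO", include_pe = FALSE, service_sire = FALSE)
  ph6 <- dplyr::arrange(toy$ph, animal_id, parity)[1:6, ]
  op <- assemble_covariance(ph6, vc0, toy$A, spec0, "direct")
  dos <- setNames(seq_along(op$animals) - 1, op$animals)
  res <- snp_layer_tests(y = op$y, fixed_design = matrix(1, 6, 1),
                         cov_op = op, dosage = dos)
  Z <- (dos[op$rec$animal_id] - mean(dos)) *
    eval_basis(op$basis, op$rec$parity)
  ols <- stats::lm(op$y ~ 1 + Z)
  expect_equal(res$beta0, unname(coef(ols))[2], tolerance = 1e-10)
  expect_equal(res$beta1, unname(coef(ols))[3], tolerance = 1e-10)
})

test_that("the joint statistic decomposes when the effect covariance is diagonal", {
  ## engineered 2x2 system: orthogonal whitened covariates
  res <- rrgwas:::gls_snp_chunk(
    op = list(transform = function(M) as.matrix(M),
              vsolve = function(M) as.matrix(M)),
    proj = list(Xw = matrix(1, 8, 1), yw = matrix(rnorm(8)),
                cA = chol(matrix(8, 1, 1)),
                w = matrix(0, 1, 1), Viy = NULL),
    Z0 = matrix(rep(c(1, -1), 4)), Z1 = matrix(rep(c(1, 1, -1, -1), 2)))
  expect_equal(res$chisq_joint, res$chisq_intercept + res$chisq_slope,
               tolerance = 1e-10)
})

test_that("monomorphic SNPs yield flagged NA rows, not dropped rows", {
  op <- assemble_covariance(toy$ph, toy$vc, toy$A, toy$spec, "direct")
  res <- snp_layer_tests(cov_op = op,
                         dosage = rep(1, length(op$animals)))
  expect_true(is.na(res$p_joint))
  expect_true(res$degenerate)
})

test_that("Wald statistics are invariant to allele relabeling", {
  op <- assemble_covariance(toy$ph, toy$vc, toy$A, toy$spec, "direct")
  d <- toy$g$dosage[, 11]
  r1 <- snp_layer_tests(cov_op = op, dosage = d)
  r2 <- snp_layer_tests(cov_op = op, dosage = 2 - d)
  expect_equal(r1$beta0, -r2$beta0)
  expect_equal(r1$beta1, -r2$beta1)
  expect_equal(r1$p_intercept, r2$p_intercept, tolerance = 1e-12)
  expect_equal(r1$p_slope, r2$p_slope, tolerance = 1e-12)
  expect_equal(r1$p_joint, r2$p_joint, tolerance = 1e-12)
})

test_that("the joint test is invariant to basis reparameterization; layers are not", {
  ## pure rescaling of each basis function (normalized vs raw Legendre)
  ## leaves every layer statistic unchanged...
  spec_n <- rr_model_spec("DO", basis = legendre_basis(1, 6))
  spec_r <- rr_model_spec("DO", basis = legendre_basis(1, 6, normalized = FALSE))
  Tm <- diag(c(sqrt(1 / 2), sqrt(3 / 2)))  # raw -> normalized coefficients
  vc_r <- list(G_a = Tm %*% toy$vc$G_a %*% t(Tm),
               P_pe = Tm %*% toy$vc$P_pe %*% t(Tm),
               var_s = toy$vc$var_s, var_e = toy$vc$var_e)
  op_n <- assemble_covariance(toy$ph, toy$vc, toy$A, spec_n, "direct")
  op_r <- assemble_covariance(toy$ph, vc_r, toy$A, spec_r, "direct")
  d <- toy$g$dosage[, 19]
  r_n <- snp_layer_tests(cov_op = op_n, dosage = d)
  r_r <- snp_layer_tests(cov_op = op_r, dosage = d)
  expect_equal(r_n$chisq_joint, r_r$chisq_joint, tolerance = 1e-8)
  expect_equal(r_n$chisq_slope, r_r$chisq_slope, tolerance = 1e-8)

  ## ...whereas a reparameterization that mixes intercept into slope keeps
  ## the 2-df joint statistic (same column space) but changes the layers
  proj <- rrgwas:::gls_projection(op_n, op_n$X, op_n$y)
  phi <- op_n$phi_rec
  drec <- (d[op_n$animals] - mean(d[op_n$animals]))[op_n$anim_idx]
  Z0 <- matrix(drec * phi[, 1]); Z1 <- matrix(drec * phi[, 2])
  r1 <- rrgwas:::gls_snp_chunk(op_n, proj, Z0, Z1)
  r2 <- rrgwas:::gls_snp_chunk(op_n, proj, Z0, Z1 + 0.5 * Z0)
  expect_equal(r1$chisq_joint, r2$chisq_joint, tolerance = 1e-8)
  ## mixing phi0 into the slope covariate redefines the baseline layer
  expect_gt(abs(r1$chisq_intercept - r2$chisq_intercept), 1e-3)
})

test_that("permuted null SNPs reject at close to the nominal level", {
  ## a null SNP permuted across animals, with fresh phenotype noise per
  ## replicate so the check averages over the generative model rather than
  ## conditioning on a single 20-animal realization
  op <- assemble_covariance(toy$ph, toy$vc, toy$A, toy$spec, "direct")
  phi <- op$phi_rec
  d <- toy$g$dosage[, 21]
  d <- d - mean(d)
  V <- op$vmul(diag(op$n_rec))
  Lv <- t(chol(V))
  withr::with_seed(99, {
    res <- purrr::map_dfr(1:500, function(r) {
      ystar <- drop(Lv %*% rnorm(op$n_rec))
      proj <- rrgwas:::gls_projection(op, op$X, ystar)
      dperm <- sample(d)[op$anim_idx]
      rrgwas:::gls_snp_chunk(op, proj, Z0 = matrix(dperm * phi[, 1]),
                             Z1 = matrix(dperm * phi[, 2]))
    })
  })
  for (l in c("p_intercept", "p_slope", "p_joint")) {
    rate <- mean(res[[l]] < 0.05, na.rm = TRUE)
    expect_gte(rate, 0.035 - 0.007)
    expect_lte(rate, 0.065 + 0.01)
  }
})

test_that("run_gwas orders rows, computes MAF and flags planted intercept QTL", {
  bs <- make_balanced_sim(n_founders = 60, seed = 71, var_e = 40,
                          G_a = matrix(c(30, 8, 8, 16), 2))
  g <- simulate_genotypes(bs$ped, n_snps = 60, seed = 72)
  qtl <- tibble::tibble(snp = 13L, beta_intercept = 4, beta_slope = 0)
  arch <- trait_architecture(
    "DO", G_a = bs$arch$G_a, P_pe = bs$arch$P_pe, var_s = bs$arch$var_s,
    var_e = bs$arch$var_e, qtl = qtl, parity_survival = rep(1, 5),
    n_hys = 4, n_age_classes = 3)
  sim <- simulate_phenotypes(bs$ped, g, arch, seed = 73)
  vc <- list(G_a = arch$G_a, P_pe = arch$P_pe, var_s = arch$var_s,
             var_e = arch$var_e)
  gw <- run_gwas(sim$phenotypes, g, vc, bs$A, rr_model_spec("DO"),
                 mode = "direct")
  expect_s3_class(gw, "rr_gwas")
  expect_equal(nrow(gw), 60)
  ord <- order(rrgwas:::chrom_order(gw$chrom), gw$pos)
  expect_equal(ord, seq_len(nrow(gw)))
  expect_true(all(gw$maf >= 0 & gw$maf <= 0.5))
  row <- gw[gw$snp_id == "snp00013", ]
  ## planted baseline effect: intercept layer more significant than slope
  expect_lt(row$p_intercept, row$p_slope)
  expect_lt(row$p_intercept, 0.05)
})

test_that("ID misalignment between tables is a named error", {
  expect_error(
    run_gwas(toy$ph, toy$g, toy$vc, toy$A[1:3, 1:3], toy$spec),
    "relationship matrix lacks")
  g_none <- toy$g
  rownames(g_none$dosage) <- paste0("Z", seq_len(nrow(g_none$dosage)))
  expect_error(run_gwas(toy$ph, g_none, toy$vc, toy$A, toy$spec),
               "phenotyped and genotyped")
})

test_that("gwas summaries: lambda, thresholds, effect correlation, varexp", {
  ## exact uniform p-value quantiles give lambda = 1 in each layer
  n <- 400
  p <- (seq_len(n) - 0.5) / n
  rows <- tibble::tibble(
    snp_id = sprintf("s%03d", seq_len(n)), chrom = "1", pos = seq_len(n),
    beta0 = rnorm(n), beta1 = rnorm(n),
    chisq_intercept = qchisq(p, 1, lower.tail = FALSE),
    chisq_slope = qchisq(p, 1, lower.tail = FALSE),
    chisq_joint = qchisq(p, 2, lower.tail = FALSE),
    p_intercept = p, p_slope = p, p_joint = p,
    degenerate = FALSE)
  s <- gwas_summaries(rows, alpha = 0.05)
  expect_equal(unname(s$lambda_per_layer), rep(1, 3), tolerance = 1e-3)
  expect_equal(s$bonferroni_p, 0.05 / n)
  expect_equal(s$suggestive_p, 1 / n)
  rows$beta1 <- rows$beta0
  expect_equal(gwas_summaries(rows)$r_intercept_slope, 1.0)
  expect_error(gwas_summaries(rows, alpha = 2), "alpha")

  ## variance explained, plugged into the stated formula by hand:
  ## p = 0.5, beta0 = 1, beta1 = 0, mean genetic variance 10 -> 0.025
  twopq <- 2 * 0.5 * 0.5
  phi0sq <- 0.5
  expect_equal(twopq * 1^2 * phi0sq / 10, 0.025)
})

test_that("varexp columns follow the plug-in formula inside run_gwas", {
  gw <- run_gwas(toy$ph, toy$g, toy$vc, toy$A, toy$spec, mode = "direct")
  i <- which(!is.na(gw$beta0))[1]
  basis <- attr(gw, "basis")
  Phi <- eval_basis(basis, sort(unique(toy$ph$parity[toy$ph$parity <= 3])))
  mean_gen <- mean(rowSums((Phi %*% toy$vc$G_a) * Phi))
  ids <- intersect(unique(toy$ph$animal_id), rownames(toy$g$dosage))
  pfreq <- mean(toy$g$dosage[ids, gw$snp_id[i]]) / 2
  expected <- 2 * pfreq * (1 - pfreq) *
    mean((gw$beta0[i] * Phi[, 1])^2) / mean_gen
  expect_equal(unname(gw$varexp_intercept[i]), unname(expected), tolerance = 1e-10)
})
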