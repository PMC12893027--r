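test_that("pedigree simulation gives the forced two-founder structure", {
  ped <- simulate_pedigree(n_founders = 2, n_generations = 1,
                           offspring_per_mating = 1, seed = 1)
  expect_equal(nrow(ped), 3)
  child <- ped[3, ]
  expect_setequal(c(child$sire_id, child$dam_id), ped$animal_id[1:2])
})

test_that("pedigree simulation is deterministic and topologically valid", {
  p1 <- simulate_pedigree(10, 3, seed = 7)
  p2 <- simulate_pedigree(10, 3, seed = 7)
  expect_identical(p1, p2)
  ## graph-traversal check: every parent appears strictly earlier
  pos <- setNames(seq_len(nrow(p1)), p1$animal_id)
  for (i in seq_len(nrow(p1))) {
    for (par in c(p1$sire_id[i], p1$dam_id[i])) {
      if (!is.na(par)) expect_lt(pos[[par]], i)
    }
  }
  expect_silent(validate_pedigree(p1))
  expect_error(simulate_pedigree(1, 1), "at least 2")
})

test_that("gene dropping is Mendelian-consistent", {
  ped <- simulate_pedigree(40, 2, seed = 3)
  g <- simulate_genotypes(ped, n_snps = 80, missing_rate = 0, seed = 3)
  D <- g$dosage
  for (i in seq_len(nrow(ped))) {
    for (par in c(ped$sire_id[i], ped$dam_id[i])) {
      if (is.na(par)) next
      o <- D[ped$animal_id[i], ]
      q <- D[par, ]
      expect_false(any((o == 0 & q == 2) | (o == 2 & q == 0)))
    }
  }
  ## homozygote parents force offspring genotypes
  ped2 <- simulate_pedigree(2, 1, offspring_per_mating = 3, seed = 1)
  g2 <- simulate_genotypes(ped2, n_snps = 200, seed = 9)
  founders <- ped2$animal_id[1:2]
  kids <- setdiff(ped2$animal_id, founders)
  both0 <- g2$dosage[founders[1], ] == 0 & g2$dosage[founders[2], ] == 0
  both2 <- g2$dosage[founders[1], ] == 2 & g2$dosage[founders[2], ] == 2
  expect_true(all(g2$dosage[kids, both0] == 0))
  expect_true(all(g2$dosage[kids, both2] == 2))
})

test_that("founder allele frequencies track the drawn frequencies", {
  ped <- simulate_pedigree(200, 1, seed = 5)
  withr::with_seed(5, {
    p_drawn <- runif(300, 0.1, 0.5)  # same stream as the generator
  })
  g <- simulate_genotypes(ped, n_snps = 300, maf_range = c(0.1, 0.5),
                          missing_rate = 0, seed = 5)
  founders <- ped$animal_id[ped$generation == 0]
  p_obs <- colMeans(g$dosage[founders, ]) / 2
  sd3 <- 3 * sqrt(p_drawn * (1 - p_drawn) / (2 * length(founders)))
  expect_gt(mean(abs(p_obs - p_drawn) <= sd3), 0.98)
})

test_that("positions increase within chromosomes and missingness is injected", {
  ped <- simulate_pedigree(10, 1, seed = 2)
  g <- simulate_genotypes(ped, n_snps = 60, n_chromosomes = 3,
                          missing_rate = 0.1, seed = 2)
  for (ch in unique(g$map$chrom)) {
    expect_true(all(diff(g$map$pos[g$map$chrom == ch]) > 0))
  }
  expect_gt(mean(is.na(g$dosage)), 0.05)
  expect_lt(mean(is.na(g$dosage)), 0.15)
})

test_that("degenerate architecture collapses phenotypes to the mean curve", {
  ped <- simulate_pedigree(10, 1, seed = 1)
  arch <- trait_architecture(
    "DO", G_a = matrix(0, 2, 2), P_pe = matrix(0, 2, 2), var_s = 0,
    var_e = 0, sd_hys = 0, sd_age = 0, mean_intercept = 100, mean_slope = 0,
    parity_survival = rep(1, 5))
  sim <- simulate_phenotypes(ped, arch = arch, seed = 1)
  expect_equal(unique(sim$phenotypes$value), 100 * sqrt(0.5))
  ## full retention -> every animal has a record at every parity
  counts <- table(sim$phenotypes$animal_id)
  expect_true(all(counts == 6))
})

test_that("record counts are non-increasing in parity under culling", {
  ped <- simulate_pedigree(150, 1, seed = 4)
  sim <- simulate_phenotypes(ped, arch = trait_architecture("DO"), seed = 4)
  counts <- table(factor(sim$phenotypes$parity, levels = 1:6))
  expect_true(all(diff(as.integer(counts)) <= 0))
  ## and each animal's parities are consecutive from the first
  by_anim <- split(sim$phenotypes$parity, sim$phenotypes$animal_id)
  expect_true(all(vapply(by_anim, function(p) all(sort(p) == seq_along(p)), TRUE)))
})

test_that("simulated genetic variance matches phi' G_a phi across parities", {
  ped <- simulate_pedigree(n_founders = 700, n_generations = 2,
                           offspring_per_mating = 3, seed = 21)
  arch <- trait_architecture("DO")
  basis <- legendre_basis(1, 6)
  A <- a_matrix(ped)
  reps <- lapply(1:5, function(r) {
    sim <- simulate_phenotypes(ped, arch = arch, seed = 100 + r)
    tv <- sim$truth$coefficients
    dbar <- mean(diag(A)[tv$animal_id])
    Phi <- eval_basis(basis, 1:6)
    sapply(1:6, function(t) {
      g <- Phi[t, 1] * tv$a0 + Phi[t, 2] * tv$a1
      var(g) / (dbar * drop(Phi[t, , drop = FALSE] %*% arch$G_a %*%
                              t(Phi[t, , drop = FALSE])))
    })
  })
  ratio <- colMeans(do.call(rbind, reps))
  expect_true(all(abs(ratio - 1) < 0.10))
})

test_that("binary trait thresholds the liability", {
  ped <- simulate_pedigree(100, 1, seed = 6)
  sim <- simulate_phenotypes(ped, arch = trait_architecture("NRR56"), seed = 6)
  expect_true(all(sim$phenotypes$value %in% c(0, 1)))
  expect_equal(sim$phenotypes$value,
               as.numeric(sim$truth$liability > 0))
  m <- mean(sim$phenotypes$value[sim$phenotypes$parity == 0])
  expect_gt(m, 0.55); expect_lt(m, 0.85)  # heifer mean near 0.71
})

test_that("planted QTL contribute the requested covariance", {
  ped <- simulate_pedigree(300, 1, seed = 8)
  g <- simulate_genotypes(ped, n_snps = 50, seed = 8)
  qtl <- tibble::tibble(snp = c(10L, 30L), beta_intercept = c(3, 0),
                        beta_slope = c(0, 2))
  arch <- trait_architecture("DO", qtl = qtl)
  sim <- simulate_phenotypes(ped, g, arch, seed = 8)
  tv <- sim$truth$coefficients
  d <- g$dosage[tv$animal_id, 10]
  ## expected correlation ~ sqrt(2pq beta^2 / var_a1) = 0.17; null SD 0.06
  expect_gt(cor(tv$a0, d), 0.1)
})

test_that("annotation simulation covers inside/flank/far cases", {
  ped <- simulate_pedigree(4, 1, seed = 1)
  g <- simulate_genotypes(ped, n_snps = 100, n_chromosomes = 2, seed = 1)
  expect_equal(nrow(simulate_annotation(g$map, n_genes = 0, seed = 1)), 0)
  ann <- simulate_annotation(g$map, n_genes = 60, seed = 1)
  expect_true(all(ann$start <= ann$end))
  expect_false(anyDuplicated(ann$gene_id) > 0)
  a2 <- simulate_annotation(g$map, n_genes = 60, seed = 1)
  expect_identical(as.data.frame(ann), as.data.frame(a2))
})
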