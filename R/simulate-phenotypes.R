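#' Simulate multi-parity phenotypes under the random-regression model
#'
#' Generates longitudinal records following the generative model the
#' random-regression analysis assumes: for animal `i` at parity `t`,
#' `y = mu(t) + hys + age + phi(t)' a_i + phi(t)' p_i + s + e`, where
#' `a_i` are intercept+slope breeding-value coefficients (planted QTL
#' contributions plus a pedigree-correlated polygenic remainder whose
#' covariance tops total additive covariance up to `G_a`), `p_i ~ N(0,
#' P_pe)` i.i.d. permanent-environment coefficients, `s` a service-sire
#' effect drawn from a finite pool, and `e ~ N(0, var_e)`. Records at
#' parity `t` exist only while every per-parity retention draw up to `t`
#' succeeded, which reproduces record counts that decline with parity.
#' Binary traits are thresholded on the Gaussian liability.
#'
#' @param pedigree Pedigree tibble.
#' @param genotypes Optional `rr_geno`; required when `arch$qtl` is
#'   non-empty.
#' @param arch A [trait_architecture()].
#' @param animals Character vector of animals to phenotype; defaults to all
#'   females in the pedigree (all animals if no `sex` column).
#' @param seed Integer seed; defaults to `arch$seed`.
#' @return A list of class `rr_sim` with `phenotypes` (tibble `animal_id`,
#'   `trait`, `parity`, `value`, `hys`, `age_class`, `service_sire_id`) and
#'   `truth` (breeding-value/PE coefficients per animal, service-sire, HYS
#'   and age-class effects, and the liability for binary traits).
#' @examples
#' ped <- simulate_pedigree(20, 1, seed = 1)
#' sim <- simulate_phenotypes(ped, arch = trait_architecture("DO"), seed = 1)
#' head(sim$phenotypes)
#' @export
simulate_phenotypes <- function(pedigree, genotypes = NULL, arch,
                                animals = NULL, seed = NULL) {
  stopifnot(inherits(arch, "rr_arch"))
  validate_pedigree(pedigree)
  withr::local_seed(seed %||% arch$seed)

  if (is.null(animals)) {
    animals <- if ("sex" %in% names(pedigree)) {
      pedigree$animal_id[pedigree$sex == "F"]
    } else {
      pedigree$animal_id
    }
  }
  if (!all(animals %in% pedigree$animal_id)) {
    abort("`animals` must all appear in the pedigree.")
  }

  basis <- legendre_basis(arch$t_min, arch$t_max)
  parities <- seq(arch$t_min, arch$t_max)
  Phi <- eval_basis(basis, parities)

  ## --- additive-genetic coefficients -------------------------------------
  qtl_cov <- matrix(0, 2, 2)
  B <- NULL
  qtl_idx <- integer()
  if (nrow(arch$qtl)) {
    if (is.null(genotypes)) abort("`genotypes` required when QTL are planted.")
    qtl_idx <- resolve_snp(arch$qtl$snp, genotypes)
    B <- rbind(arch$qtl$beta_intercept, arch$qtl$beta_slope)  # 2 x nq
    pq <- colMeans(genotypes$dosage[, qtl_idx, drop = FALSE], na.rm = TRUE) / 2
    qtl_cov <- B %*% diag(2 * pq * (1 - pq), length(pq)) %*% t(B)
  }
  G_poly <- arch$G_a - qtl_cov
  if (any(eigen(G_poly, TRUE, TRUE)$values < -1e-8)) {
    abort("planted QTL explain more covariance than `G_a` allows.")
  }

  a <- polygenic_coefficients(pedigree, G_poly)  # n_ped x 2, pedigree order
  rownames(a) <- pedigree$animal_id
  if (length(qtl_idx)) {
    d <- genotypes$dosage[, qtl_idx, drop = FALSE]
    d <- sweep(d, 2, colMeans(d, na.rm = TRUE))
    d[is.na(d)] <- 0
    common <- intersect(pedigree$animal_id, rownames(d))
    if (!all(animals %in% common)) {
      abort("phenotyped animals must be genotyped when QTL are planted.")
    }
    a[common, ] <- a[common, ] + d[common, ] %*% t(B)
  }

  ## --- other effects ------------------------------------------------------
  p_coef <- mvn_draws(length(animals), arch$P_pe)
  rownames(p_coef) <- animals
  sire_pool <- sprintf("SS%03d", seq_len(arch$n_service_sires))
  sire_eff <- setNames(rnorm(length(sire_pool), 0, sqrt(arch$var_s)), sire_pool)
  hys_lev <- sprintf("H%02d", seq_len(arch$n_hys))
  hys_eff <- setNames(rnorm(arch$n_hys, 0, arch$sd_hys), hys_lev)
  age_lev <- sprintf("AC%02d", seq_len(arch$n_age_classes))
  age_eff <- setNames(rnorm(arch$n_age_classes, 0, arch$sd_age), age_lev)
  use_sire <- arch$var_s > 0

  ## --- record existence: sequential retention ----------------------------
  n_par <- length(parities)
  keep <- matrix(TRUE, length(animals), n_par)
  for (j in seq_len(n_par - 1)) {
    keep[, j + 1] <- keep[, j] &
      (runif(length(animals)) < arch$parity_survival[j])
  }

  rec <- tibble(
    animal_id = rep(animals, each = n_par),
    parity = rep(parities, length(animals))
  )[as.vector(t(keep)), ]

  n_rec <- nrow(rec)
  phi <- eval_basis(basis, rec$parity)
  rec$hys <- sample(hys_lev, n_rec, replace = TRUE)
  rec$age_class <- sample(age_lev, n_rec, replace = TRUE)
  rec$service_sire_id <- if (use_sire) {
    sample(sire_pool, n_rec, replace = TRUE)
  } else {
    NA_character_
  }

  mu <- arch$mean_intercept * phi[, 1] + arch$mean_slope * phi[, 2]
  gen_part <- rowSums(phi * a[rec$animal_id, , drop = FALSE])
  pe_part <- rowSums(phi * p_coef[rec$animal_id, , drop = FALSE])
  sire_part <- if (use_sire) sire_eff[rec$service_sire_id] else 0
  liab <- mu + hys_eff[rec$hys] + age_eff[rec$age_class] + gen_part +
    pe_part + sire_part + rnorm(n_rec, 0, sqrt(arch$var_e))
  liab <- unname(liab)
  rec$value <- if (arch$binary) as.numeric(liab > arch$threshold) else liab
  rec$trait <- arch$trait
  rec <- rec[, c("animal_id", "trait", "parity", "value", "hys",
                 "age_class", "service_sire_id")]

  truth <- list(
    coefficients = tibble(
      animal_id = animals,
      a0 = a[animals, 1], a1 = a[animals, 2],
      p0 = p_coef[, 1], p1 = p_coef[, 2]
    ),
    sire_effects = tibble(service_sire_id = sire_pool,
                          effect = unname(sire_eff)),
    hys_effects = tibble(hys = hys_lev, effect = unname(hys_eff)),
    age_effects = tibble(age_class = age_lev, effect = unname(age_eff)),
    liability = if (arch$binary) unname(liab) else NULL,
    arch = arch, basis = basis
  )
  structure(list(phenotypes = rec, truth = truth), class = "rr_sim")
}

#' @export
print.rr_sim <- function(x, ...) {
  cat(sprintf("<rr_sim> %s: %d records on %d animals, parities %d..%d\n",
              x$truth$arch$trait, nrow(x$phenotypes),
              dplyr::n_distinct(x$phenotypes$animal_id),
              min(x$phenotypes$parity), max(x$phenotypes$parity)))
  invisible(x)
}

## Pedigree-recursive (gene-flow) draw of coefficient vectors with
## Cov(a_i, a_j) = A_ij * G0: founders ~ N(0, G0), descendants get the
## parent average plus Mendelian sampling with variance
## (0.5 - 0.25 (F_s + F_d)) G0.
polygenic_coefficients <- function(pedigree, G0) {
  n <- nrow(pedigree)
  k <- ncol(G0)
  Fcoef <- inbreeding_coefficients(pedigree)
  row_of <- setNames(seq_len(n), pedigree$animal_id)
  a <- matrix(0, n, k)
  L <- psd_sqrt(G0)
  for (i in seq_len(n)) {
    s <- pedigree$sire_id[i]
    d <- pedigree$dam_id[i]
    par <- c(s, d)
    known <- !is.na(par)
    if (!any(known)) {
      a[i, ] <- L %*% rnorm(k)
    } else {
      pa <- colSums(a[row_of[par[known]], , drop = FALSE]) / 2
      fbar <- mean(Fcoef[row_of[par[known]]])
      mvar <- 1 - sum(known) * 0.25 * (1 + fbar)
      a[i, ] <- pa + sqrt(max(mvar, 0)) * (L %*% rnorm(k))
    }
  }
  a
}

inbreeding_coefficients <- function(pedigree) {
  A <- a_matrix(pedigree)
  diag(A) - 1
}

mvn_draws <- function(n, Sigma) {
  matrix(rnorm(n * ncol(Sigma)), n) %*% t(psd_sqrt(Sigma))
}

psd_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(S)) %*% t(e$vectors)
}

resolve_snp <- function(snp, genotypes) {
  if (is.numeric(snp)) {
    idx <- as.integer(snp)
    if (any(idx < 1 | idx > ncol(genotypes$dosage))) {
      abort("QTL SNP index out of range.")
    }
    return(idx)
  }
  idx <- match(snp, colnames(genotypes$dosage))
  if (anyNA(idx)) abort("QTL SNP id not found in genotypes.")
  idx
}
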