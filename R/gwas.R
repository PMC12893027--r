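#' Per-SNP intercept, slope and joint Wald tests
#'
#' Generalized least squares fit of one SNP's intercept and slope effects
#' jointly with all other fixed effects, with the covariance operator held
#' fixed. The SNP enters through two record-level covariates, dosage times
#' `phi0(t)` and dosage times `phi1(t)` (dosage centered over the analyzed
#' animals). Wald statistics: the intercept ("outer") layer tests `beta0`
#' against chi-square(1), the slope ("middle") layer `beta1` likewise, and
#' the joint ("inner") layer tests `(beta0, beta1)` against chi-square(2)
#' using the full 2x2 covariance of the estimates — the combination that
#' accounts for the covariance between intercept and slope.
#'
#' @param y Response vector (record order of `cov_op`). Defaults to the
#'   phenotype vector stored in the operator.
#' @param fixed_design Fixed-effect design matrix (record order of
#'   `cov_op`); defaults to the design stored in the operator.
#' @param cov_op An [assemble_covariance()] operator.
#' @param dosage Dosage vector named by (or ordered as) the operator's
#'   animals.
#' @param basis Basis for the SNP covariates; defaults to the operator's.
#' @return A one-row tibble: `beta0`, `beta1`, `var_beta0`, `cov_beta01`,
#'   `var_beta1`, `chisq_intercept`, `chisq_slope`, `chisq_joint`,
#'   `p_intercept`, `p_slope`, `p_joint`, `degenerate`. Collinear
#'   (monomorphic) SNPs give an all-`NA` flagged row.
#' @export
snp_layer_tests <- function(y = NULL, fixed_design = NULL, cov_op, dosage,
                            basis = NULL) {
  stopifnot(inherits(cov_op, "rr_covop"))
  basis <- basis %||% cov_op$basis
  y <- y %||% cov_op$y
  X <- fixed_design %||% cov_op$X
  if (!is.null(names(dosage))) dosage <- dosage[cov_op$animals]
  if (length(dosage) != length(cov_op$animals)) {
    abort("`dosage` must hold one value per analyzed animal.")
  }
  d <- dosage - mean(dosage)
  proj <- gls_projection(cov_op, X, y)
  phi <- eval_basis(basis, cov_op$rec$parity)
  drec <- d[cov_op$anim_idx]
  res <- gls_snp_chunk(cov_op, proj,
                       Z0 = matrix(drec * phi[, 1]),
                       Z1 = matrix(drec * phi[, 2]))
  res
}

## Precompute the fixed-effect projections shared across SNPs.
gls_projection <- function(op, X, y) {
  Xw <- op$transform(X)
  yw <- op$transform(matrix(y))
  ViX <- op$vsolve(Xw)
  A <- crossprod(Xw, ViX)
  cA <- chol(A)
  Xty <- crossprod(ViX, yw)
  w <- backsolve(cA, backsolve(cA, Xty, transpose = TRUE))
  list(Xw = Xw, yw = yw, ViX = ViX, cA = cA, w = w,
       Viy = op$vsolve(yw))
}

## Vectorized GLS layer statistics for a chunk of SNP covariate pairs.
gls_snp_chunk <- function(op, proj, Z0, Z1, cond_max = 1e12) {
  Z0w <- op$transform(Z0)
  Z1w <- op$transform(Z1)
  ViZ0 <- op$vsolve(Z0w)
  ViZ1 <- op$vsolve(Z1w)
  a00 <- colSums(Z0w * ViZ0)
  a01 <- colSums(Z0w * ViZ1)
  a11 <- colSums(Z1w * ViZ1)
  b0 <- drop(crossprod(ViZ0, proj$yw))
  b1 <- drop(crossprod(ViZ1, proj$yw))
  B0 <- crossprod(proj$Xw, ViZ0)    # p x c
  B1 <- crossprod(proj$Xw, ViZ1)
  AiB0 <- backsolve(proj$cA, backsolve(proj$cA, B0, transpose = TRUE))
  AiB1 <- backsolve(proj$cA, backsolve(proj$cA, B1, transpose = TRUE))
  c00 <- a00 - colSums(B0 * AiB0)
  c01 <- a01 - colSums(B0 * AiB1)
  c11 <- a11 - colSums(B1 * AiB1)
  r0 <- b0 - drop(crossprod(B0, proj$w))
  r1 <- b1 - drop(crossprod(B1, proj$w))

  det <- c00 * c11 - c01^2
  scale2 <- pmax(c00, c11)^2
  ok <- c00 > 0 & c11 > 0
  degen <- ok & (det <= scale2 / cond_max)
  usable <- ok & !degen
  flagged <- degen | !ok   # monomorphic/collinear rows carry the flag too

  beta0 <- beta1 <- chisq_i <- chisq_s <- chisq_j <- rep(NA_real_, length(a00))
  df_joint <- rep(2, length(a00))
  beta0[usable] <- (c11[usable] * r0[usable] - c01[usable] * r1[usable]) / det[usable]
  beta1[usable] <- (c00[usable] * r1[usable] - c01[usable] * r0[usable]) / det[usable]
  chisq_i[usable] <- beta0[usable]^2 * det[usable] / c11[usable]
  chisq_s[usable] <- beta1[usable]^2 * det[usable] / c00[usable]
  chisq_j[usable] <- beta0[usable] * r0[usable] + beta1[usable] * r1[usable]

  ## rank-deficient 2x2: pseudo-inverse along the dominant direction (1 df)
  if (any(degen)) {
    i <- which(degen)
    use0 <- c00[i] >= c11[i]
    b <- ifelse(use0, r0[i] / c00[i], r1[i] / c11[i])
    st <- ifelse(use0, r0[i]^2 / c00[i], r1[i]^2 / c11[i])
    beta0[i] <- ifelse(use0, b, NA_real_)
    beta1[i] <- ifelse(use0, NA_real_, b)
    chisq_i[i] <- ifelse(use0, st, NA_real_)
    chisq_s[i] <- ifelse(use0, NA_real_, st)
    chisq_j[i] <- st
    df_joint[i] <- 1
  }

  var_beta0 <- ifelse(usable, c11 / det, ifelse(degen, 1 / c00, NA_real_))
  var_beta1 <- ifelse(usable, c00 / det, ifelse(degen, 1 / c11, NA_real_))
  cov_beta01 <- ifelse(usable, -c01 / det, NA_real_)

  tibble(
    beta0 = beta0, beta1 = beta1,
    var_beta0 = var_beta0, cov_beta01 = cov_beta01, var_beta1 = var_beta1,
    chisq_intercept = chisq_i, chisq_slope = chisq_s, chisq_joint = chisq_j,
    p_intercept = chisq_p(chisq_i, 1),
    p_slope = chisq_p(chisq_s, 1),
    p_joint = chisq_p(chisq_j, df_joint),
    degenerate = flagged
  )
}

## chi-square upper-tail p computed in log space to stay accurate far into
## the tail, then exponentiated (p-values below ~1e-300 underflow to the
## smallest representable double rather than to an exact zero).
chisq_p <- function(stat, df) {
  lp <- pchisq(stat, df, lower.tail = FALSE, log.p = TRUE)
  p <- exp(lp)
  ifelse(is.na(stat), NA_real_, pmax(p, .Machine$double.xmin))
}

#' Run the longitudinal GWAS scan
#'
#' One-SNP-at-a-time generalized least squares scan of all SNPs, with the
#' step-1 variance components fixed in the record covariance. The analysis
#' is restricted to animals that are both phenotyped and genotyped.
#'
#' @param phenotypes Phenotype tibble.
#' @param genotypes `rr_geno` object (post-QC: complete dosages).
#' @param vc Variance components (`rr_reml` fit or compatible list).
#' @param relationship Relationship matrix covering the analyzed animals
#'   (typically the genomic matrix over genotyped cows).
#' @param spec An [rr_model_spec()].
#' @param mode `"direct"` (any design) or `"eigen"` (balanced designs).
#' @param coding `"dosage"` (additive 0/1/2, the default; 1/1/2-df tests) or
#'   `"factor"` (genotype-as-factor; 2/2/4-df tests).
#' @param chunk_size SNPs per vectorized chunk.
#' @param progress Emit progress messages?
#' @return A tibble of class `rr_gwas`, one row per SNP ordered by
#'   (chromosome, position): map fields, `maf`, effect estimates, their
#'   covariance, layer chi-squares and p-values, and the fractions of total
#'   additive genetic variance explained (`varexp_intercept`,
#'   `varexp_slope`, `varexp_joint`).
#' @export
run_gwas <- function(phenotypes, genotypes, vc, relationship, spec,
                     mode = c("direct", "eigen"),
                     coding = c("dosage", "factor"),
                     chunk_size = 256, progress = FALSE) {
  mode <- match.arg(mode)
  coding <- match.arg(coding)
  stopifnot(inherits(genotypes, "rr_geno"))
  ph <- as_tibble(phenotypes)
  ph <- ph[ph$trait == spec$trait, , drop = FALSE]
  gen_ids <- rownames(genotypes$dosage)
  analyzed <- intersect(unique(ph$animal_id), gen_ids)
  if (!length(analyzed)) {
    abort("no animal is both phenotyped and genotyped.")
  }
  miss_rel <- setdiff(analyzed, rownames(relationship))
  if (length(miss_rel)) {
    abort(sprintf("relationship matrix lacks analyzed animals: %s%s",
                  paste(head(miss_rel, 5), collapse = ", "),
                  if (length(miss_rel) > 5) ", ..." else ""))
  }
  ph <- ph[ph$animal_id %in% analyzed, , drop = FALSE]

  des <- rr_design(ph, spec, relationship)
  op <- covop_build(des, vc, relationship, spec, mode)
  proj <- gls_projection(op, op$X, op$y)

  D <- genotypes$dosage[op$animals, , drop = FALSE]
  storage.mode(D) <- "double"
  pfreq <- colMeans(D) / 2
  maf <- pmin(pfreq, 1 - pfreq)
  Dc <- sweep(D, 2, 2 * pfreq)
  phi <- op$phi_rec
  n_snps <- ncol(D)

  chunks <- split(seq_len(n_snps), ceiling(seq_len(n_snps) / chunk_size))
  out <- vector("list", length(chunks))
  for (ci in seq_along(chunks)) {
    ix <- chunks[[ci]]
    if (coding == "dosage") {
      drec <- Dc[op$anim_idx, ix, drop = FALSE]
      res <- gls_snp_chunk(op, proj,
                           Z0 = drec * phi[, 1], Z1 = drec * phi[, 2])
    } else {
      res <- bind_rows(lapply(ix, function(j) {
        gls_snp_factor(op, proj, D[, j], phi)
      }))
    }
    out[[ci]] <- res
    if (progress) {
      inform(sprintf("gwas: %d / %d SNPs", max(ix), n_snps))
    }
  }
  res <- bind_rows(out)
  res <- bind_cols(genotypes$map, tibble(maf = unname(maf)), res)

  ## variance explained relative to the parity-averaged genetic variance
  parities <- sort(unique(op$rec$parity))
  Phi_t <- eval_basis(op$basis, parities)
  mean_gen <- mean(rowSums((Phi_t %*% op$vc$G_a) * Phi_t))
  twopq <- 2 * pfreq * (1 - pfreq)
  vx <- function(b0, b1) {
    eff <- outer(ifelse(is.na(b0), 0, b0), Phi_t[, 1]) +
      outer(ifelse(is.na(b1), 0, b1), Phi_t[, 2])
    out <- twopq * rowMeans(eff^2) / mean_gen
    out[is.na(b0) & is.na(b1)] <- NA_real_
    out
  }
  res$varexp_intercept <- vx(res$beta0, rep(NA_real_, n_snps))
  res$varexp_slope <- vx(rep(NA_real_, n_snps), res$beta1)
  res$varexp_joint <- vx(res$beta0, res$beta1)

  res <- arrange(res, chrom_order(.data$chrom), .data$pos)
  attr(res, "vc") <- op$vc
  attr(res, "basis") <- op$basis
  attr(res, "n_analyzed") <- length(op$animals)
  attr(res, "mode") <- mode
  class(res) <- c("rr_gwas", class(res))
  res
}

chrom_order <- function(chrom) {
  suppressWarnings(num <- as.numeric(chrom))
  ifelse(is.na(num), rank(chrom, ties.method = "min") + 1e6, num)
}

## genotype-as-factor coding: 2 dummy columns per layer, 2/2/4-df tests
gls_snp_factor <- function(op, proj, d, phi) {
  lev <- sort(unique(d))
  if (length(lev) < 2) {
    return(tibble(beta0 = NA_real_, beta1 = NA_real_, var_beta0 = NA_real_,
                  cov_beta01 = NA_real_, var_beta1 = NA_real_,
                  chisq_intercept = NA_real_, chisq_slope = NA_real_,
                  chisq_joint = NA_real_, p_intercept = NA_real_,
                  p_slope = NA_real_, p_joint = NA_real_, degenerate = TRUE))
  }
  dummies <- vapply(lev[-1], function(l) as.numeric(d == l),
                    numeric(length(d)))
  drec <- dummies[op$anim_idx, , drop = FALSE]
  Z <- cbind(drec * phi[, 1], drec * phi[, 2])
  q <- ncol(drec)
  Zw <- op$transform(Z)
  ViZ <- op$vsolve(Zw)
  Czz <- crossprod(Zw, ViZ)
  Bz <- crossprod(proj$Xw, ViZ)
  AiB <- backsolve(proj$cA, backsolve(proj$cA, Bz, transpose = TRUE))
  Czz <- Czz - crossprod(Bz, AiB)
  rz <- drop(crossprod(ViZ, proj$yw)) - drop(crossprod(Bz, proj$w))
  beta <- tryCatch(solve(Czz, rz), error = function(e) NULL)
  if (is.null(beta)) {
    return(gls_snp_factor(op, proj, rep(0, length(d)), phi))
  }
  wald <- function(ix) {
    Ci <- solve(Czz)[ix, ix, drop = FALSE]
    drop(t(beta[ix]) %*% solve(Ci) %*% beta[ix])
  }
  i0 <- seq_len(q); i1 <- q + seq_len(q)
  chi_i <- wald(i0); chi_s <- wald(i1)
  chi_j <- drop(t(beta) %*% Czz %*% beta)
  tibble(beta0 = NA_real_, beta1 = NA_real_, var_beta0 = NA_real_,
         cov_beta01 = NA_real_, var_beta1 = NA_real_,
         chisq_intercept = chi_i, chisq_slope = chi_s, chisq_joint = chi_j,
         p_intercept = chisq_p(chi_i, q), p_slope = chisq_p(chi_s, q),
         p_joint = chisq_p(chi_j, 2 * q), degenerate = FALSE)
}
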