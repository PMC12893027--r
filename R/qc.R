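#' Genotype quality-control thresholds
#'
#' @param maf_min Minimum minor allele frequency (SNPs below are removed).
#' @param call_rate_min Minimum per-SNP call rate.
#' @param hwe_p_min SNPs with a 1-df chi-square Hardy-Weinberg test p-value
#'   below this are removed.
#' @param dup_rel_max Animal pairs with a provisional genomic relationship
#'   above this are treated as duplicates (the first-listed animal is kept).
#' @param mendel_check Resolve Mendelian conflicts against genotyped
#'   parents?
#' @param drop_monomorphic Remove SNPs with allele frequency 0 or 1?
#' @param mendel_animal_max Animals whose fraction of parent-offspring
#'   conflicts exceeds this are removed.
#' @return An object of class `rr_qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.05, call_rate_min = 0.90,
                          hwe_p_min = 1e-6, dup_rel_max = 0.95,
                          mendel_check = TRUE, drop_monomorphic = TRUE,
                          mendel_animal_max = 0.02) {
  fr <- c(maf_min = maf_min, call_rate_min = call_rate_min,
          hwe_p_min = hwe_p_min, dup_rel_max = dup_rel_max)
  if (any(fr < 0 | fr > 1)) abort("thresholds must lie in [0, 1].")
  structure(as.list(environment()), class = "rr_qc_thresholds")
}

#' Genotype quality control
#'
#' Applies, in a fixed documented order, the standard pre-GWAS filters:
#' per-SNP call rate, monomorphic SNPs, minor allele frequency,
#' Hardy-Weinberg equilibrium (1-df chi-square of observed vs expected
#' genotype counts), Mendelian conflicts against genotyped parents
#' (conflicting offspring entries are set missing; animals with more than
#' `mendel_animal_max` conflicting SNPs are dropped) and duplicate animals
#' (provisional genomic relationship above `dup_rel_max`; the first-listed
#' animal of a pair is kept). Remaining missing dosages are imputed to twice
#' the observed allele frequency.
#'
#' @param genotypes An `rr_geno` object.
#' @param pedigree Optional pedigree used for the Mendelian-conflict filter.
#' @param thresholds A [qc_thresholds()] object.
#' @return A list with `genotypes` (filtered and imputed `rr_geno`; dosages
#'   become numeric) and `report` (an `rr_qc_report`: per-filter removal
#'   tallies and surviving dimensions).
#' @export
qc_filter <- function(genotypes, pedigree = NULL,
                      thresholds = qc_thresholds()) {
  stopifnot(inherits(genotypes, "rr_geno"),
            inherits(thresholds, "rr_qc_thresholds"))
  X <- genotypes$dosage
  storage.mode(X) <- "double"
  map <- genotypes$map
  n_snp0 <- ncol(X)
  n_ani0 <- nrow(X)
  steps <- list()
  log_step <- function(axis, filter, removed) {
    steps[[length(steps) + 1]] <<- tibble(axis = axis, filter = filter,
                                          removed = as.integer(removed))
  }
  drop_snps <- function(bad, filter) {
    log_step("snp", filter, sum(bad))
    if (any(bad)) {
      X <<- X[, !bad, drop = FALSE]
      map <<- map[!bad, , drop = FALSE]
    }
  }

  ## 1. call rate
  cr <- colMeans(!is.na(X))
  drop_snps(cr < thresholds$call_rate_min, "call_rate")

  ## 2. monomorphic
  p <- colMeans(X, na.rm = TRUE) / 2
  if (thresholds$drop_monomorphic) {
    drop_snps(p == 0 | p == 1, "monomorphic")
  } else {
    log_step("snp", "monomorphic", 0L)
  }

  ## 3. MAF
  p <- colMeans(X, na.rm = TRUE) / 2
  drop_snps(pmin(p, 1 - p) < thresholds$maf_min, "maf")

  ## 4. HWE (1-df chi-square on genotype counts)
  hwe_p <- apply(X, 2, hwe_chisq_p)
  drop_snps(hwe_p < thresholds$hwe_p_min, "hwe")

  ## 5. Mendelian conflicts
  n_conflict_entries <- 0L
  dropped_mendel <- 0L
  if (thresholds$mendel_check && !is.null(pedigree)) {
    ids <- rownames(X)
    ped <- pedigree[pedigree$animal_id %in% ids, , drop = FALSE]
    conflict_count <- setNames(integer(nrow(X)), ids)
    compared <- pmax(ncol(X), 1L)
    for (col in c("sire_id", "dam_id")) {
      off <- ped$animal_id[!is.na(ped[[col]]) & ped[[col]] %in% ids]
      par <- ped[[col]][!is.na(ped[[col]]) & ped[[col]] %in% ids]
      if (!length(off)) next
      o <- X[off, , drop = FALSE]
      q <- X[par, , drop = FALSE]
      conf <- (o == 0 & q == 2) | (o == 2 & q == 0)
      conf[is.na(conf)] <- FALSE
      if (any(conf)) {
        Xo <- X[off, , drop = FALSE]
        Xo[conf] <- NA_real_
        X[off, ] <- Xo
        conflict_count[off] <- conflict_count[off] + rowSums(conf)
        n_conflict_entries <- n_conflict_entries + sum(conf)
      }
    }
    bad_animal <- conflict_count / compared > thresholds$mendel_animal_max
    dropped_mendel <- sum(bad_animal)
    if (dropped_mendel) X <- X[!bad_animal, , drop = FALSE]
  }
  log_step("animal", "mendel", dropped_mendel)

  ## 6. duplicate animals on a provisional GRM
  dup_dropped <- 0L
  if (ncol(X) > 0 && nrow(X) > 1) {
    p <- colMeans(X, na.rm = TRUE) / 2
    poly <- p > 0 & p < 1
    if (any(poly)) {
      Ximp <- X[, poly, drop = FALSE]
      pp <- p[poly]
      for (j in seq_len(ncol(Ximp))) {
        miss <- is.na(Ximp[, j])
        if (any(miss)) Ximp[miss, j] <- 2 * pp[j]
      }
      Gprov <- grm_vanraden(Ximp)
      off <- which(Gprov > thresholds$dup_rel_max & upper.tri(Gprov),
                   arr.ind = TRUE)
      if (nrow(off)) {
        drop <- unique(pmax(off[, 1], off[, 2]))
        dup_dropped <- length(drop)
        X <- X[-drop, , drop = FALSE]
      }
    }
  }
  log_step("animal", "duplicate", dup_dropped)

  if (ncol(X) == 0 || nrow(X) == 0) {
    report <- new_qc_report(steps, n_snp0, n_ani0, ncol(X), nrow(X))
    abort("no SNPs/animals survive quality control.",
          class = "rrgwas_qc_empty", report = report)
  }

  ## impute remaining missing dosages to 2p
  p <- colMeans(X, na.rm = TRUE) / 2
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- 2 * p[j]
  }

  report <- new_qc_report(steps, n_snp0, n_ani0, ncol(X), nrow(X))
  list(genotypes = structure(list(dosage = X, map = map), class = "rr_geno"),
       report = report)
}

hwe_chisq_p <- function(g) {
  g <- g[!is.na(g)]
  n <- length(g)
  if (n == 0) return(1)
  obs <- c(sum(g == 0), sum(g == 1), sum(g == 2))
  p <- mean(g) / 2
  exp <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  if (any(exp == 0)) return(1)
  stat <- sum((obs - exp)^2 / exp)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

new_qc_report <- function(steps, n_snp0, n_ani0, n_snp1, n_ani1) {
  structure(
    list(steps = bind_rows(steps),
         input = c(snps = n_snp0, animals = n_ani0),
         surviving = c(snps = n_snp1, animals = n_ani1)),
    class = "rr_qc_report"
  )
}

#' @export
print.rr_qc_report <- function(x, ...) {
  cat(sprintf("<rr_qc_report> %d/%d SNPs, %d/%d animals retained\n",
              x$surviving["snps"], x$input["snps"],
              x$surviving["animals"], x$input["animals"]))
  print(as.data.frame(x$steps), row.names = FALSE)
  invisible(x)
}

#' @method tidy rr_qc_report
#' @export
tidy.rr_qc_report <- function(x, ...) x$steps
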