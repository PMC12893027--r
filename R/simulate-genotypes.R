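#' Simulate SNP genotypes by gene dropping through a pedigree
#'
#' Founder haplotypes are drawn from per-SNP allele frequencies sampled
#' uniformly in `maf_range`; every descendant receives one allele from each
#' parent (independent transmissions per SNP, no linkage). Genotypes are
#' therefore Mendelian-consistent by construction, which makes the
#' Mendelian-conflict QC filter exercisable by corrupting entries
#' afterwards. Missing entries are injected completely at random at
#' `missing_rate`.
#'
#' @param pedigree Pedigree tibble (parents before offspring).
#' @param n_snps Number of SNPs (>= 1).
#' @param maf_range Founder allele-frequency range, within (0, 0.5].
#' @param n_chromosomes SNPs are split over this many chromosomes with
#'   strictly increasing positions within each.
#' @param missing_rate Fraction of entries set to missing (`NA`).
#' @param seed Integer seed.
#' @return An object of class `rr_geno`: a list with `dosage` (animals x
#'   SNPs matrix of alt-allele counts 0/1/2 or `NA`, dimnames = IDs) and
#'   `map` (tibble `snp_id`, `chrom`, `pos`, `ref`, `alt`).
#' @examples
#' ped <- simulate_pedigree(4, 1, seed = 1)
#' g <- simulate_genotypes(ped, n_snps = 10, seed = 1)
#' dim(g$dosage)
#' @export
simulate_genotypes <- function(pedigree, n_snps = 1000,
                               maf_range = c(0.05, 0.5),
                               n_chromosomes = 5, missing_rate = 0,
                               seed = 1L) {
  if (n_snps < 1) abort("`n_snps` must be at least 1.")
  if (!(maf_range[1] > 0 && maf_range[1] <= maf_range[2] &&
        maf_range[2] <= 0.5)) {
    abort("need 0 < maf_low <= maf_high <= 0.5.")
  }
  validate_pedigree(pedigree)
  withr::local_seed(seed)

  n <- nrow(pedigree)
  ids <- pedigree$animal_id
  p <- runif(n_snps, maf_range[1], maf_range[2])

  h1 <- matrix(0L, n, n_snps)
  h2 <- matrix(0L, n, n_snps)
  row_of <- setNames(seq_len(n), ids)
  for (i in seq_len(n)) {
    s <- pedigree$sire_id[i]
    d <- pedigree$dam_id[i]
    if (is.na(s)) {
      h1[i, ] <- rbinom(n_snps, 1L, p)
    } else {
      si <- row_of[[s]]
      pick <- runif(n_snps) < 0.5
      h1[i, ] <- ifelse(pick, h1[si, ], h2[si, ])
    }
    if (is.na(d)) {
      h2[i, ] <- rbinom(n_snps, 1L, p)
    } else {
      di <- row_of[[d]]
      pick <- runif(n_snps) < 0.5
      h2[i, ] <- ifelse(pick, h1[di, ], h2[di, ])
    }
  }
  dosage <- h1 + h2
  if (missing_rate > 0) {
    dosage[runif(length(dosage)) < missing_rate] <- NA_integer_
  }

  snp_ids <- sprintf("snp%05d", seq_len(n_snps))
  dimnames(dosage) <- list(ids, snp_ids)
  chrom <- sort(rep_len(seq_len(n_chromosomes), n_snps))
  pos <- unlist(lapply(split(seq_len(n_snps), chrom), function(ix) {
    cumsum(sample(10000:60000, length(ix), replace = TRUE))
  }), use.names = FALSE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_snps, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  map <- tibble(snp_id = snp_ids, chrom = as.character(chrom), pos = pos,
                ref = ref, alt = unname(alt))

  new_rr_geno(dosage, map)
}

new_rr_geno <- function(dosage, map) {
  stopifnot(ncol(dosage) == nrow(map),
            identical(colnames(dosage), map$snp_id))
  by_chr <- split(map$pos, map$chrom)
  if (any(vapply(by_chr, function(x) any(diff(x) <= 0), TRUE))) {
    abort("positions must be strictly increasing within chromosomes.")
  }
  bad <- !(dosage %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) abort("dosage entries must be 0, 1, 2 or NA.")
  structure(list(dosage = dosage, map = as_tibble(map)), class = "rr_geno")
}

#' @export
print.rr_geno <- function(x, ...) {
  cat(sprintf("<rr_geno> %d animals x %d SNPs on %d chromosome(s), %.2f%% missing\n",
              nrow(x$dosage), ncol(x$dosage),
              length(unique(x$map$chrom)),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}
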