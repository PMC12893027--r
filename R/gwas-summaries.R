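#' Scan-level GWAS summaries
#'
#' Computes, per layer, the genomic inflation factor
#' `lambda = median(observed chi-square) / median(reference chi-square)`
#' (reference medians 0.4549 for 1 df, 1.3863 for 2 df), the Bonferroni
#' (`alpha / n_snps`) and suggestive (`1 / n_snps`, one expected false
#' positive per scan) thresholds, the Pearson correlation between intercept
#' and slope SNP effects, and the per-layer lists of SNPs passing each
#' threshold.
#'
#' @param rows An `rr_gwas` tibble (or any tibble with the layer chi-square
#'   and p-value columns).
#' @param n_snps Number of tests used for the thresholds; defaults to the
#'   number of non-`NA` rows.
#' @param alpha Genome-wide error rate for the Bonferroni threshold.
#' @return An object of class `rr_gwas_summary`.
#' @export
gwas_summaries <- function(rows, n_snps = NULL, alpha = 0.05) {
  if (!nrow(rows)) abort("`rows` must be non-empty.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  n_snps <- n_snps %||% sum(!is.na(rows$p_joint))
  layers <- c(intercept = 1, slope = 1, joint = 2)
  lambda <- vapply(names(layers), function(l) {
    st <- rows[[paste0("chisq_", l)]]
    df <- if (l == "joint" && "degenerate" %in% names(rows)) {
      ifelse(rows$degenerate, 1, layers[[l]])
    } else {
      layers[[l]]
    }
    median(st / qchisq(0.5, df), na.rm = TRUE)
  }, 0)
  bonferroni_p <- alpha / n_snps
  suggestive_p <- 1 / n_snps
  cc <- if (all(c("beta0", "beta1") %in% names(rows))) {
    stats::complete.cases(rows[c("beta0", "beta1")])
  } else {
    FALSE
  }
  r_is <- if (sum(cc) > 2 && sd(rows$beta0[cc]) > 0 && sd(rows$beta1[cc]) > 0) {
    cor(rows$beta0[cc], rows$beta1[cc])
  } else {
    NA_real_
  }
  sig <- lapply(names(layers), function(l) {
    pl <- rows[[paste0("p_", l)]]
    keep <- !is.na(pl) & pl < suggestive_p
    pk <- pl[keep]
    tibble(
      snp_id = if ("snp_id" %in% names(rows)) rows$snp_id[keep] else which(keep),
      p = pk,
      bonferroni = pk < bonferroni_p
    )
  })
  names(sig) <- names(layers)
  structure(
    list(lambda_per_layer = lambda, bonferroni_p = bonferroni_p,
         suggestive_p = suggestive_p, r_intercept_slope = r_is,
         significant = sig, n_snps = n_snps, alpha = alpha),
    class = "rr_gwas_summary"
  )
}

#' @export
print.rr_gwas_summary <- function(x, ...) {
  cat("<rr_gwas_summary>\n")
  cat(sprintf("  lambda: intercept %.3f, slope %.3f, joint %.3f\n",
              x$lambda_per_layer[["intercept"]],
              x$lambda_per_layer[["slope"]],
              x$lambda_per_layer[["joint"]]))
  cat(sprintf("  thresholds (%d SNPs): bonferroni %.3g, suggestive %.3g\n",
              x$n_snps, x$bonferroni_p, x$suggestive_p))
  cat(sprintf("  r(intercept, slope effects) = %.3f\n", x$r_intercept_slope))
  for (l in names(x$significant)) {
    cat(sprintf("  %s: %d suggestive (%d bonferroni)\n", l,
                nrow(x$significant[[l]]), sum(x$significant[[l]]$bonferroni)))
  }
  invisible(x)
}
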