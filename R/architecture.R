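#' Trait architecture for the phenotype simulator
#'
#' Bundles the ground-truth parameters of the generative random-regression
#' model: the 2x2 additive-genetic (`G_a`) and permanent-environment
#' (`P_pe`) coefficient covariances on the Legendre intercept+slope basis, a
#' scalar service-sire variance, the residual variance, fixed-effect class
#' structure, QTL effects, per-parity retention (culling) probabilities and,
#' for binary traits, the liability threshold.
#'
#' Defaults reproduce the three dairy fertility traits the package targets:
#' `NRR56` (binary non-return rate at 56 days, parities 0-6), `CTFS`
#' (calving to first service, days, parities 1-6) and `DO` (days open,
#' days, parities 1-6), with low heritabilities, a service-sire variance for
#' NRR56 and DO only, and record counts that decline with parity. Variance
#' components are interpreted on the normalized Legendre coefficient scale.
#'
#' @param trait One of `"NRR56"`, `"CTFS"`, `"DO"`.
#' @param G_a,P_pe 2x2 symmetric PSD coefficient covariance matrices
#'   (intercept, slope).
#' @param var_s,var_e Service-sire and residual variances (`var_s = 0`
#'   drops the effect).
#' @param qtl Tibble of planted QTL with columns `snp` (SNP id or column
#'   index), `beta_intercept`, `beta_slope` (trait units per alt-allele
#'   dosage). Empty by default: a purely polygenic trait.
#' @param n_hys,n_age_classes Numbers of herd-year-season and
#'   insemination-age classes.
#' @param sd_hys,sd_age Standard deviations of the class effects.
#' @param mean_intercept,mean_slope Fixed regression of the population mean
#'   on the (normalized) basis.
#' @param parity_survival Per-parity retention probabilities (length
#'   `t_max - t_min`); probability that an animal with records up to parity
#'   `t` also has a record at `t + 1`.
#' @param binary Threshold the Gaussian liability into 0/1?
#' @param threshold Liability threshold for binary traits.
#' @param t_min,t_max Parity range of the trait.
#' @param n_service_sires Size of the service-sire pool.
#' @param seed Default seed used by [simulate_phenotypes()] when none is
#'   supplied there.
#' @return An object of class `rr_arch`.
#' @examples
#' trait_architecture("DO")
#' @export
trait_architecture <- function(trait = c("DO", "CTFS", "NRR56"),
                               G_a = NULL, P_pe = NULL,
                               var_s = NULL, var_e = NULL,
                               qtl = NULL,
                               n_hys = 25, n_age_classes = 8,
                               sd_hys = NULL, sd_age = NULL,
                               mean_intercept = NULL, mean_slope = NULL,
                               parity_survival = NULL,
                               binary = NULL, threshold = 0,
                               t_min = NULL, t_max = 6,
                               n_service_sires = 50,
                               seed = 1L) {
  trait <- match.arg(trait)
  def <- switch(trait,
    NRR56 = list(
      G_a = matrix(c(0.0033, 0.0013, 0.0013, 0.0006), 2),
      P_pe = matrix(c(0.0048, 0.0040, 0.0040, 0.0034), 2),
      var_s = 0.0023, var_e = 0.2235,
      mean_intercept = 0.1512, mean_slope = -0.1279,
      binary = TRUE, t_min = 0,
      parity_survival = c(0.90, 0.75, 0.65, 0.55, 0.50, 0.45)
    ),
    CTFS = list(
      G_a = matrix(c(16.43, 2.56, 2.56, 8.15), 2),
      P_pe = matrix(c(58.19, 29.41, 29.41, 19.09), 2),
      var_s = 0, var_e = 411.87,
      mean_intercept = 111.94, mean_slope = 1.686,
      binary = FALSE, t_min = 1,
      parity_survival = c(0.74, 0.68, 0.55, 0.50, 0.45)
    ),
    DO = list(
      G_a = matrix(c(128.04, 69.83, 69.83, 63.69), 2),
      P_pe = matrix(c(67.88, 92.91, 92.91, 138.67), 2),
      var_s = 19.41, var_e = 2576.88,
      mean_intercept = 174.08, mean_slope = 4.625,
      binary = FALSE, t_min = 1,
      parity_survival = c(0.70, 0.68, 0.50, 0.46, 0.41)
    )
  )
  G_a <- G_a %||% def$G_a
  P_pe <- P_pe %||% def$P_pe
  var_s <- var_s %||% def$var_s
  var_e <- var_e %||% def$var_e
  binary <- binary %||% def$binary
  t_min <- t_min %||% def$t_min
  mean_intercept <- mean_intercept %||% def$mean_intercept
  mean_slope <- mean_slope %||% def$mean_slope
  parity_survival <- parity_survival %||% def$parity_survival
  sd_hys <- sd_hys %||% (0.10 * sqrt(var_e))
  sd_age <- sd_age %||% (0.05 * sqrt(var_e))
  qtl <- qtl %||% tibble(snp = integer(), beta_intercept = double(),
                         beta_slope = double())

  check_psd <- function(M, nm) {
    if (!isTRUE(all.equal(M, t(M))) || any(eigen(M, TRUE, TRUE)$values < -1e-10)) {
      abort(sprintf("`%s` must be symmetric positive semi-definite.", nm))
    }
  }
  check_psd(G_a, "G_a"); check_psd(P_pe, "P_pe")
  if (var_s < 0 || var_e < 0) abort("`var_s` and `var_e` must be >= 0.")
  if (length(parity_survival) != t_max - t_min) {
    abort("`parity_survival` must have one entry per parity transition.")
  }
  if (any(parity_survival <= 0 | parity_survival > 1)) {
    abort("retention probabilities must lie in (0, 1].")
  }

  structure(
    list(trait = trait, G_a = G_a, P_pe = P_pe, var_s = var_s, var_e = var_e,
         qtl = as_tibble(qtl), n_hys = n_hys, n_age_classes = n_age_classes,
         sd_hys = sd_hys, sd_age = sd_age,
         mean_intercept = mean_intercept, mean_slope = mean_slope,
         parity_survival = parity_survival, binary = binary,
         threshold = threshold, t_min = t_min, t_max = t_max,
         n_service_sires = n_service_sires, seed = seed),
    class = "rr_arch"
  )
}

#' @export
print.rr_arch <- function(x, ...) {
  cat(sprintf("<rr_arch> %s, parities %d..%d%s\n", x$trait, x$t_min, x$t_max,
              if (x$binary) " (binary liability)" else ""))
  cat(sprintf("  var_a1 %.4g  cov_a %.4g  var_a2 %.4g\n",
              x$G_a[1, 1], x$G_a[1, 2], x$G_a[2, 2]))
  cat(sprintf("  var_p1 %.4g  cov_p %.4g  var_p2 %.4g\n",
              x$P_pe[1, 1], x$P_pe[1, 2], x$P_pe[2, 2]))
  cat(sprintf("  var_s %.4g  var_e %.4g  qtl %d\n",
              x$var_s, x$var_e, nrow(x$qtl)))
  invisible(x)
}
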