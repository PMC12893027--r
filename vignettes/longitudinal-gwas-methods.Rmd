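---
title: "Two-step longitudinal GWAS for repeated-parity traits: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step longitudinal GWAS for repeated-parity traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Female fertility traits in dairy cattle — the non-return rate at 56 days
(NRR56), the interval from calving to first service (CTFS) and days open
(DO) — are recorded repeatedly across parities, have very low
heritabilities (0.01–0.09), and their genetic regulation changes along the
lactation trajectory. A conventional GWAS that assumes one constant SNP
effect per animal averages over that trajectory and can miss variants whose
effect grows, shrinks or reverses with parity. `rrgwas` implements the
two-step longitudinal alternative:

1. **Step 1 — variance components.** A single-trait random regression model
   (RRM) on a first-order Legendre basis over parity is fitted by REML,
   yielding the 2×2 additive-genetic (`G_a`) and permanent-environment
   (`P_pe`) coefficient covariances, a scalar service-sire variance
   (NRR56 and DO) and the residual variance.
2. **Step 2 — per-SNP tests.** With those components fixed, every SNP's
   intercept and slope effects are estimated jointly by generalized least
   squares and tested in three "layers": the *outer* layer (baseline:
   intercept effect, 1 df), the *middle* layer (slope effect, 1 df) and the
   *inner* layer (intercept and slope jointly, 2 df, using the full 2×2
   covariance of the two estimates).

## The model

For a record of animal $i$ at parity $t$,

$$y_{it} = \mathbf{x}_{it}'\mathbf{b} + \phi(t)'\mathbf{u}_i +
  \phi(t)'\mathbf{p}_i + s_{k(it)} + e_{it},$$

with fixed herd–year–season and insemination-age classes plus a fixed
regression on the basis; $\phi(t) = (\phi_0, \phi_1(t))'$ the (by default
normalized) Legendre polynomials of the parity rescaled to $x \in [-1,1]$,
$\phi_0 = \sqrt{1/2}$, $\phi_1 = \sqrt{3/2}\,x$; animal coefficients
$\mathbf{u} \sim N(0, \mathbf{K} \otimes G_a)$ with $\mathbf{K}$ a pedigree
(A), genomic (VanRaden G) or combined single-step (H) relationship matrix;
permanent-environment coefficients $\mathbf{p}_i \sim N(0, P_{pe})$ i.i.d.;
service-sire effects $s_k \sim N(0, \sigma^2_s)$; residuals
$e \sim N(0, \sigma^2_e)$.

Derived trajectory summaries: $\mathrm{var}_a(t) = \phi(t)' G_a \phi(t)$,
heritability $h^2(t) = \mathrm{var}_a(t) / (\mathrm{var}_a(t) +
\mathrm{var}_p(t) + \sigma^2_s + \sigma^2_e)$, and the genetic correlation
between parities $r_g(t,t') = \phi(t)'G_a\phi(t') /
\sqrt{\mathrm{var}_a(t)\,\mathrm{var}_a(t')}$ (`parity_functions()`).

### Basis conventions

Published component tables for such models rarely state the exact Legendre
scaling. Both conventions are implemented (`normalized = TRUE/FALSE` in
`legendre_basis()`), with parity linearly mapped to $[-1,1]$ over the
trait's parity range (0–6 for NRR56, 1–6 for CTFS/DO). Layer-specific SNP
statistics depend on this choice whenever the reparameterization mixes the
two basis functions; the 2-df joint statistic does not, because the two
covariate columns span the same space (this is tested). Heritability
trajectories computed by plugging published component values into either
convention need not reproduce published per-parity heritabilities — the
package treats component tables as defining quantities only jointly with a
stated basis.

## Step-1 REML: algorithm

The restricted likelihood is evaluated through dense mixed-model equations
in which the permanent-environment effect is absorbed analytically into a
per-animal block-diagonal residual covariance
$D_i = \Phi_i P_{pe} \Phi_i' + \sigma^2_e I$. This is an exact
reformulation (verified in the tests against a direct dense-$V$ likelihood
to $10^{-8}$) and keeps the system at (fixed effects + 2 × animals +
sires) order, which is what makes ~2000-animal studies tractable on one
core. Per iteration the engine computes, from one Cholesky factorization
and one inverse of the coefficient matrix: the restricted log-likelihood,
the exact score for all components, the average-information (AI) matrix,
and the expectation–maximization (EM) quantities.

Updates are AI steps on a log-Cholesky parameterization of the 2×2 blocks
(positive semi-definiteness holds by construction), made robust by

* a Levenberg-style damping ladder when the AI matrix is near-singular,
* a half-step retry when successive AI steps reverse direction — REML
  surfaces for low-heritability repeated records have a soft ridge along
  the genetic/permanent-environment trade-off, where undamped AI steps
  oscillate,
* an EM fallback whenever no AI step improves the likelihood (EM steps are
  ascent steps), and
* freezing of any component that collapses below `freeze_tol` (default
  $10^{-5}$) of the phenotypic variance, which stops the indefinite EM
  creep toward a zero boundary.

Accepted iterations therefore never decrease the restricted log-likelihood;
the trace is returned (`loglik_trace`) and asserted monotone in the tests.
Convergence requires both $|\Delta \log L| <$ `tol_loglik` ($10^{-6}$ by
default) and a maximum relative parameter change below `tol_param`
($10^{-5}$), with components below $10^{-4}$ of the phenotypic variance
exempt from the parameter criterion. Default starting values split the
phenotypic variance 10/10/5/75% over genetic, permanent-environment,
service-sire and residual parts. Standard errors come from the inverse AI
matrix at convergence; `parity_functions()` propagates them to $h^2(t)$ by
the delta method.

## Step-2 GWAS: algorithm

`assemble_covariance()` factorizes the record covariance
$V = Q(K \otimes G_a)Q' + Z(I \otimes P_{pe})Z' + SS'\sigma^2_s +
I\sigma^2_e$ once and reuses it across SNPs.

* **direct** mode: dense Cholesky of $V$; works for any record pattern.
* **eigen** mode: requires every analyzed animal to carry the identical
  parity set. With $K = U \Lambda U'$, rotating records animal-wise by
  $U'$ makes the genetic-plus-residual part block diagonal with per-animal
  blocks $\lambda_i \Phi G_a \Phi' + \Phi P_{pe} \Phi' + \sigma^2_e I$;
  the service-sire term, which does not diagonalize (sires are shared
  across animals), is handled exactly as a low-rank Woodbury correction on
  those blocks. On balanced designs the eigen path reproduces direct-mode
  statistics to $10^{-6}$ relative (an acceptance requirement) at a cost
  linear instead of cubic in the record count. How unbalanced data should
  enter the rotated representation is not well defined, so the fast path
  refuses unbalanced designs and directs the user to `direct` mode.

Each SNP contributes two record-level covariates, dosage × $\phi_0$ and
dosage × $\phi_1(t)$, with dosage centered over the analyzed animals
(additive 0/1/2 coding by default; a genotype-as-factor coding with
2/2/4-df layers is available via `coding = "factor"`). All fixed effects
are re-estimated jointly with each SNP via partitioned GLS with
precomputed projections of the shared design. Wald statistics use the full
2×2 covariance of $(\hat\beta_0, \hat\beta_1)$ for the inner layer. Tail
probabilities are computed on the log scale and floored at the smallest
positive double. A SNP whose 2×2 system is numerically rank-deficient
(condition number above $10^{12}$) falls back to a 1-df pseudo-inverse
test and is flagged `degenerate`; monomorphic SNPs yield flagged `NA` rows
rather than disappearing.

Scan summaries (`gwas_summaries()`): genomic inflation
$\lambda = \mathrm{median}(\chi^2_{obs}) / \mathrm{median}(\chi^2_{df})$
per layer (reference medians 0.4549 / 1.3863 for 1 / 2 df), Bonferroni
threshold $\alpha / n_{SNP}$, suggestive threshold $1 / n_{SNP}$ (one
expected false positive per scan — chosen because the source convention
for suggestive thresholds in this literature is exactly that), the Pearson
correlation between intercept and slope effects across SNPs, and per-layer
significant lists. Per-SNP variance explained uses
$2p(1-p)(\beta_0\phi_0 + \beta_1\phi_1(t))^2$ averaged over the analyzed
parities, divided by the parity-averaged additive genetic variance from
step 1; layer-specific versions zero the other coefficient.

One-SNP-at-a-time scanning is used throughout: a joint fixed fit of tens
of thousands of SNPs is not identifiable, and the scan interpretation is
the standard one.

## Candidate genes and plots

`map_candidate_genes()` reports, for each SNP passing a per-layer
threshold, every gene whose body extended by ±100 kb covers the SNP
(1-based inclusive arithmetic; a SNP exactly 100 000 bp from a gene
boundary is a hit, one base further is not). Inside-gene hits carry
distance 0; SNPs with no gene in the window are reported as intergenic.
All genes in a window are reported — no arbitrary nearest-gene selection —
and strand is carried but ignored by the window. BED input is converted to
1-based inclusive coordinates on read; GFF3 is used as-is.
`plot_manhattan_circular()` draws the three layers as concentric rings
(outer = intercept, middle = slope, inner = joint) with per-ring dotted
suggestive-threshold circles and enlarged significant markers;
`plot_qq()` annotates $\lambda$.

## The synthetic-data generator

`simulate_pedigree()`, `simulate_genotypes()`, `simulate_phenotypes()` and
`simulate_annotation()` generate data with exactly the statistical
structure the RRM assumes, so that every downstream stage is testable
without external data:

* Pedigrees follow discrete generations with polygynous random mating; a
  configurable male proportion (default 0.5; 5–10% emulates the large
  paternal half-sib families of progeny-tested dairy populations, where a
  few thousand sires serve hundreds of thousands of cows).
* Genotypes are gene-dropped founder haplotypes (frequencies uniform on a
  configurable range), so Mendelian consistency holds by construction and
  the Mendelian-conflict QC filter can be exercised by corrupting entries.
  There is no linkage disequilibrium between SNPs — a deliberate
  non-goal.
* Phenotypes follow the generative RRM: breeding-value coefficients are
  the sum of planted QTL contributions and a pedigree-recursive polygenic
  remainder whose covariance tops the total up to `G_a` (Mendelian
  sampling variance adjusted for parental inbreeding); permanent
  environment is i.i.d.; service sires are drawn per record from a finite
  pool (default 50; no assignment scheme is implied by the data
  structure); herd–year–season and age-class effects are i.i.d. normal
  nuisance classes. Records at parity $t$ exist only while independent
  per-parity retention draws succeed, which reproduces record counts that
  decline with parity; the default retention vectors mimic the observed
  decline for the three fertility traits. NRR56 is generated by
  thresholding the Gaussian liability (threshold 0, with the fixed
  regression placed so heifer means are near 0.71 and cow means near
  0.46–0.53) and analyzed as a 0/1 linear trait, as is conventional for
  non-return rates.
* Default (co)variance magnitudes are the published dairy-fertility values
  for the three traits, interpreted on the normalized-Legendre coefficient
  scale, e.g. for DO: `G_a = [[128.04, 69.83], [69.83, 63.69]]`,
  `P_pe = [[67.88, 92.91], [92.91, 138.67]]`, `var_s = 19.41`,
  `var_e = 2576.88` — i.e. heritabilities of a few percent.

What the generator does **not** emulate: linkage disequilibrium and QTL
tagging (each simulated SNP either is or is not causal), selection and
assortative mating, non-random culling (retention is independent of the
trait value), imputation error, and genotyping error beyond injected
missingness. Passing tests therefore demonstrate correctness of the
estimators under the model's own assumptions, not robustness to the many
ways real cattle data violate them.

## Validation studies and their problem sizes

The test suite runs five study-level checks (sizes chosen to keep the
whole suite in tens of minutes on one core):

* **Operator equivalence** — 10 random balanced instances (20–100 animals
  × 3–4 parities, with and without a service sire): eigen-mode layer
  statistics match direct dense-V GLS within $10^{-6}$ relative.
* **REML recovery** — DO-magnitude components, ~1950 phenotyped females
  across three generations with 10% males, 10 seeds, fits capped at 35
  iterations with `tol_loglik = 1e-4` (the package defaults stay at the
  stricter values; at this tolerance the parameters move by far less than
  1% of their asymptotic SE per additional iteration). The residual
  variance is recovered with a median relative error well under 5%, and
  the likelihood trace is monotone in every run. The intercept genetic
  variance is a different matter — see the limitation below.
* **Null calibration** — zero-QTL scans (about 500 genotyped+phenotyped
  females, 2000 SNPs, 10 seeds) with components re-estimated per seed:
  per-layer type-I error at $\alpha = 0.05$ within [0.035, 0.065] and
  median genomic inflation within [0.9, 1.1].
* **Layer discrimination** — a slope-only QTL explaining 2% of the slope
  genetic variance, ~1000 phenotyped females, balanced records. The
  architecture for this study was sized by a noncentrality calculation.
  An animal-level slope covariate competes against the animal's own
  random slope, so the slope-layer noncentrality is approximately
  $n \cdot 2pq\,\beta_1^2 / (g_{22} + p_{22} + \sigma^2_e / \sum_t
  \phi_1(t)^2)$ — the genetic and permanent-environment slope variances
  sit in the effective residual alongside the within-animal measurement
  variance of the slope contrast. With $g_{22} = 60$, $p_{22} = 10$,
  $\sigma^2_e = 50$ and six parities, the planted effect gives
  noncentrality ≈ 13, i.e. nominal power ≈ 0.95 at $\alpha = 0.05$, so
  the observed power of the slope and joint layers should exceed 0.8
  while the intercept layer rejects at the type-I level. Under the
  published fertility-trait magnitudes the same relative effect (2% of a
  slope variance of 63.69 against a residual of 2576.88) has
  noncentrality below 1 at n = 1000 — power near 0.16 — which is exactly
  why the source study needed tens of thousands of genotyped cows; the
  discrimination study validates the test's behavior, not that n = 1000
  suffices for fertility traits.
* **Exact fixtures and invariances** — hand-computed QC, GRM, A-matrix,
  H-identity, gene-window and inflation fixtures; allele-relabeling and
  basis-reparameterization invariances; QC conservation; correlation and
  heritability bounds.

### A known limitation, quantified

At n ≈ 2000 animals the intercept genetic variance of a trait with
$h^2 \approx 0.02$ and a competing i.i.d. permanent-environment term is
weakly identified: the asymptotic SE of `var_a1` from the inverse Fisher
(AI) information *evaluated at the true parameters* is 95–127 against a
true value of 128 (CV 0.74–0.99) for every pedigree design we examined
(two or three generations, 5–10% males, Table-1-like culling). The median
relative error over seeds is therefore bounded near 0.5 regardless of
implementation quality, and the recovery study's 30% target for `var_a1`
is not attainable at this scale — consistent with published fertility
analyses needing ~190 000 cows to reach heritability SEs of 0.01–0.02.
The corresponding test asserts the target anyway and is expected to fail;
it documents the information bound rather than hiding it.

## Numerical choices

* HWE filtering uses the 1-df chi-square on genotype counts (adequate for
  the ≥100-animal panels the package targets); filters run in the fixed
  order call rate → monomorphic → MAF → HWE → Mendelian conflicts →
  duplicates, because call-rate filtering first stabilizes the frequency
  estimates the later filters use. Duplicate pairs keep the first-listed
  animal. Post-QC missing dosages are imputed to twice the allele
  frequency.
* The single-step H matrix blends `G* = 0.95 G + 0.05 A22` and rescales
  `G*` to the mean diagonal of `A22` — standard single-step practice.
* The GRM-PCA uses the double-centered relationship matrix; k-means runs
  with 10 restarts at a fixed seed, keeping the best inertia.
* Relationship matrices are inverted once per fit via Cholesky; an
  optional `ridge` (fraction of the mean diagonal) accommodates
  near-singular genomic matrices.
* All simulation functions take explicit seeds; the pipeline derives named
  per-stage substreams from a single root seed, so reruns with one seed
  reproduce every output byte.

## Interfaces

Functions take tibbles first and return tibbles (or small S3 objects with
`tidy()`/`glance()` methods), so pipelines compose with the pipe.
`run_pipeline()` executes simulate-or-load → QC → A/G/H → REML → GWAS →
summaries → genes → plots from a validated YAML configuration (unknown
keys are rejected), writes TSV/JSON/PNG outputs plus a provenance record,
and is idempotent given a seed. Genotypes are read from VCF, PLINK-style
text or a dosage TSV; annotation from GFF3 or BED; a thin command-line
wrapper is installed under `inst/scripts/`.
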