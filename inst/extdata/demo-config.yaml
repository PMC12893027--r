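# Demo configuration: simulate a small days-open study end-to-end.
# Run with: run_pipeline(system.file("extdata", "demo-config.yaml",
#                                    package = "rrgwas"))
version: 1
seed: 11
trait: DO
simulate:
  n_founders: 60
  n_generations: 2
  offspring_per_mating: 2
  n_snps: 300
  n_chromosomes: 3
  missing_rate: 0.01
  n_genes: 25
  n_qtl: 2
basis:
  t_min: 1
  t_max: 6
  normalized: true
qc:
  maf_min: 0.05
  call_rate_min: 0.9
  hwe_p_min: 1.0e-6
  dup_rel_max: 0.95
reml:
  max_iter: 25
  tol_loglik: 1.0e-4
  tol_param: 1.0e-3
gwas:
  mode: direct
  coding: dosage
alpha: 0.05
window_bp: 100000
paths:
  out_dir: rrgwas-demo-output
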