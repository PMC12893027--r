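#' Run the full two-step longitudinal GWAS pipeline
#'
#' Executes, in order: input simulation (when the config has a `simulate`
#' block) or loading; genotype QC; pedigree (A), genomic (G) and combined
#' (H) relationship matrices; PCA/k-means stratification check; REML
#' variance components on H over all phenotyped animals; the longitudinal
#' GWAS over the genotyped-and-phenotyped subset with G; scan summaries;
#' candidate-gene windowing; and plots. Results and a provenance record
#' (config copy, seed, package version, per-stage wall time, config hash)
#' are written under the configured output directory; a rerun with the
#' same config and seed reproduces the outputs.
#'
#' @param config An `rr_config`, a path to a YAML config, or a list.
#' @param seed Optional root-seed override.
#' @return Invisibly, a result bundle: inputs, QC report, relationship
#'   matrices, the REML fit, the GWAS table, summaries, candidate hits and
#'   stage timings.
#' @export
run_pipeline <- function(config, seed = NULL) {
  cfg <- if (inherits(config, "rr_config")) config else load_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  out_dir <- cfg$paths$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- withCallingHandlers(
      tryCatch(force(expr), error = function(e) {
        abort(sprintf("pipeline stage '%s' failed: %s", name,
                      conditionMessage(e)), parent = e)
      })
    )
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    inform(sprintf("stage %-12s %.1fs", name, timings[[name]]))
    res
  }

  inputs <- stage("inputs", {
    if (!is.null(cfg$simulate)) {
      simulate_inputs(cfg, out_dir)
    } else {
      load_inputs(cfg)
    }
  })

  qc <- stage("qc", {
    thr <- do.call(qc_thresholds, cfg$qc %||% list())
    qc_filter(inputs$genotypes, inputs$pedigree, thr)
  })
  readr::write_tsv(qc$report$steps, file.path(out_dir, "qc_report.tsv"))

  rel <- stage("relmat", {
    A <- a_matrix(inputs$pedigree)
    G <- grm_vanraden(qc$genotypes)
    H <- h_matrix(A, G)
    pca <- pca_kmeans(G, seed = stage_seed(cfg$seed, "pca"))
    list(A = A, G = G, H = H, pca = pca)
  })

  basis <- if (!is.null(cfg$basis)) {
    legendre_basis(cfg$basis$t_min, cfg$basis$t_max,
                   cfg$basis$normalized %||% TRUE)
  } else if (cfg$trait == "NRR56") {
    legendre_basis(0, 6)
  } else {
    legendre_basis(1, 6)
  }
  spec <- rr_model_spec(cfg$trait, basis)

  fit <- stage("varcomp", {
    opts <- do.call(reml_options, cfg$reml %||% list())
    reml_rrm(inputs$phenotypes, rel$H, spec, opts)
  })
  write_varcomp_tsv(fit, file.path(out_dir, "varcomp.tsv"))

  gwas <- stage("gwas", {
    run_gwas(inputs$phenotypes, qc$genotypes, fit, rel$G, spec,
             mode = cfg$gwas$mode, coding = cfg$gwas$coding)
  })
  readr::write_tsv(as_tibble(gwas), file.path(out_dir, "gwas_results.tsv"))

  summ <- stage("summaries", gwas_summaries(gwas, alpha = cfg$alpha))
  jsonlite::write_json(
    list(lambda = as.list(summ$lambda_per_layer),
         bonferroni_p = summ$bonferroni_p, suggestive_p = summ$suggestive_p,
         r_intercept_slope = summ$r_intercept_slope),
    file.path(out_dir, "gwas_summary.json"), auto_unbox = TRUE, digits = NA)

  hits <- NULL
  if (!is.null(inputs$annotation)) {
    hits <- stage("genes", {
      map_candidate_genes(gwas, inputs$annotation,
                          threshold_p = summ$suggestive_p,
                          window_bp = cfg$window_bp)
    })
    readr::write_tsv(hits, file.path(out_dir, "candidate_genes.tsv"))
  }

  stage("plots", render_plots(gwas, summ, file.path(out_dir, "plots")))

  provenance <- list(
    config = unclass(cfg),
    config_hash = rlang::hash(unclass(cfg)),
    seed = cfg$seed,
    package_version = as.character(packageVersion("rrgwas")),
    stage_seconds = timings
  )
  yaml::write_yaml(provenance, file.path(out_dir, "provenance.yaml"))

  invisible(list(inputs = inputs, qc = qc, relationships = rel, fit = fit,
                 gwas = gwas, summary = summ, hits = hits,
                 timings = timings, config = cfg))
}

simulate_inputs <- function(cfg, out_dir) {
  s <- cfg$simulate
  ped <- simulate_pedigree(
    n_founders = s$n_founders %||% 60,
    n_generations = s$n_generations %||% 2,
    offspring_per_mating = s$offspring_per_mating %||% 2,
    seed = stage_seed(cfg$seed, "pedigree"))
  gen <- simulate_genotypes(
    ped, n_snps = s$n_snps %||% 500,
    maf_range = c(s$maf_low %||% 0.05, s$maf_high %||% 0.5),
    n_chromosomes = s$n_chromosomes %||% 3,
    missing_rate = s$missing_rate %||% 0.01,
    seed = stage_seed(cfg$seed, "genotypes"))
  arch <- trait_architecture(cfg$trait)
  if (!is.null(s$n_qtl) && s$n_qtl > 0) {
    qsnp <- seq(1, ncol(gen$dosage), length.out = s$n_qtl)
    sc <- sqrt(diag(arch$G_a) / (2 * s$n_qtl))
    arch <- trait_architecture(
      cfg$trait,
      qtl = tibble(snp = as.integer(qsnp),
                   beta_intercept = sc[1], beta_slope = sc[2]))
  }
  sim <- simulate_phenotypes(ped, gen, arch,
                             seed = stage_seed(cfg$seed, "phenotypes"))
  ann <- simulate_annotation(gen$map, n_genes = s$n_genes %||% 40,
                             seed = stage_seed(cfg$seed, "annotation"))
  write_pedigree_csv(ped, file.path(out_dir, "pedigree.csv"))
  write_phenotypes_csv(sim$phenotypes, file.path(out_dir, "phenotypes.csv"))
  write_vcf(gen, file.path(out_dir, "genotypes.vcf"))
  write_gff3(ann, file.path(out_dir, "annotation.gff3"))
  write_truth_tsv(sim, file.path(out_dir, "truth.tsv"))
  list(genotypes = gen, pedigree = ped, phenotypes = sim$phenotypes,
       annotation = ann, sim = sim)
}
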