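#' Load and validate a pipeline configuration
#'
#' Configurations are YAML with a versioned schema; unknown keys are
#' rejected outright so typos fail fast. Referenced input paths must exist
#' at load time (unless the run simulates its own inputs).
#'
#' @param path Path to a YAML configuration file, or a list already parsed.
#' @return A validated config list of class `rr_config`.
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  schema <- list(
    version = NULL, seed = NULL, trait = NULL, window_bp = NULL,
    alpha = NULL,
    paths = list(genotypes = NULL, pedigree = NULL, phenotypes = NULL,
                 annotation = NULL, out_dir = NULL),
    simulate = list(n_founders = NULL, n_generations = NULL,
                    offspring_per_mating = NULL, n_snps = NULL,
                    n_chromosomes = NULL, maf_low = NULL, maf_high = NULL,
                    missing_rate = NULL, n_genes = NULL, n_qtl = NULL),
    basis = list(t_min = NULL, t_max = NULL, normalized = NULL),
    qc = list(maf_min = NULL, call_rate_min = NULL, hwe_p_min = NULL,
              dup_rel_max = NULL, mendel_check = NULL,
              drop_monomorphic = NULL, mendel_animal_max = NULL),
    reml = list(max_iter = NULL, tol_loglik = NULL, tol_param = NULL,
                n_em = NULL, ridge = NULL, verbose = NULL),
    gwas = list(mode = NULL, coding = NULL, chunk_size = NULL)
  )
  check_keys <- function(x, sch, where) {
    unknown <- setdiff(names(x), names(sch))
    if (length(unknown)) {
      abort(sprintf("unknown configuration key(s) %s%s",
                    paste(unknown, collapse = ", "),
                    if (nzchar(where)) sprintf(" under '%s'", where) else ""))
    }
    for (k in names(x)) {
      if (is.list(sch[[k]]) && is.list(x[[k]])) {
        check_keys(x[[k]], sch[[k]], paste0(where, if (nzchar(where)) "." else "", k))
      }
    }
  }
  check_keys(cfg, schema, "")
  if (is.null(cfg$version)) cfg$version <- 1
  if (cfg$version != 1) abort("unsupported configuration version.")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$trait)) abort("`trait` is required.")
  if (is.null(cfg$window_bp)) cfg$window_bp <- 100000
  if (is.null(cfg$alpha)) cfg$alpha <- 0.05
  if (is.null(cfg$gwas$mode)) cfg$gwas$mode <- "direct"
  if (is.null(cfg$gwas$coding)) cfg$gwas$coding <- "dosage"
  if (is.null(cfg$paths$out_dir)) cfg$paths$out_dir <- "rrgwas-output"
  if (is.null(cfg$simulate)) {
    for (k in c("genotypes", "pedigree", "phenotypes")) {
      pth <- cfg$paths[[k]]
      if (is.null(pth)) abort(sprintf("paths$%s is required without `simulate`.", k))
      if (!file.exists(pth)) abort(sprintf("input path does not exist: %s", pth))
    }
  }
  class(cfg) <- c("rr_config", "list")
  cfg
}

#' Load the pipeline inputs declared in a configuration
#'
#' Reads genotypes (VCF, `.ped`/`.map` or dosage TSV, chosen by file
#' extension), pedigree and phenotype CSVs and the optional annotation
#' (GFF3 or BED), cross-validates the ID sets and logs a manifest of
#' row/column counts.
#'
#' @param config An `rr_config` (or path to one).
#' @return A list: `genotypes`, `pedigree`, `phenotypes`, `annotation`.
#' @export
load_inputs <- function(config) {
  cfg <- if (inherits(config, "rr_config")) config else load_config(config)
  gpath <- cfg$paths$genotypes
  genotypes <- if (grepl("\\.vcf(\\.gz)?$", gpath)) {
    read_vcf(gpath)
  } else if (grepl("\\.ped$", gpath)) {
    read_plink(gpath)
  } else {
    read_dosage_tsv(gpath)
  }
  pedigree <- read_pedigree_csv(cfg$paths$pedigree)
  phenotypes <- read_phenotypes_csv(cfg$paths$phenotypes)
  annotation <- NULL
  if (!is.null(cfg$paths$annotation)) {
    annotation <- if (grepl("\\.bed$", cfg$paths$annotation)) {
      read_bed(cfg$paths$annotation)
    } else {
      read_gff3(cfg$paths$annotation)
    }
  }
  not_in_ped <- setdiff(unique(phenotypes$animal_id), pedigree$animal_id)
  if (length(not_in_ped)) {
    abort(sprintf("%d phenotyped animals missing from the pedigree (e.g. %s)",
                  length(not_in_ped), paste(head(not_in_ped, 5), collapse = ", ")))
  }
  inform(sprintf(
    "loaded %d animals x %d SNPs, %d pedigree rows, %d phenotype records%s",
    nrow(genotypes$dosage), ncol(genotypes$dosage), nrow(pedigree),
    nrow(phenotypes),
    if (!is.null(annotation)) sprintf(", %d genes", nrow(annotation)) else ""))
  list(genotypes = genotypes, pedigree = pedigree,
       phenotypes = phenotypes, annotation = annotation)
}

## named per-stage substreams derived from the root seed
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1000003 + h * 7919) %% 2147483647)
}
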