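#' Simulate a gene annotation over a SNP map
#'
#' Places genes on the chromosomes of a SNP map such that the candidate-gene
#' window logic downstream has positive and negative cases: roughly a third
#' of the genes are centred on a SNP (inside-gene hits), a third start
#' within the 100 kb flank of a SNP, and a third are placed well beyond any
#' window.
#'
#' @param map SNP map tibble (`snp_id`, `chrom`, `pos`), e.g.
#'   `genotypes$map`.
#' @param n_genes Number of genes to place.
#' @param length_range Gene length range in bp.
#' @param seed Integer seed.
#' @return A tibble of class `rr_annotation` columns: `gene_id`, `chrom`,
#'   `start`, `end`, `strand` (1-based inclusive coordinates).
#' @examples
#' ped <- simulate_pedigree(4, 1, seed = 1)
#' g <- simulate_genotypes(ped, n_snps = 50, seed = 1)
#' simulate_annotation(g$map, n_genes = 10, seed = 1)
#' @export
simulate_annotation <- function(map, n_genes = 50,
                                length_range = c(5000, 80000), seed = 1L) {
  if (!nrow(map)) abort("`map` must be non-empty.")
  withr::local_seed(seed)
  if (n_genes == 0) {
    return(new_rr_annotation(tibble(
      gene_id = character(), chrom = character(),
      start = integer(), end = integer(), strand = character()
    )))
  }
  anchor <- map[sample(nrow(map), n_genes, replace = TRUE), ]
  len <- sample(length_range[1]:length_range[2], n_genes, replace = TRUE)
  kind <- sample(c("spanning", "flank", "far"), n_genes, replace = TRUE)
  offset <- dplyr::case_when(
    kind == "spanning" ~ -len %/% 2L,
    kind == "flank" ~ sample(1000:99000, n_genes, replace = TRUE),
    TRUE ~ 150000L + sample(0:200000, n_genes, replace = TRUE)
  )
  start <- pmax(anchor$pos + offset, 1L)
  genes <- tibble(
    gene_id = sprintf("GENE%04d", seq_len(n_genes)),
    chrom = anchor$chrom,
    start = as.integer(start),
    end = as.integer(start + len - 1L),
    strand = sample(c("+", "-"), n_genes, replace = TRUE)
  )
  new_rr_annotation(genes)
}

new_rr_annotation <- function(genes) {
  genes <- as_tibble(genes)
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  if (!"strand" %in% names(genes)) genes$strand <- "+"
  if (any(genes$start > genes$end)) abort("gene start must be <= end.")
  if (anyDuplicated(genes$gene_id)) abort("gene IDs must be unique.")
  class(genes) <- c("rr_annotation", class(genes))
  genes
}
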