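#' Map significant SNPs to candidate genes
#'
#' For every SNP whose layer p-value falls below `threshold_p`, reports all
#' genes on the same chromosome whose body, extended by `window_bp` on each
#' side, covers the SNP position (1-based inclusive arithmetic, so a SNP
#' exactly `window_bp` away is a hit and one base further is not). A SNP
#' inside the gene body has `inside_gene = TRUE` and `distance_bp = 0`;
#' flanking hits carry the distance to the nearest gene boundary. SNPs with
#' no gene in the window are reported as intergenic (`gene_id = NA`).
#' Strand is carried through but does not affect the window.
#'
#' @param rows GWAS result tibble (needs `snp_id`, `chrom`, `pos` and the
#'   per-layer p-value columns).
#' @param annotation Gene annotation tibble (`gene_id`, `chrom`, `start`,
#'   `end`, optional `strand`; 1-based inclusive).
#' @param threshold_p Significance threshold; defaults to the suggestive
#'   threshold `1 / n_snps`.
#' @param window_bp Flank size in bp (default 100 kb).
#' @param layers Which layers to scan (default all three).
#' @return A tibble of candidate hits: `layer`, `snp_id`, `chrom`,
#'   `snp_pos`, `p`, `gene_id`, `gene_start`, `gene_end`, `strand`,
#'   `inside_gene`, `distance_bp`.
#' @export
map_candidate_genes <- function(rows, annotation, threshold_p = NULL,
                                window_bp = 100000,
                                layers = c("intercept", "slope", "joint")) {
  ann <- as_tibble(annotation)
  threshold_p <- threshold_p %||% (1 / sum(!is.na(rows$p_joint)))
  if (nrow(ann) && !any(unique(rows$chrom) %in% unique(ann$chrom))) {
    abort(sprintf(
      "chromosome names do not match: results use {%s}, annotation uses {%s}",
      paste(sort(unique(rows$chrom)), collapse = ", "),
      paste(sort(unique(ann$chrom)), collapse = ", ")))
  }
  hits <- list()
  for (l in layers) {
    p <- rows[[paste0("p_", l)]]
    sig <- rows[!is.na(p) & p < threshold_p, , drop = FALSE]
    pv <- p[!is.na(p) & p < threshold_p]
    if (!nrow(sig)) next
    for (i in seq_len(nrow(sig))) {
      g <- ann[ann$chrom == sig$chrom[i] &
                 ann$start - window_bp <= sig$pos[i] &
                 sig$pos[i] <= ann$end + window_bp, , drop = FALSE]
      if (!nrow(g)) {
        hits[[length(hits) + 1]] <- tibble(
          layer = l, snp_id = sig$snp_id[i], chrom = sig$chrom[i],
          snp_pos = sig$pos[i], p = pv[i], gene_id = NA_character_,
          gene_start = NA_integer_, gene_end = NA_integer_,
          strand = NA_character_, inside_gene = FALSE,
          distance_bp = NA_integer_)
      } else {
        inside <- g$start <= sig$pos[i] & sig$pos[i] <= g$end
        dist <- ifelse(inside, 0L,
                       pmin(abs(sig$pos[i] - g$start),
                            abs(sig$pos[i] - g$end)))
        hits[[length(hits) + 1]] <- tibble(
          layer = l, snp_id = sig$snp_id[i], chrom = sig$chrom[i],
          snp_pos = sig$pos[i], p = pv[i], gene_id = g$gene_id,
          gene_start = g$start, gene_end = g$end,
          strand = if ("strand" %in% names(g)) g$strand else NA_character_,
          inside_gene = inside, distance_bp = as.integer(dist))
      }
    }
  }
  if (!length(hits)) {
    return(tibble(layer = character(), snp_id = character(),
                  chrom = character(), snp_pos = integer(), p = double(),
                  gene_id = character(), gene_start = integer(),
                  gene_end = integer(), strand = character(),
                  inside_gene = logical(), distance_bp = integer()))
  }
  bind_rows(hits)
}
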