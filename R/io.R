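#' @name rrgwas-io
#' @title Readers and writers for the pipeline's file formats
#'
#' @description Genotypes move as VCF (GT field; `./.` becomes missing),
#' PLINK-style text `.ped`/`.map` pairs, or a dosage TSV with a side-car
#' map; pedigree and phenotypes as CSV (unknown parents written as
#' `UNKNOWN`); gene annotation as GFF3 (1-based inclusive) or BED6
#' (0-based half-open, converted on read); relationship matrices and GWAS
#' results as TSV.
NULL

unknown_token <- "UNKNOWN"

#' @rdname rrgwas-io
#' @param pedigree,path Pedigree tibble and file path.
#' @export
write_pedigree_csv <- function(pedigree, path) {
  out <- pedigree
  out$sire_id[is.na(out$sire_id)] <- unknown_token
  out$dam_id[is.na(out$dam_id)] <- unknown_token
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname rrgwas-io
#' @export
read_pedigree_csv <- function(path) {
  ped <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c",
                                                 generation = "i"))
  ped$sire_id[ped$sire_id == unknown_token] <- NA_character_
  ped$dam_id[ped$dam_id == unknown_token] <- NA_character_
  validate_pedigree(ped)
  ped
}

#' @rdname rrgwas-io
#' @param phenotypes Phenotype tibble.
#' @export
write_phenotypes_csv <- function(phenotypes, path) {
  readr::write_csv(phenotypes, path)
  invisible(path)
}

#' @rdname rrgwas-io
#' @param trait_ranges Named list of legal `(min, max)` parity ranges used
#'   for validation.
#' @export
read_phenotypes_csv <- function(path,
                                trait_ranges = list(NRR56 = c(0, 6),
                                                    CTFS = c(1, 6),
                                                    DO = c(1, 6))) {
  ph <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          animal_id = "c", trait = "c", parity = "i",
                          value = "d", .default = "c"))
  for (tr in intersect(unique(ph$trait), names(trait_ranges))) {
    rng <- trait_ranges[[tr]]
    bad <- ph$trait == tr & (ph$parity < rng[1] | ph$parity > rng[2])
    if (any(bad)) {
      abort(sprintf(
        "%d %s record(s) have parity outside [%d, %d] (first offending row %d)",
        sum(bad), tr, rng[1], rng[2], which(bad)[1]))
    }
  }
  ph
}

#' @rdname rrgwas-io
#' @param genotypes An `rr_geno` object.
#' @export
write_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "rr_geno"))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  D <- genotypes$dosage
  ids <- rownames(D)
  map <- genotypes$map
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=rrgwas",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(map)), function(j) {
    g <- D[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    paste(c(map$chrom[j], map$pos[j], map$snp_id[j], map$ref[j], map$alt[j],
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, "")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' @rdname rrgwas-io
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- gsub("\\|", "/", gt)
  count_alt <- function(x) {
    ifelse(is.na(x) | x %in% c("./.", "."), NA_integer_,
           stringr::str_count(x, "1"))
  }
  dosage <- matrix(count_alt(alleles), nrow = nrow(alleles))
  dosage <- t(dosage)  # animals x snps
  rownames(dosage) <- colnames(gt)
  colnames(dosage) <- v@fix[, "ID"]
  map <- tibble(snp_id = v@fix[, "ID"], chrom = v@fix[, "CHROM"],
                pos = as.integer(v@fix[, "POS"]), ref = v@fix[, "REF"],
                alt = v@fix[, "ALT"])
  new_rr_geno(dosage, map)
}

#' @rdname rrgwas-io
#' @param map_path Side-car map TSV path (defaults to `<path>.map`).
#' @export
write_dosage_tsv <- function(genotypes, path, map_path = paste0(path, ".map")) {
  stopifnot(inherits(genotypes, "rr_geno"))
  df <- as.data.frame(genotypes$dosage)
  df <- cbind(animal_id = rownames(genotypes$dosage), df)
  readr::write_tsv(as_tibble(df), path)
  readr::write_tsv(genotypes$map, map_path)
  invisible(path)
}

#' @rdname rrgwas-io
#' @export
read_dosage_tsv <- function(path, map_path = paste0(path, ".map")) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  map <- readr::read_tsv(map_path, show_col_types = FALSE,
                         col_types = readr::cols(snp_id = "c", chrom = "c",
                                                 pos = "i", .default = "c"))
  D <- as.matrix(df[, -1])
  storage.mode(D) <- "integer"
  rownames(D) <- df[[1]]
  new_rr_geno(D, map)
}

#' @rdname rrgwas-io
#' @param ped_path,map_path2 PLINK-style `.ped` and `.map` paths. Dosages
#'   count copies of the minor allele; `0 0` is missing.
#' @export
read_plink <- function(ped_path, map_path2 = sub("\\.ped$", ".map", ped_path)) {
  mp <- read.table(map_path2, header = FALSE,
                   col.names = c("chrom", "snp_id", "cm", "pos"),
                   colClasses = c("character", "character", "numeric",
                                  "integer"))
  pd <- read.table(ped_path, header = FALSE, colClasses = "character")
  n_snps <- nrow(mp)
  if (ncol(pd) != 6 + 2 * n_snps) {
    abort(sprintf(".ped has %d columns; expected %d for %d SNPs.",
                  ncol(pd), 6 + 2 * n_snps, n_snps))
  }
  ids <- pd[[2]]
  dosage <- matrix(NA_integer_, nrow(pd), n_snps,
                   dimnames = list(ids, mp$snp_id))
  ref <- alt <- character(n_snps)
  for (j in seq_len(n_snps)) {
    a1 <- pd[[6 + 2 * j - 1]]
    a2 <- pd[[6 + 2 * j]]
    obs <- c(a1, a2)
    obs <- obs[obs != "0"]
    lev <- names(sort(table(obs), decreasing = TRUE))
    if (!length(lev)) next
    major <- lev[1]
    minor <- if (length(lev) > 1) lev[2] else lev[1]
    miss <- a1 == "0" | a2 == "0"
    d <- (a1 == minor) + (a2 == minor)
    if (length(lev) == 1) d <- rep(0L, length(d))
    d[miss] <- NA_integer_
    dosage[, j] <- d
    ref[j] <- major; alt[j] <- minor
  }
  map <- tibble(snp_id = mp$snp_id, chrom = mp$chrom, pos = mp$pos,
                ref = ref, alt = alt)
  new_rr_geno(dosage, map)
}

#' @rdname rrgwas-io
#' @param annotation An annotation tibble (1-based inclusive).
#' @export
write_gff3 <- function(annotation, path) {
  lines <- c("##gff-version 3",
             vapply(seq_len(nrow(annotation)), function(i) {
               paste(annotation$chrom[i], "rrgwas", "gene",
                     annotation$start[i], annotation$end[i], ".",
                     annotation$strand[i] %||% "+", ".",
                     sprintf("ID=%s", annotation$gene_id[i]), sep = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname rrgwas-io
#' @export
read_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("the rtracklayer package is required to read GFF3.")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  id <- gr$ID %||% gr$gene_id
  new_rr_annotation(tibble(
    gene_id = as.character(id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  ))
}

#' @rdname rrgwas-io
#' @export
write_bed <- function(annotation, path) {
  ## BED is 0-based half-open: start - 1, end unchanged
  lines <- vapply(seq_len(nrow(annotation)), function(i) {
    paste(annotation$chrom[i], annotation$start[i] - 1L, annotation$end[i],
          annotation$gene_id[i], 0, annotation$strand[i] %||% "+",
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname rrgwas-io
#' @export
read_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("the rtracklayer package is required to read BED.")
  }
  gr <- rtracklayer::import(path, format = "bed")
  new_rr_annotation(tibble(
    gene_id = as.character(gr$name),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),   # rtracklayer converts to 1-based
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  ))
}

#' @rdname rrgwas-io
#' @param M Relationship matrix with ID dimnames.
#' @export
write_relmat_tsv <- function(M, path) {
  df <- as.data.frame(M)
  df <- cbind(animal_id = rownames(M), df)
  readr::write_tsv(as_tibble(df), path)
  invisible(path)
}

#' @rdname rrgwas-io
#' @param sim An `rr_sim` object.
#' @export
write_truth_tsv <- function(sim, path) {
  readr::write_tsv(sim$truth$coefficients, path)
  invisible(path)
}

#' @rdname rrgwas-io
#' @param fit An `rr_reml` fit; written as one TSV row in the standard
#'   component layout plus convergence metadata.
#' @export
write_varcomp_tsv <- function(fit, path) {
  td <- tidy(fit)
  row <- as_tibble(setNames(as.list(td$estimate), td$component))
  row$loglik <- fit$loglik
  row$converged <- fit$converged
  row$n_iter <- fit$n_iter
  readr::write_tsv(row, path)
  invisible(path)
}
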