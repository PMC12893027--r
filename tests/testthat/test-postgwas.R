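gwas_rows <- function(pos, p_joint, chrom = "1") {
  n <- length(pos)
  tibble::tibble(
    snp_id = sprintf("s%02d", seq_len(n)), chrom = chrom, pos = pos,
    beta0 = 0, beta1 = 0,
    chisq_intercept = 1, chisq_slope = 1, chisq_joint = 1,
    p_intercept = 1, p_slope = 1, p_joint = p_joint, degenerate = FALSE)
}

annot <- function(...) {
  rrgwas:::new_rr_annotation(tibble::tibble(...))
}

test_that("window arithmetic is inclusive at exactly 100 kb", {
  rows <- gwas_rows(pos = 500000, p_joint = 1e-8)
  ann <- annot(gene_id = c("gLeft", "gFar"), chrom = "1",
               start = c(600000, 600001), end = c(700000, 700001),
               strand = "+")
  hits <- map_candidate_genes(rows, ann, threshold_p = 1e-6,
                              layers = "joint")
  ## SNP is exactly 100,000 bp upstream of gLeft; 100,001 bp of gFar
  expect_identical(hits$gene_id, "gLeft")
  expect_equal(hits$distance_bp, 100000L)
  expect_false(hits$inside_gene)
})

test_that("three-gene fixture yields exactly two hits, one inside", {
  rows <- gwas_rows(pos = 1000000, p_joint = 1e-9)
  ann <- annot(gene_id = c("span", "near", "far"), chrom = "1",
               start = c(990000, 1050000, 1150001),
               end = c(1010000, 1070000, 1200000), strand = c("+", "-", "+"))
  hits <- map_candidate_genes(rows, ann, threshold_p = 1e-6,
                              layers = "joint")
  expect_equal(nrow(hits), 2)
  expect_setequal(hits$gene_id, c("span", "near"))
  expect_equal(sum(hits$inside_gene), 1)
  expect_equal(hits$distance_bp[hits$gene_id == "span"], 0L)
  expect_equal(hits$distance_bp[hits$gene_id == "near"], 50000L)
  ## inside hits are a subset of all hits; distances within the window
  expect_true(all(hits$distance_bp <= 100000))
})

test_that("intergenic significant SNPs are reported with NA gene", {
  rows <- gwas_rows(pos = c(100, 5000000), p_joint = c(1e-9, 1e-9))
  ann <- annot(gene_id = "g1", chrom = "1", start = 4950000, end = 4960000,
               strand = "+")
  hits <- map_candidate_genes(rows, ann, threshold_p = 1e-6,
                              layers = "joint")
  expect_equal(nrow(hits), 2)
  expect_true(is.na(hits$gene_id[hits$snp_id == "s01"]))
  expect_identical(hits$gene_id[hits$snp_id == "s02"], "g1")
})

test_that("chromosome name mismatches raise a listing error", {
  rows <- gwas_rows(pos = 100, p_joint = 1e-9, chrom = "chr1")
  ann <- annot(gene_id = "g1", chrom = "1", start = 50, end = 200,
               strand = "+")
  expect_error(map_candidate_genes(rows, ann, threshold_p = 1e-6),
               "chromosome names")
})

test_that("strand is carried but does not affect the window", {
  rows <- gwas_rows(pos = 1000, p_joint = 1e-9)
  for (s in c("+", "-")) {
    ann <- annot(gene_id = "g", chrom = "1", start = 50000, end = 60000,
                 strand = s)
    hits <- map_candidate_genes(rows, ann, threshold_p = 1e-6,
                                layers = "joint")
    expect_equal(nrow(hits), 1)
    expect_identical(hits$strand, s)
  }
})

test_that("qq and manhattan plots build with the expected layers", {
  withr::with_seed(8, {
    n <- 100
    rows <- gwas_rows(pos = sort(sample(1e6, n)), p_joint = runif(n))
    rows$p_intercept <- runif(n)
    rows$p_slope <- runif(n)
    rows$chisq_joint <- qchisq(rows$p_joint, 2, lower.tail = FALSE)
    rows$chisq_intercept <- qchisq(rows$p_intercept, 1, lower.tail = FALSE)
    rows$chisq_slope <- qchisq(rows$p_slope, 1, lower.tail = FALSE)
  })
  q <- plot_qq(rows, "joint")
  expect_s3_class(q, "ggplot")
  qd <- ggplot2::ggplot_build(q)$data
  ## points lie near the identity band for uniform p-values
  pts <- qd[[2]]
  expect_lt(max(abs(pts$y - pts$x)), 1.2)

  ## a single significant SNP is enlarged in the circular plot; keep the
  ## other p-values away from the suggestive threshold
  rows$p_joint <- runif(n, 0.2, 1)
  rows$p_intercept <- runif(n, 0.2, 1)
  rows$p_slope <- runif(n, 0.2, 1)
  rows$p_joint[5] <- 1e-7
  s <- gwas_summaries(rows)
  circ <- plot_manhattan_circular(rows, s)
  cd <- ggplot2::ggplot_build(circ)$data[[1]]
  big <- cd[cd$size > 2, ]
  expect_equal(nrow(big), 1)
  ## determinism of the underlying plot data
  circ2 <- plot_manhattan_circular(rows, s)
  expect_identical(ggplot2::ggplot_build(circ)$data,
                   ggplot2::ggplot_build(circ2)$data)

  m <- plot_manhattan(rows, "joint", s)
  expect_s3_class(m, "ggplot")
})

test_that("render_plots writes the full deterministic set", {
  withr::with_seed(9, {
    rows <- gwas_rows(pos = sort(sample(1e6, 50)), p_joint = runif(50))
    rows$p_intercept <- runif(50); rows$p_slope <- runif(50)
    rows$chisq_joint <- qchisq(rows$p_joint, 2, lower.tail = FALSE)
    rows$chisq_intercept <- qchisq(rows$p_intercept, 1, lower.tail = FALSE)
    rows$chisq_slope <- qchisq(rows$p_slope, 1, lower.tail = FALSE)
  })
  out <- withr::local_tempdir()
  paths <- render_plots(rows, out_dir = file.path(out, "plots"))
  expect_length(paths, 7)
  expect_true(all(file.exists(paths)))
})
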