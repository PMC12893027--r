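#' Pedigree (numerator) relationship matrix
#'
#' Builds A by the tabular (recursive) method; the diagonal equals one plus
#' the inbreeding coefficient. The pedigree is topologically sorted first
#' (parents before offspring); a cyclic pedigree is an error.
#'
#' @param pedigree Pedigree tibble (`animal_id`, `sire_id`, `dam_id`).
#' @return A symmetric matrix with animal IDs as dimnames, ordered as the
#'   input pedigree, with attribute `kind = "A"`.
#' @examples
#' ped <- simulate_pedigree(4, 1, seed = 1)
#' a_matrix(ped)
#' @export
a_matrix <- function(pedigree) {
  ped <- pedigree_toposort(pedigree)
  n <- nrow(ped)
  row_of <- setNames(seq_len(n), ped$animal_id)
  si <- ifelse(is.na(ped$sire_id), 0L, row_of[ped$sire_id])
  di <- ifelse(is.na(ped$dam_id), 0L, row_of[ped$dam_id])
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      rel <- numeric(i - 1L)
      if (s > 0) rel <- rel + 0.5 * A[j, s]
      if (d > 0) rel <- rel + 0.5 * A[j, d]
      A[j, i] <- rel
      A[i, j] <- rel
    }
    A[i, i] <- 1 + if (s > 0 && d > 0) 0.5 * A[s, d] else 0
  }
  dimnames(A) <- list(ped$animal_id, ped$animal_id)
  ord <- pedigree$animal_id
  A <- A[ord, ord]
  attr(A, "kind") <- "A"
  A
}

pedigree_toposort <- function(pedigree) {
  n <- nrow(pedigree)
  ## fast path: already sorted parents-before-offspring
  pos <- match(pedigree$animal_id, pedigree$animal_id)
  spos <- match(pedigree$sire_id, pedigree$animal_id)
  dpos <- match(pedigree$dam_id, pedigree$animal_id)
  unknown_sire <- is.na(pedigree$sire_id)
  unknown_dam <- is.na(pedigree$dam_id)
  if (any(is.na(spos) & !unknown_sire) || any(is.na(dpos) & !unknown_dam)) {
    missing_par <- setdiff(c(pedigree$sire_id, pedigree$dam_id),
                           c(NA, pedigree$animal_id))
    abort(sprintf("parents not present as animals: %s",
                  paste(head(missing_par, 5), collapse = ", ")))
  }
  if (all(spos < pos | unknown_sire, na.rm = TRUE) &&
      all(dpos < pos | unknown_dam, na.rm = TRUE)) {
    return(pedigree)
  }
  placed <- setNames(rep(FALSE, n), pedigree$animal_id)
  order_idx <- integer(0)
  remaining <- seq_len(n)
  repeat {
    ready <- remaining[vapply(remaining, function(i) {
      ok <- TRUE
      for (p in c(pedigree$sire_id[i], pedigree$dam_id[i])) {
        if (!is.na(p) && p %in% names(placed) && !placed[[p]]) ok <- FALSE
      }
      ok
    }, TRUE)]
    if (!length(ready)) {
      if (length(remaining)) abort("pedigree contains a cycle.")
      break
    }
    order_idx <- c(order_idx, ready)
    placed[pedigree$animal_id[ready]] <- TRUE
    remaining <- setdiff(remaining, ready)
    if (!length(remaining)) break
  }
  missing_par <- setdiff(
    c(pedigree$sire_id, pedigree$dam_id),
    c(NA, pedigree$animal_id)
  )
  if (length(missing_par)) {
    abort(sprintf("parents not present as animals: %s",
                  paste(head(missing_par, 5), collapse = ", ")))
  }
  pedigree[order_idx, , drop = FALSE]
}

#' VanRaden genomic relationship matrix
#'
#' `G = Z Z' / (2 sum_j p_j (1 - p_j))` with `Z` the dosage matrix centered
#' by twice the observed alt-allele frequency per SNP.
#'
#' @param genotypes An `rr_geno` object or a complete (no missing) dosage
#'   matrix with animal-ID rownames.
#' @return A symmetric matrix with attribute `kind = "G"`.
#' @export
grm_vanraden <- function(genotypes) {
  X <- if (inherits(genotypes, "rr_geno")) genotypes$dosage else genotypes
  if (anyNA(X)) abort("dosages must be complete (run qc_filter first).")
  storage.mode(X) <- "double"
  p <- colMeans(X) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom == 0) abort("all SNPs are monomorphic; GRM denominator is zero.")
  Z <- sweep(X, 2, 2 * p)
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(X), rownames(X))
  attr(G, "kind") <- "G"
  G
}

#' Single-step combined relationship matrix (H)
#'
#' Blends the genomic matrix with the pedigree relationships of the
#' genotyped subset (`G* = (1 - w) G + w A22`, rescaled so the mean diagonal
#' of `G*` matches the mean diagonal of `A22`) and assembles H by the
#' standard single-step identities:
#' `H22 = G*`, `H12 = A12 A22^-1 G*`,
#' `H11 = A11 + A12 A22^-1 (G* - A22) A22^-1 A21`.
#'
#' @param A Pedigree relationship matrix over all animals.
#' @param G Genomic relationship matrix over the genotyped animals.
#' @param genotyped_ids Animal IDs of `G`'s rows; must be a subset of `A`'s.
#' @param blend_weight Weight `w` on `A22` in the blend (default 0.05).
#' @return A symmetric matrix over all animals of `A` with attribute
#'   `kind = "H"`.
#' @export
h_matrix <- function(A, G, genotyped_ids = rownames(G), blend_weight = 0.05) {
  ids <- rownames(A)
  if (is.null(ids)) abort("`A` must carry animal IDs as dimnames.")
  if (!all(genotyped_ids %in% ids)) {
    abort("`genotyped_ids` must be a subset of A's animals.")
  }
  if (length(genotyped_ids) == 0) {
    H <- A
    attr(H, "kind") <- "H"
    return(H)
  }
  G <- G[genotyped_ids, genotyped_ids, drop = FALSE]
  ung <- setdiff(ids, genotyped_ids)
  A22 <- A[genotyped_ids, genotyped_ids, drop = FALSE]
  Gs <- (1 - blend_weight) * G + blend_weight * A22
  Gs <- Gs * mean(diag(A22)) / mean(diag(Gs))
  A22inv <- tryCatch(solve(A22), error = function(e) {
    abort("A22 is singular; cannot assemble H.")
  })
  H <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  H[genotyped_ids, genotyped_ids] <- Gs
  if (length(ung)) {
    A11 <- A[ung, ung, drop = FALSE]
    A12 <- A[ung, genotyped_ids, drop = FALSE]
    P12 <- A12 %*% A22inv
    H[ung, genotyped_ids] <- P12 %*% Gs
    H[genotyped_ids, ung] <- t(P12 %*% Gs)
    H[ung, ung] <- A11 + P12 %*% (Gs - A22) %*% t(P12)
  }
  H <- (H + t(H)) / 2
  attr(H, "kind") <- "H"
  H
}

#' PCA of the genomic relationship matrix with k-means clustering
#'
#' Eigen-decomposes the double-centered relationship matrix; PC scores are
#' eigenvectors scaled by the square root of their eigenvalues, the variance
#' explained per PC is its eigenvalue over the trace, and k-means (10
#' restarts, best inertia) is run on the first `n_pcs` scores.
#'
#' @param G Symmetric relationship matrix.
#' @param n_pcs Number of leading PCs fed to k-means (default 5).
#' @param k Number of clusters (default 4).
#' @param seed Integer seed for the k-means restarts.
#' @param nstart Number of k-means restarts.
#' @return An `rr_pca` list: `scores`, `variance_explained`,
#'   `cluster_labels`, `k`.
#' @export
pca_kmeans <- function(G, n_pcs = 5, k = 4, seed = 1L, nstart = 10) {
  n <- nrow(G)
  if (k > n) abort("`k` cannot exceed the number of animals.")
  C <- sweep(sweep(G, 1, rowMeans(G)), 2, colMeans(G)) + mean(G)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  keep <- seq_len(min(n_pcs, n))
  scores <- e$vectors %*% diag(sqrt(ev), n)
  rownames(scores) <- rownames(G)
  colnames(scores) <- paste0("PC", seq_len(n))
  withr::local_seed(seed)
  km <- kmeans(scores[, keep, drop = FALSE], centers = k, nstart = nstart)
  structure(
    list(scores = scores,
         variance_explained = ev / sum(ev),
         cluster_labels = setNames(km$cluster, rownames(G)),
         k = k),
    class = "rr_pca"
  )
}

#' @export
print.rr_pca <- function(x, ...) {
  cat(sprintf("<rr_pca> %d animals, k = %d clusters\n",
              length(x$cluster_labels), x$k))
  ve <- x$variance_explained
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * head(ve, 5)), collapse = " "), "\n")
  invisible(x)
}
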