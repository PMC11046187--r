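# Population-substructure screening: identity-by-state distances over
# autosomal SNPs and classical (metric) multidimensional scaling.

#' Pairwise identity-by-state distance matrix
#'
#' For each sample pair, distance = 1 - (shared alleles) / (2 x
#' co-called SNPs), with allele sharing per SNP in {0, 1, 2} computed
#' from a1-allele dosages (2 - |d_i - d_j|). Restricted to autosomes
#' (chromosome codes 1-29) by default, mirroring the exclusion of
#' non-autosomal variants from the IBS computation; pairs are compared
#' over SNPs where both are called.
#'
#' @param x A \code{paired_genotypes} object.
#' @param autosomes_only Restrict to chromosomes 1-29 (default TRUE).
#' @return Symmetric distance matrix with zero diagonal, entries in
#'   [0, 1], dimnames = animal ids.
#' @export
ibs_distance <- function(x, autosomes_only = TRUE) {
  keep <- if (autosomes_only) x$snps$chrom >= 1L & x$snps$chrom <= 29L else
    rep(TRUE, nrow(x$snps))
  d <- dosage_a1(x)[, keep, drop = FALSE]
  n <- nrow(d)
  out <- matrix(0, n, n, dimnames = list(rownames(d), rownames(d)))
  called <- !is.na(d)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- called[i, ] & called[j, ]
      m <- sum(both)
      if (m == 0L) {
        stop("samples ", rownames(d)[i], " and ", rownames(d)[j],
             " share no co-called SNPs")
      }
      shared <- sum(2L - abs(d[i, both] - d[j, both]))
      out[i, j] <- out[j, i] <- 1 - shared / (2 * m)
    }
  }
  out
}

#' Classical (metric) multidimensional scaling
#'
#' Double-centered Gram eigendecomposition of the squared distance
#' matrix; coordinates ordered by eigenvalue. Eigenvector signs are
#' fixed deterministically so that the loading with the largest
#' magnitude in each dimension is positive.
#'
#' @param distances Symmetric distance matrix.
#' @param k Number of dimensions requested.
#' @return Numeric matrix (samples x k'), columns \code{C1..Ck'};
#'   truncated with a warning when fewer than k positive eigenvalues
#'   exist.
#' @export
classical_mds <- function(distances, k = 2L) {
  stopifnot(k >= 1L)
  fit <- cmdscale(as.dist(distances), k = min(k, nrow(distances) - 1L),
                  eig = TRUE)
  n_pos <- sum(fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig)))
  coords <- fit$points
  if (ncol(coords) < k) {
    warning("only ", ncol(coords), " positive dimension(s) available; ",
            "requested ", k)
  }
  if (ncol(coords) > n_pos) coords <- coords[, seq_len(n_pos), drop = FALSE]
  for (j in seq_len(ncol(coords))) {
    i_max <- which.max(abs(coords[, j]))
    if (coords[i_max, j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("C", seq_len(ncol(coords)))
  rownames(coords) <- rownames(distances)
  coords
}

#' MDS coordinates keyed by pair
#'
#' Convenience table for Figure-style scatter plots in which the two
#' members of each pen-mate pair can be connected.
#'
#' @param x A \code{paired_genotypes} object.
#' @param k Dimensions (default 2).
#' @param autosomes_only Passed to \code{\link{ibs_distance}}.
#' @return data.frame: \code{iid}, \code{pair}, \code{phenotype},
#'   \code{C1..Ck}.
#' @export
mds_by_pair <- function(x, k = 2L, autosomes_only = TRUE) {
  coords <- classical_mds(ibs_distance(x, autosomes_only), k)
  cbind(x$animals[match(rownames(coords), x$animals$iid),
                  c("iid", "pair", "phenotype")],
        as.data.frame(coords), row.names = NULL)
}
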