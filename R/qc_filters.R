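# Pre-association SNP filters (MAF, missingness, Hardy-Weinberg exact
# mid-p) and the post-association removals (no informative pairs,
# unmapped / Y / mitochondrial SNPs).

#' Genotype counts at one SNP
#'
#' @param calls Character vector of one-letter codes for one SNP column.
#' @param a1,a2 The SNP's two alleles.
#' @return Named integer vector \code{(n_a1a1, n_a1a2, n_a2a2, n_missing)}.
#' @export
genotype_counts <- function(calls, a1, a2) {
  het <- iupac_het(a1, a2)
  legal <- c(a1, het, a2, missing_call())
  if (!all(calls %in% legal)) {
    stop("call(s) outside the SNP's legal code set: ",
         paste(unique(calls[!(calls %in% legal)]), collapse = ", "))
  }
  c(n_a1a1 = sum(calls == a1), n_a1a2 = sum(calls == het),
    n_a2a2 = sum(calls == a2), n_missing = sum(calls == missing_call()))
}

#' Minor allele frequency from genotype counts
#'
#' @param counts Vector \code{(n_a1a1, n_a1a2, n_a2a2, ...)} as from
#'   \code{\link{genotype_counts}}.
#' @return \code{min(p, 1 - p)} with p the a1 allele frequency among
#'   non-missing calls; \code{NA} when every call is missing.
#' @export
maf <- function(counts) {
  n <- counts[[1]] + counts[[2]] + counts[[3]]
  if (n == 0L) return(NA_real_)
  p <- (2 * counts[[1]] + counts[[2]]) / (2 * n)
  min(p, 1 - p)
}

#' Hardy-Weinberg exact test with mid-p adjustment
#'
#' Exact conditional test on the heterozygote count given the observed
#' allele counts (Levene-Haldane distribution). The mid-p value sums the
#' probabilities of all heterozygote configurations strictly less
#' probable than the observed one plus half the probability of those
#' equally probable (the observed configuration included). Degenerate
#' inputs admitting a single configuration return 1.
#'
#' @param n_a1a1,n_a1a2,n_a2a2 Non-negative genotype counts.
#' @return Mid-p value in (0, 1].
#' @export
hwe_exact_midp <- function(n_a1a1, n_a1a2, n_a2a2) {
  stopifnot(n_a1a1 >= 0, n_a1a2 >= 0, n_a2a2 >= 0)
  n <- n_a1a1 + n_a1a2 + n_a2a2
  if (n < 1L) stop("need at least one genotyped animal")
  n1 <- 2L * n_a1a1 + n_a1a2  # a1 allele count
  rare <- min(n1, 2L * n - n1)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  if (length(hets) <= 1L) return(1.0)
  # Levene-Haldane: P(h) proportional to 2^h / (n11! h! n22!) given the
  # allele totals; normalize over the parity-consistent support
  h11 <- (rare - hets) / 2
  h22 <- n - h11 - hets
  logp <- hets * log(2) - lfactorial(h11) - lfactorial(hets) - lfactorial(h22)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_a1a2, hets)]
  if (is.na(obs)) stop("heterozygote count inconsistent with allele parity")
  eps <- 1e-12
  less <- sum(prob[prob < obs - eps * obs])
  equal <- sum(prob[abs(prob - obs) <= eps * obs])
  min(1, less + 0.5 * equal)
}

#' Apply pre-association SNP filters
#'
#' A SNP is kept iff its minor allele frequency is at least
#' \code{maf_min}, its missing-call fraction is at most \code{geno_max}
#' and its Hardy-Weinberg exact mid-p is at least \code{hwe_min},
#' mirroring the PLINK \code{--maf}, \code{--geno} and
#' \code{--hwe midp} options. The removal report attributes each dropped
#' SNP to the first failing filter in the order MAF, missingness, HWE;
#' the kept set is the conjunction and does not depend on that order.
#' All-missing SNPs are attributed to the MAF filter (frequency
#' undefined).
#'
#' @param x A \code{paired_genotypes} object.
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param geno_max Maximum missing-call fraction (default 0.05).
#' @param hwe_min Minimum HWE exact mid-p (default 1e-4).
#' @return List with the filtered matrix (\code{matrix}) and a
#'   \code{filter_report}.
#' @export
apply_pre_filters <- function(x, maf_min = 0.05, geno_max = 0.05,
                              hwe_min = 1e-4) {
  M <- nrow(x$snps)
  n_animals <- nrow(x$animals)
  maf_v <- miss_v <- hwe_v <- numeric(M)
  for (j in seq_len(M)) {
    cnt <- genotype_counts(x$calls[, j], x$snps$a1[j], x$snps$a2[j])
    maf_v[j] <- maf(cnt)
    miss_v[j] <- cnt[["n_missing"]] / n_animals
    hwe_v[j] <- if (cnt[["n_missing"]] == n_animals) 1.0 else
      hwe_exact_midp(cnt[["n_a1a1"]], cnt[["n_a1a2"]], cnt[["n_a2a2"]])
  }
  fail_maf <- is.na(maf_v) | maf_v < maf_min
  fail_geno <- miss_v > geno_max
  fail_hwe <- hwe_v < hwe_min
  reason <- rep("kept", M)
  reason[fail_hwe] <- "hwe"
  reason[fail_geno] <- "missing"
  reason[fail_maf] <- "maf"
  keep <- reason == "kept"
  report <- filter_report(
    n_input = M,
    n_removed_maf = sum(reason == "maf"),
    n_removed_missing = sum(reason == "missing"),
    n_removed_hwe = sum(reason == "hwe"),
    kept_ids = x$snps$snp_id[keep]
  )
  filtered <- x
  filtered$snps <- x$snps[keep, , drop = FALSE]
  filtered$calls <- x$calls[, keep, drop = FALSE]
  list(matrix = filtered, report = report)
}

#' Filter report constructor
#'
#' @param n_input Number of SNPs entering the filter.
#' @param n_removed_maf,n_removed_missing,n_removed_hwe Counts removed
#'   by each pre-association filter.
#' @param n_removed_no_informative,n_removed_unplaced_y_mt Counts
#'   removed after association testing.
#' @param kept_ids Ids of surviving SNPs.
#' @return A \code{filter_report} object.
#' @export
filter_report <- function(n_input, n_removed_maf = 0L,
                          n_removed_missing = 0L, n_removed_hwe = 0L,
                          n_removed_no_informative = 0L,
                          n_removed_unplaced_y_mt = 0L, kept_ids) {
  rep <- structure(list(
    n_input = n_input,
    n_removed_maf = n_removed_maf,
    n_removed_missing = n_removed_missing,
    n_removed_hwe = n_removed_hwe,
    n_removed_no_informative = n_removed_no_informative,
    n_removed_unplaced_y_mt = n_removed_unplaced_y_mt,
    kept_ids = kept_ids
  ), class = "filter_report")
  total <- rep$n_removed_maf + rep$n_removed_missing + rep$n_removed_hwe +
    rep$n_removed_no_informative + rep$n_removed_unplaced_y_mt +
    length(rep$kept_ids)
  if (total != rep$n_input) {
    stop("filter report does not conserve SNP counts: ", total,
         " accounted vs ", rep$n_input, " input")
  }
  rep
}

#' @export
print.filter_report <- function(x, ...) {
  cat("SNP filter report:", x$n_input, "input,",
      length(x$kept_ids), "kept\n")
  cat("  removed: maf", x$n_removed_maf, "| missing", x$n_removed_missing,
      "| hwe", x$n_removed_hwe, "| no informative pairs",
      x$n_removed_no_informative, "| unplaced/Y/MT",
      x$n_removed_unplaced_y_mt, "\n")
  invisible(x)
}

#' Post-association removals
#'
#' Drops scan rows for SNPs that had no informative pairs (b + c = 0)
#' in every scenario and SNPs assigned to unmapped (0), Y (31) or
#' mitochondrial (32) chromosome codes. The X chromosome (30) is kept.
#'
#' @param scan Results table from \code{\link{run_genome_scan}}.
#' @return List with the pruned table (\code{scan}) and a
#'   \code{filter_report} over the SNPs that entered.
#' @export
apply_post_filters <- function(scan) {
  bc <- tapply(scan$b + scan$c, scan$snp_id, max)
  no_inf_ids <- names(bc)[bc == 0]
  snp_first <- scan[!duplicated(scan$snp_id), c("snp_id", "chrom")]
  bad_chrom_ids <- snp_first$snp_id[snp_first$chrom %in% c(0L, 31L, 32L)]
  # chromosome removal takes precedence in the attribution
  no_inf_ids <- setdiff(no_inf_ids, bad_chrom_ids)
  drop <- scan$snp_id %in% c(no_inf_ids, bad_chrom_ids)
  kept_ids <- setdiff(unique(scan$snp_id), c(no_inf_ids, bad_chrom_ids))
  report <- filter_report(
    n_input = length(unique(scan$snp_id)),
    n_removed_no_informative = length(no_inf_ids),
    n_removed_unplaced_y_mt = length(bad_chrom_ids),
    kept_ids = kept_ids
  )
  list(scan = scan[!drop, , drop = FALSE], report = report)
}
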