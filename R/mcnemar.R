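# McNemar's test over matched pen-mate pairs: per-SNP 2x2 tabulation
# under six allele-by-inheritance scenarios, mid-p and exact conditional
# p-values, chi-squared, odds ratio with Wald CI, Cohen's g and the
# per-marker polygenic risk factor value.

.models <- c("one_copy", "one_or_two", "two_copy")

#' The six risk-allele scenarios
#'
#' Each biallelic SNP is tested with either allele as the hypothesized
#' risk factor under three inheritance models: 1-copy (heterozygous
#' only), 1-or-2-copies (dominant) and 2-copies (homozygous only).
#'
#' @return data.frame with columns \code{allele} (\code{"a1"}/\code{"a2"})
#'   and \code{model}.
#' @export
scenarios <- function() {
  expand.grid(allele = c("a1", "a2"), model = .models,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

# exposure indicator from an a1-dosage vector/matrix (NA preserved)
exposure_from_dosage <- function(d, allele, model) {
  k <- if (allele == "a1") d else 2L - d
  switch(model,
    one_copy = k == 1L,
    one_or_two = k >= 1L,
    two_copy = k == 2L,
    stop("unknown model: ", model)
  )
}

#' Tabulate McNemar quadrants for one SNP and scenario
#'
#' A pair contributes only when both members have a non-missing call at
#' the SNP. Quadrant a counts pairs where case and control both carry
#' the risk genotype, b case-only (informative, supporting risk), c
#' control-only (informative, supporting protection), d neither.
#'
#' @param x A \code{paired_genotypes} object.
#' @param snp_id SNP identifier.
#' @param allele \code{"a1"} or \code{"a2"}.
#' @param model One of \code{"one_copy"}, \code{"one_or_two"},
#'   \code{"two_copy"}.
#' @return Named vector \code{(a, b, c, d, n_pairs_used)}.
#' @export
tabulate_pairs <- function(x, snp_id, allele, model) {
  j <- match(snp_id, x$snps$snp_id)
  if (is.na(j)) stop("unknown snp_id: ", snp_id)
  pr <- pair_rows(x)
  d <- dosage_a1(x)[, j]
  e <- exposure_from_dosage(d, allele, model)
  ec <- e[pr$case]
  eo <- e[pr$control]
  ok <- !is.na(ec) & !is.na(eo)
  c(a = sum(ec & eo & ok, na.rm = TRUE),
    b = sum(ec & !eo & ok, na.rm = TRUE),
    c = sum(!ec & eo & ok, na.rm = TRUE),
    d = sum(!ec & !eo & ok, na.rm = TRUE),
    n_pairs_used = sum(ok))
}

#' McNemar mid-p value
#'
#' Two-sided mid-p for discordant-pair counts, computed on the
#' conditional Binomial(b + c, 1/2) distribution as
#' \code{2 * (F(min(b, c)) - 0.5 * f(min(b, c)))} with F the binomial
#' CDF and f the PMF, capped at 1.
#'
#' @param b,c Discordant-pair counts (vectorized).
#' @return Mid-p in (0, 1]; \code{NA} where b + c = 0.
#' @export
mcnemar_mid_p <- function(b, c) {
  t <- b + c
  k <- pmin(b, c)
  p <- 2 * (pbinom(k, t, 0.5) - 0.5 * dbinom(k, t, 0.5))
  p <- pmin(1, p)
  p[t == 0] <- NA_real_
  p
}

#' McNemar exact conditional p-value
#'
#' Two-sided exact conditional (sign-test) p-value
#' \code{min(1, 2 * F(min(b, c); b + c, 1/2))}.
#'
#' @param b,c Discordant-pair counts (vectorized).
#' @return Exact p in (0, 1]; \code{NA} where b + c = 0.
#' @export
mcnemar_exact_p <- function(b, c) {
  t <- b + c
  p <- pmin(1, 2 * pbinom(pmin(b, c), t, 0.5))
  p[t == 0] <- NA_real_
  p
}

#' McNemar chi-squared statistic
#'
#' \code{(b - c)^2 / (b + c)}, or with the continuity correction
#' \code{(|b - c| - 1)^2 / (b + c)} floored at 0 when |b - c| < 1.
#'
#' @param b,c Discordant-pair counts (vectorized).
#' @param continuity Apply the continuity correction?
#' @return Statistic, \code{NA} where b + c = 0.
#' @export
mcnemar_chi2 <- function(b, c, continuity = TRUE) {
  t <- b + c
  stat <- if (continuity) pmax(abs(b - c) - 1, 0)^2 / t else (b - c)^2 / t
  stat[t == 0] <- NA_real_
  stat
}

#' Discordant-pair odds ratio with Wald confidence interval
#'
#' OR = b / c with \code{exp(log(OR) +/- z * sqrt(1/b + 1/c))} bounds.
#' When b or c is 0 the ratio and bounds are degenerate and flagged: no
#' continuity (Haldane) correction is applied.
#'
#' @param b,c Discordant-pair counts (vectorized).
#' @param level Confidence level (default 0.95).
#' @return data.frame with \code{or}, \code{ci_low}, \code{ci_high} and
#'   logical \code{defined}.
#' @export
odds_ratio_ci <- function(b, c, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  or <- b / c
  se <- sqrt(1 / b + 1 / c)
  lo <- exp(log(or) - z * se)
  hi <- exp(log(or) + z * se)
  defined <- b > 0 & c > 0
  lo[!defined] <- NA_real_
  hi[!defined] <- NA_real_
  data.frame(or = or, ci_low = lo, ci_high = hi, defined = defined)
}

#' Cohen's g effect size for paired binary data
#'
#' \code{max(b, c) / (b + c) - 0.5}, in [0, 0.5].
#'
#' @param b,c Discordant-pair counts (vectorized).
#' @return Effect size, \code{NA} where b + c = 0.
#' @export
cohens_g <- function(b, c) {
  t <- b + c
  g <- pmax(b, c) / t - 0.5
  g[t == 0] <- NA_real_
  g
}

#' Per-marker polygenic risk factor value
#'
#' Effect size times the proportion of informative pairs,
#' \code{g * (b + c) / n_pairs_used}, a component for summing an
#' animal's polygenic risk score.
#'
#' @param g Cohen's g.
#' @param b,c Discordant-pair counts.
#' @param n_pairs_used Pairs with both members genotyped at the SNP.
#' @return PRS value (vectorized).
#' @export
prs_value <- function(g, b, c, n_pairs_used) {
  g * (b + c) / n_pairs_used
}

# assemble the full derived-statistics block for vectors of b, c, n
mcnemar_stats <- function(b, c, n_pairs_used) {
  orci <- odds_ratio_ci(b, c)
  g <- cohens_g(b, c)
  mid <- mcnemar_mid_p(b, c)
  data.frame(
    or = orci$or, ci_low = orci$ci_low, ci_high = orci$ci_high,
    chi2 = mcnemar_chi2(b, c, continuity = FALSE),
    chi2_cc = mcnemar_chi2(b, c, continuity = TRUE),
    mid_p = mid,
    exact_p = mcnemar_exact_p(b, c),
    neglog10_mid_p = -log10(mid),
    cohens_g = g,
    prop_informative = (b + c) / n_pairs_used,
    prs_value = prs_value(g, b, c, n_pairs_used)
  )
}

#' Genome-wide McNemar scan
#'
#' Scores every SNP under all six scenarios (both alleles as the risk
#' factor, three inheritance models each), producing the full table of
#' quadrants and derived statistics. Rows are ordered by SNP (input
#' order) then scenario; ties in any downstream p-value sort are broken
#' by chromosome then position (stable).
#'
#' @param x A (filtered) \code{paired_genotypes} object.
#' @return data.frame with columns \code{chrom, pos_bp, snp_id,
#'   risk_allele, model, a, b, c, d, n_pairs, OR, CI_low, CI_high, chi2,
#'   chi2_cc, mid_p, exact_p, neglog10_mid_p, cohens_g,
#'   prop_informative, prs_value}; \code{risk_allele} holds the actual
#'   nucleotide letter and \code{allele} its a1/a2 label.
#' @export
run_genome_scan <- function(x) {
  pr <- pair_rows(x)
  dos <- dosage_a1(x)
  dc <- dos[pr$case, , drop = FALSE]
  do <- dos[pr$control, , drop = FALSE]
  ok <- !is.na(dc) & !is.na(do)
  n_used <- colSums(ok)
  sc <- scenarios()
  M <- nrow(x$snps)
  out <- vector("list", nrow(sc))
  for (i in seq_len(nrow(sc))) {
    ec <- exposure_from_dosage(dc, sc$allele[i], sc$model[i])
    eo <- exposure_from_dosage(do, sc$allele[i], sc$model[i])
    ec[!ok] <- NA
    eo[!ok] <- NA
    a <- colSums(ec & eo, na.rm = TRUE)
    b <- colSums(ec & !eo, na.rm = TRUE)
    cc <- colSums(!ec & eo, na.rm = TRUE)
    d <- colSums(!ec & !eo, na.rm = TRUE)
    allele_letter <- if (sc$allele[i] == "a1") x$snps$a1 else x$snps$a2
    stats <- mcnemar_stats(b, cc, n_used)
    out[[i]] <- data.frame(
      chrom = x$snps$chrom, pos_bp = x$snps$pos_bp,
      snp_id = x$snps$snp_id,
      allele = sc$allele[i], risk_allele = allele_letter,
      model = sc$model[i],
      a = a, b = b, c = cc, d = d, n_pairs = n_used,
      OR = stats$or, CI_low = stats$ci_low, CI_high = stats$ci_high,
      chi2 = stats$chi2, chi2_cc = stats$chi2_cc,
      mid_p = stats$mid_p, exact_p = stats$exact_p,
      neglog10_mid_p = stats$neglog10_mid_p,
      cohens_g = stats$cohens_g,
      prop_informative = stats$prop_informative,
      prs_value = stats$prs_value,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  res <- do.call(rbind, out)
  # stable order: SNP in input order, then scenario
  res <- res[order(match(res$snp_id, x$snps$snp_id)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Sort scan rows by significance
#'
#' Ascending p-value with stable chromosome-then-position tie-breaking.
#'
#' @param scan Scan table.
#' @param p_col Column to sort on (default \code{"mid_p"}).
#' @return Reordered scan table.
#' @export
sort_scan <- function(scan, p_col = "mid_p") {
  scan[order(scan[[p_col]], scan$chrom, scan$pos_bp), , drop = FALSE]
}
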