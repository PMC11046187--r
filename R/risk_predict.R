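# Two-locus homozygous-risk classification ("two-SNP test"):
# genotype-configuration risk tiers, combined-exposure McNemar testing
# and prevalence-adjusted predictive values.

#' Count risk-allele copies from a one-letter genotype code
#'
#' Requires the declared risk allele and the locus's allele pair so the
#' IUPAC heterozygote letter can be disambiguated; refuses loci whose
#' two alleles do not map to a unique ambiguity code.
#'
#' @param call One-letter genotype code.
#' @param risk_allele The declared risk nucleotide.
#' @param alleles Character vector of the locus's two alleles.
#' @return 0, 1 or 2; \code{NA} for a missing call.
#' @export
risk_allele_copies <- function(call, risk_allele, alleles) {
  stopifnot(length(alleles) == 2L, risk_allele %in% alleles)
  het <- iupac_het(alleles[1], alleles[2])
  other <- setdiff(alleles, risk_allele)
  if (call == missing_call()) return(NA_integer_)
  if (call == risk_allele) return(2L)
  if (call == het) return(1L)
  if (call == other) return(0L)
  stop("genotype code ", call, " is not legal for alleles {",
       paste(alleles, collapse = ","), "}")
}

#' Classify an animal's two-locus risk configuration
#'
#' Maps the diploid risk-allele copy counts at two loci to the disease
#' risk tier (28x when homozygous at both, 8x when homozygous at exactly
#' one, else 1x), the relative breeding rank (1 best to 5 worst) and the
#' probability of transmitting a risk allele (25% per carried copy).
#'
#' @param genotype_locus1,genotype_locus2 One-letter genotype codes.
#' @param risk_alleles Character vector: the risk nucleotide at each
#'   locus.
#' @param alleles_locus1,alleles_locus2 The two alleles of each locus.
#' @return A \code{risk_configuration} list with \code{copies_locus1},
#'   \code{copies_locus2}, \code{total_risk_alleles}, \code{tier_label},
#'   \code{breeding_rank}, \code{transmission_prob}; or flagged
#'   unclassifiable when a genotype is missing.
#' @export
classify_animal <- function(genotype_locus1, genotype_locus2, risk_alleles,
                            alleles_locus1, alleles_locus2) {
  c1 <- risk_allele_copies(genotype_locus1, risk_alleles[1], alleles_locus1)
  c2 <- risk_allele_copies(genotype_locus2, risk_alleles[2], alleles_locus2)
  if (is.na(c1) || is.na(c2)) {
    return(structure(list(copies_locus1 = c1, copies_locus2 = c2,
                          total_risk_alleles = NA_integer_,
                          tier_label = NA_character_,
                          breeding_rank = NA_integer_,
                          transmission_prob = NA_real_,
                          classifiable = FALSE),
                     class = "risk_configuration"))
  }
  cfg <- risk_tier(c1, c2)
  cfg$classifiable <- TRUE
  cfg
}

#' Risk tier from copy counts
#'
#' Pure function of the two copy counts; enumeration over all nine
#' configurations reproduces the published tier table.
#'
#' @param copies_locus1,copies_locus2 Risk-allele copies (0, 1 or 2).
#' @return A \code{risk_configuration} list.
#' @export
risk_tier <- function(copies_locus1, copies_locus2) {
  stopifnot(copies_locus1 %in% 0:2, copies_locus2 %in% 0:2)
  total <- copies_locus1 + copies_locus2
  n_hom <- (copies_locus1 == 2L) + (copies_locus2 == 2L)
  tier <- c("1x", "8x", "28x")[n_hom + 1L]
  rank <- total + 1L
  structure(list(copies_locus1 = copies_locus1,
                 copies_locus2 = copies_locus2,
                 total_risk_alleles = total,
                 tier_label = tier,
                 breeding_rank = rank,
                 transmission_prob = 25 * total),
            class = "risk_configuration")
}

#' Combined two-locus McNemar test
#'
#' Exposure is carrying the homozygous risk genotype at BOTH loci; the
#' matched pairs are then tabulated and scored exactly as for a single
#' SNP.
#'
#' @param x A \code{paired_genotypes} object.
#' @param locus1,locus2 SNP ids.
#' @param risk_alleles Risk nucleotide at each locus (defaults to each
#'   locus's a1).
#' @return One-row data.frame with quadrants and the derived McNemar
#'   statistics.
#' @export
combined_exposure_mcnemar <- function(x, locus1, locus2,
                                      risk_alleles = NULL) {
  j1 <- match(locus1, x$snps$snp_id)
  j2 <- match(locus2, x$snps$snp_id)
  if (is.na(j1) || is.na(j2)) stop("locus not found in SNP table")
  if (is.null(risk_alleles)) {
    risk_alleles <- c(x$snps$a1[j1], x$snps$a1[j2])
  }
  pr <- pair_rows(x)
  exposed <- x$calls[, j1] == risk_alleles[1] &
    x$calls[, j2] == risk_alleles[2]
  called <- x$calls[, j1] != missing_call() &
    x$calls[, j2] != missing_call()
  ec <- exposed[pr$case]
  eo <- exposed[pr$control]
  ok <- called[pr$case] & called[pr$control]
  a <- sum(ec & eo & ok)
  b <- sum(ec & !eo & ok)
  cc <- sum(!ec & eo & ok)
  d <- sum(!ec & !eo & ok)
  cbind(data.frame(locus1 = locus1, locus2 = locus2,
                   a = a, b = b, c = cc, d = d, n_pairs = sum(ok),
                   stringsAsFactors = FALSE),
        mcnemar_stats(b, cc, sum(ok)))
}

#' Prevalence-adjusted predictive values
#'
#' Bayes' rule: PPV = se * pi / (se * pi + (1 - sp) (1 - pi)),
#' NPV = sp (1 - pi) / (sp (1 - pi) + (1 - se) pi).
#'
#' @param sensitivity,specificity Test operating characteristics.
#' @param prevalence Disease prevalence pi in the screened population.
#' @return A \code{classifier_metrics} list with all five quantities;
#'   degenerate denominators yield \code{NA} with \code{defined = FALSE}.
#' @export
predictive_values <- function(sensitivity, specificity, prevalence) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1,
            prevalence >= 0, prevalence <= 1)
  den_p <- sensitivity * prevalence + (1 - specificity) * (1 - prevalence)
  den_n <- specificity * (1 - prevalence) + (1 - sensitivity) * prevalence
  ppv <- if (den_p > 0) sensitivity * prevalence / den_p else NA_real_
  npv <- if (den_n > 0) specificity * (1 - prevalence) / den_n else NA_real_
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 prevalence = prevalence, ppv = ppv, npv = npv,
                 defined = den_p > 0 && den_n > 0),
            class = "classifier_metrics")
}

#' Per-cohort two-locus risk summary
#'
#' Tier counts and the fraction homozygous for the risk allele at both
#' loci, per cohort. Animals missing a genotype at either locus are
#' flagged and excluded from the denominator.
#'
#' @param genotypes data.frame with columns \code{cohort},
#'   \code{locus1}, \code{locus2} (one-letter codes).
#' @param risk_alleles Risk nucleotide at each locus.
#' @param alleles_locus1,alleles_locus2 The two alleles of each locus.
#' @return data.frame, one row per cohort: \code{n_typed},
#'   \code{n_unclassified}, tier counts \code{n_1x}, \code{n_8x},
#'   \code{n_28x} and \code{frac_both_hom}.
#' @export
cohort_risk_summary <- function(genotypes, risk_alleles,
                                alleles_locus1, alleles_locus2) {
  cfg <- mapply(function(g1, g2) {
    cl <- classify_animal(g1, g2, risk_alleles,
                          alleles_locus1, alleles_locus2)
    c(tier = if (isTRUE(cl$classifiable)) cl$tier_label else NA_character_)
  }, genotypes$locus1, genotypes$locus2)
  tiers <- unname(cfg)
  out <- lapply(split(tiers, genotypes$cohort), function(tt) {
    typed <- !is.na(tt)
    data.frame(n_typed = sum(typed), n_unclassified = sum(!typed),
               n_1x = sum(tt[typed] == "1x"),
               n_8x = sum(tt[typed] == "8x"),
               n_28x = sum(tt[typed] == "28x"),
               frac_both_hom = if (any(typed))
                 sum(tt[typed] == "28x") / sum(typed) else NA_real_)
  })
  res <- do.call(rbind, out)
  res <- cbind(cohort = names(out), res)
  rownames(res) <- NULL
  res
}
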