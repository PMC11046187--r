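# Seeded generator of matched pen-mate ped/map datasets with the
# statistical structure the analysis assumes: null SNPs in
# Hardy-Weinberg proportions with a within-pair correlation from shared
# origin, and designated risk loci with a controlled discordant-pair
# odds ratio.

#' Simulation configuration for matched-pair genotype data
#'
#' Defaults emulate the study design this package targets: 102 matched
#' pen-mate pairs, SNPs spread over 29 autosomes plus X, post-filter
#' minor-allele frequencies in [0.05, 0.5], a mild shared-origin
#' within-pair correlation and a low array missing-call rate.
#'
#' @param n_pairs Number of case-control pairs.
#' @param n_null_snps Number of null (unassociated) SNPs.
#' @param risk_loci data.frame with columns \code{chrom}, \code{pos},
#'   \code{maf}, \code{model} (inheritance scenario of the risk allele)
#'   and \code{theta} (target discordant-pair odds ratio); the risk
#'   allele is the major allele (frequency 1 - maf).
#' @param maf_range Range the null-SNP minor-allele frequencies are
#'   drawn from.
#' @param within_pair_corr rho in [0, 1): correlation of the pair-level
#'   latent allele frequency (shared ranch origin).
#' @param missing_rate Per-call missing probability.
#' @param n_chromosomes Autosome count (X is appended as code 30).
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A validated \code{sim_config} list.
#' @export
sim_config <- function(n_pairs = 102L, n_null_snps = 1000L,
                       risk_loci = NULL, maf_range = c(0.05, 0.5),
                       within_pair_corr = 0.1, missing_rate = 0.01,
                       n_chromosomes = 29L, seed = 1L) {
  stopifnot(n_pairs >= 1, n_null_snps >= 0,
            maf_range[1] >= 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            within_pair_corr >= 0, within_pair_corr < 1,
            missing_rate >= 0, missing_rate < 1, n_chromosomes >= 1)
  if (!is.null(risk_loci)) {
    stopifnot(is.data.frame(risk_loci),
              all(c("chrom", "pos", "maf", "model", "theta") %in%
                    names(risk_loci)))
    stopifnot(all(risk_loci$theta > 0),
              all(risk_loci$maf >= 0 & risk_loci$maf <= 0.5),
              all(risk_loci$model %in% .models))
    for (i in seq_len(nrow(risk_loci))) {
      pi0 <- .exposure_prevalence(1 - risk_loci$maf[i], risk_loci$model[i])
      if (pi0 <= 0 || pi0 >= 1) {
        stop("infeasible risk locus ", i, ": exposure prevalence ", pi0,
             " leaves no discordant-cell probability")
      }
    }
  }
  structure(list(n_pairs = as.integer(n_pairs),
                 n_null_snps = as.integer(n_null_snps),
                 risk_loci = risk_loci, maf_range = maf_range,
                 within_pair_corr = within_pair_corr,
                 missing_rate = missing_rate,
                 n_chromosomes = as.integer(n_chromosomes),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# HWE exposure prevalence of the risk allele (frequency p) under a model
.exposure_prevalence <- function(p, model) {
  switch(model,
    one_copy = 2 * p * (1 - p),
    one_or_two = 1 - (1 - p)^2,
    two_copy = p^2,
    stop("unknown model: ", model)
  )
}

# sample a dosage (copies of the risk allele) conditional on exposure
# status under HWE with risk-allele frequency p
.dosage_given_exposure <- function(n, exposed, p, model) {
  probs <- c(`0` = (1 - p)^2, `1` = 2 * p * (1 - p), `2` = p^2)
  in_set <- switch(model,
    one_copy = c(FALSE, TRUE, FALSE),
    one_or_two = c(FALSE, TRUE, TRUE),
    two_copy = c(FALSE, FALSE, TRUE)
  )
  out <- integer(n)
  for (ex in c(TRUE, FALSE)) {
    idx <- which(exposed == ex)
    if (!length(idx)) next
    pr <- probs * (if (ex) in_set else !in_set)
    out[idx] <- sample(0:2, length(idx), replace = TRUE, prob = pr)
  }
  out
}

#' Generate a synthetic matched-pair genotype matrix
#'
#' Null SNPs: each pair draws a shared latent allele frequency from a
#' Beta distribution with mean the configured frequency and
#' intra-class correlation \code{within_pair_corr}, then both members'
#' genotypes are drawn from Hardy-Weinberg proportions at that
#' frequency. Risk loci: the pair's 2x2 exposure outcome is drawn first
#' from the cell probabilities implied by the HWE exposure prevalence
#' and the target discordant odds ratio theta (case margin
#' \code{theta * pi0 / (1 - pi0 + theta * pi0)}), then genotypes are
#' sampled from the conditional HWE distribution given exposure status.
#' Missingness is applied independently per call. Major/minor allele
#' labels (a1/a2) are assigned from the realized sample frequencies,
#' ties broken alphabetically.
#'
#' @param config A \code{sim_config}.
#' @param prefix Optional path prefix; when given, ped/map files are
#'   also written via \code{\link{write_ped_map}}.
#' @return A \code{paired_genotypes} object with a \code{manifest}
#'   attribute recording the seed, per-locus risk-allele letters and
#'   realized summary statistics.
#' @export
generate_pairs <- function(config, prefix = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  N <- config$n_pairs
  n_risk <- if (is.null(config$risk_loci)) 0L else nrow(config$risk_loci)
  M <- config$n_null_snps + n_risk
  if (M == 0L) stop("config generates zero SNPs")
  letters4 <- c("A", "C", "G", "T")
  # chromosomes 1..n_autosomes then X (=30) for null SNPs
  chrom_pool <- c(seq_len(config$n_chromosomes), 30L)
  chrom <- sample(chrom_pool, config$n_null_snps, replace = TRUE)
  pos <- sample.int(1e8L, config$n_null_snps, replace = TRUE)
  target_maf <- runif(config$n_null_snps, config$maf_range[1],
                      config$maf_range[2])
  is_risk <- logical(M)
  if (n_risk > 0L) {
    chrom <- c(chrom, normalize_chrom(config$risk_loci$chrom))
    pos <- c(pos, config$risk_loci$pos)
    target_maf <- c(target_maf, config$risk_loci$maf)
    is_risk[config$n_null_snps + seq_len(n_risk)] <- TRUE
  }
  rho <- config$within_pair_corr
  # dosage of the designated major (risk) allele, rows = 2N animals in
  # control-first pair order
  dos <- matrix(NA_integer_, 2L * N, M)
  risk_letter <- other_letter <- character(M)
  for (j in seq_len(M)) {
    al <- sample(letters4, 2L)
    risk_letter[j] <- al[1]
    other_letter[j] <- al[2]
    p <- 1 - target_maf[j]
    if (is_risk[j]) {
      rl <- config$risk_loci[sum(is_risk[seq_len(j)]), ]
      pi0 <- .exposure_prevalence(p, rl$model)
      pi1 <- rl$theta * pi0 / (1 - pi0 + rl$theta * pi0)
      e_ctrl <- runif(N) < pi0
      e_case <- runif(N) < pi1
      d_ctrl <- .dosage_given_exposure(N, e_ctrl, p, rl$model)
      d_case <- .dosage_given_exposure(N, e_case, p, rl$model)
    } else {
      f <- if (rho > 0) {
        rbeta(N, p * (1 - rho) / rho, (1 - p) * (1 - rho) / rho)
      } else rep(p, N)
      d_ctrl <- rbinom(N, 2L, f)
      d_case <- rbinom(N, 2L, f)
    }
    dos[seq(1L, 2L * N, by = 2L), j] <- d_ctrl
    dos[seq(2L, 2L * N, by = 2L), j] <- d_case
  }
  if (config$missing_rate > 0) {
    dos[runif(length(dos)) < config$missing_rate] <- NA_integer_
  }
  # dosage -> one-letter codes
  calls <- matrix(missing_call(), 2L * N, M)
  for (j in seq_len(M)) {
    het <- iupac_het(risk_letter[j], other_letter[j])
    calls[which(dos[, j] == 2L), j] <- risk_letter[j]
    calls[which(dos[, j] == 1L), j] <- het
    calls[which(dos[, j] == 0L), j] <- other_letter[j]
  }
  # realized major/minor labels from sample frequencies (alphabetical on
  # ties), matching what read_ped would assign
  a1 <- a2 <- character(M)
  for (j in seq_len(M)) {
    n_risk_al <- sum(dos[, j], na.rm = TRUE)
    n_called <- 2L * sum(!is.na(dos[, j]))
    freq_risk <- if (n_called > 0) n_risk_al / n_called else 0.5
    flip <- freq_risk < 0.5 ||
      (freq_risk == 0.5 && other_letter[j] < risk_letter[j])
    a1[j] <- if (flip) other_letter[j] else risk_letter[j]
    a2[j] <- if (flip) risk_letter[j] else other_letter[j]
  }
  snp_id <- sprintf("snp%06d", seq_len(M))
  snp_id[is_risk] <- sprintf("risk%03d", seq_len(sum(is_risk)))
  snps <- data.frame(chrom = chrom, snp_id = snp_id, cm = 0,
                     pos_bp = pos, a1 = a1, a2 = a2,
                     stringsAsFactors = FALSE)
  sex_pair <- sample(1:2, N, replace = TRUE)
  animals <- data.frame(
    pair = rep(seq_len(N), each = 2L),
    iid = paste0(rep(c("ctrl", "case"), N), rep(seq_len(N), each = 2L)),
    pat = "0", mat = "0",
    sex = rep(sex_pair, each = 2L),
    phenotype = rep(c(1L, 2L), N),
    stringsAsFactors = FALSE
  )
  # SNPs ordered by chromosome then position for a realistic map
  ord <- order(snps$chrom, snps$pos_bp)
  snps <- snps[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  x <- paired_genotypes(animals, snps, calls)
  attr(x, "manifest") <- list(
    seed = config$seed,
    risk_snp_ids = snp_id[is_risk],
    risk_alleles = risk_letter[is_risk],
    target_maf = target_maf[ord],
    realized_missing = mean(calls == missing_call())
  )
  if (!is.null(prefix)) write_ped_map(x, prefix)
  x
}

#' Deterministic fixture realizing given McNemar quadrants
#'
#' Constructs explicit pair genotypes whose tabulation under the stated
#' scenario returns exactly the quadrant counts (a, b, c, d). When
#' \code{snps} has several rows, every SNP realizes the same pattern
#' (useful for two-locus combined-exposure fixtures).
#'
#' @param a,b,c,d Quadrant counts; \code{a + b + c + d} pairs are built.
#' @param allele \code{"a1"} or \code{"a2"}: which allele label of
#'   \code{snps} is the risk allele.
#' @param model Inheritance scenario.
#' @param snps SNP metadata data.frame (columns \code{chrom},
#'   \code{snp_id}, \code{cm}, \code{pos_bp}, \code{a1}, \code{a2}).
#' @return A \code{paired_genotypes} object.
#' @export
fixture_from_quadrants <- function(a, b, c, d, allele = "a1",
                                   model = "two_copy", snps) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, model %in% .models,
            allele %in% c("a1", "a2"))
  N <- a + b + c + d
  stopifnot(N >= 1)
  risk <- if (allele == "a1") snps$a1 else snps$a2
  other <- if (allele == "a1") snps$a2 else snps$a1
  het <- iupac_het(snps$a1, snps$a2)
  exposed_code <- switch(model, two_copy = risk, one_copy = het,
                         one_or_two = risk)
  unexposed_code <- switch(model, two_copy = het, one_copy = other,
                           one_or_two = other)
  # pair exposure pattern: (case, control) per quadrant
  case_exp <- rep(c(TRUE, TRUE, FALSE, FALSE), c(a, b, c, d))
  ctrl_exp <- rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, c, d))
  M <- nrow(snps)
  calls <- matrix(missing_call(), 2L * N, M)
  for (j in seq_len(M)) {
    ctrl <- ifelse(ctrl_exp, exposed_code[j], unexposed_code[j])
    case <- ifelse(case_exp, exposed_code[j], unexposed_code[j])
    calls[seq(1L, 2L * N, by = 2L), j] <- ctrl
    calls[seq(2L, 2L * N, by = 2L), j] <- case
  }
  animals <- data.frame(
    pair = rep(seq_len(N), each = 2L),
    iid = paste0(rep(c("ctrl", "case"), N), rep(seq_len(N), each = 2L)),
    pat = "0", mat = "0", sex = 0L,
    phenotype = rep(c(1L, 2L), N),
    stringsAsFactors = FALSE
  )
  paired_genotypes(animals, snps, calls)
}
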