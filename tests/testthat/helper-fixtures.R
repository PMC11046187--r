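# Shared fixtures built in code.

# minimal SNP metadata table
snp_meta <- function(n = 1L, chrom = 7L, a1 = "A", a2 = "G") {
  data.frame(chrom = rep_len(chrom, n),
             snp_id = sprintf("s%02d", seq_len(n)),
             cm = 0, pos_bp = 1000 * seq_len(n),
             a1 = rep_len(a1, n), a2 = rep_len(a2, n),
             stringsAsFactors = FALSE)
}

# enumeration oracle for the two-sided McNemar p-values: sum binomial
# PMF terms directly over the support
oracle_mcnemar <- function(b, c, mid = TRUE) {
  t <- b + c
  k <- min(b, c)
  pmf <- dbinom(0:t, t, 0.5)
  lower <- sum(pmf[seq_len(k + 1)])          # P(X <= k)
  p <- if (mid) 2 * (lower - 0.5 * pmf[k + 1]) else 2 * lower
  min(1, p)
}

# enumeration oracle for the Hardy-Weinberg exact mid-p: enumerate all
# genotype tables with the observed allele totals
oracle_hwe_midp <- function(n11, n12, n22) {
  n <- n11 + n12 + n22
  n1 <- 2 * n11 + n12
  rare <- min(n1, 2 * n - n1)
  hets <- seq(rare %% 2, rare, by = 2)
  if (length(hets) <= 1) return(1)
  prob <- vapply(hets, function(h) {
    a <- (rare - h) / 2
    exp(h * log(2) - lfactorial(a) - lfactorial(h) -
          lfactorial(n - a - h))
  }, numeric(1))
  prob <- prob / sum(prob)
  obs <- prob[hets == n12]
  rel <- prob / obs
  min(1, sum(prob[rel < 1 - 1e-9]) + 0.5 * sum(prob[abs(rel - 1) <= 1e-9]))
}
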