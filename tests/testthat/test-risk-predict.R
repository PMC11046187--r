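test_that("all nine two-locus configurations map to the published tiers", {
  expected <- rbind(
    c(0, 0, 0, "1x",   0, 1),
    c(1, 0, 1, "1x",  25, 2),
    c(0, 1, 1, "1x",  25, 2),
    c(1, 1, 2, "1x",  50, 3),
    c(2, 0, 2, "8x",  50, 3),
    c(0, 2, 2, "8x",  50, 3),
    c(2, 1, 3, "8x",  75, 4),
    c(1, 2, 3, "8x",  75, 4),
    c(2, 2, 4, "28x", 100, 5)
  )
  for (i in seq_len(nrow(expected))) {
    cfg <- risk_tier(as.integer(expected[i, 1]), as.integer(expected[i, 2]))
    expect_equal(cfg$total_risk_alleles, as.integer(expected[i, 3]))
    expect_equal(cfg$tier_label, expected[i, 4])
    expect_equal(cfg$transmission_prob, as.numeric(expected[i, 5]))
    expect_equal(cfg$breeding_rank, as.integer(expected[i, 6]))
    expect_equal(cfg$transmission_prob, 25 * cfg$total_risk_alleles)
  }
})

test_that("copy counting disambiguates IUPAC heterozygotes per locus", {
  expect_equal(risk_allele_copies("A", "A", c("A", "G")), 2L)
  expect_equal(risk_allele_copies("R", "A", c("A", "G")), 1L)
  expect_equal(risk_allele_copies("G", "A", c("A", "G")), 0L)
  expect_true(is.na(risk_allele_copies(missing_call(), "A", c("A", "G"))))
  expect_error(risk_allele_copies("Y", "A", c("A", "G")), "not legal")
  cl <- classify_animal("A", "T", c("A", "T"), c("A", "G"), c("T", "C"))
  expect_equal(cl$tier_label, "28x")
  cl2 <- classify_animal("N", "T", c("A", "T"), c("A", "G"), c("T", "C"))
  expect_false(cl2$classifiable)
})

test_that("combined two-locus exposure reproduces the published two-gene test", {
  snps <- snp_meta(2, chrom = c(7L, 3L), a1 = c("A", "T"), a2 = c("G", "C"))
  x <- fixture_from_quadrants(73, 28, 1, 0, "a1", "two_copy", snps)
  res <- combined_exposure_mcnemar(x, "s01", "s02")
  expect_equal(res$b, 28)
  expect_equal(res$c, 1)
  expect_equal(res$or, 28)
  expect_equal(res$exact_p, 1.1e-7, tolerance = 0.02)
  expect_equal(res$ci_high, 206, tolerance = 0.005)
  expect_equal(res$ci_low, 4, tolerance = 0.06)
  # single-locus tabulation agrees with the generic scan machinery
  tab <- tabulate_pairs(x, "s01", "a1", "two_copy")
  expect_equal(unname(tab[c("a", "b", "c", "d")]), c(73, 28, 1, 0))
})

test_that("predictive values follow Bayes rule and invert", {
  m <- predictive_values(0.91, 0.58, 0.05)
  expect_equal(m$ppv, 0.10, tolerance = 0.03)
  expect_equal(m$npv, 0.99, tolerance = 0.005)
  expect_equal(predictive_values(1, 1, 0.3)$ppv, 1)
  expect_equal(predictive_values(1, 1, 0.3)$npv, 1)
  expect_equal(predictive_values(0.5, 0.5, 0.5)$ppv, 0.5)
  expect_equal(predictive_values(0.5, 0.5, 0.5)$npv, 0.5)
  # forward-backward inversion: solve (se, sp) back from (ppv, npv, pi)
  se <- 0.73; sp <- 0.62; pi <- 0.12
  m2 <- predictive_values(se, sp, pi)
  # from ppv: se*pi/(se*pi + (1-sp)(1-pi)) = ppv and npv likewise; solve
  # the 2x2 linear system in se, sp
  A <- rbind(c(pi * (1 - m2$ppv), m2$ppv * (1 - pi)),
             c(pi * m2$npv, (1 - pi) * (1 - m2$npv)))
  rhs <- c(m2$ppv * (1 - pi), pi * m2$npv)
  sol <- solve(A, rhs)
  expect_equal(sol[1], se, tolerance = 1e-9)
  expect_equal(sol[2], sp, tolerance = 1e-9)
})

test_that("cohort summaries recover known tier mixtures", {
  g <- data.frame(
    cohort = c("a", "a", "a", "a", "b", "b"),
    locus1 = c("A", "R", "A", "G", "N", "A"),
    locus2 = c("T", "T", "Y", "C", "T", "T"),
    stringsAsFactors = FALSE
  )
  out <- cohort_risk_summary(g, c("A", "T"), c("A", "G"), c("T", "C"))
  a <- out[out$cohort == "a", ]
  expect_equal(a$n_typed, 4)
  expect_equal(a$n_28x, 1)      # only (A, T) is 28x
  expect_equal(a$frac_both_hom, 0.25)
  b <- out[out$cohort == "b", ]
  expect_equal(b$n_unclassified, 1)
  expect_equal(b$n_typed, 1)
  # simulated mixture recovered
  set.seed(77)
  n <- 400
  tiers <- sample(c("low", "one", "both"), n, TRUE, c(0.5, 0.3, 0.2))
  l1 <- ifelse(tiers == "both" | (tiers == "one" & runif(n) < 0.5),
               "A", "R")
  l2 <- ifelse(tiers == "both" | (tiers == "one" & l1 != "A"), "T", "Y")
  g2 <- data.frame(cohort = "sim", locus1 = l1, locus2 = l2)
  out2 <- cohort_risk_summary(g2, c("A", "T"), c("A", "G"), c("T", "C"))
  expect_equal(out2$frac_both_hom, mean(tiers == "both"), tolerance = 1e-12)
})
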