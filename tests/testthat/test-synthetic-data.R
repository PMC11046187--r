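test_that("generation is reproducible and matches configured frequencies", {
  cfg <- sim_config(n_pairs = 102, n_null_snps = 200, missing_rate = 0.02,
                    within_pair_corr = 0, seed = 41)
  x <- generate_pairs(cfg)
  y <- generate_pairs(cfg)
  expect_identical(x$calls, y$calls)
  expect_identical(x$snps, y$snps)
  # different seed differs
  z <- generate_pairs(sim_config(n_pairs = 102, n_null_snps = 200,
                                 missing_rate = 0.02,
                                 within_pair_corr = 0, seed = 42))
  expect_false(identical(x$calls, z$calls))
  # realized MAF within 3 binomial SE of the manifest's target
  target <- attr(x, "manifest")$target_maf
  for (j in seq_len(50)) {
    cnt <- genotype_counts(x$calls[, j], x$snps$a1[j], x$snps$a2[j])
    n_called <- sum(cnt[1:3])
    se <- sqrt(target[j] * (1 - target[j]) / (2 * n_called))
    expect_lt(abs(maf(cnt) - target[j]), 3 * se + 1e-9)
  }
})

test_that("within-pair correlation increases with the rho knob", {
  est_corr <- function(rho, seed) {
    cfg <- sim_config(n_pairs = 150, n_null_snps = 150,
                      missing_rate = 0, within_pair_corr = rho,
                      maf_range = c(0.2, 0.4), seed = seed)
    x <- generate_pairs(cfg)
    d <- dosage_a1(x)
    ctrl <- d[seq(1, nrow(d), 2), ]
    case <- d[seq(2, nrow(d), 2), ]
    mean(vapply(seq_len(ncol(d)), function(j) {
      suppressWarnings(cor(ctrl[, j], case[, j]))
    }, numeric(1)), na.rm = TRUE)
  }
  c0 <- est_corr(0, 1)
  c2 <- est_corr(0.2, 2)
  c5 <- est_corr(0.5, 3)
  expect_lt(c0, c2)
  expect_lt(c2, c5)
  expect_lt(abs(c0), 0.05)
})

test_that("risk loci realize the configured discordant odds ratio", {
  # moderate replication: median estimated OR near theta = 8
  reps <- 60
  ors <- cover <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_pairs = 102, n_null_snps = 0,
                      risk_loci = data.frame(chrom = 7, pos = 9e7,
                                             maf = 0.45,
                                             model = "two_copy",
                                             theta = 8),
                      missing_rate = 0, seed = 1000 + r)
    x <- generate_pairs(cfg)
    man <- attr(x, "manifest")
    j <- match(man$risk_snp_ids, x$snps$snp_id)
    risk <- man$risk_alleles
    al <- if (x$snps$a1[j] == risk) "a1" else "a2"
    tab <- tabulate_pairs(x, man$risk_snp_ids, al, "two_copy")
    ors[r] <- tab["b"] / tab["c"]
    ci <- odds_ratio_ci(tab["b"], tab["c"])
    cover[r] <- isTRUE(ci$ci_low <= 8 && ci$ci_high >= 8)
  }
  expect_gt(median(ors), 6.5)
  expect_lt(median(ors), 10)
  expect_gt(mean(cover), 0.85)
})

test_that("infeasible risk configurations are rejected", {
  expect_error(
    sim_config(risk_loci = data.frame(chrom = 1, pos = 1, maf = 0,
                                      model = "one_copy", theta = 2)),
    "infeasible")
  expect_error(
    sim_config(risk_loci = data.frame(chrom = 1, pos = 1, maf = 0.3,
                                      model = "two_copy", theta = -1)))
})

test_that("quadrant fixtures tabulate to exactly the requested counts", {
  for (model in c("one_copy", "one_or_two", "two_copy")) {
    x <- fixture_from_quadrants(55, 42, 5, 0, "a1", model, snp_meta(1))
    tab <- tabulate_pairs(x, "s01", "a1", model)
    expect_equal(unname(tab), c(55, 42, 5, 0, 102))
  }
  # the published top row emerges verbatim from the pipeline statistics
  x <- fixture_from_quadrants(55, 42, 5, 0, "a1", "two_copy", snp_meta(1))
  scan <- run_genome_scan(x)
  row <- scan[scan$allele == "a1" & scan$model == "two_copy", ]
  expect_equal(row$b, 42)
  expect_equal(row$c, 5)
  expect_equal(round(row$neglog10_mid_p, 2), 7.86)
  expect_equal(round(row$chi2_cc, 1), 27.6)
  expect_equal(round(row$OR, 1), 8.4)
  expect_equal(round(row$cohens_g, 3), 0.394)
  expect_equal(round(row$prop_informative, 3), 0.461)
  expect_equal(round(row$prs_value, 2), 0.18)
  # all-concordant fixture is removed by the post-filter
  x0 <- fixture_from_quadrants(0, 0, 0, 20, "a1", "two_copy", snp_meta(1))
  out <- apply_post_filters(run_genome_scan(x0))
  expect_equal(nrow(out$scan), 0L)
  expect_equal(out$report$n_removed_no_informative, 1L)
})

test_that("spiked loci rank at the top of a genome scan", {
  hits <- 0L
  n_seeds <- 5L
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(
      n_pairs = 102, n_null_snps = 2000,
      risk_loci = data.frame(chrom = c(5, 7, 12), pos = c(1e7, 2e7, 3e7),
                             maf = 0.45, model = "two_copy", theta = 8),
      missing_rate = 0.01, seed = 300 + s)
    x <- generate_pairs(cfg)
    scan <- run_genome_scan(x)
    two <- scan[scan$model == "two_copy" & scan$b >= scan$c, ]
    two <- sort_scan(two)
    top10 <- unique(two$snp_id)[1:10]
    if (all(attr(x, "manifest")$risk_snp_ids %in% top10)) hits <- hits + 1L
  }
  expect_gte(hits, n_seeds - 1L)
})
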