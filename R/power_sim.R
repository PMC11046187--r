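# Power analysis for the paired McNemar design: Monte-Carlo simulation
# and a continuity-corrected normal approximation cross-check.
#
# Under a discordant-pair odds ratio theta, a discordant pair is
# case-only with probability p1 = theta / (1 + theta); the number of
# discordant pairs is Binomial(n_pairs, psi).

#' Power specification for the paired McNemar design
#'
#' @param n_pairs Number of matched pairs.
#' @param discordant_prob psi, probability a pair is discordant.
#' @param odds_ratio theta, the discordant-pair odds ratio to detect.
#' @param alpha Two-sided significance level.
#' @param test_variant \code{"exact"}, \code{"mid_p"} or
#'   \code{"chi2_cc"}.
#' @param n_reps Monte-Carlo replicates.
#' @param seed Integer seed.
#' @return A validated \code{power_spec} list.
#' @export
power_spec <- function(n_pairs, discordant_prob, odds_ratio,
                       alpha = 0.01,
                       test_variant = c("exact", "mid_p", "chi2_cc"),
                       n_reps = 20000L, seed = 1L) {
  stopifnot(n_pairs >= 1, discordant_prob > 0, discordant_prob < 1,
            odds_ratio > 0, alpha > 0, alpha < 1, n_reps >= 1)
  structure(list(n_pairs = as.integer(n_pairs),
                 discordant_prob = discordant_prob,
                 odds_ratio = odds_ratio, alpha = alpha,
                 test_variant = match.arg(test_variant),
                 n_reps = as.integer(n_reps), seed = as.integer(seed)),
            class = "power_spec")
}

# p-value of the chosen test variant for vectors b, t (t = b + c)
.paired_test_p <- function(b, t, variant) {
  c_ <- t - b
  p <- switch(variant,
    exact = mcnemar_exact_p(b, c_),
    mid_p = mcnemar_mid_p(b, c_),
    chi2_cc = pchisq(mcnemar_chi2(b, c_, continuity = TRUE), df = 1,
                     lower.tail = FALSE)
  )
  p[t == 0] <- 1
  p
}

#' Simulated power of the paired McNemar test
#'
#' Per replicate the discordant total t ~ Binomial(n_pairs, psi) and the
#' case-only count b ~ Binomial(t, theta / (1 + theta)); the null is
#' rejected when the chosen test's p-value is at most alpha.
#'
#' @param spec A \code{power_spec}.
#' @return List with \code{power} (rejection fraction) and \code{mcse}
#'   (Monte-Carlo standard error).
#' @export
simulate_power <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  set.seed(spec$seed)
  p1 <- spec$odds_ratio / (1 + spec$odds_ratio)
  t <- rbinom(spec$n_reps, spec$n_pairs, spec$discordant_prob)
  b <- rbinom(spec$n_reps, t, p1)
  p <- .paired_test_p(b, t, spec$test_variant)
  pow <- mean(p <= spec$alpha)
  list(power = pow, mcse = sqrt(pow * (1 - pow) / spec$n_reps))
}

#' Analytic power (closed form)
#'
#' Deterministic cross-check for the simulator: the rejection
#' probability of the chosen test is summed exactly over the joint
#' lattice, integrating b ~ Binomial(t, theta / (1 + theta)) over
#' t ~ Binomial(n_pairs, psi). No Monte-Carlo error; agreement with
#' \code{\link{simulate_power}} is limited only by the simulator's
#' replicate count.
#'
#' @param spec A \code{power_spec}.
#' @return Power in [0, 1].
#' @export
approx_power <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  p1 <- spec$odds_ratio / (1 + spec$odds_ratio)
  n <- spec$n_pairs
  wt <- dbinom(0:n, n, spec$discordant_prob)
  total <- 0
  for (t in seq.int(1L, n)) {
    if (wt[t + 1] < 1e-14) next
    k <- 0:t
    rej <- .paired_test_p(k, rep(t, t + 1L), spec$test_variant) <=
      spec$alpha
    if (any(rej)) total <- total + wt[t + 1] * sum(dbinom(k[rej], t, p1))
  }
  total
}

#' Power over a grid of operating points
#'
#' @param n_pairs Pairs.
#' @param psi_grid,theta_grid Discordant probabilities and odds ratios.
#' @param alpha Significance level.
#' @param test_variant Test used for rejection.
#' @param n_reps Replicates per grid point.
#' @param seed Base seed (each grid point offsets it deterministically).
#' @return data.frame: \code{psi}, \code{theta}, \code{power},
#'   \code{mcse}, \code{approx}.
#' @export
power_grid <- function(n_pairs, psi_grid, theta_grid, alpha = 0.01,
                       test_variant = "exact", n_reps = 20000L,
                       seed = 1L) {
  grid <- expand.grid(psi = psi_grid, theta = theta_grid,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sp <- power_spec(n_pairs, grid$psi[i], grid$theta[i], alpha,
                     test_variant, n_reps, seed + i)
    sim <- simulate_power(sp)
    data.frame(psi = grid$psi[i], theta = grid$theta[i],
               power = sim$power, mcse = sim$mcse,
               approx = approx_power(sp))
  })
  do.call(rbind, res)
}
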