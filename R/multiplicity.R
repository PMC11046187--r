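# Genome-wide significance control for the discrete McNemar p-value
# lattice: Bonferroni threshold, Storey q-values with bootstrap and
# cubic-polynomial pi0 estimation, and lattice-aware expected p-value
# distributions for Q-Q plots.

#' Bonferroni genome-wide significance threshold
#'
#' @param alpha Family-wise significance level.
#' @param m_tests Number of filtered SNP tests.
#' @return List with \code{threshold} = alpha / m and its
#'   \code{neglog10} form.
#' @export
bonferroni_threshold <- function(alpha, m_tests) {
  stopifnot(alpha > 0, alpha < 1, m_tests >= 1)
  thr <- alpha / m_tests
  list(threshold = thr, neglog10 = -log10(thr))
}

# pi0(lambda) = #{p > lambda} / (m * (1 - lambda)); one sort, then a
# single findInterval over the whole grid
.pi0_lambda <- function(p, lambda) {
  m <- length(p)
  sp <- sort(p)
  (m - findInterval(lambda, sp)) / (m * (1 - lambda))
}

#' Estimate the proportion of true nulls (pi0)
#'
#' Storey's lambda-tuned estimator. The bootstrap method picks the
#' lambda whose bootstrap mean squared error against the minimum
#' pi0(lambda) over the grid is smallest (Storey & Tibshirani 2003);
#' the polynomial method fits a cubic in lambda to pi0(lambda) and
#' evaluates the fit at the grid maximum. The estimate is clamped to
#' (0, 1].
#'
#' @param p_values Vector of p-values.
#' @param method \code{"bootstrap"} or \code{"polynomial"}.
#' @param lambda_grid Tuning grid in [0, 1); default
#'   \code{seq(0, 0.95, by = 0.01)}.
#' @param n_boot Bootstrap resamples (bootstrap method only).
#' @return List with \code{pi0}, \code{method}, \code{lambda_grid},
#'   \code{pi0_lambda} diagnostics and (bootstrap) the selected
#'   \code{lambda}.
#' @export
estimate_pi0 <- function(p_values, method = c("bootstrap", "polynomial"),
                         lambda_grid = seq(0, 0.95, by = 0.01),
                         n_boot = 100L) {
  method <- match.arg(method)
  p <- p_values[!is.na(p_values)]
  m <- length(p)
  stopifnot(m > 0)
  pl <- .pi0_lambda(p, lambda_grid)
  if (all(p == p[1])) {
    warning("all p-values identical; pi0 set to 1")
    return(list(pi0 = 1, method = method, lambda_grid = lambda_grid,
                pi0_lambda = pl, lambda = NA_real_))
  }
  if (method == "polynomial") {
    fit <- lm(pl ~ poly(lambda_grid, 3, raw = TRUE))
    pi0 <- unname(predict(fit, data.frame(lambda_grid = max(lambda_grid))))
    lam <- max(lambda_grid)
  } else {
    min_pi0 <- min(pl)
    mse <- numeric(length(lambda_grid))
    for (b in seq_len(n_boot)) {
      pb <- p[sample.int(m, m, replace = TRUE)]
      plb <- .pi0_lambda(pb, lambda_grid)
      mse <- mse + (plb - min_pi0)^2
    }
    lam <- lambda_grid[which.min(mse)]
    pi0 <- pl[which.min(mse)]
  }
  pi0 <- min(max(pi0, .Machine$double.eps), 1)
  list(pi0 = pi0, method = method, lambda_grid = lambda_grid,
       pi0_lambda = pl, lambda = lam)
}

#' Storey q-values
#'
#' q(i) = pi0 * m * p(i) / rank(i) on the ascending p-values, made
#' monotone by a cumulative minimum from the largest p downward, then
#' mapped back to the input order. With pi0 = 1 this reduces to the
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param p_values Vector of p-values.
#' @param pi0 Proportion of true nulls in (0, 1].
#' @return Numeric vector of q-values aligned to the input.
#' @export
q_values <- function(p_values, pi0 = 1) {
  stopifnot(pi0 > 0, pi0 <= 1)
  m <- length(p_values)
  ord <- order(p_values)
  q <- pi0 * m * p_values[ord] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

#' Build a Storey q-value set
#'
#' Convenience wrapper bundling pi0 estimation and q-value computation.
#'
#' @inheritParams estimate_pi0
#' @return A \code{qvalue_set} list with \code{p_values}, \code{pi0},
#'   \code{pi0_method}, \code{lambda_grid}, \code{q_values}.
#' @export
qvalue_set <- function(p_values, method = c("bootstrap", "polynomial"),
                       lambda_grid = seq(0, 0.95, by = 0.01),
                       n_boot = 100L) {
  est <- estimate_pi0(p_values, method, lambda_grid, n_boot)
  structure(list(
    p_values = p_values, pi0 = est$pi0, pi0_method = est$method,
    lambda_grid = lambda_grid,
    q_values = q_values(p_values, est$pi0)
  ), class = "qvalue_set")
}

#' @export
print.qvalue_set <- function(x, ...) {
  cat("qvalue_set:", length(x$p_values), "tests, pi0 =",
      signif(x$pi0, 4), "(", x$pi0_method, ")\n")
  invisible(x)
}

#' Discrete null support of a set of McNemar tests
#'
#' For a test with t = b + c discordant pairs the null distribution of
#' the p-value is concentrated on the achievable values p(k), k = 0..t,
#' each with probability Binomial(k; t, 1/2).
#'
#' @param t_values Vector of per-SNP discordant-pair totals.
#' @param statistic \code{"mid_p"} or \code{"exact_p"}.
#' @return A \code{discrete_null} list with the pooled achievable
#'   p-values (\code{p}) and their total null probabilities (\code{w},
#'   summing to \code{length(t_values)}).
#' @export
discrete_null <- function(t_values, statistic = c("mid_p", "exact_p")) {
  statistic <- match.arg(statistic)
  t_values <- t_values[t_values > 0]
  if (length(t_values) == 0L) stop("no tests with informative pairs")
  tab <- table(t_values)
  ps <- ws <- vector("list", length(tab))
  for (i in seq_along(tab)) {
    t <- as.integer(names(tab)[i])
    k <- 0:t
    b <- k
    c <- t - k
    pv <- if (statistic == "mid_p") mcnemar_mid_p(b, c) else
      mcnemar_exact_p(b, c)
    ps[[i]] <- pv
    ws[[i]] <- dbinom(k, t, 0.5) * as.integer(tab[i])
  }
  p <- unlist(ps)
  w <- unlist(ws)
  agg <- rowsum(w, group = p)
  structure(list(p = as.numeric(rownames(agg)), w = as.numeric(agg)),
            class = "discrete_null")
}

#' Expected p-value quantiles for a lattice-aware Q-Q plot
#'
#' Deterministic quantiles of the pooled discrete null distribution of
#' p-values, for pairing with the observed sorted p-values. Expected
#' values are returned ascending so that
#' \code{-log10(expected)} descends like a standard Q-Q x-axis.
#'
#' @param null A \code{discrete_null} object.
#' @param n_points Number of plotting quantiles.
#' @return Numeric vector of expected p-values (ascending), length
#'   \code{n_points}.
#' @export
qq_expected <- function(null, n_points) {
  stopifnot(inherits(null, "discrete_null"), n_points >= 1)
  total <- sum(null$w)
  cw <- cumsum(null$w) / total
  probs <- (seq_len(n_points) - 0.5) / n_points
  idx <- findInterval(probs, cw, left.open = TRUE) + 1L
  idx <- pmin(idx, length(null$p))
  null$p[idx]
}

#' Q-Q plot coordinates
#'
#' Pairs the observed p-values (sorted) with the lattice-aware expected
#' quantiles, both on the -log10 scale.
#'
#' @param observed_p Observed p-values.
#' @param t_values Discordant totals defining the discrete null.
#' @param statistic \code{"mid_p"} or \code{"exact_p"}.
#' @return data.frame with \code{expected} and \code{observed} -log10
#'   p-values, ascending.
#' @export
qq_coords <- function(observed_p, t_values, statistic = "mid_p") {
  nn <- discrete_null(t_values, statistic)
  obs <- sort(observed_p[!is.na(observed_p)])   # ascending p
  exp_p <- qq_expected(nn, length(obs))         # ascending p
  data.frame(expected = -log10(exp_p), observed = -log10(obs))
}
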