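# Synthetic-data generators and the Monte-Carlo drivers behind the
# calibration, phase-transition and graphical simulation studies.

# multivariate normal draws from a precomputed upper Cholesky factor
rmvn_chol <- function(n, mean, chol_up) {
  p <- length(mean)
  sweep(matrix(stats::rnorm(n * p), n, p) %*% chol_up, 2, mean, `+`)
}

#' Draw a null pair of samples
#'
#' Two independent samples from the same multivariate normal distribution.
#' By affine invariance the null distribution of every statistic in the
#' package does not depend on the generating mean or covariance, so the
#' default uses a zero mean and identity covariance; pass a covariance (and
#' optionally a mean) to exercise the invariance, or `sigma = "random_spd"`
#' for a randomly generated positive definite covariance with a random mean.
#'
#' @param p Dimension.
#' @param n1,n2 Group sample sizes.
#' @param sigma `NULL` (identity), a p-by-p positive definite matrix, or
#'   `"random_spd"`.
#' @param mean Mean vector (recycled); default 0.
#' @param seed Optional integer seed for exact reproducibility.
#' @return A [two_sample_data] with labels `"1".."p"`.
#' @export
simulate_null_pair <- function(p, n1, n2, sigma = NULL, mean = 0,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (identical(sigma, "random_spd")) {
    a <- matrix(stats::rnorm(p * p), p)
    sigma <- crossprod(a) / p + diag(0.5, p)
    mean <- stats::rnorm(p)
  }
  mu <- rep_len(mean, p)
  r <- if (is.null(sigma)) diag(p) else chol(sigma)
  two_sample_data(rmvn_chol(n1, mu, r), rmvn_chol(n2, mu, r),
                  labels = as.character(seq_len(p)))
}

#' Covariance matrix Markov with respect to a graph
#'
#' Builds a positive definite covariance whose inverse (precision matrix) has
#' zeros exactly at the non-edges of the graph, so that a Gaussian vector
#' with this covariance is Markov with respect to it.  The precision matrix
#' starts from the identity with `-strength` at every edge (so `strength` is
#' the partial-correlation magnitude); if that matrix is not positive
#' definite the strength is shrunk by 10% until it is (with a message).  The
#' result is rescaled to unit diagonal, which preserves both the zero pattern
#' and the partial correlations.
#'
#' @param graph An [undirected_graph] or a [rip_structure] (its graph is
#'   reconstituted from the cliques).
#' @param strength Target partial-correlation magnitude on edges; default
#'   0.3.
#' @return A unit-diagonal positive definite covariance matrix with node
#'   labels as dimnames.
#' @examples
#' k <- solve(graph_markov_sigma(four_clique_graph()))
#' max(abs(k[!four_clique_graph()$adj & !diag(14)]))  # ~ 0: non-edges vanish
#' @export
graph_markov_sigma <- function(graph, strength = 0.3) {
  if (inherits(graph, "rip_structure")) {
    edges <- do.call(rbind, lapply(graph$cliques, function(cl) {
      if (length(cl) > 1) t(utils::combn(cl, 2)) else NULL
    }))
    graph <- undirected_graph(edges, nodes = graph$nodes)
  }
  stopifnot(inherits(graph, "undirected_graph"))
  p <- length(graph$nodes)
  s <- strength
  repeat {
    k <- diag(p)
    dimnames(k) <- list(graph$nodes, graph$nodes)
    if (nrow(graph$edges)) {
      k[graph$edges] <- -s
      k[graph$edges[, 2:1, drop = FALSE]] <- -s
    }
    if (min(eigen(k, symmetric = TRUE, only.values = TRUE)$values) > 1e-8)
      break
    s <- 0.9 * s
  }
  if (s < strength)
    message("edge strength ", strength, " gives an indefinite precision ",
            "matrix; shrunk to ", signif(s, 3))
  sig <- solve(k)
  d <- 1 / sqrt(diag(sig))
  sig <- sig * tcrossprod(d)
  dimnames(sig) <- list(graph$nodes, graph$nodes)
  sig
}

# binomial Monte-Carlo standard error
mc_se <- function(rate, reps) sqrt(rate * (1 - rate) / reps)

#' Graphical simulation study: altered clique, null remainder
#'
#' Reproduces the decomposable-model experiment on the
#' [four_clique_graph()]: condition 1 has all means 1.0 and a unit-diagonal
#' covariance Markov with respect to the graph (partial-correlation strength
#' 0.3); condition 2 is identical except that nodes `"1"` and `"2"` (inside
#' the first clique, outside every separator) have their means multiplied by
#' 1.5 and their variances halved, with all correlations preserved.  Hence
#' the local hypothesis on \eqn{C_1} is false while the conditional
#' hypotheses \eqn{C_i|S_i}, \eqn{i \ge 2}, remain true.  Each replicate
#' computes the uncorrected and delta-corrected local statistics and records
#' rejections at level `alpha` against the local chi-square references.
#'
#' Because the alteration touches only coordinates 1 and 2, the marginal
#' laws over \eqn{C_2, C_3, C_4} and all separators are identical across
#' conditions; with `altered = FALSE` both samples are drawn from condition 1
#' (global null), which leaves rows 2-4 distributionally unchanged and turns
#' row 1 into a null cell as well.
#'
#' @param nj Common group sample size (> 9 so the 8-node clique tests exist).
#' @param reps Number of Monte-Carlo replicates (default 2000; the published
#'   table uses 10000).
#' @param alpha Significance level, default 0.05.
#' @param altered If `FALSE`, simulate under the global null.
#' @param mean_multiplier,var_multiplier Alteration applied to nodes 1-2 in
#'   condition 2; defaults 1.5 and 0.5.
#' @param corrections Character vector among `"none"`, `"delta"`, `"rho"`.
#' @param seed Optional integer seed.
#' @return Object of class `mc_report` whose `rates` data frame has one row
#'   per (term, statistic): empirical rejection rate and binomial Monte-Carlo
#'   standard error.
#' @export
clique_alteration_study <- function(nj, reps = 2000, alpha = 0.05,
                                    altered = TRUE,
                                    mean_multiplier = 1.5,
                                    var_multiplier = 0.5,
                                    corrections = c("none", "delta"),
                                    seed = NULL) {
  stopifnot(nj > 9, reps >= 1)
  corrections <- match.arg(corrections, c("none", "delta", "rho"),
                           several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  g <- four_clique_graph()
  s <- rip_structure(g)
  sigma1 <- graph_markov_sigma(g)
  mu1 <- rep(1, 14)
  if (altered) {
    d <- rep(1, 14); d[1:2] <- sqrt(var_multiplier)
    sigma2 <- sigma1 * tcrossprod(d)
    mu2 <- mu1; mu2[1:2] <- mu2[1:2] * mean_multiplier
  } else {
    sigma2 <- sigma1; mu2 <- mu1
  }
  r1 <- chol(sigma1); r2 <- chol(sigma2)
  sizes_c <- vapply(s$cliques, length, integer(1))
  sizes_s <- vapply(s$separators, length, integer(1))
  dfs <- equality_df(sizes_c) -
    vapply(sizes_s, function(ps) if (ps) equality_df(ps) else 0L, integer(1))
  crit <- stats::qchisq(1 - alpha, dfs)
  factors <- vapply(corrections, function(kind) {
    vapply(seq_along(sizes_c), function(i)
      local_factor(kind, sizes_c[i], sizes_s[i], nj, nj), numeric(1))
  }, numeric(length(sizes_c)))
  labels <- as.character(1:14)
  rej <- array(0L, dim = c(length(dfs), length(corrections)))
  for (r in seq_len(reps)) {
    d <- two_sample_data(rmvn_chol(nj, mu1, r1), rmvn_chol(nj, mu2, r2),
                         labels = labels)
    w <- local_wn_stats(d, s)
    rej <- rej + (outer(w, rep(1, length(corrections))) * factors >
                    outer(crit, rep(1, length(corrections))))
  }
  rates <- data.frame(
    term = rep(local_labels(s), times = length(corrections)),
    statistic = rep(ifelse(corrections == "none", "Wn",
                           ifelse(corrections == "delta", "Tn", "rho*Wn")),
                    each = length(dfs)),
    df = rep(dfs, times = length(corrections)),
    nj = nj,
    rate = as.vector(rej) / reps,
    stringsAsFactors = FALSE)
  rates$se <- mc_se(rates$rate, reps)
  mc_report(rates, config = list(scenario = "clique_alteration", nj = nj,
                                 reps = reps, alpha = alpha,
                                 altered = altered, seed = seed))
}

#' Phase-transition experiment for the chi-square approximations
#'
#' Empirical Type-I error of the uncorrected, rho-corrected and
#' delta-corrected statistics when the dimension grows as a power of the
#' sample size, \eqn{p = \langle n_1^\varepsilon \rangle} (nearest integer),
#' under the null.  The chi-square approximation of each statistic holds up
#' to its boundary exponent: 1/2 for \eqn{W_n}, 2/3 for \eqn{\rho W_n} and 1
#' for \eqn{T_n}, so plotting the rate against \eqn{\varepsilon} displays
#' the three transitions.
#'
#' @param nj Common group sample size (published study: 100, 500, 1000).
#' @param eps Grid of exponents in (0, 1); default
#'   `c(6:23, 23.5) / 24`.
#' @param reps Replicates per grid point (default 1000, as published).
#' @param alpha Nominal level.
#' @param seed Optional integer seed.
#' @return An `mc_report`; rows with `p >= nj - 1` are flagged inadmissible
#'   (`NA` rate) rather than computed.
#' @export
phase_transition_study <- function(nj, eps = c(6:23, 23.5) / 24,
                                   reps = 1000, alpha = 0.05, seed = NULL) {
  stopifnot(all(eps < 1), reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  stats_names <- c("Wn", "rho*Wn", "Tn")
  out <- vector("list", length(eps))
  for (k in seq_along(eps)) {
    p <- as.integer(round(nj^eps[k]))
    if (p >= nj - 1) {
      out[[k]] <- data.frame(eps = eps[k], p = p, statistic = stats_names,
                             rate = NA_real_, se = NA_real_,
                             admissible = FALSE, stringsAsFactors = FALSE)
      next
    }
    f <- equality_df(p)
    crit <- stats::qchisq(1 - alpha, f)
    thresholds <- crit / c(1, rho_factor(p, nj, nj), f / mu_wn(p, nj, nj))
    rej <- numeric(3)
    for (r in seq_len(reps)) {
      w <- wn_statistic(simulate_null_pair(p, nj, nj))$statistic
      rej <- rej + (w > thresholds)
    }
    rate <- rej / reps
    out[[k]] <- data.frame(eps = eps[k], p = p, statistic = stats_names,
                           rate = rate, se = mc_se(rate, reps),
                           admissible = TRUE, stringsAsFactors = FALSE)
  }
  mc_report(do.call(rbind, out),
            config = list(scenario = "phase_transition", nj = nj,
                          reps = reps, alpha = alpha, seed = seed))
}

#' Null-distribution approximation study
#'
#' For each dimension in `p`, draws null replicates at fixed group size and
#' retains the samples of the four statistics — \eqn{W_n}, \eqn{\rho W_n},
#' \eqn{T_n} (all against \eqn{\chi^2_f}) and the CLT z-score (against the
#' standard normal) — together with summary moments and the
#' Kolmogorov-Smirnov distance to the reference law.
#'
#' @param p Vector of dimensions (published study: 2, 30, 40 at `nj = 50`).
#' @param nj Common group sample size.
#' @param reps Replicates per dimension (default 2000; published: 5000).
#' @param seed Optional integer seed.
#' @param keep_samples Retain the raw statistic samples (default `TRUE`).
#' @return An `mc_report` whose `rates` table holds, per (p, statistic):
#'   mean, variance, skewness, KS distance and the reference distribution;
#'   raw draws are in `$samples` (a list of reps-by-4 matrices) when kept.
#' @export
approximation_study <- function(p = c(2, 30, 40), nj = 50, reps = 2000,
                                seed = NULL, keep_samples = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  samples <- list()
  rows <- list()
  skew <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
  for (pp in p) {
    f <- equality_df(pp)
    rho <- rho_factor(pp, nj, nj)
    delta <- f / mu_wn(pp, nj, nj)
    sd_ll <- sqrt(wn_null_moments(pp, nj, nj)$var) / 2
    mu_n <- -mu_wn(pp, nj, nj) / 2
    w <- numeric(reps)
    for (r in seq_len(reps))
      w[r] <- wn_statistic(simulate_null_pair(pp, nj, nj))$statistic
    draws <- cbind(Wn = w, `rho*Wn` = rho * w, Tn = delta * w,
                   z = (-w / 2 - mu_n) / sd_ll)
    if (keep_samples) samples[[as.character(pp)]] <- draws
    refs <- c("chi_square", "chi_square", "chi_square", "standard_normal")
    ks <- c(vapply(1:3, function(j)
      suppressWarnings(stats::ks.test(draws[, j], "pchisq", df = f))$statistic,
      numeric(1)),
      suppressWarnings(stats::ks.test(draws[, 4], "pnorm"))$statistic)
    rows[[as.character(pp)]] <- data.frame(
      p = pp, statistic = colnames(draws), reference = refs, df = f,
      mean = colMeans(draws), var = apply(draws, 2, stats::var),
      skewness = apply(draws, 2, skew), ks = ks,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  rep_out <- mc_report(do.call(rbind, rows),
                       config = list(scenario = "approximation", nj = nj,
                                     reps = reps, seed = seed))
  if (keep_samples) rep_out$samples <- samples
  rep_out
}

mc_report <- function(rates, config) {
  structure(list(rates = rates, config = config), class = "mc_report")
}

#' @export
print.mc_report <- function(x, digits = 3, ...) {
  cat("Monte-Carlo report:", x$config$scenario,
      "(reps =", x$config$reps, ")\n")
  print(x$rates, digits = digits, row.names = FALSE)
  invisible(x)
}
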