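# Finite-sample corrections of the equality LRT: the expansion-based rho
# factor, the mean-based delta factor (Tn = delta_n * Wn), a CLT
# standardization, and exact null moments used to validate both.

#' Degrees of freedom of the equality test
#'
#' The asymptotic chi-square null distribution of the two-sample equality LRT
#' in dimension `p` has \eqn{f = p(p+3)/2} degrees of freedom (\eqn{p} mean
#' parameters plus \eqn{p(p+1)/2} covariance parameters).
#'
#' @param p Integer dimension, `p >= 1`.
#' @return Integer `p * (p + 3) / 2`.
#' @examples
#' equality_df(c(2, 30, 40))  # 5, 495, 860
#' @export
equality_df <- function(p) {
  if (any(p < 1) || any(p != round(p)))
    stop("p must be a positive integer", call. = FALSE)
  as.integer(p * (p + 3) / 2)
}

#' Expansion-based Bartlett correction factor rho
#'
#' Box-type multiplicative correction for the two-sample equality LRT,
#' \deqn{\rho = 1 - \frac{2p^2 + 9p + 11}{6(p+3)\,n}
#'   \left(\sum_{j=1}^2 \frac{n}{n_j} - 1\right), \quad n = n_1 + n_2,}
#' so that \eqn{\rho W_n} is closer to its \eqn{\chi^2_f} reference than
#' \eqn{W_n}.  The correction is accurate while \eqn{p/n^{2/3} \to 0} and
#' degrades when \eqn{p} grows proportionally to \eqn{n}.
#'
#' @param p Dimension.
#' @param n1,n2 Group sample sizes, both `> p + 1`.
#' @return The scalar factor, in `(0, 1]` for all admissible sizes used here.
#' @seealso [delta_factor()] for the mean-based correction.
#' @export
rho_factor <- function(p, n1, n2) {
  check_sizes(p, n1, n2)
  n <- n1 + n2
  1 - (2 * p^2 + 9 * p + 11) / (6 * (p + 3) * n) * (n / n1 + n / n2 - 1)
}

#' Approximate null mean of the equality LRT statistic
#'
#' Computes \eqn{\mu_{w_n} = -2\mu_n}, an analytic approximation of
#' \eqn{E_{H_0}[W_n]} valid also when \eqn{p} grows with \eqn{n}, where
#' \deqn{\mu_n = \tfrac14\Big[-4p - \sum_j p/n_j + n\,r_n^2\,(2p - 2n + 3)
#'  - \sum_j n_j\,r_{n_j'}^2\,(2p - 2n_j + 3)\Big],}
#' with \eqn{n_j' = n_j - 1}, \eqn{n = n_1 + n_2} and
#' \eqn{r_x^2 = -\log(1 - p/x)} for \eqn{x > p}.  As \eqn{n_j \to \infty}
#' with \eqn{p} fixed, \eqn{\mu_{w_n} \to f = p(p+3)/2}.
#'
#' The bracketed group term admits a second typographic reading
#' (\eqn{2p - 2n_j' + 3}); it is available via `last_factor = "njprime"` but
#' is far from the exact null mean (see [wn_null_moments()]) and is not the
#' default.
#'
#' @param p Dimension, `p < min(n1, n2) - 1`.
#' @param n1,n2 Group sample sizes.
#' @param last_factor Which reading of the final factor to use; keep the
#'   default.
#' @return Positive scalar approximating the null mean of \eqn{W_n}.
#' @export
mu_wn <- function(p, n1, n2, last_factor = c("nj", "njprime")) {
  last_factor <- match.arg(last_factor)
  check_sizes(p, n1, n2, strict = TRUE)
  n <- n1 + n2
  nj <- c(n1, n2)
  njp <- nj - 1
  rx2 <- function(x) -log(1 - p / x)
  fac <- if (last_factor == "nj") 2 * p - 2 * nj + 3 else 2 * p - 2 * njp + 3
  mu_n <- 0.25 * (-4 * p - sum(p / nj) +
                    n * rx2(n) * (2 * p - 2 * n + 3) -
                    sum(nj * rx2(njp) * fac))
  -2 * mu_n
}

#' Mean-based correction factor delta and specification objects
#'
#' The adjusted statistic is \eqn{T_n = \delta_n W_n} with
#' \eqn{\delta_n = f / \mu_{w_n}}: the ratio between the chi-square degrees of
#' freedom and the approximate null mean of \eqn{W_n} from [mu_wn()].  Its
#' chi-square approximation holds whenever \eqn{p/n \to 0}, covering regimes
#' (such as \eqn{p} close to \eqn{n_j}) where both the raw statistic and the
#' \eqn{\rho} correction fail.
#'
#' `correction_spec()` builds the same record for any correction kind and is
#' what [corrected_test()] consumes.
#'
#' @param p Dimension.
#' @param n1,n2 Group sample sizes.
#' @param kind One of `"none"`, `"rho"`, `"delta"`.
#' @return A list of class `correction_spec` with fields `kind`, `factor`,
#'   `p`, `n1`, `n2`.
#' @examples
#' delta_factor(40, 50, 50)$factor  # well below rho_factor(40, 50, 50)
#' @export
delta_factor <- function(p, n1, n2) correction_spec("delta", p, n1, n2)

#' @rdname delta_factor
#' @export
correction_spec <- function(kind = c("delta", "rho", "none"), p, n1, n2) {
  kind <- match.arg(kind)
  factor <- switch(kind,
                   none  = 1,
                   rho   = rho_factor(p, n1, n2),
                   delta = equality_df(p) / mu_wn(p, n1, n2))
  structure(list(kind = kind, factor = factor, p = as.integer(p),
                 n1 = as.integer(n1), n2 = as.integer(n2)),
            class = "correction_spec")
}

#' @export
print.correction_spec <- function(x, ...) {
  cat(sprintf("correction '%s' (p = %d, n1 = %d, n2 = %d): factor = %.6g\n",
              x$kind, x$p, x$n1, x$n2, x$factor))
  invisible(x)
}

#' Apply a multiplicative correction to an uncorrected LRT result
#'
#' Rescales the statistic by the factor in `spec`, keeps the degrees of
#' freedom, and recomputes the upper-tail chi-square p-value.
#'
#' @param base An uncorrected `lrt_test` (from [wn_statistic()],
#'   [marginal_wn()] or [conditional_wn()]).
#' @param spec A `correction_spec` whose `p` matches the dimension implied by
#'   `base$df` (marginal tests only; conditional tests are corrected inside
#'   [ggm_equality_test()] where both dimensions are known).
#' @return The corrected `lrt_test`.
#' @export
corrected_test <- function(base, spec) {
  stopifnot(inherits(base, "lrt_test"), inherits(spec, "correction_spec"))
  if (base$correction != "none")
    stop("`base` is already corrected (", base$correction, ")", call. = FALSE)
  if (!length(base$conditioning) && base$df != equality_df(spec$p))
    stop("correction dimension p = ", spec$p,
         " does not match the test's degrees of freedom", call. = FALSE)
  w <- base$statistic * spec$factor
  out <- base
  out$statistic <- w
  out$p.value <- chi2_pvalue(w, base$df)
  out$correction <- spec$kind
  out$factor <- spec$factor
  out
}

#' Exact null moments of the equality LRT statistic
#'
#' Under the null, \eqn{\Lambda_n} factorizes into independent pieces — a
#' matrix-beta determinant pair (covariance part) and a univariate beta
#' (Wilks' lambda for the mean, hypothesis df 1) — whose log-moments are sums
#' of digamma/trigamma values.  This yields the exact finite-sample mean and
#' variance of \eqn{W_n = -2\log\Lambda_n}, used as the dispersion term of
#' [clt_zscore()] and as an independent oracle for [mu_wn()] and
#' [rho_factor()] in the test suite.
#'
#' @param p Dimension, `p < min(n1, n2) - 1`.
#' @param n1,n2 Group sample sizes.
#' @return Named list with `mean` and `var` of \eqn{W_n} under \eqn{H_0}.
#' @export
wn_null_moments <- function(p, n1, n2) {
  check_sizes(p, n1, n2, strict = TRUE)
  m1 <- n1 - 1; m2 <- n2 - 1; m <- m1 + m2; n <- n1 + n2
  i <- seq_len(p)
  sdig <- function(a) sum(digamma(a - (i - 1) / 2))
  stri <- function(a) sum(trigamma(a - (i - 1) / 2))
  e_lb  <- sdig(m1 / 2) - sdig(m / 2)   # E log det B,  B ~ matrix-Beta
  e_lib <- sdig(m2 / 2) - sdig(m / 2)   # E log det (I - B)
  e_lu  <- digamma((n - 1 - p) / 2) - digamma((n - 1) / 2)  # E log U
  mean_wn <- -p * (n * log(n) - n1 * log(n1) - n2 * log(n2)) -
    n1 * e_lb - n2 * e_lib - n * e_lu
  v_lb  <- stri(m1 / 2) - stri(m / 2)
  v_lib <- stri(m2 / 2) - stri(m / 2)
  c_ll  <- -stri(m / 2)                 # Cov(log det B, log det (I - B))
  v_lu  <- trigamma((n - 1 - p) / 2) - trigamma((n - 1) / 2)
  var_wn <- n1^2 * v_lb + n2^2 * v_lib + 2 * n1 * n2 * c_ll + n^2 * v_lu
  list(mean = mean_wn, var = var_wn)
}

#' CLT standardization of the log likelihood ratio
#'
#' High-dimensional comparator: centers \eqn{\log\Lambda_n} at the analytic
#' mean \eqn{\mu_n = -\mu_{w_n}/2} and scales by the exact finite-sample
#' standard deviation of \eqn{\log\Lambda_n} (from [wn_null_moments()]),
#' referring the result to a standard normal.  Evidence against equality
#' shrinks \eqn{\Lambda_n}, so the test is one-sided: the p-value is the
#' lower tail of the z-score.  Accurate when \eqn{p} is large (even close to
#' \eqn{n_j}) but poor for small \eqn{p}, where the LRT distribution is
#' markedly skewed.
#'
#' @param log_lambda Observed \eqn{\log\Lambda_n}, i.e. `-statistic / 2` from
#'   an uncorrected [wn_statistic()] result.
#' @param p Dimension.
#' @param n1,n2 Group sample sizes.
#' @return An `lrt_test` with `reference = "standard_normal"`; `statistic` is
#'   the signed z-score.
#' @export
clt_zscore <- function(log_lambda, p, n1, n2) {
  mu_n <- -mu_wn(p, n1, n2) / 2
  sd_ll <- sqrt(wn_null_moments(p, n1, n2)$var) / 2
  z <- (log_lambda - mu_n) / sd_ll
  new_lrt_test(z, df = equality_df(p), p_value = stats::pnorm(z),
               reference = "standard_normal", correction = "clt",
               n1 = n1, n2 = n2)
}

# shared admissibility checks; strict additionally needs p < n_j - 1 so that
# r_{n_j'} (and the exact moments) are defined
check_sizes <- function(p, n1, n2, strict = FALSE) {
  if (p < 1 || p != round(p)) stop("p must be a positive integer", call. = FALSE)
  if (n1 <= p + 1 || n2 <= p + 1)
    stop("group sizes must exceed p + 1 (p = ", p, ", n1 = ", n1,
         ", n2 = ", n2, ")", call. = FALSE)
  if (strict && (p >= n1 - 1 || p >= n2 - 1))
    stop("p must be smaller than n_j - 1", call. = FALSE)
  invisible(TRUE)
}
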