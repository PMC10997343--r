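# Core likelihood ratio statistics for equality of two multivariate normal
# distributions: full variable set, marginal subsets, and conditional
# (clique-given-separator) form.

# assemble a test-result record; `statistic` is clipped/validated upstream
new_lrt_test <- function(statistic, df, p_value, reference, correction,
                         subset = character(), conditioning = character(),
                         n1 = NA_integer_, n2 = NA_integer_, factor = NA_real_) {
  structure(list(statistic = statistic, df = df, p.value = p_value,
                 reference = reference, correction = correction,
                 subset = subset, conditioning = conditioning,
                 n1 = n1, n2 = n2, factor = factor),
            class = "lrt_test")
}

#' @export
print.lrt_test <- function(x, digits = 4, ...) {
  lab <- if (length(x$conditioning))
    paste0(paste(x$subset, collapse = ","), " | ",
           paste(x$conditioning, collapse = ","))
  else if (length(x$subset)) paste(x$subset, collapse = ",")
  else "all variables"
  cat("Two-sample equality LRT (", lab, ")\n", sep = "")
  stat_name <- switch(x$correction, none = "Wn", rho = "rho*Wn", delta = "Tn",
                      clt = "z")
  if (x$reference == "chi_square") {
    cat(sprintf("%s = %.*g, df = %d, p-value = %.*g\n", stat_name,
                digits, x$statistic, x$df, digits, x$p.value))
  } else {
    cat(sprintf("%s = %.*g (standard normal), p-value = %.*g\n", stat_name,
                digits, x$statistic, digits, x$p.value))
  }
  cat("correction:", x$correction, "\n")
  invisible(x)
}

# floating-point guard shared by all statistic forms: an LRT is nonnegative,
# so tiny negatives are rounding noise and anything worse is a bug
clip_nonneg <- function(w) {
  if (w < -1e-9)
    stop("internal consistency failure: LRT statistic = ", w,
         " is negative beyond numerical tolerance", call. = FALSE)
  max(w, 0)
}

# statistic from the three log-determinants
wn_from_logdets <- function(ld, n1, n2) {
  clip_nonneg((n1 + n2) * ld[["pooled"]] -
                n1 * ld[["group_1"]] - n2 * ld[["group_2"]])
}

#' Likelihood ratio statistic for equality of two multivariate normals
#'
#' Computes \eqn{W_n = -2\log\Lambda_n} for the hypothesis that both samples
#' share one mean vector and one covariance matrix, i.e.
#' \deqn{W_n = n\log\det\hat\Sigma - n_1\log\det\hat\Sigma_1 -
#'   n_2\log\det\hat\Sigma_2,}
#' with likelihood-based (divide-by-\eqn{n_j}) covariance estimates from
#' [mle_summary()].  Under the null, \eqn{W_n} is asymptotically chi-square
#' with \eqn{f = p(p+3)/2} degrees of freedom; the returned p-value uses that
#' reference without correction (see [corrected_test()] for the adjusted
#' versions).
#'
#' @param data A [two_sample_data] object.
#' @return An object of class `lrt_test` with fields `statistic`, `df`,
#'   `p.value`, `reference`, `correction`, `subset`, `conditioning`.
#' @seealso [marginal_wn()], [conditional_wn()], [ggm_equality_test()]
#' @examples
#' set.seed(1)
#' d <- two_sample_data(matrix(rnorm(100), 50), matrix(rnorm(100), 50))
#' wn_statistic(d)
#' @export
wn_statistic <- function(data) {
  n1 <- nrow(data$x1); n2 <- nrow(data$x2); p <- length(data$labels)
  if (n1 <= p + 1L || n2 <= p + 1L)
    stop("LRT requires n_j > p + 1 in both groups (p = ", p,
         ", n1 = ", n1, ", n2 = ", n2, ")", call. = FALSE)
  mle <- mle_summary(data)
  w <- wn_from_logdets(mle$logdets, mle$n1, mle$n2)
  df <- equality_df(mle$p)
  new_lrt_test(w, df, chi2_pvalue(w, df), "chi_square", "none",
               n1 = mle$n1, n2 = mle$n2)
}

#' Marginal equality LRT on a subset of variables
#'
#' The equality statistic \eqn{W_n^A} computed on the columns named in `vars`:
#' identical to [wn_statistic()] applied to the column subset, with
#' \eqn{f_A = p_A(p_A+3)/2} degrees of freedom, \eqn{p_A = |A|}.
#'
#' @param data A [two_sample_data] object.
#' @param vars Non-empty character vector of variable labels.
#' @return An `lrt_test` with the subset recorded.
#' @export
marginal_wn <- function(data, vars) {
  res <- wn_statistic(subset_data(data, vars))
  res$subset <- as.character(vars)
  res
}

#' Conditional equality LRT for a clique given its separator
#'
#' Tests equality across conditions of the conditional distribution of
#' \eqn{X_{A\setminus B}} given \eqn{X_B}.  Because the marginal statistics
#' telescope, the conditional statistic is the difference
#' \eqn{W_n^{A|B} = W_n^A - W_n^B}, itself an LRT and hence nonnegative, with
#' \eqn{f_A - f_B} degrees of freedom.  An empty `given` reduces to
#' [marginal_wn()].
#'
#' @param data A [two_sample_data] object.
#' @param vars Character vector: the full set \eqn{A} (clique).
#' @param given Character vector: the conditioning set \eqn{B}, strictly
#'   contained in `vars` (possibly empty).
#' @return An `lrt_test`; `subset` holds \eqn{A\setminus B} and
#'   `conditioning` holds \eqn{B}.
#' @export
conditional_wn <- function(data, vars, given = character()) {
  vars <- as.character(vars); given <- as.character(given)
  if (!length(given)) return(marginal_wn(data, vars))
  if (length(setdiff(given, vars)) || !length(setdiff(vars, given)))
    stop("`given` must be strictly contained in `vars`", call. = FALSE)
  wa <- marginal_wn(data, vars)
  wb <- marginal_wn(data, given)
  w <- clip_nonneg(wa$statistic - wb$statistic)
  df <- wa$df - wb$df
  new_lrt_test(w, df, chi2_pvalue(w, df), "chi_square", "none",
               subset = setdiff(vars, given), conditioning = given,
               n1 = wa$n1, n2 = wa$n2)
}

#' Upper-tail chi-square p-value
#'
#' @param statistic Nonnegative test statistic.
#' @param df Positive integer degrees of freedom.
#' @return \eqn{P(\chi^2_{df} > statistic)}.
#' @export
chi2_pvalue <- function(statistic, df) {
  if (statistic < 0) stop("statistic must be nonnegative", call. = FALSE)
  if (df < 1) stop("df must be a positive integer", call. = FALSE)
  stats::pchisq(statistic, df = df, lower.tail = FALSE)
}
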