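#' Paired two-sample data container
#'
#' Bundles two numeric sample matrices observed on the same set of variables,
#' one per condition.  Rows are observations, columns are variables; both
#' matrices must carry the same variable labels in the same order (use
#' [read_two_sample()] to align files whose columns are ordered differently).
#'
#' @param x1,x2 Numeric matrices (or data frames) with observations in rows
#'   and the same named variables in columns.
#' @param labels Optional character vector of variable labels; defaults to the
#'   column names of `x1` (or `V1..Vp` when unnamed).
#'
#' @return An object of class `two_sample_data`: a list with elements `x1`,
#'   `x2` (numeric matrices with column names) and `labels`.
#' @examples
#' d <- two_sample_data(matrix(rnorm(40), 20), matrix(rnorm(60), 30))
#' d$labels
#' @export
two_sample_data <- function(x1, x2, labels = NULL) {
  x1 <- as.matrix(x1)
  x2 <- as.matrix(x2)
  if (!is.numeric(x1) || !is.numeric(x2))
    stop("both samples must be numeric matrices", call. = FALSE)
  if (ncol(x1) != ncol(x2))
    stop("samples have different numbers of variables (", ncol(x1), " vs ",
         ncol(x2), ")", call. = FALSE)
  p <- ncol(x1)
  if (p < 1L) stop("at least one variable is required", call. = FALSE)
  if (nrow(x1) < 2L || nrow(x2) < 2L)
    stop("each sample needs at least 2 observations", call. = FALSE)
  if (anyNA(x1) || anyNA(x2))
    stop("missing values are not supported", call. = FALSE)
  if (is.null(labels)) {
    labels <- colnames(x1)
    if (is.null(labels)) labels <- paste0("V", seq_len(p))
  }
  labels <- as.character(labels)
  if (length(labels) != p || anyDuplicated(labels))
    stop("variable labels must be ", p, " unique strings", call. = FALSE)
  if (!is.null(colnames(x2)) && !identical(colnames(x2), colnames(x1)) &&
      !is.null(colnames(x1)))
    stop("column labels of the two samples differ; align them first ",
         "(see read_two_sample)", call. = FALSE)
  colnames(x1) <- colnames(x2) <- labels
  structure(list(x1 = x1, x2 = x2, labels = labels),
            class = "two_sample_data")
}

#' @export
print.two_sample_data <- function(x, ...) {
  cat("Two-sample data: p =", length(x$labels),
      "variables; n1 =", nrow(x$x1), ", n2 =", nrow(x$x2), "\n")
  cat("Variables:", paste(utils::head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) "...", "\n")
  invisible(x)
}

#' @export
dim.two_sample_data <- function(x) {
  c(n1 = nrow(x$x1), n2 = nrow(x$x2), p = length(x$labels))
}

# column subset by label, keeping the container contract
subset_data <- function(data, vars) {
  unknown <- setdiff(vars, data$labels)
  if (length(unknown))
    stop("unknown variable label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!length(vars)) stop("variable subset must be non-empty", call. = FALSE)
  two_sample_data(data$x1[, vars, drop = FALSE],
                  data$x2[, vars, drop = FALSE], labels = vars)
}

#' Maximum likelihood summaries under the null and the alternative
#'
#' Computes the group means, the likelihood-based (divide-by-\eqn{n_j})
#' covariance estimates of each sample, and the pooled estimates under the
#' null hypothesis of a common mean and covariance (grand mean, divide by
#' \eqn{n = n_1 + n_2}), together with the three log-determinants.
#'
#' The estimates exist (are almost surely nonsingular) when
#' \eqn{n_j \ge p + 1}; smaller samples raise an error, and singular input is
#' detected operationally as failure of the Cholesky factorization used for
#' the log-determinants.  The test statistics themselves additionally require
#' \eqn{n_j > p + 1} (see [wn_statistic()]).
#'
#' @param data A [two_sample_data] object.
#' @return A list of class `mle_summary` with elements `mean_1`, `mean_2`,
#'   `mean_pooled`, `cov_1`, `cov_2`, `cov_pooled`, `logdets` (named numeric
#'   vector), `n1`, `n2`, `p`.
#' @examples
#' d <- two_sample_data(matrix(0:1 * 2, 2, 1), matrix(c(1, 3), 2, 1))
#' mle_summary(d)$cov_pooled  # 1.25 by hand arithmetic on the 4 numbers
#' @export
mle_summary <- function(data) {
  stopifnot(inherits(data, "two_sample_data"))
  n1 <- nrow(data$x1); n2 <- nrow(data$x2); p <- length(data$labels)
  if (n1 < p + 1L || n2 < p + 1L)
    stop("covariance MLE requires n_j >= p + 1 in both groups (p = ", p,
         ", n1 = ", n1, ", n2 = ", n2, ")", call. = FALSE)
  m1 <- colMeans(data$x1)
  m2 <- colMeans(data$x2)
  s1 <- crossprod(sweep(data$x1, 2, m1)) / n1
  s2 <- crossprod(sweep(data$x2, 2, m2)) / n2
  pooled <- rbind(data$x1, data$x2)
  mp <- colMeans(pooled)
  sp <- crossprod(sweep(pooled, 2, mp)) / (n1 + n2)
  ld <- c(pooled  = logdet_pd(sp, "pooled sample"),
          group_1 = logdet_pd(s1, "group 1"),
          group_2 = logdet_pd(s2, "group 2"))
  structure(list(mean_1 = m1, mean_2 = m2, mean_pooled = mp,
                 cov_1 = s1, cov_2 = s2, cov_pooled = sp,
                 logdets = ld, n1 = n1, n2 = n2, p = p),
            class = "mle_summary")
}

# log-determinant of a symmetric positive definite matrix via Cholesky;
# factorization failure is the operational definition of "singular"
logdet_pd <- function(s, what) {
  r <- tryCatch(chol(s), error = function(e) NULL)
  if (is.null(r))
    stop("LRT undefined: covariance estimate for ", what,
         " is (numerically) singular", call. = FALSE)
  2 * sum(log(diag(r)))
}
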