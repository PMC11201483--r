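# Partial correlations and the Bayes-factor conditional-independence test.
#
# For data generated by a linear SEM with homoscedastic, uncorrelated noise,
# a vanishing partial correlation rho_{ij|Z} is equivalent to the conditional
# independence of X_i and X_j given Z, which is what licenses its use as the
# CI test throughout the constraint phase. Significance is judged by a
# BIC-approximation Bayes factor BF01 rather than a p-value; small BF01
# favours dependence.

#' Pearson correlation matrix of a data matrix
#'
#' @param data A `data_matrix` (or coercible data frame).
#' @return Symmetric n x n correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(data) {
  dm <- as_data_matrix(data)
  sds <- apply(dm$values, 2L, sd)
  bad <- which(sds == 0)
  if (length(bad)) {
    stop("zero-variance column(s): ", paste(dm$names[bad], collapse = ", "),
         call. = FALSE)
  }
  r <- cor(dm$values)
  dimnames(r) <- list(dm$names, dm$names)
  r
}

# Invert a (sub)correlation matrix, falling back to a small ridge on the
# diagonal when it is numerically singular (duplicated columns, |Z| near m).
invert_corr <- function(r, ridge = 1e-10) {
  out <- tryCatch(solve(r), error = function(e) NULL)
  if (is.null(out)) {
    warning("singular correlation matrix; adding ridge ", ridge,
            " to the diagonal", call. = FALSE)
    out <- tryCatch(solve(r + diag(ridge, nrow(r))), error = function(e) NULL)
    if (is.null(out)) {
      stop("correlation matrix is singular even after ridge regularisation",
           call. = FALSE)
    }
  }
  out
}

#' Full partial correlation matrix
#'
#' Entry (i, j) is the partial correlation of X_i and X_j given all other
#' variables, obtained from the inverse correlation (precision) matrix P as
#' -P\[i,j\] / sqrt(P\[i,i\] P\[j,j\]). The diagonal is set to 1 by convention.
#'
#' @param r A correlation matrix (as from [correlation_matrix()]).
#' @return Symmetric matrix of full partial correlations.
#' @export
full_partial_matrix <- function(r) {
  p <- invert_corr(r)
  d <- 1 / sqrt(diag(p))
  rho <- -p * tcrossprod(d)
  diag(rho) <- 1
  rho
}

#' Conditional-independence testing context
#'
#' Bundles the correlation matrix with the sample size, total variable count
#' and Bayes-factor threshold so local tests are cheap submatrix inversions.
#' A context can also be built from a population covariance
#' ([ci_context_cov()]) to run the constraint phase in the population limit.
#'
#' @param data A `data_matrix` or data frame.
#' @param k Bayes-factor threshold; BF01 below `k` declares dependence.
#' @return An object of class `ci_context`.
#' @export
ci_context <- function(data, k = 0.01) {
  dm <- as_data_matrix(data)
  if (dm$m <= dm$n) {
    stop("need more samples than variables (m > n) for the t test's ",
         "m - n degrees of freedom", call. = FALSE)
  }
  structure(
    list(r = correlation_matrix(dm), m = dm$m, n = dm$n, k = k,
         names = dm$names),
    class = "ci_context"
  )
}

#' @rdname ci_context
#' @param sigma A population covariance matrix.
#' @param m Nominal sample size used in the t statistic and Bayes factor
#'   (population analyses have no sampling noise, so `m` only sets the
#'   sharpness of the decision).
#' @param names Optional variable names.
#' @param limit If `TRUE`, decisions use the population-limit test
#'   |rho| > `limit_tol` instead of the Bayes factor: with an analytic
#'   covariance this is the m -> infinity behaviour of the BF threshold and
#'   makes dependence coincide exactly with d-separation under
#'   faithfulness.
#' @param limit_tol Zero tolerance of the limit test.
#' @export
ci_context_cov <- function(sigma, m = 10000L, k = 0.01, names = NULL,
                           limit = FALSE, limit_tol = 1e-8) {
  d <- 1 / sqrt(diag(sigma))
  r <- sigma * tcrossprod(d)
  if (is.null(names)) names <- colnames(sigma)
  if (is.null(names)) names <- paste0("V", seq_len(nrow(r)))
  dimnames(r) <- list(names, names)
  structure(
    list(r = r, m = as.integer(m), n = nrow(r), k = k, names = names,
         limit_tol = if (isTRUE(limit)) limit_tol else NULL),
    class = "ci_context"
  )
}

#' Local partial correlation
#'
#' rho_{ij|Z} computed by inverting the sub-correlation matrix over
#' \{i, j\} union Z; identical (to numerical precision) to correlating the
#' residuals of the two least-squares regressions of X_i and X_j on Z.
#'
#' @param ctx A `ci_context`.
#' @param i,j Distinct variable indices.
#' @param z Integer vector of conditioning indices, excluding `i` and `j`;
#'   may be empty (plain Pearson correlation).
#' @return The partial correlation, clamped to \[-1, 1\].
#' @export
local_partial <- function(ctx, i, j, z = integer(0)) {
  stopifnot(i != j, !(i %in% z), !(j %in% z))
  if (length(z) == 0L) {
    return(ctx$r[i, j])
  }
  idx <- c(i, j, z)
  p <- invert_corr(ctx$r[idx, idx, drop = FALSE])
  rho <- -p[1L, 2L] / sqrt(p[1L, 1L] * p[2L, 2L])
  max(-1, min(1, rho))
}

#' t statistic for a partial correlation
#'
#' t = rho / sqrt((1 - rho^2) / (m - n)), approximately t-distributed with
#' m - n degrees of freedom for large m. The total variable count n is used
#' for the degrees of freedom of local tests as well; at the sample sizes
#' this test is meant for (m >= 1000) the difference from m - |Z| - 2 is
#' negligible.
#'
#' @param rho Partial correlation in \[-1, 1\].
#' @param m Sample size; must exceed `n`.
#' @param n Total number of variables.
#' @return The t statistic; signed `Inf` when |rho| = 1.
#' @export
t_statistic <- function(rho, m, n) {
  if (m <= n) {
    stop("m must exceed n for the m - n degrees of freedom", call. = FALSE)
  }
  if (abs(rho) >= 1) {
    return(sign(rho) * Inf)
  }
  rho / sqrt((1 - rho^2) / (m - n))
}

#' BIC-approximation Bayes factor for the independence null
#'
#' BF01 = sqrt(m) * (1 + t^2 / (m - n))^(-m / 2), evaluated in log space to
#' avoid underflow at large |t|. Strictly decreasing in |t|, equal to
#' sqrt(m) at t = 0, and tending to 0 as |t| grows, so thresholding BF01 at
#' k is equivalent to thresholding |t|.
#'
#' @inheritParams t_statistic
#' @param t The t statistic.
#' @return BF01 > 0 (0 only by floating-point underflow at extreme |t|).
#' @export
bayes_factor <- function(t, m, n) {
  if (m <= n) {
    stop("m must exceed n", call. = FALSE)
  }
  if (!is.finite(t)) {
    return(0)
  }
  exp(0.5 * log(m) - (m / 2) * log1p(t^2 / (m - n)))
}

#' Conditional-independence decision
#'
#' Computes rho_{ij|Z}, its t statistic and Bayes factor, and declares the
#' pair dependent when BF01 < k (ties at BF01 == k resolve to independent).
#'
#' @inheritParams local_partial
#' @return A list of class `ci_test` with elements `rho`, `t`, `bf01`,
#'   `dependent`.
#' @export
ci_decision <- function(ctx, i, j, z = integer(0)) {
  rho <- local_partial(ctx, i, j, z)
  t <- t_statistic(rho, ctx$m, ctx$n)
  bf <- bayes_factor(t, ctx$m, ctx$n)
  dep <- if (is.null(ctx$limit_tol)) bf < ctx$k else
    abs(rho) > ctx$limit_tol
  structure(
    list(rho = rho, t = t, bf01 = bf, dependent = dep),
    class = "ci_test"
  )
}

# Vectorised dependence decision for a matrix of partial correlations:
# returns a logical matrix (diagonal FALSE).
dependent_matrix <- function(rho, m, n, k) {
  t2 <- ifelse(abs(rho) >= 1, Inf, rho^2 / ((1 - rho^2) / (m - n)))
  logbf <- 0.5 * log(m) - (m / 2) * log1p(t2 / (m - n))
  dep <- logbf < log(k)
  diag(dep) <- FALSE
  dep
}
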