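# Density layer of the two-level mixture. Everything is computed in log
# space: with K datasets and tail z-scores beyond +-8, products of K normal
# densities underflow double precision long before K reaches 10.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp over the columns of a matrix.
row_logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  ok <- is.finite(m)
  out <- m
  if (any(ok)) out[ok] <- m[ok] + log(rowSums(exp(x[ok, , drop = FALSE] - m[ok])))
  out
}

# log phi(z[, k]; mu[j, k], sigma2[j, k]) for all genes, components and
# datasets at once; returns an m x 3 x K array.
log_phi_array <- function(z, params) {
  m <- nrow(z)
  K <- params$K
  out <- array(NA_real_, dim = c(m, 3L, K))
  for (k in seq_len(K)) {
    for (j in 1:3) {
      out[, j, k] <- stats::dnorm(z[, k], params$mu[j, k],
                                  sqrt(params$sigma2[j, k]), log = TRUE)
    }
  }
  out
}

# Per-gene log f_CI and the three per-gene CC component log products
# log(prod_k phi_jk), given the log_phi_array. Shared by density, E-step and
# the discordance posterior.
log_ci_cc_parts <- function(lphi, params) {
  m <- dim(lphi)[1]
  K <- dim(lphi)[3]
  lrho <- log(params$rho)
  log_ci <- numeric(m)
  log_cc_prod <- matrix(0, m, 3L)        # log prod_k phi(z_k; mu_j, s2_j)
  for (k in seq_len(K)) {
    lk <- lphi[, , k, drop = FALSE]
    dim(lk) <- c(m, 3L)
    mix_k <- row_logsumexp(sweep(lk, 2L, lrho[, k], "+"))
    log_ci <- log_ci + mix_k
    log_cc_prod <- log_cc_prod + lk
  }
  list(log_ci = log_ci, log_cc_prod = log_cc_prod)
}

log_cc_from_parts <- function(parts, params) {
  row_logsumexp(sweep(parts$log_cc_prod, 2L, log(params$pi), "+"))
}

#' Complete-independence density of a z-score row
#'
#' The CI layer models a gene whose regulation state (null/up/down) is drawn
#' independently in each dataset: a product of K univariate three-component
#' normal mixtures.
#'
#' @param z_row Numeric K-vector of z-scores for one gene.
#' @param params A [mixture_params()] object.
#' @param log Return the log density?
#' @return A single density value.
#' @export
ci_density <- function(z_row, params, log = FALSE) {
  validate_mixture_params(params)
  z <- matrix(z_row, nrow = 1)
  stopifnot(ncol(z) == params$K, all(is.finite(z)))
  parts <- log_ci_cc_parts(log_phi_array(z, params), params)
  if (log) parts$log_ci else exp(parts$log_ci)
}

#' Complete-concordance density of a z-score row
#'
#' The CC layer models a gene that occupies the same regulation state in all
#' K datasets: a three-component mixture whose components are products of K
#' normal densities sharing one state.
#'
#' @inheritParams ci_density
#' @return A single density value.
#' @export
cc_density <- function(z_row, params, log = FALSE) {
  validate_mixture_params(params)
  z <- matrix(z_row, nrow = 1)
  stopifnot(ncol(z) == params$K, all(is.finite(z)))
  parts <- log_ci_cc_parts(log_phi_array(z, params), params)
  lcc <- log_cc_from_parts(parts, params)
  if (log) lcc else exp(lcc)
}

#' Two-level mixture density of a z-score row
#'
#' The convex combination `lambda * f_CC + (1 - lambda) * f_CI`; means and
#' variances are shared between the two layers, so the parameter count grows
#' linearly in K.
#'
#' @inheritParams ci_density
#' @return A single density value.
#' @export
two_level_density <- function(z_row, params, log = FALSE) {
  validate_mixture_params(params)
  z <- matrix(z_row, nrow = 1)
  stopifnot(ncol(z) == params$K, all(is.finite(z)))
  parts <- log_ci_cc_parts(log_phi_array(z, params), params)
  ld <- log_two_level_from_parts(parts, params)
  if (log) ld else exp(ld)
}

log_two_level_from_parts <- function(parts, params) {
  lcc <- log_cc_from_parts(parts, params)
  lam <- params$lambda
  if (lam == 0) return(parts$log_ci)
  if (lam == 1) return(lcc)
  m <- length(lcc)
  a <- cbind(log(lam) + lcc, log1p(-lam) + parts$log_ci)
  row_logsumexp(a)
}

#' Log-likelihood of a z-score matrix under the two-level model
#'
#' Sum over genes of the log two-level density, used as the EM convergence
#' criterion.
#'
#' @param z Numeric m x K matrix of z-scores.
#' @param params A [mixture_params()] object.
#' @return A single numeric value.
#' @export
loglik <- function(z, params) {
  validate_mixture_params(params)
  z <- as.matrix(z)
  stopifnot(ncol(z) == params$K, all(is.finite(z)))
  parts <- log_ci_cc_parts(log_phi_array(z, params), params)
  sum(log_two_level_from_parts(parts, params))
}
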