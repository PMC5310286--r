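# EM for the two-level mixture. The E-step computes, for every gene, the
# posterior weight of the CC layer (omega), the joint CC-layer/component
# responsibilities (xi) and the CI-layer per-dataset component
# responsibilities (eta). The M-step is the closed-form weighted update of
# lambda, pi, rho and of the free (up/down) means and variances; the null
# component stays pinned at N(0, 1).

#' E-step: posterior membership expectations
#'
#' Computes `E(omega_i)` (CC-layer posterior), `E(omega_i xi_ij)` (joint
#' posterior of CC layer and concordant component j) and
#' `E((1 - omega_i) eta_ijk)` (joint posterior of CI layer and component j in
#' dataset k), all in log space.  For every gene the xi row sums to omega and
#' each eta slice sums to `1 - omega`.
#'
#' @param z Numeric m x K matrix of z-scores.
#' @param params A [mixture_params()] object.
#' @return A list of class `posterior_memberships` with elements `omega`
#'   (m-vector), `xi` (m x 3), `eta` (m x 3 x K) and `loglik` (the
#'   log-likelihood of `z` under `params`, a free by-product).
#' @export
e_step <- function(z, params) {
  validate_mixture_params(params)
  z <- as.matrix(z)
  stopifnot(ncol(z) == params$K, all(is.finite(z)))
  m <- nrow(z)
  K <- params$K

  lphi <- log_phi_array(z, params)
  lrho <- log(params$rho)

  # per-dataset CI mixture logs and within-dataset responsibilities
  log_mix <- matrix(NA_real_, m, K)      # log sum_j rho_jk phi_jk
  resp <- array(NA_real_, dim = c(m, 3L, K))  # rho phi / mix per dataset
  log_cc_prod <- matrix(0, m, 3L)
  for (k in seq_len(K)) {
    lk <- lphi[, , k, drop = FALSE]
    dim(lk) <- c(m, 3L)
    w <- sweep(lk, 2L, lrho[, k], "+")
    log_mix[, k] <- row_logsumexp(w)
    resp[, , k] <- exp(w - log_mix[, k])
    log_cc_prod <- log_cc_prod + lk
  }
  log_ci <- rowSums(log_mix)
  log_cc_terms <- sweep(log_cc_prod, 2L, log(params$pi), "+")
  log_cc <- row_logsumexp(log_cc_terms)

  lam <- params$lambda
  if (lam == 0) {
    log_den <- log_ci
    omega <- numeric(m)
    xi <- matrix(0, m, 3L)
  } else if (lam == 1) {
    log_den <- log_cc
    omega <- rep(1, m)
    xi <- exp(log_cc_terms - log_cc)
  } else {
    log_den <- row_logsumexp(cbind(log(lam) + log_cc, log1p(-lam) + log_ci))
    omega <- exp(log(lam) + log_cc - log_den)
    xi <- exp(log(lam) + log_cc_terms - log_den)
  }
  if (any(!is.finite(log_den)))
    stop("degenerate z-score row: zero density under both CC and CI layers")

  ci_post <- 1 - omega
  eta <- resp * array(rep(ci_post, 3L * K), dim = c(m, 3L, K))

  structure(
    list(omega = omega, xi = xi, eta = eta, loglik = sum(log_den)),
    class = "posterior_memberships"
  )
}

#' M-step: closed-form parameter updates
#'
#' Given posterior memberships, recomputes `lambda` (mean omega), `pi`
#' (normalised xi column sums), each `rho` column (normalised eta sums) and
#' the weighted means/variances of the up and down components, where the
#' weights pool the CC and CI responsibilities of the component.  The null
#' component is not updated.  If an M-step drives an up (down) mean
#' non-positive (non-negative) it is clamped to +0.01 (-0.01) so component
#' identities never swap; variances are floored at `1e-4` and proportions at
#' `1e-8` against component collapse.
#'
#' @param z Numeric m x K matrix of z-scores.
#' @param post A `posterior_memberships` object from [e_step()].
#' @param prev Optional `mixture_params` supplying values to carry over when
#'   a layer has zero total responsibility (e.g. lambda at the 0/1 boundary).
#' @param dataset_ids Dataset names for the returned object.
#' @return A `mixture_params` object.
#' @export
m_step <- function(z, post, prev = NULL, dataset_ids = NULL) {
  z <- as.matrix(z)
  m <- nrow(z)
  K <- ncol(z)
  stopifnot(length(post$omega) == m, dim(post$eta)[3] == K)
  if (is.null(dataset_ids))
    dataset_ids <- if (!is.null(prev)) prev$dataset_ids else colnames(z)

  prop_floor <- 1e-8
  var_floor <- 1e-4

  lambda <- mean(post$omega)

  cc_tot <- sum(post$omega)
  if (cc_tot > .Machine$double.eps * m) {
    pi_hat <- colSums(post$xi) / cc_tot
  } else {
    pi_hat <- if (!is.null(prev)) prev$pi else rep(1 / 3, 3)
  }
  pi_hat <- pmax(pi_hat, prop_floor)
  pi_hat <- pi_hat / sum(pi_hat)

  ci_tot <- sum(1 - post$omega)
  rho <- matrix(NA_real_, 3L, K)
  mu <- matrix(0, 3L, K)
  sigma2 <- matrix(1, 3L, K)
  collapsed <- FALSE
  for (k in seq_len(K)) {
    ek <- post$eta[, , k, drop = FALSE]
    dim(ek) <- c(m, 3L)
    if (ci_tot > .Machine$double.eps * m) {
      rho[, k] <- colSums(ek) / ci_tot
    } else {
      rho[, k] <- if (!is.null(prev)) prev$rho[, k] else rep(1 / 3, 3)
    }
    rho[, k] <- pmax(rho[, k], prop_floor)
    rho[, k] <- rho[, k] / sum(rho[, k])
    for (j in 2:3) {                     # up, down; null stays N(0, 1)
      w <- post$xi[, j] + ek[, j]
      sw <- sum(w)
      if (sw <= .Machine$double.eps * m) {
        collapsed <- TRUE
        mu[j, k] <- if (!is.null(prev)) prev$mu[j, k] else c(NA, 2, -2)[j]
        sigma2[j, k] <- if (!is.null(prev)) prev$sigma2[j, k] else 1
        next
      }
      mu[j, k] <- sum(w * z[, k]) / sw
      sigma2[j, k] <- sum(w * (z[, k] - mu[j, k])^2) / sw
    }
    if (mu[2, k] <= 0) mu[2, k] <- 0.01
    if (mu[3, k] >= 0) mu[3, k] <- -0.01
    sigma2[2:3, k] <- pmax(sigma2[2:3, k], var_floor)
  }
  if (collapsed)
    warning("a mixture component received (near-)zero responsibility; ",
            "its mean/variance were carried over")

  mixture_params(lambda = lambda, pi = pi_hat, rho = rho, mu = mu,
                 sigma2 = sigma2, dataset_ids = dataset_ids)
}

#' Data-driven starting values for the EM
#'
#' Null-heavy overdispersed start: `lambda = 0.5`, `pi = (0.8, 0.1, 0.1)`,
#' every `rho` column `(0.8, 0.1, 0.1)`; the up-mean of each dataset is the
#' mean of z-scores above that dataset's 90th percentile (falling back to +2
#' when that mean is not positive), the down-mean is the mirrored quantity,
#' and all free variances start at 1.
#'
#' @param z Numeric m x K matrix of z-scores.
#' @return A `mixture_params` object.
#' @export
auto_init <- function(z) {
  z <- as.matrix(z)
  K <- ncol(z)
  mu <- matrix(0, 3L, K)
  for (k in seq_len(K)) {
    zk <- z[, k]
    up <- zk[zk > stats::quantile(zk, 0.9)]
    dn <- zk[zk < stats::quantile(zk, 0.1)]
    mu[2, k] <- if (length(up) && mean(up) > 0) mean(up) else 2
    mu[3, k] <- if (length(dn) && mean(dn) < 0) mean(dn) else -2
  }
  mixture_params(
    lambda = 0.5, pi = c(0.8, 0.1, 0.1),
    rho = matrix(c(0.8, 0.1, 0.1), 3L, K),
    mu = mu, sigma2 = matrix(1, 3L, K),
    dataset_ids = colnames(z)
  )
}

#' Fit the two-level mixture by EM
#'
#' Alternates [e_step()] and [m_step()] until the log-likelihood improves by
#' less than `tol` between iterations (or `max_iter` is reached).  The
#' log-likelihood trace is non-decreasing up to numerical tolerance; the fit
#' is deterministic given `z` and the initial values.
#'
#' @param z Numeric m x K matrix of z-scores (rows: genes).
#' @param init A `mixture_params` object, or `"auto"` for [auto_init()].
#' @param tol Convergence tolerance on the log-likelihood difference.
#' @param max_iter Iteration cap.
#' @param min_genes Minimum number of genes required for a stable fit.
#' @return A list of class `em_fit` with elements `params`, `loglik_trace`,
#'   `n_iter`, `converged` and `posteriors` (the final [e_step()] output).
#' @export
#' @examples
#' set.seed(1)
#' truth <- mixture_params(0.6, c(0.8, 0.1, 0.1),
#'                         rho = matrix(c(0.6, 0.2, 0.2), 3, 3),
#'                         mu = matrix(c(0, 2.5, -2.5), 3, 3),
#'                         sigma2 = matrix(1, 3, 3))
#' z <- sample_zscores(simulation_scenario(truth, m = 500, seed = 7))$z
#' fit <- fit_em(z, tol = 1e-3)
#' fit$params$lambda
fit_em <- function(z, init = "auto", tol = 1e-4, max_iter = 2000L,
                   min_genes = 50L) {
  z <- as.matrix(z)
  if (nrow(z) < min_genes)
    stop(sprintf("need at least %d genes for a stable fit (got %d)",
                 min_genes, nrow(z)))
  stopifnot(all(is.finite(z)), tol > 0, max_iter >= 1)
  params <- if (identical(init, "auto")) auto_init(z) else init
  validate_mixture_params(params)
  if (params$K != ncol(z)) stop("init has wrong K for this z-score matrix")

  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  post <- NULL
  for (it in seq_len(max_iter)) {
    post <- e_step(z, params)
    if (!is.finite(post$loglik))
      stop(sprintf("non-finite log-likelihood at iteration %d", it))
    trace <- c(trace, post$loglik)
    if (it > 1 && abs(post$loglik - ll_prev) < tol) {
      converged <- TRUE
      break
    }
    ll_prev <- post$loglik
    params <- m_step(z, post, prev = params)
  }
  structure(
    list(params = params, loglik_trace = trace, n_iter = length(trace),
         converged = converged, posteriors = post),
    class = "em_fit"
  )
}

#' @export
print.em_fit <- function(x, ...) {
  cat(sprintf("Two-level mixture EM fit: %d iterations, %sconverged\n",
              x$n_iter, if (x$converged) "" else "NOT "))
  cat(sprintf("  final log-likelihood: %.4f\n", utils::tail(x$loglik_trace, 1)))
  print(x$params)
  invisible(x)
}
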