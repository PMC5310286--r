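#' Construct a two-level mixture parameter set
#'
#' Bundles the parameters of the two-level three-component normal mixture
#' model for K-dimensional z-score rows: an outer weight `lambda` on the
#' complete-concordance (CC) layer, CC component proportions `pi`
#' (null/up/down), per-dataset complete-independence (CI) proportions `rho`,
#' and the shared component means and variances.  Component rows are ordered
#' null, up, down; the null component is pinned at N(0, 1) because z-scores of
#' non-differentially expressed genes are standard normal by construction.
#'
#' @param lambda Weight of the CC layer, in \[0, 1\].
#' @param pi Length-3 probability vector of CC component proportions
#'   (null, up, down).
#' @param rho 3 x K matrix of CI component proportions; each column is a
#'   probability vector (null, up, down) for one dataset.
#' @param mu 3 x K matrix of component means; row 1 must be 0, row 2 positive
#'   (up-regulation), row 3 negative (down-regulation).
#' @param sigma2 3 x K matrix of component variances; row 1 must be 1.
#' @param dataset_ids Optional character vector of K dataset names.
#'
#' @return An object of class `mixture_params`.
#' @export
#' @examples
#' p <- mixture_params(
#'   lambda = 0.6, pi = c(0.8, 0.1, 0.1),
#'   rho = matrix(c(0.6, 0.2, 0.2), 3, 2),
#'   mu = matrix(c(0, 2.5, -2.5), 3, 2),
#'   sigma2 = matrix(1, 3, 2)
#' )
#' p$K
mixture_params <- function(lambda, pi, rho, mu, sigma2, dataset_ids = NULL) {
  rho <- as.matrix(rho)
  mu <- as.matrix(mu)
  sigma2 <- as.matrix(sigma2)
  K <- ncol(rho)
  if (is.null(dataset_ids)) dataset_ids <- paste0("z", seq_len(K))
  obj <- structure(
    list(K = K, lambda = lambda, pi = as.numeric(pi), rho = rho,
         mu = mu, sigma2 = sigma2, dataset_ids = as.character(dataset_ids)),
    class = "mixture_params"
  )
  validate_mixture_params(obj)
  obj
}

#' Validate a mixture_params object
#'
#' Checks the structural invariants: probability vectors sum to one, the null
#' component is N(0, 1), up/down means have the right signs and all variances
#' are positive.  Called by the constructor and before every density or EM
#' computation that takes user-supplied parameters.
#'
#' @param params A `mixture_params` object.
#' @param tol Tolerance for sum-to-one checks.
#' @return `params`, invisibly; signals an error on violation.
#' @export
validate_mixture_params <- function(params, tol = 1e-8) {
  stopifnot(inherits(params, "mixture_params"))
  K <- params$K
  if (length(params$lambda) != 1L || !is.finite(params$lambda) ||
      params$lambda < 0 || params$lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  if (length(params$pi) != 3L || any(params$pi < -tol) ||
      abs(sum(params$pi) - 1) > tol)
    stop("pi must be a length-3 probability vector")
  for (mat in c("rho", "mu", "sigma2")) {
    m <- params[[mat]]
    if (!is.matrix(m) || nrow(m) != 3L || ncol(m) != K || !all(is.finite(m)))
      stop(sprintf("%s must be a finite 3 x K matrix", mat))
  }
  if (any(params$rho < -tol) || any(abs(colSums(params$rho) - 1) > tol))
    stop("each rho column must be a probability vector")
  if (any(abs(params$mu[1, ]) > tol))
    stop("null component means must be 0")
  if (any(abs(params$sigma2[1, ] - 1) > tol))
    stop("null component variances must be 1")
  if (any(params$mu[2, ] <= 0))
    stop("up-regulation means mu[2, ] must be positive")
  if (any(params$mu[3, ] >= 0))
    stop("down-regulation means mu[3, ] must be negative")
  if (any(params$sigma2 <= 0))
    stop("variances must be positive")
  if (length(params$dataset_ids) != K)
    stop("dataset_ids must have length K")
  invisible(params)
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf("Two-level mixture parameters (K = %d datasets)\n", x$K))
  cat(sprintf("  lambda (CC weight): %.4f\n", x$lambda))
  cat("  pi (CC null/up/down):", sprintf("%.4f", x$pi), "\n")
  cat("  rho (CI proportions), mu, sigma2 per dataset:\n")
  for (k in seq_len(x$K)) {
    cat(sprintf("   %s: rho = (%.3f, %.3f, %.3f)  mu = (0, %.3f, %.3f)  s2 = (1, %.3f, %.3f)\n",
                x$dataset_ids[k], x$rho[1, k], x$rho[2, k], x$rho[3, k],
                x$mu[2, k], x$mu[3, k], x$sigma2[2, k], x$sigma2[3, k]))
  }
  invisible(x)
}

#' Number of free parameters of the two-level model
#'
#' Grows linearly in K: lambda (1), pi (2 free), and per dataset a free rho
#' pair, two free means and two free variances.
#'
#' @param params A `mixture_params` object.
#' @return Integer count `1 + 2 + 6 K`.
#' @export
n_free_params <- function(params) {
  stopifnot(inherits(params, "mixture_params"))
  1L + 2L + params$K * (2L + 2L + 2L)
}

#' Serialize fitted parameters to JSON
#'
#' @param params A `mixture_params` object.
#' @param path Output file path.
#' @param meta Optional named list of fit metadata stored alongside.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(params, path, meta = list()) {
  validate_mixture_params(params)
  # 3 x K matrices stored flattened column-major; K disambiguates the shape
  obj <- list(
    K = params$K, lambda = params$lambda, pi = params$pi,
    rho = as.numeric(params$rho), mu = as.numeric(params$mu),
    sigma2 = as.numeric(params$sigma2),
    dataset_ids = params$dataset_ids, meta = meta
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read fitted parameters from JSON
#'
#' @param path File written by [write_params_json()].
#' @return A `mixture_params` object.
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mixture_params(
    lambda = obj$lambda, pi = obj$pi,
    rho = matrix(unlist(obj$rho), nrow = 3),
    mu = matrix(unlist(obj$mu), nrow = 3),
    sigma2 = matrix(unlist(obj$sigma2), nrow = 3),
    dataset_ids = obj$dataset_ids
  )
}
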