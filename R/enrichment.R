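# Discordance enrichment layer. A gene shows "clearly discordant" behaviour
# when its latent regulation-state list across the K datasets contains at
# least one "up" and at least one "down". Under the two-level model only the
# complete-independence layer can produce such lists, and the probability of
# the complementary events (pure lists, null/up mixes, null/down mixes)
# factorises, giving closed forms for both the population proportion theta
# and the per-gene posterior zeta.

#' Model-based proportion of clearly discordant genes
#'
#' The probability that a random gene's latent regulation-state list has at
#' least one up and at least one down state.  Uses the inclusion-exclusion
#' identity
#' `theta = (1 - lambda) * (1 + prod_k rho_0k - prod_k (rho_0k + rho_1k)
#'  - prod_k (rho_0k + rho_2k))`,
#' which avoids enumerating the 3^K state lists and equals that enumeration
#' exactly.
#'
#' @param params A [mixture_params()] object.
#' @return A probability in `[0, 1 - lambda]`; 0 when `K = 1` (a single
#'   dataset cannot contain both directions).
#' @export
#' @examples
#' p <- mixture_params(0.4, c(0.8, 0.1, 0.1),
#'                     rho = matrix(c(0.6, 0.2, 0.2), 3, 3),
#'                     mu = matrix(c(0, 2, -2), 3, 3),
#'                     sigma2 = matrix(1, 3, 3))
#' discordance_theta(p)
discordance_theta <- function(params) {
  validate_mixture_params(params)
  r <- params$rho
  val <- (1 - params$lambda) *
    (1 + prod(r[1, ]) - prod(r[1, ] + r[2, ]) - prod(r[1, ] + r[3, ]))
  min(max(val, 0), 1)
}

#' Per-gene posterior probability of clear discordance
#'
#' `Pr(U_i = 1 | z_i)`: the conditional probability, given a gene's observed
#' z-scores and the model, that its latent regulation-state list contains at
#' least one up and at least one down state.  The numerator applies the same
#' inclusion-exclusion identity as [discordance_theta()] with weights
#' `rho_jk * phi(z_k; mu_jk, sigma2_jk)`; the denominator is the two-level
#' density.  Computed in log space and clamped to `[0, 1]` against roundoff.
#'
#' @param z_row Numeric K-vector of one gene's z-scores.
#' @param params A [mixture_params()] object.
#' @return A probability; 0 when `lambda = 1` or `K = 1`.
#' @export
gene_discordance_prob <- function(z_row, params) {
  validate_mixture_params(params)
  stopifnot(length(z_row) == params$K, all(is.finite(z_row)))
  as.numeric(discordance_posteriors(matrix(z_row, nrow = 1), params))
}

#' Discordance posteriors for every row of a z-score matrix
#'
#' Vectorised form of [gene_discordance_prob()].
#'
#' @param z Numeric m x K matrix of z-scores.
#' @param params A [mixture_params()] object.
#' @return Numeric m-vector of probabilities, named by rownames of `z`.
#' @export
discordance_posteriors <- function(z, params) {
  validate_mixture_params(params)
  z <- as.matrix(z)
  stopifnot(ncol(z) == params$K, all(is.finite(z)))
  m <- nrow(z)
  if (params$lambda == 1) return(stats::setNames(numeric(m), rownames(z)))

  lphi <- log_phi_array(z, params)
  lrho <- log(params$rho)
  # log weights per gene: lw[i, j, k] = log rho_jk + log phi_jk(z_ik)
  lw <- lphi + rep(lrho, each = m)

  s_all <- matrix(0, m, 1)
  s01 <- matrix(0, m, 1)
  s02 <- matrix(0, m, 1)
  s0 <- matrix(0, m, 1)
  log_cc_prod <- matrix(0, m, 3L)
  for (k in seq_len(params$K)) {
    lk <- lw[, , k, drop = FALSE]
    dim(lk) <- c(m, 3L)
    s_all <- s_all + row_logsumexp(lk)
    s01 <- s01 + row_logsumexp(lk[, c(1, 2), drop = FALSE])
    s02 <- s02 + row_logsumexp(lk[, c(1, 3), drop = FALSE])
    s0 <- s0 + lk[, 1]
    lpk <- lphi[, , k, drop = FALSE]
    dim(lpk) <- c(m, 3L)
    log_cc_prod <- log_cc_prod + lpk
  }
  parts <- list(log_ci = as.numeric(s_all), log_cc_prod = log_cc_prod)
  log_den <- log_two_level_from_parts(parts, params)

  top <- pmax(s_all, pmax(s01, pmax(s02, s0)))
  num <- exp(s_all - top) - exp(s01 - top) - exp(s02 - top) + exp(s0 - top)
  zeta <- (1 - params$lambda) * as.numeric(num) * exp(as.numeric(top) - log_den)
  zeta <- pmin(pmax(zeta, 0), 1)
  stats::setNames(zeta, rownames(z))
}

#' Exact Discordance Enrichment Score
#'
#' `DES = Pr(X > m_S * theta)` where `X` is the sum of independent Bernoulli
#' variables with the genes' discordance posteriors as success probabilities
#' (a Poisson-binomial sum).  The full distribution of `X` is built by
#' dynamic-programming convolution in `O(m_S^2)`.  The inequality is strict:
#' when `m_S * theta` is an exact integer `c` the event is `X >= c + 1`; set
#' `inclusive = TRUE` for `X >= c` semantics instead.
#'
#' @param zetas Numeric vector of per-gene discordance probabilities in
#'   `[0, 1]` for the genes of one set.
#' @param theta Genome-wide discordance proportion from
#'   [discordance_theta()].
#' @param inclusive Use `>=` at an exact-integer threshold instead of the
#'   default strict `>`.
#' @return The tail probability, in `[0, 1]`.
#' @export
#' @examples
#' des_exact(c(0.9, 0.8, 0.1), theta = 0.3)
des_exact <- function(zetas, theta, inclusive = FALSE) {
  if (length(zetas) == 0) stop("empty gene set: DES is undefined")
  stopifnot(all(is.finite(zetas)), all(zetas >= 0), all(zetas <= 1),
            is.finite(theta), theta >= 0, theta <= 1)
  m_s <- length(zetas)
  bound <- m_s * theta
  c_int <- floor(bound)
  min_count <- if (inclusive && isTRUE(all.equal(c_int, bound)))
    c_int else c_int + 1
  if (min_count > m_s) return(0)
  # pmf[x + 1] = Pr(X = x) after convolving each Bernoulli in turn
  pmf <- c(1, numeric(m_s))
  for (i in seq_len(m_s)) {
    p <- zetas[i]
    pmf <- c(pmf[-(m_s + 1)] * (1 - p), 0) + c(0, pmf[-(m_s + 1)] * p)
  }
  min(max(sum(pmf[(min_count + 1):(m_s + 1)]), 0), 1)
}

#' Monte Carlo Discordance Enrichment Score
#'
#' Simulates `B` independent Bernoulli vectors with success probabilities
#' `zetas` and returns the fraction of replicates whose event count exceeds
#' `m_S * theta`.  Matches the tail event of [des_exact()]; useful for very
#' large sets where the exact convolution is not needed.
#'
#' @inheritParams des_exact
#' @param B Number of Monte Carlo replicates (default 2000).
#' @param seed Optional integer seed for reproducibility.
#' @return The estimated tail probability.
#' @export
des_monte_carlo <- function(zetas, theta, B = 2000L, seed = NULL,
                            inclusive = FALSE) {
  if (length(zetas) == 0) stop("empty gene set: DES is undefined")
  stopifnot(B >= 1, all(zetas >= 0), all(zetas <= 1),
            theta >= 0, theta <= 1)
  if (!is.null(seed)) set.seed(seed)
  m_s <- length(zetas)
  bound <- m_s * theta
  c_int <- floor(bound)
  min_count <- if (inclusive && isTRUE(all.equal(c_int, bound)))
    c_int else c_int + 1
  counts <- stats::rbinom(B * m_s, 1L, rep(zetas, times = B))
  x <- colSums(matrix(counts, nrow = m_s))
  mean(x >= min_count)
}

#' Model-based FDR from a sorted DES list
#'
#' Each DES is the posterior probability that its set is truly enriched, so
#' `1 - mean(DES)` over the top `T` sets is the expected false-discovery
#' proportion of that report.
#'
#' @param sorted_des Numeric vector of DES values sorted in decreasing
#'   order.
#' @return A list with `fdr` (scalar, for the full list) and `fdr_at_rank`
#'   (running prefix value at every rank).
#' @export
fdr_from_des <- function(sorted_des) {
  if (length(sorted_des) == 0) stop("empty DES list: FDR is undefined")
  stopifnot(all(sorted_des >= 0), all(sorted_des <= 1),
            !is.unsorted(rev(sorted_des)))
  at_rank <- 1 - cumsum(sorted_des) / seq_along(sorted_des)
  list(fdr = at_rank[length(at_rank)], fdr_at_rank = at_rank)
}

#' Flag genes with clear observed discordance
#'
#' Descriptive utility: a gene is flagged when it has at least one z-score
#' above `threshold` and at least one below `-threshold`, i.e. clearly
#' positive and clearly negative evidence in different datasets.
#'
#' @param z Numeric m x K matrix of z-scores with gene rownames.
#' @param threshold Positive magnitude cutoff (default 4).
#' @return A list with `flagged` (named logical m-vector), `count` and
#'   `proportion`.
#' @export
#' @examples
#' flag_clear_discordance(table1_fixture())$count
flag_clear_discordance <- function(z, threshold = 4) {
  z <- as.matrix(z)
  stopifnot(threshold > 0, all(is.finite(z)))
  flagged <- apply(z, 1L, function(r) any(r > threshold) && any(r < -threshold))
  list(flagged = flagged, count = sum(flagged),
       proportion = mean(flagged))
}

#' Score a gene-set collection for discordance enrichment
#'
#' Computes theta once from the fitted model, the discordance posterior zeta
#' for every gene in the z-score universe, then a DES per set over the genes
#' the set shares with the universe.  Sets are returned sorted by decreasing
#' DES (ties broken by set name); sets with empty intersection are skipped
#' with a warning and listed in the metadata.
#'
#' @param z Numeric m x K z-score matrix with gene rownames (the universe).
#' @param params Fitted [mixture_params()].
#' @param sets A `gene_set_collection` from [read_gmt()] or
#'   [gene_set_collection()].
#' @param method `"exact"` (dynamic-programming convolution, default) or
#'   `"monte_carlo"`.
#' @param B Monte Carlo replicates when `method = "monte_carlo"`.
#' @param seed Seed for the Monte Carlo method.
#' @param inclusive Threshold semantics, see [des_exact()].
#' @return A list of class `discordance_result`: `theta`, `lambda`, `zeta`
#'   (named vector over the universe), `table` (data.frame with columns
#'   set_name, m_S, DES, FDR_at_rank, method, B), `fdr` (scalar over all
#'   scored sets) and `skipped_sets`.
#' @export
score_collection <- function(z, params, sets, method = c("exact", "monte_carlo"),
                             B = 2000L, seed = NULL, inclusive = FALSE) {
  method <- match.arg(method)
  validate_mixture_params(params)
  z <- as.matrix(z)
  if (is.null(rownames(z))) stop("z must have gene identifiers as rownames")
  stopifnot(inherits(sets, "gene_set_collection"))

  theta <- discordance_theta(params)
  zeta <- discordance_posteriors(z, params)
  universe <- rownames(z)

  nm <- names(sets$sets)
  kept <- character(0)
  skipped <- character(0)
  m_s <- integer(0)
  des <- numeric(0)
  if (!is.null(seed)) set.seed(seed)
  for (s in nm) {
    genes <- intersect(sets$sets[[s]], universe)
    if (length(genes) == 0) {
      skipped <- c(skipped, s)
      next
    }
    kept <- c(kept, s)
    m_s <- c(m_s, length(genes))
    des <- c(des, if (method == "exact")
      des_exact(zeta[genes], theta, inclusive = inclusive)
    else
      des_monte_carlo(zeta[genes], theta, B = B, inclusive = inclusive))
  }
  if (length(skipped))
    warning(sprintf("%d set(s) had no genes in the z-score universe and were skipped",
                    length(skipped)))
  if (length(kept) == 0) {
    tab <- data.frame(set_name = character(0), m_S = integer(0),
                      DES = numeric(0), FDR_at_rank = numeric(0),
                      method = character(0), B = integer(0),
                      stringsAsFactors = FALSE)
    return(structure(list(theta = theta, lambda = params$lambda, zeta = zeta,
                          table = tab, fdr = NA_real_, skipped_sets = skipped),
                     class = "discordance_result"))
  }
  ord <- order(-des, kept)
  fdr <- fdr_from_des(des[ord])
  tab <- data.frame(
    set_name = kept[ord], m_S = m_s[ord], DES = des[ord],
    FDR_at_rank = fdr$fdr_at_rank,
    method = method, B = if (method == "monte_carlo") as.integer(B) else NA_integer_,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(
    list(theta = theta, lambda = params$lambda, zeta = zeta, table = tab,
         fdr = fdr$fdr, skipped_sets = skipped),
    class = "discordance_result"
  )
}

#' @export
print.discordance_result <- function(x, des_cutoff = 0.80, ...) {
  cat(sprintf("Discordance enrichment: %d set(s) scored, theta = %.4f, lambda = %.4f\n",
              nrow(x$table), x$theta, x$lambda))
  top <- x$table[x$table$DES > des_cutoff, , drop = FALSE]
  if (nrow(top)) {
    cat(sprintf("Sets with DES > %.2f:\n", des_cutoff))
    print(top, digits = 4)
  } else {
    cat(sprintf("No set exceeds DES %.2f; best:\n", des_cutoff))
    print(utils::head(x$table, 3), digits = 4)
  }
  invisible(x)
}
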