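# From paired two-sample expression data to signed z-scores. Per dataset:
# paired t-statistics, sign-flip permutation p-values pooled across all
# genes (so p-values far below 1/n_perm are estimable), then the
# inverse-normal transform. Positive z means up-regulation in cases.

#' Construct a paired expression dataset
#'
#' @param values Numeric matrix, genes x (2n) columns: one case and one
#'   control column per pair.
#' @param gene_ids Unique gene identifiers (rownames of `values`).
#' @param pair_ids Length-n pair identifiers.
#' @param case_cols,control_cols Column indices (or names) of each pair's
#'   case and control measurement, aligned with `pair_ids`.
#' @param scale `"ratio"` if `values` are on the raw intensity/ratio scale
#'   (differences are taken as log2 case/control), `"log"` if already
#'   log-scale (plain differences).
#' @return An object of class `paired_dataset`.
#' @export
paired_dataset <- function(values, gene_ids, pair_ids, case_cols, control_cols,
                           scale = c("ratio", "log")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  n <- length(pair_ids)
  if (n < 2) stop("need at least 2 pairs")
  stopifnot(length(gene_ids) == nrow(values),
            length(case_cols) == n, length(control_cols) == n,
            ncol(values) == 2 * n, all(is.finite(values)))
  rownames(values) <- gene_ids
  structure(
    list(values = values, gene_ids = as.character(gene_ids),
         pair_ids = as.character(pair_ids),
         case_cols = case_cols, control_cols = control_cols, scale = scale),
    class = "paired_dataset"
  )
}

# Per-pair difference matrix (genes x n): log2(case/control) on the ratio
# scale, case - control on the log scale.
paired_differences <- function(dataset) {
  stopifnot(inherits(dataset, "paired_dataset"))
  ca <- dataset$values[, dataset$case_cols, drop = FALSE]
  co <- dataset$values[, dataset$control_cols, drop = FALSE]
  if (dataset$scale == "ratio") {
    if (any(ca <= 0) || any(co <= 0))
      stop("ratio-scale expression values must be strictly positive")
    d <- log2(ca / co)
  } else {
    d <- ca - co
  }
  colnames(d) <- dataset$pair_ids
  d
}

t_from_differences <- function(d) {
  n <- ncol(d)
  s <- rowSums(d)
  ss <- rowSums(d * d)
  v <- (ss - s^2 / n) / (n - 1)
  (s / n) / sqrt(v / n)
}

#' Paired t-statistic for one gene
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` over the per-pair differences `d`;
#' positive t means higher expression in cases.
#'
#' @param dataset A [paired_dataset()].
#' @param gene A gene identifier or row index.
#' @return A single t-statistic.
#' @export
paired_t_score <- function(dataset, gene) {
  d <- paired_differences(dataset)
  if (is.character(gene) && !gene %in% rownames(d))
    stop(sprintf("unknown gene '%s'", gene))
  di <- d[gene, , drop = TRUE]
  if (stats::sd(di) == 0)
    stop(sprintf("degenerate gene '%s': zero-variance paired differences",
                 as.character(gene)))
  t_from_differences(matrix(di, nrow = 1))
}

#' Pooled sign-flip permutation p-values for one dataset
#'
#' For each of `n_perm` permutations every pair's case/control labels are
#' independently flipped with probability 1/2 (equivalently the difference
#' signs are flipped), the paired t-statistic is recomputed for every gene,
#' and all `m * n_perm` permuted t-statistics are pooled into a single null
#' sample.  The upper-tail p-value of gene i is
#' `(1 + #\{pooled t >= t_i\}) / (1 + m * n_perm)`; the add-one continuity
#' correction keeps p strictly inside (0, 1) so z-scores are always finite.
#'
#' @param dataset A [paired_dataset()].
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the random flips.
#' @return A list with `p` (named vector of upper-tail p-values), `t`
#'   (observed t-statistics) and `degenerate` (names of zero-variance genes,
#'   whose p is NA).
#' @export
pooled_permutation_pvalues <- function(dataset, n_perm = 1000L, seed = NULL) {
  stopifnot(inherits(dataset, "paired_dataset"))
  if (n_perm < 1) stop("n_perm must be at least 1")
  d <- paired_differences(dataset)
  n <- ncol(d)
  if (n < 2) stop("need at least 2 pairs")
  m <- nrow(d)

  v0 <- apply(d, 1L, stats::var)
  degenerate <- rownames(d)[v0 == 0]
  if (length(degenerate))
    warning(sprintf("%d gene(s) with zero-variance differences flagged (p = NA)",
                    length(degenerate)))

  t_obs <- t_from_differences(d)

  if (!is.null(seed)) set.seed(seed)
  # signs: n x n_perm; one column of independent +-1 flips per permutation,
  # applied to every gene's difference vector
  signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), nrow = n)
  s_perm <- d %*% signs                  # m x n_perm row sums of flipped d
  ss <- rowSums(d * d)                   # invariant under sign flips
  v_perm <- (ss - s_perm^2 / n) / (n - 1)
  t_perm <- (s_perm / n) / sqrt(v_perm / n)
  pool <- t_perm[is.finite(t_perm)]

  total <- length(pool)
  # #\{pool >= t_i\} via the sorted pool; the small tolerance makes genuine
  # ties (e.g. the identity permutation reproducing t_i) robust to
  # floating-point noise between the observed and permuted code paths
  sorted <- sort(pool)
  tie_tol <- 1e-8 * pmax(1, abs(t_obs))
  n_ge <- total - findInterval(t_obs - tie_tol, sorted, left.open = TRUE)
  p <- (1 + n_ge) / (1 + total)
  p[v0 == 0] <- NA_real_
  names(p) <- rownames(d)
  names(t_obs) <- rownames(d)
  list(p = p, t = t_obs, degenerate = degenerate, n_pool = total)
}

#' Inverse-normal transform of upper-tail p-values
#'
#' Maps an upper-tail p-value to a signed z-score with
#' `z = qnorm(1 - p) = qnorm(p, lower.tail = FALSE)`: strong up-regulation
#' (small upper-tail p) gives a large positive z, strong down-regulation a
#' large negative z, and `p = 0.5` gives `z = 0`.
#'
#' @param p Numeric vector or matrix of upper-tail p-values strictly inside
#'   (0, 1).
#' @return z-scores of the same shape, names/dimnames preserved.
#' @export
#' @examples
#' z_transform(c(0.025, 0.5, 0.975))
z_transform <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("p-values must lie strictly inside (0, 1)")
  z <- stats::qnorm(p, lower.tail = FALSE)
  attributes(z) <- attributes(p)
  z
}

#' Build a z-score matrix from several paired datasets
#'
#' Runs [pooled_permutation_pvalues()] and [z_transform()] on each dataset
#' and assembles the m x K matrix over the genes common to all datasets
#' (genes missing anywhere, or degenerate in any dataset, are dropped).
#'
#' @param datasets List of [paired_dataset()] objects.
#' @param n_perm Permutations per dataset.
#' @param seed Base seed; dataset k uses `seed + k - 1`.
#' @param dataset_ids Column names for the result.
#' @return Numeric m x K z-score matrix with gene rownames.
#' @export
zscore_matrix <- function(datasets, n_perm = 1000L, seed = 1L,
                          dataset_ids = NULL) {
  stopifnot(length(datasets) >= 1)
  if (is.null(dataset_ids)) {
    dataset_ids <- names(datasets)
    if (is.null(dataset_ids)) dataset_ids <- paste0("z", seq_along(datasets))
  }
  common <- Reduce(intersect, lapply(datasets, `[[`, "gene_ids"))
  if (length(common) == 0) stop("no genes are common to all datasets")
  cols <- vector("list", length(datasets))
  for (k in seq_along(datasets)) {
    res <- pooled_permutation_pvalues(datasets[[k]], n_perm = n_perm,
                                      seed = seed + k - 1L)
    cols[[k]] <- res$p[common]
  }
  p <- do.call(cbind, cols)
  keep <- stats::complete.cases(p)
  z <- z_transform(p[keep, , drop = FALSE])
  dimnames(z) <- list(common[keep], dataset_ids)
  z
}
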