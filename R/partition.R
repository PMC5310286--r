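# Cohort partitioning by a single reference gene's paired expression ratio:
# the per-pair log2(case/control) values of that gene are clustered in one
# dimension and the tree cut defines ordered, non-overlapping subsets of
# pairs, so that the reference gene moves from down-regulated (subset 1) to
# up-regulated (last subset).

#' Per-pair log2 expression ratio of a reference gene
#'
#' @param dataset A [paired_dataset()].
#' @param gene_id Identifier of the reference gene.
#' @return Named numeric vector (one value per pair): log2(case/control) on
#'   the ratio scale, or the case-control difference when the dataset is
#'   already log-scale.
#' @export
log2_paired_ratio <- function(dataset, gene_id) {
  stopifnot(inherits(dataset, "paired_dataset"))
  if (!gene_id %in% dataset$gene_ids)
    stop(sprintf("unknown gene '%s'", gene_id))
  d <- paired_differences(dataset)
  d[gene_id, ]
}

#' Partition pairs by 1-D clustering of reference-gene ratios
#'
#' Agglomerative clustering of the log2 paired-ratio values with Euclidean
#' distance and median linkage; the tree is cut at `cut_height`, singleton
#' clusters are merged into the cluster with the nearest centroid, and the
#' surviving clusters are relabelled 1..K by increasing median ratio, so
#' subset 1 holds the most down-regulated pairs.
#'
#' @param ratios Named numeric vector of per-pair log2 ratios, e.g. from
#'   [log2_paired_ratio()].
#' @param cut_height Positive height at which the tree is cut.
#' @return Named integer vector of subset labels (1..K) per pair.
#' @export
#' @examples
#' cluster_partition(c(a = -2, b = -2.1, c = 2, d = 1.9), cut_height = 1)
cluster_partition <- function(ratios, cut_height) {
  stopifnot(is.numeric(ratios), all(is.finite(ratios)), cut_height > 0)
  n <- length(ratios)
  if (n < 2) stop("need at least 2 pairs")
  if (length(unique(ratios)) == 1L) {
    warning("all ratios identical: returning a single cluster")
    return(stats::setNames(rep(1L, n), names(ratios)))
  }
  hc <- stats::hclust(stats::dist(ratios), method = "median")
  labels <- stats::cutree(hc, h = cut_height)

  # fold singletons into the cluster whose centroid is nearest
  repeat {
    sizes <- table(labels)
    if (length(sizes) <= 1L || min(sizes) > 1L) break
    singleton <- as.integer(names(sizes)[which.min(sizes)])
    idx <- which(labels == singleton)[1]
    others <- setdiff(unique(labels), singleton)
    cent <- vapply(others, function(cl) mean(ratios[labels == cl]), numeric(1))
    labels[idx] <- others[which.min(abs(cent - ratios[idx]))]
  }

  # relabel by increasing cluster median
  med <- vapply(sort(unique(labels)), function(cl)
    stats::median(ratios[labels == cl]), numeric(1))
  new_id <- match(labels, sort(unique(labels))[order(med)])
  stats::setNames(as.integer(new_id), names(ratios))
}

#' Split a paired dataset into subsets of pairs
#'
#' Applies a [cluster_partition()] labelling to a full cohort, producing one
#' [paired_dataset()] per subset (subsets with fewer than 2 pairs are
#' dropped with a warning, since no paired t-test is possible there).
#'
#' @param dataset A [paired_dataset()].
#' @param labels Integer subset label per pair, aligned with
#'   `dataset$pair_ids`.
#' @return Named list of `paired_dataset` objects ("subset1", "subset2", ...).
#' @export
split_by_partition <- function(dataset, labels) {
  stopifnot(inherits(dataset, "paired_dataset"),
            length(labels) == length(dataset$pair_ids))
  out <- list()
  for (cl in sort(unique(labels))) {
    sel <- which(labels == cl)
    if (length(sel) < 2) {
      warning(sprintf("subset %d has fewer than 2 pairs and was dropped", cl))
      next
    }
    cols <- c(dataset$case_cols[sel], dataset$control_cols[sel])
    out[[paste0("subset", cl)]] <- paired_dataset(
      values = dataset$values[, cols, drop = FALSE],
      gene_ids = dataset$gene_ids,
      pair_ids = dataset$pair_ids[sel],
      case_cols = seq_along(sel),
      control_cols = length(sel) + seq_along(sel),
      scale = dataset$scale
    )
  }
  out
}
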