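make_paired <- function(d, scale = "log") {
  # build a dataset whose per-pair differences for gene 1 equal d, plus a
  # few filler genes
  n <- length(d)
  ctrl <- matrix(5, 3, n)
  case <- ctrl + rbind(d, d / 2 + 0.1, -d)
  paired_dataset(cbind(case, ctrl), paste0("g", 1:3), paste0("p", seq_len(n)),
                 case_cols = seq_len(n), control_cols = n + seq_len(n),
                 scale = scale)
}

test_that("paired t-statistic matches the textbook formula and t.test", {
  d <- c(1.0, 2.0, 3.0, 6.0)
  ds <- make_paired(d)
  expect_equal(paired_t_score(ds, "g1"), mean(d) / (sd(d) / sqrt(4)))
  expect_equal(paired_t_score(ds, "g1"),
               unname(t.test(d)$statistic))
})

test_that("swapping case and control labels negates t", {
  d <- c(0.4, -1.1, 2.3, 0.9, -0.2)
  ds <- make_paired(d)
  swapped <- paired_dataset(ds$values, ds$gene_ids, ds$pair_ids,
                            case_cols = ds$control_cols,
                            control_cols = ds$case_cols, scale = "log")
  expect_equal(paired_t_score(swapped, "g1"), -paired_t_score(ds, "g1"))
})

test_that("degenerate genes are flagged, not silently zeroed", {
  n <- 4
  case <- rbind(c(2, 2, 2, 2), c(1, 2, 3, 4), c(5, 4, 6, 3))
  vals <- cbind(case, matrix(c(2, 0, 1), 3, n))
  ds <- paired_dataset(vals, paste0("g", 1:3), paste0("p", 1:n),
                       case_cols = 1:n, control_cols = n + 1:n, scale = "log")
  expect_error(paired_t_score(ds, "g1"), "zero-variance")
  expect_warning(res <- pooled_permutation_pvalues(ds, n_perm = 10, seed = 1),
                 "zero-variance")
  expect_true("g1" %in% res$degenerate)
  expect_true(is.na(res$p["g1"]))
  expect_false(anyNA(res$p[c("g2", "g3")]))
})

test_that("ratio-scale datasets take log2 case/control differences", {
  vals <- cbind(matrix(c(8, 4), 1, 2), matrix(c(4, 4), 1, 2))
  ds <- paired_dataset(vals, "g1", c("p1", "p2"),
                       case_cols = 1:2, control_cols = 3:4, scale = "ratio")
  expect_equal(unname(log2_paired_ratio(ds, "g1")), c(1, 0))
  bad <- ds
  bad$values[1, 1] <- -1
  expect_error(paired_t_score(bad, "g1"), "positive")
})

test_that("pooled permutation p-values match a naive seeded re-computation", {
  set.seed(31)
  m <- 3; n <- 4; n_perm <- 100
  d <- matrix(rnorm(m * n), m, n, dimnames = list(paste0("g", 1:m), NULL))
  vals <- cbind(d, matrix(0, m, n))
  ds <- paired_dataset(vals, rownames(d), paste0("p", 1:n),
                       case_cols = 1:n, control_cols = n + 1:n, scale = "log")
  res <- pooled_permutation_pvalues(ds, n_perm = n_perm, seed = 77)

  # naive oracle: regenerate the same flips, loop gene by gene
  set.seed(77)
  signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), nrow = n)
  tstat <- function(x) mean(x) / (sd(x) / sqrt(length(x)))
  pool <- as.numeric(sapply(seq_len(n_perm), function(b)
    apply(d, 1, function(row) tstat(row * signs[, b]))))
  for (i in seq_len(m)) {
    t_i <- tstat(d[i, ])
    tol <- 1e-8 * max(1, abs(t_i))     # same tie rule as the implementation
    expect_equal(unname(res$p[i]),
                 (1 + sum(pool >= t_i - tol)) / (1 + m * n_perm))
  }
})

test_that("a gene at the pooled maximum gets the smallest attainable p", {
  set.seed(8)
  m <- 5; n <- 2; n_perm <- 50
  d <- matrix(rnorm(m * n, 0, 0.5), m, n)
  d[1, ] <- d[1, ] + 50           # dominates every permuted t
  vals <- cbind(d, matrix(0, m, n))
  ds <- paired_dataset(vals, paste0("g", 1:m), paste0("p", 1:n),
                       case_cols = 1:n, control_cols = n + 1:n, scale = "log")
  res <- pooled_permutation_pvalues(ds, n_perm = n_perm, seed = 3)
  # only identity-sign permutations of g1 reach its observed t; count them
  set.seed(3)
  signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), nrow = n)
  n_identity <- sum(colSums(signs == 1) == n)
  expect_gte(n_identity, 1)
  expect_equal(unname(res$p["g1"]),
               (1 + n_identity) / (1 + m * n_perm))
})

test_that("permutation p-values reject bad inputs", {
  ds <- make_paired(c(1, 2, 3))
  expect_error(pooled_permutation_pvalues(ds, n_perm = 0), "n_perm")
  expect_error(paired_dataset(matrix(1, 2, 2), c("a", "b"), "p1",
                              case_cols = 1, control_cols = 2, scale = "log"),
               "at least 2 pairs")
})

test_that("permutation p-values are order-invariant and seed-reproducible", {
  set.seed(12)
  m <- 20; n <- 5
  d <- matrix(rnorm(m * n), m, n)
  vals <- cbind(d, matrix(0, m, n))
  ids <- paste0("g", 1:m)
  ds <- paired_dataset(vals, ids, paste0("p", 1:n),
                       case_cols = 1:n, control_cols = n + 1:n, scale = "log")
  perm <- sample(m)
  ds2 <- paired_dataset(vals[perm, ], ids[perm], paste0("p", 1:n),
                        case_cols = 1:n, control_cols = n + 1:n, scale = "log")
  r1 <- pooled_permutation_pvalues(ds, n_perm = 40, seed = 9)
  r1b <- pooled_permutation_pvalues(ds, n_perm = 40, seed = 9)
  r2 <- pooled_permutation_pvalues(ds2, n_perm = 40, seed = 9)
  expect_identical(r1$p, r1b$p)
  expect_equal(r1$p[ids], r2$p[ids])
})

test_that("the inverse-normal transform follows the sign convention", {
  expect_equal(z_transform(0.5), 0)
  expect_equal(z_transform(0.025), qnorm(0.975), tolerance = 1e-12)
  p <- c(0.01, 0.2, 0.7, 0.99)
  expect_equal(z_transform(p), -z_transform(1 - p))
  # small upper-tail p (strong up-regulation) must map to positive z
  expect_gt(z_transform(0.001), 0)
  expect_error(z_transform(c(0.5, 1)), "strictly inside")
  expect_error(z_transform(0), "strictly inside")
})

test_that("z is strictly increasing in t for p-values from one pooled null", {
  set.seed(4)
  m <- 30; n <- 6
  d <- matrix(rnorm(m * n), m, n)
  vals <- cbind(d, matrix(0, m, n))
  ds <- paired_dataset(vals, paste0("g", 1:m), paste0("p", 1:n),
                       case_cols = 1:n, control_cols = n + 1:n, scale = "log")
  res <- pooled_permutation_pvalues(ds, n_perm = 60, seed = 2)
  z <- z_transform(res$p)
  ord <- order(res$t)
  expect_false(is.unsorted(z[ord]))
})

test_that("zscore_matrix drops genes missing from any dataset", {
  set.seed(99)
  mk <- function(ids) {
    n <- 4
    d <- matrix(rnorm(length(ids) * n), length(ids), n)
    paired_dataset(cbind(d, matrix(0, length(ids), n)), ids,
                   paste0("p", 1:n), case_cols = 1:n,
                   control_cols = n + 1:n, scale = "log")
  }
  z <- zscore_matrix(list(a = mk(c("g1", "g2", "g3")),
                          b = mk(c("g2", "g3", "g4"))),
                     n_perm = 20, seed = 5)
  expect_setequal(rownames(z), c("g2", "g3"))
  expect_equal(colnames(z), c("a", "b"))
  expect_true(all(is.finite(z)))
})
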