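test_that("closed-form theta equals brute-force enumeration across K", {
  set.seed(202)
  for (rep in 1:20) {
    K <- sample(1:6, 1)
    p <- rand_params(K)
    expect_equal(discordance_theta(p), brute_theta(p), tolerance = 1e-12)
  }
})

test_that("theta boundary cases are forced by the definition", {
  p <- rand_params(4, lambda = 1)
  expect_equal(discordance_theta(p), 0)
  p1 <- rand_params(1, lambda = 0.3)
  expect_equal(discordance_theta(p1), 0)   # one dataset cannot be discordant
  set.seed(7)
  for (rep in 1:10) {
    p <- rand_params(sample(1:5, 1))
    expect_lte(discordance_theta(p), 1 - p$lambda + 1e-12)
  }
})

test_that("gene discordance posterior equals latent-configuration Bayes", {
  set.seed(210)
  for (rep in 1:15) {
    K <- sample(2:5, 1)
    p <- rand_params(K)
    z <- rnorm(K, sd = 2.5)
    expect_equal(gene_discordance_prob(z, p), brute_zeta(z, p),
                 tolerance = 1e-10)
  }
  # vectorised form agrees with the scalar one
  p <- rand_params(3)
  z <- matrix(rnorm(15, sd = 2), 5, 3, dimnames = list(paste0("g", 1:5), NULL))
  zv <- discordance_posteriors(z, p)
  expect_named(zv, paste0("g", 1:5))
  for (i in 1:5) expect_equal(unname(zv[i]), gene_discordance_prob(z[i, ], p))
})

test_that("zeta is zero when no discordant list is possible", {
  p <- rand_params(4, lambda = 1)
  expect_equal(gene_discordance_prob(c(3, -3, 2, -2), p), 0)
  p1 <- rand_params(1, lambda = 0.2)
  expect_equal(gene_discordance_prob(3, p1), 0)
})

test_that("mean zeta matches theta when z is sampled from the model", {
  truth <- default_truth_params(4)
  sim <- sim_z(truth, 50000, seed = 17)
  zeta <- discordance_posteriors(sim$z, truth)
  theta <- discordance_theta(truth)
  se <- sqrt(theta * (1 - theta) / 50000)
  expect_lt(abs(mean(zeta) - theta), 4 * se)
  # and zeta is a calibrated posterior for the latent labels
  expect_lt(abs(mean(zeta) - mean(sim$discordant)), 5 * se)
})

test_that("exact DES equals enumeration over all outcome vectors", {
  set.seed(220)
  for (rep in 1:15) {
    m_s <- sample(1:10, 1)
    zetas <- runif(m_s)
    theta <- runif(1)
    expect_equal(des_exact(zetas, theta), brute_des(zetas, theta),
                 tolerance = 1e-12)
  }
})

test_that("DES handles boundary and threshold-tie cases", {
  expect_equal(des_exact(rep(0, 5), 0.3), 0)
  expect_equal(des_exact(0.3, 0.5), 0.3)        # single Bernoulli
  expect_equal(des_exact(rep(1, 4), 0.5), 1)
  # integer threshold: strict means X >= c + 1
  zetas <- c(0.5, 0.5)
  expect_equal(des_exact(zetas, 0.5), 0.25)     # Pr(X > 1) = Pr(X = 2)
  expect_equal(des_exact(zetas, 0.5, inclusive = TRUE), 0.75)  # Pr(X >= 1)
  expect_error(des_exact(numeric(0), 0.2), "empty")
})

test_that("exact DES is monotone in theta and in each zeta", {
  set.seed(230)
  for (rep in 1:10) {
    m_s <- sample(3:12, 1)
    zetas <- runif(m_s)
    th <- sort(runif(3))
    des <- vapply(th, function(t) des_exact(zetas, t), numeric(1))
    expect_false(is.unsorted(rev(des)))          # non-increasing in theta
    i <- sample(m_s, 1)
    up <- zetas; up[i] <- min(1, zetas[i] + 0.3)
    expect_gte(des_exact(up, th[2]), des_exact(zetas, th[2]))
  }
})

test_that("Monte Carlo DES is reproducible and consistent with the exact DP", {
  zetas <- seq(0.05, 0.6, length.out = 30)
  theta <- 0.2
  p_exact <- des_exact(zetas, theta)
  m1 <- des_monte_carlo(zetas, theta, B = 2000, seed = 42)
  m2 <- des_monte_carlo(zetas, theta, B = 2000, seed = 42)
  expect_identical(m1, m2)
  est <- vapply(1:30, function(s)
    des_monte_carlo(zetas, theta, B = 2000, seed = s), numeric(1))
  se <- sqrt(p_exact * (1 - p_exact) / 2000)
  expect_gte(mean(abs(est - p_exact) <= 3 * se), 0.9)
  expect_lt(abs(mean(est) - p_exact), 3 * se)
  expect_equal(des_monte_carlo(rep(1, 5), 0.5, B = 50, seed = 1), 1)
  expect_equal(des_monte_carlo(rep(0, 5), 0.5, B = 50, seed = 1), 0)
})

test_that("FDR is one minus the running mean of sorted DES", {
  expect_equal(fdr_from_des(rep(1, 4))$fdr, 0)
  r <- fdr_from_des(c(1.0, 0.9))
  expect_equal(r$fdr, 0.05)
  expect_equal(r$fdr_at_rank, c(0, 0.05))
  set.seed(240)
  des <- sort(runif(20), decreasing = TRUE)
  r2 <- fdr_from_des(des)
  expect_equal(r2$fdr_at_rank,
               vapply(1:20, function(t) 1 - mean(des[1:t]), numeric(1)))
  expect_error(fdr_from_des(numeric(0)), "empty")
  expect_error(fdr_from_des(c(0.2, 0.9)), "sorted")
})

test_that("clear-discordance flags require both signs beyond the threshold", {
  z <- table1_fixture()
  res <- flag_clear_discordance(z, threshold = 4)
  expect_equal(names(which(res$flagged)), paste0("G", 4:8))
  expect_equal(res$count, 5L)
  expect_equal(res$proportion, 5 / 9)
  expect_false(flag_clear_discordance(matrix(0, 1, 6))$flagged[1])
  # all-positive rows never flag, however large
  expect_equal(flag_clear_discordance(matrix(10, 3, 4))$count, 0L)
})

test_that("score_collection assembles theta, zeta and ranked DES per set", {
  truth <- default_truth_params(3)
  sim <- sim_z(truth, 800, seed = 19)
  genes <- rownames(sim$z)
  disc <- names(which(sim$discordant))
  conc <- setdiff(genes, disc)
  coll <- gene_set_collection(list(
    hot = c(disc[1:20], conc[1:5]),
    cold = conc[6:35],
    missing = c("nope1", "nope2")
  ))
  expect_warning(res <- score_collection(sim$z, truth, coll), "skipped")
  expect_equal(res$skipped_sets, "missing")
  expect_equal(nrow(res$table), 2L)
  expect_equal(res$theta, discordance_theta(truth))
  hot <- res$table[res$table$set_name == "hot", ]
  cold <- res$table[res$table$set_name == "cold", ]
  expect_gt(hot$DES, cold$DES)
  expect_equal(hot$m_S, 25L)
  # table is sorted by decreasing DES and FDR matches the prefix means
  expect_false(is.unsorted(rev(res$table$DES)))
  expect_equal(res$table$FDR_at_rank,
               1 - cumsum(res$table$DES) / seq_len(nrow(res$table)))
  # DES recomputable from the returned zeta
  expect_equal(hot$DES,
               des_exact(res$zeta[intersect(coll$sets$hot, genes)], res$theta))
})

test_that("duplicate genes and ties are handled deterministically", {
  truth <- default_truth_params(3)
  sim <- sim_z(truth, 300, seed = 23)
  genes <- rownames(sim$z)
  coll <- gene_set_collection(list(b_set = genes[1:10], a_set = genes[1:10]))
  res <- score_collection(sim$z, truth, coll)
  expect_equal(res$table$set_name, c("a_set", "b_set"))  # tie broken by name
  expect_equal(res$table$DES[1], res$table$DES[2])
  # collection constructor deduplicates within a set
  c2 <- gene_set_collection(list(s = c("g1", "g1", "g2")))
  expect_equal(length(c2$sets$s), 2L)
})

test_that("lambda = 1 forces every DES to zero", {
  truth <- default_truth_params(2)
  truth$lambda <- 1
  sim <- sim_z(default_truth_params(2), 200, seed = 29)
  coll <- gene_set_collection(list(all = rownames(sim$z)))
  res <- score_collection(sim$z, truth, coll)
  expect_equal(res$table$DES, 0)
})
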