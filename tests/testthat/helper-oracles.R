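# Independent brute-force oracles used across the suite. These enumerate
# latent configurations directly from the model definition and never call
# the closed-form package routines they are used to check.

# Random valid parameter draw for property-style loops.
rand_params <- function(K, lambda = stats::runif(1)) {
  rho <- apply(matrix(stats::runif(3 * K) + 0.1, 3, K), 2,
               function(co) co / sum(co))
  rho <- matrix(rho, 3, K)
  pi <- stats::runif(3) + 0.1
  mixture_params(
    lambda = lambda, pi = pi / sum(pi), rho = rho,
    mu = rbind(0, stats::runif(K, 0.5, 3), -stats::runif(K, 0.5, 3)),
    sigma2 = rbind(1, stats::runif(K, 0.5, 2), stats::runif(K, 0.5, 2))
  )
}

# All 3^K latent component lists (codes 0 null, 1 up, 2 down), one per row.
all_lists <- function(K) {
  unname(as.matrix(expand.grid(rep(list(0:2), K))))
}

list_is_discordant <- function(g) any(g == 1) && any(g == 2)

# theta by enumeration: (1 - lambda) * sum of CI list probabilities over
# lists with at least one up and at least one down.
brute_theta <- function(params) {
  K <- params$K
  g <- all_lists(K)
  pr <- apply(g, 1, function(r) prod(params$rho[cbind(r + 1, seq_len(K))]))
  disc <- apply(g, 1, list_is_discordant)
  (1 - params$lambda) * sum(pr[disc])
}

# Per-list phi values for one z row: phi[j + 1, k].
phi_table <- function(z_row, params) {
  vapply(seq_len(params$K), function(k)
    stats::dnorm(z_row[k], params$mu[, k], sqrt(params$sigma2[, k])),
    numeric(3))
}

# Full latent-configuration Bayes enumeration for one z row: returns the
# CC-component joint masses (length 3), the CI-list joint masses (3^K) and
# the list matrix, so omega/xi/eta/zeta oracles all derive from it.
brute_config_masses <- function(z_row, params) {
  K <- params$K
  phi <- phi_table(z_row, params)
  g <- all_lists(K)
  ci <- apply(g, 1, function(r)
    (1 - params$lambda) *
      prod(params$rho[cbind(r + 1, seq_len(K))] * phi[cbind(r + 1, seq_len(K))]))
  cc <- vapply(1:3, function(j)
    params$lambda * params$pi[j] * prod(phi[j, ]), numeric(1))
  list(cc = cc, ci = ci, lists = g, den = sum(cc) + sum(ci))
}

brute_zeta <- function(z_row, params) {
  m <- brute_config_masses(z_row, params)
  disc <- apply(m$lists, 1, list_is_discordant)
  sum(m$ci[disc]) / m$den
}

# Poisson-binomial tail by enumeration over all 2^m outcome vectors.
brute_des <- function(zetas, theta) {
  m_s <- length(zetas)
  u <- as.matrix(expand.grid(rep(list(0:1), m_s)))
  pr <- apply(u, 1, function(r) prod(zetas^r * (1 - zetas)^(1 - r)))
  sum(pr[rowSums(u) > m_s * theta])
}

# Small simulated z matrix from given truth, for EM tests.
sim_z <- function(params, m, seed) {
  sample_zscores(simulation_scenario(params, m = m, seed = seed))
}
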