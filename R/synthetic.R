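# Simulation from the generative two-level model, with the latent truth
# returned so every downstream computation (theta, zeta, DES, EM estimates)
# can be checked against known labels. Default parameters emulate a
# moderately concordant series of five datasets with well-separated up/down
# components, the regime the method targets.

#' Default generator truth parameters
#'
#' Five datasets, CC weight 0.6, null-heavy component proportions
#' (pi = (0.8, 0.1, 0.1), every rho column (0.6, 0.2, 0.2)) and
#' well-separated unit-variance up/down components at +-2.5.
#'
#' @param K Number of datasets.
#' @return A [mixture_params()] object.
#' @export
default_truth_params <- function(K = 5L) {
  mixture_params(
    lambda = 0.6, pi = c(0.8, 0.1, 0.1),
    rho = matrix(c(0.6, 0.2, 0.2), 3L, K),
    mu = matrix(c(0, 2.5, -2.5), 3L, K),
    sigma2 = matrix(1, 3L, K)
  )
}

#' Describe a simulation scenario
#'
#' @param params Truth [mixture_params()].
#' @param m Number of genes.
#' @param planted_sets Data frame with columns `name`, `m_S`,
#'   `discordant_rate` describing sets to plant, or `NULL`.
#' @param n_background Number of background (uniformly sampled) sets.
#' @param background_size Size of each background set.
#' @param seed Mandatory integer seed.
#' @return A list of class `simulation_scenario`.
#' @export
simulation_scenario <- function(params, m = 10000L, planted_sets = NULL,
                                n_background = 0L, background_size = 40L,
                                seed) {
  validate_mixture_params(params)
  stopifnot(m >= 1, !missing(seed), is.finite(seed))
  if (!is.null(planted_sets))
    stopifnot(is.data.frame(planted_sets),
              all(c("name", "m_S", "discordant_rate") %in% names(planted_sets)))
  structure(
    list(params = params, m = as.integer(m), planted_sets = planted_sets,
         n_background = as.integer(n_background),
         background_size = as.integer(background_size),
         seed = as.integer(seed)),
    class = "simulation_scenario"
  )
}

#' Sample a z-score matrix from the generative model
#'
#' Draws, per gene, the layer indicator (CC with probability lambda), then
#' either one shared component j ~ pi applied to all K datasets (CC) or an
#' independent component j_k ~ rho per dataset (CI), and finally
#' `z_k ~ N(mu_jk, sigma2_jk)`.  The full latent truth is returned.
#'
#' @param scenario A [simulation_scenario()].
#' @return A list with `z` (m x K matrix, genes g1..gm), `omega` (latent
#'   layer indicator), `components` (m x K matrix of latent component codes
#'   0 = null, 1 = up, 2 = down) and `discordant` (logical: latent list has
#'   at least one up and one down).
#' @export
sample_zscores <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  p <- scenario$params
  m <- scenario$m
  K <- p$K
  set.seed(scenario$seed)

  omega <- stats::rbinom(m, 1L, p$lambda)
  comp <- matrix(0L, m, K)
  cc <- omega == 1L
  if (any(cc)) {
    j_shared <- sample(0:2, sum(cc), replace = TRUE, prob = p$pi)
    comp[cc, ] <- matrix(rep(j_shared, K), ncol = K)
  }
  for (k in seq_len(K)) {
    ci <- !cc
    if (any(ci))
      comp[ci, k] <- sample(0:2, sum(ci), replace = TRUE, prob = p$rho[, k])
  }
  z <- matrix(NA_real_, m, K)
  for (k in seq_len(K)) {
    j <- comp[, k] + 1L
    z[, k] <- stats::rnorm(m, p$mu[j, k], sqrt(p$sigma2[j, k]))
  }
  dimnames(z) <- list(paste0("g", seq_len(m)), p$dataset_ids)
  discordant <- apply(comp, 1L, function(r) any(r == 1L) && any(r == 2L))
  list(z = z, omega = omega, components = comp,
       discordant = stats::setNames(discordant, rownames(z)))
}

#' Plant discordance-enriched gene sets in a simulated universe
#'
#' Planted sets draw the requested fraction of their genes from the truly
#' discordant pool (by latent label, so the generative model is never
#' altered) and the rest from the non-discordant pool; background sets draw
#' genes uniformly.  Used for power and false-positive experiments with
#' known ground truth.
#'
#' @param scenario A [simulation_scenario()] with `planted_sets` and/or
#'   `n_background`.
#' @param sim Output of [sample_zscores()] for the same scenario.
#' @return A list with `collection` (a [gene_set_collection()]) and `truth`
#'   (data frame: name, m_S, planted, target_rate, true_discordant).
#' @export
plant_discordant_sets <- function(scenario, sim) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  genes <- rownames(sim$z)
  disc_pool <- genes[sim$discordant]
  other_pool <- genes[!sim$discordant]
  set.seed(scenario$seed + 1L)

  sets <- list()
  truth <- list()
  ps <- scenario$planted_sets
  if (!is.null(ps)) {
    for (r in seq_len(nrow(ps))) {
      m_s <- ps$m_S[r]
      n_disc <- round(ps$discordant_rate[r] * m_s)
      if (n_disc > length(disc_pool) || (m_s - n_disc) > length(other_pool))
        stop("infeasible scenario: not enough genes with the requested latent labels")
      members <- c(sample(disc_pool, n_disc), sample(other_pool, m_s - n_disc))
      sets[[ps$name[r]]] <- sample(members)   # shuffle, no order signal
      truth[[ps$name[r]]] <- data.frame(
        name = ps$name[r], m_S = m_s, planted = TRUE,
        target_rate = ps$discordant_rate[r],
        true_discordant = n_disc, stringsAsFactors = FALSE)
    }
  }
  if (scenario$n_background > 0) {
    for (b in seq_len(scenario$n_background)) {
      nm <- sprintf("background_%03d", b)
      members <- sample(genes, scenario$background_size)
      sets[[nm]] <- members
      truth[[nm]] <- data.frame(
        name = nm, m_S = scenario$background_size, planted = FALSE,
        target_rate = NA_real_,
        true_discordant = sum(sim$discordant[members]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(sets)) stop("scenario defines no sets to plant")
  list(collection = gene_set_collection(sets, source = "synthetic"),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Worked 9-gene, 6-dataset discordance illustration
#'
#' A small fixed z-score matrix (genes G1..G9, datasets z1..z6) in which
#' five of the nine genes show clear discordance: at least one z-score above
#' 4 and at least one below -4.  Useful as a first example for
#' [flag_clear_discordance()].
#'
#' @return A 9 x 6 numeric matrix.
#' @export
#' @examples
#' flag_clear_discordance(table1_fixture())
table1_fixture <- function() {
  z <- matrix(c(
     6.4,  8.8,  6.8,  8.4, 10.4,  1.2,
     5.2,  4.5,  7.0,  5.5,  3.3,  6.3,
    -0.3, -1.9,  1.8,  2.9,  6.7,  1.5,
     4.8,  7.7,  2.3, -4.9, -7.6,  2.2,
     1.9,  6.5, -1.2,  0.9, -8.1,  2.1,
     4.0, -8.9, -1.1,  5.0, -8.6,  7.9,
     3.7, -5.6, -1.6, -0.6, -9.0,  4.6,
    -3.1, -4.8, -1.6,  5.3, -2.9, -4.1,
    -6.3, -9.7, -1.1, -6.4, -8.4, -7.1
  ), nrow = 9, byrow = TRUE,
  dimnames = list(paste0("G", 1:9), paste0("z", 1:6)))
  z
}
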