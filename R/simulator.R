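# Forward simulation of the generative model with known ground truth, and
# the named study scenarios.

#' Define a simulation scenario
#'
#' Defaults are the base scenario: K = 3 clones, M = 1000 cells, N = 100
#' variants, L = 300 variable BCR positions, variant rate v = 0.3, mean
#' reads per variant per cell mu_D = 0.01, CRP concentration alpha0 = 5,
#' BCR profile prior strength s_g = 0.01, no centroid behaviour, genotype
#' error prior Beta(1, 19), theta0 prior Beta(0.2, 99.8) and theta_i prior
#' Beta(4.5, 5.5).
#'
#' @param K,M,N,L data dimensions (clones, cells, variants, BCR positions)
#' @param v per-entry probability that a clone carries a variant
#' @param mu_D Poisson mean of the total read count per variant per cell
#' @param alpha0 CRP concentration used to draw the hyperclustering
#' @param s_g Dirichlet prior strength per nucleotide for the BCR profiles
#' @param r_clust,r_cell centroid behaviour rates: each hypercluster is
#'   selected with rate `r_clust`, and within a selected hypercluster each
#'   cell is set to the cluster's modal sequence with rate `r_cell`
#' @param xi_prior,theta0_prior,theta_i_prior Beta priors from which the
#'   error rate and read probabilities are drawn
#' @param name optional scenario name
#' @return object of class `sim_scenario`
#' @export
sim_scenario <- function(K = 3, M = 1000, N = 100, L = 300, v = 0.3,
                         mu_D = 0.01, alpha0 = 5, s_g = 0.01,
                         r_clust = 0, r_cell = 0,
                         xi_prior = c(1, 19), theta0_prior = c(0.2, 99.8),
                         theta_i_prior = c(4.5, 5.5), name = "custom") {
  stopifnot(K >= 1, M >= 1, N >= 1, L >= 1, v >= 0, v <= 1, mu_D >= 0,
            alpha0 > 0, s_g > 0,
            r_clust >= 0, r_clust <= 1, r_cell >= 0, r_cell <= 1)
  structure(list(K = K, M = M, N = N, L = L, v = v, mu_D = mu_D,
                 alpha0 = alpha0, s_g = s_g, r_clust = r_clust,
                 r_cell = r_cell, xi_prior = xi_prior,
                 theta0_prior = theta0_prior, theta_i_prior = theta_i_prior,
                 name = name),
            class = "sim_scenario")
}

#' Named scenario presets
#'
#' The base scenario plus eight variations, each changing one property:
#' high/low read depth (`mu_D` 0.05 / 0.002), sparse hyperclustering
#' (`alpha0` 50), high within-cluster BCR variance (`s_g` 1), and four
#' centroid scenarios `centroids_<x>_<y>` in which x% of cells within y%
#' of hyperclusters carry their cluster's modal BCR sequence
#' (x, y in {20, 80}).
#'
#' @param ... overrides applied to every preset (e.g. `M = 300`)
#' @return named list of [sim_scenario()] objects
#' @export
scenario_presets <- function(...) {
  base <- list(...)
  mk <- function(name, ...) {
    args <- utils::modifyList(c(list(name = name), base), list(...))
    do.call(sim_scenario, args)
  }
  list(
    basic = mk("basic"),
    high_reads = mk("high_reads", mu_D = 0.05),
    low_reads = mk("low_reads", mu_D = 0.002),
    sparse_clusters = mk("sparse_clusters", alpha0 = 50),
    high_variance_bcr = mk("high_variance_bcr", s_g = 1),
    centroids_80_80 = mk("centroids_80_80", r_cell = 0.8, r_clust = 0.8),
    centroids_80_20 = mk("centroids_80_20", r_cell = 0.8, r_clust = 0.2),
    centroids_20_80 = mk("centroids_20_80", r_cell = 0.2, r_clust = 0.8),
    centroids_20_20 = mk("centroids_20_20", r_cell = 0.2, r_clust = 0.2))
}

#' Draw a partition of M items from the Chinese Restaurant Process
#'
#' @param M number of items
#' @param alpha0 concentration parameter
#' @return integer labels in order of first appearance (1..Q)
#' @export
simulate_crp <- function(M, alpha0) {
  t <- integer(M)
  t[1] <- 1L
  Q <- 1L
  n <- c(1L, integer(M - 1))
  for (j in seq_len(M)[-1]) {
    p <- c(n[seq_len(Q)], alpha0)
    pick <- sample.int(Q + 1L, 1L, prob = p)
    if (pick > Q) Q <- Q + 1L
    n[pick] <- n[pick] + 1L
    t[j] <- pick
  }
  t
}

# Modal sequence of a profile matrix (4 x L): per-position argmax with
# ties broken in A < C < G < T order (which.max takes the first maximum).
modal_sequence <- function(B_q) {
  apply(B_q, 2, which.max)
}

#' Simulate a dataset with known ground truth
#'
#' Follows the generative model: hyperclustering from the CRP at the
#' scenario's concentration; uniform hypercluster-to-clone assignment; BCR
#' profiles from Dirichlet(s_g) and sequences from the per-cluster
#' categorical profiles, with optional centroid injection; clone genotypes
#' Bernoulli(v), observed genotypes flipped with the drawn error rate xi;
#' total reads Poisson(mu_D) and alternate reads Binomial with theta_i or
#' theta0 according to the cell's clone genotype.
#'
#' @param scenario a [sim_scenario()]
#' @param seed optional integer seed
#' @return list with `reads` ([variant_read_data()]), `bcr`
#'   ([bcr_alignment()]), `omega` (observed genotype matrix) and `truth`
#'   (hidden T, I, C, B, theta, xi and derived per-cell clone labels)
#' @export
simulate_dataset <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(seed)) set.seed(seed)
  K <- scenario$K; M <- scenario$M; N <- scenario$N; L <- scenario$L

  # Step 1: hyperclustering and clone assignment
  t_true <- simulate_crp(M, scenario$alpha0)
  Q <- max(t_true)
  i_true <- sample.int(K, Q, replace = TRUE)

  # Step 2: BCR profiles and sequences, with centroid injection
  b_true <- rdirichlet_cols(array(scenario$s_g, dim = c(4, L, Q)))
  X <- matrix(0L, M, L)
  for (q in seq_len(Q)) {
    cells <- which(t_true == q)
    for (l in seq_len(L)) {
      X[cells, l] <- sample.int(4L, length(cells), replace = TRUE,
                                prob = b_true[, l, q])
    }
  }
  centroid_cell <- rep(FALSE, M)
  centroid_cluster <- runif(Q) < scenario$r_clust
  for (q in which(centroid_cluster)) {
    cells <- which(t_true == q)
    sel <- cells[runif(length(cells)) < scenario$r_cell]
    if (length(sel) > 0)
      X[sel, ] <- matrix(modal_sequence(b_true[, , q]), length(sel), L,
                         byrow = TRUE)
    centroid_cell[sel] <- TRUE
  }

  # Step 3: genotypes and the error-prone observed matrix
  xi <- rbeta(1, scenario$xi_prior[1], scenario$xi_prior[2])
  theta0 <- rbeta(1, scenario$theta0_prior[1], scenario$theta0_prior[2])
  theta_i <- rbeta(N, scenario$theta_i_prior[1], scenario$theta_i_prior[2])
  C <- matrix(rbinom(N * K, 1L, scenario$v), N, K)
  flip <- matrix(rbinom(N * K, 1L, xi), N, K)
  omega <- abs(C - flip)

  # Step 4: read counts
  clone_of_cell <- i_true[t_true]
  Cc <- C[, clone_of_cell, drop = FALSE]
  D <- matrix(rpois(N * M, scenario$mu_D), N, M)
  p <- ifelse(Cc == 1, theta_i[row(Cc)], theta0)
  A <- matrix(rbinom(N * M, D, p), N, M)

  variant_ids <- sprintf("var_%03d", seq_len(N))
  barcodes <- sprintf("cell_%04d", seq_len(M))
  clone_ids <- sprintf("clone_%d", seq_len(K))
  dimnames(omega) <- list(variant_ids, clone_ids)
  nuc <- matrix(NUCLEOTIDES[X], M, L)
  list(
    reads = variant_read_data(A, D, variant_ids, barcodes),
    bcr = bcr_alignment(nuc, sprintf("pos_%03d", seq_len(L)), barcodes),
    omega = omega,
    truth = list(t_true = t_true, i_true = i_true, c_true = C,
                 b_true = b_true, xi = xi, theta0 = theta0,
                 theta_i = theta_i, alpha0 = scenario$alpha0,
                 clone_of_cell = clone_of_cell,
                 centroid_cell = centroid_cell,
                 centroid_cluster = centroid_cluster),
    scenario = scenario)
}

#' Hyperparameters matching a simulation scenario
#'
#' For fitting simulated data the generating priors are used throughout:
#' the Beta priors of xi, theta0 and theta_i, the Dirichlet strength `s_g`
#' on the BCR profiles, and the non-informative Gamma(1, 1) prior on
#' alpha0.  Matching `g` to the generating `s_g` matters: fitting
#' high-variance BCR data with a much smaller profile prior makes the
#' posterior prefer singleton hyperclusters and discards the read pooling
#' the hyperclusters provide.
#'
#' @param scenario a [sim_scenario()]
#' @return a [hyperparams()] set
#' @export
sim_hyperparams <- function(scenario) {
  hyperparams(kappa = scenario$xi_prior,
              nu0 = scenario$theta0_prior,
              nu_i = expand_nu_i(scenario$theta_i_prior, scenario$N),
              g = matrix(scenario$s_g, scenario$L, 4),
              alpha0_prior = c(1, 1))
}
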