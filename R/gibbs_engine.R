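# Orchestration of the Gibbs sampler: initialisation from identical-BCR
# groups, warm-up sweeps with the hyperclustering held fixed, full sweeps
# (xi, C, I, T, B, theta, alpha0), multivariate Gelman-Rubin convergence
# assessment across chains, and posterior summarisation.

# Sample one categorical draw per row of a probability matrix.
sample_rows <- function(P) {
  if (ncol(P) == 1L) {
    runif(nrow(P))  # keep the RNG stream aligned across K
    return(rep(1L, nrow(P)))
  }
  cs <- matrix(t(apply(P, 1, cumsum)), nrow = nrow(P))
  u <- runif(nrow(P))
  pmin(rowSums(cs < u) + 1L, ncol(P))
}

# Dirichlet draws for every column of a 4 x L x Q shape array.
# Underflow at very small shapes degenerates to a one-hot draw (the limit
# of the Dirichlet as the total mass goes to zero).
rdirichlet_cols <- function(shape) {
  dm <- dim(shape)
  gm <- matrix(rgamma(length(shape), shape = shape, rate = 1), nrow = 4)
  s <- colSums(gm)
  zero <- which(s == 0)
  if (length(zero) > 0) {
    gm[, zero] <- 0
    gm[cbind(sample.int(4, length(zero), replace = TRUE), zero)] <- 1
    s[zero] <- 1
  }
  array(gm / rep(s, each = 4), dim = dm)
}

#' Initialise the sampler state
#'
#' The hyperclustering starts from groups of cells with byte-identical BCR
#' sequences (missing symbols must match too).  The error rate and read
#' probabilities are drawn from their priors, the corrected genotypes start
#' at the input genotypes, and clone assignments are drawn uniformly; all
#' are then refined by [warmup()].  The BCR profiles and the concentration
#' parameter are initialised from their conditionals afterwards (see
#' [init_b_alpha0()]).
#'
#' @param data a [model_data()]
#' @param hyper a [hyperparams()] set (fully expanded)
#' @return a partial `bcrclone_state` (B and alpha0 not yet set)
#' @export
initialize_state <- function(data, hyper) {
  key <- apply(data$X, 1, paste, collapse = ",")
  t0 <- match(key, unique(key))
  Q <- max(t0)
  structure(list(
    xi = rbeta(1, hyper$kappa[1], hyper$kappa[2]),
    C = data$omega,
    t = as.integer(t0),
    I = sample.int(data$K, Q, replace = TRUE),
    B = NULL,
    theta0 = rbeta(1, hyper$nu0[1], hyper$nu0[2]),
    theta_i = rbeta(data$N, hyper$nu_i[, 1], hyper$nu_i[, 2]),
    alpha0 = NA_real_, sigma = NA_real_, logprob = NA_real_),
    class = "bcrclone_state")
}

#' Warm-up sweeps with the hyperclustering held fixed
#'
#' Samples only I, C, xi, theta0 and theta_i from their conditionals for
#' `n_init` iterations, keeping the initial BCR hyperclustering constant.
#' This resolves disagreements between the input clone genotypes and the
#' observed scRNA variant reads before the hyperclustering is relaxed.
#'
#' @inheritParams initialize_state
#' @param state state from [initialize_state()]
#' @param n_init number of warm-up iterations (>= 0)
#' @return the updated state (T unchanged)
#' @export
warmup <- function(state, data, hyper, n_init) {
  stopifnot(n_init >= 0)
  N <- data$N; K <- data$K
  for (it in seq_len(n_init)) {
    kx <- cond_xi(data$omega, state$C, hyper$kappa)
    state$xi <- rbeta(1, kx[1], kx[2])
    ldiff <- read_llik_diff(data, state)
    pc <- cond_c_impl(ldiff, state, data)
    state$C <- matrix(rbinom(N * K, 1L, pc), N, K)
    CL <- cell_clone_loglik(ldiff, state$C)
    state$I <- sample_rows(cond_i_impl(CL, state))
    th <- cond_theta(state, data, hyper)
    state$theta0 <- rbeta(1, th$nu0[1], th$nu0[2])
    state$theta_i <- rbeta(N, th$nu_i[, 1], th$nu_i[, 2])
  }
  state
}

#' Initialise BCR profiles and concentration from their conditionals
#'
#' @inheritParams warmup
#' @export
init_b_alpha0 <- function(state, data, hyper) {
  Q <- length(state$I)
  cnt <- nuc_counts_cpp(data$X, state$t, Q)
  state$B <- rdirichlet_cols(cnt + as.vector(t(hyper$g)))
  a0 <- rgamma(1, hyper$alpha0_prior[1], rate = hyper$alpha0_prior[2])
  a <- sample_alpha0(Q, data$M, hyper$alpha0_prior, a0)
  state$alpha0 <- a$alpha0
  state$sigma <- a$sigma
  state
}

#' Resample the CRP concentration parameter
#'
#' Auxiliary-variable scheme for mixture models: first draw
#' `sigma ~ Beta(alpha0 + 1, M)` using the previous alpha0, then draw
#' alpha0 from a two-component Gamma mixture
#' `pi * Gamma(Q + a, b - log sigma) + (1 - pi) * Gamma(Q + a - 1,
#' b - log sigma)` with mixture odds
#' `pi / (1 - pi) = (a + Q - 1) / (M * (b - log sigma))`, so that the
#' stationary marginal of alpha0 is proportional to
#' `Gamma(alpha0; a, b) * alpha0^(Q-1) * (alpha0 + M) * Beta(alpha0 + 1, M)`.
#'
#' @param Q number of non-empty hyperclusters (>= 1)
#' @param M number of cells (>= 1)
#' @param prior `c(a, b)` of the Gamma(shape, rate) prior on alpha0
#' @param alpha0 previous value of alpha0
#' @return list with `alpha0`, `sigma` and the mixture weight `mix_weight`
#' @export
sample_alpha0 <- function(Q, M, prior, alpha0) {
  stopifnot(Q >= 1, M >= 1, alpha0 > 0, all(prior > 0))
  sigma <- rbeta(1, alpha0 + 1, M)
  d <- prior[2] - log(sigma)
  odds <- (prior[1] + Q - 1) / (M * d)
  w <- odds / (1 + odds)
  shape <- if (runif(1) < w) prior[1] + Q else prior[1] + Q - 1
  list(alpha0 = rgamma(1, shape = shape, rate = d), sigma = sigma,
       mix_weight = w)
}

#' One full Gibbs sweep
#'
#' Updates, in order: xi, all C entries, all I labels, all T labels
#' (emptied clusters are deleted and labels compacted), all B profiles,
#' theta0 and all theta_i, then alpha0.  The complete-data joint
#' log-probability of the resulting state is stored in `state$logprob`.
#'
#' Two kernels are available for the T update.  The default `"collapsed"`
#' marginalises the BCR profiles (Dirichlet-multinomial predictive) and a
#' new cluster's clone label during the per-cell moves, reinstantiating
#' them from their conditionals afterwards; this partially collapsed move
#' targets the same joint posterior and mixes across cluster merges at
#' realistic sequence lengths.  `"auxiliary"` is the uncollapsed move that
#' conditions on the sampled profiles and offers one auxiliary cluster with
#' parameters drawn fresh from the priors (the parameters of a cluster
#' emptied by the move become the auxiliary, as Algorithm-8 correctness
#' requires).
#'
#' @inheritParams warmup
#' @param t_kernel `"collapsed"` (default) or `"auxiliary"`
#' @return the updated state
#' @export
full_sweep <- function(state, data, hyper,
                       t_kernel = c("collapsed", "auxiliary")) {
  t_kernel <- match.arg(t_kernel)
  N <- data$N; M <- data$M; K <- data$K
  kx <- cond_xi(data$omega, state$C, hyper$kappa)
  state$xi <- rbeta(1, kx[1], kx[2])
  ldiff <- read_llik_diff(data, state)
  pc <- cond_c_impl(ldiff, state, data)
  state$C <- matrix(rbinom(N * K, 1L, pc), N, K)
  CL <- cell_clone_loglik(ldiff, state$C)
  state$I <- sample_rows(cond_i_impl(CL, state))
  if (t_kernel == "collapsed") {
    sw <- sweep_t_collapsed_cpp(state$t, state$I, CL, data$X,
                                state$alpha0, hyper$g, K)
  } else {
    BL <- bcr_loglik_cpp(data$X, log(state$B))
    sw <- sweep_t_cpp(state$t, state$I, state$B, BL, CL, data$X,
                      state$alpha0, hyper$g, K)
  }
  state$t <- sw$t
  state$I <- sw$I
  Q <- length(state$I)
  cnt <- nuc_counts_cpp(data$X, state$t, Q)
  state$B <- rdirichlet_cols(cnt + as.vector(t(hyper$g)))
  th <- cond_theta(state, data, hyper)
  state$theta0 <- rbeta(1, th$nu0[1], th$nu0[2])
  state$theta_i <- rbeta(N, th$nu_i[, 1], th$nu_i[, 2])
  a <- sample_alpha0(Q, M, hyper$alpha0_prior, state$alpha0)
  state$alpha0 <- a$alpha0
  state$sigma <- a$sigma
  state$logprob <- joint_logprob(state, data, hyper)
  state
}

run_block <- function(state, data, hyper, n_sweeps,
                      t_kernel = "collapsed") {
  trace <- matrix(NA_real_, n_sweeps, 3,
                  dimnames = list(NULL, c("theta0", "theta_bar", "alpha0")))
  jlp <- numeric(n_sweeps)
  clone <- matrix(NA_integer_, n_sweeps, data$M)
  t_snap <- matrix(NA_integer_, n_sweeps, data$M)
  C_snap <- matrix(NA_integer_, n_sweeps, data$N * data$K)
  for (s in seq_len(n_sweeps)) {
    state <- full_sweep(state, data, hyper, t_kernel)
    trace[s, ] <- c(state$theta0, mean(state$theta_i), state$alpha0)
    jlp[s] <- state$logprob
    clone[s, ] <- state$I[state$t]
    t_snap[s, ] <- state$t
    C_snap[s, ] <- as.integer(state$C)
  }
  list(state = state, trace = trace, jlp = jlp, clone = clone,
       t = t_snap, C = C_snap)
}

#' Multivariate potential scale reduction factor (Brooks-Gelman)
#'
#' `sqrt((n-1)/n + (m+1)/m * lambda1)` where `lambda1` is the largest
#' eigenvalue of `W^{-1} B/n`, with `W` the pooled within-chain covariance
#' and `B/n` the between-chain covariance of the means.  Parameters that
#' are constant within and between chains are dropped; a parameter with
#' between-chain spread but zero within-chain variance gives `Inf`.
#'
#' @param traces list (one per chain) of equal-sized iteration x parameter
#'   matrices of the continuous model variables
#' @return the MPSRF (scalar)
#' @export
mpsrf_brooks_gelman <- function(traces) {
  m <- length(traces)
  n <- nrow(traces[[1]])
  p <- ncol(traces[[1]])
  means <- matrix(vapply(traces, colMeans, numeric(p)), nrow = p)
  W <- Reduce(`+`, lapply(traces, stats::cov)) / m
  Bn <- stats::cov(t(means))
  keep <- diag(W) > 0 | diag(Bn) > 0
  if (!any(keep)) return(sqrt((n - 1) / n))
  W <- W[keep, keep, drop = FALSE]
  Bn <- Bn[keep, keep, drop = FALSE]
  if (any(diag(W) == 0)) return(Inf)
  lambda <- max(Re(eigen(solve(W, Bn), only.values = TRUE)$values))
  sqrt((n - 1) / n + (m + 1) / m * lambda)
}

#' Assess convergence across chains
#'
#' @param traces list of per-chain iteration x parameter matrices
#'   (post-burn-in, equal lengths)
#' @param threshold convergence threshold on the MPSRF (default 1.001)
#' @param estimator function computing the scale reduction factor from the
#'   trace list (default [mpsrf_brooks_gelman()])
#' @return list with `mpsrf` and logical `converged`
#' @export
check_convergence <- function(traces, threshold = 1.001,
                              estimator = mpsrf_brooks_gelman) {
  if (length(traces) < 2)
    stop("convergence assessment requires at least 2 chains")
  ns <- vapply(traces, nrow, integer(1))
  if (length(unique(ns)) != 1)
    stop("chains must have equal post-burn-in lengths")
  mpsrf <- estimator(traces)
  list(mpsrf = mpsrf, converged = is.finite(mpsrf) && mpsrf < threshold)
}

#' Summarise posterior samples into point estimates
#'
#' Selects the chain with the highest mean post-burn-in joint
#' log-probability; from it computes per-cell clone assignment frequencies,
#' the modal (MAP) assignment and genotypes (genotype ties are resolved
#' toward the input genotype), and the sampled hyperclustering with the
#' highest joint log-probability across all recorded iterations.
#'
#' @param records list of per-chain recording lists (internal layout of
#'   [fit_bcrclone()])
#' @param data a [model_data()]
#' @param burn_frac fraction of each chain's samples discarded as burn-in
#' @return object of class `bcrclone_result`
#' @export
extract_results <- function(records, data, burn_frac = 0.5) {
  n <- length(records[[1]]$jlp)
  burn <- floor(n * burn_frac)
  post <- (burn + 1):n
  mean_jlp <- vapply(records, function(r) mean(r$jlp[post]), numeric(1))
  sel <- which.max(mean_jlp)
  r <- records[[sel]]
  cl <- r$clone[post, , drop = FALSE]
  probs <- vapply(seq_len(data$K), function(k) colMeans(cl == k),
                  numeric(data$M))
  probs <- matrix(probs, nrow = data$M,
                  dimnames = list(data$cell_barcodes, data$clone_ids))
  map_assignment <- max.col(probs, ties.method = "first")
  c_freq <- matrix(colMeans(r$C[post, , drop = FALSE]), data$N, data$K,
                   dimnames = list(data$variant_ids, data$clone_ids))
  ties <- c_freq == 0.5
  if (any(ties))
    message(sum(ties), " genotype tie(s) resolved toward the input genotype")
  map_genotypes <- ifelse(c_freq > 0.5, 1L, ifelse(ties, data$omega, 0L))
  ml_iter <- which.max(r$jlp)
  structure(list(
    assignment_probs = probs,
    map_assignment = map_assignment,
    map_genotypes = map_genotypes,
    genotype_probs = c_freq,
    ml_hyperclustering = r$t[ml_iter, ],
    selected_chain = sel,
    chain_summaries = data.frame(chain = seq_along(records),
                                 mean_logprob = mean_jlp,
                                 n_samples = n),
    n_burnin = burn),
    class = "bcrclone_result")
}

#' Fit the joint hypercluster / clone-assignment model
#'
#' Runs `chains` independent Gibbs chains (chain c is seeded with
#' `seed + c`): identical-BCR initialisation, `n_init` warm-up iterations
#' with the hyperclustering fixed, then blocks of `block_size` full sweeps
#' until the MPSRF over (theta0, mean theta_i, alpha0) drops below
#' `mpsrf_threshold` or `max_blocks` blocks have run.  Burn-in for
#' summaries is the warm-up plus the first half of each chain's full
#' sweeps.
#'
#' @param data a [model_data()]
#' @param hyper a [hyperparams()] set; derived from the data via
#'   [derive_hyperparams()] when `NULL`
#' @param chains number of chains (default 4)
#' @param n_init warm-up iterations (default 5000)
#' @param block_size full sweeps per convergence block (default 500)
#' @param max_blocks maximum number of blocks
#' @param mpsrf_threshold MPSRF convergence threshold (default 1.001)
#' @param seed integer seed; all randomness is derived from it
#' @param t_kernel hypercluster update kernel passed to [full_sweep()]
#' @param assess_convergence compute the MPSRF after each block (requires
#'   >= 2 chains); when `FALSE`, exactly `max_blocks` blocks are run
#' @param verbose print per-block progress
#' @return object of class `bcrclone_fit`: the `result`
#'   ([extract_results()]), per-chain records, `mpsrf`, `converged` and the
#'   configuration
#' @export
fit_bcrclone <- function(data, hyper = NULL, chains = 4, n_init = 5000,
                         block_size = 500, max_blocks = 10,
                         mpsrf_threshold = 1.001, seed = 1,
                         t_kernel = c("collapsed", "auxiliary"),
                         assess_convergence = TRUE, verbose = FALSE) {
  t_kernel <- match.arg(t_kernel)
  stopifnot(inherits(data, "bcrclone_data"))
  if (is.null(hyper))
    hyper <- derive_hyperparams(
      variant_read_data(data$A, data$D, data$variant_ids, data$cell_barcodes),
      data$K, data$L)
  hyper$nu_i <- expand_nu_i(hyper$nu_i, data$N)
  hyper$g <- expand_g(hyper$g, data$L)

  states <- vector("list", chains)
  rngs <- vector("list", chains)
  records <- replicate(chains, NULL, simplify = FALSE)
  for (c in seq_len(chains)) {
    set.seed(seed + c)
    st <- initialize_state(data, hyper)
    st <- warmup(st, data, hyper, n_init)
    st <- init_b_alpha0(st, data, hyper)
    states[[c]] <- st
    rngs[[c]] <- get(".Random.seed", envir = globalenv())
  }

  converged <- FALSE
  mpsrf <- NA_real_
  blocks <- 0
  while (blocks < max_blocks) {
    blocks <- blocks + 1
    for (c in seq_len(chains)) {
      assign(".Random.seed", rngs[[c]], envir = globalenv())
      blk <- run_block(states[[c]], data, hyper, block_size, t_kernel)
      states[[c]] <- blk$state
      records[[c]] <- if (is.null(records[[c]])) blk else
        list(state = blk$state,
             trace = rbind(records[[c]]$trace, blk$trace),
             jlp = c(records[[c]]$jlp, blk$jlp),
             clone = rbind(records[[c]]$clone, blk$clone),
             t = rbind(records[[c]]$t, blk$t),
             C = rbind(records[[c]]$C, blk$C))
      rngs[[c]] <- get(".Random.seed", envir = globalenv())
    }
    if (assess_convergence) {
      n <- blocks * block_size
      post <- (floor(n / 2) + 1):n
      cc <- check_convergence(
        lapply(records, function(r) r$trace[post, , drop = FALSE]),
        threshold = mpsrf_threshold)
      mpsrf <- cc$mpsrf
      if (verbose)
        message(sprintf("block %d: MPSRF = %.5f", blocks, mpsrf))
      if (cc$converged) { converged <- TRUE; break }
    } else if (verbose) {
      message(sprintf("block %d done", blocks))
    }
  }
  if (assess_convergence && !converged && max_blocks > 0)
    warning("chains did not reach MPSRF < ", mpsrf_threshold, " after ",
            blocks, " block(s); results are based on unconverged chains",
            call. = FALSE)

  result <- if (blocks > 0) extract_results(records, data) else NULL
  structure(list(result = result, records = records, mpsrf = mpsrf,
                 converged = converged,
                 config = list(chains = chains, n_init = n_init,
                               block_size = block_size,
                               max_blocks = max_blocks, blocks_run = blocks,
                               mpsrf_threshold = mpsrf_threshold,
                               seed = seed, t_kernel = t_kernel),
                 data_dims = list(N = data$N, M = data$M, K = data$K,
                                  L = data$L)),
            class = "bcrclone_fit")
}

#' @exportS3Method base::print
print.bcrclone_fit <- function(x, ...) {
  cat(sprintf("bcrclone_fit: %d cells, %d variants, %d clones\n",
              x$data_dims$M, x$data_dims$N, x$data_dims$K))
  cat(sprintf("  chains: %d, full sweeps per chain: %d, MPSRF: %s (%s)\n",
              x$config$chains, x$config$blocks_run * x$config$block_size,
              format(x$mpsrf, digits = 5),
              if (isTRUE(x$converged)) "converged" else "not converged"))
  if (!is.null(x$result)) {
    q <- length(unique(x$result$ml_hyperclustering))
    cat(sprintf("  ML hyperclustering: %d hyperclusters; selected chain: %d\n",
                q, x$result$selected_chain))
  }
  invisible(x)
}
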