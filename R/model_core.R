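# Model state and the exact Gibbs conditionals of the joint model:
#
#   xi            genotype error rate,        xi ~ Beta(kappa0, kappa1)
#   C[i,k]        corrected clone genotypes,  P(C=1|Omega=1) = 1 - xi
#   T[j]          cell -> hypercluster,       CRP(alpha0)
#   I[q]          hypercluster -> clone,      uniform over 1..K
#   B[,l,q]       BCR nucleotide profile,     Dirichlet(g[l,])
#   X[j,l]        observed BCR nucleotide,    Categorical(B[,l,T_j])
#   theta0        alt-read prob, non-carrier, Beta(nu0)
#   theta_i       alt-read prob, carrier,     Beta(nu_i[i,])
#   A[i,j]|D[i,j] alt UMIs out of total,      Binom(D, theta_i or theta0)
#   alpha0        CRP concentration,          Gamma(a, b)

#' Bundle validated model inputs
#'
#' Intersects cell barcodes between the read matrices and the BCR
#' alignment (dropped cells are reported), aligns the genotype matrix rows
#' to the variant ids, and encodes the BCR alignment as integer codes.
#'
#' @param reads a [variant_read_data()]
#' @param bcr a [bcr_alignment()]
#' @param omega binary N x K input clone genotype matrix; if it has
#'   rownames they must cover the variant ids
#' @return object of class `bcrclone_data` with elements `A`, `D` (N x M),
#'   `X` (M x L integer codes, 0 = missing), `omega` (N x K), and the label
#'   vectors
#' @export
model_data <- function(reads, bcr, omega) {
  stopifnot(inherits(reads, "variant_read_data"),
            inherits(bcr, "bcr_alignment"))
  common <- intersect(reads$cell_barcodes, bcr$cell_barcodes)
  if (length(common) == 0)
    stop("no cell barcodes shared between the read matrices and the BCR data")
  n_drop <- (length(reads$cell_barcodes) - length(common)) +
    (length(bcr$cell_barcodes) - length(common))
  if (n_drop > 0)
    message(n_drop, " barcode(s) absent from one input were dropped; ",
            length(common), " cells retained")
  omega <- as.matrix(omega)
  if (!is.null(rownames(omega))) {
    idx <- match(reads$variant_ids, rownames(omega))
    if (anyNA(idx))
      stop("genotype matrix is missing variants: ",
           paste(utils::head(reads$variant_ids[is.na(idx)], 5), collapse = ", "))
    omega <- omega[idx, , drop = FALSE]
  } else if (nrow(omega) != length(reads$variant_ids)) {
    stop("genotype matrix rows do not match the number of variants")
  }
  if (!all(omega %in% c(0, 1))) stop("genotype matrix entries must be 0/1")
  storage.mode(omega) <- "integer"
  A <- reads$alt[, common, drop = FALSE]
  D <- reads$total[, common, drop = FALSE]
  X <- encode_nucleotides(
    bcr$nucleotides[match(common, bcr$cell_barcodes), , drop = FALSE],
    bcr$missing_char)
  clone_ids <- colnames(omega)
  if (is.null(clone_ids)) clone_ids <- paste0("clone_", seq_len(ncol(omega)))
  obs <- which(X > 0, arr.ind = TRUE)  # cached non-missing BCR entries
  bcr_obs <- cbind(code = X[obs], pos = obs[, 2], cell = obs[, 1])
  structure(list(A = A, D = D, X = X, omega = omega, bcr_obs = bcr_obs,
                 N = nrow(A), M = ncol(A), K = ncol(omega), L = ncol(X),
                 variant_ids = reads$variant_ids,
                 cell_barcodes = common,
                 clone_ids = clone_ids,
                 position_ids = bcr$position_ids),
            class = "bcrclone_data")
}

#' One Gibbs configuration of all model variables
#'
#' @param xi error rate in (0,1)
#' @param C binary N x K corrected genotype matrix
#' @param t length-M hypercluster labels (contiguous 1..Q, all non-empty)
#' @param I length-Q clone labels in 1..K
#' @param B 4 x L x Q array of nucleotide profiles (columns sum to 1)
#' @param theta0,theta_i non-carrier / carrier alternate-read probabilities
#' @param alpha0 CRP concentration (> 0)
#' @param sigma auxiliary variable of the concentration update, in (0,1)
#' @return object of class `bcrclone_state`
#' @export
model_state <- function(xi, C, t, I, B, theta0, theta_i, alpha0,
                        sigma = NA_real_) {
  st <- structure(list(xi = xi, C = C, t = as.integer(t), I = as.integer(I),
                       B = B, theta0 = theta0, theta_i = theta_i,
                       alpha0 = alpha0, sigma = sigma),
                  class = "bcrclone_state")
  validate_state(st)
  st
}

validate_state <- function(state) {
  Q <- length(state$I)
  occ <- tabulate(state$t, Q)
  if (max(state$t) != Q || any(occ == 0))
    stop("hypercluster labels must be contiguous 1..Q with no empty cluster")
  if (!is.null(state$B)) {
    sums <- apply(state$B, c(2, 3), sum)
    if (any(abs(sums - 1) > 1e-9))
      stop("BCR profile columns must sum to 1")
    if (dim(state$B)[3] != Q) stop("B has the wrong number of hyperclusters")
  }
  if (!is.na(state$xi) && (state$xi <= 0 || state$xi >= 1))
    stop("xi must lie in (0, 1)")
  invisible(state)
}

#' Prior probability of a corrected genotype entry
#'
#' `P(C = 1 | Omega, xi)`: `1 - xi` where the input genotype is 1, `xi`
#' where it is 0 (the input matrix is error-prone with rate xi).
#'
#' @param omega 0/1 input genotype entries (vectorised)
#' @param xi error rate in (0,1)
#' @return probabilities that the true genotype is 1
#' @export
prob_c_given_omega <- function(omega, xi) {
  if (any(xi <= 0) || any(xi >= 1)) stop("xi must lie in (0, 1)")
  ifelse(omega == 1, 1 - xi, xi)
}

#' Binomial log-likelihood of one read observation
#'
#' `log Binom(a | d, theta_i)` if the cell's clone carries the mutation,
#' else `log Binom(a | d, theta0)`.  An empty observation (d = 0)
#' contributes 0.
#'
#' @param a,d alternate and total UMI counts, `0 <= a <= d`
#' @param mutated logical: does the cell's clone carry the variant
#' @param theta0,theta_i alternate-read probabilities
#' @export
read_loglik <- function(a, d, mutated, theta0, theta_i) {
  if (any(a > d)) stop("alternate count exceeds total count")
  dbinom(a, d, ifelse(mutated, theta_i, theta0), log = TRUE)
}

#' Conditional Beta parameters of the genotype error rate xi
#'
#' Beta-Binomial conjugacy over the N*K genotype entries; a "success" is a
#' disagreement between the input and corrected genotype since xi is an
#' error rate.
#'
#' @param omega,c_mat input and corrected genotype matrices
#' @param kappa length-2 Beta prior
#' @return `c(shape1, shape2)` of the Beta conditional
#' @export
cond_xi <- function(omega, c_mat, kappa) {
  disagree <- sum(omega != c_mat)
  c(kappa[1] + disagree, kappa[2] + length(omega) - disagree)
}

# Per-entry log-likelihood ratio of a read under the carrier vs non-carrier
# rate: ldiff[i,j] = log Binom(A|D,theta_i) - log Binom(A|D,theta0).
# Binomial coefficients cancel.
read_llik_diff <- function(data, state) {
  lr1 <- log(state$theta_i) - log(state$theta0)
  lr2 <- log1p(-state$theta_i) - log1p(-state$theta0)
  data$A * lr1 + (data$D - data$A) * lr2
}

# M x K matrix: total read log-likelihood of each cell under each clone's
# current corrected genotype, up to a per-cell constant.
cell_clone_loglik <- function(ldiff, C) {
  crossprod(ldiff, C)
}

row_softmax <- function(logw) {
  mx <- apply(logw, 1, max)
  w <- exp(logw - mx)
  w / rowSums(w)
}

#' Conditional probabilities P(C[i,k] = 1 | rest)
#'
#' Combines the error-model prior with the read likelihood of all cells in
#' hyperclusters currently assigned to clone k, in log space.
#'
#' @param state a [model_state()]
#' @param data a [model_data()]
#' @return N x K matrix of probabilities
#' @export
cond_c <- function(state, data) {
  ldiff <- read_llik_diff(data, state)
  cond_c_impl(ldiff, state, data)
}

cond_c_impl <- function(ldiff, state, data) {
  prior_logodds <- qlogis(prob_c_given_omega(data$omega, state$xi))
  clone_of_cell <- state$I[state$t]
  Z <- matrix(0, data$M, data$K)
  Z[cbind(seq_len(data$M), clone_of_cell)] <- 1
  plogis(prior_logodds + ldiff %*% Z)
}

#' Conditional probabilities of hypercluster-to-clone assignments
#'
#' For each non-empty hypercluster q, the posterior over clones is the
#' uniform prior times the read likelihood of its member cells under each
#' clone genotype; computed with max-subtraction in log space.
#'
#' @inheritParams cond_c
#' @return Q x K matrix of probabilities (rows sum to 1)
#' @export
cond_i <- function(state, data) {
  ldiff <- read_llik_diff(data, state)
  cond_i_impl(cell_clone_loglik(ldiff, state$C), state)
}

cond_i_impl <- function(CL, state) {
  W <- rowsum(as.matrix(CL), group = state$t)
  row_softmax(W)
}

#' Conditional probabilities of one cell's hypercluster assignment
#'
#' Existing hyperclusters are weighted by their occupancy (cell j removed)
#' under the CRP, times the cell's read likelihood under the cluster's
#' clone and its BCR likelihood under the cluster's profile.  One auxiliary
#' new cluster is weighted by alpha0 with the supplied fresh prior draws of
#' its clone label and profile.
#'
#' @param j cell index
#' @param state a [model_state()]
#' @param data a [model_data()]
#' @param fresh_clone clone label of the auxiliary cluster (prior draw)
#' @param fresh_profile 4 x L profile of the auxiliary cluster (prior draw)
#' @return length Q+1 probability vector (last entry = new cluster); a
#'   cluster left empty by removing cell j gets probability 0
#' @export
cond_t <- function(j, state, data, fresh_clone, fresh_profile) {
  Q <- length(state$I)
  nq <- tabulate(state$t, Q)
  nq[state$t[j]] <- nq[state$t[j]] - 1L
  ldiff <- read_llik_diff(data, state)
  CLj <- as.vector(crossprod(ldiff[, j, drop = FALSE], state$C))
  x <- data$X[j, ]
  obs <- which(x > 0)
  bl <- vapply(seq_len(Q), function(q) {
    sum(log(state$B[cbind(x[obs], obs, q)]))
  }, numeric(1))
  bl_new <- sum(log(fresh_profile[cbind(x[obs], obs)]))
  logw <- c(ifelse(nq > 0, log(nq), -Inf) + CLj[state$I] + bl,
            log(state$alpha0) + CLj[fresh_clone] + bl_new)
  w <- exp(logw - max(logw))
  w / sum(w)
}

#' Conditional Dirichlet parameters of one BCR profile
#'
#' Dirichlet-multinomial conjugacy: prior plus the nucleotide counts at
#' position l among the cells of hypercluster q (missing symbols are not
#' counted).
#'
#' @param l BCR position index
#' @param q hypercluster index
#' @param g L x 4 Dirichlet prior matrix
#' @param data a [model_data()]
#' @param t hypercluster labels
#' @return length-4 Dirichlet parameter vector (A, C, G, T order)
#' @export
cond_b <- function(l, q, g, data, t) {
  x <- data$X[t == q, l]
  g[l, ] + tabulate(x[x > 0], nbins = 4L)
}

#' Conditional Beta parameters of theta0 and each theta_i
#'
#' Beta-Binomial conjugacy.  theta0 pools alternate and reference counts
#' over all (variant, cell) pairs whose clone does not carry the variant;
#' each theta_i pools over cells whose clone carries variant i.
#'
#' @inheritParams cond_c
#' @param hyper a [hyperparams()] set
#' @return list with `nu0` (length 2) and `nu_i` (N x 2)
#' @export
cond_theta <- function(state, data, hyper) {
  Cc <- state$C[, state$I[state$t], drop = FALSE]  # N x M carrier indicator
  ref <- data$D - data$A
  a0 <- hyper$nu0[1] + sum((1 - Cc) * data$A)
  b0 <- hyper$nu0[2] + sum((1 - Cc) * ref)
  ai <- hyper$nu_i[, 1] + rowSums(Cc * data$A)
  bi <- hyper$nu_i[, 2] + rowSums(Cc * ref)
  list(nu0 = c(a0, b0), nu_i = cbind(ai, bi))
}

log_ddirichlet <- function(x, alpha) {
  sum((alpha - 1) * log(x)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}

# Exchangeable partition probability of the CRP.
crp_logprob <- function(t, alpha0, M = length(t)) {
  Q <- max(t)
  nq <- tabulate(t, Q)
  Q * log(alpha0) + sum(lgamma(nq)) - sum(log(alpha0 + seq_len(M) - 1))
}

#' Complete-data joint log-probability of a model state
#'
#' Sum of all prior log-densities (xi, theta, alpha0, B), the CRP partition
#' probability of T, the uniform prior of I, the genotype error model
#' P(C | Omega, xi), the binomial read likelihood, and the categorical BCR
#' likelihood.  Used for chain selection and for selecting the
#' maximum-likelihood hyperclustering.
#'
#' @inheritParams cond_theta
#' @return finite scalar; a non-finite component raises an error naming it
#' @export
joint_logprob <- function(state, data, hyper) {
  Q <- length(state$I)
  parts <- c(
    prior_xi = dbeta(state$xi, hyper$kappa[1], hyper$kappa[2], log = TRUE),
    prior_theta0 = dbeta(state$theta0, hyper$nu0[1], hyper$nu0[2], log = TRUE),
    prior_theta_i = sum(dbeta(state$theta_i, hyper$nu_i[, 1],
                              hyper$nu_i[, 2], log = TRUE)),
    prior_alpha0 = dgamma(state$alpha0, hyper$alpha0_prior[1],
                          rate = hyper$alpha0_prior[2], log = TRUE),
    prior_B = {
      # clamp log(0) from profile entries that underflowed to machine zero
      logB <- pmax(log(state$B), log(.Machine$double.xmin))
      sum((rep(as.vector(t(hyper$g)), Q) - 1) * logB) +
        Q * sum(lgamma(rowSums(hyper$g)) - rowSums(lgamma(hyper$g)))
    },
    crp_T = crp_logprob(state$t, state$alpha0, data$M),
    prior_I = -Q * log(data$K),
    genotype_error = sum(log(ifelse(
      state$C == 1,
      prob_c_given_omega(data$omega, state$xi),
      1 - prob_c_given_omega(data$omega, state$xi)))),
    reads = {
      Cc <- state$C[, state$I[state$t], drop = FALSE]
      p <- ifelse(Cc == 1, state$theta_i[row(Cc)], state$theta0)
      sum(dbinom(data$A, data$D, p, log = TRUE))
    },
    bcr = {
      bo <- data$bcr_obs
      if (is.null(bo)) {
        obs <- which(data$X > 0, arr.ind = TRUE)
        bo <- cbind(code = data$X[obs], pos = obs[, 2], cell = obs[, 1])
      }
      sum(log(state$B[cbind(bo[, 1], bo[, 2], state$t[bo[, 3]])]))
    })
  if (any(!is.finite(parts)))
    stop("non-finite joint log-probability component: ",
         paste(names(parts)[!is.finite(parts)], collapse = ", "))
  sum(parts)
}
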