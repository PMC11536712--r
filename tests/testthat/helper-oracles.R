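# Independent reference computations used as oracles.  Everything here is
# written with naive loops / closed forms, deliberately not sharing code
# with the package implementation.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Sequential CRP product over cells: each cell joins an existing cluster
# with weight n/(alpha + j - 1) or opens its own with alpha/(alpha + j - 1).
oracle_crp_logprob <- function(t, alpha0) {
  counts <- integer(max(t))
  lp <- 0
  for (j in seq_along(t)) {
    q <- t[j]
    num <- if (counts[q] == 0) alpha0 else counts[q]
    lp <- lp + log(num) - log(alpha0 + j - 1)
    counts[q] <- counts[q] + 1L
  }
  lp
}

# Complete-data joint log-probability by naive term-by-term summation.
oracle_joint_logprob <- function(state, data, hyper) {
  lp <- dbeta(state$xi, hyper$kappa[1], hyper$kappa[2], log = TRUE) +
    dbeta(state$theta0, hyper$nu0[1], hyper$nu0[2], log = TRUE) +
    dgamma(state$alpha0, hyper$alpha0_prior[1],
           rate = hyper$alpha0_prior[2], log = TRUE)
  for (i in seq_len(data$N))
    lp <- lp + dbeta(state$theta_i[i], hyper$nu_i[i, 1], hyper$nu_i[i, 2],
                     log = TRUE)
  Q <- length(state$I)
  for (q in seq_len(Q)) for (l in seq_len(data$L)) {
    a <- hyper$g[l, ]
    x <- state$B[, l, q]
    lp <- lp + lgamma(sum(a)) - sum(lgamma(a)) + sum((a - 1) * log(x))
  }
  lp <- lp + oracle_crp_logprob(state$t, state$alpha0) - Q * log(data$K)
  for (i in seq_len(data$N)) for (k in seq_len(data$K)) {
    p1 <- if (data$omega[i, k] == 1) 1 - state$xi else state$xi
    lp <- lp + log(if (state$C[i, k] == 1) p1 else 1 - p1)
  }
  for (i in seq_len(data$N)) for (j in seq_len(data$M)) {
    mut <- state$C[i, state$I[state$t[j]]] == 1
    p <- if (mut) state$theta_i[i] else state$theta0
    lp <- lp + dbinom(data$A[i, j], data$D[i, j], p, log = TRUE)
  }
  for (j in seq_len(data$M)) for (l in seq_len(data$L)) {
    x <- data$X[j, l]
    if (x > 0) lp <- lp + log(state$B[x, l, state$t[j]])
  }
  lp
}

# All set partitions of 1..M as canonical label vectors (restricted growth
# strings: label of item j is at most 1 + max of previous labels).
set_partitions <- function(M) {
  out <- list()
  grow <- function(labels) {
    if (length(labels) == M) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    top <- if (length(labels) == 0) 0L else max(labels)
    for (q in seq_len(top + 1L)) grow(c(labels, q))
  }
  grow(integer(0))
  out
}

# Canonicalise a (hyperclustering, clone assignment) pair: clusters
# relabelled in order of first appearance, clone labels carried along.
canonical_ti <- function(t, I) {
  new_of_old <- match(unique(t), unique(t))
  names(new_of_old) <- unique(t)
  t2 <- match(t, unique(t))
  I2 <- I[unique(t)]
  paste(paste(t2, collapse = ""), paste(I2, collapse = ""), sep = "|")
}

# Exact posterior over (T, I) on a tiny instance, marginalising C, xi,
# theta and B analytically (conjugate integrals) and alpha0 by quadrature.
oracle_ti_posterior <- function(data, hyper) {
  stopifnot(data$M <= 4, data$N * data$K <= 6)
  parts <- set_partitions(data$M)
  keys <- character(0)
  logw <- numeric(0)
  c_confs <- as.matrix(expand.grid(rep(list(0:1), data$N * data$K)))
  nk <- data$N * data$K
  for (t in parts) {
    Q <- max(t)
    lpT <- log(integrate(function(a) {
      vapply(a, function(al) {
        exp(oracle_crp_logprob(t, al)) *
          dgamma(al, hyper$alpha0_prior[1], rate = hyper$alpha0_prior[2])
      }, numeric(1))
    }, 0, Inf, rel.tol = 1e-10)$value)
    lbcr <- 0
    for (q in seq_len(Q)) for (l in seq_len(data$L)) {
      x <- data$X[t == q, l]
      cnt <- tabulate(x[x > 0], nbins = 4)
      g <- hyper$g[l, ]
      lbcr <- lbcr + lgamma(sum(g)) - lgamma(sum(g) + sum(cnt)) +
        sum(lgamma(g + cnt) - lgamma(g))
    }
    for (Irow in seq_len(data$K^Q)) {
      I <- arrayInd(Irow, rep(data$K, Q))[1, ]
      clone_of_cell <- I[t]
      lread <- -Inf
      for (r in seq_len(nrow(c_confs))) {
        C <- matrix(c_confs[r, ], data$N, data$K)
        d <- sum(C != data$omega)
        lC <- lbeta(hyper$kappa[1] + d, hyper$kappa[2] + nk - d) -
          lbeta(hyper$kappa[1], hyper$kappa[2])
        Cc <- C[, clone_of_cell, drop = FALSE]
        A0 <- sum((1 - Cc) * data$A)
        R0 <- sum((1 - Cc) * (data$D - data$A))
        ll <- lbeta(hyper$nu0[1] + A0, hyper$nu0[2] + R0) -
          lbeta(hyper$nu0[1], hyper$nu0[2])
        for (i in seq_len(data$N)) {
          Ai <- sum(Cc[i, ] * data$A[i, ])
          Ri <- sum(Cc[i, ] * (data$D[i, ] - data$A[i, ]))
          ll <- ll + lbeta(hyper$nu_i[i, 1] + Ai, hyper$nu_i[i, 2] + Ri) -
            lbeta(hyper$nu_i[i, 1], hyper$nu_i[i, 2])
        }
        lread <- logsumexp(c(lread, lC + ll))
      }
      keys <- c(keys, canonical_ti(t, I))
      logw <- c(logw, lpT - Q * log(data$K) + lbcr + lread)
    }
  }
  w <- exp(logw - logsumexp(logw))
  stats::setNames(w / sum(w), keys)
}

# Unnormalised stationary density of the concentration parameter given the
# cluster count: Gamma prior x alpha^(Q-1) (alpha + M) Beta(alpha + 1, M).
oracle_alpha0_density <- function(Q, M, prior) {
  function(a) {
    dgamma(a, prior[1], rate = prior[2]) * a^(Q - 1) * (a + M) *
      beta(a + 1, M)
  }
}

# Adjusted Rand index straight from the contingency-table formula.
oracle_ari <- function(x, y) {
  tab <- table(x, y)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(x), 2)
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)  # degenerate: both partitions trivial
  (sum_ij - expected) / (maxi - expected)
}
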