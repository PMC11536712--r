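# Conditional probabilities of the graphical model and the joint
# log-probability, checked against direct rules and naive-summation oracles.

test_that("genotype prior follows the error-rate rule", {
  expect_equal(prob_c_given_omega(1, 0.2), 0.8)
  expect_equal(prob_c_given_omega(0, 0.2), 0.2)
  expect_equal(prob_c_given_omega(1, 1e-12), 1, tolerance = 1e-9)
  expect_equal(prob_c_given_omega(c(1, 0, 1), 0.1), c(0.9, 0.1, 0.9))
  expect_error(prob_c_given_omega(1, 1.2), "xi")
  expect_error(prob_c_given_omega(1, 0), "xi")
})

test_that("read log-likelihood selects the right binomial and handles d = 0", {
  expect_equal(read_loglik(0, 0, TRUE, 0.002, 0.45), 0)
  expect_equal(read_loglik(0, 0, FALSE, 0.002, 0.45), 0)
  expect_equal(read_loglik(1, 2, TRUE, 0.002, 0.5), log(0.5))  # 2 * .5 * .5
  expect_equal(read_loglik(1, 1, FALSE, 0.002, 0.5), log(0.002))
  expect_error(read_loglik(3, 2, TRUE, 0.1, 0.4), "exceeds")
})

test_that("xi conditional counts disagreements as successes", {
  omega <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(cond_xi(omega, omega, c(1, 19)), c(1, 23))
  c1 <- omega; c1[1, 1] <- 0
  expect_equal(cond_xi(omega, c1, c(1, 19)), c(2, 22))
  expect_equal(cond_xi(omega, 1 - omega, c(1, 19)), c(5, 19))
})

test_that("genotype conditional matches two-case enumeration", {
  # one variant, one clone-assigned cell with A = 1, D = 1
  data <- tiny_data(M = 1, N = 1, K = 1, L = 1,
                    A = matrix(1, 1, 1), D = matrix(1, 1, 1),
                    X = matrix(1, 1, 1), omega = matrix(1, 1, 1))
  st <- tiny_state(data, Q = 1)
  st$xi <- 0.2; st$theta0 <- 0.002; st$theta_i <- 0.45
  p <- cond_c(st, data)
  expect_equal(unname(p[1, 1]), 0.8 * 0.45 / (0.8 * 0.45 + 0.2 * 0.002),
               tolerance = 1e-12)

  # no cells assigned to a clone: prior only
  data2 <- tiny_data(M = 2, N = 1, K = 2, L = 2,
                     omega = matrix(c(1, 0), 1, 2))
  st2 <- tiny_state(data2, Q = 2)
  st2$I <- c(1L, 1L)  # clone 2 has no cells
  p2 <- cond_c(st2, data2)
  expect_equal(unname(p2[1, 2]), prob_c_given_omega(0, st2$xi))

  # equal read probabilities cancel the likelihood entirely
  st2$theta_i <- rep(st2$theta0, data2$N)
  p3 <- cond_c(st2, data2)
  expect_equal(unname(p3), prob_c_given_omega(data2$omega, st2$xi))
})

test_that("clone-assignment conditional matches two-case enumeration", {
  # one cell, one SNV, A = 0, D = 2; clone 1 carries the variant
  data <- tiny_data(M = 1, N = 1, K = 2, L = 1,
                    A = matrix(0, 1, 1), D = matrix(2, 1, 1),
                    X = matrix(1, 1, 1), omega = matrix(c(1, 0), 1, 2))
  st <- tiny_state(data, Q = 1)
  st$C <- matrix(c(1L, 0L), 1, 2)
  st$theta_i <- 0.5
  st$theta0 <- 1e-14
  p <- cond_i(st, data)
  expect_equal(unname(p[1, 2]), 1 / (1 + 0.25), tolerance = 1e-10)

  # a hypercluster with no reads is uniform over clones
  dataz <- tiny_data(M = 2, N = 2, K = 3, L = 2, A = matrix(0, 2, 2),
                     D = matrix(0, 2, 2), omega = matrix(1, 2, 3))
  stz <- tiny_state(dataz, Q = 2)
  expect_equal(unname(cond_i(stz, dataz)), matrix(1 / 3, 2, 3))

  # identical genotype columns are symmetric
  st$C <- matrix(c(1L, 1L), 1, 2)
  expect_equal(unname(cond_i(st, data)[1, ]), c(0.5, 0.5))
})

test_that("BCR profile conditional accumulates nucleotide counts", {
  data <- tiny_data(M = 3, N = 1, K = 2, L = 2,
                    X = matrix(1L, 3, 2))          # all cells "A"
  g <- matrix(0.01, 2, 4)
  expect_equal(cond_b(1, 1, g, data, t = rep(1L, 3)),
               c(3.01, 0.01, 0.01, 0.01))
  # all-missing position: prior only
  datam <- tiny_data(M = 2, N = 1, K = 2, L = 1, X = matrix(0L, 2, 1))
  expect_equal(cond_b(1, 1, matrix(0.01, 1, 4), datam, t = rep(1L, 2)),
               rep(0.01, 4))
  # mixed counts (1, 1, 0, 0)
  datx <- tiny_data(M = 2, N = 1, K = 2, L = 1, X = matrix(c(1L, 2L), 2, 1))
  expect_equal(cond_b(1, 1, matrix(0.01, 1, 4), datx, t = rep(1L, 2)),
               c(1.01, 1.01, 0.01, 0.01))
})

test_that("theta conditionals implement the four pooled sums", {
  hyper <- hyperparams(kappa = c(1, 19), nu0 = c(0.2, 99.8),
                       nu_i = matrix(c(4.5, 5.5), 1, 2),
                       g = matrix(0.01, 1, 4))
  # no reads: posterior equals prior
  data0 <- tiny_data(M = 2, N = 1, K = 2, L = 1, A = matrix(0, 1, 2),
                     D = matrix(0, 1, 2))
  st0 <- tiny_state(data0, Q = 1)
  th0 <- cond_theta(st0, data0, hyper)
  expect_equal(th0$nu0, hyper$nu0)
  expect_equal(unname(th0$nu_i), unname(hyper$nu_i))

  # one mutated cell-position with A = 2, D = 5
  data1 <- tiny_data(M = 1, N = 1, K = 1, L = 1, A = matrix(2, 1, 1),
                     D = matrix(5, 1, 1), omega = matrix(1, 1, 1))
  st1 <- tiny_state(data1, Q = 1)
  st1$C <- matrix(1L, 1, 1)
  th1 <- cond_theta(st1, data1, hyper)
  expect_equal(unname(th1$nu_i[1, ]), c(4.5 + 2, 5.5 + 3))
  expect_equal(th1$nu0, hyper$nu0)

  # one non-mutated cell-position with A = 1, D = 4
  st1$C <- matrix(0L, 1, 1)
  data2 <- tiny_data(M = 1, N = 1, K = 1, L = 1, A = matrix(1, 1, 1),
                     D = matrix(4, 1, 1), omega = matrix(0, 1, 1))
  th2 <- cond_theta(st1, data2, hyper)
  expect_equal(th2$nu0, c(0.2 + 1, 99.8 + 3))
  expect_equal(unname(th2$nu_i[1, ]), c(4.5, 5.5))
})

test_that("hypercluster conditional weighs occupancy, reads and BCR terms", {
  # flat likelihoods: no reads, uninformative profiles; M = 2, alpha0 = 1
  data <- tiny_data(M = 2, N = 1, K = 2, L = 1, A = matrix(0, 1, 2),
                    D = matrix(0, 1, 2), X = matrix(1L, 2, 1))
  st <- tiny_state(data, Q = 1)
  st$alpha0 <- 1
  flat <- array(0.25, dim = c(4, 1, 1))
  st$B <- flat
  p <- cond_t(2, st, data, fresh_clone = 1,
              fresh_profile = matrix(0.25, 4, 1))
  expect_equal(p, c(0.5, 0.5))  # n/(M-1+a) = a/(M-1+a)

  # alpha0 -> 0 removes the new-cluster option
  st$alpha0 <- 1e-300
  p0 <- cond_t(2, st, data, 1, matrix(0.25, 4, 1))
  expect_lt(p0[2], 1e-290)

  # a BCR sequence impossible under existing profiles forces a new cluster
  st$alpha0 <- 1
  imposs <- array(c(0, 1, 0, 0), dim = c(4, 1, 1))  # cluster emits only C
  st$B <- imposs
  pf <- cond_t(2, st, data, 1, matrix(c(1, 0, 0, 0), 4, 1))  # fresh emits A
  expect_equal(pf[2], 1)  # cell's nucleotide is A
})

test_that("joint log-probability matches the naive summation oracle", {
  for (seed in c(2, 5, 9)) {
    data <- tiny_data(M = 3, N = 2, K = 2, L = 2, seed = seed)
    hyper <- tiny_hyper(data)
    st <- tiny_state(data, Q = 2, seed = seed + 100)
    expect_equal(joint_logprob(st, data, hyper),
                 oracle_joint_logprob(st, data, hyper), tolerance = 1e-10)
  }
})

test_that("joint log-probability is additive in single read factors", {
  data <- tiny_data(M = 3, N = 2, K = 2, L = 2, seed = 3)
  hyper <- tiny_hyper(data)
  st <- tiny_state(data, Q = 2)
  lp1 <- joint_logprob(st, data, hyper)
  data2 <- tiny_data(M = 3, N = 2, K = 2, L = 2, seed = 3,
                     A = data$A, D = data$D + (row(data$D) == 1) *
                       (col(data$D) == 1), X = data$X, omega = data$omega)
  lp2 <- joint_logprob(st, data2, hyper)
  mut <- st$C[1, st$I[st$t[1]]] == 1
  expect_equal(lp2 - lp1,
               read_loglik(data$A[1, 1], data$D[1, 1] + 1, mut, st$theta0,
                           st$theta_i[1]) -
                 read_loglik(data$A[1, 1], data$D[1, 1], mut, st$theta0,
                             st$theta_i[1]),
               tolerance = 1e-10)
})

test_that("model_state enforces its invariants", {
  data <- tiny_data()
  st <- tiny_state(data, Q = 2)
  expect_error(model_state(st$xi, st$C, c(1L, 3L, 3L), st$I, st$B,
                           st$theta0, st$theta_i, st$alpha0),
               "contiguous")
  badB <- st$B; badB[1, 1, 1] <- badB[1, 1, 1] + 0.01
  expect_error(model_state(st$xi, st$C, st$t, st$I, badB, st$theta0,
                           st$theta_i, st$alpha0), "sum to 1")
  expect_error(model_state(1.5, st$C, st$t, st$I, st$B, st$theta0,
                           st$theta_i, st$alpha0), "xi")
})
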