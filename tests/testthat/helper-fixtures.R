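# Small fixture builders (all in-code; nothing read from disk).

NUC <- c("A", "C", "G", "T")

# Tiny validated data bundle; any component can be supplied explicitly.
tiny_data <- function(M = 3, N = 2, K = 2, L = 2, A = NULL, D = NULL,
                      X = NULL, omega = NULL, seed = 42) {
  set.seed(seed)
  if (is.null(D)) D <- matrix(rpois(N * M, 1), N, M)
  if (is.null(A)) A <- matrix(rbinom(N * M, D, 0.4), N, M)
  if (is.null(X)) X <- matrix(sample.int(4, M * L, replace = TRUE), M, L)
  if (is.null(omega)) omega <- matrix(rbinom(N * K, 1, 0.5), N, K)
  chars <- matrix("N", nrow(X), ncol(X))
  chars[X > 0] <- NUC[X[X > 0]]
  reads <- variant_read_data(A, D, paste0("v", seq_len(N)),
                             paste0("c", seq_len(M)))
  bcr <- bcr_alignment(chars, paste0("p", seq_len(L)), paste0("c", seq_len(M)))
  suppressMessages(model_data(reads, bcr, omega))
}

tiny_hyper <- function(data, g_val = 1) {
  hyperparams(kappa = c(1, 3), nu0 = c(1, 9),
              nu_i = matrix(c(2, 2), data$N, 2, byrow = TRUE),
              g = matrix(g_val, data$L, 4), alpha0_prior = c(1, 1))
}

# Independent Dirichlet draw used when constructing arbitrary valid states.
rand_profiles <- function(L, Q, conc = 1) {
  arr <- array(rgamma(4 * L * Q, shape = conc), dim = c(4, L, Q))
  sweep(arr, c(2, 3), apply(arr, c(2, 3), sum), "/")
}

tiny_state <- function(data, Q = 2, seed = 7) {
  set.seed(seed)
  t <- c(seq_len(Q), sample.int(Q, data$M - Q, replace = TRUE))
  model_state(xi = 0.2,
              C = matrix(rbinom(data$N * data$K, 1, 0.5), data$N, data$K),
              t = t,
              I = sample.int(data$K, Q, replace = TRUE),
              B = rand_profiles(data$L, Q),
              theta0 = 0.01,
              theta_i = runif(data$N, 0.3, 0.6),
              alpha0 = 1.3)
}
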