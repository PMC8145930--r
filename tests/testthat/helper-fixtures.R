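# small hand-constructed models reused across tests

tiny_theta <- function() {
  # D = 3, H = 2, well-separated means, modest variances
  M <- matrix(c(0.2, 0.3, 0.25,
                0.7, 0.4, 0.3,
                0.35, 0.8, 0.6), 3, 3)
  S2 <- matrix(0.01, 3, 3)
  beta_mca_from_meanvar(M, S2, c(1, 0.4, 0.3))
}

# brute-force log joint by direct formula evaluation (independent of
# the package's grid machinery)
brute_log_joint <- function(y, s, M, S2, pi) {
  ll <- 0
  for (d in seq_along(y)) {
    act <- which(s == 1)
    h <- act[which.max(M[d, act])]
    e <- meanvar_to_natural(M[d, h], S2[d, h])
    ll <- ll + stats::dbeta(y[d], e$eta1, e$eta2, log = TRUE)
  }
  pr <- sum(ifelse(s[-1] == 1, log(pi[-1]), log1p(-pi[-1])))
  ll + pr
}

# binary state row for an integer code (row order of all_states)
states_of <- function(code, H) all_states(H)[code + 1L, ]

state_prior_of <- function(s, pi) {
  sum(ifelse(s[-1] == 1, log(pi[-1]), log1p(-pi[-1])))
}

brute_posterior <- function(y, M, S2, pi) {
  H <- length(pi) - 1L
  S <- all_states(H)
  lj <- apply(S, 1, function(s) brute_log_joint(y, s, M, S2, pi))
  w <- exp(lj - max(lj))
  list(states = S, log_joint = lj, weights = w / sum(w))
}
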