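test_that("dominant cause selection follows the active-max rule", {
  M <- matrix(c(0.1, 0.9,
                0.5, 0.2), 2, 2, byrow = TRUE)
  expect_equal(dominant_causes(c(1, 0), M), c(0, 0))
  expect_equal(dominant_causes(c(1, 1), M), c(1, 0))
  # ties break to the lowest index
  M3 <- matrix(c(0.1, 0.9, 0.9), 1, 3)
  expect_equal(dominant_cause(1, c(1, 1, 1), M3), 1)
  # background guarantees a candidate even with all causes off
  expect_equal(dominant_causes(c(1, 0, 0), M3), 0)
})

test_that("combined mean-value and mean/variance maps copy the dominant column", {
  th <- tiny_theta()
  bg <- combined_meanvalue(c(1, 0, 0), th)
  expect_equal(bg$Wbar, th$W[, 1])
  expect_equal(bg$Vbar, th$V[, 1])
  # exhaustive check against a per-observable scan
  for (code in 0:3) {
    s <- c(1, bitwAnd(code, 1L), bitwAnd(code, 2L) > 0)
    cm <- combined_meanvalue(s, th)
    mv <- per_datapoint_meanvar(s, th)
    for (d in 1:3) {
      act <- which(s == 1)
      h <- act[which.max(th$M[d, act])]
      expect_equal(cm$Wbar[d], th$W[d, h])
      expect_equal(mv$mu_bar[d], th$M[d, h])
      expect_equal(mv$sigma2_bar[d], th$Sigma2[d, h])
    }
    # feasibility bound holds pointwise
    expect_true(all(mv$sigma2_bar < mv$mu_bar * (1 - mv$mu_bar)))
  }
  # composition consistency: meanvar equals the natural-parameter path
  s <- c(1, 1, 0)
  cm <- combined_meanvalue(s, th)
  eta <- meanvalue_to_natural(cm$Wbar, cm$Vbar)
  mv2 <- natural_to_meanvar(eta$eta1, eta$eta2)
  mv <- per_datapoint_meanvar(s, th)
  expect_equal(mv$mu_bar, mv2$mu, tolerance = 1e-9)
  expect_equal(mv$sigma2_bar, mv2$sigma2, tolerance = 1e-9)
})

test_that("latent and observation sampling match the model statistics", {
  th <- tiny_theta()
  set.seed(5)
  # prior sampling: background always on, empirical rates near pi
  S <- replicate(4000, sample_latents(th$pi))
  expect_true(all(S[1, ] == 1))
  rate <- rowMeans(S[-1, , drop = FALSE])
  se <- sqrt(th$pi[-1] * (1 - th$pi[-1]) / 4000)
  expect_true(all(abs(rate - th$pi[-1]) < 3.5 * se))
  # degenerate priors
  expect_equal(sample_latents(c(1, 0, 0)), c(1L, 0L, 0L))
  expect_equal(sample_latents(c(1, 1, 1)), c(1L, 1L, 1L))
  # observation moments at a fixed state
  s <- c(1, 1, 0)
  mv <- per_datapoint_meanvar(s, th)
  Yr <- t(replicate(20000, sample_observation(s, th)))
  expect_true(all(Yr > 0 & Yr < 1))
  mc_se <- sqrt(mv$sigma2_bar / 20000)
  expect_true(all(abs(colMeans(Yr) - mv$mu_bar) < 4 * mc_se))
  expect_true(all(abs(apply(Yr, 2, var) / mv$sigma2_bar - 1) < 0.15))
})

test_that("log joint matches brute force and handles degenerate priors", {
  th <- tiny_theta()
  y <- c(0.6, 0.7, 0.5)
  for (code in 0:3) {
    s <- all_states(2)[code + 1, ]
    expect_equal(log_joint(y, s, th),
                 brute_log_joint(y, s, th$M, th$Sigma2, th$pi),
                 tolerance = 1e-12)
  }
  # additivity: duplicating observables doubles the likelihood term
  M6 <- rbind(th$M, th$M)
  S6 <- rbind(th$Sigma2, th$Sigma2)
  th6 <- beta_mca_from_meanvar(M6, S6, th$pi)
  s <- c(1, 1, 1)
  lik3 <- log_joint(y, s, th) - state_prior_of(s, th$pi)
  lik6 <- log_joint(c(y, y), s, th6) - state_prior_of(s, th$pi)
  expect_equal(lik6, 2 * lik3, tolerance = 1e-9)
  # impossible state under a zero prior
  th0 <- beta_mca_from_meanvar(th$M, th$Sigma2, c(1, 0, 0.3))
  expect_equal(log_joint(y, c(1, 1, 0), th0), -Inf)
})

test_that("exact log-likelihood reduces to independent fits at H = 0 and sums states", {
  th <- tiny_theta()
  set.seed(9)
  Y <- matrix(runif(15, 0.1, 0.9), 5, 3)
  # brute-force state sum
  ll_bf <- sum(apply(Y, 1, function(y) {
    lj <- apply(all_states(2), 1, function(s)
      brute_log_joint(y, s, th$M, th$Sigma2, th$pi))
    max(lj) + log(sum(exp(lj - max(lj))))
  }))
  expect_equal(log_likelihood(Y, th), ll_bf, tolerance = 1e-9)
  # permutation of cause labels leaves the likelihood unchanged
  perm <- c(1, 3, 2)
  thp <- beta_mca_from_meanvar(th$M[, perm], th$Sigma2[, perm],
                               th$pi[perm])
  expect_equal(log_likelihood(Y, thp), log_likelihood(Y, th),
               tolerance = 1e-9)
  # H = 0: product of background Beta densities
  th_bg <- beta_mca_from_meanvar(th$M[, 1, drop = FALSE],
                                 th$Sigma2[, 1, drop = FALSE], 1)
  ll0 <- sum(beta_logpdf(Y, matrix(th_bg$eta1[, 1], 5, 3, byrow = TRUE),
                         matrix(th_bg$eta2[, 1], 5, 3, byrow = TRUE)))
  expect_equal(log_likelihood(Y, th_bg), ll0, tolerance = 1e-9)
  expect_error(all_states(20), "cap")
})

test_that("free energy is bounded by the likelihood and tight at the posterior", {
  th <- tiny_theta()
  set.seed(21)
  Y <- matrix(runif(9, 0.1, 0.9), 3, 3)
  post <- exact_posterior(Y, th)
  ll <- sum(post$loglik)
  expect_equal(free_energy(Y, post$weights, th), ll, tolerance = 1e-9)
  # point mass gives the bare log joint
  q1 <- matrix(0, 3, 4)
  q1[, 2] <- 1
  s2 <- all_states(2)[2, ]
  expect_equal(free_energy(Y, q1, th),
               sum(apply(Y, 1, log_joint, s = s2, theta = th)),
               tolerance = 1e-9)
  # random normalized q never exceeds the likelihood
  for (i in 1:20) {
    q <- matrix(rexp(12), 3, 4)
    q <- q / rowSums(q)
    expect_lte(free_energy(Y, q, th), ll + 1e-9)
  }
  expect_error(free_energy(Y, q1 * 2, th), "normalized")
})

test_that("model construction validates inputs and caches consistent derived fields", {
  th <- tiny_theta()
  rf <- refresh_derived(th)
  expect_equal(rf$M, th$M, tolerance = 1e-9)
  expect_equal(rf$Sigma2, th$Sigma2, tolerance = 1e-9)
  expect_error(beta_mca(matrix(1, 2, 2), matrix(-1, 2, 2), c(1, 0.5)),
               "negative")
  expect_error(beta_mca_from_meanvar(matrix(0.5, 2, 2),
                                     matrix(0.3, 2, 2), c(1, 0.5)),
               "infeasible")
  expect_error(clamp_unit_interval(c(-0.1, 0.5)), "\\[0,1\\]")
  expect_equal(clamp_unit_interval(c(0, 0.5, 1)),
               c(1e-10, 0.5, 1 - 1e-10))
})
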