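test_that("expected index set partitions unit mass per observable", {
  th <- tiny_theta()
  y <- c(0.6, 0.7, 0.5)
  # point mass on the background-only state
  q0 <- c(1, 0, 0, 0)
  A0 <- expected_index_set(y, q0, th)
  expect_equal(A0[, 1], rep(1, 3))
  expect_equal(sum(A0[, -1]), 0)
  # random q: rows always sum to one
  set.seed(4)
  for (i in 1:5) {
    q <- rexp(4)
    q <- q / sum(q)
    A <- expected_index_set(y, q, th)
    expect_equal(rowSums(A), rep(1, 3), tolerance = 1e-12)
  }
  # brute-force check against enumeration
  post <- brute_posterior(y, th$M, th$Sigma2, th$pi)
  A <- expected_index_set(y, post$weights, th)
  Abf <- matrix(0, 3, 3)
  for (si in 1:4) {
    s <- post$states[si, ]
    for (d in 1:3) {
      act <- which(s == 1)
      h <- act[which.max(th$M[d, act])]
      Abf[d, h] <- Abf[d, h] + post$weights[si]
    }
  }
  expect_equal(A, Abf, tolerance = 1e-12)
})

test_that("fixed-point updates average sufficient statistics correctly", {
  th <- tiny_theta()
  # single point, posterior point mass on the all-on state: columns of
  # the dominant causes receive the raw statistics
  y <- c(0.3, 0.6, 0.8)
  q <- matrix(c(0, 0, 0, 1), 1, 4)
  Wn <- mstep_W(rbind(y), q, th)
  Vn <- mstep_V(rbind(y), q, th)
  dom <- dominant_causes(c(1, 1, 1), th$M) + 1
  for (d in 1:3) {
    expect_equal(Wn[d, dom[d]], log(y[d]))
    expect_equal(Vn[d, dom[d]], log1p(-y[d]))
  }
  # untouched columns are held at their previous values
  expect_equal(Wn[1, 3], th$W[1, 3])
  # weighted two-point average
  Y2 <- rbind(c(0.3, 0.6, 0.8), c(0.5, 0.2, 0.4))
  q2 <- rbind(c(0, 0, 0, 1), c(0, 0, 0, 1))
  q2w <- q2 * c(1, 1)
  Wn2 <- mstep_W(Y2, q2w, th)
  for (d in 1:3) {
    expect_equal(Wn2[d, dom[d]], mean(log(Y2[, d])))
  }
  # outputs are strictly negative wherever updated
  expect_true(all(Wn < 0) && all(Vn < 0))
})

test_that("prior update averages posterior marginals with fixed background", {
  q <- rbind(c(1, 0, 0, 0), c(0, 0, 0, 1))
  pin <- mstep_pi(q)
  expect_equal(pin, c(1, 0.5, 0.5))
  # uniform posteriors give 0.5 per cause
  qu <- matrix(1 / 4, 3, 4)
  expect_equal(mstep_pi(qu), c(1, 0.5, 0.5))
  # marginals 0.2 and 0.4 average to 0.3
  qa <- rbind(c(0.8, 0.2, 0, 0), c(0.6, 0.4, 0, 0))
  expect_equal(mstep_pi(qa)[2], 0.3)
})

test_that("initialization schemes produce valid reproducible models", {
  set.seed(1)
  Y <- matrix(runif(60, 0.1, 0.9), 20, 3)
  set.seed(7)
  th1 <- init_beta_mca(Y, 2, "datapoints")
  set.seed(7)
  th2 <- init_beta_mca(Y, 2, "datapoints")
  expect_identical(th1$W, th2$W)
  expect_equal(th1$pi, c(1, 0.3, 0.3))
  expect_true(all(th1$W < 0) && all(th1$V < 0))
  # identical rows give identical columns
  Yc <- matrix(rep(Y[1, ], each = 10), 10, 3)
  set.seed(3)
  thc <- init_beta_mca(Yc, 2, "datapoints")
  expect_equal(thc$W[, 1], thc$W[, 2])
  set.seed(5)
  th3 <- init_beta_mca(Y, 2, "data_mean_noise")
  expect_true(all(th3$Sigma2 < th3$M * (1 - th3$M)))
  expect_error(init_beta_mca(Y[1:2, ], 2, "datapoints"), "at least")
})

test_that("EM recovers structure and is stationary at a converged fit", {
  set.seed(31)
  M <- cbind(c(0.15, 0.2, 0.15, 0.2),
             c(0.8, 0.75, 0.2, 0.15),
             c(0.2, 0.15, 0.8, 0.85))
  S2 <- matrix(0.008, 4, 3)
  th0 <- beta_mca_from_meanvar(M, S2, c(1, 0.35, 0.35))
  set.seed(31)
  dat <- sample_beta_mca(th0, 600)
  fit <- em_fit_restarts(dat$Y, 2, em_config(n_iterations = 100, seed = 2),
                         n_restarts = 4)
  # fit quality: final free energy near the ground-truth likelihood
  ll_true <- log_likelihood(clamp_unit_interval(dat$Y), th0)
  expect_gt(fit$free_energy[100], ll_true - 5e-3 * 600)
  # learned means match ground truth after column matching
  perm_err <- function(perm) {
    mean(abs(fit$theta$M[, perm] - M))
  }
  errs <- c(perm_err(c(1, 2, 3)), perm_err(c(1, 3, 2)))
  expect_lt(min(errs), 0.05)
  # equilibrium: another fixed-point application barely moves W and V
  Yc <- clamp_unit_interval(dat$Y)
  post <- exact_posterior(Yc, fit$theta)
  Wn <- mstep_W(Yc, post$weights, fit$theta)
  expect_lt(max(abs(Wn - fit$theta$W)), 1e-6)
  # one EM iteration from the generating parameters does not collapse
  ll_path <- numeric(2)
  th <- th0
  for (i in 1:2) {
    p <- exact_posterior(Yc, th)
    ll_path[i] <- sum(p$loglik)
    th <- beta_mca(mstep_W(Yc, p$weights, th),
                   mstep_V(Yc, p$weights, th), mstep_pi(p$weights))
  }
  expect_gt(ll_path[2], ll_path[1] - abs(ll_path[1]) * 0.01)
})

test_that("truncated E-step with full subsets reproduces the exact trace", {
  set.seed(17)
  M <- matrix(runif(4 * 6, 0.2, 0.8), 4, 6)
  th0 <- beta_mca_from_meanvar(M, matrix(0.01, 4, 6),
                               c(1, rep(0.3, 5)))
  dat <- sample_beta_mca(th0, 80)
  cfg_e <- em_config(n_iterations = 8, seed = 3)
  cfg_t <- em_config(n_iterations = 8, e_step_mode = "truncated",
                     truncation_size = 2^5, seed = 3)
  fe <- em_fit(dat$Y, 5, cfg_e)
  ft <- em_fit(dat$Y, 5, cfg_t)
  expect_equal(ft$free_energy, fe$free_energy, tolerance = 1e-8)
  expect_equal(ft$theta$W, fe$theta$W, tolerance = 1e-8)
})

test_that("fits are seed-deterministic and label-permutation invariant", {
  set.seed(23)
  M <- cbind(c(0.2, 0.2, 0.2), c(0.8, 0.7, 0.2), c(0.2, 0.6, 0.85))
  th0 <- beta_mca_from_meanvar(M, matrix(0.01, 3, 3), c(1, 0.4, 0.3))
  dat <- sample_beta_mca(th0, 300)
  cfg <- em_config(n_iterations = 25, seed = 9)
  f1 <- em_fit(dat$Y, 2, cfg)
  f2 <- em_fit(dat$Y, 2, cfg)
  expect_identical(f1$free_energy, f2$free_energy)
  expect_identical(f1$theta$W, f2$theta$W)
  # relabeling the causes of the fitted model leaves the data
  # likelihood unchanged
  perm <- c(1, 3, 2)
  thp <- beta_mca(f1$theta$W[, perm], f1$theta$V[, perm],
                  f1$theta$pi[perm])
  Yc <- clamp_unit_interval(dat$Y)
  expect_equal(log_likelihood(Yc, thp), log_likelihood(Yc, f1$theta),
               tolerance = 1e-9)
})

test_that("scalar-variance EM recovers a shared variance and stays nested", {
  set.seed(41)
  M <- cbind(c(0.2, 0.25, 0.2, 0.25, 0.2),
             c(0.75, 0.7, 0.25, 0.2, 0.25),
             c(0.2, 0.25, 0.75, 0.7, 0.7))
  s2_true <- 0.012
  th0 <- beta_mca_from_meanvar(M, matrix(s2_true, 5, 3),
                               c(1, 0.35, 0.3))
  dat <- sample_beta_mca(th0, 1000)
  cfg <- em_config(n_iterations = 30, seed = 6,
                   init_scheme = "data_mean_noise")
  fit <- em_fit_scalar_variance(dat$Y, 2, cfg)
  expect_length(fit$free_energy, 30)
  expect_lt(abs(fit$theta$sigma2 / s2_true - 1), 0.2)
  # on data with heterogeneous variances the double dictionary fits at
  # least as well as the scalar model
  set.seed(42)
  Sg2 <- matrix(runif(15, 0.005, 0.05), 5, 3)
  Sg2 <- pmin(Sg2, 0.8 * M * (1 - M))
  thh <- beta_mca_from_meanvar(M, Sg2, c(1, 0.35, 0.3))
  dath <- sample_beta_mca(thh, 800)
  cmp <- compare_dictionaries(dath$Y, 2,
                              em_config(n_iterations = 25, seed = 4,
                                        init_scheme = "data_mean_noise"))
  expect_gte(cmp$double$free_energy[25], cmp$scalar$free_energy[25])
})

test_that("checkpointing writes resumable model and trace files", {
  set.seed(3)
  dat <- sample_beta_mca(tiny_theta(), 60)
  dir <- tempfile()
  fit <- em_fit(dat$Y, 2,
                em_config(n_iterations = 6, seed = 1,
                          checkpoint_dir = dir, checkpoint_every = 3L))
  expect_true(file.exists(file.path(dir, "model_iter0003.json")))
  expect_true(file.exists(file.path(dir, "model_iter0006.json")))
  final <- read_model(file.path(dir, "model_iter0006.json"))
  expect_identical(final$W, fit$theta$W)
  trace <- read.csv(file.path(dir, "trace.csv"))
  expect_equal(trace$free_energy, fit$free_energy[1:6])
})

test_that("restart selection returns the best final free energy", {
  set.seed(3)
  dat <- sample_beta_mca(tiny_theta(), 120)
  best <- em_fit_restarts(dat$Y, 2,
                          em_config(n_iterations = 10, seed = 1),
                          n_restarts = 3)
  expect_equal(best$free_energy[10], max(best$all_final_F))
})
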