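test_that("bars fixture matches its printed ground truth", {
  fx <- make_bars_fixture(N = 400, seed = 5)
  expect_true(all(fx$Y > 0 & fx$Y < 1))
  expect_equal(dim(fx$M_true), c(25, 11))
  # each bar occupies exactly five pixels at mean 0.9
  for (h in 1:10) {
    expect_length(fx$bar_pixels[[h]], 5)
    expect_equal(unname(fx$M_true[fx$bar_pixels[[h]], h + 1]),
                 rep(0.9, 5))
  }
  # causes 1 and 5 share means but not variances
  expect_equal(fx$M_true[, 2], fx$M_true[, 6])
  expect_false(isTRUE(all.equal(fx$Sigma_true[, 2], fx$Sigma_true[, 6])))
  # background checkerboard values
  expect_setequal(unique(fx$M_true[, 1]), c(0.08, 0.22))
  expect_setequal(unique(fx$Sigma_true[, 1]), c(0.01, 0.05))
  # per-bar prior 0.2 and on-average two active bars
  expect_equal(fx$pi_true[-1], rep(0.2, 10))
  n_active <- rowSums(fx$S[, -1])
  se <- sqrt(10 * 0.2 * 0.8 / 400)
  expect_lt(abs(mean(n_active) - 2), 3 * se)
  # background-only points reproduce the checkerboard mean
  bg <- n_active == 0
  expect_gt(sum(bg), 20)
  err <- colMeans(fx$Y[bg, , drop = FALSE]) - fx$M_true[, 1]
  expect_lt(max(abs(err)), 4 * max(fx$Sigma_true[, 1]) / sqrt(sum(bg)))
  # reproducibility is bit-exact
  fx2 <- make_bars_fixture(N = 400, seed = 5)
  expect_identical(fx$Y, fx2$Y)
})

test_that("bar recovery scoring is permutation-invariant and strict", {
  fx <- make_bars_fixture(N = 10, seed = 1)
  expect_equal(score_bar_recovery(fx$M_true, fx)$n_recovered, 10)
  perm <- c(1, sample(2:11))
  expect_equal(score_bar_recovery(fx$M_true[, perm], fx)$n_recovered, 10)
  # monotone rescaling does not change the score
  expect_equal(score_bar_recovery(fx$M_true * 0.5, fx)$n_recovered, 10)
  # all-background dictionary recovers nothing
  flat <- matrix(fx$M_true[, 1], 25, 11)
  expect_equal(score_bar_recovery(flat, fx)$n_recovered, 0)
})

test_that("disease fixture reproduces its generating profile", {
  prof <- default_disease_profile()
  expect_true(all(prof$sd^2 < prof$mu * (1 - prof$mu)))
  fx <- make_disease_fixture(prof, N = 2000, seed = 3)
  expect_equal(dim(fx$Y), c(2000, 9))
  # label marginals match the priors
  rate <- colMeans(fx$labels)
  se <- sqrt(prof$pi[-1] * (1 - prof$pi[-1]) / 2000)
  expect_true(all(abs(rate - prof$pi[-1]) < 3.5 * se))
  # healthy-only patients have background symptom statistics
  healthy <- rowSums(fx$labels) == 0
  err <- colMeans(fx$Y[healthy, ]) - prof$mu[, 1]
  expect_lt(max(abs(err)), 4 * max(prof$sd[, 1]) / sqrt(sum(healthy)))
  # empty fixture
  fx0 <- make_disease_fixture(prof, N = 0)
  expect_equal(nrow(fx0$Y), 0)
  # infeasible profile rejected
  bad <- prof
  bad$sd[1, 1] <- 0.9
  expect_error(make_disease_fixture(bad), "infeasible")
})

test_that("patch utilities tile and reassemble losslessly", {
  img <- matrix(runif(144), 12, 12)
  pt <- extract_patches(img, 4, stride = 2)
  expect_equal(ncol(pt$P), 16)
  # averaging the original patches reproduces the image exactly
  back <- reassemble_patches(pt$P, pt)
  expect_equal(back, img, tolerance = 1e-12)
  m <- psnr_mse(img, img)
  expect_equal(m$mse, 0)
  expect_equal(m$psnr, 100)  # capped sentinel for identical images
})

test_that("beta noise is mean-preserving up to the feasibility cap", {
  set.seed(10)
  img <- matrix(rep(c(0.3, 0.5, 0.7), each = 4000), 120, 100)
  noisy <- beta_noise(img, sd = 0.1)
  for (v in c(0.3, 0.5, 0.7)) {
    sel <- img == v
    expect_lt(abs(mean(noisy[sel]) - v), 0.01)
    expect_lt(abs(sd(noisy[sel]) - 0.1), 0.01)
  }
  # near the boundary the cap binds
  img2 <- matrix(0.98, 50, 50)
  noisy2 <- beta_noise(img2, sd = 0.3)
  expect_lt(sd(noisy2), 0.95 * sqrt(0.98 * 0.02) * 1.2)
})

test_that("posterior-mean estimator reduces to the dominant mean at a point mass", {
  th <- tiny_theta()
  # sharpen the posterior by evaluating at a state's own mean profile
  s <- c(1, 1, 0)
  mv <- per_datapoint_meanvar(s, th)
  post <- exact_posterior(mv$mu_bar, th)
  est <- betamca:::posterior_mean_estimate(rbind(mv$mu_bar), th)
  # estimator is the posterior-weighted mixture of dominant means
  Dall <- post$states
  manual <- rep(0, 3)
  for (si in seq_len(nrow(Dall))) {
    manual <- manual +
      post$weights[1, si] *
      per_datapoint_meanvar(Dall[si, ], th)$mu_bar
  }
  expect_equal(drop(est), manual, tolerance = 1e-10)
})

test_that("structured-image denoising pipeline runs end to end", {
  img <- make_structured_image(32)
  res <- denoise_image(
    img, patch_size = 5, H = 10,
    config = em_config(e_step_mode = "truncated", truncation_size = 20L,
                       n_iterations = 15L,
                       variance_freeze_fraction = 0.3, seed = 2),
    noise_sd = 0.3, stride = 2)
  expect_equal(dim(res$denoised), dim(img))
  expect_true(all(res$denoised > 0 & res$denoised < 1))
  expect_gt(res$psnr_denoised, res$psnr_noisy)
  # zero-noise path returns metrics against the clean image itself
  res0 <- denoise_image(
    img, patch_size = 5, H = 4,
    config = em_config(n_iterations = 3L,
                       init_scheme = "data_mean_noise", seed = 2),
    noise_sd = NULL, stride = 4)
  expect_equal(res0$mse_noisy, 0)
  expect_error(denoise_image(array(0, c(2, 2, 2))), "grayscale")
})

test_that("patch fixture generation is seeded and feasible", {
  fx <- make_patch_fixture(N = 50, side = 4, H = 6, seed = 9)
  expect_equal(dim(fx$Y), c(50, 16))
  expect_true(all(fx$Y > 0 & fx$Y < 1))
  fx2 <- make_patch_fixture(N = 50, side = 4, H = 6, seed = 9)
  expect_identical(fx$Y, fx2$Y)
})
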