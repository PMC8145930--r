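#' EM configuration
#'
#' Collects the tunable parameters of [em_fit()] and
#' [em_fit_scalar_variance()].
#'
#' @param n_iterations number of EM iterations (each M-step update is
#'   applied exactly once per iteration).
#' @param e_step_mode `"exact"` (full enumeration) or `"truncated"`
#'   (evolutionary search over per-point state subsets).
#' @param truncation_size subset size `|K|` per data point in truncated
#'   mode.
#' @param n_generations evolutionary generations per E-step.
#' @param n_children children per generation (default
#'   `2 * truncation_size`).
#' @param bitflip2_prob probability of a second bit flip per child.
#' @param variance_freeze_fraction fraction of initial iterations during
#'   which variances are held at their initial values and only the
#'   means and priors are updated.
#' @param init_scheme `"datapoints"` (dictionary columns from randomly
#'   chosen data points) or `"data_mean_noise"` (data mean plus Gaussian
#'   noise for the means; priors and standard deviations uniform on
#'   (0,1), infeasible variances redrawn).
#' @param seed integer seed governing initialization, any sampling and
#'   the evolutionary search.
#' @param convergence_tol optional early stop on the relative
#'   free-energy change (`NULL` runs all iterations, matching the
#'   fixed-iteration protocol used in the experiments).
#' @param checkpoint_dir optional directory receiving periodic
#'   checkpoints (model container, free-energy trace CSV and, in
#'   truncated mode, the per-point state subsets).
#' @param checkpoint_every iterations between checkpoints.
#' @param enum_cap maximum `H` for exact enumeration.
#' @param init_noise_sd Gaussian noise for the `data_mean_noise` scheme.
#' @param init_offset shift applied to the log data values in the
#'   `datapoints` scheme; raw `log(y)`/`log(1-y)` pairs sit on the
#'   degenerate (zero-variance) boundary of the mean-value domain, and
#'   the offset corresponds to a finite concentration around the chosen
#'   data point.
#' @param eps clamping margin for data in \[0,1\].
#' @return list of class `em_config`.
#' @export
em_config <- function(n_iterations = 50L,
                      e_step_mode = c("exact", "truncated"),
                      truncation_size = 60L,
                      n_generations = 1L,
                      n_children = NULL,
                      bitflip2_prob = 0.2,
                      variance_freeze_fraction = 0,
                      init_scheme = c("datapoints", "data_mean_noise"),
                      seed = 1L,
                      convergence_tol = NULL,
                      enum_cap = 15L,
                      init_noise_sd = 0.02,
                      init_offset = 0.05,
                      eps = 1e-10,
                      checkpoint_dir = NULL,
                      checkpoint_every = 10L) {
  e_step_mode <- match.arg(e_step_mode)
  init_scheme <- match.arg(init_scheme)
  if (n_iterations < 1) stop("n_iterations must be >= 1", call. = FALSE)
  if (e_step_mode == "truncated" && truncation_size < 1) {
    stop("truncation_size must be >= 1", call. = FALSE)
  }
  if (variance_freeze_fraction < 0 || variance_freeze_fraction >= 1) {
    stop("variance_freeze_fraction must lie in [0,1)", call. = FALSE)
  }
  structure(list(
    n_iterations = as.integer(n_iterations),
    e_step_mode = e_step_mode,
    truncation_size = as.integer(truncation_size),
    n_generations = as.integer(n_generations),
    n_children = n_children,
    bitflip2_prob = bitflip2_prob,
    variance_freeze_fraction = variance_freeze_fraction,
    init_scheme = init_scheme,
    seed = as.integer(seed),
    convergence_tol = convergence_tol,
    enum_cap = as.integer(enum_cap),
    init_noise_sd = init_noise_sd,
    init_offset = init_offset,
    eps = eps,
    checkpoint_dir = checkpoint_dir,
    checkpoint_every = as.integer(checkpoint_every)),
    class = "em_config")
}

#' Expected dominance index set
#'
#' Posterior expectation of the indicator that cause `h` dominates
#' observable `d`: entry `(d, h)` is
#' `sum_s q(s) 1{h = h(d, s, theta)}`.  Each state assigns exactly one
#' dominant cause per observable, so rows sum to 1.
#'
#' @param y data vector in (0,1) (unused beyond dimension checks; the
#'   index set depends on the state and parameters only).
#' @param q normalized posterior weights over all `2^H` states (in
#'   [all_states()] row order).
#' @param theta a [beta_mca()] model.
#' @return `D x (H+1)` matrix with rows summing to 1.
#' @export
expected_index_set <- function(y, q, theta) {
  q <- as.numeric(q)
  if (abs(sum(q) - 1) > 1e-8) {
    stop("q must be normalized", call. = FALSE)
  }
  S <- all_states(theta$H)
  Dom <- dominant_idx_cpp(theta$M, S)  # U x D
  A <- matrix(0, theta$D, theta$H + 1L)
  for (h in 0:theta$H) {
    A[, h + 1L] <- colSums((Dom == h) * q)
  }
  A
}

# responsibility-weighted sums over an enumerated state grid
mstep_sums_exact <- function(LY, L1Y, Q, Dom, Hp1) {
  C1 <- crossprod(Q, LY)   # U x D
  C2 <- crossprod(Q, L1Y)
  R <- colSums(Q)
  D <- ncol(LY)
  Wnum <- matrix(0, D, Hp1)
  Vnum <- matrix(0, D, Hp1)
  den <- matrix(0, D, Hp1)
  for (h in seq_len(Hp1) - 1L) {
    mask <- Dom == h
    Wnum[, h + 1L] <- colSums(mask * C1)
    Vnum[, h + 1L] <- colSums(mask * C2)
    den[, h + 1L] <- colSums(mask * R)
  }
  list(Wnum = Wnum, Vnum = Vnum, den = den)
}

apply_hold <- function(num, den, old, tol = 1e-12) {
  out <- num / den
  hold <- den <= tol
  out[hold] <- old[hold]
  out
}

#' Fixed-point M-step updates
#'
#' `mstep_W()` and `mstep_V()` implement the responsibility-weighted
#' fixed-point updates of the mean-value dictionaries:
#' `W_dh = sum_n <A_dh>_{q_n} log y_dn / sum_n <A_dh>_{q_n}` (and with
#' `log(1-y)` for `V`).  Columns with zero total responsibility are
#' held at their previous values, the unique continuous choice where
#' the update is undefined.  `mstep_pi()` sets each prior to the mean
#' posterior activation marginal; the background prior stays 1.
#'
#' @param Y `N x D` data matrix in (0,1).
#' @param q_all `N x 2^H` matrix of normalized posterior weights (in
#'   [all_states()] row order).
#' @param theta_old model under which the posteriors were computed.
#' @return updated `W` (resp. `V`) matrix; `mstep_pi()` returns the
#'   updated prior vector.
#' @export
mstep_W <- function(Y, q_all, theta_old) {
  Y <- rbind(Y)
  S <- all_states(theta_old$H)
  Dom <- dominant_idx_cpp(theta_old$M, S)
  sums <- mstep_sums_exact(log(Y), log1p(-Y), rbind(q_all), Dom,
                           theta_old$H + 1L)
  apply_hold(sums$Wnum, sums$den, theta_old$W)
}

#' @rdname mstep_W
#' @export
mstep_V <- function(Y, q_all, theta_old) {
  Y <- rbind(Y)
  S <- all_states(theta_old$H)
  Dom <- dominant_idx_cpp(theta_old$M, S)
  sums <- mstep_sums_exact(log(Y), log1p(-Y), rbind(q_all), Dom,
                           theta_old$H + 1L)
  apply_hold(sums$Vnum, sums$den, theta_old$V)
}

#' @rdname mstep_W
#' @param states optional state matrix matching the columns of `q_all`
#'   (default: all states).
#' @export
mstep_pi <- function(q_all, states = NULL) {
  q_all <- rbind(q_all)
  if (is.null(states)) {
    H <- as.integer(round(log2(ncol(q_all))))
    states <- all_states(H)
  }
  marg <- colMeans(q_all %*% states)
  marg[1] <- 1
  pmin(pmax(marg, 0), 1)
}

#' Initialize a Beta-MCA model from data
#'
#' Two schemes:
#' * `"datapoints"`: `H + 1` data points are drawn uniformly; the `W`
#'   and `V` columns are their `log(y)` and `log(1-y)` values (shifted
#'   inward by `init_offset`, see [em_config()]), and all priors start
#'   at 0.3.
#' * `"data_mean_noise"`: mean columns are the data mean plus Gaussian
#'   noise; priors and standard deviations are drawn uniformly from
#'   (0,1), redrawing any infeasible variance.
#'
#' @param Y `N x D` data matrix in (0,1).
#' @param H number of non-background causes.
#' @param scheme initialization scheme.
#' @param init_offset see [em_config()].
#' @param init_noise_sd Gaussian noise of the `data_mean_noise` scheme.
#' @return a [beta_mca()] model.
#' @export
init_beta_mca <- function(Y, H,
                          scheme = c("datapoints", "data_mean_noise"),
                          init_offset = 0.05, init_noise_sd = 0.02) {
  scheme <- match.arg(scheme)
  init_family(Y, H, scheme, family = "double",
              init_offset = init_offset, init_noise_sd = init_noise_sd)
}

# shared initializer; the mean-related draws come first so that the
# scalar and double families get identical initial means under the same
# seed (the variance draws differ in number between families)
init_family <- function(Y, H, scheme, family,
                        init_offset = 0.05, init_noise_sd = 0.02) {
  Y <- rbind(Y)
  N <- nrow(Y)
  D <- ncol(Y)
  Hp1 <- H + 1L
  if (scheme == "datapoints") {
    if (N < Hp1) {
      stop("datapoints initialization needs at least H + 1 data points",
           call. = FALSE)
    }
    idx <- sample.int(N, Hp1)
    pts <- Y[idx, , drop = FALSE]
    pi <- c(1, rep(0.3, H))
    if (family == "double") {
      W <- t(log(pts)) - init_offset
      V <- t(log1p(-pts)) - init_offset
      return(beta_mca(W, V, pi))
    }
    M <- t(pts)
    M <- pmin(pmax(M, 0.02), 0.98)
    bound <- min(M * (1 - M))
    sigma2 <- stats::runif(1, 0.2, 0.8)^2
    sigma2 <- min(sigma2, 0.9 * bound)
    return(beta_mca_scalar(M, sigma2, pi))
  }
  # data_mean_noise
  mu <- matrix(colMeans(Y), D, Hp1) +
    matrix(stats::rnorm(D * Hp1, 0, init_noise_sd), D, Hp1)
  mu <- pmin(pmax(mu, 0.02), 0.98)
  pi <- c(1, stats::runif(H))
  if (family == "double") {
    sd0 <- matrix(stats::runif(D * Hp1), D, Hp1)
    bad <- sd0^2 >= mu * (1 - mu)
    while (any(bad)) {
      sd0[bad] <- stats::runif(sum(bad))
      bad <- sd0^2 >= mu * (1 - mu)
    }
    return(beta_mca_from_meanvar(mu, sd0^2, pi))
  }
  bound <- min(mu * (1 - mu))
  s <- stats::runif(1)
  while (s^2 >= bound) s <- stats::runif(1)
  beta_mca_scalar(mu, s^2, pi)
}

#' Fit a Beta-MCA model by expectation maximization
#'
#' Alternates E-steps (exact posterior enumeration, or truncated
#' posteriors over per-point state subsets maintained by evolutionary
#' search) with the fixed-point M-step updates of `W`, `V` and `pi`,
#' each applied once per iteration.  The free energy recorded at each
#' iteration is evaluated at the current parameters with the current
#' variational distribution (for the exact E-step it equals the
#' log-likelihood).  During the first `variance_freeze_fraction` of the
#' iterations the variance dictionary is held at its initial values:
#' the updated means are recombined with the initial variances (capped
#' at the Beta feasibility bound) and only the means and priors move.
#'
#' @param Y `N x D` data matrix in \[0,1\] (boundary values are clamped
#'   inward).
#' @param H number of non-background causes.
#' @param config an [em_config()].
#' @return object of class `em_trace`: list with `theta` (final model),
#'   `free_energy` (per-iteration trace), `config`, and in truncated
#'   mode `Kcodes` (final per-point state subsets).
#' @export
em_fit <- function(Y, H, config = em_config()) {
  em_engine(Y, H, config, family = "double")
}

#' Fit the scalar-variance Beta-MCA variant
#'
#' Model variant with one mean dictionary `M` (background included) and
#' a single shared variance `sigma2`.  The E-step is identical in
#' structure to [em_fit()]; the M-step maximizes the same expected
#' complete-data log-likelihood by coordinate-wise numeric ascent over
#' the `M` entries and `sigma2`, with `sigma2` kept below the Beta
#' feasibility bound `min M(1-M)`.
#'
#' @inheritParams em_fit
#' @return an `em_trace` whose `theta` has class `beta_mca_scalar`.
#' @export
em_fit_scalar_variance <- function(Y, H, config = em_config()) {
  em_engine(Y, H, config, family = "scalar")
}

em_engine <- function(Y, H, config, family) {
  stopifnot(inherits(config, "em_config"))
  Y <- clamp_unit_interval(rbind(Y), config$eps)
  N <- nrow(Y)
  LY <- log(Y)
  L1Y <- log1p(-Y)
  set.seed(config$seed)
  theta <- init_family(Y, H, config$init_scheme, family,
                       config$init_offset, config$init_noise_sd)
  Sigma2_init <- if (family == "double") theta$Sigma2 else theta$sigma2
  n_freeze <- floor(config$variance_freeze_fraction * config$n_iterations)
  exact <- config$e_step_mode == "exact"
  if (exact) {
    states <- all_states(H, config$enum_cap)
  } else {
    Kcodes <- init_subsets(Y, theta, config$truncation_size)
  }
  Fe <- numeric(0)
  for (it in seq_len(config$n_iterations)) {
    if (exact) {
      lj <- loglik_grid(LY, L1Y, theta, states)
      lse <- apply_logsumexp(lj)
      Q <- exp(lj - lse)
      Fe[it] <- sum(lse)
      Dom <- dominant_idx_cpp(theta$M, states)
      sums <- mstep_sums_exact(LY, L1Y, Q, Dom, H + 1L)
      marg <- colMeans(Q %*% states)
    } else {
      ee <- eem_step_batch(LY, L1Y, theta, Kcodes, config$n_generations,
                           config$n_children, config$bitflip2_prob)
      Kcodes <- ee$Kcodes
      nIdx <- rep(seq_len(N), times = ncol(Kcodes))
      codes <- as.vector(Kcodes)
      ljv <- as.vector(ee$lj)
      sm <- group_softmax_cpp(ljv, nIdx, N)
      Fe[it] <- sum(sm$logsumexp)
      q <- sm$weights
      ucodes <- sort(unique(codes))
      uIdx <- match(codes, ucodes)
      tab <- state_tables(theta, ucodes)
      sums <- mstep_sums_cpp(LY, L1Y, tab$Dom, nIdx, uIdx, q, H + 1L)
      qu <- as.vector(rowsum(q, uIdx))
      marg <- colSums(tab$states * qu) / N
    }
    pinew <- pmin(pmax(marg, 0), 1)
    pinew[1] <- 1
    frozen <- it <= n_freeze
    theta <- mstep_family(theta, sums, pinew, family, frozen, Sigma2_init)
    if (!is.null(config$checkpoint_dir) &&
        it %% config$checkpoint_every == 0L) {
      write_checkpoint(config$checkpoint_dir, it, theta, Fe,
                       if (exact) NULL else Kcodes, config$seed)
    }
    if (!is.null(config$convergence_tol) && it >= 2) {
      rel <- abs(Fe[it] - Fe[it - 1]) /
        max(1, abs(Fe[it - 1]))
      if (rel < config$convergence_tol) break
    }
  }
  out <- list(theta = theta, free_energy = Fe, config = config,
              H = H, family = family)
  if (!exact) out$Kcodes <- Kcodes
  structure(out, class = "em_trace")
}

write_checkpoint <- function(dir, it, theta, Fe, Kcodes, seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_model(theta, file.path(dir, sprintf("model_iter%04d.json", it)),
              seed = seed)
  utils::write.csv(
    data.frame(iteration = seq_along(Fe), free_energy = Fe),
    file.path(dir, "trace.csv"), row.names = FALSE)
  if (!is.null(Kcodes)) {
    utils::write.csv(as.data.frame(Kcodes),
                     file.path(dir, sprintf("subsets_iter%04d.csv", it)),
                     row.names = FALSE)
  }
  invisible(NULL)
}

mstep_family <- function(theta, sums, pinew, family, frozen,
                         Sigma2_init) {
  if (family == "double") {
    Wnew <- apply_hold(sums$Wnum, sums$den, theta$W)
    Vnew <- apply_hold(sums$Vnum, sums$den, theta$V)
    if (!frozen) {
      return(beta_mca(Wnew, Vnew, pinew))
    }
    # partial freeze: keep the updated means, restore initial variances
    eta <- meanvalue_to_natural(Wnew, Vnew)
    Mnew <- matrix(eta$eta1 / (eta$eta1 + eta$eta2), theta$D)
    sig2 <- pmin(Sigma2_init, 0.95 * Mnew * (1 - Mnew))
    return(beta_mca_from_meanvar(Mnew, sig2, pinew))
  }
  # scalar family: coordinate-wise numeric ascent
  scalar_mstep(theta, sums, pinew, frozen, Sigma2_init)
}

#' @export
print.em_trace <- function(x, ...) {
  cat(sprintf(
    "Beta-MCA EM fit (%s, %s E-step): %d iterations, final F = %.4f\n",
    x$family, x$config$e_step_mode, length(x$free_energy),
    x$free_energy[length(x$free_energy)]))
  invisible(x)
}

#' Fit with multiple restarts
#'
#' Runs [em_fit()] (or the scalar variant) from `n_restarts` seeds and
#' returns the run with the highest final free energy, the standard
#' guard against local optima for maximal-causes models.
#'
#' @inheritParams em_fit
#' @param n_restarts number of independent runs; run `r` uses seed
#'   `config$seed + r - 1`.
#' @param family `"double"` or `"scalar"`.
#' @return the best `em_trace`, with an extra field `all_final_F`.
#' @export
em_fit_restarts <- function(Y, H, config = em_config(), n_restarts = 3L,
                            family = c("double", "scalar")) {
  family <- match.arg(family)
  best <- NULL
  finals <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    tr <- em_engine(Y, H, cfg, family)
    finals[r] <- tr$free_energy[length(tr$free_energy)]
    if (is.null(best) ||
        finals[r] > best$free_energy[length(best$free_energy)]) {
      best <- tr
    }
  }
  best$all_final_F <- finals
  best
}
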