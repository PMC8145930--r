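#' Construct a Beta-MCA model
#'
#' A Beta-MCA model has `H` binary latent causes plus an always-active
#' background cause (index 0).  Each cause carries one column of two
#' mean-value dictionaries `W` and `V` (the expectations of `log y` and
#' `log(1-y)` under that cause's Beta distribution, one row per
#' observable).  For a latent state `s`, the observation distribution of
#' observable `d` is the Beta distribution of the *dominant* cause: the
#' active cause with the largest entry in the derived mean dictionary
#' `M`.  The dominant cause therefore sets both the mean and the
#' variance of the observable.
#'
#' The derived quantities `M` (means), `Sigma2` (variances) and the
#' natural-parameter dictionaries are computed from `W`, `V` through the
#' digamma-system solve and cached on the object; [refresh_derived()]
#' recomputes them after any change to `W` or `V`.
#'
#' @param W,V `D x (H+1)` matrices of strictly negative mean-value
#'   parameters; column 1 is the background cause.
#' @param pi prior activation probabilities, length `H+1`; the background
#'   entry is forced to 1.
#' @param eta1,eta2 optional precomputed natural-parameter dictionaries
#'   consistent with `W`, `V` (skips the numeric solve).
#' @return an object of class `beta_mca`.
#' @seealso [beta_mca_from_meanvar()], [em_fit()], [sample_beta_mca()]
#' @export
beta_mca <- function(W, V, pi, eta1 = NULL, eta2 = NULL) {
  W <- as.matrix(W)
  V <- as.matrix(V)
  if (!identical(dim(W), dim(V))) {
    stop("W and V must have identical dimensions", call. = FALSE)
  }
  if (any(!is.finite(W)) || any(!is.finite(V)) ||
      any(W >= 0) || any(V >= 0)) {
    stop("W and V entries must be finite and strictly negative",
         call. = FALSE)
  }
  if (length(pi) != ncol(W) || any(pi < 0) || any(pi > 1)) {
    stop("pi must have length ncol(W) with entries in [0,1]",
         call. = FALSE)
  }
  pi <- as.numeric(pi)
  pi[1] <- 1  # background always active
  theta <- structure(
    list(W = W, V = V, pi = pi, D = nrow(W), H = ncol(W) - 1L),
    class = "beta_mca")
  if (is.null(eta1) || is.null(eta2)) {
    refresh_derived(theta)
  } else {
    finish_derived(theta, matrix(eta1, nrow(W)), matrix(eta2, nrow(W)))
  }
}

finish_derived <- function(theta, eta1, eta2) {
  mv <- natural_to_meanvar(eta1, eta2)
  theta$eta1 <- eta1
  theta$eta2 <- eta2
  theta$M <- matrix(mv$mu, theta$D)
  theta$Sigma2 <- matrix(mv$sigma2, theta$D)
  theta$logB <- matrix(lbeta(eta1, eta2), theta$D)
  theta
}

#' Recompute the derived dictionaries of a model
#'
#' Solves the digamma system elementwise for the natural-parameter
#' dictionaries and refreshes the cached mean (`M`) and variance
#' (`Sigma2`) dictionaries.  Idempotent.
#'
#' @param theta a [beta_mca()] model.
#' @return the model with consistent derived fields.
#' @export
refresh_derived <- function(theta) {
  eta <- tryCatch(
    meanvalue_to_natural(theta$W, theta$V),
    error = function(e) {
      stop("derived-dictionary refresh failed: ", conditionMessage(e),
           call. = FALSE)
    })
  finish_derived(theta,
                 matrix(eta$eta1, theta$D), matrix(eta$eta2, theta$D))
}

#' Construct a Beta-MCA model from mean/variance dictionaries
#'
#' Convenience constructor using the closed-form map from `(mu, sigma2)`
#' to natural parameters, avoiding the numeric digamma solve.  Used to
#' build ground-truth models from printed means and standard deviations.
#'
#' @param M `D x (H+1)` matrix of means in (0,1).
#' @param Sigma2 `D x (H+1)` matrix of feasible variances.
#' @param pi prior vector of length `H+1`.
#' @return a [beta_mca()] model.
#' @export
beta_mca_from_meanvar <- function(M, Sigma2, pi) {
  M <- as.matrix(M)
  Sigma2 <- as.matrix(Sigma2)
  eta <- meanvar_to_natural(M, Sigma2)
  eta1 <- matrix(eta$eta1, nrow(M))
  eta2 <- matrix(eta$eta2, nrow(M))
  wv <- natural_to_meanvalue(eta1, eta2)
  beta_mca(matrix(wv$w1, nrow(M)), matrix(wv$w2, nrow(M)), pi,
           eta1 = eta1, eta2 = eta2)
}

#' @export
print.beta_mca <- function(x, ...) {
  cat(sprintf(
    "Beta-MCA model: D = %d observables, H = %d causes + background\n",
    x$D, x$H))
  cat("prior pi:", format(x$pi, digits = 3), "\n")
  invisible(x)
}

#' Enumerate all latent states
#'
#' All `2^H` binary latent states with the background bit (column 1)
#' fixed at 1.  Row `i` encodes the bits of `i - 1`, so row order matches
#' the state codes `0:(2^H - 1)` used by the truncated machinery.
#'
#' @param H number of non-background causes (capped; exact enumeration is
#'   exponential in `H`).
#' @param enum_cap guard against accidental exponential blow-up.
#' @return integer matrix of size `2^H x (H+1)`.
#' @export
all_states <- function(H, enum_cap = 15L) {
  if (H > enum_cap) {
    stop(sprintf(paste0(
      "H = %d exceeds the exact-enumeration cap (%d); ",
      "use truncated inference"), H, enum_cap), call. = FALSE)
  }
  states_from_codes(0:(2^H - 1), H)
}

# decode integer bitmasks (bit h-1 = cause h) into state rows with s0 = 1
states_from_codes <- function(codes, H) {
  U <- length(codes)
  S <- matrix(0L, U, H + 1L)
  S[, 1L] <- 1L
  if (H > 0) {
    for (h in seq_len(H)) {
      S[, h + 1L] <- bitwAnd(codes, bitwShiftL(1L, h - 1L)) > 0L
    }
  }
  storage.mode(S) <- "integer"
  S
}

codes_from_states <- function(S) {
  H <- ncol(S) - 1L
  codes <- integer(nrow(S))
  for (h in seq_len(H)) {
    codes <- codes + S[, h + 1L] * bitwShiftL(1L, h - 1L)
  }
  codes
}

#' Dominant cause per observable
#'
#' For each observable `d`, the active cause with the largest mean
#' dictionary entry `M[d, h]`; ties broken by the lowest cause index.
#' The always-active background guarantees a candidate.
#'
#' @param s binary latent state of length `H+1` (background first).
#' @param M `D x (H+1)` mean dictionary.
#' @return integer vector of 0-based cause indices, one per observable.
#' @export
dominant_causes <- function(s, M) {
  drop(dominant_idx_cpp(M, matrix(as.integer(s), 1)))
}

#' @rdname dominant_causes
#' @param d observable index.
#' @export
dominant_cause <- function(d, s, M) {
  dominant_causes(s, M)[d]
}

#' Combined mean-value parameters of a latent state
#'
#' Copies, per observable, the `W` and `V` column of the dominant cause.
#'
#' @param s binary latent state (background first).
#' @param theta a [beta_mca()] model.
#' @return list with `D`-vectors `Wbar` and `Vbar`.
#' @export
combined_meanvalue <- function(s, theta) {
  idx <- dominant_causes(s, theta$M) + 1L
  pick <- cbind(seq_len(theta$D), idx)
  list(Wbar = theta$W[pick], Vbar = theta$V[pick])
}

#' Per-observable Beta mean and variance of a latent state
#'
#' The mean and variance of the observation distribution under state
#' `s`: per observable, the `M` and `Sigma2` entry of the dominant cause.
#'
#' @inheritParams combined_meanvalue
#' @return list with `D`-vectors `mu_bar` and `sigma2_bar`.
#' @export
per_datapoint_meanvar <- function(s, theta) {
  idx <- dominant_causes(s, theta$M) + 1L
  pick <- cbind(seq_len(theta$D), idx)
  list(mu_bar = theta$M[pick], sigma2_bar = theta$Sigma2[pick])
}

#' Sample a latent state from the prior
#'
#' Independent Bernoulli draws per cause; the background bit is always 1
#' regardless of `pi[1]`.  Uses the current RNG state, so wrap in
#' `set.seed()` for reproducibility.
#'
#' @param pi prior vector of length `H+1`.
#' @return integer 0/1 vector of length `H+1`.
#' @export
sample_latents <- function(pi) {
  if (any(pi < 0) || any(pi > 1)) {
    stop("pi entries must lie in [0,1]", call. = FALSE)
  }
  H <- length(pi) - 1L
  c(1L, as.integer(stats::runif(H) < pi[-1]))
}

#' Sample an observation given a latent state
#'
#' Independent Beta draws per observable with the dominant cause's
#' natural parameters; outputs are clamped into the open interval by
#' `eps`.
#'
#' @inheritParams combined_meanvalue
#' @param eps clamping margin keeping samples strictly inside (0,1).
#' @return numeric `D`-vector in (0,1).
#' @export
sample_observation <- function(s, theta, eps = 1e-10) {
  idx <- dominant_causes(s, theta$M) + 1L
  pick <- cbind(seq_len(theta$D), idx)
  y <- stats::rbeta(theta$D, theta$eta1[pick], theta$eta2[pick])
  pmin(pmax(y, eps), 1 - eps)
}

#' Ancestral sampling from a Beta-MCA model
#'
#' @param theta a [beta_mca()] model.
#' @param N number of data points.
#' @param eps clamping margin for the observations.
#' @return list with `Y` (`N x D` matrix in (0,1)) and `S`
#'   (`N x (H+1)` integer latent states, background column first).
#' @export
sample_beta_mca <- function(theta, N, eps = 1e-10) {
  H <- theta$H
  S <- matrix(0L, N, H + 1L)
  S[, 1L] <- 1L
  if (H > 0 && N > 0) {
    S[, -1L] <- matrix(
      as.integer(stats::runif(N * H) <
                   rep(theta$pi[-1], each = N)), N, H)
  }
  Y <- matrix(NA_real_, N, theta$D)
  if (N > 0) {
    codes <- codes_from_states(S)
    ucodes <- sort(unique(codes))
    map <- match(codes, ucodes)
    Dom <- dominant_idx_cpp(theta$M, states_from_codes(ucodes, H))
    D <- theta$D
    colIdx <- rep(seq_len(D), each = length(ucodes))
    lin <- as.vector(Dom * D + colIdx)  # Eta[d, h+1] at linear index h*D + d
    E1 <- matrix(theta$eta1[lin], length(ucodes), D)
    E2 <- matrix(theta$eta2[lin], length(ucodes), D)
    Y <- matrix(stats::rbeta(N * D, E1[map, ], E2[map, ]), N, D)
    Y <- pmin(pmax(Y, eps), 1 - eps)
  }
  list(Y = Y, S = S)
}

#' Clamp data into the open unit interval
#'
#' Values of exactly 0 or 1 are shifted inward by `eps` so that Beta
#' log-densities stay finite.
#'
#' @param Y numeric matrix/vector in \[0,1\].
#' @param eps shift applied at the boundary.
#' @return clamped data, same shape.
#' @export
clamp_unit_interval <- function(Y, eps = 1e-10) {
  if (any(!is.finite(Y)) || any(Y < 0) || any(Y > 1)) {
    stop("data must lie in [0,1]", call. = FALSE)
  }
  pmin(pmax(Y, eps), 1 - eps)
}

# log prior of each state row under pi (true -Inf for hard contradictions)
state_log_prior <- function(S, pi) {
  H <- length(pi) - 1L
  if (H == 0) return(rep(0, nrow(S)))
  lp <- log(pi[-1])
  l1p <- log1p(-pi[-1])
  S1 <- S[, -1L, drop = FALSE]
  out <- numeric(nrow(S))
  for (h in seq_len(H)) {
    term <- ifelse(S1[, h] == 1L, lp[h], l1p[h])
    out <- out + term
  }
  out
}

#' Log joint density of an observation and latent state
#'
#' Sum of the Beta log-densities under the dominant causes plus the
#' Bernoulli log prior of the non-background bits (the background
#' contributes `log 1 = 0`).  Hard contradictions with a degenerate
#' prior (`pi_h` in {0,1}) give `-Inf`.
#'
#' @param y observation vector in (0,1).
#' @param s binary latent state (background first).
#' @param theta a [beta_mca()] model.
#' @return scalar log joint.
#' @export
log_joint <- function(y, s, theta) {
  idx <- dominant_causes(s, theta$M) + 1L
  pick <- cbind(seq_len(theta$D), idx)
  ll <- sum(beta_logpdf(y, theta$eta1[pick], theta$eta2[pick]))
  ll + state_log_prior(matrix(as.integer(s), 1), theta$pi)
}

# N x U matrix of log p(y, s) for all data rows and state rows (BLAS path)
loglik_grid <- function(LY, L1Y, theta, S) {
  D <- theta$D
  U <- nrow(S)
  Dom <- dominant_idx_cpp(theta$M, S)
  colIdx <- rep(seq_len(D), each = U)
  lin <- as.vector(Dom * D + colIdx)
  E1 <- matrix(theta$eta1[lin], U, D)
  E2 <- matrix(theta$eta2[lin], U, D)
  cLB <- rowSums(matrix(theta$logB[lin], U, D))
  lj <- LY %*% t(E1 - 1) + L1Y %*% t(E2 - 1)
  lp <- state_log_prior(S, theta$pi) - cLB
  sweep(lj, 2L, lp, "+")
}

#' Exact log-likelihood by state enumeration
#'
#' `sum_n log sum_s p(y_n, s | theta)` over all `2^H` states with the
#' background active.  Guarded by an enumeration cap; larger models must
#' use truncated inference.
#'
#' @param Y `N x D` data matrix in (0,1) (rows are data points).
#' @param theta a [beta_mca()] model.
#' @param enum_cap maximum `H` for exact enumeration.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(Y, theta, enum_cap = 15L) {
  Y <- rbind(Y)
  S <- all_states(theta$H, enum_cap)
  lj <- loglik_grid(log(Y), log1p(-Y), theta, S)
  sum(apply_logsumexp(lj))
}

# rowwise log-sum-exp with -Inf safety
apply_logsumexp <- function(lj) {
  m <- apply(lj, 1L, max)
  m[!is.finite(m)] <- 0
  m + log(rowSums(exp(lj - m)))
}

#' Variational free energy (ELBO)
#'
#' `sum_n sum_s q_n(s) log p(y_n, s | theta) + H(q_n)` for variational
#' weights `q` over an enumerated state set.  Never exceeds the exact
#' log-likelihood; equals it when `q` is the exact posterior.
#'
#' @param Y `N x D` data matrix in (0,1).
#' @param q `N x U` matrix of normalized weights over the rows of
#'   `states`.
#' @param theta a [beta_mca()] model.
#' @param states state set (default: all `2^H` states).
#' @return scalar free energy.
#' @export
free_energy <- function(Y, q, theta, states = NULL) {
  Y <- rbind(Y)
  if (is.null(states)) states <- all_states(theta$H)
  q <- rbind(q)
  if (ncol(q) != nrow(states)) {
    stop("q must have one column per state", call. = FALSE)
  }
  if (any(q < -1e-12) || any(abs(rowSums(q) - 1) > 1e-8)) {
    stop("q rows must be normalized non-negative weights", call. = FALSE)
  }
  lj <- loglik_grid(log(Y), log1p(-Y), theta, states)
  ent <- -sum(q[q > 0] * log(q[q > 0]))
  sum(q * ifelse(q > 0, lj, 0)) + ent
}
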