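#' Binarize interval data
#'
#' Thresholds each observable at `alpha`; values at the boundary map to
#' 1.  The default threshold 0.5 is the value found to work best for
#' the noisy-OR comparison on symptom data.
#'
#' @param Y numeric matrix/vector in \[0,1\].
#' @param alpha threshold strictly inside (0,1).
#' @return binary 0/1 matrix of the same shape.
#' @export
binarize <- function(Y, alpha = 0.5) {
  if (length(alpha) != 1 || !is.finite(alpha) || alpha <= 0 ||
      alpha >= 1) {
    stop("alpha must lie strictly inside (0,1)", call. = FALSE)
  }
  out <- (Y >= alpha) * 1L
  out
}

#' Construct noisy-OR parameters
#'
#' Standard leaky noisy-OR Bayes net: cause `h` is active with prior
#' probability `priors[h]`; an active cause turns symptom `d` on with
#' probability `weights[d, h]`, and a leak term `leak[d]` models
#' background activation.
#'
#' @param priors `H`-vector of prior activation probabilities.
#' @param weights `D x H` matrix of activation probabilities.
#' @param leak `D`-vector of background activation probabilities.
#' @return object of class `noisyor`.
#' @export
noisyor_params <- function(priors, weights, leak) {
  weights <- as.matrix(weights)
  if (length(priors) != ncol(weights) ||
      length(leak) != nrow(weights)) {
    stop("dimension mismatch between priors, weights and leak",
         call. = FALSE)
  }
  vals <- c(priors, weights, leak)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    stop("all noisy-OR parameters must lie in [0,1]", call. = FALSE)
  }
  structure(list(priors = as.numeric(priors), weights = weights,
                 leak = as.numeric(leak),
                 D = nrow(weights), H = ncol(weights)),
            class = "noisyor")
}

#' Noisy-OR activation probabilities
#'
#' `p_d = 1 - (1 - leak_d) * prod_h (1 - W_dh)^{s_h}`.
#'
#' @param s binary cause vector of length `H` (no background bit).
#' @param params a [noisyor_params()] object.
#' @return `D`-vector of symptom activation probabilities.
#' @export
noisyor_prob <- function(s, params) {
  stopifnot(inherits(params, "noisyor"))
  lq <- log1p(-pmin(params$weights, 1 - 1e-15)) %*% as.numeric(s)
  1 - (1 - params$leak) * exp(drop(lq))
}

# N x S matrix of log p(b, s) for binary data B over cause states SH
noisyor_logjoint <- function(B, params, SH) {
  pe <- 1e-12
  P <- vapply(seq_len(nrow(SH)),
              function(i) noisyor_prob(SH[i, ], params),
              numeric(params$D))               # D x S
  P <- pmin(pmax(P, pe), 1 - pe)
  lj <- B %*% log(P) + (1 - B) %*% log1p(-P)   # N x S
  pr <- pmin(pmax(params$priors, pe), 1 - pe)
  lp <- SH %*% log(pr) + (1 - SH) %*% log1p(-pr)
  sweep(lj, 2L, drop(lp), "+")
}

#' Fit a noisy-OR model by EM
#'
#' Exact E-step by enumeration of the `2^H` cause states; M-step with a
#' closed-form prior update and numeric maximization (L-BFGS-B on the
#' logit scale, started from the current parameters) of the expected
#' complete-data log-likelihood over weights and leak.  Starting the
#' inner maximization at the current parameters guarantees a monotone
#' log-likelihood trace.
#'
#' @param B `N x D` binary matrix.
#' @param H number of causes.
#' @param n_iterations EM iterations.
#' @param seed RNG seed for the random initialization.
#' @param enum_cap maximum `H` for exact enumeration.
#' @return object of class `noisyor_fit`: list with `params`
#'   (a [noisyor_params()]) and `loglik` (per-iteration trace).
#' @export
noisyor_em_fit <- function(B, H, n_iterations = 50L, seed = 1L,
                           enum_cap = 15L) {
  B <- rbind(B)
  if (any(!(B %in% c(0, 1)))) stop("B must be binary", call. = FALSE)
  if (H > enum_cap) {
    stop(sprintf("H = %d exceeds the enumeration cap (%d)", H, enum_cap),
         call. = FALSE)
  }
  N <- nrow(B)
  D <- ncol(B)
  set.seed(seed)
  SH <- all_states(H)[, -1, drop = FALSE]  # 2^H x H cause states
  params <- noisyor_params(
    priors = stats::runif(H, 0.2, 0.5),
    weights = matrix(stats::runif(D * H, 0.2, 0.8), D, H),
    leak = stats::runif(D, 0.05, 0.2))
  ll <- numeric(n_iterations)
  for (it in seq_len(n_iterations)) {
    lj <- noisyor_logjoint(B, params, SH)
    lse <- apply_logsumexp(lj)
    ll[it] <- sum(lse)
    Q <- exp(lj - lse)
    priors_new <- pmin(pmax(colMeans(Q %*% SH), 1e-8), 1 - 1e-8)
    E1 <- crossprod(Q, B)        # S x D, responsibility-weighted counts
    E0 <- crossprod(Q, 1 - B)
    nq <- function(par) {
      W <- matrix(stats::plogis(par[seq_len(D * H)]), D, H)
      lk <- stats::plogis(par[D * H + seq_len(D)])
      p2 <- noisyor_params(priors_new, W, lk)
      P <- vapply(seq_len(nrow(SH)),
                  function(i) noisyor_prob(SH[i, ], p2), numeric(D))
      P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
      -sum(E1 * t(log(P)) + E0 * t(log1p(-P)))
    }
    par0 <- stats::qlogis(pmin(pmax(
      c(params$weights, params$leak), 1e-8), 1 - 1e-8))
    opt <- stats::optim(par0, nq, method = "L-BFGS-B",
                        control = list(maxit = 30))
    params <- noisyor_params(
      priors_new,
      matrix(stats::plogis(opt$par[seq_len(D * H)]), D, H),
      stats::plogis(opt$par[D * H + seq_len(D)]))
  }
  structure(list(params = params, loglik = ll, H = H),
            class = "noisyor_fit")
}

#' Posterior cause activation scores
#'
#' Exact posterior marginals `p(s_h = 1 | y)` for each test point and
#' cause, by enumeration of the latent states.  For a Beta-MCA model
#' the continuous data are used directly; for a noisy-OR fit the data
#' must already be binarized.
#'
#' @param Y `N x D` test data (continuous in (0,1) for Beta-MCA, binary
#'   for noisy-OR).
#' @param model a [beta_mca()] model, [noisyor_params()] or
#'   [noisyor_fit][noisyor_em_fit()].
#' @param ... unused.
#' @return `N x H` matrix of posterior activation probabilities.
#' @export
cause_scores <- function(Y, model, ...) {
  UseMethod("cause_scores", model)
}

#' @export
cause_scores.beta_mca <- function(Y, model, ...) {
  post <- exact_posterior(rbind(Y), model)
  post$weights %*% post$states[, -1, drop = FALSE]
}

#' @export
cause_scores.noisyor <- function(Y, model, ...) {
  B <- rbind(Y)
  SH <- all_states(model$H)[, -1, drop = FALSE]
  lj <- noisyor_logjoint(B, model, SH)
  lse <- apply_logsumexp(lj)
  exp(lj - lse) %*% SH
}

#' @export
cause_scores.noisyor_fit <- function(Y, model, ...) {
  cause_scores(Y, model$params, ...)
}

#' ROC curve and area under the curve
#'
#' Standard threshold sweep over the score values; the AUC is the
#' trapezoidal area under the resulting curve, which equals the
#' probability that a random positive outranks a random negative with
#' ties counted half.
#'
#' @param scores numeric score vector (higher = more positive).
#' @param labels binary 0/1 vector; both classes must be present.
#' @return list with `curve` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels) ||
      any(!(labels %in% c(0, 1)))) {
    stop("labels must be binary and match scores in length",
         call. = FALSE)
  }
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0 || nn == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  # collapse tied scores into single thresholds
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l)[last]
  fp <- cumsum(1 - l)[last]
  tpr <- c(0, tp / np)
  fpr <- c(0, fp / nn)
  thr <- c(Inf, s[last])
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Seeded cross-validation fold assignment
#'
#' @param n number of observations.
#' @param k number of folds.
#' @param seed optional RNG seed.
#' @return integer fold labels of length `n`, balanced across folds.
#' @export
crossval_folds <- function(n, k = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}
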