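#' Exact posterior over all latent states
#'
#' Enumerates the `2^H` states with the background active and normalizes
#' `exp(log p(y, s))` rowwise with a log-sum-exp guard.
#'
#' @param Y a data vector of length `D` or an `N x D` matrix in (0,1).
#' @param theta a [beta_mca()] model.
#' @param enum_cap maximum `H` for exact enumeration.
#' @return list with `states` (`2^H x (H+1)`), `log_joint` (`N x 2^H`),
#'   `weights` (`N x 2^H`, rows sum to 1), and `loglik` (per-point
#'   log marginal likelihood).
#' @export
exact_posterior <- function(Y, theta, enum_cap = 15L) {
  Y <- rbind(Y)
  S <- all_states(theta$H, enum_cap)
  lj <- loglik_grid(log(Y), log1p(-Y), theta, S)
  lse <- apply_logsumexp(lj)
  list(states = S, log_joint = lj, weights = exp(lj - lse), loglik = lse)
}

#' Truncated posterior over a state subset
#'
#' The exact posterior restricted and renormalized to a per-data-point
#' subset `K` of latent states: weights are the softmax of the log
#' joints over `K` and carry zero mass elsewhere.
#'
#' @param y data vector of length `D` in (0,1).
#' @param K state subset: a matrix of distinct binary state rows
#'   (background column first, all 1) or a vector of integer state codes
#'   (bit `h-1` encodes cause `h`).
#' @param theta a [beta_mca()] model.
#' @return object of class `truncated_posterior` with fields `states`,
#'   `codes`, `log_joints` and normalized `weights`.
#' @export
truncated_posterior <- function(y, K, theta) {
  if (is.matrix(K)) {
    if (nrow(K) == 0) stop("K must be non-empty", call. = FALSE)
    if (any(K[, 1] != 1L)) {
      stop("all states in K must have the background active",
           call. = FALSE)
    }
    codes <- codes_from_states(K)
  } else {
    codes <- as.integer(K)
  }
  if (length(codes) == 0) stop("K must be non-empty", call. = FALSE)
  if (anyDuplicated(codes)) {
    stop("states in K must be distinct", call. = FALSE)
  }
  S <- states_from_codes(codes, theta$H)
  lj <- drop(loglik_grid(rbind(log(y)), rbind(log1p(-y)), theta, S))
  m <- max(lj)
  w <- exp(lj - m)
  structure(
    list(states = S, codes = codes, log_joints = lj, weights = w / sum(w)),
    class = "truncated_posterior")
}

#' Expectation of a state function under a truncated posterior
#'
#' `sum_{s in K} q(s) g(s)` for a function `g` evaluated on binary state
#' vectors.
#'
#' @param g function taking a binary state vector (background first) and
#'   returning a finite scalar.
#' @param tp a [truncated_posterior()].
#' @return scalar expectation.
#' @export
truncated_expectation <- function(g, tp) {
  vals <- vapply(seq_len(nrow(tp$states)),
                 function(i) g(tp$states[i, ]), numeric(1))
  sum(tp$weights * vals)
}

# derived per-state tables for a set of unique state codes
state_tables <- function(theta, ucodes) {
  S <- states_from_codes(ucodes, theta$H)
  Dom <- dominant_idx_cpp(theta$M, S)
  U <- nrow(S)
  D <- theta$D
  colIdx <- rep(seq_len(D), each = U)
  lin <- as.vector(Dom * D + colIdx)
  list(states = S,
       Dom = Dom,
       E1 = matrix(theta$eta1[lin] - 1, U, D),
       E2 = matrix(theta$eta2[lin] - 1, U, D),
       cLB = rowSums(matrix(theta$logB[lin], U, D)),
       lprior = state_log_prior(S, theta$pi))
}

# log joints for (data point, state-code) pairs via the compiled kernel
pairs_loglik <- function(LY, L1Y, theta, nIdx, codes) {
  ucodes <- sort(unique(codes))
  uIdx <- match(codes, ucodes)
  tab <- state_tables(theta, ucodes)
  lj <- pair_loglik_cpp(LY, L1Y, tab$E1, tab$E2, tab$cLB, nIdx, uIdx)
  list(lj = lj + tab$lprior[uIdx], ucodes = ucodes, uIdx = uIdx,
       tab = tab)
}

# one evolutionary update of the per-data-point state subsets.
# Kcodes: N x S integer matrix of distinct state codes per row.
# Children are generated from parents sampled proportionally to the
# truncated weights, by single random bit flips (plus a small rate of
# second flips); elitist selection keeps the top-S distinct states by
# log joint, so truncated posterior mass never decreases.
eem_step_batch <- function(LY, L1Y, theta, Kcodes, generations = 1L,
                           n_children = NULL, bitflip2_prob = 0.2) {
  N <- nrow(Kcodes)
  Ssz <- ncol(Kcodes)
  H <- theta$H
  if (is.null(n_children)) n_children <- 2L * Ssz
  full <- 2^H
  nIdx <- rep(seq_len(N), times = Ssz)
  pl <- pairs_loglik(LY, L1Y, theta, nIdx, as.vector(Kcodes))
  lj <- matrix(pl$lj, N, Ssz)

  gens <- if (Ssz >= full) 0L else generations  # nothing to search
  for (g in seq_len(gens)) {
    sm <- group_softmax_cpp(as.vector(lj), nIdx, N)
    W <- matrix(sm$weights, N, Ssz)
    parents <- matrix(0L, N, n_children)
    for (n in seq_len(N)) {
      parents[n, ] <- sample.int(Ssz, n_children, replace = TRUE,
                                 prob = W[n, ])
    }
    pcodes <- matrix(Kcodes[cbind(rep(seq_len(N), n_children),
                                  as.vector(parents))], N, n_children)
    flip1 <- bitwShiftL(1L, sample.int(H, N * n_children,
                                       replace = TRUE) - 1L)
    child <- bitwXor(as.vector(pcodes), flip1)
    two <- stats::runif(N * n_children) < bitflip2_prob
    if (any(two)) {
      flip2 <- bitwShiftL(1L, sample.int(H, sum(two),
                                         replace = TRUE) - 1L)
      child[two] <- bitwXor(child[two], flip2)
    }
    pool_codes <- cbind(Kcodes, matrix(child, N, n_children))
    pn <- rep(seq_len(N), times = ncol(pool_codes))
    pc <- as.vector(pool_codes)
    plj <- pairs_loglik(LY, L1Y, theta, pn, pc)$lj
    # distinct (n, code) pairs; identical pairs have identical log joints
    keep <- !duplicated(pn * full + pc)
    pn <- pn[keep]
    pc <- pc[keep]
    plj <- plj[keep]
    o <- order(pn, -plj)
    pn <- pn[o]
    rank <- sequence(tabulate(pn, nbins = N))
    sel <- rank <= Ssz
    Kcodes <- matrix(pc[o][sel], N, Ssz, byrow = TRUE)
    lj <- matrix(plj[o][sel], N, Ssz, byrow = TRUE)
  }
  list(Kcodes = Kcodes, lj = lj)
}

#' Evolutionary search over latent-state subsets
#'
#' Updates one data point's state subset `K` by the evolutionary scheme
#' used in the variational E-step: parents are drawn from `K` with
#' probability proportional to their truncated posterior weights,
#' children arise by random single bit flips (with a small second-flip
#' rate), and the `|K|` distinct states with the highest log joints
#' survive.  The truncated posterior mass is therefore non-decreasing.
#' The background bit is never mutated.
#'
#' @param y data vector in (0,1).
#' @param K_prev current subset (state matrix or code vector), distinct
#'   states.
#' @param theta a [beta_mca()] model.
#' @param generations number of mutation/selection rounds (0 returns
#'   `K_prev` unchanged).
#' @param n_children children generated per generation (default
#'   `2 * |K|`).
#' @param bitflip2_prob probability of a second bit flip per child.
#' @return state subset of the same size, as a code vector sorted by
#'   decreasing log joint.
#' @export
eem_search <- function(y, K_prev, theta, generations = 1L,
                       n_children = NULL, bitflip2_prob = 0.2) {
  codes <- if (is.matrix(K_prev)) codes_from_states(K_prev)
           else as.integer(K_prev)
  if (length(codes) < 1) stop("|K| must be at least 1", call. = FALSE)
  if (anyDuplicated(codes)) {
    stop("states in K_prev must be distinct", call. = FALSE)
  }
  res <- eem_step_batch(rbind(log(y)), rbind(log1p(-y)), theta,
                        matrix(codes, 1), generations, n_children,
                        bitflip2_prob)
  drop(res$Kcodes)
}

# initial subsets: background-only state, then the singleton states
# nearest by data-to-generative-field similarity, padded with random
# distinct states
init_subsets <- function(Y, theta, size) {
  N <- nrow(Y)
  H <- theta$H
  full <- 2^H
  if (size < 1) stop("truncation size must be at least 1", call. = FALSE)
  if (size > full) {
    stop("truncation size exceeds the number of latent states",
         call. = FALSE)
  }
  sim <- Y %*% theta$M[, -1, drop = FALSE]  # N x H
  K <- matrix(0L, N, size)
  n_single <- min(size - 1L, H)
  for (n in seq_len(N)) {
    sel <- c(0L, bitwShiftL(1L, order(sim[n, ],
                                      decreasing = TRUE)[seq_len(n_single)]
                            - 1L))
    need <- size - length(sel)
    while (need > 0) {
      cand <- setdiff(sample.int(full, min(full, 2L * size)) - 1L, sel)
      take <- utils::head(cand, need)
      sel <- c(sel, take)
      need <- size - length(sel)
    }
    K[n, ] <- sel[seq_len(size)]
  }
  K
}
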