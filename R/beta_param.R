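#' Beta distribution parameterizations
#'
#' The Beta distribution on (0,1) admits three equivalent parameterizations
#' used throughout this package:
#'
#' * natural (shape) parameters `(eta1, eta2)`, both positive; for the Beta
#'   family the natural parameters coincide with the usual shapes
#'   (alpha, beta);
#' * mean-value parameters `(w1, w2)`, the expectations of the sufficient
#'   statistics `log(y)` and `log(1 - y)`, both negative;
#' * mean/variance parameters `(mu, sigma2)` with `0 < mu < 1` and
#'   `0 < sigma2 < mu * (1 - mu)` (the feasibility bound of the Beta
#'   variance).
#'
#' The closed-form maps are
#' `mu = eta1 / (eta1 + eta2)`,
#' `sigma2 = eta1 * eta2 / ((eta1 + eta2)^2 * (eta1 + eta2 + 1))`, and
#' `w_i = digamma(eta_i) - digamma(eta1 + eta2)`.  The inverse map from
#' mean-value to natural parameters has no closed form and is computed
#' numerically by [meanvalue_to_natural()].
#'
#' All conversion functions are vectorized elementwise, so matrices of
#' parameters (one entry per observable/cause pair) convert in one call.
#'
#' @name beta-parameterizations
NULL

check_eta <- function(eta1, eta2) {
  if (any(!is.finite(eta1)) || any(!is.finite(eta2)) ||
      any(eta1 <= 0) || any(eta2 <= 0)) {
    stop("natural parameters must be finite and strictly positive",
         call. = FALSE)
  }
  invisible(NULL)
}

#' @rdname beta-parameterizations
#' @param eta1,eta2 positive shape/natural parameters (vectorized).
#' @return `natural_to_meanvar()`: list with components `mu`, `sigma2`.
#' @export
natural_to_meanvar <- function(eta1, eta2) {
  check_eta(eta1, eta2)
  s <- eta1 + eta2
  list(mu = eta1 / s, sigma2 = eta1 * eta2 / (s^2 * (s + 1)))
}

#' @rdname beta-parameterizations
#' @param mu mean in (0,1) (vectorized).
#' @param sigma2 variance, positive and below `mu * (1 - mu)`.
#' @return `meanvar_to_natural()`: list with components `eta1`, `eta2`.
#' @export
meanvar_to_natural <- function(mu, sigma2) {
  if (any(!is.finite(mu)) || any(mu <= 0) || any(mu >= 1)) {
    stop("mean must lie strictly inside (0,1)", call. = FALSE)
  }
  if (any(!is.finite(sigma2)) || any(sigma2 <= 0) ||
      any(sigma2 >= mu * (1 - mu))) {
    stop("infeasible variance: need 0 < sigma2 < mu * (1 - mu)",
         call. = FALSE)
  }
  nu <- mu * (1 - mu) / sigma2 - 1
  list(eta1 = mu * nu, eta2 = (1 - mu) * nu)
}

#' @rdname beta-parameterizations
#' @return `natural_to_meanvalue()`: list with components `w1`, `w2`.
#' @export
natural_to_meanvalue <- function(eta1, eta2) {
  check_eta(eta1, eta2)
  ds <- digamma(eta1 + eta2)
  list(w1 = digamma(eta1) - ds, w2 = digamma(eta2) - ds)
}

#' Inverse digamma function
#'
#' Solves `digamma(x) = w` for `x > 0` by Newton iteration from the
#' standard asymptotic initializer (`exp(w) + 1/2` for large `w`,
#' `-1/(w + gamma)` for very negative `w`).  Vectorized.
#'
#' @param w real values (any sign).
#' @param tol convergence tolerance on the residual `digamma(x) - w`.
#' @param max_iter Newton iteration cap.
#' @return positive solutions, same shape as `w`.
#' @export
inv_digamma <- function(w, tol = 1e-12, max_iter = 60L) {
  if (any(!is.finite(w))) stop("w must be finite", call. = FALSE)
  x <- ifelse(w >= -2.22, exp(w) + 0.5, -1 / (w - digamma(1)))
  for (i in seq_len(max_iter)) {
    f <- digamma(x) - w
    # relative-scale convergence: residuals scale like |w| for tiny x
    if (all(abs(f) <= tol * pmax(1, abs(w)))) break
    step <- f / trigamma(x)
    xn <- x - step
    bad <- xn <= 0
    while (any(bad)) {
      step[bad] <- step[bad] / 2
      xn <- x - step
      bad <- xn <= 0
    }
    x <- xn
  }
  x
}

#' Map mean-value parameters to natural parameters
#'
#' Numerically inverts the digamma system
#' `w1 = digamma(eta1) - digamma(eta1 + eta2)`,
#' `w2 = digamma(eta2) - digamma(eta1 + eta2)`
#' by an alternating inverse-digamma fixed point followed by a damped
#' Newton refinement on the two-dimensional residual.  Vectorized
#' elementwise, so whole dictionaries convert in one call.
#'
#' Inputs with `w1 == w2` (symmetric Beta) are accepted: although the
#' textbook bijectivity argument assumes distinct shapes (a minimal
#' exponential-family representation), the numeric system is well
#' conditioned at symmetry and the solver converges there too.
#'
#' @param w1,w2 negative mean-value parameters (vectorized).
#' @param tol residual tolerance, scaled by `max(1, |w|)` per component.
#' @param max_iter Newton iteration cap (after the fixed-point warm start).
#' @return list with components `eta1`, `eta2` satisfying
#'   `natural_to_meanvalue(eta1, eta2) == (w1, w2)` to within `tol`.
#' @export
meanvalue_to_natural <- function(w1, w2, tol = 1e-12, max_iter = 60L) {
  if (any(!is.finite(w1)) || any(!is.finite(w2)) ||
      any(w1 >= 0) || any(w2 >= 0)) {
    stop("mean-value parameters must be finite and strictly negative",
         call. = FALSE)
  }
  n <- max(length(w1), length(w2))
  w1 <- rep_len(as.numeric(w1), n)
  w2 <- rep_len(as.numeric(w2), n)
  sc1 <- pmax(1, abs(w1))
  sc2 <- pmax(1, abs(w2))

  eta1 <- rep(1, n)
  eta2 <- rep(1, n)
  # alternating fixed point: eta_i <- psi^-1(w_i + psi(eta1 + eta2))
  for (i in 1:200) {
    t <- digamma(eta1 + eta2)
    eta1 <- inv_digamma(w1 + t)
    eta2 <- inv_digamma(w2 + t)
    f1 <- digamma(eta1) - t - w1  # t is slightly stale; fine for warm start
    f2 <- digamma(eta2) - t - w2
    if (all(abs(f1) <= 1e-6 * sc1 & abs(f2) <= 1e-6 * sc2)) break
  }
  # damped Newton on the 2-D residual
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    s <- eta1 + eta2
    ds <- digamma(s)
    f1 <- digamma(eta1) - ds - w1
    f2 <- digamma(eta2) - ds - w2
    if (all(abs(f1) <= tol * sc1 & abs(f2) <= tol * sc2)) {
      converged <- TRUE
      break
    }
    ts <- trigamma(s)
    a <- trigamma(eta1) - ts
    cc <- trigamma(eta2) - ts
    det <- a * cc - ts * ts
    st1 <- -(cc * f1 + ts * f2) / det
    st2 <- -(ts * f1 + a * f2) / det
    bad <- !is.finite(st1) | !is.finite(st2)
    st1[bad] <- 0
    st2[bad] <- 0
    n1 <- eta1 + st1
    n2 <- eta2 + st2
    neg <- n1 <= 0 | n2 <= 0
    k <- 0L
    while (any(neg) && k < 60L) {
      st1[neg] <- st1[neg] / 2
      st2[neg] <- st2[neg] / 2
      n1 <- eta1 + st1
      n2 <- eta2 + st2
      neg <- n1 <= 0 | n2 <= 0
      k <- k + 1L
    }
    eta1 <- n1
    eta2 <- n2
  }
  if (!converged) {
    s <- eta1 + eta2
    ds <- digamma(s)
    r <- max(abs(digamma(eta1) - ds - w1) / sc1,
             abs(digamma(eta2) - ds - w2) / sc2)
    if (r > tol * 100) {
      stop(sprintf(
        "digamma-system solve did not converge (max scaled residual %.3e)",
        r), call. = FALSE)
    }
  }
  list(eta1 = eta1, eta2 = eta2)
}

#' Beta log-density in natural parameters
#'
#' `(eta1 - 1) * log(y) + (eta2 - 1) * log(1 - y) - log B(eta1, eta2)`.
#'
#' @param y values strictly inside (0,1) (vectorized).
#' @param eta1,eta2 positive shape/natural parameters.
#' @return log-density values.
#' @export
beta_logpdf <- function(y, eta1, eta2) {
  check_eta(eta1, eta2)
  if (any(!is.finite(y)) || any(y <= 0) || any(y >= 1)) {
    stop("y must lie strictly inside (0,1)", call. = FALSE)
  }
  (eta1 - 1) * log(y) + (eta2 - 1) * log1p(-y) - lbeta(eta1, eta2)
}
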