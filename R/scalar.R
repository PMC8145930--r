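#' Scalar-variance Beta-MCA model
#'
#' Variant of [beta_mca()] in which each cause carries only a mean
#' column `M[, h]` and all Beta distributions share one variance
#' `sigma2` (the preliminary global-variance model).  The derived
#' natural-parameter dictionaries are obtained in closed form from
#' `(M, sigma2)`, so this family needs no digamma-system solve.
#'
#' @param M `D x (H+1)` matrix of means in (0,1); column 1 is the
#'   background.
#' @param sigma2 shared variance; must be below `min(M * (1 - M))`.
#' @param pi prior vector of length `H+1` (background forced to 1).
#' @return object of class `beta_mca_scalar` exposing the same derived
#'   fields (`M`, `eta1`, `eta2`, `logB`, `Sigma2`) as [beta_mca()], so
#'   sampling and all E-step machinery apply unchanged.
#' @export
beta_mca_scalar <- function(M, sigma2, pi) {
  M <- as.matrix(M)
  if (any(!is.finite(M)) || any(M <= 0) || any(M >= 1)) {
    stop("M entries must lie strictly inside (0,1)", call. = FALSE)
  }
  if (length(sigma2) != 1 || sigma2 <= 0 ||
      sigma2 >= min(M * (1 - M))) {
    stop("sigma2 must be a scalar below min(M * (1 - M))", call. = FALSE)
  }
  if (length(pi) != ncol(M) || any(pi < 0) || any(pi > 1)) {
    stop("pi must have length ncol(M) with entries in [0,1]",
         call. = FALSE)
  }
  pi <- as.numeric(pi)
  pi[1] <- 1
  eta <- meanvar_to_natural(M, matrix(sigma2, nrow(M), ncol(M)))
  eta1 <- matrix(eta$eta1, nrow(M))
  eta2 <- matrix(eta$eta2, nrow(M))
  structure(list(
    M = M, sigma2 = sigma2, pi = pi,
    D = nrow(M), H = ncol(M) - 1L,
    eta1 = eta1, eta2 = eta2,
    Sigma2 = matrix(sigma2, nrow(M), ncol(M)),
    logB = matrix(lbeta(eta1, eta2), nrow(M))),
    class = c("beta_mca_scalar", "beta_mca"))
}

#' @export
print.beta_mca_scalar <- function(x, ...) {
  cat(sprintf(paste0(
    "scalar-variance Beta-MCA model: D = %d observables, ",
    "H = %d causes + background, sigma2 = %.4g\n"),
    x$D, x$H, x$sigma2))
  invisible(x)
}

# expected complete-data log-likelihood contribution of one (d, h) cell
# as a function of its mean, given the shared variance and the
# responsibility-weighted sufficient statistics sw = <log y>, sv =
# <log(1-y)> (means over the responsibility mass)
scalar_cell_obj <- function(mu, s2, sw, sv) {
  nu <- mu * (1 - mu) / s2 - 1
  e1 <- mu * nu
  e2 <- (1 - mu) * nu
  (e1 - 1) * sw + (e2 - 1) * sv - lbeta(e1, e2)
}

# coordinate-wise numeric ascent for the scalar-variance M-step:
# each mean entry is optimized on its feasible interval given sigma2,
# then sigma2 on (0, 0.95 * min M(1-M)); entries with no
# responsibility are held.
scalar_mstep <- function(theta, sums, pinew, frozen, sigma2_init,
                         hold_tol = 1e-12) {
  D <- theta$D
  Hp1 <- theta$H + 1L
  M <- theta$M
  s2 <- theta$sigma2
  den <- sums$den
  Sw <- sums$Wnum / pmax(den, hold_tol)
  Sv <- sums$Vnum / pmax(den, hold_tol)
  r <- sqrt(max(0, 1 - 4 * s2))
  lo <- (1 - r) / 2 + 1e-6
  hi <- (1 + r) / 2 - 1e-6
  for (j in seq_len(D * Hp1)) {
    if (den[j] <= hold_tol || lo >= hi) next
    M[j] <- stats::optimize(scalar_cell_obj, c(lo, hi), maximum = TRUE,
                            s2 = s2, sw = Sw[j], sv = Sv[j])$maximum
  }
  if (!frozen) {
    bound <- 0.95 * min(M * (1 - M))
    used <- den > hold_tol
    obj_s2 <- function(x) {
      v <- scalar_cell_obj(M[used], x, Sw[used], Sv[used])
      sum(den[used] * v)
    }
    s2 <- stats::optimize(obj_s2, c(1e-8, bound), maximum = TRUE)$maximum
  } else {
    s2 <- min(sigma2_init, 0.95 * min(M * (1 - M)))
  }
  beta_mca_scalar(M, s2, pinew)
}
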