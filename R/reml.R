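# Single-variance-ratio REML machinery.
#
# Every mixed model in the package has exactly one genetic random term plus a
# (possibly weighted) residual, so REML reduces to a 1-D profile likelihood in
# the ratio theta = sigma2_g / sigma2_e, evaluated in closed form after one
# eigen-decomposition of the genetic covariance projected onto the residual
# (fixed-effect-free) space.

# Minimise -2 * REML log-likelihood given rotated squared residuals z2 and
# eigenvalues xi (same length, the dimension of the contrast space).
profile_reml_ratio <- function(z2, xi, lower = 1e-8, upper = 1e8) {
  n <- length(z2)
  neg2ll <- function(ltheta) {
    th <- exp(ltheta)
    v <- th * xi + 1
    s2e <- sum(z2 / v) / n
    n * log(s2e) + sum(log(v))
  }
  opt <- stats::optimize(neg2ll, c(log(lower), log(upper)), tol = 1e-8)
  theta <- exp(opt$minimum)
  s2e <- sum(z2 / (theta * xi + 1)) / n
  at_boundary <- opt$minimum < log(lower) + 1e-3 ||
    opt$minimum > log(upper) - 1e-3
  list(theta = theta, sigma2_e = s2e, sigma2_g = theta * s2e,
       at_boundary = at_boundary)
}

# REML for y = X b + g + e with g ~ N(0, sigma2_g * H) and
# e ~ N(0, sigma2_e * diag(1/weights)). Returns variance components and the
# GLS fixed effects at the optimum.
reml_onevc <- function(y, X, H, weights = NULL) {
  n <- length(y)
  if (is.null(weights)) weights <- rep(1, n)
  sw <- sqrt(weights)
  ys <- sw * y
  Xs <- sw * X
  Hs <- H * tcrossprod(sw)
  qr_x <- qr(Xs)
  p <- qr_x$rank
  K <- qr.Q(qr_x, complete = TRUE)[, (p + 1):n, drop = FALSE]
  M <- crossprod(K, Hs %*% K)
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  xi <- pmax(eg$values, 0)
  z <- crossprod(eg$vectors, crossprod(K, ys))
  fit <- profile_reml_ratio(drop(z)^2, xi)
  # GLS fixed effects at the estimated ratio
  V <- fit$theta * Hs + diag(n)
  Vi_X <- solve(V, Xs)
  Vi_y <- solve(V, ys)
  XtViX <- crossprod(Xs, Vi_X)
  beta <- solve(XtViX, crossprod(Xs, Vi_y))
  list(theta = fit$theta, sigma2_g = fit$sigma2_g, sigma2_e = fit$sigma2_e,
       beta = drop(beta), beta_cov = solve(XtViX) * fit$sigma2_e,
       at_boundary = fit$at_boundary)
}

# REML variance ratio for the marker model y = 1 mu + Z u + e,
# u ~ N(0, sigma2_u I). Works in the marker space (m x m eigen) so the cost
# does not grow with the cube of the training-set size; accepts either the
# raw (Z, y) or their sufficient statistics.
rrblup_reml <- function(Z, y, G0 = NULL) {
  n <- length(y)
  if (is.null(G0)) G0 <- crossprod(Z)
  cs <- colSums(Z)
  ybar <- mean(y)
  rrblup_reml_stats(G0 - tcrossprod(cs) / n,
                    drop(crossprod(Z, y)) - ybar * cs,
                    sum((y - ybar)^2), n)
}

rrblup_reml_stats <- function(Gc, w, ycss, n) {
  eg <- eigen(Gc, symmetric = TRUE)
  rrblup_reml_eigen(eg$vectors, pmax(eg$values, 0), w, ycss, n)
}

rrblup_reml_eigen <- function(V, xi_full, w, ycss, n) {
  keep <- xi_full > max(xi_full) * 1e-12
  xi <- xi_full[keep]
  z <- drop(crossprod(V[, keep, drop = FALSE], w)) / sqrt(xi)
  tail_n <- (n - 1) - length(xi)
  tail_ss <- max(ycss - sum(z^2), 0)
  z2 <- c(z^2, if (tail_n > 0) rep(tail_ss / tail_n, tail_n))
  xi_all <- c(xi, rep(0, max(tail_n, 0)))
  profile_reml_ratio(z2, xi_all)
}
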