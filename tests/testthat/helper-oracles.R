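# Independent numerical oracles used across the suite. These deliberately
# avoid the package's own code paths wherever they check one.

# integral of g(t) * dnorm(t, mu, sd) over the real line, by adaptive
# quadrature on a wide window.
gauss_integral <- function(g, mu, sd, rel.tol = 1e-12) {
  stats::integrate(function(t) g(t) * stats::dnorm(t, mu, sd),
                   mu - 12 * sd, mu + 12 * sd, rel.tol = rel.tol,
                   abs.tol = 0)$value
}

# Gauss-Hermite version (change of variables t = mu + sqrt(2) sd z).
gh_integral <- function(g, mu, sd, n = 64) {
  gh <- pracma::gaussHermite(n)
  sum(gh$w * g(mu + sqrt(2) * sd * gh$x)) / sqrt(pi)
}

# Evidence of a probit-GP component by brute-force tensor-grid quadrature
# over the latent thresholds at the distinct trial frequencies (1 or 2).
# trial_tab: trials() data frame; component/sigma_p as in the package.
evidence_quadrature <- function(component, trial_tab, sigma_p, n_nodes = 80) {
  xs <- sort(unique(bark(trial_tab$frequency_hz)))
  idx <- match(bark(trial_tab$frequency_hz), xs)
  pr <- component_prior_at(component, xs)
  lik <- function(t) {           # t: vector of latents, one per distinct freq
    prod(pnorm(trial_tab$response *
                 (trial_tab$intensity_db - t[idx]) / sigma_p))
  }
  gh <- pracma::gaussHermite(n_nodes)
  if (length(xs) == 1L) {
    sd <- sqrt(pr$cov[1, 1])
    return(sum(gh$w * vapply(pr$mean + sqrt(2) * sd * gh$x,
                             function(t) lik(t), 0)) / sqrt(pi))
  }
  if (length(xs) != 2L) stop("oracle supports 1 or 2 distinct frequencies")
  R <- chol(pr$cov)              # t = mean + sqrt(2) R' z
  acc <- 0
  for (i in seq_len(n_nodes)) {
    for (j in seq_len(n_nodes)) {
      z <- c(gh$x[i], gh$x[j])
      t <- pr$mean + sqrt(2) * drop(crossprod(R, z))
      acc <- acc + gh$w[i] * gh$w[j] * lik(t)
    }
  }
  acc / pi
}

# Dedicated single-GP reference path: an independent re-implementation of
# the probit-GP Laplace fit, predictive, and BALD objective, written with
# plain loops and no shared helpers, used to check the C = 1 reduction.
single_gp_laplace <- function(component, trial_tab, sigma_p) {
  xs <- sort(unique(bark(trial_tab$frequency_hz)))
  idx <- match(bark(trial_tab$frequency_hz), xs)
  n <- length(xs)
  z0 <- xs - bayespta:::bark_centre()
  m <- drop(cbind(1, z0, z0^2, z0^3) %*% component$mean_coeffs)
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    K[i, j] <- component$kernel_variance *
      exp(-(xs[i] - xs[j])^2 / (2 * component$kernel_lengthscale^2))
  }
  K <- K + diag(1e-8 * component$kernel_variance, n)
  Kinv <- solve(K)
  f <- m
  for (iter in 1:200) {
    g <- numeric(n); W <- numeric(n)
    for (i in seq_len(nrow(trial_tab))) {
      y <- trial_tab$response[i]; h <- trial_tab$intensity_db[i]
      j <- idx[i]
      zz <- y * (h - f[j]) / sigma_p
      r <- dnorm(zz) / pnorm(zz)
      g[j] <- g[j] - y * r / sigma_p
      W[j] <- W[j] + (r^2 + zz * r) / sigma_p^2
    }
    grad <- g - Kinv %*% (f - m)
    if (sqrt(sum(grad^2)) < 1e-10) break
    f <- f + solve(Kinv + diag(W, n), grad)
  }
  ll <- 0
  for (i in seq_len(nrow(trial_tab))) {
    ll <- ll + pnorm(trial_tab$response[i] *
                       (trial_tab$intensity_db[i] - f[idx[i]]) / sigma_p,
                     log.p = TRUE)
  }
  W <- numeric(n)
  for (i in seq_len(nrow(trial_tab))) {
    y <- trial_tab$response[i]; h <- trial_tab$intensity_db[i]; j <- idx[i]
    zz <- y * (h - f[j]) / sigma_p
    r <- dnorm(zz) / pnorm(zz)
    W[j] <- W[j] + (r^2 + zz * r) / sigma_p^2
  }
  H <- Kinv + diag(W, n)
  lprior <- -0.5 * t(f - m) %*% Kinv %*% (f - m) -
    0.5 * determinant(K)$modulus - (n / 2) * log(2 * pi)
  logz <- as.numeric(ll + drop(lprior) + (n / 2) * log(2 * pi) -
                       0.5 * drop(determinant(H)$modulus))
  pred <- function(x) {
    zx <- x - bayespta:::bark_centre()
    mx <- drop(cbind(1, zx, zx^2, zx^3) %*% component$mean_coeffs)
    kx <- component$kernel_variance *
      exp(-(xs - x)^2 / (2 * component$kernel_lengthscale^2))
    S <- solve(H)
    mu <- mx + drop(t(kx) %*% Kinv %*% (f - m))
    A <- Kinv %*% kx
    v <- component$kernel_variance - drop(t(kx) %*% A) +
      drop(t(A) %*% S %*% A)
    c(mu, sqrt(max(v, 1e-12)))
  }
  list(mode = f, H = H, log_evidence = logz, pred = pred)
}

# Binary entropy in bits, direct.
h2 <- function(p) {
  out <- numeric(length(p))
  ok <- p > 0 & p < 1
  out[ok] <- -p[ok] * log2(p[ok]) - (1 - p[ok]) * log2(1 - p[ok])
  out
}

# A small hand-built two-component mixture model for inference tests:
# flat component at 20 dB and sloping component, both SE kernels.
toy_model <- function(sigma_p = 5, alpha = c(0.5, 0.5)) {
  comp1 <- gp_component(c(20, 0, 0, 0), 100, 4)
  comp2 <- gp_component(c(45, 8, 0, 0), 36, 4)
  mixture_model(list(comp1, comp2),
                alpha_table(list("unspecified|unspecified" = alpha)),
                sigma_p)
}

# Single-component model wrapper.
toy_model1 <- function(comp = gp_component(c(30, 5, -0.2, 0), 64, 4),
                       sigma_p = 5) {
  mixture_model(list(comp),
                alpha_table(list("unspecified|unspecified" = 1)), sigma_p)
}
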