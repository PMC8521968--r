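## Three-step maximum-likelihood learning of the hearing-threshold mixture:
##   1. EM for a full-covariance Gaussian mixture at the standard frequencies
##      (complete-case records);
##   2. per component, Kullback-Leibler matching of a GP (cubic mean +
##      squared exponential kernel) to the fitted Gaussian;
##   3. a side-information lookup table of averaged posterior
##      responsibilities, queried by nearest neighbour.

# Log-density of rows of X under N(mu, S); via Cholesky.
dmvnorm_log <- function(X, mu, S) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
  R <- chol_jitter(S, scale = max(diag(S)) * 1e-4)
  d <- ncol(X)
  z <- backsolve(R, t(X) - mu, transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(R))) - (d / 2) * log(2 * pi)
}

# k-means++ seeding of C rows of X.
kmeanspp_centres <- function(X, C) {
  n <- nrow(X)
  centres <- X[sample.int(n, 1L), , drop = FALSE]
  while (nrow(centres) < C) {
    d2 <- apply(X, 1, function(r) min(colSums((t(centres) - r)^2)))
    centres <- rbind(centres, X[sample.int(n, 1L, prob = pmax(d2, 1e-12)), ])
  }
  centres
}

#' Maximum-likelihood Gaussian mixture by EM
#'
#' Fits a C-component full-covariance Gaussian mixture to complete audiogram
#' rows by expectation-maximisation, best of `n_init` k-means++-seeded
#' restarts. Convergence when the relative log-likelihood change falls below
#' `tol` (max `max_iter` iterations). Degenerate components (covariance
#' eigenvalue below 1e-6 dB^2) are diagonally regularised with a warning.
#'
#' With thresholds quantised to a finite resolution the unrestricted GMM
#' likelihood is unbounded (a component can collapse onto duplicated lattice
#' rows), so covariance eigenvalues are floored at `var_floor`; the floor
#' should be the within-cell variance of the quantisation, `step^2 / 12`.
#'
#' @param X Numeric matrix, records x frequencies (dB-HL), no missing values.
#' @param C Number of components (>= 1).
#' @param n_init Number of restarts (default 5).
#' @param max_iter Maximum EM iterations per restart (default 500).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param var_floor Minimum covariance eigenvalue, dB^2 (default `25 / 12`,
#'   the within-cell variance of 5 dB quantisation).
#' @param seed Optional integer seed (local to this call).
#' @return List with `weights`, `means` (C x d), `covariances` (list of
#'   d x d), `loglik`, `n_iter`, `loglik_trace`.
#' @export
fit_gmm <- function(X, C, n_init = 5, max_iter = 500, tol = 1e-6,
                    var_floor = 25 / 12, seed = NULL) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("`X` must be complete; drop incomplete records first",
                     call. = FALSE)
  n <- nrow(X); d <- ncol(X)
  if (C < 1L) stop("`C` must be >= 1", call. = FALSE)
  if (n < 10 * C) stop("need at least 10*C records", call. = FALSE)
  local_seed(seed)

  run_em <- function() {
    centres <- kmeanspp_centres(X, C)
    assign <- apply(X, 1, function(r) which.min(colSums((t(centres) - r)^2)))
    w <- pmax(tabulate(assign, C), 1) / n
    mu <- do.call(rbind, lapply(seq_len(C), function(c) {
      rows <- X[assign == c, , drop = FALSE]
      if (nrow(rows)) colMeans(rows) else centres[c, ]
    }))
    Sg <- stats::cov(X) * (n - 1) / n
    covs <- replicate(C, Sg, simplify = FALSE)

    ll_old <- -Inf; trace <- numeric(); n_reg <- 0L
    for (it in seq_len(max_iter)) {
      lp <- vapply(seq_len(C), function(c) {
        log(w[c]) + dmvnorm_log(X, mu[c, ], covs[[c]])
      }, numeric(n))                        # n x C
      row_lse <- apply(lp, 1, logsumexp)
      ll <- sum(row_lse)
      trace <- c(trace, ll)
      r <- exp(lp - row_lse)                # responsibilities
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll_old)) break
      ll_old <- ll
      nk <- colSums(r)
      w <- nk / n
      for (c in seq_len(C)) {
        mu[c, ] <- colSums(r[, c] * X) / nk[c]
        Xc <- sweep(X, 2, mu[c, ])
        S <- crossprod(Xc * r[, c], Xc) / nk[c]
        ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
        if (ev_min < max(1e-6, var_floor)) {
          n_reg <- n_reg + 1L
          S <- S + diag(max(1e-6, var_floor) - ev_min, d)
        }
        covs[[c]] <- (S + t(S)) / 2
      }
    }
    list(weights = w, means = mu, covariances = covs, loglik = ll,
         n_iter = it, loglik_trace = trace, n_regularised = n_reg)
  }

  fits <- lapply(seq_len(max(1L, n_init)), function(i) run_em())
  best <- fits[[which.max(vapply(fits, `[[`, 0, "loglik"))]]
  if (best$n_regularised > 0L) {
    warning("degenerate GMM component(s) regularised (",
            best$n_regularised, " M-step(s) floored)", call. = FALSE)
  }
  best
}

# KL(N(mu0, S0) || N(mu1, S1)), in nats.
gaussian_kl <- function(mu0, S0, mu1, S1) {
  d <- length(mu0)
  R1 <- chol(S1)
  S1inv <- chol2inv(R1)
  R0 <- chol(S0)
  dm <- mu1 - mu0
  0.5 * (sum(S1inv * S0) + sum(dm * (S1inv %*% dm)) - d +
           2 * sum(log(diag(R1))) - 2 * sum(log(diag(R0))))
}

#' Match a GP component to a Gaussian over the frequency grid
#'
#' Finds the cubic mean coefficients and SE-kernel hyperparameters whose
#' finite-dimensional prior at `xs_bark` minimises the (mass-covering)
#' divergence `KL(target || GP + noise)`. The model side is the GP prior
#' plus a fitted non-negative iid diagonal noise variance: target Gaussians
#' estimated from recorded audiograms carry quantisation/measurement noise
#' on their diagonal that a smooth SE kernel cannot (and should not)
#' represent, so it is absorbed by the noise term and discarded from the
#' returned latent-threshold component. Optimisation is quasi-Newton (BFGS)
#' over the mean coefficients and the log hyperparameters; initialisation is
#' a least-squares polynomial fit of the target mean plus a length-scale
#' grid search unless `init` is supplied.
#'
#' @param target_mean,target_cov Target Gaussian (dB-HL / dB^2) on `xs_bark`.
#' @param xs_bark Bark frequencies of the target grid.
#' @param init Optional [gp_component()] used as the starting point.
#' @return A [gp_component()] with attributes `kl` (final divergence, nats),
#'   `noise_variance` (fitted diagonal noise, dB^2) and `convergence` (the
#'   `optim` code).
#' @export
match_gp_to_gaussian <- function(target_mean, target_cov, xs_bark,
                                 init = NULL) {
  d <- length(target_mean)
  # regularise the target exactly like the GP side (1e-8 * marginal
  # variance on the diagonal) so that a perfectly matching GP attains KL 0
  target_cov <- target_cov + diag(1e-8 * max(diag(target_cov)), d)
  R0 <- tryCatch(chol(target_cov), error = function(e) NULL)
  if (is.null(R0)) {                        # singular target: jitter once
    target_cov <- target_cov + diag(1e-6 * max(diag(target_cov)), d)
    R0 <- chol(target_cov)                  # errors if still singular
  }
  z <- xs_bark - bark_centre()
  B <- cbind(1, z, z^2, z^3)

  # par = (4 mean coefficients, log v, log ell, log noise variance)
  kl_par <- function(par) {
    comp <- gp_component(par[1:4], exp(par[5]), exp(par[6]))
    S1 <- se_kernel(xs_bark, xs_bark, comp) +
      diag(1e-8 * comp$kernel_variance + exp(par[7]), d)
    kl <- tryCatch(gaussian_kl(target_mean, target_cov, B %*% par[1:4], S1),
                   error = function(e) NA_real_)
    if (!is.finite(kl)) 1e10 else kl
  }

  v0 <- mean(diag(target_cov))
  ev_min <- min(eigen(target_cov, symmetric = TRUE, only.values = TRUE)$values)
  s0 <- log(max(ev_min, 1e-8 * v0))
  if (is.null(init)) {
    coef0 <- unname(stats::lsfit(B, target_mean, intercept = FALSE)$coefficients)
    ells <- seq(0.5, 10, by = 0.5)
    kl0 <- vapply(ells, function(l) kl_par(c(coef0, log(v0), log(l), s0)), 0)
    par0 <- c(coef0, log(v0), log(ells[which.min(kl0)]), s0)
  } else {
    par0 <- c(init$mean_coeffs, log(init$kernel_variance),
              log(init$kernel_lengthscale), s0)
  }
  opt <- stats::optim(par0, kl_par, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  # polish: BFGS with numeric gradients can stall short of the optimum
  opt2 <- stats::optim(opt$par, kl_par, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-14))
  if (opt2$value < opt$value) opt <- opt2
  out <- gp_component(unname(opt$par[1:4]), unname(exp(opt$par[5])),
                      unname(exp(opt$par[6])))
  attr(out, "kl") <- opt$value
  attr(out, "noise_variance") <- unname(exp(opt$par[7]))
  attr(out, "convergence") <- opt$convergence
  out
}

#' Side-information mixing-weight table from responsibilities
#'
#' For every record, computes the posterior responsibility of each fitted
#' component given the record's tabulated thresholds (marginal Gaussian on
#' the record's defined frequencies, so incomplete records contribute), then
#' averages responsibilities within each (5-year age bucket, gender) key.
#' The `"unspecified|unspecified"` entry stores the supplied marginal
#' weights, keeping step 3 consistent with the EM mixture weights.
#'
#' The marginal density of a recorded threshold is the GP prior plus the
#' component's observation-noise variance (quantisation/measurement noise,
#' the `noise_variance` attribute set by [match_gp_to_gaussian()]). Without
#' it, recorded audiograms sit off the smooth prior manifold and the
#' responsibilities degenerate to one-hot vectors driven by the prior's
#' near-null eigenvalues rather than by curve shape.
#'
#' @param dataset An [audiogram_dataset()].
#' @param components List of fitted [gp_component()] objects.
#' @param weights Marginal mixing weights (simplex, length C).
#' @param noise_variance Per-component observation-noise variance, dB^2;
#'   defaults to each component's `noise_variance` attribute (0 if unset).
#' @return An [alpha_table()].
#' @export
build_alpha_table <- function(dataset, components, weights,
                              noise_variance = NULL) {
  if (is.null(noise_variance)) {
    noise_variance <- vapply(components, function(cc) {
      nv <- attr(cc, "noise_variance")
      if (is.null(nv)) 0 else nv
    }, 0)
  }
  noise_variance <- rep_len(noise_variance, length(components))
  df <- as.data.frame(dataset)
  if (!nrow(df)) stop("empty dataset", call. = FALSE)
  C <- length(components)
  freqs <- standard_frequencies()
  xb <- bark(freqs)
  fcols <- paste0("f", freqs)

  resp <- matrix(NA_real_, nrow(df), C)
  for (i in seq_len(nrow(df))) {
    t_i <- as.numeric(df[i, fcols])
    def <- which(!is.na(t_i))
    lp <- vapply(seq_len(C), function(c) {
      pr <- component_prior_at(components[[c]], xb[def])
      S <- pr$cov + diag(noise_variance[c], length(def))
      log(weights[c]) + dmvnorm_log(t_i[def], pr$mean, S)
    }, 0)
    resp[i, ] <- exp(lp - logsumexp(lp))
  }

  keys <- vapply(seq_len(nrow(df)), function(i) {
    alpha_key(list(age = df$age[i], gender = as.character(df$gender[i])))
  }, "")
  entries <- lapply(split(seq_len(nrow(df)), keys), function(rows) {
    w <- colMeans(resp[rows, , drop = FALSE])
    w / sum(w)
  })
  entries[["unspecified|unspecified"]] <- weights / sum(weights)
  alpha_table(entries)
}

#' Fit the full hearing-threshold mixture model
#'
#' Composes the three learning steps: complete-case EM ([fit_gmm()]),
#' per-component KL matching ([match_gp_to_gaussian()]), and the
#' side-information table ([build_alpha_table()], which also uses incomplete
#' records). Stage diagnostics (dropped-record count, EM log-likelihood,
#' per-component final KL) are reported via `message()`.
#'
#' @param dataset An [audiogram_dataset()].
#' @param C Number of mixture components.
#' @param sigma_p Perceptual-noise SD to store in the model, dB (default 5;
#'   not learnable from audiograms alone).
#' @param n_init EM restarts (default 5).
#' @param seed Optional integer seed (local to this call).
#' @return A [mixture_model()] with a `diagnostics` attribute.
#' @export
fit_model <- function(dataset, C, sigma_p = 5, n_init = 5, seed = NULL) {
  local_seed(seed)
  df <- as.data.frame(dataset)
  fcols <- paste0("f", standard_frequencies())
  X <- as.matrix(df[, fcols])
  complete <- stats::complete.cases(X)
  if (any(!complete)) {
    message(sum(!complete), " incomplete record(s) dropped for EM; ",
            "all records used for the mixing-weight table")
  }
  gmm <- fit_gmm(X[complete, , drop = FALSE], C, n_init = n_init)
  message("EM: loglik ", signif(gmm$loglik, 8), " after ", gmm$n_iter,
          " iterations")
  xb <- bark(standard_frequencies())
  comps <- lapply(seq_len(C), function(c) {
    comp <- match_gp_to_gaussian(gmm$means[c, ], gmm$covariances[[c]], xb)
    message("component ", c, ": KL = ", signif(attr(comp, "kl"), 4))
    comp
  })
  alpha <- build_alpha_table(dataset, comps, gmm$weights)
  model <- mixture_model(comps, alpha, sigma_p)
  attr(model, "diagnostics") <- list(
    gmm_loglik = gmm$loglik,
    gmm_weights = gmm$weights,
    kl = vapply(comps, attr, 0, "kl"),
    noise_variance = vapply(comps, attr, 0, "noise_variance"),
    n_dropped = sum(!complete))
  model
}
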