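## Posterior inference for the probit-GP mixture.
##
## Each mixture component is a GP probit classifier: the latent threshold at
## the distinct trial frequencies gets a Laplace approximation (the probit
## log-likelihood is concave, so the log-posterior is strictly concave and
## Newton's method converges), an evidence estimate, and GP conditioning for
## predictions at new frequencies. Components are combined with posterior
## mixing weights pi_c proportional to alpha_c(I) * Z_c.

#' Laplace posterior for one GP component
#'
#' Fits the Gaussian (Laplace) approximation of the posterior over the latent
#' threshold values at the distinct trial frequencies, under one mixture
#' component and the probit response model. Trials at the same frequency
#' share a latent value. With zero trials the posterior is the prior and the
#' log-evidence is exactly 0.
#'
#' The log-evidence is the standard Laplace estimate
#' `loglik(mode) + logprior(mode) + (n/2) log(2*pi) - 0.5 * logdet(H)` with
#' `H` the negative Hessian of the log-posterior at the mode.
#'
#' @param component A [gp_component()].
#' @param trial_tab Trial data frame from [trials()] (may have zero rows).
#' @param sigma_p Perceptual-noise SD, dB.
#' @return An object of class `component_posterior` with fields
#'   `xs` (distinct Bark frequencies), `mode` (posterior mode, dB-HL),
#'   `cov` (Laplace covariance, dB^2), `log_evidence`, and internals used by
#'   [predict_threshold_component()].
#' @export
laplace_fit_component <- function(component, trial_tab, sigma_p) {
  check_sigma_p(sigma_p)
  n_tr <- nrow(trial_tab)
  if (is.null(n_tr) || n_tr == 0L) {
    return(structure(list(xs = numeric(), mode = numeric(),
                          cov = matrix(0, 0, 0), log_evidence = 0,
                          component = component, sigma_p = sigma_p),
                     class = "component_posterior"))
  }
  x_all <- bark(trial_tab$frequency_hz)
  xs <- sort(unique(x_all))
  idx <- match(x_all, xs)                   # trial i -> latent j
  n <- length(xs)
  h <- trial_tab$intensity_db
  y <- trial_tab$response

  pr <- component_prior_at(component, xs)
  m <- pr$mean
  R <- chol_jitter(pr$cov)                  # K = R'R (jittered)
  Kinv <- chol2inv(R)

  loglik_terms <- function(t) {
    z <- y * (h - t[idx]) / sigma_p
    lPhi <- stats::pnorm(z, log.p = TRUE)
    r <- exp(stats::dnorm(z, log = TRUE) - lPhi)     # phi/Phi, stable
    grad <- vapply(seq_len(n), function(j) {
      sel <- idx == j
      -sum(y[sel] * r[sel]) / sigma_p
    }, 0)
    W <- vapply(seq_len(n), function(j) {
      sel <- idx == j
      sum(r[sel]^2 + z[sel] * r[sel]) / sigma_p^2
    }, 0)
    W <- pmax(W, 0)                         # concavity; clamp fp noise
    list(ll = sum(lPhi), grad = grad, W = W)
  }
  log_post <- function(t, ll) ll - 0.5 * sum((t - m) * (Kinv %*% (t - m)))

  t <- m
  lt <- loglik_terms(t)
  obj <- log_post(t, lt$ll)
  converged <- FALSE
  for (iter in seq_len(100L)) {
    g <- lt$grad - drop(Kinv %*% (t - m))
    if (sqrt(sum(g^2)) < 1e-8) { converged <- TRUE; break }
    H <- Kinv + diag(lt$W, n)
    step <- solve(H, g)
    alpha_ls <- 1
    repeat {                                # backtracking line search
      t_new <- t + alpha_ls * step
      lt_new <- loglik_terms(t_new)
      obj_new <- log_post(t_new, lt_new$ll)
      if (obj_new >= obj - 1e-12 || alpha_ls < 1e-8) break
      alpha_ls <- alpha_ls / 2
    }
    # fp noise floor: the accepted update no longer moves the iterate
    if (max(abs(t_new - t)) < 1e-9) { t <- t_new; lt <- lt_new
      converged <- TRUE; break }
    t <- t_new; lt <- lt_new; obj <- obj_new
  }
  if (!converged) {
    g <- lt$grad - drop(Kinv %*% (t - m))
    if (sqrt(sum(g^2)) >= 1e-6) {
      cond <- simpleError("Laplace Newton iteration did not converge")
      cond$last_iterate <- t
      stop(cond)
    }
  }
  H <- Kinv + diag(lt$W, n)
  RH <- chol(H)
  cov <- chol2inv(RH)
  log_det_H <- 2 * sum(log(diag(RH)))
  log_prior_mode <- -0.5 * sum((t - m) * (Kinv %*% (t - m))) -
    sum(log(diag(R))) - (n / 2) * log(2 * pi)
  log_evidence <- lt$ll + log_prior_mode + (n / 2) * log(2 * pi) -
    0.5 * log_det_H

  structure(list(xs = xs, mode = t, cov = cov, log_evidence = log_evidence,
                 component = component, sigma_p = sigma_p,
                 prior_mean = m, Kinv = Kinv,
                 kalpha = drop(Kinv %*% (t - m))),
            class = "component_posterior")
}

#' Predictive threshold distribution of one component
#'
#' GP-conditions the Laplace posterior from the trial frequencies to new
#' frequencies. With zero trials this is the component prior marginal.
#'
#' @param post A `component_posterior` from [laplace_fit_component()].
#' @param x Bark frequencies (vectorised).
#' @return List with `mean` (dB-HL) and `sd` (dB), each `length(x)`.
#' @export
predict_threshold_component <- function(post, x) {
  comp <- post$component
  if (!length(post$xs)) {
    return(list(mean = component_mean(comp, x),
                sd = rep(sqrt(comp$kernel_variance), length(x))))
  }
  kx <- se_kernel(post$xs, x, comp)                      # n x m
  if (is.null(dim(kx))) kx <- matrix(kx, nrow = length(post$xs))
  mu <- component_mean(comp, x) + drop(crossprod(kx, post$kalpha))
  A <- post$Kinv %*% kx                                  # K^-1 k*
  v_prior <- rep(comp$kernel_variance, length(x))
  v <- v_prior - colSums(kx * A) + colSums(A * (post$cov %*% A))
  list(mean = mu, sd = sqrt(pmax(v, 1e-12)))
}

#' Full mixture posterior from a trial collection
#'
#' Fits all C component posteriors by [laplace_fit_component()] and combines
#' them with weights `pi_c` proportional to `alpha_c(I) * Z_c`, computed in
#' log space with log-sum-exp normalisation. Refitting from the full trial
#' list means sequential and batch updating coincide exactly.
#'
#' @param model A [mixture_model()].
#' @param info A [side_info()]; conditions the prior mixing weights.
#' @param trial_tab Trial data frame from [trials()] (may be empty).
#' @return An object of class `posterior_state` with fields `model`, `info`,
#'   `trials`, `component_posteriors`, `pi`, `log_pi`.
#' @export
posterior_mixture <- function(model, info = side_info(),
                              trial_tab = trials()) {
  alpha <- mixing_weights(model, info)
  posts <- lapply(model$components, laplace_fit_component,
                  trial_tab = trial_tab, sigma_p = model$sigma_p)
  log_z <- vapply(posts, `[[`, 0, "log_evidence")
  log_pi_un <- log(alpha) + log_z
  log_pi <- log_pi_un - logsumexp(log_pi_un)
  structure(list(model = model, info = info, trials = trial_tab,
                 component_posteriors = posts,
                 pi = exp(log_pi), log_pi = log_pi),
            class = "posterior_state")
}

#' @export
print.posterior_state <- function(x, ...) {
  cat("Posterior state:", nrow(x$trials), "trials, pi = [",
      paste(signif(x$pi, 3), collapse = ", "), "]\n")
  invisible(x)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# mu_c(x), sigma_c(x) for every component at Bark frequencies x.
# Returns C x length(x) matrices.
state_component_predictions <- function(state, x_bark) {
  preds <- lapply(state$component_posteriors, predict_threshold_component,
                  x = x_bark)
  list(mean = do.call(rbind, lapply(preds, `[[`, "mean")),
       sd = do.call(rbind, lapply(preds, `[[`, "sd")))
}

#' Posterior predictive probability of an audible response
#'
#' `P(y = +1 | f, h, D) = sum_c pi_c * pnorm((h - mu_c) / sqrt(sigma_p^2 +
#' sigma_c^2))`, the probit-Gaussian convolution of each component's
#' predictive threshold distribution.
#'
#' @param state A [posterior_mixture()] result.
#' @param frequency_hz Stimulus frequency, Hz (scalar).
#' @param intensity_db Stimulus intensity, dB-HL (vectorised).
#' @return Probability of `y = +1`, in (0, 1).
#' @export
posterior_predictive_response <- function(state, frequency_hz, intensity_db) {
  p <- state_component_predictions(state, bark(frequency_hz))
  sp2 <- state$model$sigma_p^2
  drop(colSums(state$pi * stats::pnorm(
    outer(drop(p$mean), intensity_db, function(mu, h) h - mu) /
      sqrt(sp2 + drop(p$sd)^2))))
}

#' Posterior hearing-threshold estimate
#'
#' Mixture mean and standard deviation of the threshold at the requested
#' frequencies, together with the per-component predictive curves. The
#' mixture variance follows the law of total variance.
#'
#' @param state A [posterior_mixture()] result.
#' @param frequencies_hz Frequencies (Hz) at which to evaluate.
#' @return List with `frequency_hz`, `mean`, `sd` (vectors), and
#'   `component_mean`, `component_sd` (C x n matrices), `pi`.
#' @export
posterior_threshold_estimate <- function(state,
                                         frequencies_hz = standard_frequencies()) {
  p <- state_component_predictions(state, bark(frequencies_hz))
  pi <- state$pi
  mean <- drop(crossprod(p$mean, pi))
  # law of total variance in its centred, cancellation-free form
  v <- drop(crossprod(p$sd^2 + sweep(p$mean, 2, mean)^2, pi))
  list(frequency_hz = frequencies_hz, mean = mean,
       sd = sqrt(pmax(v, 0)),
       component_mean = p$mean, component_sd = p$sd, pi = pi)
}

#' Posterior log-likelihood of an audiogram
#'
#' Sum over frequencies of the log marginal mixture density of the tabulated
#' threshold: `sum_x log sum_c pi_c * dnorm(t_x; mu_c(x), sigma_c(x)^2)`,
#' evaluated in log space. This is the predictive-accuracy score used to
#' compare fitted models on held-out audiograms.
#'
#' @param state A [posterior_mixture()] result.
#' @param thresholds Threshold values, dB-HL.
#' @param frequencies_hz Frequencies (Hz) of the thresholds (same length).
#' @return Scalar log-likelihood.
#' @export
posterior_log_likelihood <- function(state, thresholds, frequencies_hz) {
  stopifnot(length(thresholds) == length(frequencies_hz))
  p <- state_component_predictions(state, bark(frequencies_hz))
  lp <- sweep(stats::dnorm(sweep(-p$mean, 2, thresholds, "+"),
                           sd = p$sd, log = TRUE),
              1, state$log_pi, "+")
  sum(apply(lp, 2, logsumexp))
}
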