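test_that("zero trials reproduce the prior with unit evidence", {
  comp <- gp_component(c(30, 5, -0.2, 0), 64, 4)
  post <- laplace_fit_component(comp, trials(), 5)
  expect_equal(post$log_evidence, 0)
  p <- predict_threshold_component(post, bark(c(250, 1000, 6000)))
  pr <- component_prior_at(comp, bark(c(250, 1000, 6000)))
  expect_equal(p$mean, pr$mean)
  expect_equal(p$sd, rep(8, 3))
  st <- posterior_mixture(toy_model(alpha = c(0.3, 0.7)))
  expect_equal(st$pi, c(0.3, 0.7), tolerance = 1e-12)
  expect_equal(posterior_mixture(toy_model1())$pi, 1)
})

test_that("Laplace evidence tracks quadrature and improves with bracketing", {
  # The Laplace evidence of a probit-GP is biased low for a lone trial at the
  # prior mean (the posterior is skewed); bracketing trials symmetrise the
  # posterior and the estimate tightens by an order of magnitude.
  comp <- gp_component(c(30, 0, 0, 0), 100, 4)
  one <- trials(1000, 30, 1L)
  post1 <- laplace_fit_component(comp, one, 5)
  q1 <- log(evidence_quadrature(comp, one, 5))
  expect_lt(abs(post1$log_evidence - q1), 0.05)
  two <- trials(c(1000, 1000), c(35, 25), c(1L, -1L))
  post2 <- laplace_fit_component(comp, two, 5)
  q2 <- log(evidence_quadrature(comp, two, 5))
  expect_lt(abs(post2$log_evidence - q2), 0.01)
  expect_lt(abs(post2$log_evidence - q2), abs(post1$log_evidence - q1))
  # tighter prior: single-trial evidence already at the 1e-2 scale
  comp_sd6 <- gp_component(c(30, 0, 0, 0), 36, 4)
  post3 <- laplace_fit_component(comp_sd6, one, 5)
  expect_lt(abs(post3$log_evidence - log(evidence_quadrature(comp_sd6, one, 5))),
            0.03)
})

test_that("an audible trial above the prior mean pulls the mode down", {
  comp <- gp_component(c(30, 0, 0, 0), 100, 4)
  post <- laplace_fit_component(comp, trials(1000, 45, 1L), 5)
  expect_lte(post$mode, 30)
  # and an inaudible trial below the mean pushes it up
  post2 <- laplace_fit_component(comp, trials(1000, 15, -1L), 5)
  expect_gte(post2$mode, 30)
})

test_that("duplicate-frequency trials share one latent value", {
  comp <- gp_component(c(30, 0, 0, 0), 100, 4)
  tr <- trials(c(1000, 1000, 1000), c(25, 35, 30), c(1L, -1L, 1L))
  post <- laplace_fit_component(comp, tr, 5)
  expect_length(post$mode, 1)
  expect_length(post$xs, 1)
})

test_that("posterior mixing weights match brute-force quadrature", {
  model <- toy_model(alpha = c(0.4, 0.6))
  tr <- trials(c(1000, 2000), c(30, 45), c(1L, -1L))
  st <- posterior_mixture(model, trial_tab = tr)
  z <- vapply(model$components, function(cc) {
    evidence_quadrature(cc, tr, model$sigma_p)
  }, 0)
  pi_oracle <- c(0.4, 0.6) * z / sum(c(0.4, 0.6) * z)
  expect_equal(st$pi, pi_oracle, tolerance = 0.02)
  expect_equal(sum(st$pi), 1, tolerance = 1e-10)
})

test_that("predictions at trial frequencies equal stored posterior entries", {
  comp <- gp_component(c(30, 5, 0, 0), 64, 4)
  tr <- trials(c(500, 2000), c(20, 50), c(-1L, 1L))
  post <- laplace_fit_component(comp, tr, 5)
  p <- predict_threshold_component(post, post$xs)
  # agreement is limited by the stabilising jitter on the prior Cholesky
  expect_equal(p$mean, post$mode, tolerance = 1e-6)
  expect_equal(p$sd, sqrt(diag(post$cov)), tolerance = 1e-6)
})

test_that("predictions far from all trials revert to the prior", {
  comp <- gp_component(c(30, 0, 0, 0), 64, 2)
  post <- laplace_fit_component(comp, trials(8000, 40, 1L), 5)
  p <- predict_threshold_component(post, bark(125))   # ~18 Bark away
  expect_equal(p$mean, 30, tolerance = 0.3)           # within 1 %
  expect_equal(p$sd, 8, tolerance = 0.08)
})

test_that("posterior predictive response equals the probit-Gaussian closed form", {
  model <- toy_model(alpha = c(0.35, 0.65))
  tr <- trials(c(1000, 4000, 1000), c(25, 60, 35), c(1L, -1L, -1L))
  st <- posterior_mixture(model, trial_tab = tr)
  for (f in c(250, 1000, 3000)) {
    for (h in c(10, 30, 55)) {
      p_pkg <- posterior_predictive_response(st, f, h)
      # oracle: mixture of exact 1-D Gaussian integrals of the probit
      preds <- lapply(st$component_posteriors, predict_threshold_component,
                      x = bark(f))
      p_or <- sum(vapply(seq_along(preds), function(c) {
        st$pi[c] * gh_integral(function(t) pnorm((h - t) / model$sigma_p),
                               preds[[c]]$mean, preds[[c]]$sd)
      }, 0))
      expect_equal(p_pkg, p_or, tolerance = 1e-6)
    }
  }
  # at the single-component posterior mean the predictive is one half
  st1 <- posterior_mixture(toy_model1(), trial_tab = trials(1000, 30, 1L))
  mu1 <- predict_threshold_component(st1$component_posteriors[[1]],
                                     bark(1000))$mean
  expect_equal(posterior_predictive_response(st1, 1000, mu1), 0.5,
               tolerance = 1e-12)
})

test_that("mixture threshold estimate obeys the law of total variance", {
  # two flat components with predictive means 0 and 10 dB, unit SDs
  m <- mixture_model(list(gp_component(c(0, 0, 0, 0), 1, 4),
                          gp_component(c(10, 0, 0, 0), 1, 4)),
                     alpha_table(list("unspecified|unspecified" = c(0.5, 0.5))),
                     5)
  est <- posterior_threshold_estimate(posterior_mixture(m), 1000)
  expect_equal(est$mean, 5)
  expect_equal(est$sd, sqrt(26), tolerance = 1e-12)
  # C = 1: mean and sd are the component's own
  st1 <- posterior_mixture(toy_model1())
  est1 <- posterior_threshold_estimate(st1, c(500, 2000))
  expect_equal(est1$mean, drop(est1$component_mean))
  expect_equal(est1$sd, drop(est1$component_sd))
  # two identical components: mixture mean independent of the weights
  m2 <- mixture_model(list(gp_component(c(15, 1, 0, 0), 25, 4),
                           gp_component(c(15, 1, 0, 0), 25, 4)),
                      alpha_table(list("unspecified|unspecified" = c(0.9, 0.1))),
                      5)
  est2 <- posterior_threshold_estimate(posterior_mixture(m2), c(250, 4000))
  expect_equal(est2$mean, drop(est2$component_mean[1, ]))
})

test_that("posterior log-likelihood matches direct density evaluation", {
  model <- toy_model(alpha = c(0.45, 0.55))
  tr <- trials(c(500, 2000), c(25, 50), c(1L, -1L))
  st <- posterior_mixture(model, trial_tab = tr)
  freqs <- c(250, 1000, 6000)
  tvals <- c(22, 35, 48)
  ll_pkg <- posterior_log_likelihood(st, tvals, freqs)
  ll_direct <- 0
  for (i in seq_along(freqs)) {
    dens <- 0
    for (c in 1:2) {
      p <- predict_threshold_component(st$component_posteriors[[c]],
                                       bark(freqs[i]))
      dens <- dens + st$pi[c] * dnorm(tvals[i], p$mean, p$sd)
    }
    ll_direct <- ll_direct + log(dens)
  }
  expect_equal(ll_pkg, ll_direct, tolerance = 1e-10)
  # C = 1 closed form at the posterior mean
  st1 <- posterior_mixture(toy_model1())
  est <- posterior_threshold_estimate(st1, freqs)
  expect_equal(posterior_log_likelihood(st1, est$mean, freqs),
               -sum(log(est$sd * sqrt(2 * pi))), tolerance = 1e-10)
  # moving the audiogram away from the posterior mean lowers the score
  expect_lt(posterior_log_likelihood(st1, est$mean + 15, freqs),
            posterior_log_likelihood(st1, est$mean, freqs))
})

test_that("sequential refits equal batch fits and uncertainty contracts", {
  model <- toy_model(alpha = c(0.5, 0.5))
  tr <- trials(c(1000, 2000, 1000, 4000), c(30, 45, 20, 60),
               c(1L, -1L, 1L, -1L))
  st_batch <- posterior_mixture(model, trial_tab = tr)
  st_seq <- posterior_mixture(model, trial_tab = trials())
  for (i in seq_len(nrow(tr))) {
    st_seq <- posterior_mixture(model, trial_tab = tr[seq_len(i), ])
  }
  expect_equal(st_seq$pi, st_batch$pi)
  expect_equal(st_seq$component_posteriors[[1]]$mode,
               st_batch$component_posteriors[[1]]$mode)
  # posterior SD at a repeatedly probed frequency shrinks on average
  sd_at <- function(n) {
    mean(replicate(10, {
      y <- sample_response(rep(30, n), rep(28, n), 5)
      st <- posterior_mixture(model,
                              trial_tab = trials(rep(1000, n), rep(30, n), y))
      posterior_threshold_estimate(st, 1000)$sd
    }))
  }
  set.seed(31)
  expect_lt(sd_at(8), sd_at(2))
  expect_lt(sd_at(2), posterior_threshold_estimate(
    posterior_mixture(model), 1000)$sd)
})
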