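test_that("binary entropy has the textbook values and domain", {
  expect_equal(binary_entropy(0.5), 1)
  expect_equal(binary_entropy(c(0, 1)), c(0, 0))
  expect_equal(binary_entropy(0.25), -0.25 * log2(0.25) - 0.75 * log2(0.75))
  expect_equal(binary_entropy(0.25), 0.8112781, tolerance = 1e-7)
  expect_error(binary_entropy(-0.1), "0, 1")
  expect_error(binary_entropy(1.2), "0, 1")
  p <- seq(0.01, 0.99, by = 0.01)
  expect_equal(binary_entropy(p), binary_entropy(1 - p))   # symmetry
})

test_that("certain stimuli carry no information", {
  st <- posterior_mixture(toy_model(alpha = c(0.5, 0.5)))
  # far above every component mean: the response is certainly audible
  expect_lt(bald_objective(st, 1000, 200), 1e-4)
  expect_lt(bald_objective(st, 1000, -150), 1e-4)
})

test_that("closed-form BALD terms match quadrature of their defining integrals", {
  st <- posterior_mixture(toy_model(alpha = c(0.3, 0.7)),
                          trial_tab = trials(1000, 30, 1L))
  sp <- st$model$sigma_p
  K <- sp * sqrt(pi * log(2) / 2)
  for (f in c(500, 2000)) {
    preds <- lapply(st$component_posteriors, predict_threshold_component,
                    x = bark(f))
    for (h in c(10, 25, 40)) {
      # predictive term: mixture of probit-Gaussian convolutions
      pred_or <- sum(vapply(1:2, function(c) {
        st$pi[c] * gauss_integral(function(t) pnorm((h - t) / sp),
                                  preds[[c]]$mean, preds[[c]]$sd)
      }, 0))
      # exponential surrogate term, integrated directly
      exp_or <- sum(vapply(1:2, function(c) {
        st$pi[c] * gauss_integral(function(t) exp(-(h - t)^2 / (2 * K^2)),
                                  preds[[c]]$mean, preds[[c]]$sd)
      }, 0))
      expect_equal(bald_objective(st, f, h),
                   binary_entropy(pred_or) - exp_or, tolerance = 1e-6)
    }
  }
})

test_that("BALD matches a Monte-Carlo mutual information estimate at C = 1", {
  set.seed(77)
  st <- posterior_mixture(toy_model1())
  p <- predict_threshold_component(st$component_posteriors[[1]], bark(1000))
  sp <- st$model$sigma_p
  for (h in c(p$mean, p$mean + 6)) {
    t_draws <- rnorm(2e5, p$mean, p$sd)
    probs <- pnorm((h - t_draws) / sp)
    mi_mc <- h2(mean(probs)) - mean(h2(probs))
    expect_equal(bald_objective(st, 1000, h), mi_mc, tolerance = 0.02)
  }
})

test_that("mutual information is symmetric between threshold and response", {
  # H[t] - E H[t|y] vs H[y] - E H[y|t] on a one-point problem, both by MC
  set.seed(5)
  mu <- 30; sd <- 8; sp <- 5; h <- 32
  n <- 2e5
  t_draws <- rnorm(n, mu, sd)
  p_aud <- pnorm((h - t_draws) / sp)
  # response side
  mi_y <- h2(mean(p_aud)) - mean(h2(p_aud))
  # threshold side: differential entropies by plug-in density estimates
  y <- ifelse(runif(n) < p_aud, 1, -1)
  ent <- function(x) {                 # differential entropy in bits
    d <- density(x, n = 2048)
    dx <- diff(d$x[1:2])
    -sum(d$y * log2(pmax(d$y, 1e-300))) * dx
  }
  mi_t <- ent(t_draws) - (mean(y == 1) * ent(t_draws[y == 1]) +
                            mean(y == -1) * ent(t_draws[y == -1]))
  expect_equal(mi_y, mi_t, tolerance = 0.03)
})

test_that("grid search returns the argmax with deterministic tie-breaks", {
  st <- posterior_mixture(toy_model(alpha = c(0.5, 0.5)),
                          trial_tab = trials(2000, 40, 1L))
  grid <- stimulus_grid()
  sel <- select_stimulus(st, grid)
  # independent re-evaluation over a shuffled enumeration of the grid
  set.seed(12)
  combos <- expand.grid(f = grid$frequencies, h = grid$intensities)
  combos <- combos[sample(nrow(combos)), ]
  combos$v <- mapply(function(f, h) bald_objective(st, f, h),
                     combos$f, combos$h)
  top <- combos[combos$v >= max(combos$v) - 1e-12, ]
  top <- top[order(top$f, top$h), ][1, ]
  expect_equal(sel$frequency_hz, top$f)
  expect_equal(sel$intensity_db, top$h)
  expect_equal(sel$objective, max(combos$v), tolerance = 1e-12)
})

test_that("exchangeable frequencies tie-break to the lowest", {
  # constant mean + stationary kernel + zero trials: the objective column is
  # bitwise identical at every frequency, so the tie must resolve low
  flat <- mixture_model(list(gp_component(c(30, 0, 0, 0), 64, 4)),
                        alpha_table(list("unspecified|unspecified" = 1)),
                        sigma_p = 5)
  st <- posterior_mixture(flat)
  grid <- stimulus_grid()
  expect_identical(bald_objective(st, 125, grid$intensities),
                   bald_objective(st, 4000, grid$intensities))
  sel <- select_stimulus(st, grid)
  expect_equal(sel$frequency_hz, 125)
  v <- bald_objective(st, 125, grid$intensities)
  expect_equal(sel$intensity_db, grid$intensities[which.max(v)])
})

test_that("BALD objective is non-negative over a sane grid", {
  st <- posterior_mixture(toy_model(alpha = c(0.4, 0.6)),
                          trial_tab = trials(c(1000, 4000), c(25, 55),
                                             c(1L, -1L)))
  grid <- stimulus_grid()
  worst <- Inf
  for (f in grid$frequencies) {
    worst <- min(worst, bald_objective(st, f, grid$intensities))
  }
  expect_gt(worst, -1e-9)
})

test_that("fast selection maximises the moment-matched variance", {
  st <- posterior_mixture(toy_model(alpha = c(0.5, 0.5)),
                          trial_tab = trials(1000, 30, 1L))
  grid <- stimulus_grid()
  sel <- select_stimulus_fast(st, grid)
  est <- posterior_threshold_estimate(st, grid$frequencies)
  j <- which.max(est$sd^2)
  expect_equal(sel$frequency_hz, grid$frequencies[j])
  expect_equal(sel$intensity_db,
               grid$intensities[which.min(abs(grid$intensities - est$mean[j]))])
  # C = 1, zero trials, stationary kernel: variance is flat, tie-break low
  st1 <- posterior_mixture(toy_model1())
  sel1 <- select_stimulus_fast(st1, grid)
  expect_equal(sel1$frequency_hz, 125)
  # and the chosen intensity snaps to the prior mean at 125 Hz
  mu125 <- posterior_threshold_estimate(st1, 125)$mean
  expect_equal(sel1$intensity_db,
               grid$intensities[which.min(abs(grid$intensities - mu125))])
})
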