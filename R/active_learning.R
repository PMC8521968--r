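## Optimal stimulus selection by greedy expected-information-gain
## maximisation (Bayesian active learning by disagreement) under the mixture
## posterior. Entropies are in bits throughout.

#' Binary entropy (bits)
#'
#' `-p log2 p - (1 - p) log2 (1 - p)` with the convention `0 log 0 = 0`.
#'
#' @param p Probability in \[0, 1\]. Vectorised.
#' @return Entropy in bits.
#' @export
binary_entropy <- function(p) {
  if (any(!is.finite(p)) || any(p < -1e-12) || any(p > 1 + 1e-12)) {
    stop("`p` must lie in [0, 1]", call. = FALSE)
  }
  p <- pmin(pmax(p, 0), 1)
  q <- 1 - p
  out <- numeric(length(p))
  ok <- p > 0 & p < 1
  out[ok] <- -p[ok] * log2(p[ok]) - q[ok] * log2(q[ok])
  out
}

# K = sigma_p * sqrt(pi * ln 2 / 2): the width that makes the squared
# exponential approximation of the binary entropy of the probit integrate in
# closed form against a Gaussian.
bald_constant <- function(sigma_p) {
  check_sigma_p(sigma_p)
  sigma_p * sqrt(pi * log(2) / 2)
}

#' Feasible stimulus grid
#'
#' @param frequencies Candidate frequencies, Hz. Default: the 11 standard
#'   audiometric frequencies.
#' @param intensities Candidate intensities, dB-HL. Default: -20 to 120 dB-HL
#'   in 5 dB steps, matching the resolution of clinical audiograms.
#' @return An object of class `stimulus_grid` (sorted ascending).
#' @export
stimulus_grid <- function(frequencies = standard_frequencies(),
                          intensities = seq(-20, 120, by = 5)) {
  if (!length(frequencies) || !length(intensities)) {
    stop("grid must be non-empty", call. = FALSE)
  }
  structure(list(frequencies = sort(unique(as.numeric(frequencies))),
                 intensities = sort(unique(as.numeric(intensities)))),
            class = "stimulus_grid")
}

# BALD objective for all intensities at one frequency, given the component
# predictive moments mu (length C) and sd (length C) there.
bald_at <- function(pi, mu, sd, sigma_p, intensities) {
  s2 <- sd^2
  pred <- drop(crossprod(
    stats::pnorm(outer(-mu, intensities, "+") / sqrt(sigma_p^2 + s2)), pi))
  K <- bald_constant(sigma_p)
  expterm <- drop(crossprod(
    exp(-outer(-mu, intensities, "+")^2 / (2 * (s2 + K^2))),
    pi * K / sqrt(s2 + K^2)))
  binary_entropy(pred) - expterm
}

#' Expected information gain of a stimulus (BALD)
#'
#' Mutual information (bits) between the binary response to the stimulus and
#' the latent hearing threshold under the current mixture posterior:
#' the binary entropy of the posterior predictive response minus the
#' expected response entropy, the latter via the squared-exponential
#' approximation of the binary entropy of the probit.
#'
#' @param state A [posterior_mixture()] result.
#' @param frequency_hz Stimulus frequency, Hz (scalar).
#' @param intensity_db Stimulus intensity, dB-HL (vectorised).
#' @return Expected information gain in bits (non-negative up to the
#'   approximation error of the exponential entropy surrogate).
#' @export
bald_objective <- function(state, frequency_hz, intensity_db) {
  p <- state_component_predictions(state, bark(frequency_hz))
  bald_at(state$pi, drop(p$mean), drop(p$sd), state$model$sigma_p,
          intensity_db)
}

#' Select the most informative stimulus (full grid search)
#'
#' Exhaustively evaluates [bald_objective()] over the grid and returns the
#' argmax. Ties break to the lowest frequency, then the lowest intensity
#' (the grid is evaluated in sorted order and only strict improvements are
#' kept).
#'
#' @param state A [posterior_mixture()] result.
#' @param grid A [stimulus_grid()].
#' @return List with `frequency_hz`, `intensity_db`, `objective` (bits).
#' @export
select_stimulus <- function(state, grid = stimulus_grid()) {
  best <- list(frequency_hz = NA_real_, intensity_db = NA_real_,
               objective = -Inf)
  for (f in grid$frequencies) {
    p <- state_component_predictions(state, bark(f))
    obj <- bald_at(state$pi, drop(p$mean), drop(p$sd), state$model$sigma_p,
                   grid$intensities)
    j <- which.max(obj)
    if (obj[j] > best$objective) {
      best <- list(frequency_hz = f, intensity_db = grid$intensities[j],
                   objective = obj[j])
    }
  }
  best
}

#' Select a stimulus by single-Gaussian moment matching (fast variant)
#'
#' Approximates the mixture posterior at each grid frequency by a single
#' Gaussian through moment matching. The chosen frequency is the one with
#' the largest moment-matched posterior variance; the chosen intensity is
#' the moment-matched posterior mean there, snapped to the nearest grid
#' intensity (ties to the lower intensity). Ties in variance break to the
#' lowest frequency.
#'
#' @inheritParams select_stimulus
#' @return List with `frequency_hz`, `intensity_db`, `variance` (dB^2).
#' @export
select_stimulus_fast <- function(state, grid = stimulus_grid()) {
  est <- posterior_threshold_estimate(state, grid$frequencies)
  v <- est$sd^2
  j <- which.max(v)                       # first max -> lowest frequency
  h_target <- est$mean[j]
  k <- which.min(abs(grid$intensities - h_target))
  list(frequency_hz = grid$frequencies[j],
       intensity_db = grid$intensities[k], variance = v[j])
}
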