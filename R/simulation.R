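## The pure-tone audiometry simulation protocol: interpolate a target
## audiogram, loop stimulus selection -> simulated response -> posterior
## refit, and track the mean absolute estimation error on the standard
## frequencies after every response.

#' Piecewise-linear threshold interpolation
#'
#' Interpolates tabulated thresholds linearly in Hz between the defined
#' frequencies, with constant extrapolation beyond the outermost ones.
#'
#' @param thresholds Named numeric vector: names are frequencies in Hz (or
#'   `"f<freq>"` column names), values are dB-HL; `NA` entries are dropped.
#' @return A function `frequency_hz -> dB-HL`.
#' @export
interpolate_threshold <- function(thresholds) {
  f <- as.numeric(sub("^f", "", names(thresholds)))
  keep <- !is.na(thresholds)
  f <- f[keep]; t <- as.numeric(thresholds[keep])
  if (length(f) < 2) stop("need at least 2 defined frequencies", call. = FALSE)
  o <- order(f)
  stats::approxfun(f[o], t[o], method = "linear", rule = 2)
}

#' Mean absolute error between an estimate and a target
#'
#' @param estimate Estimated thresholds, dB-HL.
#' @param target Target thresholds (same length), or a function of Hz.
#' @param frequencies_hz Frequencies at which to compare (required when
#'   `target` is a function).
#' @return Mean absolute difference, dB.
#' @export
mean_absolute_error <- function(estimate, target,
                                frequencies_hz = standard_frequencies()) {
  if (is.function(target)) target <- target(frequencies_hz)
  stopifnot(length(estimate) == length(target))
  mean(abs(estimate - target))
}

#' Run one adaptive pure-tone audiometry simulation
#'
#' Protocol: interpolate the target audiogram; optionally condition the
#' model on side information; then repeat `n_trials` times: select a
#' stimulus, simulate the binary response from the probit model against the
#' interpolated target, and refit the mixture posterior from the full trial
#' list. The mean absolute error of the posterior mean threshold at the 11
#' standard frequencies is recorded before any response and after every
#' response.
#'
#' @param model A [mixture_model()].
#' @param thresholds Target audiogram: named numeric vector as for
#'   [interpolate_threshold()].
#' @param info A [side_info()]; use the default to ignore side information.
#' @param n_trials Number of responses to collect (default 25).
#' @param grid A [stimulus_grid()].
#' @param selector `"full"` (exact BALD grid search), `"fast"`
#'   (moment-matched), or `"random"` (uniform baseline).
#' @param seed Optional integer seed (local to this call).
#' @param true_sigma_p Perceptual-noise SD used to simulate responses;
#'   defaults to the model's own `sigma_p`.
#' @return An object of class `pta_trace`: list with `trials`, `errors`
#'   (length `n_trials + 1`), `pi_history` ((n_trials + 1) x C), `target`
#'   (the interpolation function), and the final `state`.
#' @export
run_pta_simulation <- function(model, thresholds, info = side_info(),
                               n_trials = 25, grid = stimulus_grid(),
                               selector = c("full", "fast", "random"),
                               seed = NULL, true_sigma_p = NULL) {
  stopifnot(n_trials >= 1)
  selector <- match.arg(selector)
  if (is.null(true_sigma_p)) true_sigma_p <- model$sigma_p
  local_seed(seed)
  target <- interpolate_threshold(thresholds)
  freqs <- standard_frequencies()
  target_vals <- target(freqs)

  tr <- trials()
  state <- posterior_mixture(model, info, tr)
  C <- length(model$components)
  errors <- numeric(n_trials + 1)
  pi_hist <- matrix(0, n_trials + 1, C)
  est <- posterior_threshold_estimate(state, freqs)
  errors[1] <- mean_absolute_error(est$mean, target_vals)
  pi_hist[1, ] <- state$pi

  for (i in seq_len(n_trials)) {
    stim <- switch(selector,
      full = select_stimulus(state, grid),
      fast = select_stimulus_fast(state, grid),
      random = list(frequency_hz = sample(grid$frequencies, 1L),
                    intensity_db = sample(grid$intensities, 1L)))
    y <- sample_response(stim$intensity_db, target(stim$frequency_hz),
                         true_sigma_p)
    tr <- rbind(tr, trials(stim$frequency_hz, stim$intensity_db, y))
    state <- posterior_mixture(model, info, tr)
    est <- posterior_threshold_estimate(state, freqs)
    errors[i + 1] <- mean_absolute_error(est$mean, target_vals)
    pi_hist[i + 1, ] <- state$pi
  }
  structure(list(trials = tr, errors = errors, pi_history = pi_hist,
                 target = target, state = state),
            class = "pta_trace")
}

#' @export
print.pta_trace <- function(x, ...) {
  cat("PTA simulation:", nrow(x$trials), "trials; error",
      signif(x$errors[1], 3), "->", signif(x$errors[length(x$errors)], 3),
      "dB\n")
  invisible(x)
}

#' Run a crossed simulation experiment
#'
#' Runs [run_pta_simulation()] for every combination of model, selector and
#' side-information usage over a set of target audiograms, and summarises
#' the per-step error distribution (mean and first/third quartiles).
#'
#' @param models Named list of [mixture_model()] objects.
#' @param dataset An [audiogram_dataset()] supplying the target audiograms
#'   and their side information.
#' @param n_trials Responses per simulation (default 25).
#' @param selectors Character subset of `c("full", "fast", "random")`.
#' @param use_side_info Which of the record's fields condition the prior
#'   mixing weights: a subset of `c("none", "age", "gender", "both")`.
#'   Logical values are accepted as shorthand (`TRUE` = `"both"`,
#'   `FALSE` = `"none"`).
#' @param grid A [stimulus_grid()].
#' @param seed Optional integer seed; run `r` of every condition uses seed
#'   `seed + r`, pairing conditions across targets.
#' @param true_sigma_p Passed to [run_pta_simulation()].
#' @return List of class `pta_experiment` with `results` (long data frame:
#'   model, selector, side_info, run, step, error) and `summary` (mean, q1,
#'   q3 per condition and step).
#' @export
run_experiment <- function(models, dataset, n_trials = 25,
                           selectors = "full", use_side_info = FALSE,
                           grid = stimulus_grid(), seed = NULL,
                           true_sigma_p = NULL) {
  df <- as.data.frame(dataset)
  fcols <- paste0("f", standard_frequencies())
  if (is.null(names(models))) names(models) <- paste0("model", seq_along(models))
  if (is.logical(use_side_info)) {
    use_side_info <- ifelse(use_side_info, "both", "none")
  }
  use_side_info <- match.arg(use_side_info,
                             c("none", "age", "gender", "both"),
                             several.ok = TRUE)
  out <- list()
  for (mname in names(models)) {
    for (sel in selectors) {
      for (usi in use_side_info) {
        for (r in seq_len(nrow(df))) {
          thr <- unlist(df[r, fcols])
          age_r <- if (usi %in% c("age", "both") && !is.na(df$age[r])) {
            df$age[r]
          }
          gen_r <- if (usi %in% c("gender", "both")) {
            as.character(df$gender[r])
          } else "unspecified"
          info <- side_info(age_r, gen_r)
          tr <- run_pta_simulation(models[[mname]], thr, info, n_trials,
                                   grid, sel,
                                   seed = if (is.null(seed)) NULL else seed + r,
                                   true_sigma_p = true_sigma_p)
          out[[length(out) + 1]] <- data.frame(
            model = mname, selector = sel, side_info = usi, run = r,
            step = 0:n_trials, error = tr$errors)
        }
      }
    }
  }
  results <- do.call(rbind, out)
  summary <- do.call(rbind, lapply(
    split(results, results[c("model", "selector", "side_info", "step")],
          drop = TRUE),
    function(g) data.frame(model = g$model[1], selector = g$selector[1],
                           side_info = g$side_info[1], step = g$step[1],
                           mean = mean(g$error),
                           q1 = stats::quantile(g$error, 0.25),
                           q3 = stats::quantile(g$error, 0.75))))
  rownames(summary) <- NULL
  summary <- summary[order(summary$model, summary$selector,
                           summary$side_info, summary$step), ]
  structure(list(results = results, summary = summary),
            class = "pta_experiment")
}

#' Plot mean error against trial count
#'
#' Base-graphics summary plot of a [run_experiment()] result: one line per
#' condition with a shaded interquartile band.
#'
#' @param x A `pta_experiment`.
#' @param ... Ignored.
#' @export
plot.pta_experiment <- function(x, ...) {
  s <- x$summary
  s$cond <- paste(s$model, s$selector, ifelse(s$side_info, "+info", ""))
  conds <- unique(s$cond)
  cols <- grDevices::hcl.colors(max(3, length(conds)), "Dark 3")
  plot(NULL, xlim = range(s$step), ylim = c(0, max(s$q3)),
       xlab = "number of responses", ylab = "mean absolute error (dB)")
  for (i in seq_along(conds)) {
    g <- s[s$cond == conds[i], ]
    graphics::polygon(c(g$step, rev(g$step)), c(g$q1, rev(g$q3)),
                      col = grDevices::adjustcolor(cols[i], 0.15),
                      border = NA)
    graphics::lines(g$step, g$mean, col = cols[i], lwd = 2)
  }
  graphics::legend("topright", conds, col = cols[seq_along(conds)],
                   lwd = 2, bty = "n")
  invisible(x)
}
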