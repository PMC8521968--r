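#' Probit response probability
#'
#' Probability of a response `y` to a pure tone of intensity `h` (dB-HL) given
#' the true hearing threshold `t` (dB-HL) at the tone's frequency. The
#' threshold is assumed to be evaluated under white Gaussian perceptual noise
#' with standard deviation `sigma_p`, so
#' `P(y | h, t) = pnorm(y * (h - t) / sigma_p)`.
#'
#' @param y Response, `+1` (audible) or `-1` (inaudible). Vectorised.
#' @param h Stimulus intensity, dB-HL.
#' @param t Hearing threshold at the stimulus frequency, dB-HL.
#' @param sigma_p Perceptual-noise standard deviation, dB; must be positive.
#' @return Response probability in (0, 1).
#' @examples
#' response_probability(+1, h = 30, t = 30, sigma_p = 5)  # 0.5 at threshold
#' @export
response_probability <- function(y, h, t, sigma_p) {
  check_sigma_p(sigma_p)
  if (any(!y %in% c(-1, 1))) {
    stop("`y` must be -1 or +1", call. = FALSE)
  }
  stats::pnorm(y * (h - t) / sigma_p)
}

#' Sample binary responses from the probit model
#'
#' Draws `+1` with probability `pnorm((h - t) / sigma_p)` and `-1` otherwise,
#' using R's current RNG stream (seed with [set.seed()] or pass `seed`).
#'
#' @inheritParams response_probability
#' @param seed Optional integer; if given, the RNG state is set locally so
#'   the draw is reproducible and the caller's stream is untouched.
#' @return Integer vector of `+1` / `-1`, same length as the longest argument.
#' @export
sample_response <- function(h, t, sigma_p, seed = NULL) {
  check_sigma_p(sigma_p)
  if (any(!is.finite(h)) || any(!is.finite(t))) {
    stop("intensity and threshold must be finite", call. = FALSE)
  }
  local_seed(seed)
  p <- stats::pnorm((h - t) / sigma_p)
  ifelse(stats::runif(length(p)) < p, 1L, -1L)
}

check_sigma_p <- function(sigma_p) {
  if (!is.numeric(sigma_p) || length(sigma_p) != 1L || !is.finite(sigma_p) ||
      sigma_p <= 0) {
    stop("`sigma_p` must be a single positive number (dB)", call. = FALSE)
  }
  invisible(sigma_p)
}

# Set the RNG seed for the remainder of the calling function only.
local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  if (has_old) {
    withr::defer(assign(".Random.seed", old, envir = globalenv()), envir = env)
  }
  invisible(NULL)
}

#' Construct a trial table
#'
#' A trial records one stimulus (frequency in Hz, intensity in dB-HL) together
#' with the binary response. Trial collections are plain data frames with
#' columns `frequency_hz`, `intensity_db`, `response`.
#'
#' @param frequency_hz Stimulus frequencies, Hz (positive).
#' @param intensity_db Stimulus intensities, dB-HL (finite).
#' @param response Responses, `+1` / `-1`.
#' @return A `data.frame` with the three validated columns.
#' @export
trials <- function(frequency_hz = numeric(), intensity_db = numeric(),
                   response = integer()) {
  stopifnot(length(frequency_hz) == length(intensity_db),
            length(frequency_hz) == length(response))
  if (length(frequency_hz)) {
    if (any(frequency_hz <= 0)) stop("frequencies must be positive Hz", call. = FALSE)
    if (any(!is.finite(intensity_db))) stop("intensities must be finite", call. = FALSE)
    if (any(!response %in% c(-1, 1))) stop("responses must be -1/+1", call. = FALSE)
  }
  data.frame(frequency_hz = as.numeric(frequency_hz),
             intensity_db = as.numeric(intensity_db),
             response = as.integer(response))
}

#' Read / write a trial table as CSV
#'
#' @param path File path.
#' @return `read_trials()` returns a validated trial data frame.
#' @rdname trials_io
#' @export
read_trials <- function(path) {
  d <- utils::read.csv(path)
  trials(d$frequency_hz, d$intensity_db, d$response)
}

#' @param x Trial data frame as produced by [trials()].
#' @rdname trials_io
#' @export
write_trials <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
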