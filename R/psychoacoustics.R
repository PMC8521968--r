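#' Standard audiometric frequencies
#'
#' The eleven frequencies (Hz) at which clinical audiograms are tabulated:
#' 125, 250, 500, 750, 1000, 1500, 2000, 3000, 4000, 6000, 8000 Hz.
#'
#' @return Numeric vector of length 11, in Hz, ascending.
#' @export
standard_frequencies <- function() {
  c(125, 250, 500, 750, 1000, 1500, 2000, 3000, 4000, 6000, 8000)
}

#' Bark transformation of frequency
#'
#' Maps physical frequency (Hz) onto the Bark psycho-acoustical scale via
#' `6 * asinh(f / 600)`. All Gaussian-process computation in this package
#' happens in Bark space; Hz appears only at the I/O boundary.
#'
#' @param f Frequency in Hz, non-negative. Vectorised.
#' @return Transformed frequency in Bark.
#' @seealso [bark_inverse()]
#' @examples
#' bark(standard_frequencies())
#' @export
bark <- function(f) {
  if (any(!is.finite(f)) || any(f < 0)) {
    stop("`f` must be finite and non-negative (Hz)", call. = FALSE)
  }
  6 * asinh(f / 600)
}

#' Inverse Bark transformation
#'
#' Closed-form inverse of [bark()]: `600 * sinh(x / 6)`.
#'
#' @param x Transformed frequency in Bark. Vectorised.
#' @return Frequency in Hz.
#' @export
bark_inverse <- function(x) {
  600 * sinh(x / 6)
}

# Centre of the standard audiometric grid in Bark; the cubic mean polynomials
# are evaluated in powers of (x - bark_centre()) to keep the basis conditioned.
bark_centre <- function() {
  rng <- range(bark(standard_frequencies()))
  (rng[1] + rng[2]) / 2
}
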