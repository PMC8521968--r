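#' Gaussian-process component of the hearing-threshold prior
#'
#' One mixture component: a GP over threshold (dB-HL) as a function of
#' Bark-transformed frequency, with a cubic-polynomial mean and a squared
#' exponential kernel. The polynomial is evaluated in powers of
#' `x - bark_centre()` (the midpoint of the standard audiometric grid in
#' Bark), which keeps the basis well conditioned during fitting.
#'
#' @param mean_coeffs Numeric length 4: coefficients of `1, z, z^2, z^3`
#'   where `z = x - bark_centre()`, in dB-HL per Bark^k.
#' @param kernel_variance Positive; marginal variance of the GP, dB^2.
#' @param kernel_lengthscale Positive; SE-kernel length-scale, Bark.
#' @return An object of class `gp_component`.
#' @export
gp_component <- function(mean_coeffs, kernel_variance, kernel_lengthscale) {
  mean_coeffs <- as.numeric(mean_coeffs)
  if (length(mean_coeffs) != 4L || any(!is.finite(mean_coeffs))) {
    stop("`mean_coeffs` must be 4 finite numbers", call. = FALSE)
  }
  if (!is.finite(kernel_variance) || kernel_variance <= 0) {
    stop("`kernel_variance` must be positive (dB^2)", call. = FALSE)
  }
  if (!is.finite(kernel_lengthscale) || kernel_lengthscale <= 0) {
    stop("`kernel_lengthscale` must be positive (Bark)", call. = FALSE)
  }
  structure(list(mean_coeffs = mean_coeffs,
                 kernel_variance = kernel_variance,
                 kernel_lengthscale = kernel_lengthscale),
            class = "gp_component")
}

#' @export
print.gp_component <- function(x, ...) {
  cat("GP component: mean coeffs [",
      paste(signif(x$mean_coeffs, 4), collapse = ", "),
      "] dB, kernel sd", signif(sqrt(x$kernel_variance), 4),
      "dB, lengthscale", signif(x$kernel_lengthscale, 4), "Bark\n")
  invisible(x)
}

# Cubic mean polynomial at Bark frequencies.
component_mean <- function(component, x_bark) {
  z <- x_bark - bark_centre()
  drop(cbind(1, z, z^2, z^3) %*% component$mean_coeffs)
}

#' Squared exponential kernel
#'
#' `k(x1, x2) = v * exp(-(x1 - x2)^2 / (2 * l^2))` with `v` the kernel
#' variance (dB^2) and `l` the length-scale (Bark).
#'
#' @param x1,x2 Transformed frequencies, Bark. Vectorised (outer product is
#'   taken, so the result is `length(x1) x length(x2)` when both exceed 1).
#' @param component A [gp_component()].
#' @return Covariance (dB^2); a scalar, vector, or matrix following `outer()`.
#' @export
se_kernel <- function(x1, x2, component) {
  d <- outer(x1, x2, "-")
  k <- component$kernel_variance *
    exp(-d^2 / (2 * component$kernel_lengthscale^2))
  if (length(x1) == 1L && length(x2) == 1L) drop(k) else k
}

#' Finite-dimensional prior of one GP component
#'
#' Evaluates the component's mean vector and covariance matrix at a set of
#' Bark frequencies. Duplicate frequencies are allowed (the covariance is then
#' rank-deficient but still positive semi-definite).
#'
#' @param component A [gp_component()].
#' @param xs Non-empty numeric vector of Bark frequencies.
#' @return List with `mean` (dB-HL) and `cov` (dB^2 matrix).
#' @export
component_prior_at <- function(component, xs) {
  if (!length(xs)) stop("`xs` must be non-empty", call. = FALSE)
  list(mean = component_mean(component, xs),
       cov = as.matrix(se_kernel(xs, xs, component)))
}

# Cholesky with diagonal jitter scaled to the kernel variance; SE kernels on
# close frequencies are near-singular.
chol_jitter <- function(S, scale = NULL) {
  S <- as.matrix(S)
  if (is.null(scale)) scale <- max(diag(S))
  jit <- 1e-8 * scale
  for (i in 1:6) {
    R <- tryCatch(chol(S + diag(jit, nrow(S))), error = function(e) NULL)
    if (!is.null(R)) return(R)
    jit <- jit * 100
  }
  stop("covariance not positive definite even after jitter", call. = FALSE)
}

#' Side information about a subject
#'
#' @param age Integer 0-120, or `NULL` when unspecified.
#' @param gender One of `"unspecified"`, `"female"`, `"male"`.
#' @return An object of class `side_info`.
#' @export
side_info <- function(age = NULL, gender = "unspecified") {
  if (!is.null(age)) {
    age <- as.integer(age)
    if (length(age) != 1L || is.na(age) || age < 0L || age > 120L) {
      stop("`age` must be an integer in [0, 120] or NULL", call. = FALSE)
    }
  }
  gender <- match.arg(gender, c("unspecified", "female", "male"))
  structure(list(age = age, gender = gender), class = "side_info")
}

# 5-year age buckets; "unspecified" when age is NULL/NA.
age_bucket <- function(age) {
  if (is.null(age) || is.na(age)) "unspecified" else as.character(age %/% 5L)
}

alpha_key <- function(info) {
  paste(age_bucket(info$age), info$gender, sep = "|")
}

#' Mixing-weight lookup table
#'
#' Maps side-information keys (`"<age bucket>|<gender>"`, with 5-year age
#' buckets or `"unspecified"`) to mixing-weight vectors over the C
#' components. Must contain the `"unspecified|unspecified"` entry holding the
#' population-marginal weights.
#'
#' @param entries Named list of non-negative weight vectors, each summing to 1.
#' @return An object of class `alpha_table`.
#' @export
alpha_table <- function(entries) {
  if (!length(entries) || is.null(names(entries))) {
    stop("`entries` must be a named list", call. = FALSE)
  }
  C <- length(entries[[1]])
  for (nm in names(entries)) {
    w <- entries[[nm]]
    if (length(w) != C || any(w < 0) || abs(sum(w) - 1) > 1e-10) {
      stop("entry `", nm, "` is not a simplex vector of length ", C,
           call. = FALSE)
    }
  }
  if (!"unspecified|unspecified" %in% names(entries)) {
    stop("table must contain the `unspecified|unspecified` marginal entry",
         call. = FALSE)
  }
  structure(list(entries = lapply(entries, as.numeric), C = C),
            class = "alpha_table")
}

#' Hearing-threshold mixture model
#'
#' @param components List of [gp_component()] objects (length C >= 1).
#' @param alpha An [alpha_table()] with weight vectors of length C.
#' @param sigma_p Perceptual-noise SD, dB (default 5, matching the 5 dB
#'   resolution of clinical audiograms).
#' @return An object of class `mixture_model`.
#' @export
mixture_model <- function(components, alpha, sigma_p = 5) {
  if (!length(components) || !all(vapply(components, inherits, TRUE, "gp_component"))) {
    stop("`components` must be a non-empty list of gp_component objects",
         call. = FALSE)
  }
  if (!inherits(alpha, "alpha_table") || alpha$C != length(components)) {
    stop("`alpha` must be an alpha_table with C = length(components)",
         call. = FALSE)
  }
  check_sigma_p(sigma_p)
  structure(list(components = components, alpha = alpha, sigma_p = sigma_p),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat("Hearing-threshold GP mixture model: C =", length(x$components),
      "components, sigma_p =", x$sigma_p, "dB,",
      length(x$alpha$entries), "side-information keys\n")
  invisible(x)
}

# Distance between two alpha-table keys for nearest-neighbour lookup.
# Numeric buckets: absolute difference; exactly one side unspecified age:
# +500; gender mismatch: +1000.
key_distance <- function(key, target) {
  a <- strsplit(key, "|", fixed = TRUE)[[1]]
  b <- strsplit(target, "|", fixed = TRUE)[[1]]
  d <- 0
  if (a[1] == "unspecified" || b[1] == "unspecified") {
    if (a[1] != b[1]) d <- d + 500
  } else {
    d <- d + abs(as.numeric(a[1]) - as.numeric(b[1]))
  }
  if (a[2] != b[2]) d <- d + 1000
  d
}

#' Conditional mixing weights
#'
#' Looks up the prior mixing weights for the given side information. Exact
#' keys are returned as stored; unseen keys resolve to the nearest stored key
#' (absolute age-bucket distance, +500 for an unspecified-age mismatch, +1000
#' for a gender mismatch; ties to the first stored key). Fully unspecified
#' information returns the population-marginal weights.
#'
#' @param model A [mixture_model()].
#' @param info A [side_info()] (default: fully unspecified).
#' @return Numeric simplex vector of length C.
#' @export
mixing_weights <- function(model, info = side_info()) {
  key <- alpha_key(info)
  entries <- model$alpha$entries
  if (key == "unspecified|unspecified" || !is.null(entries[[key]])) {
    w <- entries[[if (!is.null(entries[[key]])) key else "unspecified|unspecified"]]
  } else {
    d <- vapply(names(entries), key_distance, 0, target = key)
    w <- entries[[which.min(d)]]
  }
  w / sum(w)
}

#' Sample a hearing threshold from the prior
#'
#' Draws a component index from [mixing_weights()] and then threshold values
#' from that component's multivariate Gaussian at the given Bark frequencies.
#'
#' @inheritParams mixing_weights
#' @param xs Non-empty vector of Bark frequencies.
#' @param seed Optional integer seed (local to this call).
#' @return List with `component` (index) and `threshold` (dB-HL vector).
#' @export
sample_threshold <- function(model, info = side_info(), xs, seed = NULL) {
  if (!length(xs)) stop("`xs` must be non-empty", call. = FALSE)
  local_seed(seed)
  w <- mixing_weights(model, info)
  c_idx <- sample.int(length(w), 1L, prob = w)
  pr <- component_prior_at(model$components[[c_idx]], xs)
  R <- chol_jitter(pr$cov)
  list(component = c_idx,
       threshold = drop(pr$mean + crossprod(R, stats::rnorm(length(xs)))))
}

#' Write / read a mixture model as JSON
#'
#' The model file is a human-readable JSON document holding C, the
#' per-component mean coefficients and kernel hyperparameters, `sigma_p`, and
#' the mixing-weight table keyed by `"<age bucket>|<gender>"`.
#'
#' @param model A [mixture_model()].
#' @param path File path.
#' @rdname model_io
#' @export
write_model <- function(model, path) {
  doc <- list(
    C = length(model$components),
    sigma_p = model$sigma_p,
    components = lapply(model$components, function(cc) {
      list(mean_coeffs = cc$mean_coeffs,
           kernel_variance = cc$kernel_variance,
           kernel_lengthscale = cc$kernel_lengthscale)
    }),
    alpha = model$alpha$entries
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @return `read_model()` returns the validated [mixture_model()].
#' @rdname model_io
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  comps <- lapply(seq_len(doc$C), function(i) {
    cc <- if (is.data.frame(doc$components)) {
      list(mean_coeffs = doc$components$mean_coeffs[[i]],
           kernel_variance = doc$components$kernel_variance[i],
           kernel_lengthscale = doc$components$kernel_lengthscale[i])
    } else doc$components[[i]]
    gp_component(cc$mean_coeffs, cc$kernel_variance, cc$kernel_lengthscale)
  })
  mixture_model(comps, alpha_table(as.list(doc$alpha)), doc$sigma_p)
}
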