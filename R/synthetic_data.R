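## Synthetic audiogram populations. Clinical audiogram archives are rarely
## shareable, so the package carries a generator that emulates their
## structure: thresholds quantised at 5 dB on the 11 standard frequencies,
## and age/gender-dependent membership in a small set of threshold
## archetypes (flat mild loss, high-frequency sloping "old-age" loss,
## mid-frequency "cookie-bite" loss).

#' Population specification for synthetic audiograms
#'
#' @param prototypes Named list of [gp_component()] prototype threshold
#'   shapes.
#' @param alpha_rule Named list mapping `"<age bucket>|<gender>"` keys to
#'   prototype weight vectors (simplex).
#' @param age_probs Named numeric: probability of each 5-year age bucket
#'   (names are bucket indices, i.e. `age %/% 5`).
#' @param gender_probs Named numeric over `female` / `male` (and optionally
#'   `unspecified`).
#' @param quantization_step Threshold resolution in dB (default 5).
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(prototypes, alpha_rule, age_probs, gender_probs,
                            quantization_step = 5) {
  stopifnot(length(prototypes) >= 1,
            all(vapply(prototypes, inherits, TRUE, "gp_component")),
            quantization_step > 0)
  C <- length(prototypes)
  for (k in names(alpha_rule)) {
    w <- alpha_rule[[k]]
    if (length(w) != C || any(w < 0) || abs(sum(w) - 1) > 1e-10) {
      stop("alpha_rule entry `", k, "` is not a length-", C,
           " simplex vector", call. = FALSE)
    }
  }
  stopifnot(abs(sum(age_probs) - 1) < 1e-10,
            abs(sum(gender_probs) - 1) < 1e-10)
  structure(list(prototypes = prototypes, alpha_rule = alpha_rule,
                 age_probs = age_probs, gender_probs = gender_probs,
                 quantization_step = quantization_step),
            class = "population_spec")
}

#' Default three-prototype population
#'
#' Three archetypal threshold shapes on the standard grid: flat mild loss
#' (~20 dB-HL), high-frequency sloping loss (20 dB-HL at 125 Hz rising to
#' 70 dB-HL at 8 kHz, linear in Bark), and a mid-frequency cookie-bite bump
#' peaking near 50 dB-HL around 1-2 kHz. Mixing weights depend on age
#' (older ages up-weight the sloping prototype) with a mild gender effect
#' (the cookie-bite shape up-weighted for females). The age distribution is
#' centred on late middle age, reflecting an audiology-clinic population.
#'
#' @return A [population_spec()].
#' @export
default_population <- function() {
  xb <- bark(standard_frequencies())
  z <- xb - bark_centre()
  B <- cbind(1, z, z^2, z^3)
  fit_coeffs <- function(target) {
    stats::lsfit(B, target, intercept = FALSE)$coefficients
  }
  slope_curve <- 20 + 50 * (xb - min(xb)) / (max(xb) - min(xb))
  bite_curve <- 15 + 35 * exp(-(xb - bark(1500))^2 / (2 * 2.5^2))
  prototypes <- list(
    flat = gp_component(c(20, 0, 0, 0), 36, 4),
    sloping = gp_component(fit_coeffs(slope_curve), 100, 5),
    cookie_bite = gp_component(fit_coeffs(bite_curve), 64, 3)
  )
  buckets <- 0:23                             # ages 0-119 in 5-year bins
  rule <- list()
  for (b in buckets) {
    mid <- 5 * b + 2.5
    s <- stats::plogis((mid - 60) / 12)       # sloping weight grows with age
    for (g in c("female", "male")) {
      w <- c(flat = (1 - s) * 0.7, sloping = s,
             cookie_bite = (1 - s) * 0.3)
      if (g == "female") w["cookie_bite"] <- w["cookie_bite"] * 1.5
      rule[[paste(b, g, sep = "|")]] <- unname(w / sum(w))
    }
  }
  mids <- 5 * buckets + 2.5
  age_probs <- stats::dnorm(mids, 58, 18)
  age_probs[mids < 15 | mids > 100] <- 0
  age_probs <- age_probs / sum(age_probs)
  names(age_probs) <- buckets
  population_spec(prototypes, rule, age_probs,
                  c(female = 0.5, male = 0.5))
}

#' Write / read a population spec as JSON
#'
#' @param spec A [population_spec()].
#' @param path File path.
#' @rdname population_io
#' @export
write_population <- function(spec, path) {
  doc <- list(
    prototypes = lapply(spec$prototypes, function(p) {
      list(mean_coeffs = p$mean_coeffs, kernel_variance = p$kernel_variance,
           kernel_lengthscale = p$kernel_lengthscale)
    }),
    alpha_rule = spec$alpha_rule,
    age_probs = as.list(spec$age_probs),
    gender_probs = as.list(spec$gender_probs),
    quantization_step = spec$quantization_step
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname population_io
#' @export
read_population <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  protos <- lapply(doc$prototypes, function(p) {
    gp_component(p$mean_coeffs, p$kernel_variance, p$kernel_lengthscale)
  })
  population_spec(protos, lapply(doc$alpha_rule, as.numeric),
                  unlist(doc$age_probs), unlist(doc$gender_probs),
                  doc$quantization_step)
}

# Round half away from zero to a multiple of `step`.
quantize_db <- function(t, step) {
  step * sign(t) * floor(abs(t) / step + 0.5)
}

#' Generate a synthetic annotated audiogram dataset
#'
#' Per record: draw age and gender from the spec's distributions, draw a
#' prototype from the (age bucket, gender) mixing rule, draw a continuous
#' threshold curve from the prototype GP at the standard frequencies, and
#' quantise (round half away from zero) to the spec's resolution. Latent
#' truth is returned separately and never written into the public dataset.
#'
#' @param spec A [population_spec()].
#' @param n Number of records (>= 1).
#' @param seed Optional integer seed (local to this call).
#' @return List with `dataset` (an [audiogram_dataset()]) and `truth` (data
#'   frame with `component` plus the continuous thresholds `t125` ...).
#' @export
generate_dataset <- function(spec, n, seed = NULL) {
  stopifnot(n >= 1)
  local_seed(seed)
  freqs <- standard_frequencies()
  xb <- bark(freqs)
  C <- length(spec$prototypes)

  buckets <- as.integer(names(spec$age_probs))
  b <- sample(buckets, n, replace = TRUE, prob = spec$age_probs)
  age <- pmin(5L * b + sample(0:4, n, replace = TRUE), 120L)
  gender <- sample(names(spec$gender_probs), n, replace = TRUE,
                   prob = spec$gender_probs)

  priors <- lapply(spec$prototypes, component_prior_at, xs = xb)
  chols <- lapply(priors, function(p) chol_jitter(p$cov))

  comp <- integer(n)
  Tc <- matrix(0, n, length(freqs))
  for (i in seq_len(n)) {
    key <- paste(age[i] %/% 5L, gender[i], sep = "|")
    w <- spec$alpha_rule[[key]]
    if (is.null(w)) w <- rep(1 / C, C)
    comp[i] <- sample.int(C, 1L, prob = w)
    Tc[i, ] <- priors[[comp[i]]]$mean +
      drop(crossprod(chols[[comp[i]]], stats::rnorm(length(freqs))))
  }
  Tq <- quantize_db(Tc, spec$quantization_step)

  df <- data.frame(id = seq_len(n), age = age, gender = gender)
  df[paste0("f", freqs)] <- as.data.frame(Tq)
  truth <- data.frame(component = comp)
  truth[paste0("t", freqs)] <- as.data.frame(Tc)
  list(dataset = audiogram_dataset(df), truth = truth)
}

#' Blank thresholds at random to emulate partial audiograms
#'
#' Independently blanks each non-anchor threshold with probability
#' `fraction`. The anchor frequencies 500, 1000, 2000, 4000 Hz are always
#' retained (when defined), and every record keeps at least four defined
#' frequencies (blanked cells are restored at random if needed).
#'
#' @param dataset An [audiogram_dataset()].
#' @param fraction Blanking probability in \[0, 1).
#' @param seed Optional integer seed (local to this call).
#' @return The masked [audiogram_dataset()].
#' @export
missingness_mask <- function(dataset, fraction, seed = NULL) {
  stopifnot(fraction >= 0, fraction < 1)
  if (fraction == 0) return(dataset)
  local_seed(seed)
  df <- as.data.frame(dataset)
  fcols <- paste0("f", standard_frequencies())
  anchors <- paste0("f", c(500, 1000, 2000, 4000))
  candidates <- setdiff(fcols, anchors)
  for (i in seq_len(nrow(df))) {
    def <- candidates[!is.na(df[i, candidates])]
    drop_these <- def[stats::runif(length(def)) < fraction]
    df[i, drop_these] <- NA
    n_def <- sum(!is.na(df[i, fcols]))
    if (n_def < 4 && length(drop_these)) {
      restore <- sample(drop_these, min(4 - n_def, length(drop_these)))
      df[i, restore] <- as.data.frame(dataset)[i, restore]
    }
  }
  audiogram_dataset(df)
}
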