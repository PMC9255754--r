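#' Detection-function parameters
#'
#' Bundles the parameters of a distance-decaying detection function: the
#' baseline capture probability `g0` at an animal's activity centre, the
#' spatial scale `sigma` (a home-range size index, metres), and for the
#' hazard-rate form a shape parameter `z`.
#'
#' @param g0 Probability of capture at distance zero, in (0, 1).
#' @param sigma Spatial scale in metres, positive.
#' @param kind Functional form: `"HN"` half-normal, `"EX"` negative
#'   exponential, `"HR"` hazard rate.
#' @param z Hazard-rate shape, `> 1`; ignored unless `kind = "HR"`.
#' @return A list of class `detection_params`.
#' @examples
#' detection_params(0.3, 12, "EX")
#' @export
detection_params <- function(g0, sigma, kind = c("EX", "HN", "HR"), z = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(g0) || length(g0) != 1L || g0 <= 0 || g0 >= 1) {
    stop("`g0` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("`sigma` must be a positive number of metres", call. = FALSE)
  }
  if (kind == "HR") {
    if (is.null(z) || !is.numeric(z) || length(z) != 1L || z <= 1) {
      stop("the hazard-rate form needs a shape `z` greater than 1", call. = FALSE)
    }
  } else {
    z <- NA_real_
  }
  structure(list(g0 = g0, sigma = sigma, z = z, kind = kind),
            class = "detection_params")
}

#' Evaluate a detection function
#'
#' Probability that an animal whose activity centre lies `d` metres from a
#' trap is caught there on a single occasion.
#'
#' Forms: half-normal `g0 exp(-d^2 / (2 sigma^2))`; negative exponential
#' `g0 exp(-d / sigma)`; hazard rate `g0 (1 - exp(-(d / sigma)^(-z)))`.
#'
#' @param d Distance(s) in metres, non-negative; vectorised.
#' @param params A [detection_params()] object.
#' @return Capture probabilities in (0, g0].
#' @examples
#' detect_g(12, detection_params(0.4, 12, "EX")) # 0.4 * exp(-1)
#' @export
detect_g <- function(d, params) {
  stopifnot(inherits(params, "detection_params"))
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("distances must be finite and non-negative", call. = FALSE)
  }
  with(params, switch(kind,
    HN = g0 * exp(-d^2 / (2 * sigma^2)),
    EX = g0 * exp(-d / sigma),
    HR = ifelse(d <= 0, g0, g0 * (1 - exp(-(d / sigma)^(-z))))
  ))
}

#' Per-occasion hazard of a capture probability
#'
#' Converts a per-trap capture probability into the hazard of the competing
#' risks model for multi-catch traps, `h = -log(1 - g)`.
#'
#' @param g Capture probability/ies in `[0, 1)`; vectorised.
#' @return Non-negative hazard(s), strictly increasing in `g`.
#' @export
trap_hazard <- function(g) {
  if (any(!is.finite(g)) || any(g < 0)) {
    stop("capture probabilities must be finite and non-negative", call. = FALSE)
  }
  if (any(g >= 1)) {
    stop("hazard overflows: capture probability must be strictly below 1",
         call. = FALSE)
  }
  -log1p(-g)
}

#' Competing-risk capture probabilities across a trap array
#'
#' An animal can be caught in at most one multi-catch trap per occasion, so
#' traps compete: with per-trap hazards `h_k` and total `H = sum(h_k)`, the
#' probability of ending the occasion in trap `k` is
#' `(h_k / H) (1 - exp(-H))`, and of escaping capture `exp(-H)`.  The
#' outcomes partition the occasion, so the probabilities sum to one exactly.
#'
#' @param center Numeric length-2 activity centre `(x, y)` in metres.
#' @param traps A `trap_array`.
#' @param params A [detection_params()] object.
#' @return A tibble with columns `outcome` (trap ids plus `"not_caught"`)
#'   and `prob`.
#' @export
multicatch_probs <- function(center, traps, params) {
  stopifnot(is.numeric(center), length(center) == 2L)
  d <- sqrt((traps$x - center[1])^2 + (traps$y - center[2])^2)
  h <- trap_hazard(detect_g(d, params))
  H <- sum(h)
  p <- if (H > 0) (h / H) * (-expm1(-H)) else rep(0, length(h))
  tibble::tibble(
    outcome = c(traps$trap_id, "not_caught"),
    prob = c(p, exp(-H))
  )
}

#' Overall per-session detection probability
#'
#' Probability that an animal with the given activity centre is caught at
#' least once over a session of `n_occasions` occasions.  Detection
#' parameters may differ by occasion (e.g. a time effect).
#'
#' @param center Numeric length-2 activity centre `(x, y)`.
#' @param traps A `trap_array`.
#' @param n_occasions Number of occasions in the session.
#' @param params A single [detection_params()] used on every occasion, or a
#'   list of one per occasion.
#' @return A probability, non-decreasing in `n_occasions`.
#' @export
p_dot <- function(center, traps, n_occasions, params) {
  if (!is_count(n_occasions)) stop("`n_occasions` must be a positive integer", call. = FALSE)
  if (inherits(params, "detection_params")) {
    params <- rep(list(params), n_occasions)
  }
  if (length(params) != n_occasions) {
    stop("supply one detection-parameter set per occasion", call. = FALSE)
  }
  log_escape <- purrr::map_dbl(params, function(pp) {
    d <- sqrt((traps$x - center[1])^2 + (traps$y - center[2])^2)
    -sum(trap_hazard(detect_g(d, pp)))
  })
  -expm1(sum(log_escape))
}
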