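#' Half-normal detection parameters
#'
#' Bundle and validate the two parameters of the half-normal detection
#' model: `g0`, the per-occasion probability of detection at a detector
#' placed exactly at an animal's activity centre, and `sigma`, the spatial
#' scale (metres) over which detection probability declines with distance.
#'
#' @param g0 Detection probability at distance zero; must lie strictly in
#'   (0, 1).
#' @param sigma Spatial scale of the half-normal detection function, in
#'   metres; must be positive.
#' @return An object of class `"detection_params"`: a named list with
#'   elements `g0` and `sigma`.
#' @examples
#' detection_params(0.3, 1500)
#' @export
detection_params <- function(g0, sigma) {
  if (!is.numeric(g0) || length(g0) != 1L || !is.finite(g0) ||
      g0 <= 0 || g0 >= 1) {
    stop("'g0' must be a single probability strictly between 0 and 1")
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("'sigma' must be a single positive length in metres")
  }
  structure(list(g0 = g0, sigma = sigma), class = "detection_params")
}

#' @export
print.detection_params <- function(x, ...) {
  cat(sprintf("Half-normal detection: g0 = %.4g, sigma = %.6g m\n",
              x$g0, x$sigma))
  invisible(x)
}

# Link scale used throughout: logit for g0, log for sigma. Keeps the
# optimizer unconstrained and the delta method on a scale where normality
# is a better approximation.
theta_to_link <- function(g0, sigma) {
  c(logit_g0 = stats::qlogis(g0), log_sigma = log(sigma))
}

link_to_theta <- function(link) {
  # cap g0 away from {0,1} and sigma within physically sensible bounds so a
  # wandering optimizer cannot produce NaN likelihoods
  g0 <- stats::plogis(link[[1L]])
  g0 <- min(max(g0, 1e-6), 1 - 1e-6)
  sigma <- exp(link[[2L]])
  sigma <- min(max(sigma, 1), 1e7)
  list(g0 = g0, sigma = sigma)
}

#' Half-normal detection function
#'
#' Per-occasion probability that a proximity detector at distance `d` from
#' an animal's activity centre detects it:
#' \deqn{g(d) = g_0 \exp\{-d^2 / (2\sigma^2)\}.}
#'
#' @param d Distance(s) between activity centre and detector, in metres;
#'   non-negative.
#' @param g0 Detection probability at distance zero, or a
#'   [detection_params] object (in which case `sigma` is ignored).
#' @param sigma Spatial scale in metres.
#' @return Detection probabilities, the same length as `d`.
#' @examples
#' half_normal_g(0, 0.3, 1500)      # = g0
#' half_normal_g(1500, 0.3, 1500)   # = 0.3 * exp(-1/2)
#' @export
half_normal_g <- function(d, g0, sigma) {
  if (inherits(g0, "detection_params")) {
    sigma <- g0$sigma
    g0 <- g0$g0
  }
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("distances must be finite and non-negative")
  }
  g0 * exp(-d^2 / (2 * sigma^2))
}

#' Overall detection probability for an activity centre
#'
#' Probability that an animal with activity centre at `x` is detected at
#' least once over all detectors and occasions of one array, assuming
#' independent Bernoulli detections:
#' \deqn{p_\cdot(x) = 1 - \prod_k \{1 - g(d_k(x))\}^S,}
#' where the product runs over the array's detectors and `S` is the number
#' of occasions.
#'
#' @param x A length-2 numeric vector `(x, y)` in metres, or a two-column
#'   matrix of points.
#' @param array A [detector_array].
#' @param params A [detection_params] object.
#' @return Probability of detection at least once; vector with one element
#'   per row of `x`.
#' @examples
#' tr <- detector_array("A1", x = 0, y = 0, n_occasions = 6)
#' p_dot(c(0, 0), tr, detection_params(0.3, 1500))  # 1 - 0.7^6
#' @export
p_dot <- function(x, array, params) {
  stopifnot(inherits(array, "detector_array"),
            inherits(params, "detection_params"))
  if (is.null(dim(x))) x <- matrix(x, ncol = 2L)
  d <- dist_to_detectors(x, array)
  pdot_from_dist(d, params$g0, params$sigma, array$n_occasions)
}

# Distance matrix (points x detectors), all metres.
dist_to_detectors <- function(xy, array) {
  dx <- outer(xy[, 1L], array$detectors$x, "-")
  dy <- outer(xy[, 2L], array$detectors$y, "-")
  sqrt(dx^2 + dy^2)
}

# p.(x) from a precomputed distance matrix; the workhorse shared by the
# likelihood, the effective-area integral, and the simulator.
pdot_from_dist <- function(d, g0, sigma, n_occasions) {
  g <- g0 * exp(-d^2 / (2 * sigma^2))
  if (is.null(dim(g))) g <- matrix(g, nrow = 1L)
  -expm1(n_occasions * rowSums(log1p(-g)))
}
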