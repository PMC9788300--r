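#' Probability of one capture history given an activity centre
#'
#' Probability of the observed binary history `omega_i` (occasions x
#' detectors) for an animal whose activity centre is at `x`, under
#' independent Bernoulli detections with half-normal distance decay:
#' \deqn{\Pr(\omega_i \mid x) = \prod_{s,k} p_k(x)^{\omega_{isk}}
#'   \{1 - p_k(x)\}^{1-\omega_{isk}}.}
#' Only animals detected at least once enter the conditional likelihood,
#' so an all-zero history is an error.
#'
#' @param x Length-2 numeric activity-centre location (metres).
#' @param omega_i Binary matrix, `n_occasions` x `K`.
#' @param array A [detector_array].
#' @param params A [detection_params].
#' @return A probability in (0, 1).
#' @export
history_prob <- function(x, omega_i, array, params) {
  stopifnot(inherits(array, "detector_array"),
            inherits(params, "detection_params"))
  omega_i <- as.matrix(omega_i)
  if (nrow(omega_i) != array$n_occasions ||
      ncol(omega_i) != n_detectors(array)) {
    stop("'omega_i' must be n_occasions x K for this array")
  }
  if (!all(omega_i %in% c(0L, 1L))) stop("'omega_i' must be binary")
  if (sum(omega_i) == 0L) {
    stop("all-zero capture history: undetected animals carry no term in the conditional likelihood")
  }
  d <- dist_to_detectors(matrix(x, ncol = 2L), array)[1L, ]
  g <- half_normal_g(d, params)
  # occasion-constant detection: counts per detector are sufficient
  m_k <- colSums(omega_i)
  prod(g^m_k * (1 - g)^(array$n_occasions - m_k))
}

#' Effective sampling area
#'
#' The effective sampling area of one array,
#' \eqn{a(\theta) = \int p_\cdot(x)\,dx}, approximated on a habitat mask as
#' the sum of the overall detection probability at each cell centre times
#' the cell area.
#'
#' @param params A [detection_params].
#' @param array A [detector_array].
#' @param mask A [habitat_mask] for the array.
#' @return Effective sampling area in km^2.
#' @examples
#' tr <- grid_array("A1", centre = c(0, 0))
#' m <- build_mask(tr, 6000, 750)
#' effective_area(detection_params(0.3, 1500), tr, m)
#' @export
effective_area <- function(params, array, mask) {
  stopifnot(inherits(params, "detection_params"),
            inherits(mask, "habitat_mask"))
  d <- dist_to_detectors(mask_points(mask), array)
  sum(pdot_from_dist(d, params$g0, params$sigma, array$n_occasions)) *
    mask$cell_area_km2
}

#' Conditional negative log-likelihood for one array
#'
#' The SECR likelihood for binary proximity-detector data conditioned on
#' the number of detected animals `n`; density drops out and only the
#' detection parameters remain. Each detected animal contributes
#' \deqn{\Pr(\omega_i) = \int \Pr(\omega_i \mid x)\,dx \,/\, a(\theta),}
#' with both integrals evaluated over the habitat mask.
#'
#' @param params_link Length-2 numeric: `logit(g0)`, `log(sigma)`.
#' @param data A [capture_data] with at least one animal.
#' @param array The [detector_array] sampled.
#' @param mask A [habitat_mask] for the array.
#' @return The negative log-likelihood (scalar).
#' @export
conditional_nll <- function(params_link, data, array, mask) {
  if (!all(is.finite(params_link)) || length(params_link) != 2L) {
    stop("'params_link' must be two finite link-scale values")
  }
  stopifnot(inherits(data, "capture_data"))
  if (data$n < 1L) stop("conditional likelihood requires n >= 1")
  ev <- make_array_eval(data, array, mask)
  th <- link_to_theta(params_link)
  ev(th$g0, th$sigma)
}

# Build a fast evaluator of the per-array conditional nll. Precomputes the
# squared-distance matrix (mask cells x detectors) and the sufficient
# detection-count matrix; returns function(g0, sigma) -> nll contribution.
# Cell area cancels between the numerator integral and a(theta), so the
# evaluator works in cell units.
#
# Algebra used below, writing c = -1/(2 sigma^2) and counts C[i, k]:
#   log Pr(omega_i | x_m) = sum_k C[i,k] log g(m,k)
#                         + sum_k (S - C[i,k]) log(1 - g(m,k))
#                         = m_i log g0 + c * (d2 C')[m,i]
#                         + S * rowSums(log(1-g))[m] - W[m,i],
# with W[m,i] = sum_k C[i,k] log(1 - g(m,k)). The term d2 C' does not
# depend on theta and is precomputed once per fit, leaving one dense
# product (W) per evaluation.
#
# `cache` (an environment shared by the evaluators of one joint model)
# memoizes the M x K detection field per (geometry, g0, sigma): replicate
# arrays with identical layout and mask reuse it within one likelihood
# evaluation.
make_array_eval <- function(data, array, mask, cache = NULL,
                            geom_key = "g1") {
  d2 <- dist_to_detectors(mask_points(mask), array)^2
  S <- array$n_occasions
  C <- detection_counts(data, array)          # n x K counts
  n <- data$n
  M <- nrow(d2)
  tC <- t(C)                                  # K x n
  m_i <- .rowSums(C, n, ncol(C))              # detections per animal
  tD2C <- if (n > 0L) d2 %*% tC else NULL     # M x n, theta-independent
  force(cache)
  function(g0, sigma) {
    cc <- -0.5 / sigma^2
    key <- paste(geom_key, g0, sigma)
    mk <- if (!is.null(cache)) cache[[key]] else NULL
    if (is.null(mk)) {
      l1g <- log1p(-g0 * exp(d2 * cc))        # M x K
      rl1g <- .rowSums(l1g, M, ncol(l1g))
      mk <- list(l1g = l1g, rl1g = rl1g,
                 a_log = log(sum(-expm1(S * rl1g))))
      if (!is.null(cache)) cache[[key]] <- mk
    }
    if (n == 0L) return(0)                    # no animals: no terms
    # log Pr(omega_i | x_m) assembled from the memoized field:
    # W[, i] = sum_k C[i, k] log(1 - g(m, k))
    logPr <- (cc * tD2C + (S * mk$rl1g) - mk$l1g %*% tC) +
      rep(log(g0) * m_i, each = M)
    Li <- .colSums(exp(logPr), M, n)
    if (any(Li == 0)) {
      # total underflow (pathological parameters): log-sum-exp rescue
      mx <- apply(logPr, 2L, max)
      Li <- colSums(exp(logPr - rep(mx, each = M)))
      return(-sum(log(Li) + mx) + n * mk$a_log)
    }
    -sum(log(Li)) + n * mk$a_log
  }
}

# Effective area in km^2 from a cached squared-distance matrix.
area_from_d2 <- function(d2, g0, sigma, S, cell_area_km2) {
  g <- g0 * exp(d2 * (-0.5 / sigma^2))
  sum(-expm1(S * rowSums(log1p(-g)))) * cell_area_km2
}
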