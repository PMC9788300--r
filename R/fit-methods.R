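#' @export
print.secr_fit <- function(x, ...) {
  cat("Half-normal SECR fit (conditional likelihood)\n")
  cat(sprintf("  sharing: %s; arrays: %s\n", x$sharing,
              paste(x$array_ids, collapse = ", ")))
  if (!isTRUE(x$converged)) {
    cat(sprintf("  NOT CONVERGED: %s (n = %s)\n", x$failure_reason,
                paste(x$n_j, collapse = ", ")))
    return(invisible(x))
  }
  for (j in seq_along(x$array_ids)) {
    cat(sprintf("  %s: n = %d, g0 = %.4f, sigma = %.1f m, a = %.1f km2, D = %.2f (%.2f-%.2f) per 100 km2\n",
                x$array_ids[j], x$n_j[j], x$theta$g0[j], x$theta$sigma[j],
                x$derived$a_hat_km2[j], x$derived$D_hat[j],
                x$derived$lcl[j], x$derived$ucl[j]))
  }
  if (length(x$array_ids) > 1L) {
    cat(sprintf("  pooled: n = %d, A = %.1f km2, D = %.2f (%.2f-%.2f) per 100 km2\n",
                x$total$n, x$total$A_hat_km2, x$total$D_hat,
                x$total$ci[1L], x$total$ci[2L]))
  }
  cat(sprintf("  logLik = %.3f, params = %d, AICc = %.3f\n",
              x$loglik, x$n_params, x$aicc))
  invisible(x)
}

#' @export
summary.secr_fit <- function(object, ...) {
  structure(list(sharing = object$sharing,
                 converged = object$converged,
                 failure_reason = object$failure_reason,
                 theta = object$theta, derived = object$derived,
                 total = object$total, loglik = object$loglik,
                 n_params = object$n_params, aicc = object$aicc),
            class = "summary.secr_fit")
}

#' @export
print.summary.secr_fit <- function(x, ...) {
  cat(sprintf("SECR conditional-likelihood fit (%s detection parameters)\n",
              x$sharing))
  if (!isTRUE(x$converged)) {
    cat(sprintf("  fit failed: %s\n", x$failure_reason))
    return(invisible(x))
  }
  cat("\nDetection parameters:\n")
  print(x$theta, row.names = FALSE)
  cat("\nDerived densities (per 100 km2, lognormal 95% CI):\n")
  print(x$derived, row.names = FALSE, digits = 4L)
  cat(sprintf("\nlogLik %.3f, %d parameters, AICc %.3f\n",
              x$loglik, x$n_params, x$aicc))
  invisible(x)
}

#' Extract detection-parameter estimates
#'
#' @param object A fitted `secr_fit`.
#' @param scale `"natural"` for `(g0, sigma)` per array, `"link"` for the
#'   raw link-scale parameter vector.
#' @param ... Unused.
#' @return A data frame (natural scale) or named numeric vector (link).
#' @export
coef.secr_fit <- function(object, scale = c("natural", "link"), ...) {
  scale <- match.arg(scale)
  if (!isTRUE(object$converged)) return(NULL)
  if (scale == "link") object$par else object$theta
}

#' @export
vcov.secr_fit <- function(object, ...) object$vcov_link

#' @export
logLik.secr_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n,
            class = "logLik")
}

#' Predicted detection probability by distance
#'
#' @param object A fitted `secr_fit`.
#' @param distance_m Distances (metres) at which to evaluate the fitted
#'   half-normal detection function.
#' @param ... Unused.
#' @return Data frame with columns `array_id`, `distance_m`, `g`.
#' @export
predict.secr_fit <- function(object, distance_m = seq(0, 6000, by = 100),
                             ...) {
  if (!isTRUE(object$converged)) stop("cannot predict from a failed fit")
  out <- lapply(seq_len(nrow(object$theta)), function(j) {
    data.frame(array_id = object$theta$array_id[j],
               distance_m = distance_m,
               g = half_normal_g(distance_m, object$theta$g0[j],
                                 object$theta$sigma[j]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Plot the fitted detection function
#'
#' @param x A fitted `secr_fit`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.secr_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) stop("cannot plot a failed fit")
  d <- seq(0, 4 * max(x$theta$sigma), length.out = 200L)
  g <- sapply(seq_len(nrow(x$theta)), function(j) {
    half_normal_g(d, x$theta$g0[j], x$theta$sigma[j])
  })
  graphics::matplot(d / 1000, g, type = "l", lty = 1L,
                    xlab = "Distance from activity centre (km)",
                    ylab = "Detection probability per occasion", ...)
  graphics::legend("topright", legend = x$theta$array_id, lty = 1L,
                   col = seq_len(nrow(x$theta)), bty = "n")
  invisible(x)
}

#' Confidence intervals for detection parameters
#'
#' Wald intervals on the link scale, back-transformed to the natural
#' scale.
#'
#' @param object A fitted `secr_fit`.
#' @param parm Unused (all parameters are returned).
#' @param level Confidence level.
#' @param ... Unused.
#' @return Data frame of per-array `g0` and `sigma` intervals.
#' @export
confint.secr_fit <- function(object, parm, level = 0.95, ...) {
  if (!isTRUE(object$converged)) stop("fit did not converge")
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(diag(object$vcov_link))
  lo <- object$par - z * se
  hi <- object$par + z * se
  nat <- function(v, nm) {
    ifelse(grepl("g0", nm), stats::plogis(v),
           ifelse(grepl("sigma", nm), exp(v), v))
  }
  nm <- names(object$par)
  data.frame(parameter = nm,
             estimate = nat(object$par, nm),
             lcl = nat(lo, nm), ucl = nat(hi, nm),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Parametric simulation from a fitted model
#'
#' Generates new capture data from the fitted detection parameters and
#' densities: activity centres are drawn as a Poisson process with the
#' fitted density over each array's habitat mask, and binary detections
#' follow the fitted half-normal model.
#'
#' @param object A converged `secr_fit`.
#' @param nsim Number of replicate data sets.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of length `nsim`; each element is a list of
#'   [capture_data], one per array.
#' @export
simulate.secr_fit <- function(object, nsim = 1L, seed = NULL, ...) {
  if (!isTRUE(object$converged)) stop("cannot simulate from a failed fit")
  if (!is.null(seed)) set.seed(seed)
  J <- length(object$array_ids)
  out <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    sims <- vector("list", J)
    for (j in seq_len(J)) {
      mask <- object$masks[[j]]
      arr <- object$traps[[j]]
      D <- object$derived$D_hat[j]
      N <- stats::rpois(1L, D / 100 * mask_area_km2(mask))
      idx <- sample.int(mask$n_cells, N, replace = TRUE)
      half <- mask$cell_side_m / 2
      xs <- mask$x[idx] + stats::runif(N, -half, half)
      ys <- mask$y[idx] + stats::runif(N, -half, half)
      sims[[j]] <- simulate_histories(
        xs, ys, rep(object$theta$g0[j], N), rep(object$theta$sigma[j], N),
        arr, id_prefix = sprintf("sim%d_", r))
    }
    names(sims) <- object$array_ids
    out[[r]] <- sims
  }
  out
}

#' @export
print.secr_fit_list <- function(x, ...) {
  cat(sprintf("Independent SECR fits to %d arrays:\n", length(x)))
  for (f in x) print(f)
  invisible(x)
}

#' @export
summary.secr_fit_list <- function(object, ...) {
  comp <- fit_components(object)
  cat("Per-array components from independent fits:\n")
  print(comp, row.names = FALSE, digits = 4L)
  invisible(comp)
}
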