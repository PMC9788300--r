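#' Fit a half-normal SECR model by maximizing the conditional likelihood
#'
#' The package's central model-fitting function. Estimates the detection
#' parameters `(g0, sigma)` of a half-normal detection function from
#' binary proximity-detector capture histories by maximizing the
#' likelihood conditional on the number of detected animals; density then
#' follows from the Horvitz-Thompson-like estimator
#' \eqn{\hat D = n / \hat a}, with \eqn{\hat a} the estimated effective
#' sampling area. Replicate arrays can be analysed separately
#' (`sharing = "independent"`) or jointly with detection parameters shared
#' fully (`"constant"`), shared up to additive link-scale array offsets
#' (`"additive"`), or estimated separately per array within one model
#' (`"interactive"`).
#'
#' Estimation is on the link scale (logit for `g0`, log for `sigma`).
#' Start values are `g0 = 0.2` and a root-pooled-spatial-variance (RPSV)
#' heuristic for `sigma`, falling back to half the detector spacing when
#' there are no spatial recaptures. Unless a buffer is supplied, the
#' habitat mask uses a buffer of 4 x the `sigma` start value and is
#' rebuilt once with a 4 x `sigma-hat` buffer if `sigma` is estimated
#' larger than its start (guarding against truncation of the integration
#' region), and a cell side of `min(sigma_start / 2, spacing / 2)`.
#'
#' An array is considered estimable only with at least `min_n` animals
#' and `min_spatial_recaptures` spatial recaptures; below that (or on
#' optimizer failure / a non-positive-definite Hessian) a non-converged
#' fit object is returned rather than an error, so that simulation studies
#' can record failures.
#'
#' @param captures A [capture_data] object or list of them (one per
#'   array).
#' @param traps A [detector_array] or list of them, matched to `captures`
#'   by `array_id`.
#' @param sharing How detection parameters relate across arrays:
#'   `"independent"` fits each array separately and returns a list of
#'   fits; `"constant"`, `"additive"` and `"interactive"` fit one joint
#'   model. With a single array all choices coincide.
#' @param buffer_m Habitat-mask buffer in metres; default `4 * sigma`
#'   start value with a second pass at `4 * sigma-hat` (see Details).
#' @param cell_side_m Mask cell side in metres; default
#'   `min(sigma_start / 2, spacing / 2)`.
#' @param offset_terms For `sharing = "additive"`: which parameters get
#'   per-array additive link-scale offsets (`"g0"`, `"sigma"`, or both).
#' @param start Optional link-scale start vector overriding the defaults.
#' @param two_pass Rebuild the mask once if `sigma` is estimated above its
#'   start value (default `TRUE`; ignored when `buffer_m` is given).
#' @param min_n,min_spatial_recaptures Minimum-data rule (per array for
#'   independent fits, on the pooled totals otherwise).
#' @param control Passed to [stats::optim()] (defaults: `reltol = 1e-10`,
#'   `maxit = 500`).
#' @return An object of class `"secr_fit"` (or `"secr_fit_list"`, a list
#'   of them, for `sharing = "independent"` with several arrays). Key
#'   fields: `theta` (per-array `g0`, `sigma`), `par`/`vcov_link`
#'   (link-scale MLE and covariance), `derived` (per-array `n`,
#'   effective sampling area `a_hat_km2` with SE, density `D_hat` per
#'   100 km^2 with SE and lognormal 95% CI), `total` (pooled density
#'   across the arrays in the model), `loglik`, `aicc`, `converged`.
#' @seealso [region_estimate()] to combine replicate fits;
#'   [simulate.secr_fit()] for parametric resampling.
#' @examples
#' sc <- make_scenario(1)
#' pop <- sample_population(sc, seed = 1)
#' capts <- simulate_captures(pop, sc, seed = 2)
#' fit <- fit_secr(capts[[1]], sc$design[[1]])
#' fit
#' @export
fit_secr <- function(captures, traps,
                     sharing = c("independent", "constant", "additive",
                                 "interactive"),
                     buffer_m = NULL, cell_side_m = NULL,
                     offset_terms = c("g0", "sigma"),
                     start = NULL, two_pass = TRUE,
                     min_n = 5L, min_spatial_recaptures = 1L,
                     control = list()) {
  sharing <- match.arg(sharing)
  if (inherits(captures, "capture_data")) captures <- list(captures)
  if (inherits(traps, "detector_array")) traps <- list(traps)
  stopifnot(length(captures) >= 1L, length(traps) == length(captures))
  # align by array_id
  cap_ids <- vapply(captures, `[[`, "", "array_id")
  trap_ids <- vapply(traps, `[[`, "", "array_id")
  if (!setequal(cap_ids, trap_ids) || anyDuplicated(cap_ids)) {
    stop("'captures' and 'traps' must cover the same unique array ids")
  }
  traps <- traps[match(cap_ids, trap_ids)]
  J <- length(captures)
  cl <- match.call()

  if (sharing == "independent" && J > 1L) {
    fits <- lapply(seq_len(J), function(j) {
      fit_secr(captures[[j]], traps[[j]], sharing = "independent",
               buffer_m = buffer_m, cell_side_m = cell_side_m,
               start = start, two_pass = two_pass, min_n = min_n,
               min_spatial_recaptures = min_spatial_recaptures,
               control = control)
    })
    names(fits) <- cap_ids
    return(structure(fits, class = "secr_fit_list"))
  }
  if (J < 2L && sharing %in% c("constant", "additive", "interactive")) {
    sharing <- "independent"   # pooled modes need >= 2 arrays
  }
  offset_terms <- match.arg(offset_terms, several.ok = TRUE)
  fit_secr_core(captures, traps, sharing, offset_terms, buffer_m,
                cell_side_m, start, two_pass, min_n,
                min_spatial_recaptures, control, cl)
}

# ---- internal machinery ----------------------------------------------------

# Parameter layout per sharing mode: a function mapping the link-scale
# parameter vector to a J x 2 matrix of (logit g0, log sigma) rows.
param_layout <- function(sharing, J, offset_terms) {
  if (sharing %in% c("independent", "constant")) {
    list(npar = 2L,
         names = c("logit_g0", "log_sigma"),
         theta_links = function(par) {
           matrix(par[1:2], nrow = J, ncol = 2L, byrow = TRUE)
         })
  } else if (sharing == "additive") {
    ng <- ("g0" %in% offset_terms) * (J - 1L)
    ns <- ("sigma" %in% offset_terms) * (J - 1L)
    nm <- c("logit_g0", "log_sigma",
            if (ng) paste0("dg0_", 2:J), if (ns) paste0("dsigma_", 2:J))
    list(npar = 2L + ng + ns, names = nm,
         theta_links = function(par) {
           lg0 <- rep(par[1L], J)
           lsig <- rep(par[2L], J)
           if (ng) lg0[2:J] <- lg0[2:J] + par[2L + seq_len(ng)]
           if (ns) lsig[2:J] <- lsig[2:J] + par[2L + ng + seq_len(ns)]
           cbind(lg0, lsig)
         })
  } else { # interactive: one (g0, sigma) per array in a single model
    nm <- as.vector(rbind(paste0("logit_g0_", 1:J),
                          paste0("log_sigma_", 1:J)))
    list(npar = 2L * J, names = nm,
         theta_links = function(par) {
           matrix(par, nrow = J, ncol = 2L, byrow = TRUE)
         })
  }
}

# Root pooled spatial variance of detection locations about animal-level
# means; a standard data-driven starting value for sigma.
rpsv_sigma <- function(captures, traps) {
  ss <- 0
  df <- 0L
  for (j in seq_along(captures)) {
    ev <- captures[[j]]$events
    if (!nrow(ev)) next
    det <- traps[[j]]$detectors
    xy <- det[match(ev$detector, det$id), c("x", "y")]
    for (idx in split(seq_len(nrow(ev)), ev$animal)) {
      m <- length(idx)
      if (m < 2L) next
      ss <- ss + sum((xy$x[idx] - mean(xy$x[idx]))^2 +
                       (xy$y[idx] - mean(xy$y[idx]))^2)
      df <- df + (m - 1L)
    }
  }
  if (df == 0L || ss == 0) return(NA_real_)
  sqrt(ss / (2 * df))
}

fit_failure <- function(cl, sharing, ids, nj, reason) {
  structure(
    list(call = cl, sharing = sharing, array_ids = ids, n_j = nj,
         n = sum(nj), converged = FALSE, failure_reason = reason,
         theta = NULL, par = NULL, vcov_link = NULL, derived = NULL,
         total = NULL, loglik = NA_real_, n_params = NA_integer_,
         aicc = NA_real_, n_evaluations = 0L),
    class = "secr_fit")
}

fit_secr_core <- function(captures, traps, sharing, offset_terms,
                          buffer_m, cell_side_m, start, two_pass,
                          min_n, min_spatial, control, cl) {
  J <- length(captures)
  ids <- vapply(captures, `[[`, "", "array_id")
  nj <- vapply(captures, `[[`, 0L, "n")
  spat <- vapply(captures, n_spatial_recaptures, 0L)

  # minimum-data rule: per array when fitted alone, on totals when pooled
  if (J == 1L) {
    ok <- nj[1L] >= min_n && spat[1L] >= min_spatial
  } else {
    ok <- sum(nj) >= min_n && sum(spat) >= min_spatial
  }
  if (!ok) {
    return(fit_failure(cl, sharing, ids, nj, "insufficient data"))
  }

  spacing <- min(vapply(traps, detector_spacing, 0), na.rm = TRUE)
  sigma_start <- rpsv_sigma(captures, traps)
  if (!is.finite(sigma_start) || sigma_start <= 0) {
    sigma_start <- spacing / 2
  }
  cell <- if (is.null(cell_side_m)) {
    min(sigma_start / 2, spacing / 2)
  } else cell_side_m

  lay <- param_layout(sharing, J, offset_terms)
  if (is.null(start)) {
    par0 <- numeric(lay$npar)
    base <- c(stats::qlogis(0.2), log(sigma_start))
    if (sharing == "interactive") {
      par0 <- rep(base, J)
    } else {
      par0[1:2] <- base
    }
  } else {
    stopifnot(length(start) == lay$npar)
    par0 <- start
  }

  ctl <- utils::modifyList(list(reltol = 1e-10, maxit = 500L), control)
  n_eval <- 0L

  build_evals <- function(buffers) {
    masks <- lapply(seq_len(J), function(j) {
      build_mask(traps[[j]], buffers[j], cell)
    })
    d2s <- lapply(seq_len(J), function(j) {
      dist_to_detectors(mask_points(masks[[j]]), traps[[j]])^2
    })
    # replicate arrays with identical relative geometry share one
    # detection-field computation per likelihood evaluation
    cache <- new.env(parent = emptyenv())
    geom <- integer(J)
    reps <- list()
    for (j in seq_len(J)) {
      hit <- 0L
      for (r in seq_along(reps)) {
        if (identical(dim(d2s[[j]]), dim(d2s[[reps[[r]]]])) &&
            isTRUE(all.equal(d2s[[j]], d2s[[reps[[r]]]],
                             tolerance = 1e-12))) {
          hit <- r
          break
        }
      }
      if (hit == 0L) {
        reps[[length(reps) + 1L]] <- j
        hit <- length(reps)
      }
      geom[j] <- hit
    }
    evals <- lapply(seq_len(J), function(j) {
      make_array_eval(captures[[j]], traps[[j]], masks[[j]],
                      cache = cache, geom_key = paste0("g", geom[j]))
    })
    list(masks = masks, evals = evals, d2s = d2s, cache = cache)
  }

  run_optim <- function(ev, par_start) {
    nll <- function(par) {
      n_eval <<- n_eval + 1L
      # fresh memo per evaluation: identical-geometry arrays sharing
      # parameters reuse the detection field within this evaluation
      rm(list = ls(ev$cache), envir = ev$cache)
      th <- lay$theta_links(par)
      tot <- 0
      for (j in seq_len(J)) {
        t_j <- link_to_theta(th[j, ])
        tot <- tot + ev$evals[[j]](t_j$g0, t_j$sigma)
      }
      if (!is.finite(tot)) return(1e10)
      tot
    }
    # quasi-Newton from the heuristic start; one deterministically
    # perturbed restart, then a derivative-free fallback, on failure
    try_opt <- function(p0, method) {
      tryCatch(stats::optim(p0, nll, method = method, control = ctl),
               error = function(e) list(convergence = 99L, value = Inf,
                                        par = p0))
    }
    opt <- try_opt(par_start, "BFGS")
    if (opt$convergence != 0L) {
      pert <- par_start + 0.5 * rep_len(c(1, -1), lay$npar)
      opt2 <- try_opt(pert, "BFGS")
      if (opt2$value < opt$value) opt <- opt2
    }
    if (opt$convergence != 0L) {
      opt3 <- try_opt(par_start, "Nelder-Mead")
      if (opt3$convergence == 0L) {
        # polish the simplex optimum back on the quasi-Newton path
        opt4 <- try_opt(opt3$par, "BFGS")
        opt <- if (opt4$convergence == 0L && opt4$value <= opt3$value)
          opt4 else opt3
      }
    }
    list(opt = opt, nll = nll)
  }

  buffers <- rep(if (is.null(buffer_m)) 4 * sigma_start else buffer_m, J)
  ev <- build_evals(buffers)
  res <- run_optim(ev, par0)

  # second pass: widen the mask if sigma-hat materially exceeded its start
  # value (a 4 x sigma-start buffer still covers estimates a few percent
  # above the start, so small excesses do not warrant a refit)
  if (is.null(buffer_m) && two_pass) {
    th <- lay$theta_links(res$opt$par)
    sig_hat <- vapply(seq_len(J),
                      function(j) link_to_theta(th[j, ])$sigma, 0)
    if (max(sig_hat) > 1.1 * sigma_start) {
      buffers <- 4 * pmax(sig_hat, sigma_start)
      ev <- build_evals(buffers)
      res <- run_optim(ev, res$opt$par)
    }
  }
  opt <- res$opt
  if (opt$convergence != 0L) {
    return(fit_failure(cl, sharing, ids, nj, "optimizer did not converge"))
  }

  par_hat <- opt$par
  names(par_hat) <- lay$names
  H <- fd_hessian(res$nll, par_hat)
  V <- pd_inverse(H)
  if (is.null(V)) {
    return(fit_failure(cl, sharing, ids, nj,
                       "Hessian not positive definite"))
  }
  dimnames(V) <- list(lay$names, lay$names)

  th_links <- lay$theta_links(par_hat)
  theta <- data.frame(
    array_id = ids,
    g0 = vapply(seq_len(J), function(j) link_to_theta(th_links[j, ])$g0, 0),
    sigma = vapply(seq_len(J),
                   function(j) link_to_theta(th_links[j, ])$sigma, 0),
    stringsAsFactors = FALSE)

  # per-array effective areas, delta-method variances on the link scale
  area_j <- function(par, j) {
    t_j <- link_to_theta(lay$theta_links(par)[j, ])
    area_from_d2(ev$d2s[[j]], t_j$g0, t_j$sigma,
                 traps[[j]]$n_occasions, ev$masks[[j]]$cell_area_km2)
  }
  a_hat <- numeric(J)
  grads <- matrix(0, nrow = J, ncol = lay$npar)
  for (j in seq_len(J)) {
    a_hat[j] <- area_j(par_hat, j)
    grads[j, ] <- fd_gradient(function(p) area_j(p, j), par_hat)
  }
  var_a <- vapply(seq_len(J),
                  function(j) drop(grads[j, ] %*% V %*% grads[j, ]), 0)
  var_a <- pmax(var_a, 0)
  if (any(a_hat <= 0)) {
    return(fit_failure(cl, sharing, ids, nj, "non-positive effective area"))
  }

  # local density per array: HT-like estimator with Poisson var(n) = n
  if (sharing %in% c("independent", "interactive")) {
    D_j <- 100 * nj / a_hat
    var_D_j <- ifelse(nj > 0,
                      D_j^2 * (1 / nj + var_a / a_hat^2), NA_real_)
  } else {
    # constant-density pooled model: one common density for all arrays
    gA <- colSums(grads)
    A_ <- sum(a_hat)
    vA <- max(drop(gA %*% V %*% gA), 0)
    Dc <- 100 * sum(nj) / A_
    vDc <- Dc^2 * (1 / sum(nj) + vA / A_^2)
    D_j <- rep(Dc, J)
    var_D_j <- rep(vDc, J)
  }
  ci_j <- t(vapply(seq_len(J), function(j) {
    if (is.na(var_D_j[j]) || D_j[j] <= 0) c(NA_real_, NA_real_)
    else lognormal_ci(D_j[j], var_D_j[j])
  }, numeric(2L)))

  derived <- data.frame(
    array_id = ids, n = nj,
    spatial_recaptures = spat,
    a_hat_km2 = a_hat, se_a_hat = sqrt(var_a),
    D_hat = D_j, se_D = sqrt(var_D_j),
    lcl = ci_j[, 1L], ucl = ci_j[, 2L],
    stringsAsFactors = FALSE)

  # pooled totals across the arrays in this model (Horvitz-Thompson on
  # the summed effective area); for a single array this equals the local
  # estimate
  gA <- colSums(grads)
  A_hat <- sum(a_hat)
  var_A <- max(drop(gA %*% V %*% gA), 0)
  n_tot <- sum(nj)
  D_tot <- 100 * n_tot / A_hat
  var_D_tot <- D_tot^2 * (1 / n_tot + var_A / A_hat^2)
  total <- list(n = n_tot, A_hat_km2 = A_hat, var_A_hat = var_A,
                D_hat = D_tot, var_D = var_D_tot,
                ci = lognormal_ci(D_tot, var_D_tot))

  p <- lay$npar
  ll <- -opt$value
  aicc <- if (n_tot > p + 1L) {
    -2 * ll + 2 * p + 2 * p * (p + 1) / (n_tot - p - 1)
  } else NA_real_

  structure(
    list(call = cl, sharing = sharing, array_ids = ids, n_j = nj,
         n = n_tot, converged = TRUE, failure_reason = NULL,
         theta = theta, par = par_hat, vcov_link = V,
         traps = traps, masks = ev$masks, derived = derived, total = total,
         loglik = ll, n_params = p, aicc = aicc,
         sigma_start = sigma_start, buffers_m = buffers,
         cell_side_m = cell, n_evaluations = n_eval),
    class = "secr_fit")
}

# Per-array components used by the design-based regional estimators.
fit_components <- function(fit) {
  UseMethod("fit_components")
}

#' @export
fit_components.secr_fit <- function(fit) {
  if (!isTRUE(fit$converged)) {
    return(data.frame(array_id = fit$array_ids, n = fit$n_j,
                      a_hat_km2 = NA_real_, var_a_hat = NA_real_,
                      D_hat = NA_real_, converged = FALSE,
                      stringsAsFactors = FALSE))
  }
  d <- fit$derived
  data.frame(array_id = d$array_id, n = d$n, a_hat_km2 = d$a_hat_km2,
             var_a_hat = d$se_a_hat^2,
             D_hat = 100 * d$n / d$a_hat_km2, converged = TRUE,
             stringsAsFactors = FALSE)
}

#' @export
fit_components.secr_fit_list <- function(fit) {
  do.call(rbind, lapply(fit, fit_components))
}
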