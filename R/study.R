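#' Percent relative bias
#'
#' @param estimate Numeric estimates.
#' @param truth Positive true value(s).
#' @return `100 * (estimate - truth) / truth`.
#' @examples
#' prb(9, 12)   # -25
#' @export
prb <- function(estimate, truth) {
  if (any(!is.finite(truth)) || any(truth <= 0)) {
    stop("'truth' must be positive")
  }
  100 * (estimate - truth) / truth
}

#' True local and regional densities for a scenario
#'
#' @param scenario A [make_scenario()] object.
#' @return List with `local` (data frame of per-array true density) and
#'   `regional` (mean of the per-array truths).
#' @export
scenario_truths <- function(scenario) {
  D <- scenario$bands$D_per_100km2[scenario$array_band]
  list(local = data.frame(array_id = names(scenario$design), D_true = D,
                          stringsAsFactors = FALSE),
       regional = mean(D))
}

#' Run the replicated-array simulation study
#'
#' For each iteration: simulate a population and its proximity-detector
#' capture data; fit the half-normal SECR model to each array separately
#' (independent analysis) and/or one constant-density,
#' constant-detectability model to the pooled data; compute local density
#' estimates with Poisson variances and lognormal CIs, the mean-density
#' regional estimate with both Poisson and empirical variances
#' (independent analyses), and the pooled-model regional estimate with
#' its delta-method Poisson variance.
#'
#' A master seed spawns two child seeds per iteration (population and
#' detection processes), recorded in the output so any iteration can be
#' regenerated in isolation.
#'
#' @param scenario_id Scenario 1-4 (see [make_scenario()]).
#' @param iterations Number of simulated surveys.
#' @param seed Master seed.
#' @param analyses Any of `"independent"`, `"pooled"`.
#' @param fit_args Extra arguments passed to [fit_secr()].
#' @param progress Print a dot every 10 iterations.
#' @return An object of class `"secr_study"`: `local` and `regional`
#'   record data frames (one row per iteration x array / analysis),
#'   `seeds`, `truths`, and `summary` (see [summarize_study()]).
#' @export
run_study <- function(scenario_id, iterations, seed,
                      analyses = c("independent", "pooled"),
                      fit_args = list(), progress = FALSE) {
  stopifnot(iterations >= 1L)
  analyses <- match.arg(analyses, several.ok = TRUE)
  scenario <- make_scenario(scenario_id)
  truths <- scenario_truths(scenario)
  set.seed(seed)
  child <- matrix(sample.int(.Machine$integer.max - 1L, 2L * iterations),
                  ncol = 2L)
  loc_rows <- list()
  reg_rows <- list()
  for (it in seq_len(iterations)) {
    pop <- sample_population(scenario, child[it, 1L])
    capts <- simulate_captures(pop, scenario, child[it, 2L])
    stats_ <- captures_summary(capts)
    if ("independent" %in% analyses) {
      fits <- do.call(fit_secr, c(list(capts, scenario$design,
                                       sharing = "independent"),
                                  fit_args))
      loc_rows[[length(loc_rows) + 1L]] <-
        local_records(fits, stats_, it, "independent")
      comp <- fit_components(fits)
      reg_rows[[length(reg_rows) + 1L]] <-
        regional_record_independent(comp, it)
    }
    if ("pooled" %in% analyses) {
      pfit <- do.call(fit_secr, c(list(capts, scenario$design,
                                       sharing = "constant"),
                                  fit_args))
      loc_rows[[length(loc_rows) + 1L]] <-
        local_records(pfit, stats_, it, "pooled")
      reg_rows[[length(reg_rows) + 1L]] <-
        regional_record_pooled(pfit, it)
    }
    if (progress && it %% 10L == 0L) cat(".")
  }
  if (progress) cat("\n")
  local <- do.call(rbind, loc_rows)
  regional <- do.call(rbind, reg_rows)
  summary <- summarize_study(local, regional, truths)
  structure(
    list(scenario_id = scenario_id, iterations = iterations,
         master_seed = seed, seeds = child, analyses = analyses,
         truths = truths, local = local, regional = regional,
         summary = summary),
    class = "secr_study")
}

local_records <- function(fit, stats_, iteration, analysis) {
  if (inherits(fit, "secr_fit_list")) {
    rows <- lapply(fit, function(f) {
      if (isTRUE(f$converged)) {
        d <- f$derived
        data.frame(array_id = f$array_ids, D_hat = d$D_hat, se = d$se_D,
                   lcl = d$lcl, ucl = d$ucl, converged = TRUE,
                   stringsAsFactors = FALSE)
      } else {
        data.frame(array_id = f$array_ids, D_hat = NA_real_,
                   se = NA_real_, lcl = NA_real_, ucl = NA_real_,
                   converged = FALSE, stringsAsFactors = FALSE)
      }
    })
    out <- do.call(rbind, rows)
  } else if (isTRUE(fit$converged)) {
    d <- fit$derived
    out <- data.frame(array_id = d$array_id, D_hat = d$D_hat,
                      se = d$se_D, lcl = d$lcl, ucl = d$ucl,
                      converged = TRUE, stringsAsFactors = FALSE)
  } else {
    out <- data.frame(array_id = fit$array_ids, D_hat = NA_real_,
                      se = NA_real_, lcl = NA_real_, ucl = NA_real_,
                      converged = FALSE, stringsAsFactors = FALSE)
  }
  m <- match(out$array_id, stats_$array_id)
  cbind(data.frame(iteration = iteration, analysis = analysis,
                   stringsAsFactors = FALSE),
        out[, "array_id", drop = FALSE],
        stats_[m, c("n", "recaptures", "spatial_recaptures")],
        out[, setdiff(names(out), "array_id")],
        row.names = NULL)
}

regional_record_independent <- function(comp, iteration) {
  all_ok <- all(comp$converged)
  if (all_ok) {
    re <- region_estimate(comp, estimator = "mean")
    data.frame(iteration = iteration, analysis = "independent",
               J_used = re$J, all_converged = TRUE,
               D_hat = re$D_region,
               var_poisson = re$var_poisson,
               lcl_p = re$ci_poisson[1L], ucl_p = re$ci_poisson[2L],
               var_empirical = re$var_empirical,
               lcl_e = re$ci_empirical[1L], ucl_e = re$ci_empirical[2L],
               stringsAsFactors = FALSE)
  } else {
    data.frame(iteration = iteration, analysis = "independent",
               J_used = sum(comp$converged), all_converged = FALSE,
               D_hat = NA_real_, var_poisson = NA_real_,
               lcl_p = NA_real_, ucl_p = NA_real_,
               var_empirical = NA_real_, lcl_e = NA_real_,
               ucl_e = NA_real_, stringsAsFactors = FALSE)
  }
}

regional_record_pooled <- function(pfit, iteration) {
  if (isTRUE(pfit$converged)) {
    tot <- pfit$total
    data.frame(iteration = iteration, analysis = "pooled",
               J_used = length(pfit$array_ids), all_converged = TRUE,
               D_hat = tot$D_hat, var_poisson = tot$var_D,
               lcl_p = tot$ci[1L], ucl_p = tot$ci[2L],
               var_empirical = NA_real_, lcl_e = NA_real_,
               ucl_e = NA_real_, stringsAsFactors = FALSE)
  } else {
    data.frame(iteration = iteration, analysis = "pooled",
               J_used = 0L, all_converged = FALSE, D_hat = NA_real_,
               var_poisson = NA_real_, lcl_p = NA_real_,
               ucl_p = NA_real_, var_empirical = NA_real_,
               lcl_e = NA_real_, ucl_e = NA_real_,
               stringsAsFactors = FALSE)
  }
}

#' Summarize study records into bias / precision / coverage tables
#'
#' Local estimates are summarized per array position and analysis mode
#' (median, mean percent relative bias, mean relative SE, and coverage of
#' the 95% lognormal CIs); regional estimates per analysis mode and
#' variance estimator, with percent RSEs. Iterations where an estimate
#' does not exist (failed fits) are excluded from its summaries, with
#' counts reported; coverage carries a binomial Monte Carlo standard
#' error.
#'
#' @param local,regional Record data frames from [run_study()].
#' @param truths Truth list from [scenario_truths()].
#' @return List of class `"secr_study_summary"` with elements `local`
#'   and `regional`.
#' @export
summarize_study <- function(local, regional, truths) {
  loc <- NULL
  if (!is.null(local) && nrow(local)) {
    groups <- unique(local[, c("analysis", "array_id")])
    loc <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
      g <- local[local$analysis == groups$analysis[i] &
                   local$array_id == groups$array_id[i], ]
      tr <- truths$local$D_true[truths$local$array_id ==
                                  groups$array_id[i]]
      use <- g[!is.na(g$D_hat), ]
      n_use <- nrow(use)
      cov <- mean(use$lcl <= tr & tr <= use$ucl)
      data.frame(analysis = groups$analysis[i],
                 array_id = groups$array_id[i], D_true = tr,
                 n_used = n_use, n_failed = nrow(g) - n_use,
                 median_D = stats::median(use$D_hat),
                 MPRB = mean(prb(use$D_hat, tr)),
                 MRSE = mean(use$se / use$D_hat),
                 coverage = cov,
                 coverage_mc_se = sqrt(cov * (1 - cov) / n_use),
                 stringsAsFactors = FALSE)
    }))
  }
  reg <- NULL
  if (!is.null(regional) && nrow(regional)) {
    tr <- truths$regional
    reg <- do.call(rbind, lapply(unique(regional$analysis), function(an) {
      g <- regional[regional$analysis == an, ]
      use <- g[!is.na(g$D_hat), ]
      n_use <- nrow(use)
      rows <- list()
      add <- function(variance, var_col, lcl_col, ucl_col) {
        v <- use[[var_col]]
        if (all(is.na(v))) return(NULL)
        cov <- mean(use[[lcl_col]] <= tr & tr <= use[[ucl_col]])
        data.frame(analysis = an, variance = variance, D_true = tr,
                   n_used = n_use, n_failed = nrow(g) - n_use,
                   median_D = stats::median(use$D_hat),
                   MPRB = mean(prb(use$D_hat, tr)),
                   MPRSE = mean(100 * sqrt(v) / use$D_hat),
                   coverage = cov,
                   coverage_mc_se = sqrt(cov * (1 - cov) / n_use),
                   stringsAsFactors = FALSE)
      }
      rows$p <- add("poisson", "var_poisson", "lcl_p", "ucl_p")
      rows$e <- add("empirical", "var_empirical", "lcl_e", "ucl_e")
      do.call(rbind, rows)
    }))
    row.names(reg) <- NULL
  }
  structure(list(local = loc, regional = reg),
            class = "secr_study_summary")
}

#' @export
print.secr_study_summary <- function(x, ...) {
  if (!is.null(x$local)) {
    cat("Local density estimates:\n")
    print(x$local, row.names = FALSE, digits = 3L)
  }
  if (!is.null(x$regional)) {
    cat("\nRegional density estimates:\n")
    print(x$regional, row.names = FALSE, digits = 3L)
  }
  invisible(x)
}

#' @export
print.secr_study <- function(x, ...) {
  cat(sprintf(
    "Simulation study: scenario %d, %d iterations (master seed %d)\n\n",
    x$scenario_id, x$iterations, x$master_seed))
  print(x$summary)
  invisible(x)
}

#' Plot study bias and coverage
#'
#' Dot plot of per-array mean percent relative bias with CI coverage
#' annotated, by analysis mode.
#'
#' @param x A `secr_study` object.
#' @param ... Unused.
#' @export
plot.secr_study <- function(x, ...) {
  s <- x$summary$local
  if (is.null(s)) stop("no local summaries to plot")
  ana <- unique(s$analysis)
  cols <- seq_along(ana)
  graphics::plot(NULL, xlim = range(seq_len(nrow(s) / length(ana))),
                 ylim = range(s$MPRB) + c(-5, 5),
                 xlab = "Array position", ylab = "Mean % relative bias")
  graphics::abline(h = 0, lty = 2L)
  for (i in seq_along(ana)) {
    g <- s[s$analysis == ana[i], ]
    graphics::points(seq_len(nrow(g)), g$MPRB, col = cols[i], pch = 19L)
  }
  graphics::legend("topright", legend = ana, col = cols, pch = 19L,
                   bty = "n")
  invisible(x)
}
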