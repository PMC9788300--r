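# Simulated captures shared by several fitting tests (scenario 1 truth:
# D = 12 per 100 km2, g0 = 0.30, sigma = 1500 m).
sc1 <- make_scenario(1)
pop1 <- sample_population(sc1, 301)
capts1 <- simulate_captures(pop1, sc1, 302)

test_that("insufficient data yields an explicit failure result, not an error", {
  a <- toy_array()
  # zero recaptures: two animals each seen once
  cp <- toy_captures(a, c("x", 1, "D1"), c("y", 1, "D2"),
                     c("z", 1, "D1"), c("w", 2, "D2"), c("v", 2, "D1"))
  f <- fit_secr(cp, a)
  expect_s3_class(f, "secr_fit")
  expect_false(f$converged)
  expect_match(f$failure_reason, "insufficient")
  # fewer than the minimum number of animals
  cp2 <- toy_captures(a, c("x", 1, "D1"), c("x", 1, "D2"))
  f2 <- fit_secr(cp2, a)
  expect_false(f2$converged)
  # failure results propagate as NA components
  comp <- repsecr:::fit_components(f)
  expect_true(all(is.na(comp$a_hat_km2)))
})

test_that("detection parameters are recovered within 3 SEs on dense data", {
  arr <- grid_array("R1", centre = c(0, 0))
  g0_true <- 0.30; sigma_true <- 1500
  capt <- simulate_one_array(arr, D_per_100km2 = 60, g0 = g0_true,
                             sigma = sigma_true, pad_m = 6000, seed = 71)
  expect_gt(capt$n, 100)   # dense population: strong information
  f <- fit_secr(capt, arr)
  expect_true(f$converged)
  se <- sqrt(diag(f$vcov_link))
  link_true <- repsecr:::theta_to_link(g0_true, sigma_true)
  expect_lt(abs(f$par[1] - link_true[1]), 3 * se[1])
  expect_lt(abs(f$par[2] - link_true[2]), 3 * se[2])
  # and the density estimate is in the right neighbourhood
  expect_lt(abs(f$derived$D_hat - 60) / 60, 0.25)
})

test_that("the detection MLE does not depend on the density level", {
  arr <- grid_array("R1", centre = c(0, 0))
  f_lo <- fit_secr(simulate_one_array(arr, 25, 0.3, 1500, 6000, seed = 72),
                   arr)
  f_hi <- fit_secr(simulate_one_array(arr, 100, 0.3, 1500, 6000, seed = 73),
                   arr)
  expect_true(f_lo$converged && f_hi$converged)
  # both recover the same truth within their (larger) 3-SE envelopes
  link_true <- repsecr:::theta_to_link(0.3, 1500)
  for (f in list(f_lo, f_hi)) {
    se <- sqrt(diag(f$vcov_link))
    expect_lt(abs(f$par[1] - link_true[1]), 3 * se[1])
    expect_lt(abs(f$par[2] - link_true[2]), 3 * se[2])
  }
})

test_that("interactive pooled fit reproduces independent per-array fits", {
  fi <- fit_secr(capts1, sc1$design, sharing = "interactive",
                 buffer_m = 6000, cell_side_m = 750)
  fits <- fit_secr(capts1, sc1$design, sharing = "independent",
                   buffer_m = 6000, cell_side_m = 750)
  expect_s3_class(fits, "secr_fit_list")
  ind_theta <- do.call(rbind, lapply(fits, function(f) f$theta))
  expect_equal(fi$theta$g0, ind_theta$g0, tolerance = 1e-4)
  expect_equal(fi$theta$sigma, ind_theta$sigma, tolerance = 1e-4)
  D_ind <- vapply(fits, function(f) f$derived$D_hat, 0)
  expect_equal(fi$derived$D_hat, unname(D_ind), tolerance = 1e-4)
  # regional mean density agrees between the two routes
  expect_equal(dhat_region_mean(fi$derived$n, fi$derived$a_hat_km2),
               dhat_region_mean(vapply(fits, `[[`, 0L, "n"),
                                vapply(fits, function(f)
                                  f$derived$a_hat_km2, 0)),
               tolerance = 1e-4)
})

test_that("pooling two copies of the same data leaves the MLE unchanged", {
  arr1 <- sc1$design[[1]]
  cp1 <- capts1[[1]]
  # an identical twin array far away
  arr2 <- detector_array("TWIN", arr1$detectors$x + 5e5, arr1$detectors$y,
                         detector_id = arr1$detectors$id,
                         n_occasions = arr1$n_occasions)
  cp2 <- capture_data("TWIN", cp1$events, arr2)
  single <- fit_secr(cp1, arr1, buffer_m = 6000, cell_side_m = 750)
  double <- fit_secr(list(cp1, cp2), list(arr1, arr2),
                     sharing = "constant", buffer_m = 6000,
                     cell_side_m = 750)
  expect_equal(double$theta$g0[1], single$theta$g0[1], tolerance = 1e-4)
  expect_equal(double$theta$sigma[1], single$theta$sigma[1],
               tolerance = 1e-4)
  expect_equal(double$loglik, 2 * single$loglik, tolerance = 1e-6)
})

test_that("additive sharing interpolates between constant and interactive", {
  fc <- fit_secr(capts1, sc1$design, sharing = "constant",
                 buffer_m = 6000, cell_side_m = 1000)
  fa <- fit_secr(capts1, sc1$design, sharing = "additive",
                 buffer_m = 6000, cell_side_m = 1000)
  fi <- fit_secr(capts1, sc1$design, sharing = "interactive",
                 buffer_m = 6000, cell_side_m = 1000)
  expect_equal(fc$n_params, 2L)
  expect_equal(fa$n_params, 2L + 2L * 5L)
  expect_equal(fi$n_params, 12L)
  # additive nests constant; interactive nests additive
  expect_gte(fa$loglik, fc$loglik - 1e-4)
  expect_gte(fi$loglik, fa$loglik - 1e-4)
})

test_that("delta-method var(a-hat) agrees with a parametric bootstrap", {
  f <- fit_secr(capts1[[1]], sc1$design[[1]])
  expect_true(f$converged)
  var_delta <- f$derived$se_a_hat^2
  # bootstrap oracle: resample theta from its asymptotic distribution
  set.seed(404)
  L <- chol(f$vcov_link)
  mask <- f$masks[[1]]
  draws <- vapply(1:200, function(r) {
    th <- f$par + drop(rnorm(2) %*% L)
    t_ <- repsecr:::link_to_theta(th)
    effective_area(detection_params(t_$g0, t_$sigma),
                   sc1$design[[1]], mask)
  }, 0)
  expect_equal(var(draws), var_delta, tolerance = 0.25)
})

test_that("fit methods expose the usual modelling interface", {
  f <- fit_secr(capts1[[1]], sc1$design[[1]])
  expect_output(print(f), "D = ")
  expect_s3_class(summary(f), "summary.secr_fit")
  expect_equal(nrow(coef(f)), 1L)
  expect_length(coef(f, scale = "link"), 2L)
  expect_equal(dim(vcov(f)), c(2L, 2L))
  expect_s3_class(logLik(f), "logLik")
  pr <- predict(f, distance_m = c(0, 1000))
  expect_equal(pr$g[1], f$theta$g0[1])
  ci <- confint(f)
  expect_true(all(ci$lcl < ci$estimate & ci$estimate < ci$ucl))
  sim <- simulate(f, nsim = 1, seed = 9)
  expect_s3_class(sim[[1]][[1]], "capture_data")
  # simulated data refit: estimate near the generating value
  expect_gt(sim[[1]][[1]]$n, 0)
})
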