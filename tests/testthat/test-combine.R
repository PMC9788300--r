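test_that("regional estimators reproduce hand arithmetic", {
  expect_equal(dhat_region_mean(c(10, 20), c(100, 200)), 10)
  expect_equal(dhat_region_mean(c(10, 10), c(100, 200)), 7.5)
  expect_equal(dhat_region_pooled_area(c(10, 20), c(100, 200)), 10)
  expect_equal(dhat_region_pooled_area(c(10, 10), c(100, 200)), 20 / 3)
  # J = 1: both reduce to the local estimate
  expect_equal(dhat_region_mean(7, 140), 5)
  expect_equal(dhat_region_pooled_area(7, 140), 5)
})

test_that("mean and pooled-area estimators agree iff areas are equal", {
  set.seed(31)
  for (r in 1:10) {
    n <- rpois(4, 20)
    a_eq <- rep(runif(1, 80, 300), 4)
    expect_equal(dhat_region_mean(n, a_eq),
                 dhat_region_pooled_area(n, a_eq), tolerance = 1e-12)
  }
  expect_false(isTRUE(all.equal(dhat_region_mean(c(10, 10), c(100, 200)),
                                dhat_region_pooled_area(c(10, 10),
                                                        c(100, 200)))))
})

test_that("empirical variance of the total count matches hand arithmetic", {
  expect_equal(var_n_empirical(c(4, 6)), 4)
  expect_equal(var_n_empirical(c(0, 0, 9)), 81)
  expect_equal(var_n_empirical(rep(7, 5)), 0)
  expect_error(var_n_empirical(5), "at least 2")
})

test_that("Poisson and empirical regional variances match hand arithmetic", {
  # D = 10, n = (10, 15), areas (100, 100), var(a_j) = (200, 200):
  # sum var / A^2 = 0.01; Poisson: 100 * (1/25 + 0.01) = 5
  expect_equal(var_dhat_region_poisson(10, c(10, 15), c(200, 200),
                                       c(100, 100)), 5)
  # empirical: var_n = 2 * (6.25 + 6.25) = 25 -> 100 * (25/625 + 0.01) = 5
  expect_equal(var_dhat_region_empirical(10, c(10, 15), c(200, 200),
                                         c(100, 100)), 5)
  # var(a) = 0 reduces to D^2 / n
  expect_equal(var_dhat_region_poisson(10, c(10, 15), c(0, 0),
                                       c(100, 100)), 100 / 25)
  # doubling every n_j and a_hat_j (same D) halves the count term
  v1 <- var_dhat_region_poisson(10, c(10, 15), c(0, 0), c(100, 100))
  v2 <- var_dhat_region_poisson(10, c(20, 30), c(0, 0), c(200, 200))
  expect_equal(v2, v1 / 2)
  # equal counts and zero area variance: empirical variance is zero
  expect_equal(var_dhat_region_empirical(10, c(12, 12), c(0, 0),
                                         c(100, 100)), 0)
  expect_error(var_dhat_region_poisson(10, c(0, 0), c(0, 0), c(1, 1)))
})

test_that("variance estimators are invariant to array order and units", {
  set.seed(13)
  n <- c(8, 14, 23); va <- c(50, 90, 10); a <- c(110, 140, 95)
  o <- c(3, 1, 2)
  D <- dhat_region_mean(n, a)
  expect_equal(dhat_region_mean(n[o], a[o]), D)
  expect_equal(var_dhat_region_poisson(D, n[o], va[o], a[o]),
               var_dhat_region_poisson(D, n, va, a))
  expect_equal(var_dhat_region_empirical(D, n[o], va[o], a[o]),
               var_dhat_region_empirical(D, n, va, a))
  # scaling all areas by c scales D by 1/c but leaves RSE unchanged
  cfac <- 3.7
  D2 <- dhat_region_mean(n, a * cfac)
  v1 <- var_dhat_region_poisson(D, n, va, a)
  v2 <- var_dhat_region_poisson(D2, n, va * cfac^2, a * cfac)
  expect_equal(sqrt(v2) / D2, sqrt(v1) / D, tolerance = 1e-12)
})

test_that("lognormal interval matches its closed form", {
  expect_equal(lognormal_ci(10, 0), c(lcl = 10, ucl = 10))
  ci <- lognormal_ci(10, 1)   # RSE 10%
  expect_equal(unname(ci[1]), 8.22416, tolerance = 1e-5)
  expect_equal(unname(ci[2]), 12.15930, tolerance = 1e-5)
  # multiplicative symmetry
  set.seed(3)
  for (r in 1:10) {
    D <- runif(1, 0.5, 40); v <- runif(1, 0, 25)
    ci <- lognormal_ci(D, v)
    expect_equal(unname(ci[1] * ci[2]), D^2, tolerance = 1e-10)
    expect_true(ci[1] < D && D < ci[2] || v == 0)
  }
  expect_error(lognormal_ci(-1, 1), "positive")
  expect_error(lognormal_ci(10, -1))
})

test_that("region_estimate assembles components and drops failures", {
  comp <- data.frame(array_id = c("a", "b", "c"),
                     n = c(10, 20, 3),
                     a_hat_km2 = c(100, 200, NA),
                     var_a_hat = c(0, 0, NA),
                     converged = c(TRUE, TRUE, FALSE))
  expect_message(re <- region_estimate(comp), "dropping 1")
  expect_equal(re$J, 2L)
  expect_equal(re$D_region, 10)
  expect_equal(re$dropped, "c")
  expect_true(re$ci_poisson[1] < re$D_region &&
                re$D_region < re$ci_poisson[2])
  expect_error(region_estimate(comp, drop_failed = FALSE), "non-converged")
  # pooled-area estimator carries its bias caveat
  re2 <- suppressMessages(region_estimate(comp,
                                          estimator = "pooled_area"))
  expect_match(re2$note, "biased")
})
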