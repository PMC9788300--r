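test_that("the replicated design has the stated geometry", {
  des <- make_design()
  expect_length(des, 6L)
  expect_equal(sum(vapply(des, function(a) nrow(a$detectors), 0L)), 240L)
  for (a in des) {
    expect_equal(repsecr:::detector_spacing(a), 2000)
  }
  # minimum gap between detectors of different arrays >= 30 km
  for (i in 1:5) for (j in (i + 1):6) {
    di <- des[[i]]$detectors; dj <- des[[j]]$detectors
    gap <- sqrt(outer(di$x, dj$x, "-")^2 + outer(di$y, dj$y, "-")^2)
    expect_gt(min(gap), 30000)
  }
  # negligible cross-array detectability even at the largest sigma
  p <- detection_params(0.35, 3000)
  for (j in 2:6) {
    dj <- des[[j]]$detectors
    # nearest detector of array j to array 1
    d1 <- des[[1]]$detectors
    dd <- sqrt(outer(d1$x, dj$x, "-")^2 + outer(d1$y, dj$y, "-")^2)
    nearest <- which(dd == min(dd), arr.ind = TRUE)[1L, ]
    x_at <- c(dj$x[nearest[2L]], dj$y[nearest[2L]])
    expect_lt(p_dot(x_at, des[[1]], p), 1e-6)
  }
})

test_that("scenario factory returns the four parameter sets", {
  s1 <- make_scenario(1)
  expect_equal(s1$bands$D_per_100km2, rep(12, 3))
  expect_equal(s1$bands$g0, rep(0.30, 3))
  expect_equal(s1$bands$sigma, rep(1500, 3))
  s2 <- make_scenario(2)
  expect_equal(s2$bands$D_per_100km2, c(6, 18, 12))
  expect_equal(s2$bands$g0, rep(0.30, 3))
  s3 <- make_scenario(3)
  expect_equal(s3$bands$D_per_100km2, rep(12, 3))
  expect_equal(s3$bands$g0, c(0.25, 0.30, 0.35))
  expect_equal(s3$bands$sigma, c(1000, 2000, 3000))
  s4 <- make_scenario(4)
  expect_equal(s4$bands$D_per_100km2, c(6, 18, 12))
  expect_equal(s4$bands$sigma, c(1000, 2000, 3000))
  expect_error(make_scenario(5), "unknown scenario")
  # two arrays per band, south to north
  expect_equal(unname(s1$array_band), c(1L, 1L, 2L, 2L, 3L, 3L))
})

test_that("population realizations are Poisson with the right mean", {
  sc <- make_scenario(1)
  set.seed(5)
  seeds <- sample.int(1e6, 150)
  counts <- vapply(seeds, function(s) nrow(sample_population(sc, s)), 0L)
  # mean 12 per 100 km2 x 60000 km2 / 100 = 7200
  mc_se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 7200), 3 * mc_se + 1e-9)
  # determinism
  expect_identical(sample_population(sc, 123), sample_population(sc, 123))
})

test_that("an empty band and zero detectability give empty output", {
  sc <- make_scenario(1)
  sc$bands$D_per_100km2 <- c(0, 0, 0)
  pop <- sample_population(sc, 4)
  expect_equal(nrow(pop), 0L)
  sc2 <- make_scenario(1)
  sc2$bands$g0 <- rep(1e-300, 3)
  pop2 <- sample_population(sc2, 4)
  capts <- simulate_captures(pop2, sc2, 5)
  expect_true(all(vapply(capts, `[[`, 0L, "n") == 0L))
})

test_that("per-animal detection counts follow a Binomial(S, g(d)) law", {
  # one detector, one animal at fixed distance, many replicate draws
  arr <- detector_array("Z", x = 0, y = 0, n_occasions = 6L)
  sc <- list(scenario_id = 1L, region = make_region(),
             bands = data.frame(label = "southern", ymin = 0, ymax = 3e5,
                                D_per_100km2 = 1, g0 = 0.3,
                                sigma = 1500),
             design = list(Z = arr),
             array_band = c(Z = 1L), n_occasions = 6L)
  class(sc) <- "secr_scenario"
  d <- 1200
  pop <- data.frame(id = "A1", x = d, y = 0, band = 1L, g0 = 0.3,
                    sigma = 1500, stringsAsFactors = FALSE)
  class(pop) <- c("sim_population", "data.frame")
  g <- half_normal_g(d, 0.3, 1500)
  set.seed(99)
  seeds <- sample.int(1e7, 2000)
  counts <- vapply(seeds, function(s) {
    nrow(simulate_captures(pop, sc, s)[[1]]$events)
  }, 0L)
  obs <- tabulate(counts + 1L, nbins = 7L)
  expected_p <- dbinom(0:6, 6, g)
  # pool sparse upper tail for a valid chi-square
  keep <- expected_p * length(counts) >= 5
  obs2 <- c(obs[keep], sum(obs[!keep]))
  p2 <- c(expected_p[keep], sum(expected_p[!keep]))
  pval <- suppressWarnings(chisq.test(obs2, p = p2)$p.value)
  expect_gt(pval, 0.001)
})

test_that("captures are reproducible and confined to one array", {
  sc <- make_scenario(4)
  pop <- sample_population(sc, 61)
  c1 <- simulate_captures(pop, sc, 62)
  c2 <- simulate_captures(pop, sc, 62)
  expect_identical(lapply(c1, `[[`, "events"), lapply(c2, `[[`, "events"))
  ids <- lapply(c1, `[[`, "animals")
  for (i in 1:5) for (j in (i + 1):6) {
    expect_length(intersect(ids[[i]], ids[[j]]), 0L)
  }
})
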