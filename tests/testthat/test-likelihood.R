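test_that("history_prob matches closed forms on tiny histories", {
  a1 <- detector_array("A", x = 0, y = 0, n_occasions = 1L)
  p <- detection_params(0.3, 1500)
  expect_equal(history_prob(c(0, 0), matrix(1L, 1, 1), a1, p), 0.3)
  a2 <- detector_array("A", x = 0, y = 0, n_occasions = 2L)
  expect_equal(history_prob(c(0, 0), matrix(c(1L, 0L), 2, 1), a2, p),
               0.21)
  expect_error(history_prob(c(0, 0), matrix(0L, 2, 1), a2, p),
               "all-zero")
})

test_that("history probabilities sum to p_dot over all nonzero histories", {
  # enumeration oracle: S x K small enough to enumerate every history
  p <- detection_params(0.35, 800)
  cases <- list(c(S = 2L, K = 2L), c(S = 2L, K = 3L), c(S = 4L, K = 2L))
  for (cs in cases) {
    S <- cs[["S"]]; K <- cs[["K"]]
    a <- detector_array("A", x = seq(0, by = 600, length.out = K),
                        y = rep(0, K), n_occasions = S)
    for (x in list(c(0, 0), c(300, 500), c(-900, 100))) {
      cells <- S * K
      total <- 0
      for (code in 1:(2^cells - 1L)) {
        bits <- as.integer(intToBits(code))[1:cells]
        total <- total + history_prob(x, matrix(bits, S, K), a, p)
      }
      expect_equal(total, p_dot(x, a, p), tolerance = 1e-12)
    }
  }
})

test_that("conditional nll equals an independent brute-force oracle", {
  a <- toy_array(n_occasions = 2L)
  capt <- toy_captures(a,
                       c("u", 1, "D1"), c("u", 2, "D2"),
                       c("v", 1, "D2"),
                       c("w", 2, "D1"), c("w", 2, "D2"))
  mask <- build_mask(a, buffer_m = 1500, cell_side_m = 600)  # ~25 cells
  expect_lt(mask$n_cells, 40L)   # keep the scalar-loop oracle affordable
  for (th in list(c(0.3, 800), c(0.15, 1500), c(0.6, 400))) {
    link <- repsecr:::theta_to_link(th[1], th[2])
    expect_equal(conditional_nll(link, capt, a, mask),
                 brute_force_nll(th[1], th[2], capt, a, mask),
                 tolerance = 1e-10)
  }
})

test_that("conditional nll is additive and permutation-invariant", {
  a <- toy_array(n_occasions = 2L)
  capt <- toy_captures(a, c("u", 1, "D1"), c("u", 2, "D2"),
                       c("v", 1, "D2"))
  dup <- toy_captures(a, c("u", 1, "D1"), c("u", 2, "D2"),
                      c("v", 1, "D2"),
                      c("u2", 1, "D1"), c("u2", 2, "D2"),
                      c("v2", 1, "D2"))
  perm <- toy_captures(a, c("v", 1, "D2"), c("u", 2, "D2"),
                       c("u", 1, "D1"))
  mask <- build_mask(a, 1500, 600)
  link <- repsecr:::theta_to_link(0.3, 800)
  nll1 <- conditional_nll(link, capt, a, mask)
  expect_equal(conditional_nll(link, dup, a, mask), 2 * nll1,
               tolerance = 1e-10)
  expect_equal(conditional_nll(link, perm, a, mask), nll1,
               tolerance = 1e-12)
  expect_error(conditional_nll(c(0, NA), capt, a, mask))
})

test_that("effective area behaves like an integral of p_dot", {
  tr <- grid_array("A1", centre = c(0, 0))
  mask <- build_mask(tr, 6000, 750)
  # vanishes with g0
  expect_lt(effective_area(detection_params(1e-6, 1500), tr, mask), 0.5)
  # monotone in both parameters
  set.seed(7)
  for (r in 1:5) {
    g0 <- runif(1, 0.1, 0.6); sigma <- runif(1, 700, 1800)
    a0 <- effective_area(detection_params(g0, sigma), tr, mask)
    expect_gt(effective_area(detection_params(g0 + 0.1, sigma), tr, mask), a0)
    expect_gt(effective_area(detection_params(g0, sigma * 1.2), tr, mask), a0)
  }
})

test_that("effective area agrees with a 5x finer integration grid", {
  tr <- grid_array("A1", centre = c(0, 0))
  p <- detection_params(0.30, 1500)
  coarse <- effective_area(p, tr, build_mask(tr, 6000, 750))
  fine <- effective_area(p, tr, build_mask(tr, 6000, 150))
  expect_equal(coarse, fine, tolerance = 0.005)
})
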