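# Small fixtures and independent oracles shared across test files.

# A 2-detector, 2-occasion toy array.
toy_array <- function(n_occasions = 2L) {
  detector_array("T1", x = c(0, 1000), y = c(0, 0), n_occasions = n_occasions)
}

# Capture data built from explicit event rows.
toy_captures <- function(array, ...) {
  ev <- data.frame(rbind(...), stringsAsFactors = FALSE)
  names(ev) <- c("animal", "occasion", "detector")
  ev$occasion <- as.integer(ev$occasion)
  capture_data(array$array_id, ev, array)
}

# Independent brute-force conditional nll: naive scalar loops over
# animals, cells, occasions, and detectors. Deliberately slow and written
# without any shared code with the package internals.
brute_force_nll <- function(g0, sigma, capt, array, mask) {
  S <- array$n_occasions
  det <- array$detectors
  om <- capture_tensor(capt, array)
  n <- capt$n
  # a(theta) by scalar loop
  a <- 0
  for (c in seq_len(mask$n_cells)) {
    pr_none <- 1
    for (s in seq_len(S)) {
      for (k in seq_len(nrow(det))) {
        d <- sqrt((mask$x[c] - det$x[k])^2 + (mask$y[c] - det$y[k])^2)
        pr_none <- pr_none * (1 - g0 * exp(-d^2 / (2 * sigma^2)))
      }
    }
    a <- a + (1 - pr_none) * mask$cell_area_km2
  }
  nll <- 0
  for (i in seq_len(n)) {
    integral <- 0
    for (c in seq_len(mask$n_cells)) {
      pr <- 1
      for (s in seq_len(S)) {
        for (k in seq_len(nrow(det))) {
          d <- sqrt((mask$x[c] - det$x[k])^2 + (mask$y[c] - det$y[k])^2)
          g <- g0 * exp(-d^2 / (2 * sigma^2))
          pr <- pr * if (om[i, s, k] == 1L) g else (1 - g)
        }
      }
      integral <- integral + pr * mask$cell_area_km2
    }
    nll <- nll - log(integral / a)
  }
  nll
}

# Simulated captures for one array with known parameters: population on a
# rectangle extending `pad_m` beyond the detectors, uniform locations,
# full Bernoulli detection process. Used for parameter-recovery tests.
simulate_one_array <- function(array, D_per_100km2, g0, sigma, pad_m,
                               seed) {
  set.seed(seed)
  det <- array$detectors
  x0 <- min(det$x) - pad_m; x1 <- max(det$x) + pad_m
  y0 <- min(det$y) - pad_m; y1 <- max(det$y) + pad_m
  area_km2 <- (x1 - x0) / 1000 * (y1 - y0) / 1000
  N <- rpois(1L, D_per_100km2 / 100 * area_km2)
  xs <- runif(N, x0, x1); ys <- runif(N, y0, y1)
  rows <- list()
  for (s in seq_len(array$n_occasions)) {
    d <- sqrt(outer(xs, det$x, "-")^2 + outer(ys, det$y, "-")^2)
    p <- g0 * exp(-d^2 / (2 * sigma^2))
    y <- matrix(rbinom(length(p), 1L, p), nrow = N)
    hit <- which(y == 1L, arr.ind = TRUE)
    if (nrow(hit)) {
      rows[[s]] <- data.frame(animal = paste0("B", hit[, 1L]),
                              occasion = s,
                              detector = det$id[hit[, 2L]],
                              stringsAsFactors = FALSE)
    }
  }
  capture_data(array$array_id, do.call(rbind, rows), array)
}
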