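test_that("integrated intensity is background-corrected inner signal", {
  # inner mean 100, ring mean 40, inner area 25 -> (100 - 40) * 25
  frame <- matrix(40, 20, 20)
  frame[8:12, 8:12] <- 100
  rp <- region_pair(inner = c(7, 7, 12, 12), outer = c(4, 4, 15, 15))
  expect_equal(integrated_intensity(frame, rp), (100 - 40) * 25)

  # uniform image: background equals signal
  expect_equal(integrated_intensity(matrix(7, 20, 20), rp), 0)

  expect_error(region_pair(c(5, 5, 10, 10), c(6, 6, 12, 12)),
               "contained")
  expect_error(region_pair(c(5, 5, 10, 10), c(5, 5, 10, 10)), "empty")
  expect_error(integrated_intensity(matrix(0, 8, 8), rp), "bounds")
})

test_that("integrated intensity equals brute-force pixel arithmetic", {
  set.seed(71)
  xs <- matrix(rep(0:31, each = 32), 32, 32)
  ys <- matrix(rep(0:31, 32), 32, 32)
  frame <- 20 + 300 * exp(-((xs - 15)^2 + (ys - 16)^2) / 8) +
    rnorm(1024, 0, 2)
  rp <- region_pair(inner = c(10, 11, 21, 22), outer = c(6, 7, 25, 26))

  inner_px <- frame[12:22, 11:21]      # rows = y+1, cols = x+1
  outer_px <- frame[8:26, 7:25]
  ring_sum <- sum(outer_px) - sum(inner_px)
  ring_n <- length(outer_px) - length(inner_px)
  oracle <- (mean(inner_px) - ring_sum / ring_n) * length(inner_px)
  expect_equal(integrated_intensity(frame, rp), oracle)
})

test_that("traces extract from stacks frame by frame", {
  frame <- matrix(40, 20, 20); frame[8:12, 8:12] <- 100
  rp <- region_pair(c(7, 7, 12, 12), c(4, 4, 15, 15))
  stack <- array(rep(frame, 3), c(20, 20, 3))
  tr <- extract_trace(stack, rp, times = 0:2, bleach_index = 2)
  expect_equal(tr$raw, rep(1500, 3))
  expect_error(extract_trace(stack, rp, times = 0:3, bleach_index = 2),
               "does not match")
})

test_that("normalization divides by the pre-bleach mean", {
  tr <- frap_trace(times = 0:4, raw = c(4, 4, 1, 2, 3), bleach_index = 3)
  expect_equal(normalize_trace(tr)$normalized, c(1, 1, 0.25, 0.5, 0.75))
  expect_error(normalize_trace(frap_trace(0:4, c(0, 0, 1, 2, 3), 3)),
               "positive")
  expect_error(normalize_trace(frap_trace(0:4, 1:5, 1)), "pre-bleach")
  expect_error(frap_trace(c(0, 1, 1, 2), 1:4, 2), "strictly increasing")
})

test_that("noiseless traces are recovered exactly", {
  tr <- generate_frap_trace(A = 0.8, k = 0.2, B = 0.05,
                            times = -5:30, bleach_index = 6,
                            noise_sd = 0)
  fit <- fit_recovery(normalize_trace(tr))
  expect_equal(fit$A, 0.8, tolerance = 1e-6)
  expect_equal(fit$k, 0.2, tolerance = 1e-6)
  expect_equal(fit$B, 0.05, tolerance = 1e-6)
  expect_equal(fit$t_half, log(2) / 0.2, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # the half-time identity holds exactly for every fit
  expect_equal(fit$t_half * fit$k, log(2), tolerance = 1e-12)
})

test_that("the NLS optimum matches a brute-force grid search", {
  tr <- generate_frap_trace(A = 0.7, k = 0.15, B = 0.1,
                            times = -3:40, bleach_index = 4,
                            noise_sd = 0.05, seed = 5)
  fit <- fit_recovery(normalize_trace(tr))

  x <- tr$times[4:length(tr$times)] - tr$times[4]
  y <- tr$normalized[4:length(tr$times)]
  ss <- function(A, k, B) sum((y - (A * (1 - exp(-k * x)) + B))^2)
  grid <- expand.grid(A = seq(0.4, 1.0, by = 0.01),
                      k = seq(0.05, 0.40, by = 0.005),
                      B = seq(-0.1, 0.3, by = 0.01))
  grid$ss <- mapply(ss, grid$A, grid$k, grid$B)
  best <- grid[which.min(grid$ss), ]
  expect_lte(ss(fit$A, fit$k, fit$B), best$ss + 1e-12)
  # NLS optimum within one grid step of the exhaustive-search optimum
  expect_lt(abs(fit$A - best$A), 0.011)
  expect_lt(abs(fit$k - best$k), 0.0051)
  expect_lt(abs(fit$B - best$B), 0.011)
})

test_that("fits are invariant to uniform time translation", {
  tr1 <- generate_frap_trace(0.85, 0.25, 0.08, times = -4:30,
                             bleach_index = 5, noise_sd = 0.03, seed = 9)
  tr2 <- frap_trace(tr1$times + 117.5, tr1$raw, tr1$bleach_index,
                    tr1$normalized)
  f1 <- fit_recovery(tr1)
  f2 <- fit_recovery(tr2)
  expect_equal(f1$A, f2$A, tolerance = 1e-8)
  expect_equal(f1$k, f2$k, tolerance = 1e-8)
  expect_equal(f1$t_half, f2$t_half, tolerance = 1e-8)
})

test_that("traces that grow instead of recovering are flagged", {
  # exact solution has k < 0 (unbounded growth), not a recovery
  x <- 0:30
  y <- c(1, 1, -2 * (1 - exp(0.05 * x)) - 0.5)
  tr <- frap_trace(seq_along(y) - 3, y, 3, normalized = y)
  expect_error(fit_recovery(tr), "no recovery detected")

  expect_error(fit_recovery(frap_trace(0:4, c(1, 1, 0.2, 0.4, 0.6), 3,
                                       normalized = c(1, 1, 0.2, 0.4,
                                                      0.6))),
               "at least 4 post-bleach")
  expect_error(fit_recovery(frap_trace(0:5, rep(1, 6), 2)),
               "not normalized")
})

test_that("parameter recovery: <= 5% median error at noise SD 0.05", {
  errs_A <- errs_t <- numeric(100)
  for (s in 1:100) {
    tr <- generate_frap_trace(0.9, log(2) / 5, 0.1, times = -5:60,
                              bleach_index = 6, noise_sd = 0.05,
                              seed = s)
    fit <- fit_recovery(tr)
    errs_A[s] <- abs(fit$A - 0.9) / 0.9
    errs_t[s] <- abs(fit$t_half - 5) / 5
  }
  expect_lte(median(errs_A), 0.05)
  expect_lte(median(errs_t), 0.05)
})
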