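# Three-point solver, multi-point regression, per-beta volume fit, and the
# group sweep, each checked against an independent oracle.

test_that("three-point solver recovers exact analytic exponents", {
  expect_equal(solve_three_point_beta(
    three_point_record(c(0, 1, 2), c(1, 2, 4)))$beta, 1, tolerance = 1e-8)
  # cubic V = t^3: R(2/3) = (1-2)/(1-3) = 1/2 = tau
  expect_equal(solve_three_point_beta(
    three_point_record(c(1, 2, 3), c(1, 8, 27)))$beta, 2 / 3,
    tolerance = 1e-8)
})

test_that("three-point solver inverts the forward closed form", {
  rec <- vb_record(0.5, 0.005, 1.5, c(0, 90, 180))
  est <- solve_three_point_beta(rec)
  expect_lt(abs(est$beta - 1.5), 1e-6)
  expect_lt(est$residual, 1e-8)
  # parameter recovery across the clinically relevant exponent range
  for (beta in c(0.5, 2 / 3, 1, 1.25, 1.5, 2)) {
    rec <- vb_record(0.4, 0.004, beta, c(0, 80, 170))
    expect_lt(abs(solve_three_point_beta(rec)$beta - beta), 1e-6)
  }
})

test_that("the three-point equation is strictly monotone in beta", {
  # uniqueness of the root rests on monotonicity of R(beta); probe 1000
  # random growing records on a dense grid
  set.seed(11)
  grid <- seq(-5, 10, by = 0.025)
  n_bad <- 0L
  for (i in 1:1000) {
    v <- sort(exp(rnorm(3, 0, 1.5)))
    if (any(diff(v) <= 0)) next
    l1 <- log(v[2] / v[1])
    l2 <- log(v[3] / v[1])
    lhs <- expm1((1 - grid) * l1) / expm1((1 - grid) * l2)
    lhs[abs(1 - grid) < 1e-9] <- l1 / l2
    d <- diff(lhs)
    # strictly one-signed up to floating-point slack relative to scale
    slack <- 1e-9 * pmax(abs(lhs[-1]), abs(lhs[-length(lhs)]))
    if (!(all(d < slack) || all(d > -slack))) n_bad <- n_bad + 1L
  }
  expect_identical(n_bad, 0L)
  # consequence of uniqueness: the solver never reports ambiguity on growing
  # records
  set.seed(12)
  for (i in 1:50) {
    v <- sort(exp(rnorm(3, 0, 1.5)))
    t <- sort(runif(3, 0, 300))
    if (any(diff(v) <= 0) || any(diff(t) <= 0)) next
    expect_error(
      tryCatch(solve_three_point_beta(three_point_record(t, v)),
               bm_no_root = function(e) NULL),
      NA)
  }
})

test_that("solver error contracts: no root and invalid records", {
  expect_error(three_point_record(c(0, 1, 2), c(4, 2, 1)),
               class = "bm_validation_error")
  expect_error(three_point_record(c(0, 0, 2), c(1, 2, 4)),
               class = "bm_validation_error")
  # a bracket excluding the root reports no sign change
  rec <- three_point_record(c(0, 1, 2), c(1, 2, 4))
  expect_error(solve_three_point_beta(rec, bracket = c(5, 10)),
               class = "bm_no_root")
})

test_that("multipoint fit is exact on equally spaced exponential data", {
  t <- c(0, 5, 10, 15, 20)
  s <- volume_series("x", "other", t, exp(0.2 * t))
  est <- fit_multipoint_beta(s)
  expect_equal(est$beta, 1, tolerance = 1e-10)
})

test_that("multipoint fit matches hand-computed normal equations on a cubic", {
  d <- c(7, 14, 18, 21)
  v <- d^3
  s <- volume_series("c", "mouse", d, v)
  est <- fit_multipoint_beta(s)
  # independent least squares via the normal equations on the 3 log-log points
  x <- log(v[-1])
  y <- log(diff(v) / diff(d))
  slope <- (mean(x * y) - mean(x) * mean(y)) / (mean(x^2) - mean(x)^2)
  expect_equal(est$beta, slope, tolerance = 1e-12)
})

test_that("multipoint fit applies the mouse day-21 filter and exclusion rule", {
  d <- c(7, 14, 18, 21, 25, 28)
  p <- vb_params(0.01, 0.1, 1.2, t0 = 7)
  v <- vb_volume(p, d)
  v[5:6] <- v[4] * c(1.01, 1.02)  # saturated late points
  s <- volume_series("m", "mouse", d, v)
  with_filter <- fit_multipoint_beta(s)          # drops days 25/28
  without <- fit_multipoint_beta(s, max_time = Inf)
  expect_equal(with_filter$n_pairs, 3L)
  expect_lt(without$beta, with_filter$beta)      # saturation bias
  # decreasing series is excluded, not fitted
  v2 <- v
  v2[3] <- v2[2] * 0.9
  expect_error(fit_multipoint_beta(volume_series("m2", "mouse", d, v2)),
               class = "bm_exclusion")
  expect_error(fit_multipoint_beta(volume_series("m3", "mouse", d[1:2],
                                                 c(1, 2))),
               class = "bm_validation_error")
})

test_that("best_fit_volumes_for_beta matches exhaustive enumeration", {
  rec <- three_point_record(c(0, 1, 2), c(1, 2, 4))
  # brute-force oracle on the same tiny grid, straight from the equation
  enumerate <- function(rec, beta, n0, n1) {
    t <- rec$times
    v <- rec$volumes
    tau <- (t[2] - t[1]) / (t[3] - t[1])
    v0g <- seq(0, v[2], length.out = n0)
    v0g <- v0g[v0g > 0]
    v1g <- seq(v[1], v[3], length.out = n1)
    best <- Inf
    for (a in v0g) for (b in v1g) {
      if (abs(1 - beta) < 1e-6) {
        v2 <- a * (b / a)^(1 / tau)
      } else {
        base <- 1 - (1 - (b / a)^(1 - beta)) / tau
        if (is.na(base) || base <= 0) next
        v2 <- a * base^(1 / (1 - beta))
      }
      err <- abs(a - v[1]) / v[1] + abs(b - v[2]) / v[2] + abs(v2 - v[3]) / v[3]
      if (err < best) best <- err
    }
    best
  }
  for (beta in c(0.5, 1, 1.7)) {
    got <- best_fit_volumes_for_beta(rec, beta, n_v0 = 4L, n_v1 = 3L)
    expect_equal(got$rel_error, enumerate(rec, beta, 4L, 3L),
                 tolerance = 1e-12, info = sprintf("beta=%g", beta))
  }
  # the exact model point is approached as the grid refines
  errs <- vapply(c(20L, 100L, 400L), function(n) {
    best_fit_volumes_for_beta(rec, 1, n_v0 = n, n_v1 = n)$rel_error
  }, 1)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.01)
})

test_that("group sweep equals brute force and recovers the true exponent", {
  recs <- list(vb_record(0.3, 0.004, 1.5, c(0, 70, 150)),
               vb_record(0.8, 0.003, 1.5, c(0, 95, 170)))
  sw <- sweep_group_beta(recs, n_beta = 5L, n_v0 = 10L, n_v1 = 10L)
  # exhaustive triple loop over the same grids
  brute <- vapply(sw$beta_grid, function(b) {
    sum(vapply(recs, function(r) {
      best_fit_volumes_for_beta(r, b, n_v0 = 10L, n_v1 = 10L)$rel_error
    }, 1))
  }, 1)
  expect_equal(sw$cumulative_error, brute, tolerance = 1e-12)
  expect_equal(sw$beta_star, sw$beta_grid[which.min(brute)])

  # five noiseless lesions at beta = 1.5: recovered within one grid step
  recs5 <- lapply(1:5, function(i) {
    vb_record(0.2 + 0.15 * i, 0.004, 1.5, c(0, 60 + 5 * i, 140 + 7 * i))
  })
  sw5 <- sweep_group_beta(recs5, n_beta = 61L, n_v0 = 250L, n_v1 = 250L)
  step <- diff(sw5$beta_grid[1:2])
  expect_lte(abs(sw5$beta_star - 1.5), step + 1e-12)
  expect_error(sweep_group_beta(list()), class = "bm_validation_error")
})

test_that("sweep argmin tie-breaks toward the smaller exponent", {
  # single exact exponential record on a grid containing beta = 1
  rec <- three_point_record(c(0, 1, 2), c(1, 2, 4))
  sw <- sweep_group_beta(list(rec), beta_range = c(0, 2), n_beta = 5L,
                         n_v0 = 40L, n_v1 = 40L)
  expect_equal(sw$beta_star, 1)
  expect_true(all(sw$cumulative_error >= sw$cumulative_error[sw$beta_grid == 1]))
})
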