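## The three growth-exponent estimators: the three-point implicit solver,
## the multi-point discretized log-linear fit, and the group-level grid sweep
## minimizing cumulative relative error.

#' Three-point measurement record
#'
#' Three consecutive longitudinal measurements `(t0, V0), (t1, V1), (t2, V2)`
#' of a single lesion. Inclusion requires strict growth at every time point
#' (the clinical analysis studies growing lesions only), so
#' `0 < V0 < V1 < V2` and `t0 < t1 < t2`.
#'
#' @param times Numeric length-3, strictly increasing (days).
#' @param volumes Numeric length-3, strictly increasing and positive (cm^3).
#' @param lesion_id Optional identifier.
#' @return An object of class `three_point_record`.
#' @export
three_point_record <- function(times, volumes, lesion_id = NA_character_) {
  bm_assert(is.numeric(times) && length(times) == 3L && all(is.finite(times)),
            "bm_validation_error", "times must be 3 finite numbers")
  bm_assert(is.numeric(volumes) && length(volumes) == 3L &&
              all(is.finite(volumes)),
            "bm_validation_error", "volumes must be 3 finite numbers")
  bm_assert(all(diff(times) > 0), "bm_validation_error",
            "times must be strictly increasing")
  bm_assert(volumes[1] > 0 && all(diff(volumes) > 0), "bm_validation_error",
            "volumes must be positive and strictly increasing (growth required)")
  structure(list(times = as.numeric(times), volumes = as.numeric(volumes),
                 lesion_id = lesion_id),
            class = "three_point_record")
}

## R(beta) = (1 - r1^(1-beta)) / (1 - r2^(1-beta)), r_i = V_i/V0, evaluated
## through expm1 on the log scale for stability at large volume ratios; the
## beta = 1 singularity is removable with limit log(r1)/log(r2).
three_point_lhs <- function(beta, r1, r2, beta_tol = 1e-9) {
  l1 <- log(r1)
  l2 <- log(r2)
  om <- 1 - beta
  out <- expm1(om * l1) / expm1(om * l2)
  near1 <- abs(om) < beta_tol
  if (any(near1)) out[near1] <- l1 / l2
  out
}

bisect_root <- function(f, lo, hi, tol = 1e-8, maxit = 200L) {
  flo <- f(lo)
  fhi <- f(hi)
  if (flo == 0) return(lo)
  if (fhi == 0) return(hi)
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0 || (hi - lo) / 2 < tol) return(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid
      flo <- fm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

#' Solve the three-point implicit equation for the growth exponent
#'
#' Finds the root of
#' `(1 - (V1/V0)^(1-beta)) / (1 - (V2/V0)^(1-beta)) = (t1-t0)/(t2-t0)`
#' by a uniform sign-change scan over the bracket followed by bisection.
#' The left-hand side is strictly monotone in `beta` for any valid growing
#' record, so the root is unique; should a pathological input ever produce
#' several sign changes, all roots are solved and reported in an
#' `bm_ambiguous_root` error rather than silently picking one.
#'
#' @param record A [three_point_record()].
#' @param bracket Search interval for `beta` (default `c(-5, 10)` covers every
#'   exponent seen in practice).
#' @param scan_step Step of the uniform sign-change scan.
#' @param tol Bisection tolerance on `beta`.
#' @return A `beta_estimate` list with elements `beta`, `method`
#'   (`"three_point"`), `residual` (absolute value of the defining equation at
#'   the root) and `bracket`.
#' @examples
#' rec <- three_point_record(c(0, 1, 2), c(1, 2, 4))
#' solve_three_point_beta(rec)$beta  # 1: exact exponential
#' @export
solve_three_point_beta <- function(record, bracket = c(-5, 10),
                                   scan_step = 0.01, tol = 1e-8) {
  stopifnot(inherits(record, "three_point_record"))
  bm_assert(is.numeric(bracket) && length(bracket) == 2L &&
              bracket[1] < bracket[2],
            "bm_validation_error", "bracket must be an increasing interval")
  t <- record$times
  v <- record$volumes
  r1 <- v[2] / v[1]
  r2 <- v[3] / v[1]
  tau <- (t[2] - t[1]) / (t[3] - t[1])
  g <- function(beta) three_point_lhs(beta, r1, r2) - tau

  grid <- seq(bracket[1], bracket[2], by = scan_step)
  if (grid[length(grid)] < bracket[2]) grid <- c(grid, bracket[2])
  gv <- g(grid)

  roots <- grid[gv == 0]
  flips <- which(gv[-length(gv)] * gv[-1] < 0)
  for (i in flips) {
    roots <- c(roots, bisect_root(g, grid[i], grid[i + 1], tol = tol))
  }
  roots <- sort(unique(roots))
  if (length(roots) == 0L) {
    bm_error("bm_no_root",
             sprintf("no sign change of the three-point equation in [%g, %g]",
                     bracket[1], bracket[2]))
  }
  if (length(roots) > 1L) {
    bm_error("bm_ambiguous_root",
             sprintf("multiple roots found: %s",
                     paste(signif(roots, 8), collapse = ", ")),
             roots = roots)
  }
  beta <- roots[[1]]
  structure(list(beta = beta, method = "three_point",
                 residual = abs(g(beta)), bracket = bracket,
                 lesion_id = record$lesion_id),
            class = "beta_estimate")
}

#' Multi-point growth exponent by discretized log-linear fit
#'
#' For series with more than three measurements (mouse bioluminescence data),
#' the growth law is discretized over consecutive pairs and log-transformed:
#' `ln((V_i - V_{i-1}) / (t_i - t_{i-1})) = ln(alpha) + beta * ln(V_i)`.
#' The ordinary least-squares slope over all usable pairs is the growth
#' exponent. Late measurements taken when the tumor approaches the whole-brain
#' volume are excluded via `max_time` (default: points after day 21 are
#' dropped for mouse-group series, mirroring the saturation filter of the
#' animal analysis). Any non-positive volume increment is an exclusion error
#' (series with volume decrease are removed from the analysis, as were four
#' mice in the original cohort).
#'
#' @param series A [volume_series()] object.
#' @param max_time Latest measurement time (days) retained. `NULL` means
#'   21 for series with group `"mouse"`, `Inf` otherwise.
#' @return A `beta_estimate` with elements `beta` (slope), `alpha`
#'   (exp(intercept)), `method` (`"multipoint_regression"`), `residual`
#'   (regression RMSE) and `n_pairs`.
#' @export
fit_multipoint_beta <- function(series, max_time = NULL) {
  stopifnot(inherits(series, "volume_series"))
  if (is.null(max_time)) {
    max_time <- if (identical(series$group, "mouse")) 21 else Inf
  }
  keep <- series$times <= max_time
  t <- series$times[keep]
  v <- series$volumes[keep]
  bm_assert(length(t) >= 3L, "bm_validation_error",
            "fewer than 3 usable time points after filtering")
  dv <- diff(v)
  if (any(dv <= 0)) {
    bm_error("bm_exclusion",
             sprintf("series %s excluded: non-increasing volume within the fitted window",
                     series$lesion_id))
  }
  y <- log(dv / diff(t))
  x <- log(v[-1])
  fit <- lm.fit(cbind(1, x), y)
  beta <- unname(fit$coefficients[2])
  structure(list(beta = beta, alpha = exp(unname(fit$coefficients[1])),
                 method = "multipoint_regression",
                 residual = sqrt(mean(fit$residuals^2)),
                 n_pairs = length(y), lesion_id = series$lesion_id),
            class = "beta_estimate")
}

## Closed-form V2' from the three-point equation given beta and a candidate
## (V0', V1'): V2' = V0' * (1 - (1 - (V1'/V0')^(1-beta)) / tau)^(1/(1-beta)),
## with the log-limit form at beta = 1. Returns NA where the power base is
## non-positive (infeasible candidate). Vectorized over matrices.
predict_v2 <- function(v0p, v1p, beta, tau, beta_tol = 1e-6) {
  ratio <- v1p / v0p
  if (abs(1 - beta) < beta_tol) {
    return(v0p * ratio^(1 / tau))
  }
  om <- 1 - beta
  base <- 1 - (-expm1(om * log(ratio))) / tau
  out <- ifelse(base > 0, v0p * base^(1 / om), NA_real_)
  out
}

#' Best-fitting volume triple at a fixed growth exponent
#'
#' For a fixed `beta`, sweeps candidate first and second volumes
#' `V0'` over `(0, V1]` and `V1'` over `[V0, V2]` on uniform grids; each
#' candidate pair determines `V2'` in closed form from the three-point
#' equation. Returns the triple minimizing the relative error
#' `|V0'-V0|/V0 + |V1'-V1|/V1 + |V2'-V2|/V2`.
#'
#' @param record A [three_point_record()].
#' @param beta Fixed growth exponent.
#' @param n_v0,n_v1 Grid resolutions (defaults 500, matching the original
#'   group-analysis resolution).
#' @return List with `V0p`, `V1p`, `V2p`, `rel_error`.
#' @export
best_fit_volumes_for_beta <- function(record, beta, n_v0 = 500L, n_v1 = 500L) {
  stopifnot(inherits(record, "three_point_record"))
  bm_assert(is_scalar_num(beta), "bm_validation_error", "beta must be finite")
  t <- record$times
  v <- record$volumes
  tau <- (t[2] - t[1]) / (t[3] - t[1])
  v0g <- seq(0, v[2], length.out = n_v0)
  v0g <- v0g[v0g > 0]
  v1g <- seq(v[1], v[3], length.out = n_v1)
  ## rows: V0' candidates, cols: V1' candidates
  v0m <- matrix(v0g, nrow = length(v0g), ncol = length(v1g))
  v1m <- matrix(v1g, nrow = length(v0g), ncol = length(v1g), byrow = TRUE)
  v2m <- predict_v2(v0m, v1m, beta, tau)
  err <- abs(v0m - v[1]) / v[1] + abs(v1m - v[2]) / v[2] +
    abs(v2m - v[3]) / v[3]
  if (all(is.na(err))) {
    bm_error("bm_no_fit",
             sprintf("no feasible (V0', V1') candidate at beta = %g", beta))
  }
  k <- which.min(err)  # ties: first index = smallest V0', then smallest V1'
  list(V0p = v0m[k], V1p = v1m[k], V2p = v2m[k], rel_error = err[k])
}

#' Group-level sweep for the best common growth exponent
#'
#' Evaluates a uniform grid of candidate exponents `beta'` on `beta_range`;
#' for each lesion and each `beta'` the minimal relative error over the
#' volume grids of [best_fit_volumes_for_beta()] is computed, and errors are
#' summed over lesions. The group exponent `beta*` is the grid argmin of the
#' cumulative error (ties broken toward the smaller exponent). Default
#' resolutions (300 x 500 x 500) match the original analysis and amount to
#' ~75 million candidate evaluations per lesion -- expect roughly a minute per
#' lesion; reduce the grids for exploratory runs and tests.
#'
#' @param records List of [three_point_record()] objects.
#' @param beta_range Exponent interval (default `c(0, 3)`).
#' @param n_beta,n_v0,n_v1 Grid resolutions.
#' @return A `group_sweep_result` list with `beta_grid`, `cumulative_error`,
#'   `beta_star`, and `per_lesion_error` (lesions x grid matrix).
#' @export
sweep_group_beta <- function(records, beta_range = c(0, 3), n_beta = 300L,
                             n_v0 = 500L, n_v1 = 500L) {
  bm_assert(is.list(records) && length(records) >= 1L &&
              all(vapply(records, inherits, TRUE, "three_point_record")),
            "bm_validation_error",
            "records must be a non-empty list of three_point_record objects")
  beta_grid <- seq(beta_range[1], beta_range[2], length.out = n_beta)
  per <- matrix(NA_real_, nrow = length(records), ncol = n_beta)
  for (i in seq_along(records)) {
    t <- records[[i]]$times
    v <- records[[i]]$volumes
    tau <- (t[2] - t[1]) / (t[3] - t[1])
    v0g <- seq(0, v[2], length.out = n_v0)
    v0g <- v0g[v0g > 0]
    v0m <- matrix(v0g, nrow = length(v0g), ncol = n_v1)
    v1m <- matrix(seq(v[1], v[3], length.out = n_v1),
                  nrow = length(v0g), ncol = n_v1, byrow = TRUE)
    ## beta-independent pieces, hoisted out of the grid loop
    lr <- log(v1m / v0m)
    e01 <- abs(v0m - v[1]) / v[1] + abs(v1m - v[2]) / v[2]
    for (j in seq_len(n_beta)) {
      beta <- beta_grid[j]
      if (abs(1 - beta) < 1e-6) {
        v2m <- v0m * exp(lr / tau)
        err <- e01 + abs(v2m - v[3]) / v[3]
      } else {
        om <- 1 - beta
        base <- 1 + expm1(om * lr) / tau
        feas <- base > 0
        v2m <- v0m * exp(log(ifelse(feas, base, 1)) / om)
        err <- ifelse(feas, e01 + abs(v2m - v[3]) / v[3], NA_real_)
      }
      per[i, j] <- if (all(is.na(err))) Inf else min(err, na.rm = TRUE)
    }
  }
  cumulative <- colSums(per)
  k <- which.min(cumulative)  # first minimum = smallest beta'
  structure(list(beta_grid = beta_grid, cumulative_error = cumulative,
                 beta_star = beta_grid[k], per_lesion_error = per),
            class = "group_sweep_result")
}
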