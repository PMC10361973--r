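## Robustness checks for the three-point exponent computation: a per-lesion
## perturbation screen, and exponent distributions on canonical growth curves
## under random triplet sampling with multiplicative noise.

#' Perturbation screen for a three-point record
#'
#' Each replicate multiplies each of the three volumes by an independent
#' factor drawn uniformly from `[1 - max_rel_err, 1 + max_rel_err]` (the
#' minimal reading of "a random error smaller or equal to +-5%"; segmentation
#' error is multiplicative) and re-solves for the exponent. Replicates whose
#' perturbed volumes are no longer strictly increasing, or for which the
#' solver finds no root, are counted as failures and excluded from the mean.
#' The record passes the screen when the mean perturbed exponent differs from
#' the unperturbed exponent by less than `threshold`.
#'
#' @param record A [three_point_record()].
#' @param n_reps Number of perturbation replicates (default 200).
#' @param max_rel_err Half-width of the multiplicative error (default 0.05).
#' @param threshold Consistency criterion on `|mean(beta') - beta|`
#'   (default 0.5).
#' @param seed Optional integer seed for reproducibility.
#' @param ... Passed to [solve_three_point_beta()].
#' @return A `perturbation_screen_result` list with `beta_original`,
#'   `beta_perturbed` (successful replicates), `beta_star_av`, `n_failed`,
#'   `passed`.
#' @export
perturbation_screen <- function(record, n_reps = 200L, max_rel_err = 0.05,
                                threshold = 0.5, seed = NULL, ...) {
  stopifnot(inherits(record, "three_point_record"))
  bm_assert(is_scalar_num(max_rel_err) && max_rel_err >= 0 && max_rel_err < 1,
            "bm_validation_error", "max_rel_err must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  beta0 <- solve_three_point_beta(record, ...)$beta
  betas <- rep(NA_real_, n_reps)
  for (i in seq_len(n_reps)) {
    f <- runif(3L, 1 - max_rel_err, 1 + max_rel_err)
    vp <- record$volumes * f
    if (any(diff(vp) <= 0)) next
    betas[i] <- tryCatch(
      solve_three_point_beta(
        three_point_record(record$times, vp, record$lesion_id), ...)$beta,
      bm_error = function(e) NA_real_)
  }
  ok <- !is.na(betas)
  if (!any(ok)) {
    bm_error("bm_screen_undefined", "all perturbation replicates failed")
  }
  av <- mean(betas[ok])
  structure(list(beta_original = beta0, beta_perturbed = betas[ok],
                 beta_star_av = av, n_reps = n_reps,
                 n_failed = sum(!ok),
                 passed = abs(av - beta0) < threshold),
            class = "perturbation_screen_result")
}

#' Exponent distributions on a canonical growth curve
#'
#' Draws `n_triplets` random time triplets on a discretized version of the
#' curve's `t_range` (distinct points, at least one grid step apart, sorted),
#' evaluates the curve there, and solves the three-point equation -- once on
#' the clean volumes and once after multiplying each volume by an independent
#' uniform factor in `[1 - noise_level, 1 + noise_level]`. Exponential and
#' cubic curves yield point masses (1 and 2/3); saturating curves
#' (Gompertz, logistic) yield spreads below 1; noise widens the spreads around
#' the clean values.
#'
#' @param curve A [canonical_curve()].
#' @param n_triplets Number of random triplets (default 100).
#' @param noise_level Multiplicative noise half-width for the noisy pass
#'   (default 0.2).
#' @param seed Optional integer seed.
#' @param n_grid Size of the time discretization (default 200).
#' @return A `curve_beta_sample` list with `kind`, `betas_clean`,
#'   `betas_noisy` (NA where a solve failed), `n_failed_clean`,
#'   `n_failed_noisy`.
#' @export
curve_family_beta_distribution <- function(curve, n_triplets = 100L,
                                           noise_level = 0.2, seed = NULL,
                                           n_grid = 200L) {
  stopifnot(inherits(curve, "canonical_curve"))
  if (!is.null(seed)) set.seed(seed)
  tg <- seq(curve$t_range[1], curve$t_range[2], length.out = n_grid)
  solve_triplet <- function(tt, vv) {
    if (any(diff(vv) <= 0)) return(NA_real_)
    tryCatch(
      solve_three_point_beta(three_point_record(tt, vv))$beta,
      bm_error = function(e) NA_real_)
  }
  clean <- noisy <- rep(NA_real_, n_triplets)
  for (i in seq_len(n_triplets)) {
    idx <- sort(sample.int(n_grid, 3L))  # distinct grid points, >= 1 step apart
    tt <- tg[idx]
    vv <- canonical_volume(curve, tt)
    clean[i] <- solve_triplet(tt, vv)
    noisy[i] <- solve_triplet(tt, vv * runif(3L, 1 - noise_level,
                                             1 + noise_level))
  }
  structure(list(kind = curve$kind, n_triplets = n_triplets,
                 noise_level = noise_level,
                 betas_clean = clean, betas_noisy = noisy,
                 n_failed_clean = sum(is.na(clean)),
                 n_failed_noisy = sum(is.na(noisy))),
            class = "curve_beta_sample")
}
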