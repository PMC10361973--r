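## Synthetic longitudinal cohorts and mouse-style series with the statistical
## structure the estimators assume. The clinical MRI dataset behind the
## original analysis is not public, so every pipeline stage is validated by
## parameter recovery on data generated here, with ground truth emitted
## alongside.

#' Volume time series of one lesion
#'
#' @param lesion_id Identifier.
#' @param group Label; one of `"untreated"`, `"CT"`, `"RT"`, `"RT+CT"`,
#'   `"simulated"`, `"mouse"`, `"other"`.
#' @param times Strictly increasing measurement times (days).
#' @param volumes Positive volumes (cm^3), same length (length >= 2).
#' @param patient_id Optional patient identifier.
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(lesion_id, group, times, volumes,
                          patient_id = NA_character_) {
  groups <- c("untreated", "CT", "RT", "RT+CT", "simulated", "mouse", "other")
  bm_assert(group %in% groups, "bm_validation_error",
            sprintf("group must be one of %s", paste(groups, collapse = ", ")))
  bm_assert(length(times) >= 2L && length(times) == length(volumes),
            "bm_validation_error",
            "need >= 2 measurements with matching times/volumes lengths")
  bm_assert(all(diff(times) > 0), "bm_validation_error",
            sprintf("lesion %s: times must be strictly increasing", lesion_id))
  bm_assert(all(volumes > 0), "bm_validation_error",
            sprintf("lesion %s: volumes must be positive", lesion_id))
  structure(list(lesion_id = as.character(lesion_id), group = group,
                 times = as.numeric(times), volumes = as.numeric(volumes),
                 patient_id = as.character(patient_id)),
            class = "volume_series")
}

#' Group specification for a synthetic cohort
#'
#' Ships with two presets for demos: an untreated-like group with exponents
#' centered near 1.5 and a treated-like group centered near 0.65. These are
#' synthetic defaults for recovery experiments, not reproductions of any
#' clinical table. `V0` is drawn log-normally around a median of ~0.5 cm^3
#' (typical follow-up volumes); the intake coefficient `alpha` is solved from
#' a drawn total fold-change `V2/V0` (log-uniform on `fold_range`), which
#' guarantees every lesion's scan window stays below the finite blow-up time
#' when `beta > 1`.
#'
#' @param label Group label (controlled vocabulary of [volume_series()]).
#' @param n_lesions Number of lesions.
#' @param beta_mean,beta_sd,beta_range Truncated-normal exponent
#'   distribution.
#' @param v0_meanlog,v0_sdlog Log-normal first-scan volume (cm^3).
#' @param fold_range Range of total fold-change over the two scan intervals.
#' @return An object of class `cohort_group_spec`.
#' @export
cohort_group_spec <- function(label, n_lesions = 30L, beta_mean = 1.5,
                              beta_sd = 0.2, beta_range = c(0.8, 2.2),
                              v0_meanlog = log(0.5), v0_sdlog = 1,
                              fold_range = c(1.5, 20)) {
  bm_assert(n_lesions >= 1L, "bm_validation_error", "n_lesions must be >= 1")
  bm_assert(beta_range[1] < beta_range[2] && beta_sd >= 0,
            "bm_validation_error", "invalid beta distribution")
  bm_assert(all(fold_range > 1), "bm_validation_error",
            "fold_range must exceed 1 (growing lesions)")
  structure(list(label = label, n_lesions = as.integer(n_lesions),
                 beta_mean = beta_mean, beta_sd = beta_sd,
                 beta_range = beta_range, v0_meanlog = v0_meanlog,
                 v0_sdlog = v0_sdlog, fold_range = fold_range),
            class = "cohort_group_spec")
}

#' Treated-like group preset
#' @param label Group label.
#' @param n_lesions Number of lesions.
#' @return A [cohort_group_spec()] centered near beta = 0.65.
#' @export
treated_group_spec <- function(label = "RT", n_lesions = 30L) {
  cohort_group_spec(label, n_lesions, beta_mean = 0.65, beta_sd = 0.2,
                    beta_range = c(0.1, 1.3))
}

rtruncnorm1 <- function(mean, sd, range) {
  if (sd == 0) return(mean)
  repeat {
    x <- rnorm(1L, mean, sd)
    if (x >= range[1] && x <= range[2]) return(x)
  }
}

#' Generate a synthetic three-scan cohort
#'
#' Per lesion: draw `(V0, beta)` from the group spec, draw the two inter-scan
#' gaps log-normally with the configured medians (defaults 92.5 and 80.4 days,
#' i.e. 3.04 and 2.64 months, the typical follow-up cadence), solve `alpha`
#' from a drawn fold-change, evaluate the closed-form growth law at the three
#' times, apply multiplicative uniform noise, and redraw any lesion violating
#' the strict-growth inclusion criterion. Ground truth is attached as
#' attribute `ground_truth`; the number of discarded draws as `n_discarded`.
#'
#' @param groups List of [cohort_group_spec()] objects.
#' @param gap_medians Median inter-scan gaps (days), length 2.
#' @param gap_sdlog Log-scale spread of the gaps (default 0.25).
#' @param noise_level Multiplicative volume error half-width in `[0, 0.5]`
#'   (default 0.05, the segmentation-error scale).
#' @param seed Optional integer seed.
#' @param max_redraws Redraw budget per lesion before a validation error.
#' @return List of [volume_series()] with attributes `ground_truth`
#'   (data.frame: lesion_id, group, true_beta, true_alpha, true_V0) and
#'   `n_discarded`.
#' @examples
#' coh <- generate_cohort(list(cohort_group_spec("untreated", 5)), seed = 1)
#' attr(coh, "ground_truth")
#' @export
generate_cohort <- function(groups, gap_medians = c(92.5, 80.4),
                            gap_sdlog = 0.25, noise_level = 0.05, seed = NULL,
                            max_redraws = 1000L) {
  bm_assert(is.list(groups) && length(groups) >= 1L &&
              all(vapply(groups, inherits, TRUE, "cohort_group_spec")),
            "bm_validation_error", "groups must be cohort_group_spec objects")
  bm_assert(noise_level >= 0 && noise_level <= 0.5, "bm_validation_error",
            "noise_level must be in [0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  gt <- list()
  discarded <- 0L
  k <- 0L
  for (gs in groups) {
    for (j in seq_len(gs$n_lesions)) {
      k <- k + 1L
      id <- sprintf("%s_%03d", gs$label, j)
      for (attempt in seq_len(max_redraws)) {
        beta <- rtruncnorm1(gs$beta_mean, gs$beta_sd, gs$beta_range)
        V0 <- rlnorm(1L, gs$v0_meanlog, gs$v0_sdlog)
        gaps <- rlnorm(2L, log(gap_medians), gap_sdlog)
        tt <- c(0, cumsum(gaps))
        F <- exp(runif(1L, log(gs$fold_range[1]), log(gs$fold_range[2])))
        V2 <- F * V0
        om <- 1 - beta
        alpha <- if (abs(om) < 1e-9) {
          log(F) / tt[3]
        } else {
          (V2^om - V0^om) / (om * tt[3])
        }
        vols <- vb_volume(vb_params(V0, alpha, beta), tt)
        vols <- vols * runif(3L, 1 - noise_level, 1 + noise_level)
        if (all(diff(vols) > 0)) {
          out[[k]] <- volume_series(id, gs$label, tt, vols,
                                    patient_id = sprintf("P%03d", k))
          gt[[k]] <- data.frame(lesion_id = id, group = gs$label,
                                true_beta = beta, true_alpha = alpha,
                                true_V0 = V0)
          break
        }
        discarded <- discarded + 1L
        if (attempt == max_redraws) {
          bm_error("bm_validation_error",
                   "redraw budget exhausted: spec yields almost no growing lesions")
        }
      }
    }
  }
  attr(out, "ground_truth") <- do.call(rbind, gt)
  attr(out, "n_discarded") <- discarded
  out
}

#' Mouse-style series specification
#'
#' Emulates bioluminescence-derived intracranial growth curves: measurements
#' on fixed days (default 7, 14, 18, 21, 25, 28), exponents centered near
#' 1.44, a volume ceiling at late days standing in for the whole-brain volume
#' constraint, and an injected late decrease in a configurable fraction of
#' animals to exercise the exclusion rule (four of the original 24 mice were
#' excluded for volume decrease).
#'
#' @param n_mice Number of animals (default 24).
#' @param measurement_days Strictly increasing days (default
#'   `c(7, 14, 18, 21, 25, 28)`).
#' @param beta_mean,beta_sd,beta_range Truncated-normal exponent
#'   distribution.
#' @param v0_meanlog,v0_sdlog Log-normal day-7 volume (cm^3); default median
#'   0.01 cm^3.
#' @param fold_range Fold-change of the noiseless curve between the first and
#'   last pre-ceiling day.
#' @param noise_level Multiplicative measurement noise half-width.
#' @param ceiling_volume Cap applied to measurements after `ceiling_after`
#'   (default 0.4 cm^3, roughly a rodent brain).
#' @param ceiling_after Day after which the ceiling applies (default 21).
#' @param decrease_fraction Fraction of mice given a late decrease
#'   (default 4/24).
#' @return An object of class `mouse_spec`.
#' @export
mouse_spec <- function(n_mice = 24L,
                       measurement_days = c(7, 14, 18, 21, 25, 28),
                       beta_mean = 1.44, beta_sd = 0.25,
                       beta_range = c(0.6, 2.2),
                       v0_meanlog = log(0.01), v0_sdlog = 0.4,
                       fold_range = c(12, 30), noise_level = 0.05,
                       ceiling_volume = 0.4, ceiling_after = 21,
                       decrease_fraction = 4 / 24) {
  bm_assert(all(diff(measurement_days) > 0), "bm_validation_error",
            "measurement_days must be strictly increasing")
  structure(list(n_mice = as.integer(n_mice),
                 measurement_days = measurement_days, beta_mean = beta_mean,
                 beta_sd = beta_sd, beta_range = beta_range,
                 v0_meanlog = v0_meanlog, v0_sdlog = v0_sdlog,
                 fold_range = fold_range, noise_level = noise_level,
                 ceiling_volume = ceiling_volume,
                 ceiling_after = ceiling_after,
                 decrease_fraction = decrease_fraction),
            class = "mouse_spec")
}

#' Generate mouse-style growth series
#'
#' Evaluates noiseless growth-law trajectories at the measurement days, caps
#' volumes at the ceiling after `ceiling_after` (space-limitation emulation),
#' applies multiplicative noise, and injects a late decrease (final
#' pre-ceiling measurement scaled by 0.8) in the first
#' `round(decrease_fraction * n_mice)` animals.
#'
#' @param spec A [mouse_spec()].
#' @param seed Optional integer seed.
#' @return List of [volume_series()] (group `"mouse"`) with attribute
#'   `ground_truth`.
#' @export
generate_mouse_series <- function(spec = mouse_spec(), seed = NULL) {
  stopifnot(inherits(spec, "mouse_spec"))
  if (!is.null(seed)) set.seed(seed)
  days <- spec$measurement_days
  fit_days <- days[days <= spec$ceiling_after]
  n_dec <- round(spec$decrease_fraction * spec$n_mice)
  out <- list()
  gt <- list()
  for (i in seq_len(spec$n_mice)) {
    beta <- rtruncnorm1(spec$beta_mean, spec$beta_sd, spec$beta_range)
    V0 <- rlnorm(1L, spec$v0_meanlog, spec$v0_sdlog)
    F <- exp(runif(1L, log(spec$fold_range[1]), log(spec$fold_range[2])))
    om <- 1 - beta
    Tspan <- max(fit_days) - min(days)
    alpha <- if (abs(om) < 1e-9) log(F) / Tspan else
      ((F * V0)^om - V0^om) / (om * Tspan)
    params <- vb_params(V0, alpha, beta, t0 = min(days))
    tstar <- vb_blowup_time(params)
    ## late measurements may sit beyond the finite blow-up time for beta > 1;
    ## physically the animal's brain caps the volume there anyway
    vols <- vapply(days, function(d) {
      if (d < tstar) vb_volume(params, d) else Inf
    }, numeric(1))
    late <- days > spec$ceiling_after
    vols[late] <- pmin(vols[late], spec$ceiling_volume)
    if (spec$noise_level > 0) {
      vols <- vols * runif(length(vols), 1 - spec$noise_level,
                           1 + spec$noise_level)
    }
    if (i <= n_dec) {
      j <- which(days == max(fit_days))
      vols[j] <- vols[j - 1] * 0.8  # injected decrease -> exclusion rule
    }
    ## keep capped late measurements weakly growing so the ceiling bias (not
    ## the decrease-exclusion rule) is what an unfiltered fit sees
    for (j in seq_along(vols)[-1]) {
      if (vols[j] <= vols[j - 1] && days[j] > spec$ceiling_after) {
        vols[j] <- vols[j - 1] * 1.001
      }
    }
    out[[i]] <- volume_series(sprintf("mouse_%02d", i), "mouse", days, vols)
    gt[[i]] <- data.frame(lesion_id = sprintf("mouse_%02d", i),
                          group = "mouse", true_beta = beta,
                          true_alpha = alpha, true_V0 = V0)
  }
  attr(out, "ground_truth") <- do.call(rbind, gt)
  out
}
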