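## Closed-form growth laws: the Von Bertalanffy power law with zero
## maintenance, and the four canonical curves used by the sensitivity module.

#' Von Bertalanffy growth-law parameters
#'
#' Parameter container for the growth law `dV/dt = alpha * V^beta - b * V`.
#' Throughout this package the maintenance coefficient `b` is fixed at zero:
#' for growing lesions essentially all metabolic intake is routed to
#' biosynthesis, and three measurements per lesion can identify at most
#' `(V0, alpha, beta)`.
#'
#' For `beta > 1` the solution blows up in finite time
#' `t* = t0 + V0^(1-beta) / ((beta - 1) * alpha)`; evaluation at or beyond
#' `t*` is a domain error.
#'
#' @param V0 Volume (cm^3) at the reference time, strictly positive.
#' @param alpha Energy-intake coefficient (cm^3^(1-beta) day^-1), positive.
#' @param beta Dimensionless growth exponent.
#' @param t0 Reference time (days).
#' @param b Maintenance coefficient (day^-1). Must be 0 in this package.
#' @return An object of class `vb_params`.
#' @examples
#' p <- vb_params(V0 = 0.5, alpha = 0.1, beta = 1.5)
#' vb_volume(p, c(0, 30, 60))
#' @export
vb_params <- function(V0, alpha, beta, t0 = 0, b = 0) {
  bm_assert(is_scalar_num(V0) && V0 > 0, "bm_validation_error",
            "V0 must be a positive finite scalar")
  bm_assert(is_scalar_num(alpha) && alpha > 0, "bm_validation_error",
            "alpha must be a positive finite scalar")
  bm_assert(is_scalar_num(beta), "bm_validation_error",
            "beta must be a finite scalar")
  bm_assert(is_scalar_num(t0), "bm_validation_error",
            "t0 must be a finite scalar")
  bm_assert(is_scalar_num(b) && b == 0, "bm_validation_error",
            "the maintenance coefficient b is fixed at 0 in this package")
  structure(list(V0 = V0, alpha = alpha, beta = beta, t0 = t0, b = 0),
            class = "vb_params")
}

#' Finite blow-up time of the Von Bertalanffy law
#'
#' @param params A [vb_params()] object.
#' @return The blow-up time `t*` (days) for `beta > 1`, otherwise `Inf`.
#' @export
vb_blowup_time <- function(params) {
  stopifnot(inherits(params, "vb_params"))
  if (params$beta <= 1) return(Inf)
  params$t0 + params$V0^(1 - params$beta) / ((params$beta - 1) * params$alpha)
}

#' Evaluate the Von Bertalanffy growth law
#'
#' Closed-form solution of `dV/dt = alpha * V^beta` (b = 0):
#' `V(t) = (V0^(1-beta) + (1-beta) * alpha * (t - t0))^(1/(1-beta))`,
#' switching to the exponential limit `V0 * exp(alpha * (t - t0))` when
#' `|1 - beta|` is below `beta_tol` (the singularity at `beta = 1` is
#' removable).
#'
#' @param params A [vb_params()] object.
#' @param t Vector of evaluation times (days), all `>= t0` and, for
#'   `beta > 1`, strictly below the blow-up time [vb_blowup_time()].
#' @param beta_tol Switch-over tolerance for the exponential limit.
#' @return Vector of volumes (cm^3).
#' @export
vb_volume <- function(params, t, beta_tol = 1e-6) {
  stopifnot(inherits(params, "vb_params"))
  bm_assert(is.numeric(t) && all(is.finite(t)), "bm_validation_error",
            "t must be finite numeric")
  bm_assert(all(t >= params$t0), "bm_validation_error",
            "evaluation times must satisfy t >= t0")
  om <- 1 - params$beta
  if (abs(om) < beta_tol) {
    return(params$V0 * exp(params$alpha * (t - params$t0)))
  }
  if (params$beta > 1) {
    tstar <- vb_blowup_time(params)
    bm_assert(all(t < tstar), "bm_domain_error",
              sprintf("evaluation at/after the blow-up time t* = %.6g", tstar))
  }
  base <- params$V0^om + om * params$alpha * (t - params$t0)
  base^(1 / om)
}

canonical_kinds <- c("exponential", "cubic", "gompertz", "logistic")

canonical_defaults <- list(
  exponential = list(pars = list(V0 = 1, r = 0.1), t_range = c(0, 60)),
  cubic       = list(pars = list(a = 0.01, s = 1), t_range = c(0, 60)),
  ## default windows for the saturating curves cover the rising phase (up to
  ## ~80-90% of the plateau): deeply saturated triplets have no admissible
  ## growth exponent in the default solver bracket
  gompertz    = list(pars = list(A = 10, c = 2.3026, d = 0.05),
                     t_range = c(0, 60)),
  logistic    = list(pars = list(A = 10, m = 9, r = 0.08), t_range = c(0, 45))
)

#' Canonical growth-curve specification
#'
#' The four textbook curves used to probe the three-point exponent
#' computation: exponential `V0 * exp(r t)`, cubic `a * (t + s)^3`, Gompertz
#' `A * exp(-c * exp(-d t))`, and logistic `A / (1 + m * exp(-r t))`. All
#' parameters must be positive and the curve strictly increasing on
#' `t_range`. Defaults are package choices (the exact values do not matter
#' for the qualitative exponent behavior, which is what these curves test).
#'
#' @param kind One of `"exponential"`, `"cubic"`, `"gompertz"`, `"logistic"`.
#' @param pars Named list of curve parameters; missing entries take the
#'   package defaults for that kind.
#' @param t_range Length-2 numeric evaluation interval (days).
#' @return An object of class `canonical_curve`.
#' @examples
#' cv <- canonical_curve("gompertz")
#' canonical_volume(cv, c(0, 50, 100))
#' @export
canonical_curve <- function(kind, pars = list(), t_range = NULL) {
  bm_assert(is.character(kind) && length(kind) == 1L &&
              kind %in% canonical_kinds,
            "bm_validation_error",
            sprintf("unknown curve kind; must be one of %s",
                    paste(canonical_kinds, collapse = ", ")))
  def <- canonical_defaults[[kind]]
  p <- utils::modifyList(def$pars, pars)
  bm_assert(all(vapply(p, is_scalar_num, TRUE)) && all(unlist(p) > 0),
            "bm_validation_error", "curve parameters must be positive scalars")
  if (is.null(t_range)) t_range <- def$t_range
  bm_assert(is.numeric(t_range) && length(t_range) == 2L &&
              t_range[1] < t_range[2],
            "bm_validation_error", "t_range must be an increasing interval")
  curve <- structure(list(kind = kind, pars = p, t_range = t_range),
                     class = "canonical_curve")
  grid <- seq(t_range[1], t_range[2], length.out = 256L)
  v <- canonical_volume(curve, grid)
  bm_assert(all(diff(v) > 0), "bm_validation_error",
            "curve is not strictly increasing on t_range")
  curve
}

#' Evaluate a canonical growth curve
#'
#' @param curve A [canonical_curve()] object.
#' @param t Times (days) within the curve's `t_range`.
#' @return Vector of volumes.
#' @export
canonical_volume <- function(curve, t) {
  stopifnot(inherits(curve, "canonical_curve"))
  bm_assert(all(t >= curve$t_range[1] - 1e-12) &&
              all(t <= curve$t_range[2] + 1e-12),
            "bm_validation_error", "t outside the curve's t_range")
  p <- curve$pars
  switch(curve$kind,
         exponential = p$V0 * exp(p$r * t),
         cubic = p$a * (t + p$s)^3,
         gompertz = p$A * exp(-p$c * exp(-p$d * t)),
         logistic = p$A / (1 + p$m * exp(-p$r * t)))
}
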