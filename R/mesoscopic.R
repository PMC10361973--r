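## Stochastic discrete mesoscopic simulator of brain-metastasis growth with
## two competing clonal populations on a 3D voxel lattice, plus treatment
## operators, exponent extraction from trajectories, and advantage sweeps.

#' Binomial update of a whole clonal population
#'
#' The simulator's elementary move: the joint outcome of `N` identical cells
#' each attempting a process with success probability `p` is a single draw
#' from `Binomial(N, p)`. Exposed for direct use and testing; the lattice
#' stepper applies the same primitive per voxel, population and process.
#'
#' @param N Non-negative integer cell count.
#' @param p Success probability in `[0, 1]`.
#' @return Integer number of successes.
#' @export
binomial_process_update <- function(N, p) {
  bm_assert(is_scalar_num(N) && N >= 0 && N == floor(N),
            "bm_validation_error", "N must be a non-negative integer")
  bm_assert(is_scalar_num(p) && p >= 0 && p <= 1, "bm_validation_error",
            "p must be a probability in [0, 1]")
  as.integer(rbinom(1L, as.integer(N), p))
}

#' Read a simulator configuration file
#'
#' Plain key-value file (`key: value` or `key = value`, `#` comments) whose
#' keys mirror the simulation parameter names: `lattice_size`, `voxel_size`,
#' `K`, `dt`, `initial_cells`, `initial_aggressive_fraction`, `limit_volume`,
#' `max_days`, `seed`, plus the trait keys `division_rate`, `death_rate`,
#' `migration_coefficient`, `v_div`, `v_mig`.
#'
#' @param path File path.
#' @return List with `config` (a [sim_config()]) and `traits` (list of two
#'   [bm_traits()]).
#' @export
read_sim_config_file <- function(path) {
  bm_assert(file.exists(path), "bm_parse_error",
            sprintf("config file not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "[:=]")
  bad <- lines[lengths(kv) != 2L]
  bm_assert(length(bad) == 0L, "bm_parse_error",
            sprintf("malformed config line(s): %s", paste(bad, collapse = "; ")))
  vals <- lapply(kv, function(x) as.numeric(trimws(x[2])))
  names(vals) <- vapply(kv, function(x) trimws(x[1]), "")
  bm_assert(!anyNA(unlist(vals)), "bm_parse_error",
            "non-numeric config value")
  cfg_keys <- c("lattice_size", "voxel_size", "K", "dt", "initial_cells",
                "initial_aggressive_fraction", "subclone_floor",
                "limit_volume", "max_days", "seed")
  trait_keys <- c("division_rate", "death_rate", "migration_coefficient",
                  "v_div", "v_mig")
  unknown <- setdiff(names(vals), c(cfg_keys, trait_keys))
  bm_assert(length(unknown) == 0L, "bm_parse_error",
            sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  cfg <- do.call(sim_config, vals[intersect(names(vals), cfg_keys)])
  base_keys <- intersect(names(vals), c("division_rate", "death_rate",
                                        "migration_coefficient"))
  base <- do.call(bm_traits, vals[base_keys])
  aggr <- do.call(bm_traits, vals[intersect(names(vals), trait_keys)])
  list(config = cfg, traits = list(base, aggr))
}

#' Clonal population traits
#'
#' Characteristic rates of one clonal population, together with the advantage
#' coefficients of the aggressive clone. A `v_div = 2` means the aggressive
#' population divides at twice the base rate (half the division time);
#' likewise `v_mig` for migration. Defaults are the calibrated base rates of
#' the mesoscopic brain-metastasis model.
#'
#' @param division_rate Division rate (day^-1, default 0.36).
#' @param death_rate Death rate (day^-1, default 0.144).
#' @param migration_coefficient Migration speed (mm^2 day^-1, default 2.88).
#' @param v_div,v_mig Advantage coefficients, `>= 1` (default 1: baseline
#'   population).
#' @return An object of class `bm_traits`.
#' @export
bm_traits <- function(division_rate = 0.36, death_rate = 0.144,
                      migration_coefficient = 2.88, v_div = 1, v_mig = 1) {
  for (x in list(division_rate, death_rate, migration_coefficient)) {
    bm_assert(is_scalar_num(x) && x >= 0, "bm_validation_error",
              "rates must be non-negative finite scalars")
  }
  bm_assert(is_scalar_num(v_div) && v_div >= 1 &&
              is_scalar_num(v_mig) && v_mig >= 1,
            "bm_validation_error", "advantage coefficients must be >= 1")
  structure(list(division_rate = division_rate, death_rate = death_rate,
                 migration_coefficient = migration_coefficient,
                 v_div = v_div, v_mig = v_mig),
            class = "bm_traits")
}

#' Simulator configuration
#'
#' @param lattice_size Voxels per dimension (default 80; 40 is the reduced
#'   mode for continuous-integration runs).
#' @param voxel_size Voxel edge length in mm (default 1).
#' @param K Carrying capacity per voxel (default 2e5 cells).
#' @param dt Step length in days (default 1/6, i.e. 4 hours).
#' @param initial_cells Cells seeded in the central voxel (default 10).
#' @param initial_aggressive_fraction Fraction of the seed belonging to the
#'   aggressive population (default 0).
#' @param subclone_floor When `initial_aggressive_fraction * initial_cells`
#'   falls below 1 cell the seed is raised to this many cells so the stated
#'   proportion is representable (default 1000).
#' @param limit_volume Stop once total volume reaches this (cm^3, default 10).
#' @param max_days Step budget expressed in days (default 1500).
#' @param seed Optional integer RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(lattice_size = 80L, voxel_size = 1, K = 2e5, dt = 1 / 6,
                       initial_cells = 10L, initial_aggressive_fraction = 0,
                       subclone_floor = 1000L, limit_volume = 10,
                       max_days = 1500, seed = NULL) {
  bm_assert(is_scalar_num(lattice_size) && lattice_size >= 3,
            "bm_config_error", "lattice_size must be >= 3")
  bm_assert(is_scalar_num(K) && K >= 1, "bm_config_error", "K must be >= 1")
  bm_assert(is_scalar_num(dt) && dt > 0, "bm_config_error", "dt must be > 0")
  bm_assert(is_scalar_num(initial_cells) && initial_cells >= 1,
            "bm_config_error", "initial_cells must be >= 1")
  bm_assert(is_scalar_num(initial_aggressive_fraction) &&
              initial_aggressive_fraction >= 0 &&
              initial_aggressive_fraction <= 1,
            "bm_config_error", "initial_aggressive_fraction must be in [0, 1]")
  structure(list(lattice_size = as.integer(lattice_size),
                 voxel_size = voxel_size, K = K, dt = dt,
                 initial_cells = as.integer(initial_cells),
                 initial_aggressive_fraction = initial_aggressive_fraction,
                 subclone_floor = as.integer(subclone_floor),
                 limit_volume = limit_volume, max_days = max_days,
                 seed = seed),
            class = "sim_config")
}

## Per-step success probabilities. Division carries the free-space factor
## (1 - N/K) and death the crowding factor N/K inside the C++ core; here we
## compute the density-independent prefactors and check they are probabilities.
step_probs <- function(traits1, traits2, config) {
  p <- list(
    pdiv1 = traits1$v_div * traits1$division_rate * config$dt,
    pdiv2 = traits2$v_div * traits2$division_rate * config$dt,
    pdeath = traits1$death_rate * config$dt,
    pmig1 = traits1$v_mig * traits1$migration_coefficient * config$dt /
      config$voxel_size^2,
    pmig2 = traits2$v_mig * traits2$migration_coefficient * config$dt /
      config$voxel_size^2
  )
  bad <- names(p)[vapply(p, function(x) x > 1 || x < 0, TRUE)]
  if (length(bad)) {
    bm_error("bm_config_error",
             sprintf("per-step probabilities outside [0, 1] after advantage scaling: %s (reduce dt or the advantage coefficients)",
                     paste(bad, collapse = ", ")))
  }
  p
}

#' Lattice state constructor
#'
#' Builds an empty lattice state, optionally seeding cells in the central
#' voxel. Used internally by [simulate_bm()] and directly by tests that
#' exercise [meso_step()].
#'
#' @param config A [sim_config()].
#' @param n1,n2 Cells of the less aggressive / aggressive population placed in
#'   the central voxel.
#' @return A `lattice_state` list with integer arrays `pop1`, `pop2`
#'   (dim `L^3` flattened), `time` (days) and the active bounding box.
#' @export
lattice_state <- function(config, n1 = 0L, n2 = 0L) {
  L <- config$lattice_size
  pop1 <- integer(L^3)
  pop2 <- integer(L^3)
  c0 <- (L %/% 2)
  center <- 1L + c0 + L * (c0 + L * c0)
  pop1[center] <- as.integer(n1)
  pop2[center] <- as.integer(n2)
  structure(list(pop1 = pop1, pop2 = pop2, time = 0,
                 bbox = rep(c0, 6L), L = L),
            class = "lattice_state")
}

#' Advance the lattice state by one or more steps
#'
#' Low-level synchronous update: per voxel and population, division successes
#' are drawn from `B(N, v_div * r_div * dt * (1 - Ntot/K))`, deaths from
#' `B(N, r_death * dt * Ntot/K)`, and migrants from
#' `B(N, v_mig * D * dt / dx^2)`, the latter distributed uniformly over the 6
#' face neighbors with no-flux boundaries and capacity-respecting overflow
#' return. All draws use the pre-step state.
#'
#' @param state A [lattice_state()].
#' @param traits List of two [bm_traits()] (less aggressive, aggressive).
#' @param config The [sim_config()].
#' @param nsteps Number of steps to advance.
#' @param check_capacity Track the per-step maximum voxel occupancy (slower;
#'   used by invariant tests).
#' @return Updated `lattice_state` with attributes `totals` (matrix
#'   `nsteps x 2` of population totals) and `maxvox`.
#' @export
meso_step <- function(state, traits, config, nsteps = 1L,
                      check_capacity = FALSE) {
  stopifnot(inherits(state, "lattice_state"))
  p <- step_probs(traits[[1]], traits[[2]], config)
  res <- meso_advance(state$pop1, state$pop2, state$L, config$K,
                      as.integer(nsteps), p$pdiv1, p$pdiv2, p$pdeath,
                      p$pmig1, p$pmig2, as.integer(state$bbox),
                      isTRUE(check_capacity))
  out <- structure(list(pop1 = res$pop1, pop2 = res$pop2,
                        time = state$time + nsteps * config$dt,
                        bbox = res$bbox, L = state$L),
                   class = "lattice_state")
  attr(out, "totals") <- cbind(pop1 = res$tot1, pop2 = res$tot2)
  attr(out, "maxvox") <- res$maxvox
  out
}

#' Treatment specification
#'
#' Three post-radiosurgery scenarios: complete depletion of the aggressive
#' clone, complete depletion of the less aggressive clone, or a balanced
#' reduction where a fraction of cells survives and the aggressive proportion
#' is reset (per-voxel binomial thinning).
#'
#' @param scenario One of `"deplete_aggressive"`, `"deplete_less_aggressive"`,
#'   `"balanced"`.
#' @param trigger_volume Apply when the total volume first reaches this
#'   (cm^3, default 1). Ignored when `trigger_time` is given.
#' @param trigger_time Apply at this absolute time (days), or `NULL`.
#' @param survival_fraction Overall fraction of cells surviving a balanced
#'   treatment. The default 1e-4 reflects the multi-log cell kill of
#'   radiosurgery; by the trigger volume the aggressive clone typically
#'   dominates the tumor almost completely, so only a small overall survival
#'   leaves enough less aggressive cells to restore a mixed composition.
#' @param post_aggressive_fraction Aggressive proportion among survivors of a
#'   balanced treatment (default 0.1: the aggressive clone is the more
#'   treatment-sensitive one, so treatment resets it to a minority).
#' @return An object of class `treatment_spec`.
#' @export
treatment_spec <- function(scenario = c("deplete_aggressive",
                                        "deplete_less_aggressive",
                                        "balanced"),
                           trigger_volume = 1, trigger_time = NULL,
                           survival_fraction = 1e-4,
                           post_aggressive_fraction = 0.1) {
  scenario <- match.arg(scenario)
  bm_assert(survival_fraction >= 0 && survival_fraction <= 1 &&
              post_aggressive_fraction >= 0 && post_aggressive_fraction <= 1,
            "bm_validation_error", "treatment fractions must be in [0, 1]")
  structure(list(scenario = scenario, trigger_volume = trigger_volume,
                 trigger_time = trigger_time,
                 survival_fraction = survival_fraction,
                 post_aggressive_fraction = post_aggressive_fraction),
            class = "treatment_spec")
}

#' Apply a treatment to a lattice state
#'
#' @param state A [lattice_state()].
#' @param spec A [treatment_spec()].
#' @return The treated `lattice_state`.
#' @export
apply_treatment <- function(state, spec) {
  stopifnot(inherits(state, "lattice_state"), inherits(spec, "treatment_spec"))
  if (spec$scenario == "deplete_aggressive") {
    state$pop2[] <- 0L
    return(state)
  }
  if (spec$scenario == "deplete_less_aggressive") {
    state$pop1[] <- 0L
    return(state)
  }
  A <- sum(as.numeric(state$pop2))
  B <- sum(as.numeric(state$pop1))
  S <- spec$survival_fraction * (A + B)
  tA <- spec$post_aggressive_fraction * S
  tB <- S - tA
  if ((tA > 0 && A == 0) || (tB > 0 && B == 0) || tA > A || tB > B) {
    bm_error("bm_treatment_error",
             "requested post-treatment composition is infeasible for this state")
  }
  pA <- if (A > 0) tA / A else 0
  pB <- if (B > 0) tB / B else 0
  iA <- which(state$pop2 > 0L)
  iB <- which(state$pop1 > 0L)
  state$pop2[iA] <- as.integer(rbinom(length(iA), state$pop2[iA], pA))
  state$pop1[iB] <- as.integer(rbinom(length(iB), state$pop1[iB], pB))
  state
}

#' Simulate longitudinal growth of a virtual brain metastasis
#'
#' Seeds `initial_cells` in the central voxel (split by
#' `initial_aggressive_fraction`; if the aggressive share would round to zero
#' cells the seed is raised to `subclone_floor` cells so the proportion is
#' representable), then advances the lattice until the total volume reaches
#' `limit_volume`, the population goes extinct, or the step budget runs out
#' (the latter raises a stagnation warning and returns the partial
#' trajectory). Volume is `total cells / K * voxel volume` converted to cm^3:
#' a voxel at carrying capacity contributes exactly its physical volume.
#'
#' @param config A [sim_config()].
#' @param traits List of two [bm_traits()]: less aggressive population first,
#'   aggressive second. Default: base rates vs an aggressive clone with
#'   `v_div = 1.8`, `v_mig = 1.925` (80% / 92.5% advantages).
#' @param treatment Optional [treatment_spec()], applied once when its trigger
#'   is met.
#' @param record_interval Trajectory recording cadence (days, default 1).
#' @param check_capacity Assert the per-voxel capacity bound every step.
#' @return A `sim_trajectory` data.frame with columns `time_days`,
#'   `volume_cm3`, `cells_pop1`, `cells_pop2`, and attributes
#'   `treatment_time` (NA if untreated) and `final_state`.
#' @export
simulate_bm <- function(config = sim_config(),
                        traits = list(bm_traits(),
                                      bm_traits(v_div = 1.8, v_mig = 1.925)),
                        treatment = NULL, record_interval = 1,
                        check_capacity = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  step_probs(traits[[1]], traits[[2]], config)  # fail fast on bad config
  if (!is.null(config$seed)) set.seed(config$seed)

  ncell <- config$initial_cells
  f <- config$initial_aggressive_fraction
  if (f > 0 && round(f * ncell) < 1) ncell <- max(ncell, config$subclone_floor)
  n2 <- if (f > 0) max(1L, as.integer(round(f * ncell))) else 0L
  n1 <- as.integer(ncell) - n2
  state <- lattice_state(config, n1 = n1, n2 = n2)

  vol_factor <- config$voxel_size^3 / (config$K * 1000)  # cells -> cm^3
  steps_per_rec <- max(1L, as.integer(round(record_interval / config$dt)))
  max_recs <- ceiling(config$max_days / (steps_per_rec * config$dt))

  times <- 0
  vols <- (n1 + n2) * vol_factor
  c1 <- as.numeric(n1)
  c2 <- as.numeric(n2)
  treat_time <- NA_real_
  treated <- is.null(treatment)

  for (rec in seq_len(max_recs)) {
    state <- meso_step(state, traits, config, nsteps = steps_per_rec,
                       check_capacity = check_capacity)
    tot <- attr(state, "totals")
    last <- nrow(tot)
    if (check_capacity &&
        any(attr(state, "maxvox") > config$K)) {
      bm_error("bm_capacity_error", "per-voxel capacity exceeded")
    }
    t1 <- tot[last, 1]
    t2 <- tot[last, 2]
    vol <- (t1 + t2) * vol_factor
    times <- c(times, state$time)
    vols <- c(vols, vol)
    c1 <- c(c1, t1)
    c2 <- c(c2, t2)

    if (!treated) {
      hit <- if (!is.null(treatment$trigger_time)) {
        state$time >= treatment$trigger_time
      } else {
        vol >= treatment$trigger_volume
      }
      if (hit) {
        state <- apply_treatment(state, treatment)
        treat_time <- state$time
        treated <- TRUE
        t1 <- sum(as.numeric(state$pop1))
        t2 <- sum(as.numeric(state$pop2))
        ## overwrite the record at the trigger time with the treated state so
        ## recorded times stay strictly increasing
        n <- length(times)
        vols[n] <- (t1 + t2) * vol_factor
        c1[n] <- t1
        c2[n] <- t2
      }
    }

    if (t1 + t2 == 0) break                   # extinction
    if (vols[length(vols)] >= config$limit_volume) break
    if (rec == max_recs) {
      warning(structure(
        class = c("bm_stagnation_warning", "warning", "condition"),
        list(message = "step budget exhausted before reaching the limit volume; returning partial trajectory",
             call = NULL)))
    }
  }

  traj <- data.frame(time_days = times, volume_cm3 = vols,
                     cells_pop1 = c1, cells_pop2 = c2)
  class(traj) <- c("sim_trajectory", "data.frame")
  attr(traj, "treatment_time") <- treat_time
  attr(traj, "final_state") <- state
  traj
}

#' Growth exponent from a simulated trajectory
#'
#' Picks one uniformly random recorded time point from each third of the
#' trajectory's time span, forms a three-point record, and solves the
#' three-point equation. Draws violating strict volume growth are resampled
#' up to `retries` times. For treated trajectories the post-treatment segment
#' is used by default (the exponent of interest is the regrowth exponent).
#'
#' @param traj A `sim_trajectory` from [simulate_bm()].
#' @param from_time Restrict to recorded times `>= from_time`; default is the
#'   treatment time when one is present, otherwise the trajectory start.
#' @param retries Resampling budget for non-monotone draws (default 100).
#' @return A `beta_estimate` (see [solve_three_point_beta()]) with the sampled
#'   record attached as `record`.
#' @export
beta_from_trajectory <- function(traj, from_time = NULL, retries = 100L) {
  stopifnot(inherits(traj, "sim_trajectory") || is.data.frame(traj))
  if (is.null(from_time)) {
    tt <- attr(traj, "treatment_time")
    from_time <- if (!is.null(tt) && !is.na(tt)) tt else -Inf
  }
  keep <- traj$time_days >= from_time & traj$volume_cm3 > 0
  t <- traj$time_days[keep]
  v <- traj$volume_cm3[keep]
  bm_assert(length(t) >= 3L, "bm_sampling_error",
            "trajectory has fewer than 3 usable recorded points")
  edges <- seq(min(t), max(t), length.out = 4L)
  thirds <- list(which(t <= edges[2]),
                 which(t > edges[2] & t <= edges[3]),
                 which(t > edges[3]))
  bm_assert(all(lengths(thirds) > 0), "bm_sampling_error",
            "a third of the time span contains no recorded point")
  for (i in seq_len(retries)) {
    idx <- vapply(thirds, function(ix) ix[sample.int(length(ix), 1L)], 1L)
    tt <- t[idx]
    vv <- v[idx]
    if (all(diff(tt) > 0) && all(diff(vv) > 0)) {
      est <- tryCatch(
        solve_three_point_beta(three_point_record(tt, vv)),
        bm_error = function(e) NULL)
      if (!is.null(est)) {
        est$record <- list(times = tt, volumes = vv)
        return(est)
      }
    }
  }
  bm_error("bm_sampling_error",
           "retry budget exhausted: no strictly growing triple found")
}

#' Sweep of the advantage coefficients
#'
#' Runs untreated two-population simulations over a grid of
#' `(v_div, v_mig)` advantage pairs, extracts the growth exponent from each
#' trajectory, and averages over replicate seeds. Restarts from scratch at
#' each grid point with the given initial aggressive proportion (the
#' post-treatment proportion in the treatment-effectiveness reading).
#'
#' @param v_div_grid,v_mig_grid Advantage values to explore. Values whose
#'   per-step migration probability would exceed 1 are rejected at
#'   construction (see [bm_traits()]); at the default 4-hour step this caps
#'   usable `v_mig` near 2.08.
#' @param initial_aggressive_fraction Initial aggressive proportion
#'   (default 0.1).
#' @param replicates Replicate simulations per grid point (default 5).
#' @param config Base [sim_config()]; each replicate derives its seed from
#'   `config$seed`.
#' @param base_traits The non-advantaged population's [bm_traits()].
#' @return Data.frame with columns `v_div`, `v_mig`, `mean_beta`, `n_ok`, and
#'   attribute `argmax` (row of the largest mean exponent).
#' @export
advantage_sweep <- function(v_div_grid, v_mig_grid,
                            initial_aggressive_fraction = 0.1,
                            replicates = 5L, config = sim_config(),
                            base_traits = bm_traits()) {
  grid <- expand.grid(v_div = v_div_grid, v_mig = v_mig_grid,
                      KEEP.OUT.ATTRS = FALSE)
  seed0 <- if (is.null(config$seed)) 1L else config$seed
  mean_beta <- n_ok <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    betas <- rep(NA_real_, replicates)
    for (r in seq_len(replicates)) {
      cfg <- config
      cfg$seed <- (seed0 + 7919L * g + r) %% .Machine$integer.max
      cfg$initial_aggressive_fraction <- initial_aggressive_fraction
      traits <- list(base_traits,
                     bm_traits(base_traits$division_rate,
                               base_traits$death_rate,
                               base_traits$migration_coefficient,
                               v_div = grid$v_div[g], v_mig = grid$v_mig[g]))
      betas[r] <- tryCatch({
        traj <- simulate_bm(cfg, traits)
        beta_from_trajectory(traj)$beta
      }, bm_error = function(e) NA_real_)
    }
    mean_beta[g] <- mean(betas, na.rm = TRUE)
    n_ok[g] <- sum(!is.na(betas))
  }
  out <- cbind(grid, mean_beta = mean_beta, n_ok = n_ok)
  attr(out, "argmax") <- out[which.max(out$mean_beta), , drop = FALSE]
  out
}
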