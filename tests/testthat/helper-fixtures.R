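# Shared fixtures: forward-model records and an independent RK4 oracle for
# the growth ODE dV/dt = alpha * V^beta (b = 0).

rk4_vb <- function(V0, alpha, beta, times, h = 0.01) {
  f <- function(v) alpha * v^beta
  out <- numeric(length(times))
  v <- V0
  t <- times[1]
  out[1] <- v
  for (k in seq_along(times)[-1]) {
    while (t < times[k] - 1e-12) {
      hh <- min(h, times[k] - t)
      k1 <- f(v)
      k2 <- f(v + hh / 2 * k1)
      k3 <- f(v + hh / 2 * k2)
      k4 <- f(v + hh * k3)
      v <- v + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + hh
    }
    out[k] <- v
  }
  out
}

# three-point record generated from the closed-form law
vb_record <- function(V0, alpha, beta, times, t0 = times[1]) {
  v <- vb_volume(vb_params(V0, alpha, beta, t0 = t0), times)
  three_point_record(times, v)
}

# tiny deterministic config for lattice tests
small_config <- function(...) {
  sim_config(lattice_size = 11L, K = 1000, initial_cells = 10L, ...)
}
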