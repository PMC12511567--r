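# Independent numerical oracle for the 3-state loading/discharge cycle:
# A <-> B (k1, k2), A -> C (k3), C -> A (kd), integrated to long time.
cycle_steady_state_ode <- function(p, t_end = 1e5) {
  rhs <- function(t, y, parms) {
    A <- y[1]; B <- y[2]; C <- y[3]
    list(c(-parms$k1 * A + parms$k2 * B - parms$k3 * A + parms$kd * C,
           parms$k1 * A - parms$k2 * B,
           parms$k3 * A - parms$kd * C))
  }
  out <- deSolve::ode(y = c(A = 1, B = 0, C = 0), times = c(0, t_end),
                      func = rhs, parms = p, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  unname(out[2, "C"] / sum(out[2, c("A", "B", "C")]))
}

# random two-state parameter draw for property sweeps
random_kinetic_params <- function() {
  kinetic_params(k1 = 10^stats::runif(1, -2, 1.5),
                 k2 = 10^stats::runif(1, -2, 1.5),
                 k3 = 10^stats::runif(1, -1, 2),
                 total = 0.75)
}
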