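# shared fixtures and independent oracles

table1 <- rate_constants()        # packaged defaults

uni_sat_chain <- function() {
  build_absorbing_chain(build_unicycle(), condition(atp = 1000))
}

# random but well-behaved experimental conditions
draw_conditions <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    condition(atp = runif(1, 1, 2000), adp = runif(1, 0, 400),
              p = runif(1, 0, 0.5), force = runif(1, -1, 1.5)))
}

both_networks <- function() {
  list(unicycle = build_unicycle(),
       branched = build_branched(rate_constants(gating_g = 10)))
}

# Kolmogorov-Smirnov distance between a sample and an analytic dwell density
ks_distance <- function(sample, dist) {
  x <- sort(sample)
  n <- length(x)
  Fx <- pdwell(dist, x)
  max(abs(seq_len(n) / n - Fx), abs((seq_len(n) - 1) / n - Fx))
}

# mixture integral of a spectral dwell density (should be 1)
density_area <- function(d) Re(sum(d$weights / d$rates))

# two-state toy network: single dwell state with forward/backward exits
toy_two_exit <- function(k_fwd, k_bwd) {
  rc <- rate_constants(step_fwd = k_fwd, step_bwd = k_bwd)
  tr <- rbind(
    data.frame(from = "A", to = "A", rate = "step_fwd", law = "mechanical",
               species = NA, direction = "forward", slip = FALSE,
               offset = 1L, cycles = I(list("F"))),
    data.frame(from = "A", to = "A", rate = "step_bwd", law = "mechanical",
               species = NA, direction = "backward", slip = FALSE,
               offset = -1L, cycles = I(list("F"))),
    data.frame(from = "B", to = "A", rate = "p_release", law = "release",
               species = "P", direction = NA, slip = FALSE,
               offset = 0L, cycles = I(list("F"))))
  motor_network(c("A", "B"), tr, rc, id = "toy")
}
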