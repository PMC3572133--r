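test_that("occupancies start at the initial condition and conserve probability", {
  ch <- uni_sat_chain()
  occ <- solve_occupancies(ch, "DT", c(0, 0.001, 0.005, 0.01, 0.05, 0.2))
  expect_equal(occ$DT[1], 1)
  expect_equal(occ$DD[1] + occ$ED[1] + occ$TD[1], 0, tolerance = 1e-12)
  tot <- rowSums(occ[, c("DD", "ED", "TD", "DT", "forward", "backward")])
  expect_equal(tot, rep(1, nrow(occ)), tolerance = 1e-9)
  # transient occupancy vanishes at long times
  occ_inf <- solve_occupancies(ch, "DT", c(0, 5))
  expect_lt(sum(occ_inf[2, c("DD", "ED", "TD", "DT")]), 1e-10)
})

test_that("spectral propagator agrees with the matrix exponential", {
  # dual route: eigen-expansion vs Matrix::expm on the same generator
  ch <- build_absorbing_chain(build_unicycle(), condition(atp = 10, adp = 40))
  p0 <- c(DD = 0, ED = 0, TD = 0, DT = 1)
  for (t in c(0.003, 0.05, 0.4)) {
    direct <- as.vector(as.matrix(Matrix::expm(Matrix::Matrix(ch$Q * t))) %*% p0)
    occ <- solve_occupancies(ch, "DT", c(0, t))
    expect_equal(unlist(occ[2, c("DD", "ED", "TD", "DT")]), 
                 setNames(direct, c("DD", "ED", "TD", "DT")), tolerance = 1e-9)
  }
})

test_that("absorption probabilities match the single-branch ratio", {
  ch <- uni_sat_chain()
  ab <- absorption_probabilities(ch)
  # from DT the only backward exit is the backstep, everything downstream
  # absorbs forward
  expect_equal(ab$pi["backward", "DT"], 0.65 / 250.65, tolerance = 1e-12)
  expect_equal(ab$pi["forward", "TD"], 1, tolerance = 1e-12)
  expect_equal(unname(colSums(ab$pi)), rep(1, 4), tolerance = 1e-12)
})

test_that("the backward conditional dwell from DT is the memoryless exit law", {
  ch <- uni_sat_chain()
  rho <- conditional_density(ch, "DT", "backward")
  tt <- c(0.0001, 0.002, 0.01, 0.03)
  expect_equal(ddwell(rho, tt), 250.65 * exp(-250.65 * tt), tolerance = 1e-8)
  expect_equal(mean(rho), 1 / 250.65, tolerance = 1e-8)
  expect_equal(ddwell(rho, -0.1), 0)
})

test_that("undefined conditionals raise an error", {
  # blocked reverse chemistry and no ADP: from TD, backward absorption is
  # impossible only when the backstep cannot be undone... use a condition
  # where one direction truly has zero probability: toy chain with k_bwd = 0
  net <- toy_two_exit(5, 0)
  ch <- build_absorbing_chain(net, condition(), force_model())
  expect_error(conditional_density(ch, "A", "backward"), "absorption probability")
})

test_that("step densities mix with stationary step-type frequencies", {
  ch <- uni_sat_chain()
  sd <- step_densities(ch)
  expect_equal(sd$p_f + sd$p_b, 1, tolerance = 1e-12)
  expect_equal(sd$p_b, 2.587e-3, tolerance = 1e-3)
  # mixture identity: rho_total = p_f rho_f + p_b rho_b pointwise
  tt <- c(0.001, 0.01, 0.1, 0.3)
  expect_equal(ddwell(sd$rho_total, tt),
               sd$p_f * ddwell(sd$rho_f, tt) + sd$p_b * ddwell(sd$rho_b, tt),
               tolerance = 1e-9)
})

test_that("densities are normalized across random conditions and networks", {
  conds <- draw_conditions(20, seed = 23)
  nets <- both_networks()
  for (cond in conds) {
    for (net in nets) {
      ch <- build_absorbing_chain(net, cond)
      sd <- step_densities(ch)
      for (d in list(sd$rho_f, sd$rho_b, sd$rho_total)) {
        if (is.null(d)) next
        expect_lt(abs(density_area(d) - 1), 1e-6)
      }
    }
  }
  # independent quadrature check on one case
  ch <- build_absorbing_chain(build_unicycle(), condition(atp = 10, adp = 40))
  d <- step_densities(ch)$rho_total
  area <- integrate(function(t) ddwell(d, t), 0, Inf, rel.tol = 1e-9)$value
  expect_equal(area, 1, tolerance = 1e-6)
})

test_that("decay spectrum equals exit rates for the acyclic transient graph", {
  expect_equal(as.numeric(decay_spectrum(uni_sat_chain())),
               c(12, 250.65, 900, 7000), tolerance = 1e-10)
  ch2 <- build_absorbing_chain(build_unicycle(), condition(atp = 2))
  expect_equal(min(decay_spectrum(ch2)), 1.8, tolerance = 1e-10)
})

test_that("slow eigenvalues approach ADP release and ATP binding as [ADP] -> 0", {
  # convergence is linear in [ADP]; allow a proportional band
  for (adp in c(0.1, 1e-3)) {
    sp <- decay_spectrum(build_absorbing_chain(build_unicycle(),
                                               condition(atp = 5, adp = adp)))
    expect_equal(sort(unclass(sp))[1:2], c(0.9 * 5, 12), tolerance = 1.5 * adp)
  }
})

test_that("the density tail decays at the smallest eigenvalue", {
  ch <- build_absorbing_chain(build_unicycle(), condition(atp = 100, adp = 20))
  sp <- decay_spectrum(ch)
  lmin <- min(sp)
  d <- step_densities(ch)$rho_total
  t1 <- 5 / lmin; t2 <- 10 / lmin
  slope <- (log(ddwell(d, t2)) - log(ddwell(d, t1))) / (t2 - t1)
  expect_equal(-slope, lmin, tolerance = 0.01)
})

test_that("mean dwell matches first-step analysis and density first moment", {
  ch <- uni_sat_chain()
  hand <- 1 / 250.65 + (250 / 250.65) * (1 / 12 + 1 / 900 + 1 / 7000)
  expect_equal(mean_dwell(ch, "DT"), hand, tolerance = 1e-12)
  d <- conditional_density(ch, "DT", "forward")
  dtot <- dwellnet:::make_dwell_dist(ch, "DT", c("forward", "backward"), "total")
  expect_equal(mean(dtot), mean_dwell(ch, "DT"), tolerance = 1e-8)
  # uniform rescaling of all rates by c scales the mean by 1/c
  rc2 <- rate_constants(atp_bind = 1.8, adp_bind = 9, adp_release_trail = 24,
                        p_release = 500, step_fwd = 14000, step_bwd = 1.3)
  ch2 <- build_absorbing_chain(build_unicycle(rc2), condition(atp = 1000))
  expect_equal(mean_dwell(ch2, "DT"), hand / 2, tolerance = 1e-12)
})
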