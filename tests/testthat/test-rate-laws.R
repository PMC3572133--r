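test_that("effective rates follow the chemical and mechanical rate laws", {
  fm <- force_model()
  bind_atp <- list(type = "binding", species = "ATP")
  expect_equal(transition_rate(0.9, bind_atp, condition(atp = 1), fm), 0.9)
  expect_equal(transition_rate(0.9, bind_atp, condition(atp = 0), fm), 0)
  expect_equal(transition_rate(4.5, list(type = "binding", species = "ADP"),
                               condition(adp = 400), fm), 1800)
  mech_f <- list(type = "mechanical", direction = "forward")
  expect_equal(transition_rate(7000, mech_f, condition(force = 0), fm), 7000)
  expect_equal(transition_rate(7000, mech_f, condition(force = 0),
                               force_model(theta = 0.2)), 7000)
  # release laws ignore concentration
  expect_equal(transition_rate(12, list(type = "release", species = "ADP"),
                               condition(adp = 400), fm), 12)
})

test_that("forward and backward factors multiply to the Boltzmann ratio", {
  # product of forward factor and inverse backward factor at 1 pN
  fm <- force_model(theta = 0.5)
  cond <- condition(force = 1)
  f <- transition_rate(1, list(type = "mechanical", direction = "forward"), cond, fm)
  b <- transition_rate(1, list(type = "mechanical", direction = "backward"), cond, fm)
  expect_equal(f / b, exp(-36 / 4.114), tolerance = 1e-12)

  set.seed(1)
  for (i in 1:100) {
    fmr <- force_model(theta = runif(1))
    condr <- condition(force = runif(1, -4, 4))
    fr <- transition_rate(1, list(type = "mechanical", direction = "forward"), condr, fmr)
    br <- transition_rate(1, list(type = "mechanical", direction = "backward"), condr, fmr)
    expect_equal(fr / br, exp(-condr$force * 36 / 4.114), tolerance = 1e-12)
  }
})

test_that("mechanical rates are monotone in load and recover bare constants at F = 0", {
  fm <- force_model()
  Fgrid <- seq(-2, 3, 0.5)
  fwd <- vapply(Fgrid, function(f) transition_rate(
    7000, list(type = "mechanical", direction = "forward"), condition(force = f), fm),
    numeric(1))
  bwd <- vapply(Fgrid, function(f) transition_rate(
    0.65, list(type = "mechanical", direction = "backward"), condition(force = f), fm),
    numeric(1))
  expect_true(all(diff(fwd) < 0))
  expect_true(all(diff(bwd) > 0))

  # every transition of both networks recovers its bare constant at F = 0
  for (net in both_networks()) {
    tr <- net$transitions
    rates <- dwellnet:::transition_rates_at(net, condition(atp = 1, adp = 1, p = 1),
                                            fm)
    bare <- vapply(tr$rate, dwellnet:::resolve_rate, numeric(1), rc = net$rates)
    expect_equal(unname(rates), unname(bare), tolerance = 1e-15)
  }
})

test_that("the threshold chemical-force policy suppresses only nucleotide binding", {
  fm <- force_model(chem_force_mode = "threshold",
                    chem_force_threshold = 2, chem_force_scale = 1)
  below <- condition(atp = 1, force = 1.5)
  above <- condition(atp = 1, force = 4)
  bind_atp <- list(type = "binding", species = "ATP")
  expect_equal(transition_rate(0.9, bind_atp, below, fm), 0.9)
  expect_equal(transition_rate(0.9, bind_atp, above, fm),
               0.9 * exp(-2 * 36 / 4.114))
  # release rates and P binding stay load-independent
  expect_equal(transition_rate(12, list(type = "release", species = "ADP"), above, fm), 12)
  expect_equal(transition_rate(2, list(type = "binding", species = "P"),
                               condition(p = 1, force = 4), fm), 2)
})

test_that("invalid inputs are rejected", {
  expect_error(condition(atp = -1), "concentration")
  expect_error(rate_constants(gating_g = 0.5), "gating_g")
  expect_error(rate_constants(atp_bind = -1), ">= 0")
  expect_error(force_model(theta = 1.5), "theta")
  expect_error(transition_rate(1, list(type = "binding", species = "GTP"),
                               condition(), force_model()), "species")
  expect_error(transition_rate(
    1, list(type = "mechanical", direction = "backward"),
    condition(force = 1e6), force_model()), "overflow")
})
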