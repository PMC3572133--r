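test_that("synthetic bundles are reproducible from parameters and seed", {
  cond <- condition(atp = 10, adp = 0.1)
  b1 <- generate_synthetic("branched", cond = cond, n_dwells = 300,
                           bin_width = 0.05, seed = 8)
  b2 <- generate_synthetic("branched", cond = cond, n_dwells = 300,
                           bin_width = 0.05, seed = 8)
  expect_identical(b1$histogram, b2$histogram)
  expect_identical(b1$sample$dwell_s, b2$sample$dwell_s)
  expect_equal(sum(b1$histogram$density) * attr(b1$histogram, "bin_width"), 1,
               tolerance = 1e-12)
})

test_that("empirical dwells converge to the analytic total density", {
  cond <- condition(atp = 10, adp = 0.1)
  b <- generate_synthetic("unicycle", cond = cond, n_dwells = 1e4,
                          bin_width = 0.05, seed = 12)
  d <- step_densities(build_absorbing_chain(build_unicycle(), cond))$rho_total
  expect_lt(ks_distance(b$sample$dwell_s, d), 0.02)
})

test_that("the fixture suite covers the documented conditions deterministically", {
  suite <- make_fixture_suite(seed = 5, n_dwells = 300)
  man <- attr(suite, "manifest")
  expect_equal(nrow(man), 6)
  expect_setequal(man$fixture, c("sat_atp", "adp_400", "atp_10", "atp_2",
                                 "substall", "superstall"))
  expect_true(all(man$network == "branched" & man$gating_g == 10))
  # any fixture regenerates bit-identically from its manifest row
  row <- man[man$fixture == "atp_10", ]
  fm <- if (row$chem_force_mode == "threshold")
    force_model(chem_force_mode = "threshold") else force_model()
  again <- generate_synthetic("branched",
                              rc = rate_constants(gating_g = row$gating_g),
                              cond = condition(atp = row$atp_uM, adp = row$adp_uM,
                                               p = row$p_uM, force = row$force_pN),
                              fm = fm, n_dwells = row$n_dwells,
                              bin_width = row$bin_width_s, seed = row$seed)
  expect_identical(again$histogram, suite$atp_10$histogram)
})

test_that("added ADP broadens the uni-cycle dwell-time distribution", {
  # the ADP inhibition acts through ED -> DD rebinding in the
  # chemomechanical cycle; asserted on the uni-cycle, where it is not
  # confounded by the reconstruction's long-lived EE state
  base <- generate_synthetic("unicycle", cond = condition(atp = 1000, adp = 0),
                             n_dwells = 2000, bin_width = 0.02, seed = 91)
  plus <- generate_synthetic("unicycle", cond = condition(atp = 1000, adp = 400),
                             n_dwells = 2000, bin_width = 0.05, seed = 92)
  x <- base$sample$dwell_s
  y <- plus$sample$dwell_s
  se <- sqrt(var(x) / length(x) + var(y) / length(y))
  expect_gt(mean(y) - mean(x), 3 * se)
})

test_that("weak gating lengthens dwells at limiting ATP", {
  cond <- condition(atp = 2, adp = 0.1)
  g1 <- generate_synthetic("branched", rc = rate_constants(gating_g = 1),
                           cond = cond, n_dwells = 1000, bin_width = 0.1,
                           seed = 14)
  g10 <- generate_synthetic("branched", rc = rate_constants(gating_g = 10),
                            cond = cond, n_dwells = 1000, bin_width = 0.1,
                            seed = 15)
  x <- g1$sample$dwell_s; y <- g10$sample$dwell_s
  se <- sqrt(var(x) / length(x) + var(y) / length(y))
  expect_gt(mean(x) - mean(y), 3 * se)
})

test_that("superstall ratcheting dwells are exponential", {
  suite <- make_fixture_suite(seed = 2, n_dwells = 2000)
  dw <- suite$superstall$sample$dwell_s
  p <- stats::ks.test(dw, "pexp", 1 / mean(dw))$p.value
  expect_gt(p, 0.05)
})
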