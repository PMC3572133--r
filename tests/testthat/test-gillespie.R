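test_that("identical seeds reproduce trajectories exactly", {
  net <- build_unicycle()
  cond <- condition(atp = 50, adp = 10)
  t1 <- simulate_motor(net, cond, n_steps = 500, seed = 99)
  t2 <- simulate_motor(net, cond, n_steps = 500, seed = 99)
  expect_identical(t1$events, t2$events)
  t3 <- simulate_motor(net, cond, n_steps = 500, seed = 100)
  expect_false(identical(t1$events, t3$events))
})

test_that("waiting times and branch fractions follow the exponential race", {
  # single dwell state with two equal competing exits
  net <- toy_two_exit(4, 4)
  traj <- simulate_motor(net, condition(), n_events = 2e4, seed = 3,
                         init_state = "A")
  w <- diff(c(0, traj$events$time))
  expect_equal(mean(w), 1 / 8, tolerance = 3 / sqrt(length(w)) * 1)
  frac_fwd <- mean(traj$events$offset > 0)
  se <- sqrt(0.25 / length(w))
  expect_lt(abs(frac_fwd - 0.5), 3 * se)
})

test_that("backstep fraction matches the absorption probabilities", {
  net <- build_unicycle()
  traj <- simulate_motor(net, condition(atp = 1000), n_steps = 1e5, seed = 17)
  steps <- traj$events$offset[traj$events$offset != 0]
  p_bwd <- mean(steps < 0)
  p_expect <- 2.5867e-3
  se <- sqrt(p_expect * (1 - p_expect) / length(steps))
  expect_lt(abs(p_bwd - p_expect), 3 * se)
})

test_that("dwell extraction follows the step-to-step definition", {
  traj <- structure(list(
    events = data.frame(time = c(0.4, 1.0, 2.5, 2.8, 3.0),
                        transition = c(1L, 5L, 5L, 2L, 6L),
                        offset = c(0L, 1L, 1L, 0L, -1L)),
    condition = condition(), seed = 1, network_id = "manual",
    step_size = 36, final_time = 3, absorbed = FALSE),
    class = "motor_trajectory")
  dw <- extract_dwells(traj)
  expect_equal(dw$dwell_s, c(1.5, 0.5))
  expect_equal(dw$prev, c("f", "f"))
  expect_equal(dw[["next"]], c("f", "b"))
  # dwell count is one less than the mechanical event count
  expect_equal(nrow(dw), sum(traj$events$offset != 0) - 1)

  traj$events <- traj$events[1:2, ]
  expect_warning(dw0 <- extract_dwells(traj), "fewer than 2")
  expect_equal(nrow(dw0), 0)
})

test_that("every forward mechanical event displaces the motor by one step", {
  traj <- simulate_motor(build_unicycle(), condition(atp = 500), n_events = 1e4,
                         seed = 5)
  pos <- trajectory_positions(traj)
  jumps <- diff(pos$position_nm)
  fwd <- jumps[jumps > 0]
  expect_equal(mean(fwd), 36)
  expect_true(all(abs(jumps) == 36))
})

test_that("long-run simulated velocity matches the periodic steady state", {
  net <- build_unicycle()
  cond <- condition(atp = 10, adp = 5)
  traj <- simulate_motor(net, cond, n_steps = 2e4, seed = 21)
  pos <- trajectory_positions(traj)
  v_sim <- pos$position_nm[nrow(pos)] / traj$final_time
  v_exact <- velocity(net, cond)
  # renewal CLT: relative sd of order sqrt(2/n_steps)
  expect_lt(abs(v_sim - v_exact) / v_exact, 3 * sqrt(2 / 2e4))
})

test_that("histograms are area-normalized and honour the dead time", {
  dw <- c(0.004, 0.02, 0.05, 0.06, 0.3)
  h <- dwell_histogram(dw, bin_width = 0.05)
  expect_equal(sum(h$density) * attr(h, "bin_width"), 1, tolerance = 1e-12)
  h2 <- dwell_histogram(dw, bin_width = 0.05, dead_time = 0.01)
  expect_equal(attr(h2, "n"), 4)
  expect_equal(sum(h2$density) * attr(h2, "bin_width"), 1, tolerance = 1e-12)
  expect_error(dwell_histogram(dw, bin_width = 0.05, dead_time = 1),
               "no dwells")
  expect_error(dwell_histogram(dw, bin_width = -1), "bin_width")
})
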