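test_that("windowed features capture orbit, ramp and Brownian signatures", {
  # noiseless circular orbit at 2 Hz: angular speed 2 pi / period; a full
  # turn per window leaves little net displacement (low directedness)
  t <- seq(0, 6, by = 0.01)
  orbit <- trajectory(t, 0.5 * cos(4 * pi * t), 0.5 * sin(4 * pi * t),
                      frame_rate = 100)
  f <- compute_features(orbit, smooth = 0.01)
  expect_equal(mean(f$ang_speed), 4 * pi, tolerance = 0.02)
  expect_true(all(abs(f$ang_net) > pi / 2))
  expect_lt(mean(f$directedness), 0.5)
  # linear outward ramp: directedness ~ 1, radial velocity = ramp speed
  ramp <- trajectory(t, 0.2 * t, rep(0, length(t)), frame_rate = 100)
  fr <- compute_features(ramp, smooth = 0.01)
  expect_true(all(fr$directedness > 0.95))
  expect_equal(mean(fr$r_vel), 0.2, tolerance = 0.01)
  expect_error(compute_features(orbit, window = 0.01), "5 frames")
})

test_that("Brownian motion shows no net rotation across windows", {
  cfg <- trapped_config(seed = 61)
  sim <- simulate_trapped_bead(cfg, behavior_schedule("brownian", 60))
  f <- compute_features(sim$trajectory, center = c(0, 0))
  se <- sd(f$ang_net) / sqrt(nrow(f))
  expect_lt(abs(mean(f$ang_net)), 3 * se + 1e-9)
})

test_that("pure states classify into single covering intervals", {
  trap <- default_trap(1)
  cfg <- trapped_config(seed = 62)
  br <- simulate_trapped_bead(cfg, behavior_schedule("brownian", 30))
  ev_br <- classify_states(compute_features(br$trajectory), trap)
  expect_equal(ev_br$state, "brownian")
  gy <- simulate_trapped_bead(cfg, behavior_schedule("gyration", 30),
                              noise = FALSE)
  ev_gy <- classify_states(compute_features(gy$trajectory), trap)
  expect_equal(ev_gy$state, "gyration")
  expect_equal(ev_gy$start, 0)
  expect_error(classify_states(compute_features(br$trajectory), trap,
                               thresholds = list(r_thresh = 0, d_thresh = 0,
                                                 a_thresh = 0)),
               "configuration error")
})

test_that("state partition covers each track and fractions sum to one", {
  trap <- default_trap(1)
  cfg <- trapped_config(seed = 63)
  sch <- behavior_schedule(c("gyration", "pilus_cycle", "gyration",
                             "brownian"), c(30, 13, 10, 20))
  sim <- simulate_trapped_bead(cfg, sch)
  ev <- classify_states(compute_features(sim$trajectory), trap)
  dur <- ev$end - ev$start
  expect_equal(sum(dur), ev$end[nrow(ev)] - ev$start[1])
  expect_equal(ev$start[-1], ev$end[-nrow(ev)])
  expect_true(all(dur >= 0.4 - 1e-9)) # hysteresis floor
})

test_that("mixed schedules segment with at least 90% frame accuracy", {
  trap <- default_trap(1)
  accs <- vapply(71:73, function(s) {
    cfg <- trapped_config(seed = s)
    sch <- behavior_schedule(c("gyration", "pilus_cycle", "gyration",
                               "brownian"), c(30, 13, 10, 20))
    sim <- simulate_trapped_bead(cfg, sch)
    ev <- classify_states(compute_features(sim$trajectory), trap)
    frame_accuracy(sim$events, ev, sim$trajectory$t)
  }, numeric(1))
  expect_true(all(accs >= 0.9))
})

test_that("raising the displacement gate never adds pilus time", {
  trap <- default_trap(1)
  cfg <- trapped_config(seed = 64)
  sch <- behavior_schedule(c("gyration", "pilus_cycle", "gyration"),
                           c(15, 12, 10))
  sim <- simulate_trapped_bead(cfg, sch)
  f <- compute_features(sim$trajectory)
  base <- default_thresholds(trap)
  pilus_time <- vapply(c(0.5, 1, 2, 4), function(mult) {
    ev <- classify_states(f, trap,
                          thresholds = list(r_thresh = mult * base$r_thresh))
    sum((ev$end - ev$start)[ev$state == "pilus_attached"])
  }, numeric(1))
  expect_true(all(diff(pilus_time) <= 1e-9))
})

test_that("pilus cycles resolve sub-phases and flag censored intervals", {
  trap <- default_trap(1)
  cfg <- trapped_config(seed = 65)
  sch <- behavior_schedule(c("gyration", "pilus_cycle", "gyration"),
                           c(10, 12, 8))
  sim <- simulate_trapped_bead(cfg, sch)
  ev <- classify_states(compute_features(sim$trajectory), trap)
  cyc <- extract_pilus_cycles(ev, sim$trajectory)
  expect_equal(nrow(cyc), 1)
  expect_true(cyc$resolved)
  expect_true(cyc$complete)
  expect_equal(cyc$duration, 12, tolerance = 0.1) # within ~1 window
  expect_lt(cyc$attach, 10.6)
  expect_gt(cyc$release_speed, cyc$retract_speed)
  # attach < retract end <= hold end
  expect_lt(cyc$attach, cyc$retract_end)
  expect_lte(cyc$retract_end, cyc$hold_end)

  # censored: retraction still running at track end
  sch2 <- behavior_schedule(c("gyration", "pilus_cycle"), c(10, 12))
  sim2 <- simulate_trapped_bead(cfg, sch2)
  ev2 <- classify_states(compute_features(sim2$trajectory), trap)
  cyc2 <- extract_pilus_cycles(ev2, sim2$trajectory)
  expect_true(nrow(cyc2) >= 1)
  expect_false(cyc2$complete[nrow(cyc2)])

  # too short to resolve sub-phases
  ev3 <- event_table("pilus_attached", 10, 11)
  attr(ev3, "center") <- c(0, 0)
  cyc3 <- extract_pilus_cycles(ev3, sim$trajectory)
  expect_false(cyc3$resolved)
})

test_that("event summaries reproduce the reported time-partition arithmetic", {
  # planted pili 100.6 s vs flagellum 230.9 s -> pili fraction ~ 30%
  ev <- event_table(c("gyration", "pilus_attached"), c(0, 230.9),
                    c(230.9, 331.5))
  ss <- summarize_events(ev)
  expect_equal(ss$time_fraction$pili, 100.6 / 331.5, tolerance = 1e-9)
  expect_equal(round(ss$time_fraction$pili, 2), 0.30)
  # one cycle and one gap: SDs are zero
  ev2 <- event_table(c("pilus_attached", "gyration", "pilus_attached"),
                     c(0, 12, 20), c(12, 20, 30))
  ss2 <- summarize_events(ev2)
  expect_equal(ss2$intercycle_period$mean, 8)
  expect_equal(ss2$intercycle_period$sd, 0)
  expect_equal(ss2$cycle_duration$mean, 11)
  # flagellum-free track: flagellum fraction zero
  ev3 <- event_table(c("brownian", "pilus_attached", "brownian"),
                     c(0, 10, 22), c(10, 22, 30))
  ss3 <- summarize_events(ev3)
  expect_equal(ss3$time_fraction$flagellum, 0)
  expect_equal(ss3$flagellum_time, 0)
})

test_that("activity and rotation stages are read off the segmentation", {
  trap <- default_trap(1)
  cfg <- trapped_config(seed = 66)
  sch <- behavior_schedule(
    c("brownian", "gyration", "long_axis_rotation", "brownian"),
    c(5, 50, 10, 10))
  sim <- simulate_trapped_bead(cfg, sch)
  ev <- classify_states(compute_features(sim$trajectory), trap)
  ss <- summarize_events(ev)
  expect_equal(ss$activity_duration, 60, tolerance = 0.05)
  expect_equal(ss$rotation_stage_duration, 10, tolerance = 0.1)
})
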