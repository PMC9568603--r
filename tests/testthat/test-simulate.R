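test_that("Brownian-only simulation reproduces the OU stationary law", {
  d <- paper_defaults()
  trap <- default_trap(0.05)
  bead <- bead_geometry(1.5)
  # 1e5 frames sampled at 25 Hz: ~7000 relaxation times, so the sample
  # variance estimates the stationary variance to ~2%
  cfg <- sim_config(trap = trap, bead = bead, frame_rate = 25,
                    integration_step = 2e-3, seed = 101)
  sim <- cached("ou_long", simulate_trapped_bead(
    cfg, behavior_schedule("brownian", 4000)))
  ref <- thermal_reference(trap, bead)
  v <- c(var(sim$trajectory$x), var(sim$trajectory$y))
  expect_equal(v[1], unname(ref$stationary_variance[["x"]]), tolerance = 0.05)
  expect_equal(v[2], unname(ref$stationary_variance[["y"]]), tolerance = 0.05)
  # autocorrelation time gamma/kappa from the lag-1 autocorrelation
  z <- sim$trajectory$x - mean(sim$trajectory$x)
  n <- length(z)
  tau_hat <- -(1 / 25) / log(cor(z[-n], z[-1]))
  expect_equal(tau_hat, unname(ref$relaxation_time[["x"]]), tolerance = 0.1)
  # zero driving: mean displacement from the center is 0 within 3 SE
  n_eff <- 4000 / (2 * ref$relaxation_time[["x"]])
  se <- sqrt(ref$stationary_variance[["x"]] / n_eff)
  expect_lt(abs(mean(sim$trajectory$x)), 3 * se)
  expect_lt(abs(mean(sim$trajectory$y)), 3 * se)
})

test_that("identical config and seed give bit-identical output", {
  cfg <- trapped_config(seed = 11)
  sch <- behavior_schedule(c("gyration", "pilus_cycle", "brownian"),
                           c(5, 6, 4))
  a <- simulate_trapped_bead(cfg, sch)
  b <- simulate_trapped_bead(cfg, sch)
  expect_identical(a$trajectory$x, b$trajectory$x)
  expect_identical(a$trajectory$y, b$trajectory$y)
  expect_identical(a$events, b$events)
})

test_that("every simulated frame is covered by exactly one ground-truth state", {
  cfg <- trapped_config(seed = 12)
  sch <- behavior_schedule(c("gyration", "pilus_cycle", "brownian"),
                           c(5, 6, 4))
  sim <- simulate_trapped_bead(cfg, sch)
  cover <- vapply(sim$trajectory$t, function(t) {
    sum(t >= sim$events$start & t < sim$events$end)
  }, numeric(1))
  expect_true(all(cover == 1))
})

test_that("noiseless gyration settles on the planted circular orbit", {
  cfg <- trapped_config(seed = 13)
  sim <- simulate_trapped_bead(cfg, behavior_schedule("gyration", 10),
                               noise = FALSE)
  d <- paper_defaults()
  r <- sqrt(sim$trajectory$x^2 + sim$trajectory$y^2)
  tail_r <- r[500:1000]
  expect_equal(mean(tail_r), d$driving$orbit_radius, tolerance = 0.01)
  expect_lt(diff(range(tail_r)), 1e-3) # steady circle, not a spiral
  expect_equal(sim$events$state, "gyration")
  # phase advances at the planted gyration frequency, CCW positive
  th <- atan2(sim$trajectory$y, sim$trajectory$x)
  dth <- diff(th[500:1000])
  dth <- (dth + pi) %% (2 * pi) - pi
  expect_equal(mean(dth) * cfg$frame_rate / (2 * pi),
               d$driving$gyration_freq, tolerance = 0.01)
})

test_that("noiseless pilus cycle ramps, holds, then relaxes on trap timescale", {
  d <- paper_defaults()
  cfg <- sim_config(trap = default_trap(1), frame_rate = 100, seed = 14,
                    pilus = list(retract_speed = 0.1,
                                 hold_displacement = 0.5))
  sch <- behavior_schedule(c("pilus_cycle", "brownian"), c(9, 3))
  sim <- simulate_trapped_bead(cfg, sch, noise = FALSE)
  r <- sqrt(sim$trajectory$x^2 + sim$trajectory$y^2)
  t <- sim$trajectory$t
  # the tether anchor is placed so the trap+tether equilibrium tracks the
  # prescribed path: the bead itself moves at the planted retraction speed
  ramp <- t >= 1 & t <= 4 # interior of the 5 s ramp to 0.5 um
  fit <- coef(lm(r[ramp] ~ t[ramp]))
  expect_equal(unname(fit[2]), 0.1, tolerance = 0.02)
  hold <- t >= 6 & t < 9
  expect_equal(mean(r[hold]), 0.5, tolerance = 0.01)
  expect_lt(diff(range(r[hold])), 1e-3)
  # release decays with the trap relaxation time gamma/kappa
  tau <- cfg$bead$drag / 1
  rel <- which(t >= 9 + 1 / cfg$frame_rate & t <= 9 + 5 * tau)
  pred <- mean(r[hold]) * exp(-(t[rel] - 9) / tau)
  expect_equal(r[rel], pred, tolerance = 0.05)
  # release speed exceeds retraction by at least the planted factor
  release_speed <- max(-diff(r[t >= 9 - 0.2]) * cfg$frame_rate)
  expect_gte(release_speed / 0.1, cfg$pilus$release_speed_factor)
})

test_that("unphysical pilus configurations are rejected or flagged", {
  cfg <- sim_config(trap = default_trap(1), frame_rate = 100, seed = 1,
                    driving = list(trans_force = 0.001),
                    pilus = list(hold_displacement = 0.8))
  expect_error(simulate_trapped_bead(cfg, behavior_schedule("pilus_cycle", 5)),
               "unphysical")
  cfg2 <- sim_config(trap = default_trap(0.05), frame_rate = 100, seed = 1)
  expect_warning(simulate_trapped_bead(cfg2,
                                       behavior_schedule("pilus_cycle", 5)),
                 "release/retract")
  cfg3 <- trapped_config(seed = 1)
  expect_error(simulate_trapped_bead(cfg3, behavior_schedule("bending", 5)),
               "states")
})

test_that("free swimmer recovers planted dwell means and time fraction", {
  d <- paper_defaults()
  cfg <- sim_config(bead = bead_geometry(d$physical$assembly_radius_swimmer),
                    frame_rate = 20, seed = 21)
  sim <- cached("swimmer_500", simulate_free_swimmer(cfg, n_sequences = 500))
  ev <- sim$events
  dir <- vapply(ev$attributes, `[[`, character(1), "direction")
  dur <- ev$end - ev$start
  # exponential-mean recovery at n = 250 per direction
  expect_equal(mean(dur[dir == "push"]), d$swim$tau_push, tolerance = 0.1)
  expect_equal(mean(dur[dir == "pull"]), d$swim$tau_pull, tolerance = 0.1)
  # renewal-process time fraction tau_push / (tau_push + tau_pull) = 0.647
  frac <- sum(dur[dir == "push"]) / sum(dur)
  expect_equal(frac, 2.2 / 3.4, tolerance = 0.05)
  # strict alternation
  expect_true(all(dir[-1] != dir[-length(dir)]))
})

test_that("deterministic swimmer limit is a straight back-and-forth line", {
  cfg <- sim_config(bead = bead_geometry(1.5), frame_rate = 20, seed = 22,
                    swim = list(v_push = 10, v_push_sd = 1e-9,
                                v_pull = 10, v_pull_sd = 1e-9,
                                rotational_diffusion = 0))
  sim <- simulate_free_swimmer(cfg, n_sequences = 6, noise = FALSE)
  xy <- cbind(sim$trajectory$x, sim$trajectory$y)
  # all positions collinear with the initial heading
  sv <- svd(scale(xy, scale = FALSE))$d
  expect_lt(sv[2] / sv[1], 1e-6)
  expect_error(sim_config(swim = list(tau_push = -2)), "positive")
})

test_that("pole track generates exact quadrature with direction labels", {
  cfg <- sim_config(frame_rate = 200, seed = 31)
  sch <- behavior_schedule("long_axis_rotation", 2,
                           params = list(list(freq = 25, direction = "CCW")))
  sim <- simulate_pole_track(cfg, sch, noise = FALSE)
  # pure quadrature at 25 Hz: radius constant, phase rate 2 pi 25
  d <- paper_defaults()
  r <- sqrt(sim$trajectory$x^2 + sim$trajectory$y^2)
  expect_equal(mean(r), d$pole$amplitude, tolerance = 1e-6)
  th <- atan2(sim$trajectory$y, sim$trajectory$x)
  dth <- diff(th)
  dth <- (dth + pi) %% (2 * pi) - pi
  expect_equal(mean(dth) * 200 / (2 * pi), 25, tolerance = 1e-6)

  iv <- data.frame(freq = c(20, 30), direction = c("CCW", "CW"),
                   duration = c(1, 1))
  sim2 <- simulate_pole_track(cfg, behavior_schedule(
    "long_axis_rotation", 2, params = list(list(intervals = iv))))
  expect_equal(sim2$events$state, rep("long_axis_rotation", 2))
  expect_equal(vapply(sim2$events$attributes, `[[`, character(1),
                      "direction"), c("CCW", "CW"))
  # aliasing guard: 80 Hz needs at least 320 Hz sampling
  expect_error(simulate_pole_track(cfg, behavior_schedule(
    "long_axis_rotation", 1, params = list(list(freq = 80)))), "aliasing")
})

test_that("planted pole frequencies sample the population mean", {
  d <- paper_defaults()
  set.seed(45)
  f <- rtnorm_matched(50, d$pole$freq_ccw_mean, d$pole$freq_ccw_sd,
                      d$pole$freq_min, d$pole$freq_ccw_max)
  se <- sd(f) / sqrt(50)
  expect_lt(abs(mean(f) - d$pole$freq_ccw_mean), 2 * se + 1e-9)
})
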