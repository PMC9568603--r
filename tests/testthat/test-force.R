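test_that("trap force follows Hooke's law with radial/tangential identity", {
  trap <- trap_model(1, center = c(0, 0))
  # 3-4-5 triangle: displacement (0.3, 0.4) at unit stiffness -> 0.5 pN
  tr <- trajectory(c(0, 0.01, 0.02), rep(0.3, 3), rep(0.4, 3),
                   frame_rate = 100)
  fs <- displacement_force(tr, trap, sg_window = 0)
  expect_equal(sqrt(fs$fx^2 + fs$fy^2), rep(0.5, 3))
  # |F|^2 = radial^2 + tangential^2 frame by frame
  expect_equal(fs$fx^2 + fs$fy^2, fs$f_radial^2 + fs$f_tangential^2,
               tolerance = 1e-12)
  # bead at the exact center: zero force, flagged angular velocity 0
  tr0 <- trajectory(c(0, 0.01), c(0, 0), c(0, 0), frame_rate = 100)
  fs0 <- displacement_force(tr0, trap, sg_window = 0)
  expect_true(all(fs0$fx == 0 & fs0$fy == 0))
  expect_true(all(fs0$angular_velocity == 0))
  expect_equal(attr(fs0, "degenerate_frames"), 1:2)
})

test_that("noiseless circular orbits give pure radial trap force", {
  t <- seq(0, 4, by = 0.01)
  tr <- trajectory(t, 1.2 * cos(pi * t), 1.2 * sin(pi * t), frame_rate = 100)
  fs <- displacement_force(tr, trap_model(1))
  expect_equal(abs(fs$f_radial), rep(1.2, length(t)), tolerance = 1e-9)
  expect_lt(max(abs(fs$f_tangential)), 1e-9)
  # CCW orbit: positive angular velocity; CW: negative
  i <- 10:390
  expect_true(all(fs$angular_velocity[i] > 0))
  tr_cw <- trajectory(t, 1.2 * cos(pi * t), -1.2 * sin(pi * t),
                      frame_rate = 100)
  fs_cw <- displacement_force(tr_cw, trap_model(1))
  expect_true(all(fs_cw$angular_velocity[i] < 0))
})

test_that("drag balance reproduces the closed-form rotational force", {
  # orbit r = 0.3 um, period 2 s: F_rot = gamma * pi * 0.3 = 2.66e-2 pN
  bead <- bead_geometry(1.5)
  t <- seq(0, 10, by = 0.01)
  tr <- trajectory(t, 0.3 * cos(pi * t), 0.3 * sin(pi * t), frame_rate = 100)
  trap <- trap_model(1)
  fs <- displacement_force(tr, trap)
  ev <- event_table("gyration", 0, 10.01)
  sm <- summarize_forces(fs, bead, ev, trap)
  expect_equal(sm$F_rot, bead$drag * pi * 0.3, tolerance = 0.01)
  expect_equal(sm$F_rot, 2.664e-2, tolerance = 0.01)
})

test_that("a held bead returns exactly kappa times its displacement", {
  trap <- trap_model(1)
  bead <- bead_geometry(1.5)
  d_hold <- 0.8
  t <- seq(0, 5, by = 0.01)
  tr <- trajectory(t, rep(d_hold, length(t)), rep(0, length(t)),
                   frame_rate = 100)
  fs <- displacement_force(tr, trap)
  sm <- summarize_forces(fs, bead, event_table("brownian", 0, 5.01), trap)
  expect_equal(sm$F_trans_max, 1 * d_hold, tolerance = 1e-9)
  # empty gyration set: F_rot absent, not zero
  expect_null(sm$F_rot)
})

test_that("planted driving forces are recovered across a force/noise grid", {
  d <- paper_defaults()
  bead <- bead_geometry(d$physical$bead_radius_trapped)
  trap <- default_trap(1)
  for (freq in c(1, 2, 3)) {
    for (temp_scale in c(0.25, 1, 2)) {
      ff <- gyration_forces(freq, d$driving$orbit_radius, 1, bead$drag)
      trap_t <- trap_model(1, temperature = 303.15 * temp_scale)
      cfg <- sim_config(trap = trap_t, bead = bead, frame_rate = 100,
                        seed = 600 + round(10 * freq) + round(temp_scale * 4),
                        driving = list(gyration_freq = freq,
                                       rot_force = ff[["rot_force"]],
                                       trans_force = ff[["trans_force"]]))
      sim <- simulate_trapped_bead(cfg, behavior_schedule("gyration", 30))
      fs <- displacement_force(sim$trajectory, trap_t)
      sm <- summarize_forces(fs, bead, sim$events, trap_t)
      expect_equal(sm$F_rot, unname(ff[["rot_force"]]), tolerance = 0.15)
      expect_equal(sm$F_trans_max, unname(ff[["trans_force"]]),
                   tolerance = 0.12)
    }
  }
})

test_that("maximal translational force is monotone under concatenation", {
  trap <- trap_model(1)
  bead <- bead_geometry(1.5)
  t1 <- seq(0, 3, by = 0.01)
  a <- trajectory(t1, 0.3 * cos(2 * pi * t1), 0.3 * sin(2 * pi * t1),
                  frame_rate = 100)
  t2 <- seq(0, 6, by = 0.01)
  b <- trajectory(t2, c(a$x, 0.7 * cos(2 * pi * t1[-1]))[seq_along(t2)],
                  c(a$y, 0.7 * sin(2 * pi * t1[-1]))[seq_along(t2)],
                  frame_rate = 100)
  ev <- function(T) event_table("gyration", 0, T)
  f_a <- summarize_forces(displacement_force(a, trap), bead, ev(3.01), trap)
  f_b <- summarize_forces(displacement_force(b, trap), bead, ev(6.01), trap)
  expect_gte(f_b$F_trans_max, f_a$F_trans_max)
})
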