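make_line_traj <- function(v, total = 10, fr = 20, heading = 0) {
  t <- seq(0, total, by = 1 / fr)
  tr <- trajectory(t, v * t * cos(heading), v * t * sin(heading),
                   frame_rate = fr)
  attr(tr, "heading") <- rep(heading, length(t))
  tr
}

test_that("constant velocity along the axis is one forward sequence", {
  tr <- make_line_traj(8)
  seqs <- classify_swim_sequences(tr)
  expect_equal(nrow(seqs), 1)
  expect_equal(seqs$direction, "push")
  expect_equal(seqs$mean_speed, 8, tolerance = 1e-6)
})

test_that("frames below the speed floor are excluded from sequences", {
  fr <- 20
  t <- seq(0, 12, by = 1 / fr)
  v <- ifelse(t %% 4 < 1.5, 10, ifelse(t %% 4 < 2, 0, -10))
  x <- cumsum(v / fr)
  tr <- trajectory(t, x, rep(0, length(t)), frame_rate = fr)
  attr(tr, "heading") <- rep(0, length(t))
  seqs <- classify_swim_sequences(tr)
  expect_true(all(seqs$direction %in% c("push", "pull")))
  expect_true(all(seqs$mean_speed > 5))
  # the zero-speed gaps do not belong to any sequence
  expect_lt(sum(seqs$duration), 12)
  expect_true(any(seqs$direction == "pull"))
})

test_that("swim statistics reproduce the mean-duration arithmetic", {
  seqs <- data.frame(direction = c("push", "push", "pull", "pull"),
                     start = c(0, 4, 2, 8), end = c(2, 6.4, 3, 9.4),
                     duration = c(2, 2.4, 1.0, 1.4),
                     mean_speed = c(12, 13, 17, 18))
  class(seqs) <- c("swim_sequences", "data.frame")
  st <- swim_statistics(seqs)
  expect_equal(st$push$duration_mean, 2.2)
  expect_equal(st$pull$duration_mean, 1.2)
  expect_equal(unname(st$count_fraction[["push"]]), 0.5)
  # single pull sequence: push stats absent, not zero
  one <- seqs[3, , drop = FALSE]
  class(one) <- c("swim_sequences", "data.frame")
  st1 <- swim_statistics(one)
  expect_null(st1$push)
  expect_equal(st1$pull$n, 1)
})

test_that("planted renewal time fraction is recovered end to end", {
  d <- paper_defaults()
  cfg <- sim_config(bead = bead_geometry(d$physical$assembly_radius_swimmer),
                    frame_rate = 20, seed = 81)
  sim <- simulate_free_swimmer(cfg, n_sequences = 400)
  seqs <- classify_swim_sequences(sim$trajectory)
  st <- swim_statistics(seqs)
  expect_equal(unname(st$time_fraction[["push"]]), 2.2 / 3.4,
               tolerance = 0.08)
})

test_that("push/pull labels survive a global rotation of coordinates", {
  d <- paper_defaults()
  cfg <- sim_config(bead = bead_geometry(d$physical$assembly_radius_swimmer),
                    frame_rate = 20, seed = 82)
  sim <- simulate_free_swimmer(cfg, n_sequences = 40)
  tr <- sim$trajectory
  seqs <- classify_swim_sequences(tr, axis = "estimate")
  phi <- 1.1
  rot <- trajectory(tr$t, cos(phi) * tr$x - sin(phi) * tr$y,
                    sin(phi) * tr$x + cos(phi) * tr$y,
                    frame_rate = frame_rate(tr))
  seqs_rot <- classify_swim_sequences(rot, axis = "estimate")
  expect_equal(nrow(seqs_rot), nrow(seqs))
  expect_equal(seqs_rot$duration, seqs$duration, tolerance = 1e-6)
  # labels agree up to at most a single global flip
  agree <- mean(seqs_rot$direction == seqs$direction)
  expect_true(agree == 1 || agree == 0)
})

test_that("rotation direction is exact on noiseless quadrature signals", {
  fr <- 250
  t <- seq(0, 2, by = 1 / fr)
  for (f in c(2, 5, 10, 20, 30, 45, 55)) {
    ccw <- trajectory(t, 0.4 * cos(2 * pi * f * t),
                      0.4 * sin(2 * pi * f * t), frame_rate = fr, pole = TRUE)
    est <- rotation_frequency(ccw)
    expect_true(all(est$direction == "CCW"))
    expect_equal(est$frequency[1], f, tolerance = 0.02)
    cw <- trajectory(t, 0.4 * cos(2 * pi * f * t),
                     -0.4 * sin(2 * pi * f * t), frame_rate = fr, pole = TRUE)
    est_cw <- rotation_frequency(cw)
    expect_true(all(est_cw$direction == "CW"))
  }
})

test_that("frequency bias stays below 0.5 Hz at SNR >= 5", {
  fr <- 200
  t <- seq(0, 2, by = 1 / fr)
  set.seed(91)
  errs <- unlist(lapply(seq(5, 50, by = 5), function(f) {
    vapply(1:4, function(i) {
      x <- 0.4 * cos(2 * pi * f * t) + rnorm(length(t), 0, 0.08)
      y <- 0.4 * sin(2 * pi * f * t) + rnorm(length(t), 0, 0.08)
      est <- rotation_frequency(trajectory(t, x, y, frame_rate = fr,
                                           pole = TRUE))
      est$frequency[which.max(est$end - est$start)] - f
    }, numeric(1))
  }))
  expect_lt(abs(mean(errs)), 0.5)
  expect_lt(max(abs(errs)), 1)
})

test_that("direction switching yields separate labeled intervals", {
  cfg <- sim_config(frame_rate = 250, seed = 92)
  iv <- data.frame(freq = c(22, 35), direction = c("CCW", "CW"),
                   duration = c(2, 2))
  sim <- simulate_pole_track(cfg, behavior_schedule(
    "long_axis_rotation", 4, params = list(list(intervals = iv))))
  est <- rotation_frequency(sim$trajectory)
  expect_setequal(unique(est$direction), c("CCW", "CW"))
  f_ccw <- est$frequency[est$direction == "CCW"][1]
  f_cw <- est$frequency[est$direction == "CW"][1]
  expect_equal(f_ccw, 22, tolerance = 0.05)
  expect_equal(f_cw, 35, tolerance = 0.05)
})

test_that("bending metrics report amplitude, duration, or absence", {
  fr <- 100
  t <- seq(0, 130, by = 1 / fr)
  x <- ifelse(t < 5, 0, ifelse(t < 125, 2 * sin(2 * pi * 0.3 * (t - 5)), 0))
  pole <- trajectory(t, x, rep(0, length(t)), frame_rate = fr, pole = TRUE)
  ev <- event_table(c("bending", "long_axis_rotation"), c(5, 125),
                    c(125, 130.01))
  bm <- bending_metrics(pole, ev)
  expect_equal(bm$amplitude, 2, tolerance = 1e-3)
  expect_equal(bm$duration, 120)
  # flat track, no bending interval: absent result
  flat <- trajectory(t, rep(0, length(t)), rep(0, length(t)),
                     frame_rate = fr, pole = TRUE)
  expect_null(bending_metrics(flat, event_table("released", 0, 130.01)))
})

test_that("simulated bending stage round-trips through the metrics", {
  d <- paper_defaults()
  cfg <- sim_config(frame_rate = 100, seed = 93)
  # pre-onset rotation supplies the baseline the bend is measured from
  sch <- behavior_schedule(
    c("long_axis_rotation", "bending", "long_axis_rotation"), c(2, 120, 5),
    params = list(list(freq = 15), NULL, list(freq = 20)))
  sim <- simulate_pole_track(cfg, sch, noise = FALSE)
  bm <- bending_metrics(sim$trajectory, sim$events)
  expect_equal(bm$duration, 120, tolerance = 0.01)
  expect_equal(bm$amplitude, d$pole$bend_amplitude, tolerance = 0.02)
})
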