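#' Parameter-recovery experiments
#'
#' Each experiment plants the assay's reported values through the synthetic
#' generator, runs the inference pipeline on the simulated data and returns
#' recovered estimates next to the planted per-run sample values and the
#' fixture parameters — the package's verification currency: the analysis is
#' correct when it recovers what was planted.
#'
#' @name experiments
NULL

#' Free-swimmer speed and dwell-time recovery
#'
#' Simulates a run-reverse swimmer with the fixture's speed and dwell
#' parameters, classifies push/pull sequences on the ground-truth body axis
#' and summarizes them.
#'
#' @param n_sequences Number of swim sequences.
#' @param seed Master seed.
#' @return A list with `stats` ([swim_statistics()] output), `planted`
#'   (per-run sample means of the planted speeds and dwell times per
#'   direction) and `fixture` (the swim parameter block).
#' @export
experiment_swim <- function(n_sequences = 200, seed = 1) {
  d <- paper_defaults()
  cfg <- sim_config(
    trap = trap_model(d$physical$kappa_trap,
                      temperature = d$physical$temperature),
    bead = bead_geometry(d$physical$assembly_radius_swimmer,
                         d$physical$viscosity, d$physical$temperature),
    frame_rate = d$physical$frame_rate_swimmer,
    seed = derive_seed(seed, 1L)
  )
  sim <- simulate_free_swimmer(cfg, n_sequences = n_sequences)
  seqs <- classify_swim_sequences(sim$trajectory, axis = "ground_truth")
  stats <- swim_statistics(seqs)

  ev <- sim$events
  planted_dir <- vapply(ev$attributes, `[[`, character(1), "direction")
  planted_speed <- vapply(ev$attributes, `[[`, numeric(1), "speed")
  planted_dur <- ev$end - ev$start
  planted <- list(
    v_push = mean(planted_speed[planted_dir == "push"]),
    v_pull = mean(planted_speed[planted_dir == "pull"]),
    tau_push = mean(planted_dur[planted_dir == "push"]),
    tau_pull = mean(planted_dur[planted_dir == "pull"])
  )
  list(stats = stats, planted = planted, fixture = cfg$swim,
       n_sequences = nrow(ev))
}

# Draw the alternating rotation-gap / pilus-cycle schedule for one track.
pilus_schedule <- function(n_cycles, pil, flagellum) {
  if (flagellum) {
    gaps <- rtnorm_matched(n_cycles + 1L, pil$intercycle_mean,
                           pil$intercycle_sd, lower = pil$intercycle_min)
    cyc <- rtnorm_matched(n_cycles, pil$cycle_duration_mean,
                          pil$cycle_duration_sd,
                          lower = pil$cycle_duration_min)
    gap_state <- "gyration"
  } else {
    gaps <- rtnorm_matched(n_cycles + 1L, pil$intercycle_mean_noflag,
                           pil$intercycle_sd_noflag,
                           lower = pil$intercycle_min)
    cyc <- rtnorm_matched(n_cycles, pil$cycle_duration_mean_noflag,
                          pil$cycle_duration_sd_noflag,
                          lower = pil$cycle_duration_min)
    gap_state <- "brownian"
  }
  states <- character(2 * n_cycles + 1L)
  durs <- numeric(2 * n_cycles + 1L)
  states[seq(1, 2 * n_cycles + 1, by = 2)] <- gap_state
  durs[seq(1, 2 * n_cycles + 1, by = 2)] <- gaps
  states[seq(2, 2 * n_cycles, by = 2)] <- "pilus_cycle"
  durs[seq(2, 2 * n_cycles, by = 2)] <- cyc
  list(schedule = behavior_schedule(states, durs),
       cycles = cyc, gaps = gaps[2:n_cycles])
}

#' Pilus attachment-cycle recovery
#'
#' Simulates trapped-bead tracks with interleaved rotation-gap and
#' pilus-cycle states (or Brownian gaps in flagellum-disabled mode),
#' segments them and extracts pilus cycles.
#'
#' @param n_tracks Number of tracks.
#' @param cycles_per_track Planted pilus cycles per track.
#' @param seed Master seed.
#' @param flagellum `FALSE` disables gyration (the hook-deletion control:
#'   cells without the outer flagellum; gaps between cycles are Brownian and
#'   the no-flagellum cycle statistics are planted).
#' @return A list with recovered and planted cycle / inter-cycle means,
#'   pooled frame-level segmentation accuracy, recovered gyration time and
#'   counts.
#' @export
experiment_pilus <- function(n_tracks = 20, cycles_per_track = 5, seed = 1,
                             flagellum = TRUE) {
  d <- paper_defaults()
  trap <- trap_model(d$physical$kappa_trap,
                     temperature = d$physical$temperature)
  planted_cyc <- numeric(0)
  planted_gap <- numeric(0)
  rec_cyc <- numeric(0)
  rec_gap <- numeric(0)
  acc_num <- 0
  acc_den <- 0
  gyration_time <- 0
  for (k in seq_len(n_tracks)) {
    cfg <- sim_config(trap = trap, frame_rate = d$physical$frame_rate_trapped,
                      seed = derive_seed(seed, 100L + k))
    set.seed(derive_seed(seed, 500L + k))
    sch <- pilus_schedule(cycles_per_track, cfg$pilus, flagellum)
    sim <- simulate_trapped_bead(cfg, sch$schedule)
    fs <- compute_features(sim$trajectory, center = trap$center)
    ev <- classify_states(fs, trap)
    cycles <- extract_pilus_cycles(ev, sim$trajectory)
    ss <- summarize_events(ev, cycles)

    planted_cyc <- c(planted_cyc, sch$cycles)
    planted_gap <- c(planted_gap, sch$gaps)
    rec_cyc <- c(rec_cyc, cycles$duration[cycles$complete])
    pidx <- which(ev$state == "pilus_attached")
    if (length(pidx) > 1) {
      rec_gap <- c(rec_gap,
                   ev$start[pidx[-1]] - ev$end[pidx[-length(pidx)]])
    }
    truth <- state_at(sim$events, sim$trajectory$t)
    truth[truth == "pilus_cycle"] <- "pilus_attached"
    inferred <- state_at(ev, sim$trajectory$t, default = "brownian")
    acc_num <- acc_num + sum(truth == inferred)
    acc_den <- acc_den + length(truth)
    gyration_time <- gyration_time + sum(
      (ev$end - ev$start)[ev$state %in% c("gyration", "long_axis_rotation")])
  }
  list(
    recovered_cycle_mean = mean(rec_cyc),
    planted_cycle_mean = mean(planted_cyc),
    recovered_intercycle_mean = mean(rec_gap),
    planted_intercycle_mean = mean(planted_gap),
    n_cycles = length(rec_cyc), n_gaps = length(rec_gap),
    accuracy = acc_num / acc_den,
    gyration_time = gyration_time,
    flagellum = flagellum
  )
}

#' Flagellar-activity and rotation-stage duration recovery
#'
#' Simulates trapped-bead tracks through the full separation sequence
#' (Brownian lead-in, gyration, long-axis rotation, terminal Brownian),
#' planting the fixture's activity and rotation-stage duration distributions,
#' and recovers both stages from segmentation (onset = start of the first
#' rotation interval; separation = transition into the terminal Brownian
#' interval).
#'
#' @param n_tracks Number of tracks.
#' @param seed Master seed.
#' @return A list with recovered and planted mean activity and
#'   rotation-stage durations and per-track values.
#' @export
experiment_stages <- function(n_tracks = 30, seed = 1) {
  d <- paper_defaults()
  trap <- trap_model(d$physical$kappa_trap,
                     temperature = d$physical$temperature)
  st <- d$stages
  rec_act <- numeric(0)
  rec_rot <- numeric(0)
  pl_act <- numeric(0)
  pl_rot <- numeric(0)
  for (k in seq_len(n_tracks)) {
    cfg <- sim_config(trap = trap, frame_rate = d$physical$frame_rate_trapped,
                      seed = derive_seed(seed, 2000L + k))
    set.seed(derive_seed(seed, 2500L + k))
    a <- rtnorm_matched(1, st$activity_mean, st$activity_sd,
                        st$activity_range[1], st$activity_range[2])
    r <- rtnorm_matched(1, st$rotation_stage_mean, st$rotation_stage_sd,
                        st$rotation_stage_range[1], st$rotation_stage_range[2])
    sch <- behavior_schedule(
      c("brownian", "gyration", "long_axis_rotation", "brownian"),
      c(5, a - r, r, 10))
    sim <- simulate_trapped_bead(cfg, sch)
    fs <- compute_features(sim$trajectory, center = trap$center)
    ev <- classify_states(fs, trap)
    ss <- summarize_events(ev)
    if (!is.null(ss$activity_duration)) {
      rec_act <- c(rec_act, ss$activity_duration)
      pl_act <- c(pl_act, a)
    }
    if (!is.null(ss$rotation_stage_duration)) {
      rec_rot <- c(rec_rot, ss$rotation_stage_duration)
      pl_rot <- c(pl_rot, r)
    }
  }
  list(recovered_activity_mean = mean(rec_act),
       planted_activity_mean = mean(pl_act),
       recovered_rotation_mean = mean(rec_rot),
       planted_rotation_mean = mean(pl_rot),
       n_activity = length(rec_act), n_rotation = length(rec_rot))
}

#' Pole rotation-frequency recovery
#'
#' Simulates flagellated-pole tracks of surface-attached predivisional cells,
#' one CCW and one CW rotation interval per cell with frequencies drawn from
#' the fixture distributions, and recovers the pooled direction-wise mean
#' frequencies with [rotation_frequency()].
#'
#' @param n_cells Number of cells.
#' @param seed Master seed.
#' @param interval_duration Duration of each rotation interval (s).
#' @return A list with recovered and planted CCW / CW mean frequencies and
#'   the per-cell values.
#' @export
experiment_pole <- function(n_cells = 50, seed = 1, interval_duration = 2) {
  d <- paper_defaults()
  po <- d$pole
  set.seed(derive_seed(seed, 3000L))
  f_ccw <- rtnorm_matched(n_cells, po$freq_ccw_mean, po$freq_ccw_sd,
                          po$freq_min, po$freq_ccw_max)
  f_cw <- rtnorm_matched(n_cells, po$freq_cw_mean, po$freq_cw_sd,
                         po$freq_min, po$freq_cw_max)
  rec_ccw <- rep(NA_real_, n_cells)
  rec_cw <- rep(NA_real_, n_cells)
  for (k in seq_len(n_cells)) {
    cfg <- sim_config(frame_rate = d$physical$frame_rate_pole,
                      seed = derive_seed(seed, 3000L + k))
    iv <- data.frame(freq = c(f_ccw[k], f_cw[k]),
                     direction = c("CCW", "CW"),
                     duration = rep(interval_duration, 2))
    sch <- behavior_schedule("long_axis_rotation", 2 * interval_duration,
                             params = list(list(intervals = iv)))
    sim <- simulate_pole_track(cfg, sch)
    est <- rotation_frequency(sim$trajectory)
    for (dd in c("CCW", "CW")) {
      sub <- est[est$direction == dd, , drop = FALSE]
      if (nrow(sub)) {
        # weight by interval length; splits of one planted interval average out
        wmean <- sum(sub$frequency * (sub$end - sub$start)) /
          sum(sub$end - sub$start)
        if (dd == "CCW") rec_ccw[k] <- wmean else rec_cw[k] <- wmean
      }
    }
  }
  list(recovered_ccw_mean = mean(rec_ccw, na.rm = TRUE),
       planted_ccw_mean = mean(f_ccw),
       recovered_cw_mean = mean(rec_cw, na.rm = TRUE),
       planted_cw_mean = mean(f_cw),
       n_ccw = sum(!is.na(rec_ccw)), n_cw = sum(!is.na(rec_cw)),
       planted_ccw = f_ccw, planted_cw = f_cw)
}

#' Trap-stiffness calibration recovery
#'
#' Simulates a Brownian-only trapped bead and calibrates it with both the
#' equipartition and the power-spectral-density estimators.
#'
#' @param kappa Planted stiffness (pN/um; recycled to both axes).
#' @param n_frames Frames to simulate.
#' @param frame_rate Sampling rate (Hz).
#' @param seed Master seed.
#' @return A list with the planted `kappa`, both `calibration_result`s and
#'   the closed-form references.
#' @export
experiment_calibration <- function(kappa = 0.05, n_frames = 1e5,
                                   frame_rate = 25, seed = 1) {
  d <- paper_defaults()
  trap <- trap_model(kappa, temperature = d$physical$temperature)
  bead <- bead_geometry(d$physical$bead_radius_trapped,
                        d$physical$viscosity, d$physical$temperature)
  cfg <- sim_config(trap = trap, bead = bead, frame_rate = frame_rate,
                    seed = derive_seed(seed, 4000L))
  sch <- behavior_schedule("brownian", n_frames / frame_rate)
  sim <- simulate_trapped_bead(cfg, sch)
  eq <- stiffness_equipartition(sim$trajectory, trap$temperature,
                                n_boot = 500)
  psd <- stiffness_psd(sim$trajectory, trap$temperature, bead$drag)
  list(kappa = kappa, equipartition = eq, psd = psd,
       reference = thermal_reference(trap, bead))
}

#' Run the full recovery pipeline
#'
#' Orchestrates all recovery experiments at their acceptance-grade sizes,
#' writes the outputs (summary JSON, recovery table CSV, one example
#' trajectory and event table per scenario) into `out_dir`, and returns the
#' recovery table: planted vs recovered vs reported reference value for every
#' headline quantity. Fully deterministic under a fixed master seed.
#'
#' @param seed Master seed.
#' @param out_dir Output directory (created if missing); `NULL` writes
#'   nothing.
#' @param flagellum `FALSE` runs the flagellum-disabled ablation: rows that
#'   require a flagellum are reported absent (`NA`).
#' @param sizes Named list overriding experiment sizes (`swim_sequences`,
#'   `swim_dwell_sequences`, `pilus_tracks`, `stage_tracks`, `pole_cells`).
#' @return Invisibly, a list with `table` (data frame: quantity, units,
#'   planted, recovered, reference, n) and the raw experiment results.
#' @export
run_pipeline <- function(seed = 1, out_dir = NULL, flagellum = TRUE,
                         sizes = list()) {
  sz <- utils::modifyList(
    list(swim_sequences = 400, swim_dwell_sequences = 1000,
         pilus_tracks = 20, pilus_cycles_per_track = 5,
         stage_tracks = 30, pole_cells = 50),
    sizes)
  d <- paper_defaults()

  sw_speed <- experiment_swim(sz$swim_sequences, seed = derive_seed(seed, 11L))
  sw_dwell <- experiment_swim(sz$swim_dwell_sequences,
                              seed = derive_seed(seed, 12L))
  pil <- experiment_pilus(sz$pilus_tracks, sz$pilus_cycles_per_track,
                          seed = derive_seed(seed, 13L), flagellum = flagellum)
  pil_nf <- experiment_pilus(sz$pilus_tracks, sz$pilus_cycles_per_track,
                             seed = derive_seed(seed, 14L), flagellum = FALSE)
  stages <- if (flagellum) {
    experiment_stages(sz$stage_tracks, seed = derive_seed(seed, 15L))
  } else {
    NULL
  }
  pole <- if (flagellum) {
    experiment_pole(sz$pole_cells, seed = derive_seed(seed, 16L))
  } else {
    NULL
  }

  row <- function(q, units, planted, recovered, reference, n) {
    data.frame(quantity = q, units = units,
               planted = if (is.null(planted)) NA_real_ else planted,
               recovered = if (is.null(recovered)) NA_real_ else recovered,
               reference = reference,
               n = if (is.null(n)) NA_integer_ else n)
  }
  tab <- rbind(
    row("swim_speed_pull", "um/s", sw_speed$planted$v_pull,
        sw_speed$stats$pull$speed_mean, d$swim$v_pull,
        sw_speed$stats$pull$n),
    row("swim_speed_push", "um/s", sw_speed$planted$v_push,
        sw_speed$stats$push$speed_mean, d$swim$v_push,
        sw_speed$stats$push$n),
    row("swim_duration_push", "s", sw_dwell$planted$tau_push,
        sw_dwell$stats$push$duration_mean, d$swim$tau_push,
        sw_dwell$stats$push$n),
    row("swim_duration_pull", "s", sw_dwell$planted$tau_pull,
        sw_dwell$stats$pull$duration_mean, d$swim$tau_pull,
        sw_dwell$stats$pull$n),
    if (flagellum) {
      row("pilus_cycle_duration", "s", pil$planted_cycle_mean,
          pil$recovered_cycle_mean, d$pilus$cycle_duration_mean,
          pil$n_cycles)
    } else {
      row("pilus_cycle_duration", "s", NA_real_, NA_real_,
          d$pilus$cycle_duration_mean, NA_integer_)
    },
    if (flagellum) {
      row("intercycle_period", "s", pil$planted_intercycle_mean,
          pil$recovered_intercycle_mean, d$pilus$intercycle_mean,
          pil$n_gaps)
    } else {
      row("intercycle_period", "s", NA_real_, NA_real_,
          d$pilus$intercycle_mean, NA_integer_)
    },
    row("pilus_cycle_duration_noflag", "s", pil_nf$planted_cycle_mean,
        pil_nf$recovered_cycle_mean, d$pilus$cycle_duration_mean_noflag,
        pil_nf$n_cycles),
    row("pole_freq_ccw", "Hz",
        if (flagellum) pole$planted_ccw_mean else NULL,
        if (flagellum) pole$recovered_ccw_mean else NULL,
        d$pole$freq_ccw_mean, if (flagellum) pole$n_ccw else NULL),
    row("pole_freq_cw", "Hz",
        if (flagellum) pole$planted_cw_mean else NULL,
        if (flagellum) pole$recovered_cw_mean else NULL,
        d$pole$freq_cw_mean, if (flagellum) pole$n_cw else NULL),
    row("activity_duration", "s",
        if (flagellum) stages$planted_activity_mean else NULL,
        if (flagellum) stages$recovered_activity_mean else NULL,
        d$stages$activity_mean, if (flagellum) stages$n_activity else NULL),
    row("rotation_stage_duration", "s",
        if (flagellum) stages$planted_rotation_mean else NULL,
        if (flagellum) stages$recovered_rotation_mean else NULL,
        d$stages$rotation_stage_mean,
        if (flagellum) stages$n_rotation else NULL)
  )

  results <- list(table = tab, swim_speed = sw_speed, swim_dwell = sw_dwell,
                  pilus = pil, pilus_noflag = pil_nf, stages = stages,
                  pole = pole, seed = seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(out_dir, "recovery_table.csv"),
                     row.names = FALSE)
    summary_list <- list(
      seed = seed, flagellum = flagellum,
      recovered = stats::setNames(as.list(tab$recovered), tab$quantity),
      planted = stats::setNames(as.list(tab$planted), tab$quantity),
      reference = stats::setNames(as.list(tab$reference), tab$quantity)
    )
    jsonlite::write_json(summary_list, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    # one example track per scenario, for inspection
    ex_cfg <- sim_config(frame_rate = d$physical$frame_rate_trapped,
                         seed = derive_seed(seed, 99L))
    set.seed(derive_seed(seed, 98L))
    ex <- simulate_trapped_bead(ex_cfg,
                                pilus_schedule(2, ex_cfg$pilus,
                                               flagellum)$schedule)
    write_trajectory(ex$trajectory,
                     file.path(out_dir, "example_trapped_trajectory.csv"))
    write_event_table(ex$events,
                      file.path(out_dir, "example_trapped_events.csv"))
  }
  invisible(results)
}
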