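{
  "comment": "Headline assay parameters: reported summary values of the bacteria-on-a-bead experiments plus declared physical defaults for quantities the study never printed. Units: um, s, pN, pN/um, Hz, K.",
  "physical": {
    "temperature": 303.15,
    "viscosity": 0.001,
    "kappa_trap": 1.0,
    "bead_radius_trapped": 1.5,
    "bead_radius_swimmer": 0.5,
    "assembly_radius_swimmer": 1.5,
    "frame_rate_trapped": 100,
    "frame_rate_swimmer": 20,
    "frame_rate_pole": 250
  },
  "driving": {
    "gyration_freq": 2.0,
    "orbit_radius": 0.5,
    "gyration_direction": "CCW",
    "slow_rotation_factor": 0.5
  },
  "pilus": {
    "retract_speed": 0.15,
    "release_speed_factor": 10,
    "hold_displacement": 0.8,
    "tether_stiffness": 20,
    "anchor_jitter_deg": 45,
    "cycle_duration_mean": 12.9,
    "cycle_duration_sd": 11.4,
    "cycle_duration_min": 2.0,
    "cycle_duration_mean_noflag": 19.9,
    "cycle_duration_sd_noflag": 16.8,
    "intercycle_mean": 10.5,
    "intercycle_sd": 5.1,
    "intercycle_mean_noflag": 23.4,
    "intercycle_sd_noflag": 22.0,
    "intercycle_min": 0.5
  },
  "swim": {
    "v_push": 12.8,
    "v_push_sd": 6.1,
    "v_pull": 17.7,
    "v_pull_sd": 6.5,
    "speed_min": 2.5,
    "tau_push": 2.2,
    "tau_pull": 1.2,
    "refractory": 0.25,
    "rotational_diffusion": 0.05,
    "push_count_fraction": 0.667
  },
  "pole": {
    "freq_ccw_mean": 20.4,
    "freq_ccw_sd": 15.0,
    "freq_cw_mean": 29.9,
    "freq_cw_sd": 25.6,
    "freq_min": 1.0,
    "amplitude": 0.4,
    "snr": 10,
    "bend_amplitude": 2.0,
    "bend_freq": 0.3,
    "bending_mean": 120,
    "bending_sd": 60,
    "bending_range": [10, 420],
    "dwell_cw": 1.1,
    "dwell_ccw": 0.8
  },
  "stages": {
    "activity_mean": 99.8,
    "activity_sd": 57.3,
    "activity_range": [40, 180],
    "rotation_stage_mean": 10.3,
    "rotation_stage_sd": 7.6,
    "rotation_stage_range": [2, 17]
  },
  "partition": {
    "pili_time_mean": 100.6,
    "pili_time_sd": 60.8,
    "flagellum_time_mean": 230.9,
    "flagellum_time_sd": 207.4
  }
}
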