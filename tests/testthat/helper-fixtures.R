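# Shared fixtures and lazily cached expensive runs (computed once per suite).

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

default_trap <- function(kappa = 1) {
  d <- paper_defaults()
  trap_model(kappa, temperature = d$physical$temperature)
}

trapped_config <- function(seed, kappa = 1, frame_rate = 100) {
  d <- paper_defaults()
  sim_config(trap = default_trap(kappa),
             bead = bead_geometry(d$physical$bead_radius_trapped,
                                  d$physical$viscosity,
                                  d$physical$temperature),
             frame_rate = frame_rate, seed = seed)
}

# frame-level accuracy of inferred vs ground-truth events
frame_accuracy <- function(truth_events, inferred_events, times) {
  truth <- state_at(truth_events, times)
  truth[truth == "pilus_cycle"] <- "pilus_attached"
  inferred <- state_at(inferred_events, times, default = "brownian")
  mean(truth == inferred)
}
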