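# Shared fixtures: finite-difference oracle, default specs, small worlds.

fd_gradient <- function(spec, w, u, h = 1e-6) {
  vapply(seq_along(w), function(i) {
    wp <- w; wm <- w
    wp[i] <- wp[i] + h
    wm[i] <- wm[i] - h
    (evaluate_value(spec, wp, u) - evaluate_value(spec, wm, u)) / (2 * h)
  }, numeric(1))
}

all_kinds <- c("linear", "output_saturation", "component_saturation",
               "gaussian_complexity")

# Noise-free world with a fixed stimulus and constant motivation, for
# deterministic recursion checks.
deterministic_world <- function() {
  rms <- lapply(all_kinds, reward_model)
  names(rms) <- all_kinds
  rms$linear$noise_sd <- 0
  world_spec(stimulus = stimulus_spec(sd = 0),
             motivation = motivation_spec("constant"),
             reward_models = rms)
}

# Small configuration for fast engine tests.
desk_config <- function(n = 2e4, tail = 5e3, thin = 5L)
  engine_config(n_iterations = n, tail_window = tail, thin = thin)
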