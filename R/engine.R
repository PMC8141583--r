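.kinds <- c("linear", "output_saturation", "component_saturation",
            "gaussian_complexity")

#' Build one of the 16 experimental conditions
#'
#' The experiment crosses four reward models with four value functions
#' and three update strategies, in four sets of four conditions each:
#'
#' \describe{
#'   \item{purely_linear (1--4)}{linear value function and linear
#'     gradient, whatever the reward model.}
#'   \item{mixed_linear (5--8)}{value function matched to the reward
#'     model, but the update still steps along the linear gradient (the
#'     stimulus vector).}
#'   \item{full_gradient (9--12)}{matched value function and its own
#'     analytic gradient.}
#'   \item{shortest_path (13--16)}{matched value function updated by the
#'     shortest-path (phi) rule.}
#' }
#'
#' Within each set the reward model cycles linear, output-saturation,
#' component-saturation, gaussian-complexity.  Conditions 1, 5 and 9 are
#' therefore identical specifications.
#'
#' @param id integer condition id, 1--16.
#' @return an object of class `condition_spec` with fields `id`,
#'   `set_name`, `reward_kind`, `value_kind`, `rule` and
#'   `gradient_source` (a value-function kind, or `NA` under the phi
#'   rule).
#' @export
#' @examples
#' build_condition(4)   # gaussian-complexity reward, linear value/gradient
#' build_condition(16)  # gaussian-complexity reward + value, phi rule
build_condition <- function(id) {
  if (length(id) != 1L || is.na(id) || id != as.integer(id) ||
      id < 1 || id > 16)
    stop("condition id must be an integer in 1..16", call. = FALSE)
  id <- as.integer(id)
  set <- (id - 1L) %/% 4L + 1L
  reward_kind <- .kinds[(id - 1L) %% 4L + 1L]
  set_name <- c("purely_linear", "mixed_linear", "full_gradient",
                "shortest_path")[set]
  value_kind <- if (set == 1L) "linear" else reward_kind
  rule <- if (set == 4L) "phi" else "gradient"
  gradient_source <- switch(set, "linear", "linear", value_kind, NA_character_)
  structure(list(id = id, set_name = set_name, reward_kind = reward_kind,
                 value_kind = value_kind, rule = rule,
                 gradient_source = gradient_source),
            class = "condition_spec")
}

#' @export
print.condition_spec <- function(x, ...) {
  cat(sprintf("<condition %d> %s: reward=%s value=%s rule=%s%s\n",
              x$id, x$set_name, x$reward_kind, x$value_kind, x$rule,
              if (!is.na(x$gradient_source))
                paste0(" grad=", x$gradient_source) else ""))
  invisible(x)
}

#' Engine configuration
#'
#' Defaults are the standard simulation parameters: start at
#' \eqn{w(t_0) = (0, 0)}, learning rates \eqn{\epsilon_\delta = 0.01}
#' (delta rule) and \eqn{\epsilon_\Phi = 0.007454} (phi rule; the delta
#' rate scaled by the root-mean-square stimulus magnitude so the two
#' rules take comparable step sizes), unit time step, 1,000,000
#' iterations and 10 repetitions per condition.  Trajectories store
#' every `thin`-th iteration plus the final `tail_window` iterations
#' unthinned (the statistics need the full tail).
#'
#' @param n_iterations iterations per run.
#' @param n_repetitions repetitions per condition in [run_experiment()].
#' @param eps_delta,eps_phi learning rates of the two rules (per unit
#'   time).
#' @param dt time step; the per-iteration rates are `eps * dt`.
#' @param w0 initial weights.
#' @param thin storage thinning factor outside the tail window.
#' @param tail_window number of final iterations always stored unthinned
#'   (capped at `n_iterations`).
#' @param grid [weight_grid()] for phi-rule isoline extraction.
#' @return an object of class `engine_config`.
#' @export
engine_config <- function(n_iterations = 1e6, n_repetitions = 10,
                          eps_delta = 0.01, eps_phi = 0.007454, dt = 1,
                          w0 = c(0, 0), thin = 10L, tail_window = 1e5,
                          grid = weight_grid()) {
  if (n_iterations < 1) stop("n_iterations must be >= 1", call. = FALSE)
  if (eps_delta < 0 || eps_phi < 0)
    stop("learning rates must be >= 0", call. = FALSE)
  tail_window <- min(tail_window, n_iterations)
  structure(list(n_iterations = as.integer(n_iterations),
                 n_repetitions = as.integer(n_repetitions),
                 eps_delta = eps_delta, eps_phi = eps_phi, dt = dt,
                 w0 = as.numeric(w0), thin = as.integer(thin),
                 tail_window = as.integer(tail_window), grid = grid),
            class = "engine_config")
}

#' World specification
#'
#' Bundles the stimulus sampler, the motivation gate and the four reward
#' models used by the engine.  Reward models default to the standard
#' parameter set (see [reward_model()]).
#'
#' @param stimulus a [stimulus_spec()].
#' @param motivation a [motivation_spec()].
#' @param reward_models named list of [reward_model()]s, one per kind.
#' @return an object of class `world_spec`.
#' @export
world_spec <- function(stimulus = stimulus_spec(),
                       motivation = motivation_spec(),
                       reward_models = NULL) {
  if (is.null(reward_models)) {
    reward_models <- lapply(.kinds, reward_model)
    names(reward_models) <- .kinds
  }
  structure(list(stimulus = stimulus, motivation = motivation,
                 reward_models = reward_models),
            class = "world_spec")
}

# Value function matched to a condition: the reward model's own spec
# (same constants) when the kinds agree, otherwise the default form.
.condition_value_spec <- function(cond, world) {
  rm <- world$reward_models[[cond$reward_kind]]
  if (cond$value_kind == rm$kind) rm$value_spec
  else value_function(cond$value_kind)
}

#' Run one seeded simulation
#'
#' Executes the simulation loop: at each iteration a stimulus is drawn,
#' a fully-motivated reward is sampled from the condition's reward
#' model, the mean motivation at the stimulus is computed, and the
#' weights are updated by the condition's rule.  The recorded learning
#' signal is \eqn{\delta(t) = \bar m(u)\,(r^*(t) - \mu(u : w(t-1)))}.
#' Fully deterministic given `seed`.
#'
#' @param cond a [build_condition()] result or a condition id.
#' @param cfg an [engine_config()].
#' @param world a [world_spec()].
#' @param seed integer seed for the run.
#' @return an object of class `aesval_trajectory`: a list with `data`
#'   (data frame of stored iterations: `t`, `w1`, `w2`, `delta`, `u_b`,
#'   `u_c`, `r_star`, `m_bar`), `condition`, `value_spec`, `seed`,
#'   `config`, `tail_start` and `phi_fallbacks`.
#' @export
run_simulation <- function(cond, cfg = engine_config(),
                           world = world_spec(), seed = 1L) {
  if (!inherits(cond, "condition_spec")) cond <- build_condition(cond)
  rm <- world$reward_models[[cond$reward_kind]]
  vs <- .condition_value_spec(cond, world)
  gs <- if (is.na(cond$gradient_source)) vs
        else if (cond$gradient_source == vs$kind) vs
        else value_function(cond$gradient_source)
  eps <- (if (cond$rule == "phi") cfg$eps_phi else cfg$eps_delta) * cfg$dt
  mot <- world$motivation
  set.seed(as.integer(seed))
  res <- run_sim_cpp(cfg$n_iterations, cfg$thin, cfg$tail_window,
                     .kind_code(rm$kind), rm$true_weights,
                     .kind_consts(rm$value_spec), rm$noise_sd,
                     .kind_code(vs$kind), .kind_consts(vs),
                     if (cond$rule == "phi") 1L else 0L,
                     .kind_code(gs$kind), .kind_consts(gs),
                     eps, cfg$w0,
                     world$stimulus$mean, world$stimulus$sd,
                     if (mot$form == "constant") 0L else 1L,
                     mot$floor, mot$center, mot$width,
                     cfg$grid$bounds, cfg$grid$res)
  structure(list(
    data = data.frame(t = res$t, w1 = res$w1, w2 = res$w2,
                      delta = res$delta, u_b = res$u_b, u_c = res$u_c,
                      r_star = res$r_star, m_bar = res$m_bar),
    condition = cond, value_spec = vs, seed = as.integer(seed),
    config = cfg, tail_start = res$tail_start,
    phi_fallbacks = res$phi_fallbacks),
    class = "aesval_trajectory")
}

#' @export
print.aesval_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> condition %d (%s), seed %d, %d iterations (%d stored)\n",
              x$condition$id, x$condition$set_name, x$seed,
              x$config$n_iterations, nrow(x$data)))
  if (x$phi_fallbacks > 0)
    cat("  phi fallbacks (clamped target level):", x$phi_fallbacks, "\n")
  invisible(x)
}

#' Run repeated simulations over several conditions
#'
#' Runs `cfg$n_repetitions` independent repetitions of each condition.
#' Repetition seeds are `base_seed + condition_id * 10^4 + repetition`,
#' so they are disjoint across conditions and repetitions.
#'
#' @param conditions vector of condition ids (or list of condition
#'   specs).
#' @param cfg an [engine_config()].
#' @param world a [world_spec()].
#' @param base_seed integer base seed.
#' @return a list with `trajectories` (list of [run_simulation()]
#'   results) and `manifest` (data frame: condition, repetition, seed,
#'   phi_fallbacks).
#' @export
run_experiment <- function(conditions = 1:16, cfg = engine_config(),
                           world = world_spec(), base_seed = 0L) {
  conds <- lapply(conditions, function(cn)
    if (inherits(cn, "condition_spec")) cn else build_condition(cn))
  trajectories <- list()
  manifest <- NULL
  for (cond in conds) {
    for (rep in seq_len(cfg$n_repetitions)) {
      seed <- as.integer(base_seed + cond$id * 1e4 + rep)
      tr <- run_simulation(cond, cfg, world, seed)
      trajectories[[length(trajectories) + 1L]] <- tr
      manifest <- rbind(manifest,
                        data.frame(condition = cond$id, repetition = rep,
                                   seed = seed,
                                   phi_fallbacks = tr$phi_fallbacks))
    }
  }
  list(trajectories = trajectories, manifest = manifest)
}
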