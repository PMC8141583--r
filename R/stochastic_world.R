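#' Stimulus sampling specification
#'
#' Stimuli are two-dimensional, \eqn{u = (u_b, u_c)} with visual balance
#' and visual complexity each in \eqn{[0, 1]}, concentrated around the
#' modal stimulus \eqn{(0.5, 0.5)}.  Each component is drawn
#' independently from a Gaussian truncated to \eqn{[0, 1]} by rejection.
#' The default spread of 1/6 keeps three standard deviations inside the
#' unit interval and yields a root-mean-square stimulus magnitude of
#' about 0.745, the quantity used to scale the shortest-path learning
#' rate.
#'
#' @param mean length-2 numeric, per-component means inside the bounds.
#' @param sd per-component standard deviation; `0` gives a degenerate
#'   sampler that always returns `mean` (useful for deterministic
#'   checks).
#' @return an object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(mean = c(0.5, 0.5), sd = 1 / 6) {
  if (length(mean) != 2L || any(mean < 0) || any(mean > 1))
    stop("mean must be a length-2 vector inside [0,1]^2", call. = FALSE)
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  structure(list(mean = as.numeric(mean), sd = sd, bounds = c(0, 1)),
            class = "stimulus_spec")
}

#' Reward-model specification
#'
#' The generating counterpart of a value function: rewards are Gaussian
#' around \eqn{\langle r^* \rangle(u) = \mu(u : w^{true})}, the matching
#' value function evaluated at the fixed true weights, with standard
#' deviation `noise_sd`.  By construction the optimal value function for
#' a reward model is the model's own mean, so
#' `mean_reward(rm, u) == evaluate_value(value function with true
#' weights, u)` holds exactly.
#'
#' Default constants and true weights follow the standard parameter set
#' of the simulated experiment:
#' linear \eqn{w = (0.6, 0.9)}; output-saturation \eqn{w = (1.2, 1.8)},
#' \eqn{\alpha = 10, \beta = 1.5}; component-saturation
#' \eqn{w = (1.2, 1.8)}, \eqn{\alpha = (10, 10), \beta = (0.6, 0.9)};
#' gaussian-complexity \eqn{w = (0.6, 1)}, centre 0.75, width 0.1.  All
#' use `noise_sd = 0.1414`.
#'
#' @param kind reward-model kind; same four kinds as [value_function()].
#' @param true_weights length-2 numeric vector of generating weights.
#' @param noise_sd reward noise standard deviation, \eqn{\ge 0}.
#' @param ... fixed constants passed to [value_function()] (`alpha`,
#'   `beta`, `center`, `width`).
#' @return an object of class `reward_model`, containing the matched
#'   `value_spec` in `$value_spec`.
#' @export
#' @examples
#' rm <- reward_model("linear")
#' mean_reward(rm, c(0.5, 0.5))  # 0.75
reward_model <- function(kind = c("linear", "output_saturation",
                                  "component_saturation",
                                  "gaussian_complexity"),
                         true_weights = NULL, noise_sd = 0.1414, ...) {
  kind <- match.arg(kind)
  if (is.null(true_weights))
    true_weights <- switch(kind,
      linear = c(0.6, 0.9),
      output_saturation = c(1.2, 1.8),
      component_saturation = c(1.2, 1.8),
      gaussian_complexity = c(0.6, 1))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(kind = kind,
                 true_weights = as.numeric(true_weights),
                 noise_sd = noise_sd,
                 value_spec = value_function(kind, ...)),
            class = "reward_model")
}

#' Motivation specification
#'
#' Motivation gates learning multiplicatively and is replaced by its
#' conditional mean \eqn{\bar m(u) \in [0, 1]} given the stimulus (a
#' mean-field simplification of the sampled motivation).  Two forms are
#' available: `"constant"` returns 1 everywhere (used for controls that
#' switch motivation off), and `"gaussian"` is a complexity-tuned gate
#' \deqn{\bar m(u) = m_0 + (1 - m_0)\, e^{-(u_c - c)^2 / 2 s^2},}
#' peaking at 1 for stimuli of preferred complexity \eqn{c} and decaying
#' to the floor \eqn{m_0}.
#'
#' @param form `"gaussian"` (default) or `"constant"`.
#' @param floor baseline motivation \eqn{m_0 \in [0, 1]}.
#' @param center preferred complexity \eqn{c \in [0, 1]}.
#' @param width gate width \eqn{s > 0}.
#' @return an object of class `motivation_spec`.
#' @export
motivation_spec <- function(form = c("gaussian", "constant"),
                            floor = 0.2, center = 0.5, width = 0.25) {
  form <- match.arg(form)
  if (floor < 0 || floor > 1) stop("floor must be in [0,1]", call. = FALSE)
  if (width <= 0) stop("width must be > 0", call. = FALSE)
  structure(list(form = form, floor = floor, center = center, width = width),
            class = "motivation_spec")
}

#' Sample stimuli
#'
#' Draws `n` independent stimuli, each component a Gaussian truncated to
#' \eqn{[0, 1]} by rejection.  Deterministic given the R random seed.
#'
#' @param n number of stimuli.
#' @param spec a [stimulus_spec()].
#' @return an `n x 2` matrix with columns `u_b`, `u_c`.
#' @export
sample_stimulus <- function(n, spec = stimulus_spec()) {
  if (!inherits(spec, "stimulus_spec")) stop("need a stimulus_spec", call. = FALSE)
  out <- sample_stimulus_cpp(as.integer(n), spec$mean, spec$sd)
  colnames(out) <- c("u_b", "u_c")
  out
}

#' Expected reward of a reward model at a stimulus
#'
#' @param rm a [reward_model()].
#' @param u length-2 stimulus.
#' @return scalar expected reward \eqn{\langle r^* \rangle(u)}.
#' @export
mean_reward <- function(rm, u) {
  if (!inherits(rm, "reward_model")) stop("need a reward_model", call. = FALSE)
  evaluate_value(rm$value_spec, rm$true_weights, u)
}

#' Sample fully-motivated rewards
#'
#' Gaussian draws around [mean_reward()] with standard deviation
#' `rm$noise_sd`; unbounded.  With `noise_sd = 0` the mean is returned
#' exactly.
#'
#' @inheritParams mean_reward
#' @param n number of draws.
#' @return numeric vector of length `n`.
#' @export
sample_reward <- function(rm, u, n = 1L) {
  m <- mean_reward(rm, u)
  if (rm$noise_sd == 0) return(rep(m, n))
  stats::rnorm(n, mean = m, sd = rm$noise_sd)
}

#' Mean motivation at a stimulus
#'
#' @param spec a [motivation_spec()].
#' @param u length-2 stimulus (only the complexity component is used by
#'   the Gaussian gate).
#' @return scalar in \eqn{[0, 1]}.
#' @export
mean_motivation <- function(spec, u) {
  if (!inherits(spec, "motivation_spec")) stop("need a motivation_spec", call. = FALSE)
  if (spec$form == "constant") return(1)
  spec$floor + (1 - spec$floor) *
    exp(-(u[2] - spec$center)^2 / (2 * spec$width^2))
}
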