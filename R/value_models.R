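#' Construct a value-function specification
#'
#' A value function \eqn{\mu(u : w)} maps a two-dimensional sensory
#' stimulus \eqn{u = (u_b, u_c)} (visual balance, visual complexity) to a
#' predicted fully-motivated reward, parameterised by the free weight
#' vector \eqn{w}.  Four functional forms are supported:
#'
#' \describe{
#'   \item{`linear`}{\eqn{\mu = w \cdot u}.  No fixed constants.}
#'   \item{`output_saturation`}{a sigmoid of the linear drive,
#'     \eqn{\mu = \tanh(\alpha (w \cdot u - \beta)/2)}, centred on
#'     \eqn{\beta} with rise speed \eqn{\alpha > 0}; bounded in
#'     \eqn{(-1, 1)}.}
#'   \item{`component_saturation`}{a sum of per-component sigmoids,
#'     \eqn{\mu = \sum_i \tanh(\alpha_i (w_i u_i - \beta_i)/2)}; bounded
#'     in \eqn{(-N, N)}.}
#'   \item{`gaussian_complexity`}{linear in balance and Gaussian-tuned in
#'     complexity,
#'     \eqn{\mu = -w_1 + 2 w_1 u_1 + w_2 (e^{-(u_2 - c)^2 / 2 s^2} -
#'     \theta(c, s))}, where \eqn{\theta} is the normaliser returned by
#'     [theta_normalizer()].}
#' }
#'
#' The sigmoidal forms are evaluated as `tanh(z/2)` of the exponent
#' argument, which is algebraically identical to
#' \eqn{(e^z - 1)/(e^z + 1)} but does not overflow at large \eqn{|z|}.
#'
#' @param kind one of `"linear"`, `"output_saturation"`,
#'   `"component_saturation"`, `"gaussian_complexity"`.
#' @param alpha sigmoid gain(s); scalar for `output_saturation`, vector
#'   of length `n_components` for `component_saturation`.  Must be
#'   strictly positive.
#' @param beta sigmoid centre(s); scalar or vector to match `alpha`.
#' @param center,width centre and width (both in stimulus units, width
#'   strictly positive) of the complexity tuning curve of
#'   `gaussian_complexity`.
#' @param n_components stimulus dimensionality for
#'   `component_saturation` (default 2).
#'
#' @return an object of class `value_spec`: a list with elements `kind`
#'   and `constants`.
#' @seealso [evaluate_value()], [value_gradient()], [theta_normalizer()]
#' @export
#' @examples
#' vf <- value_function("linear")
#' evaluate_value(vf, w = c(0.6, 0.9), u = c(0.5, 0.5))  # 0.75
value_function <- function(kind = c("linear", "output_saturation",
                                    "component_saturation",
                                    "gaussian_complexity"),
                           alpha = NULL, beta = NULL,
                           center = NULL, width = NULL,
                           n_components = 2L) {
  kind <- match.arg(kind)
  constants <- switch(kind,
    linear = list(),
    output_saturation = {
      if (is.null(alpha)) alpha <- 10
      if (is.null(beta)) beta <- 1.5
      if (length(alpha) != 1L || length(beta) != 1L)
        stop("output_saturation takes scalar alpha and beta", call. = FALSE)
      if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
      list(alpha = alpha, beta = beta)
    },
    component_saturation = {
      if (is.null(alpha)) alpha <- rep(10, n_components)
      if (is.null(beta)) beta <- c(0.6, 0.9)[seq_len(n_components)]
      if (length(alpha) != n_components || length(beta) != n_components)
        stop("component_saturation needs alpha and beta of length ",
             n_components, call. = FALSE)
      if (any(alpha <= 0)) stop("all alpha must be > 0", call. = FALSE)
      list(alpha = alpha, beta = beta)
    },
    gaussian_complexity = {
      if (is.null(center)) center <- 0.75
      if (is.null(width)) width <- 0.1
      if (width <= 0) stop("width must be > 0", call. = FALSE)
      list(center = center, width = width,
           theta = theta_normalizer(center, width))
    })
  structure(list(kind = kind, constants = constants),
            class = "value_spec")
}

#' @export
print.value_spec <- function(x, ...) {
  cat("<value_spec>", x$kind, "\n")
  if (length(x$constants))
    cat("  constants:",
        paste(names(x$constants),
              vapply(x$constants, function(v) paste(signif(v, 6), collapse = ","),
                     character(1)),
              sep = "=", collapse = "  "), "\n")
  invisible(x)
}

.check_value_spec <- function(spec) {
  if (!inherits(spec, "value_spec"))
    stop("not a value_spec; build one with value_function()", call. = FALSE)
  invisible(spec)
}

#' Normaliser of the Gaussian complexity tuning curve
#'
#' Computes \eqn{\theta(c, s) = \int_0^1 e^{-(x - c)^2 / 2 s^2}\,dx},
#' the average of the (unnormalised) Gaussian tuning curve over the unit
#' complexity interval.  Subtracting \eqn{\theta} inside the
#' `gaussian_complexity` value function makes the complexity term have
#' zero mean over uniformly covered stimuli.
#'
#' The integral is evaluated in closed form through the standard normal
#' CDF, \eqn{\theta = s \sqrt{2\pi}\,(\Phi((1-c)/s) - \Phi(-c/s))},
#' which is exact and cheap enough for hot loops; numeric quadrature is
#' retained only as a test oracle.
#'
#' @param center tuning-curve centre \eqn{c}.
#' @param width tuning-curve width \eqn{s > 0}.
#' @return a scalar in \eqn{(0, \min(1, s\sqrt{2\pi}))}.
#' @export
#' @examples
#' theta_normalizer(0.75, 0.1)  # ~0.2491
theta_normalizer <- function(center, width) {
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    stop("width must be a single positive number", call. = FALSE)
  width * sqrt(2 * pi) *
    (stats::pnorm((1 - center) / width) - stats::pnorm(-center / width))
}

#' Evaluate a value function
#'
#' Returns \eqn{\mu(u : w)} for the given specification.
#'
#' @param spec a [value_function()] specification.
#' @param w numeric weight vector (free parameters), length matching the
#'   stimulus.
#' @param u numeric stimulus vector in \eqn{[0,1]^N}.
#' @return a single numeric value.
#' @export
evaluate_value <- function(spec, w, u) {
  .check_value_spec(spec)
  k <- spec$constants
  switch(spec$kind,
    linear = sum(w * u),
    output_saturation = tanh(k$alpha * (sum(w * u) - k$beta) / 2),
    component_saturation = sum(tanh(k$alpha * (w * u - k$beta) / 2)),
    gaussian_complexity =
      -w[1] + 2 * w[1] * u[1] +
        w[2] * (exp(-(u[2] - k$center)^2 / (2 * k$width^2)) - k$theta))
}

#' Analytic gradient of a value function with respect to the weights
#'
#' Returns \eqn{\nabla_w \mu(u : w)}.  For the linear form the gradient
#' is the stimulus vector itself; the other forms follow by
#' differentiating the sigmoid or Gaussian terms.
#'
#' @inheritParams evaluate_value
#' @return a numeric vector of the same length as `w`.
#' @export
value_gradient <- function(spec, w, u) {
  .check_value_spec(spec)
  k <- spec$constants
  switch(spec$kind,
    linear = as.numeric(u),
    output_saturation = {
      th <- tanh(k$alpha * (sum(w * u) - k$beta) / 2)
      (k$alpha / 2) * (1 - th^2) * u
    },
    component_saturation = {
      th <- tanh(k$alpha * (w * u - k$beta) / 2)
      (k$alpha * u / 2) * (1 - th^2)
    },
    gaussian_complexity =
      c(-1 + 2 * u[1],
        exp(-(u[2] - k$center)^2 / (2 * k$width^2)) - k$theta))
}

# Vectorised evaluation over rows of a weight matrix at a fixed stimulus;
# used by the value-trace metric, where W holds one stored iteration per row.
.eval_value_rows <- function(spec, W, u) {
  k <- spec$constants
  switch(spec$kind,
    linear = drop(W %*% u),
    output_saturation = tanh(k$alpha * (drop(W %*% u) - k$beta) / 2),
    component_saturation = {
      acc <- 0
      for (i in seq_along(u))
        acc <- acc + tanh(k$alpha[i] * (W[, i] * u[i] - k$beta[i]) / 2)
      acc
    },
    gaussian_complexity =
      W[, 1] * (-1 + 2 * u[1]) +
        W[, 2] * (exp(-(u[2] - k$center)^2 / (2 * k$width^2)) - k$theta))
}

# Integer codes shared with the C++ engine.
.kind_code <- function(kind) {
  match(kind, c("linear", "output_saturation", "component_saturation",
                "gaussian_complexity")) - 1L
}

# Flat constants vector shared with the C++ engine
# (gaussian_complexity passes theta precomputed).
.kind_consts <- function(spec) {
  k <- spec$constants
  switch(spec$kind,
    linear = numeric(0),
    output_saturation = c(k$alpha, k$beta),
    component_saturation = as.numeric(rbind(k$alpha, k$beta)),
    gaussian_complexity = c(k$center, k$width, k$theta))
}
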