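#' Weight-space grid for isoline extraction
#'
#' The shortest-path rule extracts isolines of the value function over a
#' square grid in weight space.  The default grid, \eqn{[0, 3]^2} at
#' 101 x 101 points, encloses all standard true weights and the observed
#' trajectories with margin.
#'
#' @param bounds length-2 numeric, lower and upper bound of each axis.
#' @param res points per axis (at least 2).
#' @return an object of class `weight_grid`.
#' @export
weight_grid <- function(bounds = c(0, 3), res = 101L) {
  if (length(bounds) != 2L || !all(is.finite(bounds)) || bounds[1] >= bounds[2])
    stop("bounds must be two finite increasing numbers", call. = FALSE)
  if (res < 2L) stop("res must be >= 2", call. = FALSE)
  structure(list(bounds = as.numeric(bounds), res = as.integer(res)),
            class = "weight_grid")
}

# Value of mu(u : w) over the full grid; rows index w1, columns w2.
.value_grid <- function(spec, u, x, y) {
  k <- spec$constants
  switch(spec$kind,
    linear = outer(x * u[1], y * u[2], "+"),
    output_saturation =
      tanh(k$alpha * (outer(x * u[1], y * u[2], "+") - k$beta) / 2),
    component_saturation =
      outer(tanh(k$alpha[1] * (x * u[1] - k$beta[1]) / 2),
            tanh(k$alpha[2] * (y * u[2] - k$beta[2]) / 2), "+"),
    gaussian_complexity =
      outer(x * (-1 + 2 * u[1]),
            y * (exp(-(u[2] - k$center)^2 / (2 * k$width^2)) - k$theta),
            "+"))
}

#' Extract value-function isolines in weight space
#'
#' Computes the level set \eqn{\{w : \mu(u : w) = \mathrm{level}\}} over
#' a weight grid by marching squares (via [grDevices::contourLines()]).
#' The result is empty when the level is not attained on the grid.
#'
#' @param spec a [value_function()] specification.
#' @param u length-2 stimulus at which the value function is sliced.
#' @param level target value \eqn{r^*}.
#' @param grid a [weight_grid()].
#' @return an object of class `isoline_set`: a list with `level`,
#'   `polylines` (a list of `n x 2` matrices of weight-space vertices),
#'   and `grid`.
#' @export
extract_isolines <- function(spec, u, level, grid = weight_grid()) {
  .check_value_spec(spec)
  if (!inherits(grid, "weight_grid")) stop("need a weight_grid", call. = FALSE)
  x <- seq(grid$bounds[1], grid$bounds[2], length.out = grid$res)
  z <- .value_grid(spec, u, x, x)
  cl <- grDevices::contourLines(x, x, z, levels = level)
  polylines <- lapply(cl, function(p) cbind(w1 = p$x, w2 = p$y))
  structure(list(level = level, polylines = polylines, grid = grid,
                 value_range = range(z)),
            class = "isoline_set")
}

#' Closest point on a set of isolines
#'
#' Finds the point of minimum Euclidean distance from `w` to the
#' polylines of an [extract_isolines()] result, measuring distance to
#' segments (not just vertices).  Ties are broken deterministically by
#' lowest polyline index, then lowest vertex index.
#'
#' @param w length-2 weight vector.
#' @param isolines an `isoline_set`.
#' @return a list of class `phi_step` with `w_opt` (closest point),
#'   `direction` (unit vector from `w` toward `w_opt`, or the zero
#'   vector when the distance is zero) and `distance`.  If the isoline
#'   set is empty an error of class `aesval_unattainable_level` is
#'   signalled, which [apply_update()] turns into the clamped-level
#'   fallback.
#' @export
closest_point <- function(w, isolines) {
  if (!inherits(isolines, "isoline_set")) stop("need an isoline_set", call. = FALSE)
  if (length(isolines$polylines) == 0L)
    stop(structure(class = c("aesval_unattainable_level", "error", "condition"),
                   list(message = "target level not attained on the grid",
                        call = sys.call())))
  best <- Inf
  best_pt <- c(NA_real_, NA_real_)
  for (poly in isolines$polylines) {
    n <- nrow(poly)
    if (n == 1L) {
      d2 <- sum((w - poly[1, ])^2)
      if (d2 < best) { best <- d2; best_pt <- poly[1, ] }
      next
    }
    a <- poly[-n, , drop = FALSE]
    b <- poly[-1, , drop = FALSE]
    ab <- b - a
    L2 <- rowSums(ab^2)
    tt <- (((w[1] - a[, 1]) * ab[, 1]) + ((w[2] - a[, 2]) * ab[, 2])) /
      ifelse(L2 > 0, L2, 1)
    tt <- pmin(pmax(ifelse(L2 > 0, tt, 0), 0), 1)
    px <- a[, 1] + tt * ab[, 1]
    py <- a[, 2] + tt * ab[, 2]
    d2 <- (w[1] - px)^2 + (w[2] - py)^2
    i <- which.min(d2)           # which.min keeps the lowest index on ties
    if (d2[i] < best) { best <- d2[i]; best_pt <- c(px[i], py[i]) }
  }
  dist <- sqrt(best)
  dir <- if (dist > 0) (best_pt - w) / dist else c(0, 0)
  structure(list(w_opt = unname(best_pt), direction = unname(dir),
                 distance = dist),
            class = "phi_step")
}

#' Update-rule specification
#'
#' @param rule `"gradient"` for the delta rule (step along
#'   \eqn{\nabla_w \mu}) or `"phi"` for the shortest-path rule (step
#'   along the unit vector toward the closest point on the target
#'   isoline).
#' @param learning_rate positive step size (the per-iteration rate,
#'   i.e. the continuous-time rate times the time step).
#' @param gradient_source for the gradient rule, the [value_function()]
#'   whose analytic gradient is used.  This may deliberately differ from
#'   the value function being learned (the mixed-linear conditions use
#'   the linear gradient under nonlinear value functions).  Defaults to
#'   the value function passed to [apply_update()].
#' @param grid [weight_grid()] used for isoline extraction under the phi
#'   rule with nonlinear value functions.
#' @return an object of class `update_rule`.
#' @export
update_rule <- function(rule = c("gradient", "phi"), learning_rate = 0.01,
                        gradient_source = NULL, grid = weight_grid()) {
  rule <- match.arg(rule)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (!is.null(gradient_source)) .check_value_spec(gradient_source)
  structure(list(rule = rule, learning_rate = learning_rate,
                 gradient_source = gradient_source, grid = grid),
            class = "update_rule")
}

#' Apply one parameter update
#'
#' Performs one discretised update of the weight vector.  With
#' `rule = "gradient"`:
#' \deqn{w' = w + \epsilon\, \bar m\, (r^* - \mu(u : w))\, \nabla_w
#'   \mu_{src}(u : w),}
#' where the gradient source \eqn{\mu_{src}} defaults to the value
#' function itself.  With `rule = "phi"` the weights move toward the
#' closest point on the target isoline \eqn{\mu(u : \cdot) = r^*} with
#' speed \eqn{\epsilon\, \bar m\, |r^* - \mu(u : w)|}; the unit vector
#' \eqn{\Phi} multiplying the signed error thus follows the gradient's
#' sign convention.  For the linear value function
#' the closest point is computed by closed-form orthogonal projection;
#' other kinds use marching squares on `rule$grid`.  When the target
#' level is not attained on the grid, the level is clamped to the
#' nearest attainable value and the projection made onto that isoline;
#' the returned vector then carries the attribute `phi_fallback = TRUE`.
#'
#' @param rule an [update_rule()].
#' @param w length-2 weight vector.
#' @param u length-2 stimulus.
#' @param r_star sampled fully-motivated reward.
#' @param m_bar mean motivation in \eqn{[0, 1]}.
#' @param value_spec the [value_function()] being learned (supplies
#'   \eqn{\mu} for the prediction error).
#' @return the updated weight vector.
#' @export
#' @examples
#' ur <- update_rule("gradient", learning_rate = 0.01)
#' apply_update(ur, w = c(0, 0), u = c(0.5, 0.5), r_star = 0.75,
#'              m_bar = 1, value_spec = value_function("linear"))
apply_update <- function(rule, w, u, r_star, m_bar, value_spec) {
  if (!inherits(rule, "update_rule")) stop("need an update_rule", call. = FALSE)
  .check_value_spec(value_spec)
  if (m_bar < 0 || m_bar > 1) stop("m_bar must be in [0,1]", call. = FALSE)
  delta <- m_bar * (r_star - evaluate_value(value_spec, w, u))
  if (rule$rule == "gradient") {
    src <- if (is.null(rule$gradient_source)) value_spec else rule$gradient_source
    return(w + rule$learning_rate * delta * value_gradient(src, w, u))
  }
  # Phi rule: step toward the closest point on the target isoline with
  # speed epsilon * m_bar * |r* - mu|.  The direction that multiplies the
  # signed error thus carries the gradient's sign convention (normalised
  # gradient at the projected point, up to the sign of the error); using
  # the raw geometric direction with the signed error would move away
  # from the isoline whenever the value overestimates the reward.
  fallback <- FALSE
  if (value_spec$kind == "linear") {
    den <- sum(u^2)
    dvec <- if (den > 0) ((r_star - sum(w * u)) / den) * u else c(0, 0)
    dist <- sqrt(sum(dvec^2))
    dir <- if (dist > 0) dvec / dist else c(0, 0)
  } else {
    iso <- extract_isolines(value_spec, u, r_star, rule$grid)
    if (length(iso$polylines) == 0L) {
      # clamp the level just inside the attainable range and retry
      rng <- iso$value_range
      eps <- 1e-9 * max(diff(rng), 1)
      lvl <- min(max(r_star, rng[1] + eps), rng[2] - eps)
      iso <- extract_isolines(value_spec, u, lvl, rule$grid)
      fallback <- TRUE
      if (length(iso$polylines) == 0L)
        return(structure(w, phi_fallback = TRUE))
    }
    step <- closest_point(w, iso)
    dir <- step$direction
  }
  out <- w + rule$learning_rate * abs(delta) * dir
  if (fallback) attr(out, "phi_fallback") <- TRUE
  out
}
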