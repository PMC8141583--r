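#' Fully-motivated value trace at the modal stimulus
#'
#' Evaluates \eqn{v^*(t) = \mu((0.5, 0.5) : w(t))} for every stored
#' iteration.  This trace drives the convergence and recovery
#' statistics: although the weights need not converge to a unique point,
#' the value at the modal stimulus does.
#'
#' @param traj an [run_simulation()] trajectory.
#' @param spec value function to evaluate; defaults to the trajectory's
#'   own.
#' @param u_mode the modal stimulus.
#' @return a data frame with columns `t` and `v`.
#' @export
motivated_value_trace <- function(traj, spec = NULL, u_mode = c(0.5, 0.5)) {
  if (is.null(spec)) spec <- traj$value_spec
  W <- cbind(traj$data$w1, traj$data$w2)
  data.frame(t = traj$data$t, v = .eval_value_rows(spec, W, u_mode))
}

#' Time of convergence
#'
#' The first time at which the value trace reaches 90% of its
#' steady-state level, the latter taken as the median of the trace over
#' the final `tail_window` iterations.  "Reaches" means crossing toward
#' the median: at or above the threshold when the tail median is
#' positive, at or below when it is negative.  Runs that never reach the
#' threshold are flagged non-converged and assigned the run length.
#'
#' @param v numeric value trace, or the data frame from
#'   [motivated_value_trace()].
#' @param t iteration times matching `v` (defaults to `0, 1, ...` for a
#'   bare vector).
#' @param tail_window length (in iterations) of the steady-state window.
#' @return the convergence time \eqn{\tau_c} (an iteration count), with
#'   attribute `converged`.
#' @export
convergence_time <- function(v, t = NULL, tail_window = 1e5) {
  if (is.data.frame(v)) { t <- v$t; v <- v$v }
  if (is.null(t)) t <- seq_along(v) - 1
  n_total <- max(t)
  if (n_total <= tail_window)
    stop("trace must extend beyond the tail window", call. = FALSE)
  med <- stats::median(v[t > n_total - tail_window])
  thr <- 0.9 * med
  hit <- if (med >= 0) v >= thr else v <= thr
  if (!any(hit)) {
    warning("value trace never reached 90% of its tail median")
    return(structure(n_total, converged = FALSE))
  }
  structure(t[which(hit)[1]], converged = TRUE)
}

#' Time of recovery from fluctuation errors
#'
#' The smallest lag at which the sample autocorrelation of the
#' steady-state value trace decays to 0.1 or below.  The autocorrelation
#' is computed on the mean-removed tail with the biased (divide by n)
#' normalisation; no interpolation between lags.  If the threshold is
#' never reached the window length is returned with a warning.
#'
#' @param v_tail numeric vector: the unthinned tail of the value trace.
#' @param threshold autocorrelation threshold (default 0.1).
#' @return the recovery lag \eqn{\tau_r} in iterations.
#' @export
recovery_time <- function(v_tail, threshold = 0.1) {
  n <- length(v_tail)
  if (n < 2L) stop("tail too short", call. = FALSE)
  if (stats::sd(v_tail) == 0)
    stop("zero-variance tail: autocorrelation undefined", call. = FALSE)
  lag_max <- min(n - 1L, 2000L)
  repeat {
    ac <- stats::acf(v_tail, lag.max = lag_max, plot = FALSE,
                     demean = TRUE)$acf[-1]
    idx <- which(ac <= threshold)
    if (length(idx)) return(idx[1])
    if (lag_max >= n - 1L) {
      warning("autocorrelation never decayed to ", threshold,
              "; returning the window length")
      return(n)
    }
    lag_max <- min(n - 1L, lag_max * 4L)
  }
}

#' Final regret and final free parameters
#'
#' Component-wise medians of \eqn{\delta} and \eqn{w} over the final
#' \eqn{2 \tau_r} iterations — two recovery times, so the window spans
#' two sets of temporally independent measurements.
#'
#' @param traj a trajectory.
#' @param tau_r recovery time from [recovery_time()].
#' @return a list with `delta_f` (scalar) and `w_f` (length-2).
#' @export
final_estimates <- function(traj, tau_r) {
  d <- traj$data
  n_iter <- traj$config$n_iterations
  if (2 * tau_r > n_iter - traj$tail_start + 1)
    stop("stored tail shorter than 2 * tau_r", call. = FALSE)
  keep <- d$t > n_iter - 2 * tau_r
  list(delta_f = stats::median(d$delta[keep]),
       w_f = c(stats::median(d$w1[keep]), stats::median(d$w2[keep])))
}

#' Initial slope of the weight trajectory
#'
#' The early weight trajectory is close to a straight line through the
#' origin, \eqn{w_2(t) = k\, w_1(t)}.  The slope is estimated by robust
#' through-origin regression (M-estimation with Tukey's biweight) over
#' all iterations up to the convergence time.
#'
#' @param traj a trajectory.
#' @param tau_c convergence time from [convergence_time()].
#' @return the slope `k`.
#' @export
initial_slope <- function(traj, tau_c) {
  d <- traj$data[traj$data$t <= tau_c, ]
  if (nrow(d) < 2L)
    stop("need at least 2 stored iterations before tau_c", call. = FALSE)
  if (all(abs(d$w1) < 1e-12))
    stop("degenerate early trajectory: w1 never leaves 0", call. = FALSE)
  fit <- MASS::rlm(w2 ~ w1 - 1, data = d, psi = MASS::psi.bisquare,
                   maxit = 200)
  unname(stats::coef(fit)[1])
}

#' Deviation from straightness
#'
#' Signed ratio measuring how far the final weights \eqn{w_f} depart
#' from the early straight-line trajectory \eqn{w_2 = k w_1}:
#' \deqn{\rho = \frac{w_{f,2} - k\, w_{f,1}}{k\, w_{f,2} + w_{f,1}},}
#' the distance from \eqn{w_f} to its nearest point on the line divided
#' by the distance from that point to the origin.  Positive when
#' \eqn{w_f} lies above the line (bias toward complexity), negative
#' below (bias toward balance), zero exactly on it.
#'
#' @param w_f length-2 final weights (positive quadrant).
#' @param k positive slope from [initial_slope()].
#' @return the signed deviation.
#' @export
straightness_deviation <- function(w_f, k) {
  if (k <= 0) stop("k must be > 0", call. = FALSE)
  den <- k * w_f[2] + w_f[1]
  if (den <= 0)
    stop("non-positive denominator: final weights out of regime", call. = FALSE)
  (w_f[2] - k * w_f[1]) / den
}

#' All run statistics for one trajectory
#'
#' Computes the value trace and derives \eqn{\tau_c}, \eqn{\tau_r},
#' \eqn{\delta_f}, \eqn{w_f}, the initial slope \eqn{k} and the
#' deviation from straightness.  If the early trajectory is degenerate
#' the slope and deviation are `NA`.
#'
#' @param traj a trajectory.
#' @return a list of class `run_statistics`.
#' @export
run_statistics <- function(traj) {
  vt <- motivated_value_trace(traj)
  tw <- traj$config$n_iterations - traj$tail_start + 1
  tau_c <- convergence_time(vt, tail_window = tw)
  v_tail <- vt$v[vt$t >= traj$tail_start]
  tau_r <- recovery_time(v_tail)
  fin <- final_estimates(traj, tau_r)
  k <- tryCatch(initial_slope(traj, tau_c), error = function(e) NA_real_)
  rho <- if (is.na(k)) NA_real_ else
    tryCatch(straightness_deviation(fin$w_f, k), error = function(e) NA_real_)
  structure(list(condition = traj$condition$id, seed = traj$seed,
                 tau_c = as.numeric(tau_c), tau_r = tau_r,
                 delta_f = fin$delta_f, w_f = fin$w_f,
                 slope_k = k, rho_straight = rho,
                 converged = isTRUE(attr(tau_c, "converged"))),
            class = "run_statistics")
}

#' @export
print.run_statistics <- function(x, ...) {
  cat(sprintf(paste0("<run_statistics> condition %d seed %d\n",
                     "  tau_c=%g tau_r=%g delta_f=%.5f w_f=[%.4f, %.4f]",
                     " k=%.4f rho=%.4f\n"),
              x$condition, x$seed, x$tau_c, x$tau_r, x$delta_f,
              x$w_f[1], x$w_f[2], x$slope_k, x$rho_straight))
  invisible(x)
}

#' Tidy statistics table for a set of runs
#'
#' @param stats_list list of [run_statistics()] results.
#' @return a long data frame: condition, repetition (seed), metric,
#'   value.
#' @export
statistics_table <- function(stats_list) {
  do.call(rbind, lapply(stats_list, function(s)
    data.frame(condition = s$condition, seed = s$seed,
               metric = c("tau_c", "tau_r", "delta_f", "w_f1", "w_f2",
                          "slope_k", "rho_straight"),
               value = c(s$tau_c, s$tau_r, s$delta_f, s$w_f[1], s$w_f[2],
                         s$slope_k, s$rho_straight))))
}

#' Compare statistics across conditions
#'
#' For each metric, runs a one-way ANOVA across conditions followed by
#' uncorrected pairwise two-sided t-tests, and computes the robust
#' Kendall rank correlation between the convergence and recovery times
#' across conditions (on per-condition means).
#'
#' @param stats_df long data frame from [statistics_table()].
#' @return a list of class `condition_comparison` with `anova` (one row
#'   per metric: F, df, p), `pairwise` (per-metric matrices of t-test
#'   p-values, uncorrected) and `kendall_tau_c_tau_r` (the `cor.test`
#'   result, or `NULL` with fewer than 3 conditions).
#' @export
compare_conditions <- function(stats_df) {
  metrics <- unique(stats_df$metric)
  anova_rows <- NULL
  pairwise <- list()
  for (m in metrics) {
    d <- stats_df[stats_df$metric == m & is.finite(stats_df$value), ]
    n_groups <- length(unique(d$condition))
    if (n_groups < 2L || nrow(d) <= n_groups) next  # need residual df
    if (all(tapply(d$value, d$condition, stats::sd) == 0) &&
        length(unique(d$value)) == 1L) {
      anova_rows <- rbind(anova_rows,
                          data.frame(metric = m, F = 0, df1 = NA, df2 = NA,
                                     p = 1))
      next
    }
    fit <- stats::aov(value ~ factor(condition), data = d)
    s <- summary(fit)[[1]]
    anova_rows <- rbind(anova_rows,
                        data.frame(metric = m, F = s[["F value"]][1],
                                   df1 = s[["Df"]][1], df2 = s[["Df"]][2],
                                   p = s[["Pr(>F)"]][1]))
    pairwise[[m]] <- tryCatch(
      stats::pairwise.t.test(
        d$value, factor(d$condition), p.adjust.method = "none",
        pool.sd = FALSE, alternative = "two.sided")$p.value,
      error = function(e) NULL)  # e.g. zero-variance groups
  }
  tc <- stats_df[stats_df$metric == "tau_c", ]
  tr <- stats_df[stats_df$metric == "tau_r", ]
  kt <- NULL
  if (length(unique(tc$condition)) >= 3L) {
    mc <- tapply(tc$value, tc$condition, mean)
    mr <- tapply(tr$value, tr$condition, mean)
    kt <- suppressWarnings(
      stats::cor.test(mc, mr[names(mc)], method = "kendall"))
  }
  structure(list(anova = anova_rows, pairwise = pairwise,
                 kendall_tau_c_tau_r = kt),
            class = "condition_comparison")
}

#' Residence times before and beyond the target isoline
#'
#' At each stored iteration the weights sit either before the target
#' isoline (value underestimates the sampled reward,
#' \eqn{\mu(u : w) < r^*}) or beyond it (overestimation).  The side is
#' read off the recorded learning signal (\eqn{\delta > 0} means
#' before).  Runs of consecutive same-side iterations are collected into
#' two run-length vectors.
#'
#' @param traj a trajectory.
#' @param window optional `c(from, to)` iteration range; defaults to the
#'   unthinned tail.
#' @return a list with numeric vectors `before` and `beyond` of run
#'   lengths (in stored iterations).
#' @export
isoline_residence <- function(traj, window = NULL) {
  d <- traj$data
  if (is.null(window)) window <- c(traj$tail_start, traj$config$n_iterations)
  d <- d[d$t >= window[1] & d$t <= window[2], ]
  side <- sign(d$delta)
  side[side == 0] <- 1   # exact hits counted with "before"
  r <- rle(side)
  list(before = as.numeric(r$lengths[r$values > 0]),
       beyond = as.numeric(r$lengths[r$values < 0]))
}

#' Learning signal versus stimulus direction
#'
#' Pairs the stimulus direction angle \eqn{\mathrm{atan2}(u_c, u_b)}
#' with the recorded learning signal \eqn{\delta} over an iteration
#' window, and summarises their association by a Spearman rank
#' correlation.  For a well-matched linear condition the correlation is
#' near zero; mismatched nonlinear conditions show structured
#' dependence.
#'
#' @param traj a trajectory.
#' @param window `c(from, to)` iteration range.
#' @return a list with `data` (data frame: `t`, `angle`, `delta`) and
#'   `rank_cor`.
#' @export
delta_direction_profile <- function(traj, window) {
  d <- traj$data[traj$data$t >= window[1] & traj$data$t <= window[2], ]
  if (nrow(d) == 0L) stop("empty window", call. = FALSE)
  angle <- atan2(d$u_c, d$u_b)
  list(data = data.frame(t = d$t, angle = angle, delta = d$delta),
       rank_cor = suppressWarnings(
         stats::cor(angle, d$delta, method = "spearman")))
}

#' Motivation-weighted squared prediction error
#'
#' Time average of \eqn{\bar m (r^* - \mu)^2} over an iteration window
#' — the objective on which the delta rule performs stochastic gradient
#' descent.  Recovered from the stored signal as
#' \eqn{\delta^2 / \bar m}.
#'
#' @param traj a trajectory.
#' @param window `c(from, to)` iteration range.
#' @return a non-negative scalar.
#' @export
weighted_error <- function(traj, window) {
  d <- traj$data[traj$data$t >= window[1] & traj$data$t <= window[2], ]
  if (nrow(d) == 0L) stop("empty window", call. = FALSE)
  mean(ifelse(d$m_bar > 0, d$delta^2 / d$m_bar, 0))
}
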