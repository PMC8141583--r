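test_that("convergence time finds the 90% crossing", {
  # step trace
  v <- c(rep(0, 100), rep(1, 2e5))
  expect_equal(as.numeric(convergence_time(v, tail_window = 1e5)), 100)
  # constant positive trace converges immediately
  v2 <- rep(2, 2e5)
  expect_equal(as.numeric(convergence_time(v2, tail_window = 1e5)), 0)
  # exponential rise: crossing at ceiling(tau * ln 10)
  tau <- 1000
  t <- 0:(3e5)
  v3 <- 1 - exp(-t / tau)
  expect_equal(as.numeric(convergence_time(v3, t, tail_window = 1e5)),
               ceiling(tau * log(10)))
  # negative steady state crosses downward
  v4 <- -(1 - exp(-t / tau))
  expect_equal(as.numeric(convergence_time(v4, t, tail_window = 1e5)),
               ceiling(tau * log(10)))
  expect_error(convergence_time(rep(1, 10), tail_window = 1e5), "tail")
})

test_that("recovery time reads the autocorrelation decay", {
  # series with exactly geometric autocorrelation 0.9^lag:
  # 0.9^21 = 0.109 > 0.1 >= 0.9^22 = 0.0985, so the crossing is lag 22
  expect_equal(recovery_time(0.9^(0:5000)), 22)
  # stochastic AR(1) tail lands near the same lag
  set.seed(123)
  x <- as.numeric(arima.sim(list(ar = 0.9), 1e5))
  expect_true(recovery_time(x) %in% 19:25)
  # white noise decorrelates at the first lag
  set.seed(5)
  expect_equal(recovery_time(rnorm(1e4)), 1)
  # near-constant tail with one spike: finite result, no crash
  y <- c(rep(1, 5000), 5, rep(1, 4999))
  expect_true(recovery_time(y) >= 1)
  expect_error(recovery_time(rep(1, 100)), "zero-variance")
})

test_that("final estimates are tail medians robust to outliers", {
  tr <- run_simulation(1, desk_config(5000, 2000, 1L), seed = 9)
  fe <- final_estimates(tr, tau_r = 500)
  keep <- tr$data$t > 5000 - 1000
  expect_identical(fe$delta_f, median(tr$data$delta[keep]))
  expect_identical(fe$w_f, c(median(tr$data$w1[keep]),
                             median(tr$data$w2[keep])))
  expect_error(final_estimates(tr, tau_r = 5000), "tail")
})

test_that("initial slope is exact on clean data and robust to outliers", {
  mk_traj <- function(w1, w2, n_iter = length(w1)) {
    structure(list(
      data = data.frame(t = seq_along(w1), w1 = w1, w2 = w2,
                        delta = 0, u_b = 0.5, u_c = 0.5, r_star = 0,
                        m_bar = 1),
      config = engine_config(n_iterations = n_iter, tail_window = 10),
      tail_start = n_iter - 9), class = "aesval_trajectory")
  }
  w1 <- seq(0.01, 1, length.out = 100)
  expect_equal(initial_slope(mk_traj(w1, 2 * w1), tau_c = 100), 2,
               tolerance = 1e-8)
  # 5% gross outliers barely move the biweight estimate
  w2 <- 2 * w1
  w2[seq(5, 100, by = 20)] <- 10
  expect_equal(initial_slope(mk_traj(w1, w2), tau_c = 100), 2,
               tolerance = 0.05)
  expect_error(initial_slope(mk_traj(w1[1], 2 * w1[1]), tau_c = 1),
               "at least 2")
  expect_error(initial_slope(mk_traj(rep(0, 50), seq_len(50)), tau_c = 50),
               "degenerate")
})

test_that("straightness deviation matches its closed form and symmetry", {
  expect_equal(straightness_deviation(c(1, 2), k = 2), 0)
  expect_equal(straightness_deviation(c(0, 1), k = 1), 1)
  expect_equal(straightness_deviation(c(1, 2), k = 1), 1 / 3)
  expect_error(straightness_deviation(c(1, 1), k = -1), "k")
  # reflecting w_f across the fitted line flips the sign
  reflect <- function(w, k) {
    # reflection across y = k x
    d <- 1 + k^2
    c(((1 - k^2) * w[1] + 2 * k * w[2]) / d,
      (2 * k * w[1] - (1 - k^2) * w[2]) / d)
  }
  set.seed(13)
  for (i in 1:25) {
    k <- runif(1, 0.3, 3)
    w <- runif(2, 0.2, 2)
    r1 <- straightness_deviation(w, k)
    r2 <- straightness_deviation(reflect(w, k), k)
    expect_equal(r1, -r2, tolerance = 1e-10)
  }
})

test_that("condition comparison matches textbook statistics", {
  # hand fixture 1: two groups for one metric; one-way ANOVA F by hand:
  # groups (1,2,3) and (3,4,5): grand mean 3, SSB = 6, SSW = 4,
  # F = (6/1)/(4/4) = 6
  df1 <- data.frame(condition = rep(1:2, each = 3), seed = 1:6,
                    metric = "delta_f", value = c(1, 2, 3, 3, 4, 5))
  cmp1 <- compare_conditions(df1)
  expect_equal(cmp1$anova$F[1], 6)
  expect_equal(cmp1$anova$p[1], 1 - pf(6, 1, 4))
  # hand fixture 2: identical groups give F = 0
  df2 <- data.frame(condition = rep(1:2, each = 3), seed = 1:6,
                    metric = "delta_f", value = rep(c(1, 2, 3), 2))
  expect_equal(compare_conditions(df2)$anova$F[1], 0)
  # hand fixture 3: Kendall tau on the 4-point pattern (1,2,3,4) vs
  # (1,3,2,4): 5 concordant, 1 discordant of 6 pairs -> 2/3
  df3 <- rbind(
    data.frame(condition = rep(1:4, each = 2), seed = 1:8, metric = "tau_c",
               value = rep(c(1, 2, 3, 4), each = 2)),
    data.frame(condition = rep(1:4, each = 2), seed = 1:8, metric = "tau_r",
               value = rep(c(1, 3, 2, 4), each = 2)))
  kt <- compare_conditions(df3)$kendall_tau_c_tau_r
  expect_equal(unname(kt$estimate), 2 / 3)
  # perfectly concordant condition means give tau = 1
  df4 <- rbind(
    data.frame(condition = rep(1:4, each = 2), seed = 1:8, metric = "tau_c",
               value = rep(1:4, each = 2)),
    data.frame(condition = rep(1:4, each = 2), seed = 1:8, metric = "tau_r",
               value = rep(2 * (1:4), each = 2)))
  expect_equal(unname(compare_conditions(df4)$kendall_tau_c_tau_r$estimate), 1)
})

test_that("isoline residence splits runs by the sign of the learning signal", {
  mk <- function(delta) structure(list(
    data = data.frame(t = seq_along(delta), w1 = 0, w2 = 0, delta = delta,
                      u_b = 0.5, u_c = 0.5, r_star = 0, m_bar = 1),
    config = engine_config(n_iterations = length(delta),
                           tail_window = length(delta)),
    tail_start = 1), class = "aesval_trajectory")
  # always underestimating: one "before" run of full length
  r1 <- isoline_residence(mk(rep(0.2, 50)))
  expect_identical(r1$before, 50)
  expect_length(r1$beyond, 0)
  # alternating signs: all runs of length 1
  r2 <- isoline_residence(mk(rep(c(0.1, -0.1), 25)))
  expect_true(all(c(r2$before, r2$beyond) == 1))
})

test_that("learning-signal direction profile detects monotone structure", {
  n <- 2000
  set.seed(17)
  u_b <- runif(n, 0.1, 0.9); u_c <- runif(n, 0.1, 0.9)
  ang <- atan2(u_c, u_b)
  mk <- function(delta) structure(list(
    data = data.frame(t = 1:n, w1 = 0, w2 = 0, delta = delta,
                      u_b = u_b, u_c = u_c, r_star = 0, m_bar = 1),
    config = engine_config(n_iterations = n, tail_window = n),
    tail_start = 1), class = "aesval_trajectory")
  # delta = cos(angle) is monotone on the sampled angle range
  p1 <- delta_direction_profile(mk(cos(ang)), c(1, n))
  expect_gt(abs(p1$rank_cor), 0.99)
  # independent delta decorrelates
  p2 <- delta_direction_profile(mk(rnorm(n)), c(1, n))
  expect_lt(abs(p2$rank_cor), 0.1)
  expect_error(delta_direction_profile(mk(rnorm(n)), c(n + 1, n + 2)),
               "empty")
})

test_that("weighted error evaluates the gated squared regret", {
  mk <- function(delta, m) structure(list(
    data = data.frame(t = seq_along(delta), w1 = 0, w2 = 0, delta = delta,
                      u_b = 0.5, u_c = 0.5, r_star = 1, m_bar = m),
    config = engine_config(n_iterations = length(delta),
                           tail_window = length(delta)),
    tail_start = 1), class = "aesval_trajectory")
  # single sample m = 1, r* = 1, mu = 0: delta = 1, error 1
  expect_equal(weighted_error(mk(1, 1), c(1, 1)), 1)
  # mu == r* everywhere -> 0; m == 0 everywhere -> 0
  expect_equal(weighted_error(mk(rep(0, 10), 1), c(1, 10)), 0)
  expect_equal(weighted_error(mk(rep(0, 10), 0), c(1, 10)), 0)
  # decreases from the first to the last tenth of a converging run
  tr <- run_simulation(1, desk_config(3e4, 5e3), seed = 20)
  n <- tr$config$n_iterations
  expect_lt(weighted_error(tr, c(0.9 * n, n)),
            weighted_error(tr, c(1, 0.1 * n)))
})

test_that("run statistics assemble all metrics coherently", {
  tr <- run_simulation(1, desk_config(3e4, 1e4), seed = 30)
  s <- run_statistics(tr)
  expect_true(s$tau_c >= 1 && s$tau_c <= 3e4)
  expect_true(s$tau_r >= 1 && s$tau_r <= 1e4)
  expect_true(s$converged)
  expect_gt(s$slope_k, 0)
  tab <- statistics_table(list(s))
  expect_equal(nrow(tab), 7)
  expect_equal(tab$value[tab$metric == "w_f1"], s$w_f[1])
})
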