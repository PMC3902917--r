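# MSD estimator, apparent diffusion coefficients, confinement fitting.

test_that("time-averaged MSD matches hand-enumerated and brute-force oracles", {
  tr <- trajectory(t_s = 0:3, x_um = c(0, 1, 2, 3), y_um = numeric(4))
  cu <- compute_msd(tr, axis = "long", max_lag = 3)
  expect_equal(cu$msd_um2, c(1, 4, 9))
  expect_equal(cu$n_pairs, c(3, 2, 1))

  still <- trajectory(t_s = 0:9, x_um = rep(0.5, 10), y_um = rep(-0.1, 10))
  expect_true(all(compute_msd(still, axis = "2d")$msd_um2 == 0))

  set.seed(99)
  x <- cumsum(rnorm(40)); y <- cumsum(rnorm(40))
  rnd <- trajectory(t_s = seq(0, 78, 2), x_um = x, y_um = y)
  for (ax in c("long", "short", "2d")) {
    cu <- compute_msd(rnd, axis = ax, max_lag = 30)
    expect_equal(cu$msd_um2, msd_brute_force(x, y, 2, ax, nrow(cu)))
  }
  # n_pairs is non-increasing in lag
  expect_true(all(diff(compute_msd(rnd, axis = "long")$n_pairs) <= 0))
})

test_that("ensemble mode uses displacements from the first point only", {
  tr <- trajectory(t_s = 0:3, x_um = c(0, 1, 3, 6), y_um = numeric(4))
  cu <- compute_msd(tr, axis = "long", mode = "ensemble", max_lag = 3)
  expect_equal(cu$msd_um2, c(1, 9, 36))
  expect_true(all(cu$n_pairs == 1L))
})

test_that("averaging MSD curves weights by pair counts", {
  c1 <- compute_msd(trajectory(t_s = 0:3, x_um = c(0, 1, 2, 3),
                               y_um = numeric(4)), axis = "long")
  c2 <- compute_msd(trajectory(t_s = 0:2, x_um = c(0, 0, 0),
                               y_um = numeric(3)), axis = "long")
  av <- average_msd(list(c1, c2))
  # lag 1: (3*1 + 2*0) / 5
  expect_equal(av$msd_um2[1], 0.6)
  expect_equal(av$n_pairs[1], 5L)
})

test_that("D_app applies MSD/(tau*q_i), including the 0.20 um / 5 s case", {
  expect_equal(compute_dapp(0, 5)$d_app, 0)
  expect_equal(compute_dapp(0.20^2, tau = 5, q_i = 4)$d_app, 2.0e-3)
  expect_equal(compute_dapp(0.01, tau = 2.5, q_i = 4)$d_app, 1.0e-3)
  expect_equal(compute_dapp(0.02, tau = 5, q_i = 2)$d_app, 2e-3)
  expect_error(compute_dapp(0.01, 1, q_i = 3), "q_i")
})

test_that("step-size statistics: degenerate, ballistic and diffusive cases", {
  still <- trajectory(t_s = seq(0, 45, 5), x_um = rep(1, 10),
                      y_um = rep(0, 10))
  s <- step_size_stats(still, 5)
  expect_equal(c(s$mean_um_s, s$sd_um_s), c(0, 0))

  ball <- trajectory(t_s = seq(0, 45, 5), x_um = seq(0, 0.9, 0.1),
                     y_um = rep(0, 10))
  s <- step_size_stats(ball, 5)
  expect_equal(s$mean_um_s, 0.02)
  expect_equal(s$sd_um_s, 0)
  expect_error(step_size_stats(ball, 7), "multiple")

  # 2D diffusive steps are Rayleigh; mean speed = sqrt(pi * D / tau)
  D <- 2.5e-3; tau <- 5
  sp <- unlist(lapply(1:60, function(i) {
    tr <- gen_confined_trajectory(D = D, box_long = 1e6, box_short = 1e6,
                                  dt = tau, n_steps = 60, seed = 600 + i)
    dx <- diff(tr$x_um); dy <- diff(tr$y_um)
    sqrt(dx^2 + dy^2) / tau
  }))
  expect_equal(mean(sp), sqrt(pi * D / tau),
               tolerance = 3 * sd(sp) / sqrt(length(sp)) / sqrt(pi * D / tau))
})

test_that("confinement fit recovers noise-free closed-form curves exactly", {
  cu <- exact_msd_curve(L = 0.6, D = 2e-3, lags = seq(10, 600, 10))
  fit <- fit_confinement(cu, cell_dim = 3)
  expect_equal(fit$L, 0.6, tolerance = 1e-6)
  expect_equal(fit$D, 2e-3, tolerance = 1e-6)
  expect_true(fit$plateau_reached)
  expect_equal(fit$asymptote, 0.6^2 / 6, tolerance = 1e-6)
  # with a noise-floor offset
  cuo <- exact_msd_curve(L = 0.5, D = 1e-3, lags = seq(5, 500, 5),
                         offset = 0.004)
  fito <- fit_confinement(cuo, cell_dim = 3, with_offset = TRUE)
  expect_equal(fito$L, 0.5, tolerance = 1e-4)
  expect_equal(fito$offset, 0.004, tolerance = 1e-3)
})

test_that("unconfined (linear) MSD curves are flagged as plateau not reached", {
  lags <- seq(2.5, 25, 2.5)
  lin <- structure(data.frame(lag_s = lags, msd_um2 = 2 * 2.5e-3 * lags,
                              n_pairs = rev(seq_along(lags))),
                   class = c("msd_curve", "data.frame"), axis = "long")
  fit <- fit_confinement(lin, cell_dim = 3)
  expect_false(fit$plateau_reached)
})

test_that("fit methods are coherent (coef/predict/residuals/summary)", {
  cu <- exact_msd_curve(L = 0.6, D = 2e-3, lags = seq(10, 600, 10))
  fit <- fit_confinement(cu, cell_dim = 3)
  expect_named(coef(fit), c("L", "D"))
  expect_equal(predict(fit), cu$msd_um2, tolerance = 1e-6)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-8)
  expect_output(print(summary(fit)), "relaxation")
})

test_that("fitted L tracks the true confinement over increasing box sizes", {
  levels <- c(0.3, 0.4, 0.5, 0.6, 0.7)
  med_L <- vapply(seq_along(levels), function(j) {
    ens <- fit_ensemble_L(15, levels[j], D = 2.5e-3, dt = 10, n_steps = 120,
                          seed0 = 1000 * j)
    median(ens$L)
  }, 0)
  expect_equal(cor(med_L, levels, method = "spearman"), 1)
})

test_that("ensembles at measured-confinement scale recover L and D", {
  ens <- fit_ensemble_L(100, 0.43, D = 2.5e-3, dt = 10, n_steps = 120,
                        seed0 = 5000)
  expect_gt(ens$n_kept, 50)
  expect_equal(median(ens$L), 0.43, tolerance = 0.10)
  expect_equal(median(ens$D), 2.5e-3, tolerance = 0.20)
})

test_that("apparent D declines with lag on confined synthetic data", {
  curves <- lapply(1:50, function(i) {
    tr <- gen_confined_trajectory(D = 2.5e-3, box_long = 0.43,
                                  box_short = 0.4, dt = 2.5, n_steps = 100,
                                  seed = 9000 + i)
    compute_msd(tr, axis = "long", max_lag = 25)
  })
  av <- average_msd(curves)
  dapp <- av$msd_um2 / (av$lag_s * 2)
  expect_true(all(diff(dapp) < 0))
})
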