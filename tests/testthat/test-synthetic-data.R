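# Generators: determinism, closed-form moments, barrier behaviour.

test_that("generators are deterministic under a seed and reject bad specs", {
  a <- gen_confined_trajectory(D = 1e-3, box_long = 1, box_short = 0.5,
                               dt = 2, n_steps = 50, loc_noise_sd = 0.02,
                               seed = 42)
  b <- gen_confined_trajectory(D = 1e-3, box_long = 1, box_short = 0.5,
                               dt = 2, n_steps = 50, loc_noise_sd = 0.02,
                               seed = 42)
  expect_identical(a, b)

  cell <- cell_geometry(3, 1, rbind(c(0.2, 0.8)))
  h1 <- gen_hop_trajectory(cell, D = 1e-3, p_hop = 0.1, dt = 1,
                           n_steps = 100, seed = 7)
  h2 <- gen_hop_trajectory(cell, D = 1e-3, p_hop = 0.1, dt = 1,
                           n_steps = 100, seed = 7)
  expect_identical(h1, h2)

  expect_identical(gen_qpcr_plate(2, ct_noise_sd = 0.1, seed = 3),
                   gen_qpcr_plate(2, ct_noise_sd = 0.1, seed = 3))
  expect_identical(gen_edu_counts(0.1, 10, 50, seed = 9),
                   gen_edu_counts(0.1, 10, 50, seed = 9))
  expect_identical(gen_spot_image(cbind(5, 5), seed = 1, shape = c(16, 16)),
                   gen_spot_image(cbind(5, 5), seed = 1, shape = c(16, 16)))

  expect_error(gen_confined_trajectory(D = 1e-3, box_long = 0, box_short = 1,
                                       dt = 1, n_steps = 10), "box_long")
  expect_error(gen_confined_trajectory(D = 1e-3, box_long = 1, box_short = 1,
                                       dt = -1, n_steps = 10), "dt")
  expect_error(cell_geometry(3, 1, rbind(c(0.1, 0.5), c(0.4, 0.9))),
               "disjoint")
  expect_error(cell_geometry(3, 1, rbind(c(0.5, 1.2))), "0 <= start")
})

test_that("a frozen particle shows only localization noise", {
  tr <- gen_confined_trajectory(D = 0, box_long = 1, box_short = 1, dt = 1,
                                n_steps = 2000, loc_noise_sd = 0.03, seed = 5)
  expect_equal(length(unique(attr(tr, "x_true"))), 1L)
  expect_equal(sd(tr$x_um), 0.03, tolerance = 0.1)
  expect_equal(sd(tr$y_um), 0.03, tolerance = 0.1)
})

test_that("unconfined MSD at one frame matches 2*D*dt within 3 SE", {
  D <- 2.5e-3; dt <- 2.5
  tr <- gen_confined_trajectory(D = D, box_long = 1e6, box_short = 1e6,
                                dt = dt, n_steps = 20001, seed = 11,
                                start = c(5e5, 0))
  steps <- diff(tr$x_um)
  m <- mean(steps^2)
  se <- sd(steps^2) / sqrt(length(steps))
  expect_lt(abs(m - 2 * D * dt), 3 * se)
})

test_that("long confined runs reach the uniform stationary variance box^2/12", {
  box <- 0.43
  tr <- gen_confined_trajectory(D = 2.5e-3, box_long = box, box_short = box,
                                dt = 5, n_steps = 20000, seed = 13)
  expect_equal(var(attr(tr, "x_true")), box^2 / 12, tolerance = 0.1)
})

test_that("hop diffusion respects absolute, permeable and absent barriers", {
  cell <- cell_geometry(3, 1, rbind(c(0.2, 0.8)))
  # p_hop = 0: a particle starting at a pole never enters the nucleoid
  tr0 <- gen_hop_trajectory(cell, D = 2.5e-3, p_hop = 0, dt = 1,
                            n_steps = 3000, seed = 3, start = c(0.3, 0))
  x0 <- attr(tr0, "x_true")
  expect_true(all(x0 <= 0.6 + 1e-12))
  # p_hop = 1: uniform occupancy, subinterval occupancy ~ its length
  tr1 <- gen_hop_trajectory(cell, D = 2.5e-2, p_hop = 1, dt = 1,
                            n_steps = 20000, seed = 4)
  x1 <- attr(tr1, "x_true") / 3
  expect_equal(mean(pmin(x1, 1 - x1) <= 0.2), 0.4, tolerance = 0.12)
  expect_equal(mean(x1 > 0.25 & x1 < 0.5), 0.25, tolerance = 0.15)
  # p_hop = 0.01: strong polar enrichment above the uniform 0.4
  tr2 <- gen_hop_trajectory(cell, D = 2.5e-2, p_hop = 0.01, dt = 1,
                            n_steps = 20000, seed = 5)
  x2 <- attr(tr2, "x_true") / 3
  expect_gt(mean(pmin(x2, 1 - x2) <= 0.2), 0.4)
})

test_that("p_hop = 1 hop steps match plain confined diffusion (KS)", {
  cell <- cell_geometry(2, 2, rbind(c(0.3, 0.7)))
  hop <- gen_hop_trajectory(cell, D = 2e-3, p_hop = 1, dt = 1,
                            n_steps = 5000, seed = 21)
  conf <- gen_confined_trajectory(D = 2e-3, box_long = 2, box_short = 2,
                                  dt = 1, n_steps = 5000, seed = 22)
  ks <- suppressWarnings(
    ks.test(diff(attr(hop, "x_true")), diff(attr(conf, "x_true"))))
  expect_gt(ks$p.value, 0.01)
})

test_that("qPCR plate Ct structure encodes the true ratio", {
  p1 <- gen_qpcr_plate(true_ratio = 1, ct_noise_sd = 0, n_replicates = 1)
  expect_equal(p1$ct[p1$target == "chr"], p1$ct[p1$target == "pl"])
  p8 <- gen_qpcr_plate(true_ratio = 8, ct_noise_sd = 0, n_replicates = 1)
  expect_equal(p8$ct[p8$target == "chr"] - p8$ct[p8$target == "pl"], 3)
  expect_error(gen_qpcr_plate(0), "true_ratio")
  expect_error(gen_qpcr_plate(2, eff_pl = 2.5), "eff_pl")
})

test_that("EdU counts follow the Poisson calibration", {
  expect_true(all(gen_edu_counts(0, 10, 100, seed = 1)$n_spots == 0))
  cts <- gen_edu_counts(1 / 17.6, window_min = 17.6, n_cells = 4000, seed = 2)
  expect_equal(mean(cts$n_spots), 1.0, tolerance = 3 / sqrt(4000))
  cts6 <- gen_edu_counts(1 / 17.6, window_min = 6, n_cells = 4000, seed = 3)
  frac <- mean(cts6$n_spots >= 1)
  expect_equal(frac, 1 - exp(-6 / 17.6), tolerance = 0.03)
})

test_that("spot images render and round-trip through the localizer", {
  blank <- gen_spot_image(matrix(numeric(0), ncol = 2), noise_sd = 1,
                          shape = c(32, 32), seed = 1)
  expect_equal(nrow(localize_spots(blank)), 0L)

  one <- gen_spot_image(cbind(17.3, 12.6), amplitude = 100, psf_sd = 1.5,
                        noise_sd = 0, shape = c(32, 32))
  det <- localize_spots(one)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$x - 17.3), 0.1)
  expect_lt(abs(det$y - 12.6), 0.1)

  two <- gen_spot_image(rbind(c(10, 16), c(20, 16)), amplitude = 100,
                        psf_sd = 1.5, noise_sd = 0.5, shape = c(32, 32),
                        seed = 2)
  expect_equal(nrow(localize_spots(two)), 2L)
  expect_error(gen_spot_image(cbind(40, 5), shape = c(32, 32)), "inside")
})
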