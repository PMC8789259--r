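test_that("conductivity tensors follow the fiber direction", {
  cfg <- monodomain_config()
  lab <- matrix(1L, 3, 3)
  cc <- assemble_conductivity(lab, theta = 0, config = cfg)
  expect_equal(cc$Dxx[2, 2], cfg$D_l)
  expect_equal(cc$Dyy[2, 2], cfg$D_t)
  expect_equal(cc$Dxy[2, 2], 0)
  # isotropic conductivity is fiber-independent
  iso <- monodomain_config(sigma_t = vh_config()$sigma_l)
  c1 <- assemble_conductivity(lab, theta = 0.3, config = iso)
  c2 <- assemble_conductivity(lab, theta = 1.2, config = iso)
  expect_equal(c1$Dxx, c2$Dxx, tolerance = 1e-12)
  expect_equal(c1$Dxy, matrix(0, 3, 3), tolerance = 1e-12)
  # dense and background nodes carry zero tensors
  lab2 <- lab; lab2[1, 1] <- 3L; lab2[3, 3] <- 0L
  c3 <- assemble_conductivity(lab2, theta = 0, config = cfg)
  expect_equal(c3$Dxx[1, 1], 0)
  expect_equal(c3$Dxx[3, 3], 0)
  # non-unit fibers are rejected
  expect_error(assemble_conductivity(lab, config = cfg,
                                     fibers = matrix(2, 9, 2)), "unit")
})

test_that("unstimulated tissue is quiescent and stationary", {
  lab <- matrix(1L, 8, 8)
  cfg <- monodomain_config(dx_mm = 0.5, dt_ms = 0.045)
  rec <- simulate_monodomain(lab, cfg, stimuli = list(), duration = 1000,
                             stop_quiescent = FALSE)
  expect_true(all(rec$n_act == 0))
  v_final <- rec$state[1, ]
  expect_lt(max(abs(v_final - vh_config()$rest_state[1])), 0.01)
})

test_that("solution is invariant under grid-axis permutation", {
  lab <- matrix(1L, 14, 9)
  lab[5:7, 2:4] <- 3L
  cfg <- monodomain_config(dx_mm = 0.5, dt_ms = 0.045, cv_scale = 0.5)
  st <- list(list(nodes = c(1L, 2L, 15L, 16L), onset = 0, dur = 2, amp = -52))
  r1 <- simulate_monodomain(lab, cfg, st, duration = 80, theta = 0,
                            stop_quiescent = FALSE)
  # transpose the domain and swap the fiber axis accordingly
  labT <- t(lab)
  stT <- list(list(nodes = c(1L, 10L, 2L, 11L), onset = 0, dur = 2, amp = -52))
  r2 <- simulate_monodomain(labT, cfg, stT, duration = 80, theta = pi / 2,
                            stop_quiescent = FALSE)
  a1 <- matrix(first_activation(r1), 14, 9)
  a2 <- matrix(first_activation(r2), 9, 14)
  expect_equal(a1, t(a2), tolerance = 1e-9)
})

test_that("a planar wave activates linearly in distance", {
  cfg <- monodomain_config(dx_mm = 0.35, dt_ms = 0.02)
  nx <- 58; ny <- 9
  lab <- matrix(1L, nx, ny)
  stim <- list(list(nodes = as.integer(outer(1:2, (0:(ny - 1)) * nx, `+`)),
                    onset = 0, dur = 2, amp = -52))
  rec <- simulate_monodomain(lab, cfg, stim, duration = 120, theta = 0,
                             stop_quiescent = TRUE, min_run_ms = 10)
  cv <- measure_cv(rec, c(1, 0))
  expect_gt(cv$r_squared, 0.999)
  expect_gt(cv$cv_m_s, 0.3)
})

test_that("a point stimulus in an isotropic sheet gives circular isochrones", {
  iso <- monodomain_config(sigma_t = vh_config()$sigma_l,
                           dx_mm = 0.35, dt_ms = 0.02)
  n <- 41
  lab <- matrix(1L, n, n)
  ctr <- (n + 1) %/% 2
  nodes <- which((row(lab) - ctr)^2 + (col(lab) - ctr)^2 <= 4)
  rec <- simulate_monodomain(lab, iso,
    list(list(nodes = as.integer(nodes), onset = 0, dur = 2, amp = -52)),
    duration = 40, stop_quiescent = FALSE)
  ft <- matrix(first_activation(rec), n, n)
  # compare arrival times at equal distance along the two axes
  t_x <- ft[ctr + 15, ctr]; t_y <- ft[ctr, ctr + 15]
  expect_lt(abs(t_x - t_y) / max(t_x, t_y), 0.02)
  t_d <- ft[ctr + 11, ctr + 11]          # ~ same euclidean distance
  expect_lt(abs(t_d - t_x) / t_x, 0.15)  # modest lattice anisotropy allowed
})

test_that("dense scar is a no-flux barrier", {
  # two normal compartments separated by a dense wall: stimulating one
  # side must leave the other at rest
  lab <- matrix(1L, 21, 9)
  lab[11, ] <- 3L
  cfg <- monodomain_config(dx_mm = 0.5, dt_ms = 0.045, cv_scale = 0.5)
  stim <- list(list(nodes = as.integer(outer(1:2, (0:8) * 21, `+`)),
                    onset = 0, dur = 2, amp = -52))
  rec <- simulate_monodomain(lab, cfg, stim, duration = 150,
                             stop_quiescent = FALSE)
  ft <- matrix(first_activation(rec), 21, 9)
  expect_true(all(!is.na(ft[1:10, ])))   # paced side fully activates
  expect_true(all(is.na(ft[12:21, ])))   # far side never activates
  v_far <- matrix(rec$state[1, ], 21, 9)[12:21, ]
  expect_lt(max(abs(v_far - vh_config()$rest_state[1])), 0.01)
})

test_that("the CFL guard rejects unstable configurations", {
  lab <- matrix(1L, 6, 6)
  cfg <- monodomain_config(dx_mm = 0.1, dt_ms = 0.05)
  expect_error(simulate_monodomain(lab, cfg, duration = 1), "unstable")
})

test_that("remodeled tissue has a longer wavelength on a 1D cable", {
  cfg <- monodomain_config(dx_mm = 0.35, dt_ms = 0.02)
  cv_n <- planar_cv(cfg, TRUE, length_mm = 15, width_mm = 1, variant = "normal")
  cv_r <- planar_cv(cfg, TRUE, length_mm = 15, width_mm = 1,
                    variant = "remodeled")
  expect_lt(abs(cv_r - cv_n) / cv_n, 0.1)   # conduction barely changes
  wl_n <- cv_n * apd90(make_ionic_params("normal"), 1000, 20)
  wl_r <- cv_r * apd90(make_ionic_params("remodeled"), 1000, 20)
  expect_gt(wl_r, wl_n)                      # APD effect dominates
})
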