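test_that("seven pacing sites land on distinct endocardial sectors", {
  rg <- tiny_ring()
  lab <- rg$labels$labels[, , 1]
  sites <- place_pacing_sites(rg$labels)
  expect_length(sites, 7)
  expect_setequal(vapply(sites, `[[`, "", "sector"), vh_config()$aha_sectors)
  expect_true("mid anteroseptal" %in% vapply(sites, `[[`, "", "sector"))
  expect_true("basal inferolateral" %in% vapply(sites, `[[`, "", "sector"))
  # endocardial membership: each site node touches the cavity
  n <- nrow(lab)
  ctr <- (n + 1) / 2
  for (s in sites) {
    i <- ((s$node - 1) %% n) + 1; j <- ((s$node - 1) %/% n) + 1
    r <- sqrt((i - ctr)^2 + (j - ctr)^2) * 0.5
    expect_lt(r, 5.2)                      # at the inner wall (r_in = 4.1 mm)
    expect_equal(lab[s$node], 1L)
  }
  # distinct angular positions
  expect_equal(length(unique(vapply(sites, `[[`, 0, "node"))), 7L)
})

test_that("quiescent and echo-only records are not classified as reentry", {
  rec <- list(act = matrix(NA_real_, 5, 4), n_act = rep(0L, 4),
              t_end = 500, quiescent = TRUE, nx = 2, ny = 2,
              labels = matrix(1L, 2, 2))
  class(rec) <- "activation_record"
  expect_false(detect_reentry(rec, 100, 300)$induced)
  # one paced activation plus a single echo, then quiescence
  rec$act[1, ] <- c(110, 112, 114, 116)
  rec$act[2, ] <- c(300, 302, 304, 306)
  rec$n_act <- rep(2L, 4)
  expect_false(detect_reentry(rec, 100, 300)$induced)
  # truncated non-quiescent record is an error
  rec$quiescent <- FALSE
  rec$t_end <- 250
  expect_error(detect_reentry(rec, 100, 300), "observation window")
})

test_that("a cross-field rotor on a homogeneous sheet is detected", {
  n <- 61
  lab <- matrix(1L, n, n)
  cfg <- substrate_config(isotropic = TRUE)
  short <- make_ionic_params("normal", scale = c(g_Kr = 3, g_Ks = 3))
  left <- as.integer(outer(1:2, (0:(n - 1)) * n, `+`))
  lower <- which(col(lab) <= n / 2)
  stims <- list(list(nodes = left, onset = 0, dur = 2, amp = -52),
                list(nodes = lower, onset = 260, dur = 2, amp = -52))
  rec <- simulate_monodomain(lab, cfg, stims, duration = 1460,
                             params_normal = short, stop_quiescent = TRUE)
  det <- detect_reentry(rec, 262, 1100)
  expect_true(det$induced)
  expect_true(det$descriptor$cycle_length_ms > 100 &&
              det$descriptor$cycle_length_ms < 400)
  expect_true(det$descriptor$core_sector %in% vh_config()$aha_sectors)
})

test_that("morphology clustering groups identical cores and cycle lengths", {
  expect_equal(count_unique_morphologies(list()), 0L)
  d <- function(sec, cl) list(cycle_length_ms = cl, core_sector_index = sec)
  expect_equal(count_unique_morphologies(list(d(3, 400), d(3, 415))), 1L)
  expect_equal(count_unique_morphologies(list(d(1, 400), d(2, 400), d(5, 400))),
               3L)
  expect_equal(count_unique_morphologies(list(d(3, 400), d(3, 480))), 2L)
  # brute-force check on a random set: same-sector pairs within 10% merge
  set.seed(1)
  ds <- lapply(1:6, function(i) d(sample(1:2, 1), sample(c(300, 400), 1)))
  got <- count_unique_morphologies(ds)
  key <- unique(vapply(ds, function(x)
    paste(x$core_sector_index, x$cycle_length_ms), ""))
  expect_equal(got, length(key))
})

test_that("a protocol without extrastimuli never induces", {
  rg <- tiny_ring(arcs = list(list(center = pi / 2, half_width = pi / 4,
                                   label = 2L)))
  prot <- pacing_protocol(s1_count = 2, s1_cycle_ms = 450,
                          max_extrastimuli = 0, observe_ms = 300)
  cfg <- substrate_config()
  sites <- place_pacing_sites(rg$labels)
  r <- run_protocol(rg$labels, sites[[2]], prot, cfg, theta = rg$theta)
  expect_false(r$induced)
  expect_equal(r$n_trials, 0L)
})

test_that("induction is deterministic for identical substrate and protocol", {
  rg <- tiny_ring(arcs = list(list(center = pi / 2, half_width = pi / 4,
                                   label = 2L)))
  prot <- desk_pacing_protocol()
  cfg <- substrate_config()
  sites <- place_pacing_sites(rg$labels)
  r1 <- run_protocol(rg$labels, sites[[7]], prot, cfg, theta = rg$theta)
  r2 <- run_protocol(rg$labels, sites[[7]], prot, cfg, theta = rg$theta)
  expect_identical(r1$induced, r2$induced)
  expect_identical(r1$couplings_ms, r2$couplings_ms)
  expect_identical(r1$descriptor, r2$descriptor)
})
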