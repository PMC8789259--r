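make_slice <- function(n = 48, seed = 1, blob_frac = 0.15, blob_lift = 80) {
  set.seed(seed)
  intens <- matrix(rnorm(n * n, 100, 10), n, n)
  mask <- matrix(TRUE, n, n)
  blob <- matrix(FALSE, n, n)
  nb <- round(blob_frac * n * n)
  blob[seq_len(nb)] <- TRUE
  intens[blob] <- intens[blob] + blob_lift
  list(intens = intens, mask = mask, blob = blob)
}

test_that("remote statistics recover the low-intensity component", {
  s <- make_slice(seed = 2)
  rs <- estimate_remote_stats(s$intens, s$mask)
  truth <- c(mean(s$intens[!s$blob]), sd(s$intens[!s$blob]))
  expect_lt(abs(rs$mean - truth[1]), 2.5)
  expect_lt(abs(rs$sd - truth[2]), 2.5)
  # a slice with a small bright blob: remote stats track the 95% component
  s2 <- make_slice(seed = 3, blob_frac = 0.05)
  rs2 <- estimate_remote_stats(s2$intens, s2$mask)
  expect_lt(abs(rs2$mean - mean(s2$intens[!s2$blob])), 2.5)
  expect_error(estimate_remote_stats(matrix(5, 30, 30), matrix(TRUE, 30, 30)),
               "degenerate")
  expect_error(estimate_remote_stats(matrix(rnorm(64), 8, 8),
                                     matrix(TRUE, 8, 8)), "100")
})

test_that("LGE classification follows the SD-threshold rule", {
  rs <- structure(list(mean = 100, sd = 10), class = "remote_stats")
  thr <- personalized_thresholds(3, 5)
  intens <- array(c(100, 140, 155, 129.9, 150.0001, 131), c(6, 1, 1))
  stack <- structure(list(intensities = intens,
                          lv_mask = array(TRUE, c(6, 1, 1)),
                          spacing = c(2, 8), slice_z = 0),
                     class = "lge_stack")
  lab <- classify_lge(stack, rs, thr)$labels
  # mean + 4 sd -> diffuse; exactly at mean -> normal; > 5 sd -> dense
  expect_equal(as.integer(lab), c(1L, 2L, 3L, 1L, 3L, 2L))
})

test_that("classified fractions equal brute-force voxel counting", {
  set.seed(9)
  n <- 40
  intens <- array(rnorm(n * n * 3, 100, 15), c(n, n, 3))
  mask <- array(TRUE, c(n, n, 3))
  stack <- structure(list(intensities = intens, lv_mask = mask,
                          spacing = c(2, 8), slice_z = c(0, 8, 16)),
                     class = "lge_stack")
  rs <- structure(list(mean = 100, sd = 15), class = "remote_stats")
  thr <- personalized_thresholds(0.5, 1.2)
  fr <- quantify_fibrosis(classify_lge(stack, rs, thr))
  expect_equal(fr$dense_pct, 100 * mean(intens > 100 + 1.2 * 15))
  expect_equal(fr$diffuse_pct,
               100 * mean(intens > 100 + 0.5 * 15 & intens <= 100 + 1.2 * 15))
})

test_that("T1 classification uses the relaxation-time bands", {
  tm <- matrix(c(349, 350, 450, 451, 500, 349.99), 6, 1)
  t1 <- structure(list(times_ms = tm, lv_mask = matrix(TRUE, 6, 1),
                       spacing = c(1.5, 8), slice_z = 32),
                  class = "t1_map")
  expect_equal(as.integer(classify_t1(t1)), c(3L, 2L, 2L, 1L, 1L, 3L))
  t1$times_ms[2] <- -1
  expect_error(classify_t1(t1), "positive")
})

test_that("slice matching picks the nearest z with lower-index ties", {
  stack <- structure(list(intensities = array(0, c(2, 2, 11)),
                          lv_mask = array(TRUE, c(2, 2, 11)),
                          spacing = c(2, 8), slice_z = seq(0, 80, by = 8)),
                     class = "lge_stack")
  t1 <- structure(list(times_ms = matrix(500, 2, 2),
                       lv_mask = matrix(TRUE, 2, 2),
                       spacing = c(1.5, 8), slice_z = 40),
                  class = "t1_map")
  expect_equal(match_slice(stack, t1), 6L)       # z = 40 is slice 6 (1-based)
  t1$slice_z <- 36                               # tie between 32 and 40
  expect_equal(match_slice(stack, t1), 5L)
  t1$slice_z <- 40.9                             # nearest-neighbour robustness
  expect_equal(match_slice(stack, t1), 6L)
  t1$slice_z <- 300
  expect_error(match_slice(stack, t1), "z-range")
})

test_that("threshold transfer reproduces the T1 fractions on the matching slice", {
  spec <- synthetic_cohort_spec(seed = 21)
  pair <- generate_lge_t1_pair(spec)
  k <- match_slice(pair$lge, pair$t1)
  rs <- estimate_remote_stats(pair$lge$intensities[, , k], pair$lge$lv_mask[, , k])
  thr <- derive_personalized_thresholds(pair$lge, rs, pair$t1)
  expect_lt(thr$t_diffuse, thr$t_dense)
  lab <- classify_lge(pair$lge, rs, thr)
  got <- quantify_fibrosis(lab$labels[, , k])
  want <- virtuheart:::t1_fractions_on_lge_grid(pair$lge, pair$t1)
  one_voxel <- 100 / sum(pair$lge$lv_mask[, , k])
  expect_lt(abs(got$dense_pct - 100 * want[["dense"]]), one_voxel + 1e-9)
  expect_lt(abs(got$diffuse_pct - 100 * want[["diffuse"]]), 2 * one_voxel + 1e-9)
})

test_that("fixed (3,5) thresholds reproduce the LGE-only pipeline exactly", {
  spec <- synthetic_cohort_spec(seed = 22)
  pair <- generate_lge_t1_pair(spec)
  rs <- remote_stats_by_slice(pair$lge)
  a <- apply_thresholds_to_stack(pair$lge, rs, personalized_thresholds(3, 5))
  b <- fuse_lge_t1(pair$lge, mode = "lge_only")
  expect_identical(a$labels, b$labels$labels)
})

test_that("diffuse burden is monotone non-increasing in the diffuse threshold", {
  spec <- synthetic_cohort_spec(seed = 23)
  pair <- generate_lge_t1_pair(spec)
  rs <- remote_stats_by_slice(pair$lge)
  d_at <- function(t) quantify_fibrosis(
    apply_thresholds_to_stack(pair$lge, rs,
                              personalized_thresholds(t, 8)))$diffuse_pct
  vals <- vapply(c(0.5, 1.5, 2.5, 3.5), d_at, numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("a stack of copies of the matching slice has uniform fractions", {
  spec <- synthetic_cohort_spec(seed = 24)
  pair <- generate_lge_t1_pair(spec)
  k <- match_slice(pair$lge, pair$t1)
  n_slices <- dim(pair$lge$intensities)[3]
  stack <- pair$lge
  for (j in seq_len(n_slices)) {
    stack$intensities[, , j] <- pair$lge$intensities[, , k]
    stack$lv_mask[, , j] <- pair$lge$lv_mask[, , k]
  }
  rs1 <- estimate_remote_stats(stack$intensities[, , k], stack$lv_mask[, , k])
  rs <- rep(list(rs1), n_slices)
  thr <- derive_personalized_thresholds(stack, rs1, pair$t1)
  lab <- classify_lge(stack, rs, thr)
  per_slice <- vapply(seq_len(n_slices), function(j)
    quantify_fibrosis(lab$labels[, , j])$diffuse_pct, numeric(1))
  expect_true(all(abs(per_slice - per_slice[k]) < 1e-12))
})
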