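test_that("cohort spec validates its invariants", {
  expect_error(synthetic_cohort_spec(dense_fraction = 0.6, diffuse_fraction = 0.5),
               "< 1")
  expect_error(synthetic_cohort_spec(dense_fraction = -0.1), "fractions")
  expect_error(synthetic_cohort_spec(correlation_length_mm = 0), "positive")
  expect_error(synthetic_cohort_spec(t1_remote_ms = 400), "450")
})

test_that("generated label fractions match the requested fractions", {
  spec <- synthetic_cohort_spec(diffuse_fraction = 0.40, dense_fraction = 0.04,
                                seed = 1)
  pair <- generate_lge_t1_pair(spec)
  fr <- pair$truth$fractions
  expect_lt(abs(fr[["diffuse"]] - 0.40), 0.02)
  expect_lt(abs(fr[["dense"]] - 0.04), 0.02)
  # geometry and metadata
  expect_gte(dim(pair$lge$intensities)[3], 8)
  expect_equal(unname(pair$lge$spacing), c(2, 8))
  expect_equal(unname(pair$t1$spacing), c(1.5, 8))
  expect_true(all(pair$lge$lv_mask[pair$labels$labels > 0]))
})

test_that("empty substrate gives all-normal labels inside the LV mask", {
  spec <- synthetic_cohort_spec(dense_fraction = 0, diffuse_fraction = 0,
                                noise_sd = 0, seed = 2)
  pair <- generate_lge_t1_pair(spec)
  lab <- pair$labels$labels
  expect_true(all(lab[pair$lge$lv_mask] == 1L))
  expect_true(all(lab[!pair$lge$lv_mask] == 0L))
})

test_that("generation is deterministic for a fixed seed", {
  spec <- synthetic_cohort_spec(seed = 7)
  a <- generate_lge_t1_pair(spec)
  b <- generate_lge_t1_pair(spec)
  expect_identical(a$lge$intensities, b$lge$intensities)
  expect_identical(a$t1$times_ms, b$t1$times_ms)
  expect_identical(a$labels$labels, b$labels$labels)
})

test_that("noise-free T1 times reverse the rank order of LGE intensities", {
  spec <- synthetic_cohort_spec(noise_sd = 0, seed = 11)
  pair <- generate_lge_t1_pair(spec)
  k <- pair$truth$mid_slice
  # nearest-neighbour map from T1 pixels back to LGE voxels
  n_l <- dim(pair$lge$intensities)[1]; n_t <- nrow(pair$t1$times_ms)
  c_l <- (n_l + 1) / 2; c_t <- (n_t + 1) / 2
  src <- pmin(pmax(round(((seq_len(n_t) - c_t) * 1.5) / 2 + c_l), 1), n_l)
  lge_on_t1 <- pair$lge$intensities[src, src, k]
  m <- pair$t1$lv_mask
  expect_equal(order(pair$t1$times_ms[m]),
               order(-lge_on_t1[m]))
})

test_that("substrate phantoms have the advertised structure", {
  hom <- generate_substrate_phantom("homogeneous")
  expect_true(all(hom$labels == 1L))

  sc <- generate_substrate_phantom("scar_isthmus")
  lab <- sc$labels[, , 1]
  expect_equal(count_components(lab == 3L), 2L)
  expect_true(all(lab[lab != 3L] == 1L))   # normal channel by default

  scd <- generate_substrate_phantom("scar_isthmus", channel = "diffuse")
  expect_gt(sum(scd$labels == 2L), 0)

  dp <- generate_substrate_phantom("diffuse_patch", dims = c(64L, 64L))
  fr <- quantify_fibrosis(dp)
  expect_lt(abs(fr$diffuse_pct - 36.2), 1.5)
  expect_equal(count_components(dp$labels[, , 1] == 2L), 1L)

  expect_error(generate_substrate_phantom("nope"), "arg")
})

test_that("cohort outcome fixture encodes the study counts", {
  fx <- cohort_outcomes_fixture()
  expect_equal(nrow(fx), 26L)
  expect_equal(sum(fx$clinical_va), 13L)
  expect_equal(sum(fx$lge_t1), 14L)
  expect_equal(sum(fx$lge_t1 & fx$clinical_va), 11L)
  expect_equal(sum(fx$lge_only), 12L)
  expect_equal(sum(fx$lge_only & fx$clinical_va), 9L)
  expect_equal(sum(fx$accf_aha & fx$clinical_va), 6L)
  expect_equal(sum(fx$esc & fx$clinical_va), 7L)
})

test_that("paired ring substrates nest their diffuse regions", {
  pr <- generate_substrate_pair(seed = 5)
  b <- pr$base$labels; e <- pr$enriched$labels
  expect_identical(b > 0L, e > 0L)              # same myocardium
  expect_true(all(e[b == 2L] == 2L))            # enriched superset
  expect_lt(pr$diffuse_pct[["base"]], 15)
  expect_gt(pr$diffuse_pct[["enriched"]], 30)
  # the base speckle count matches the requested fraction
  expect_equal(sum(b == 2L), round(0.09 * sum(b > 0L)))
})

test_that("NIfTI export writes voxel spacing and survives a round trip", {
  dir <- withr::local_tempdir()
  spec <- synthetic_cohort_spec(seed = 4)
  pair <- generate_lge_t1_pair(spec)
  paths <- write_lge_t1_nifti(pair, dir)
  img <- RNifti::readNifti(paths[1])
  expect_equal(RNifti::pixdim(img), c(2, 2, 8))
  expect_equal(as.array(img), pair$lge$intensities, ignore_attr = TRUE,
               tolerance = 1e-6)
  lab <- RNifti::readNifti(paths[5])
  expect_equal(as.array(lab), pair$labels$labels + 0, ignore_attr = TRUE)
})
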