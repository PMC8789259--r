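test_that("grid construction hits the target resolution arithmetic", {
  lab <- structure(list(labels = array(1L, c(10, 10, 1)),
                        spacing = c(inplane_mm = 2, slice_mm = 8)),
                   class = "tissue_labels")
  g <- build_grid(lab, target_resolution_um = 355)
  k <- round(2000 / 355)                       # 6 subdivisions per voxel
  expect_equal(g$nx, 10 * k)
  expect_equal(g$ny, 10 * k)
  expect_equal(g$nx * g$ny, 3600L)
  expect_equal(g$dx_mm, 2 / k)
  # mean edge length within 20% of the requested 355 um
  expect_lt(abs(g$dx_mm * 1000 - 355) / 355, 0.20)
  expect_error(build_grid(lab, target_resolution_um = -1), "positive")
})

test_that("dense-only label maps yield fully non-conducting grids", {
  lab <- structure(list(labels = array(3L, c(4, 4, 1)),
                        spacing = c(inplane_mm = 2, slice_mm = 8)),
                   class = "tissue_labels")
  g <- build_grid(lab, 500)
  expect_true(all(!g$conducting))
})

test_that("Laplace solution is exact on a 1D rod and a uniform slab", {
  lab <- matrix(1L, 12, 1); attr(lab, "spacing_mm") <- 1
  g <- build_grid(lab, 1000)
  left <- 1 + g$nnx * (0:(g$nny - 1))
  right <- g$nnx + g$nnx * (0:(g$nny - 1))
  sol <- matrix(solve_laplace(g, list(left, right), c(0, 1)), g$nnx, g$nny)
  expect_equal(sol[7, 1], 0.5, tolerance = 1e-12)
  expect_lt(max(abs(sol[, 1] - seq(0, 1, length.out = g$nnx))), 1e-6)

  # slab: endo = bottom row, epi = top row -> linear transmural field
  slab <- matrix(1L, 8, 6); attr(slab, "spacing_mm") <- 1
  gs <- build_grid(slab, 1000)
  bottom <- seq_len(gs$nnx)
  top <- seq_len(gs$nnx) + gs$nnx * (gs$nny - 1)
  f <- matrix(solve_laplace(gs, list(bottom, top), c(0, 1)), gs$nnx, gs$nny)
  want <- matrix(rep(seq(0, 1, length.out = gs$nny), each = gs$nnx),
                 gs$nnx, gs$nny)
  expect_lt(max(abs(f - want)), 1e-6)
})

test_that("Laplace solver matches a dense direct-solve oracle", {
  set.seed(42)
  for (rep in 1:5) {
    nx <- sample(4:8, 1); ny <- sample(4:8, 1)
    lab <- matrix(1L, nx, ny)
    lab[sample(nx * ny, round(0.15 * nx * ny))] <- 3L   # random scar holes
    attr(lab, "spacing_mm") <- 1
    g <- build_grid(lab, 1000)
    act <- which(virtuheart:::grid_active_nodes(g))
    b1 <- act[seq_len(3)]
    b2 <- act[seq(length(act) - 2, length(act))]
    got <- try(solve_laplace(g, list(b1, b2), c(0, 1)), silent = TRUE)
    if (inherits(got, "try-error")) next   # disconnected draw: checked below
    want <- dense_laplace_oracle(g, list(b1, b2), c(0, 1))
    expect_lt(max(abs(got - want), na.rm = TRUE), 1e-8)
  }
})

test_that("Laplace solutions obey the discrete maximum principle", {
  set.seed(7)
  for (rep in 1:20) {
    nx <- sample(5:9, 1); ny <- sample(5:9, 1)
    lab <- matrix(1L, nx, ny); attr(lab, "spacing_mm") <- 1
    g <- build_grid(lab, 1000)
    nn <- g$nnx * g$nny
    bnodes <- sample(nn, 6)
    vals <- runif(2, -5, 5)
    sol <- solve_laplace(g, list(bnodes[1:3], bnodes[4:6]), vals)
    expect_true(all(sol >= min(vals) - 1e-10 & sol <= max(vals) + 1e-10))
  }
})

test_that("disconnected conducting components without a boundary error out", {
  lab <- matrix(1L, 9, 3)
  lab[5, ] <- 3L                              # scar wall splits the rod
  attr(lab, "spacing_mm") <- 1
  g <- build_grid(lab, 1000)
  left <- 1 + g$nnx * (0:(g$nny - 1))
  expect_error(solve_laplace(g, list(left[1:2], left[3]), c(0, 1)),
               "no Dirichlet boundary")
})

test_that("fiber angles interpolate between the surface helix angles", {
  slab <- matrix(1L, 10, 9); attr(slab, "spacing_mm") <- 1
  g <- build_grid(slab, 1000)
  bottom <- seq_len(g$nnx)
  top <- seq_len(g$nnx) + g$nnx * (g$nny - 1)
  tm <- solve_laplace(g, list(bottom, top), c(0, 1))
  ff <- assign_fibers(g, tm, angle_endo_deg = 60, angle_epi_deg = -60)
  # boundary rows: depth ~ 1/16 from the surface (element centroids)
  d <- ff$depth
  expect_equal(ff$angle_deg, 60 * (1 - d) + (-60) * d, tolerance = 1e-9)
  mid <- which(abs(d - 0.5) < 1e-9)
  expect_true(length(mid) > 0)
  expect_equal(ff$angle_deg[mid], rep(0, length(mid)), tolerance = 1e-9)
  # unit norm and orthogonality to the transmural gradient
  nrm <- sqrt(rowSums(ff$fibers^2))
  expect_lt(max(abs(nrm - 1)), 1e-9)
  dots <- rowSums(ff$fibers * ff$normal)
  expect_lt(max(abs(dots)), 1e-6)
})

test_that("fiber field rotates with the geometry", {
  # slab with transmural gradient along +y, and the same slab rotated by
  # +90 degrees (gradient along -x); fibers must rotate with it
  slab <- matrix(1L, 10, 8); attr(slab, "spacing_mm") <- 1
  g <- build_grid(slab, 1000)
  tm <- outer(rep(1, g$nnx), seq(0, 1, length.out = g$nny))
  ff <- assign_fibers(g, as.vector(tm))

  slab2 <- matrix(1L, 8, 10); attr(slab2, "spacing_mm") <- 1
  g2 <- build_grid(slab2, 1000)
  tm2 <- outer(seq(1, 0, length.out = g2$nnx), rep(1, g2$nny))
  ff2 <- assign_fibers(g2, as.vector(tm2))

  rot90 <- function(v) c(-v[2], v[1], v[3])
  # compare elements at exactly matching transmural depths
  for (d in unique(round(ff$depth, 9))) {
    e1 <- which(abs(ff$depth - d) < 1e-9)[1]
    e2 <- which(abs(ff2$depth - d) < 1e-9)[1]
    expect_false(is.na(e2))
    expect_lt(max(abs(ff2$fibers[e2, ] - rot90(ff$fibers[e1, ]))), 1e-9)
  }
})
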