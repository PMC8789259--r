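## Synthetic LGE-CMR / postcontrast-T1 image pairs, substrate phantoms,
## and the cohort-outcome fixture.  Everything is seeded and generated in
## code so the downstream pipeline is testable without patient data.

#' Specification for a synthetic LGE/T1 patient
#'
#' Defaults emulate the cohort means of the study conditions: diffuse
#' fibrosis 40.5% and dense fibrosis (scar) 3.8% of the LV myocardium,
#' spatially correlated fibrotic texture, and a postcontrast T1
#' relaxation time above 450 ms in remote myocardium.
#'
#' @param n_patients Number of patients in the emulated cohort.
#' @param dense_fraction Fraction of LV myocardium that is dense fibrosis.
#' @param diffuse_fraction Fraction that is diffuse fibrosis.
#' @param correlation_length_mm Spatial correlation length of the
#'   fibrosis texture (mm).
#' @param noise_sd Measurement noise, in units of the remote-myocardium
#'   intensity SD.
#' @param t1_remote_ms Postcontrast T1 of remote myocardium (> 450 ms).
#' @param seed Integer seed; every stochastic operation uses it.
#' @return List of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_patients = 26L,
                                  dense_fraction = 0.038,
                                  diffuse_fraction = 0.405,
                                  correlation_length_mm = 8,
                                  noise_sd = 0.5,
                                  t1_remote_ms = 550,
                                  seed = 1L) {
  if (dense_fraction < 0 || dense_fraction >= 1 ||
      diffuse_fraction < 0 || diffuse_fraction >= 1)
    stop("fibrosis fractions must lie in [0, 1)")
  if (dense_fraction + diffuse_fraction >= 1)
    stop("dense_fraction + diffuse_fraction must be < 1")
  if (correlation_length_mm <= 0) stop("correlation_length_mm must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (t1_remote_ms <= 450) stop("t1_remote_ms must exceed 450 ms")
  structure(list(n_patients = as.integer(n_patients),
                 dense_fraction = dense_fraction,
                 diffuse_fraction = diffuse_fraction,
                 correlation_length_mm = correlation_length_mm,
                 noise_sd = noise_sd,
                 t1_remote_ms = t1_remote_ms,
                 seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

# periodic Gaussian smoothing of a 2D field via FFT
gaussian_smooth_fft <- function(x, sigma_px) {
  n1 <- nrow(x); n2 <- ncol(x)
  f1 <- c(0:floor(n1 / 2), -(ceiling(n1 / 2) - 1):-1) / n1
  f2 <- c(0:floor(n2 / 2), -(ceiling(n2 / 2) - 1):-1) / n2
  H <- exp(-2 * pi^2 * sigma_px^2 * outer(f1^2, f2^2, `+`))
  Re(fft(fft(x) * H, inverse = TRUE)) / (n1 * n2)
}

#' Generate a synthetic short-axis LGE stack with a matched T1 map
#'
#' Builds an annular left-ventricular short-axis stack (truncated-taper
#' geometry) on a 2-mm in-plane / 8-mm slice grid, with remote-myocardium
#' intensity texture N(100, 10^2) plus spatially correlated hyperintense
#' fibrotic regions from a thresholded Gaussian random field.  A single
#' mid-ventricular postcontrast T1 map (1.5-mm in-plane) is derived from
#' the same underlying field through a strictly decreasing piecewise-linear
#' transform (more contrast retention, i.e. brighter LGE, means shorter
#' T1), with independent noise.  Ground-truth labels use the noiseless
#' intensity quantiles matching the requested fractions, so dense voxels
#' are the brightest/shortest-T1 tissue.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @param n_slices Number of short-axis slices (>= 8).
#' @param fov_mm In-plane field of view (mm).
#' @return List with `lge` (class `lge_stack`: `intensities`, `lv_mask`,
#'   `spacing`, `slice_z`), `t1` (class `t1_map`: `times_ms`, `lv_mask`,
#'   `spacing`, `slice_z`), `labels` (class `tissue_labels`: integer array,
#'   0 background / 1 normal / 2 diffuse / 3 dense), and `truth`
#'   (generator ground truth: remote mean/sd, noiseless fields, realized
#'   fractions).
#' @export
generate_lge_t1_pair <- function(spec, n_slices = 10L, fov_mm = 128) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"), n_slices >= 8)
  set.seed(spec$seed)
  dpx <- 2                       # LGE in-plane resolution, mm
  dz <- 8                        # slice spacing, mm
  n <- round(fov_mm / dpx)
  cx <- (n + 1) / 2
  remote_mean <- 100; remote_sd <- 10

  # annular LV geometry, tapering toward the apex (slice 1)
  r_base <- 0.44 * fov_mm / 2
  wall <- 9
  xs <- (seq_len(n) - cx) * dpx
  rr <- sqrt(outer(xs^2, xs^2, `+`))
  mask <- array(FALSE, c(n, n, n_slices))
  r_out <- numeric(n_slices)
  for (k in seq_len(n_slices)) {
    r_out[k] <- r_base * sqrt((k + 1) / (n_slices + 1))
    r_in <- max(r_out[k] - wall, 2)
    mask[, , k] <- rr <= r_out[k] & rr > r_in
  }

  # spatially correlated fibrosis field: per-slice smoothed white noise
  # with AR(1) coupling across slices
  sig_px <- spec$correlation_length_mm / (2 * dpx)
  rho <- exp(-dz / spec$correlation_length_mm)
  g <- array(0, c(n, n, n_slices))
  prev <- gaussian_smooth_fft(matrix(rnorm(n * n), n, n), sig_px)
  g[, , 1] <- prev
  for (k in seq_len(n_slices)[-1]) {
    e <- gaussian_smooth_fft(matrix(rnorm(n * n), n, n), sig_px)
    prev <- rho * prev + sqrt(1 - rho^2) * e
    g[, , k] <- prev
  }
  g <- (g - mean(g[mask])) / sd(g[mask])

  # noiseless intensity: remote texture plus a ramp above the fibrosis
  # onset quantile, scaled so dense tissue starts ~6 remote-SD up
  f_d <- spec$dense_fraction; f_f <- spec$diffuse_fraction
  q_f <- if (f_d + f_f > 0) quantile(g[mask], 1 - f_d - f_f, names = FALSE) else Inf
  ramp <- pmax(g - q_f, 0)
  gain <- 0
  if (f_d + f_f > 0) {
    q_d_g <- if (f_d > 0) quantile(g[mask], 1 - f_d, names = FALSE) else
      max(g[mask]) * 1.001
    gain <- 6 * remote_sd / max(q_d_g - q_f, 1e-6)
  }
  i0 <- remote_mean + remote_sd * array(rnorm(n * n * n_slices), dim(g)) +
    gain * ramp
  i0[!mask] <- 0

  # ground-truth labels from noiseless-intensity quantiles
  lab <- array(0L, dim(g))
  lab[mask] <- 1L
  c_f <- if (f_d + f_f > 0) quantile(i0[mask], 1 - f_d - f_f, names = FALSE) else Inf
  c_d <- if (f_d > 0) quantile(i0[mask], 1 - f_d, names = FALSE) else Inf
  lab[mask & i0 > c_f] <- 2L
  lab[mask & i0 > c_d] <- 3L

  lge_int <- i0 + remote_sd * spec$noise_sd * array(rnorm(length(i0)), dim(i0))
  lge_int[!mask] <- 0
  slice_z <- (seq_len(n_slices) - 1) * dz

  # T1 map: mid-ventricular slice on a 1.5-mm grid, nearest-neighbour
  # sampled from the underlying noiseless field, then a strictly
  # decreasing piecewise-linear transform plus independent noise
  k_mid <- as.integer(ceiling(n_slices / 2))
  dpx_t1 <- 1.5
  n_t1 <- floor(fov_mm / dpx_t1)
  ct <- (n_t1 + 1) / 2
  src_idx <- pmin(pmax(round(((seq_len(n_t1) - ct) * dpx_t1) / dpx + cx), 1), n)
  i0_t1 <- i0[src_idx, src_idx, k_mid]
  mask_t1 <- mask[src_idx, src_idx, k_mid]

  i_min <- min(i0[mask])
  t1_of <- t1_transform(spec$t1_remote_ms, i_min, c_f, c_d)
  times <- t1_of(i0_t1)
  times <- times + 20 * spec$noise_sd * matrix(rnorm(length(times)), n_t1, n_t1)
  times[!mask_t1] <- 0
  times[mask_t1] <- pmax(times[mask_t1], 50)

  lge <- structure(list(intensities = lge_int, lv_mask = mask,
                        spacing = c(inplane_mm = dpx, slice_mm = dz),
                        slice_z = slice_z),
                   class = "lge_stack")
  t1 <- structure(list(times_ms = times, lv_mask = mask_t1,
                       spacing = c(inplane_mm = dpx_t1, slice_mm = dz),
                       slice_z = slice_z[k_mid]),
                  class = "t1_map")
  labels <- structure(list(labels = lab,
                           spacing = c(inplane_mm = dpx, slice_mm = dz)),
                      class = "tissue_labels")
  truth <- list(remote_mean = remote_mean, remote_sd = remote_sd,
                noiseless = i0, noiseless_t1 = t1_of(i0_t1),
                mid_slice = k_mid,
                fractions = c(diffuse = mean(lab[mask] == 2L),
                              dense = mean(lab[mask] == 3L)))
  list(lge = lge, t1 = t1, labels = labels, truth = truth)
}

# strictly decreasing piecewise-linear intensity -> T1 transform with the
# diffuse band [350, 450] ms anchored at the generating thresholds
t1_transform <- function(t1_remote, i_min, c_f, c_d) {
  if (!is.finite(c_f)) {
    # no fibrosis: stay above 450 ms
    force(t1_remote); force(i_min)
    return(function(x) t1_remote - pmax(x - i_min, 0) * 0.05)
  }
  s1 <- (t1_remote - 450) / max(c_f - i_min, 1e-6)
  s2 <- if (is.finite(c_d)) (450 - 350) / max(c_d - c_f, 1e-6) else s1
  function(x) {
    y <- ifelse(x <= c_f, t1_remote - s1 * (x - i_min),
                450 - s2 * (x - c_f))
    y
  }
}

#' Substrate phantoms for the electrophysiological pipeline
#'
#' Small 2D tissue label maps at simulation resolution:
#' \describe{
#'   \item{homogeneous}{All-normal sheet.}
#'   \item{scar_isthmus}{Two inexcitable dense blocks separated by a
#'     conducting channel (protected isthmus); the channel is normal
#'     tissue by default or diffuse-fibrosis (remodeled) tissue with
#'     `channel = "diffuse"`.}
#'   \item{diffuse_patch}{A contiguous central diffuse region covering
#'     `patch_fraction` of the sheet.}
#' }
#'
#' @param kind Phantom type.
#' @param dims Grid dimensions (nodes), `c(nx, ny)`.
#' @param spacing_mm Node spacing (mm).
#' @param channel Tissue class of the isthmus channel.
#' @param patch_fraction Target diffuse area fraction for
#'   `diffuse_patch`.
#' @return A `tissue_labels` object whose `labels` field is an
#'   `nx x ny x 1` integer array.
#' @export
generate_substrate_phantom <- function(kind = c("homogeneous", "scar_isthmus",
                                                "diffuse_patch"),
                                       dims = c(45L, 45L), spacing_mm = 0.5,
                                       channel = c("normal", "diffuse"),
                                       patch_fraction = 0.362) {
  kind <- match.arg(kind)
  channel <- match.arg(channel)
  nx <- dims[1]; ny <- dims[2]
  lab <- matrix(1L, nx, ny)
  if (kind == "scar_isthmus") {
    # channel mouth opens toward the right boundary, flanked by side
    # corridors, so the paced premature beat reaches the isthmus while
    # still premature
    x0 <- round(nx * 0.25); x1 <- round(nx * 0.80)
    ymid <- round(ny / 2) + 1L
    hw <- max(2L, round(1 / spacing_mm))          # channel half-width
    sh <- max(3L, round(3.5 / spacing_mm))        # scar thickness
    lab[x0:x1, (ymid + hw + 1):(ymid + hw + sh)] <- 3L
    lab[x0:x1, (ymid - hw - sh):(ymid - hw - 1)] <- 3L
    if (channel == "diffuse")
      lab[x0:x1, (ymid - hw):(ymid + hw)] <- 2L
  } else if (kind == "diffuse_patch") {
    stopifnot(patch_fraction > 0, patch_fraction < 1)
    xs <- seq_len(nx) - (nx + 1) / 2
    ys <- seq_len(ny) - (ny + 1) / 2
    r2 <- outer(xs^2, ys^2, `+`)
    r_target <- sqrt(patch_fraction * nx * ny / pi)
    lab[r2 <= r_target^2] <- 2L
  }
  structure(list(labels = array(lab, c(nx, ny, 1L)),
                 spacing = c(inplane_mm = spacing_mm, slice_mm = spacing_mm)),
            class = "tissue_labels")
}

#' Annular ring substrate with fibrotic arcs
#'
#' Mid-wall short-axis ring (circumferential fibers) carrying angular
#' arcs of dense or diffuse fibrosis — the minimal 2D geometry that
#' supports anatomical reentry around the cavity.
#'
#' @param arcs List of arcs: `list(center, half_width, label,
#'   outer_only)` with angles in radians, labels 2 (diffuse) or 3
#'   (dense); `outer_only` restricts the arc to the outer half-wall.
#' @param n Grid size (nodes per side).
#' @param r_out,r_in Outer/inner ring radius (mm).
#' @param spacing_mm Node spacing (mm).
#' @return List with `labels` (a `tissue_labels`) and `theta` (the
#'   circumferential fiber-angle matrix, radians).
#' @export
ring_substrate <- function(arcs = list(), n = 31L, r_out = 6.6, r_in = 4.1,
                           spacing_mm = 0.5) {
  ctr <- (n + 1) / 2
  ij <- arrayInd(seq_len(n * n), c(n, n))
  x <- (ij[, 1] - ctr) * spacing_mm
  y <- (ij[, 2] - ctr) * spacing_mm
  r <- sqrt(x^2 + y^2)
  a <- atan2(y, x)
  lab <- matrix(0L, n, n)
  lab[r <= r_out & r > r_in] <- 1L
  rmid <- (r_out + r_in) / 2
  for (arc in arcs) {
    d <- atan2(sin(a - arc$center), cos(a - arc$center))
    sel <- lab != 0L & abs(d) <= arc$half_width
    if (isTRUE(arc$outer_only)) sel <- sel & r > rmid
    lab[sel] <- as.integer(arc$label)
  }
  list(labels = structure(list(labels = array(lab, c(n, n, 1L)),
                               spacing = c(inplane_mm = spacing_mm,
                                           slice_mm = spacing_mm)),
                          class = "tissue_labels"),
       theta = matrix(a + pi / 2, n, n))
}

#' Paired ring substrates differing only in diffuse-fibrosis burden
#'
#' Generates a matched pair of ring substrates for the substrate-level
#' comparison of LGE-only-like versus LGE-T1-like diffuse-fibrosis
#' burdens.  Both substrates share an identical speckle of scattered
#' single-node diffuse fibrosis (~9% of the myocardium, the burden a
#' fixed 3/5-SD segmentation reports); speckle this fine is smoothed
#' electrotonically and creates no coherent repolarization gradient.
#' The enriched substrate adds coherent diffuse arcs on top (total
#' ~40%, the burden revealed by T1-personalized thresholds), whose
#' edges are the repolarization gradients where premature beats block.
#' The enriched diffuse region is a strict superset of the base one, so
#' the pair isolates the effect of adding contiguous diffuse fibrosis —
#' reflecting that it is the distribution of diffuse fibrosis, more
#' than its amount, that creates the arrhythmogenic substrate.
#'
#' @param seed Integer seed.
#' @param n_arcs Number of coherent diffuse arcs in the enriched
#'   substrate.
#' @param arc_half_width_deg Angular half-width of each arc.
#' @param speckle_frac Scattered diffuse fraction shared by both.
#' @return List with `base`, `enriched` (each a `tissue_labels`),
#'   `seed`, and the realized diffuse percentages.
#' @export
generate_substrate_pair <- function(seed, n_arcs = 9L,
                                    arc_half_width_deg = 12,
                                    speckle_frac = 0.09) {
  set.seed(seed)
  hw <- arc_half_width_deg * pi / 180
  cen <- (runif(1, -pi, pi) + (0:(n_arcs - 1)) * 2 * pi / n_arcs +
            rnorm(n_arcs, 0, 0.06)) %% (2 * pi) - pi
  base <- ring_substrate()
  lab_b <- base$labels$labels[, , 1]
  myo <- which(lab_b == 1L)
  spk <- sample(myo, round(speckle_frac * length(myo)))
  lab_b[spk] <- 2L
  enriched <- ring_substrate(lapply(cen, function(ct)
    list(center = ct, half_width = hw, label = 2L)))
  lab_e <- enriched$labels$labels[, , 1]
  lab_e[spk] <- 2L
  wrap <- function(m) structure(
    list(labels = array(m, c(nrow(m), ncol(m), 1L)),
         spacing = base$labels$spacing),
    class = "tissue_labels")
  pct <- function(m) 100 * mean(m[m > 0] == 2L)
  list(base = wrap(lab_b), enriched = wrap(lab_e), seed = seed,
       diffuse_pct = c(base = pct(lab_b), enriched = pct(lab_e)))
}

#' Cohort outcome fixture (26 patients)
#'
#' Per-patient clinical ventricular-arrhythmia outcome together with the
#' at-risk verdicts of the two clinical risk scores (ACCF/AHA, ESC) and
#' of the two virtual-heart model variants (LGE-T1 fusion, LGE only),
#' encoding the prediction counts of the study cohort: 13 of 26 patients
#' with clinical VA; 14 LGE-T1 models inducible of which 11 with
#' clinical VA; 12 LGE-only models inducible of which 9 with clinical
#' VA; ACCF/AHA correct on 6 and ESC on 7 of the VA group.
#'
#' @param file Optional path; if given, the fixture is also written as
#'   CSV.
#' @return Data frame with columns `patient_id`, `clinical_va`,
#'   `accf_aha`, `esc`, `lge_t1`, `lge_only` (logicals).
#' @export
cohort_outcomes_fixture <- function(file = NULL) {
  id <- 1:26
  fx <- data.frame(
    patient_id = id,
    clinical_va = id <= 13,
    accf_aha = id %in% c(8:13, 14:20),   # 6 TP, 7 FP
    esc      = id %in% c(7:13, 14:21),   # 7 TP, 8 FP
    lge_t1   = id %in% c(3:13, 14:16),   # 11 TP, 3 FP (patients 1-2 missed)
    lge_only = id %in% c(5:13, 14:16)    # 9 TP, 3 FP
  )
  if (!is.null(file)) utils::write.csv(fx, file, row.names = FALSE)
  fx
}

#' Write an LGE/T1 pair to NIfTI files
#'
#' One file per modality plus the label map (integer codes 0 background,
#' 1 normal, 2 diffuse, 3 dense), with voxel spacing in the headers.
#'
#' @param pair Output of [generate_lge_t1_pair()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_lge_t1_nifti <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp_lge <- c(pair$lge$spacing[[1]], pair$lge$spacing[[1]], pair$lge$spacing[[2]])
  sp_t1 <- c(pair$t1$spacing[[1]], pair$t1$spacing[[1]], pair$t1$spacing[[2]])
  paths <- file.path(dir, c("lge.nii", "lge_mask.nii", "t1.nii",
                            "t1_mask.nii", "labels.nii"))
  put <- function(x, sp, path) {
    img <- RNifti::asNifti(x)
    RNifti::pixdim(img) <- sp
    RNifti::writeNifti(img, path)
  }
  put(pair$lge$intensities, sp_lge, paths[1])
  put(pair$lge$lv_mask * 1L, sp_lge, paths[2])
  put(pair$t1$times_ms, sp_t1, paths[3])
  put(pair$t1$lv_mask * 1L, sp_t1, paths[4])
  put(pair$labels$labels, sp_lge, paths[5])
  invisible(paths)
}
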