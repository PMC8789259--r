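## LGE/T1 fusion segmentation: SD-based LGE thresholding, T1
## relaxation-time classification, and the transfer of T1-derived tissue
## fractions into personalized LGE thresholds applied to the whole stack.

LAB_BACKGROUND <- 0L; LAB_NORMAL <- 1L; LAB_DIFFUSE <- 2L; LAB_DENSE <- 3L

#' Remote-myocardium intensity statistics
#'
#' LGE-CMR is an image of relative intensity, so fibrosis thresholds are
#' expressed in SD units above the mean of the low-signal-intensity
#' (remote) myocardium.  The remote component is identified by a one- or
#' two-component Gaussian mixture fit (BIC-selected) on the masked
#' intensities; with two components the lower-mean one is taken as
#' remote.
#'
#' @param lge_slice Numeric matrix of slice intensities.
#' @param mask Logical matrix, LV myocardium of the slice.
#' @return List of class `remote_stats` with `mean` and `sd`.
#' @export
estimate_remote_stats <- function(lge_slice, mask) {
  x <- lge_slice[mask]
  if (length(x) < 100) stop("need at least 100 masked voxels")
  if (sd(x) == 0) stop("degenerate (constant-intensity) slice")
  fit <- Mclust(x, G = 1:2, modelNames = "V", verbose = FALSE)
  i <- which.min(fit$parameters$mean)
  out <- list(mean = unname(fit$parameters$mean[i]),
              sd = sqrt(unname(fit$parameters$variance$sigmasq[min(
                i, length(fit$parameters$variance$sigmasq))])))
  if (out$sd <= 0) stop("degenerate remote component")
  class(out) <- "remote_stats"
  out
}

#' Personalized LGE thresholds in remote-SD units
#'
#' @param t_diffuse Diffuse-fibrosis (intermediate-intensity) threshold.
#' @param t_dense Dense-fibrosis (high-intensity) threshold.
#' @return List of class `personalized_thresholds`.
#' @export
personalized_thresholds <- function(t_diffuse, t_dense) {
  if (!(t_diffuse < t_dense)) stop("t_diffuse must be below t_dense")
  structure(list(t_diffuse = t_diffuse, t_dense = t_dense),
            class = "personalized_thresholds")
}

# label one intensity matrix given remote stats and thresholds
classify_slice <- function(intens, mask, remote, thr) {
  lab <- matrix(LAB_BACKGROUND, nrow(intens), ncol(intens))
  lab[mask] <- LAB_NORMAL
  hi_f <- remote$mean + thr$t_diffuse * remote$sd
  hi_d <- remote$mean + thr$t_dense * remote$sd
  lab[mask & intens > hi_f] <- LAB_DIFFUSE
  lab[mask & intens > hi_d] <- LAB_DENSE
  lab
}

#' Classify an LGE stack into normal / diffuse / dense tissue
#'
#' A voxel is dense fibrosis if its intensity exceeds
#' `mean + t_dense * sd`, diffuse if it lies in
#' `(mean + t_diffuse * sd, mean + t_dense * sd]`, and normal otherwise.
#' The standard one-size-fits-all thresholds are 3 and 5 SD.
#'
#' @param stack An `lge_stack`.
#' @param remote_stats A single `remote_stats` or a list of one per slice.
#' @param thresholds A `personalized_thresholds`.
#' @return A `tissue_labels` object.
#' @export
classify_lge <- function(stack, remote_stats, thresholds) {
  stopifnot(inherits(stack, "lge_stack"),
            inherits(thresholds, "personalized_thresholds"))
  n_slices <- dim(stack$intensities)[3]
  per_slice <- !inherits(remote_stats, "remote_stats")
  if (per_slice) stopifnot(length(remote_stats) == n_slices)
  lab <- array(LAB_BACKGROUND, dim(stack$intensities))
  for (k in seq_len(n_slices)) {
    rs <- if (per_slice) remote_stats[[k]] else remote_stats
    lab[, , k] <- classify_slice(as.matrix(stack$intensities[, , k]),
                                 as.matrix(stack$lv_mask[, , k]),
                                 rs, thresholds)
  }
  structure(list(labels = lab, spacing = stack$spacing),
            class = "tissue_labels")
}

#' Classify a postcontrast T1 map by relaxation time
#'
#' Relaxation times below 350 ms indicate dense fibrosis (scar), the
#' band 350-450 ms (closed interval) diffuse fibrosis, and longer times
#' normal myocardium.
#'
#' @param t1_map A `t1_map`.
#' @return Integer label matrix (0 background, 1 normal, 2 diffuse,
#'   3 dense).
#' @export
classify_t1 <- function(t1_map) {
  stopifnot(inherits(t1_map, "t1_map"))
  tm <- t1_map$times_ms; mask <- t1_map$lv_mask
  if (any(tm[mask] <= 0)) stop("non-positive relaxation times in mask")
  lab <- matrix(LAB_BACKGROUND, nrow(tm), ncol(tm))
  lab[mask] <- LAB_NORMAL
  lab[mask & tm <= 450] <- LAB_DIFFUSE
  lab[mask & tm < 350] <- LAB_DENSE
  lab
}

#' Index of the LGE slice matching the T1 map
#'
#' Nearest slice by z-axis coordinate; exact ties resolve to the lower
#' index.
#'
#' @param stack An `lge_stack`.
#' @param t1_map A `t1_map`.
#' @return Integer slice index.
#' @export
match_slice <- function(stack, t1_map) {
  z <- t1_map$slice_z
  zr <- range(stack$slice_z)
  if (z < zr[1] - 1e-9 || z > zr[2] + 1e-9)
    stop("T1 slice position outside the LGE stack z-range")
  which.min(abs(stack$slice_z - z))
}

# nearest-neighbour resample of the T1 label map onto the masked voxels
# of the matching LGE slice; returns the T1-derived area fractions
t1_fractions_on_lge_grid <- function(stack, t1_map) {
  k <- match_slice(stack, t1_map)
  t1lab <- classify_t1(t1_map)
  n_l <- dim(stack$intensities)[1]
  n_t <- nrow(t1lab)
  d_l <- stack$spacing[[1]]; d_t <- t1_map$spacing[[1]]
  c_l <- (n_l + 1) / 2; c_t <- (n_t + 1) / 2
  map_idx <- pmin(pmax(round(((seq_len(n_l) - c_l) * d_l) / d_t + c_t), 1), n_t)
  res <- t1lab[map_idx, map_idx]
  m <- stack$lv_mask[, , k]
  vals <- res[m]
  vals <- vals[vals != LAB_BACKGROUND]   # T1 mask may differ slightly at edges
  if (length(vals) == 0) stop("empty overlap between T1 and LGE masks")
  c(dense = mean(vals == LAB_DENSE), diffuse = mean(vals == LAB_DIFFUSE))
}

#' Derive personalized LGE thresholds from the T1 map
#'
#' The T1-derived dense and diffuse area fractions (after
#' nearest-neighbour resampling onto the LGE grid) are transferred to
#' the matching LGE slice as intensity quantiles: `t_dense` is the
#' `1 - f_dense` quantile and `t_diffuse` the `1 - f_dense - f_diffuse`
#' quantile of the masked slice intensities, each expressed in SD units
#' above the remote mean.  Applying the result to the matching slice
#' reproduces the T1 fractions to within one voxel's area fraction.
#'
#' @param stack An `lge_stack`.
#' @param remote_stats `remote_stats` of the matching slice.
#' @param t1_map A `t1_map`.
#' @return A `personalized_thresholds`.
#' @export
derive_personalized_thresholds <- function(stack, remote_stats, t1_map) {
  fr <- t1_fractions_on_lge_grid(stack, t1_map)
  if (sum(fr) >= 1) stop("T1-derived fibrosis fractions sum to >= 1")
  k <- match_slice(stack, t1_map)
  x <- stack$intensities[, , k][stack$lv_mask[, , k]]
  eps <- 1e-9
  q_of <- function(f) {
    if (f <= 0) return(max(x) + eps)           # empty class: above max
    quantile(x, 1 - f, names = FALSE, type = 7)
  }
  t_dense <- (q_of(fr[["dense"]]) - remote_stats$mean) / remote_stats$sd
  t_diffuse <- (q_of(fr[["dense"]] + fr[["diffuse"]]) - remote_stats$mean) /
    remote_stats$sd
  if (t_diffuse >= t_dense) t_diffuse <- t_dense - eps
  personalized_thresholds(t_diffuse, t_dense)
}

#' Apply personalized thresholds to every slice of the stack
#'
#' Each slice is classified with its own remote statistics and the given
#' SD-unit thresholds; with thresholds (3, 5) this is exactly the
#' one-size-fits-all LGE-only pipeline.
#'
#' @param stack An `lge_stack`.
#' @param remote_stats_per_slice List of `remote_stats`, one per slice
#'   (computed if `NULL`).
#' @param thresholds A `personalized_thresholds`.
#' @return A `tissue_labels` object.
#' @export
apply_thresholds_to_stack <- function(stack, remote_stats_per_slice = NULL,
                                      thresholds = personalized_thresholds(3, 5)) {
  if (is.null(remote_stats_per_slice))
    remote_stats_per_slice <- remote_stats_by_slice(stack)
  classify_lge(stack, remote_stats_per_slice, thresholds)
}

#' Remote statistics for every slice of a stack
#' @param stack An `lge_stack`.
#' @return List of `remote_stats`, one per slice.
#' @export
remote_stats_by_slice <- function(stack) {
  n_slices <- dim(stack$intensities)[3]
  lapply(seq_len(n_slices), function(k)
    estimate_remote_stats(stack$intensities[, , k], stack$lv_mask[, , k]))
}

#' Dense and diffuse fibrosis burden of a label map
#'
#' @param labelmap A `tissue_labels` object (or an integer array/matrix).
#' @return List of class `fibrosis_fractions` with `diffuse_pct` and
#'   `dense_pct`, percentages of the LV myocardial voxels.
#' @export
quantify_fibrosis <- function(labelmap) {
  lab <- if (inherits(labelmap, "tissue_labels")) labelmap$labels else labelmap
  myo <- lab[lab != LAB_BACKGROUND]
  if (length(myo) == 0) stop("label map contains no myocardium")
  structure(list(diffuse_pct = 100 * mean(myo == LAB_DIFFUSE),
                 dense_pct = 100 * mean(myo == LAB_DENSE)),
            class = "fibrosis_fractions")
}

#' Full fusion pipeline for one patient
#'
#' Runs the LGE-T1 fusion (personalized thresholds from the T1 map,
#' applied to all slices) or the LGE-only pipeline (fixed 3/5-SD
#' thresholds).
#'
#' @param lge An `lge_stack`.
#' @param t1 A `t1_map` (required for `mode = "lge_t1"`).
#' @param mode `"lge_t1"` or `"lge_only"`.
#' @return List with `labels`, `thresholds`, `remote_stats` (per slice),
#'   and `fractions`.
#' @export
fuse_lge_t1 <- function(lge, t1 = NULL, mode = c("lge_t1", "lge_only")) {
  mode <- match.arg(mode)
  rs <- remote_stats_by_slice(lge)
  thr <- if (mode == "lge_t1") {
    if (is.null(t1)) stop("mode 'lge_t1' requires a T1 map")
    derive_personalized_thresholds(lge, rs[[match_slice(lge, t1)]], t1)
  } else {
    personalized_thresholds(3, 5)
  }
  labels <- apply_thresholds_to_stack(lge, rs, thr)
  list(labels = labels, thresholds = thr, remote_stats = rs,
       fractions = quantify_fibrosis(labels))
}
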