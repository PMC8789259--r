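## Ventricular-arrhythmia induction: pacing-site placement, the rapid
## pacing protocol (S1 train plus progressively premature extrastimuli),
## reentry detection, and unique-morphology counting.

#' Place the seven endocardial pacing sites
#'
#' One site per AHA-style sector (the seven fixed sectors listed in
#' [vh_config()]), each at the endocardial-boundary node closest to the
#' sector's central angle.  For an annular slice the endocardium is the
#' inner boundary of the conducting region; for a sheet phantom without
#' a cavity, the outer boundary stands in.  The stimulated node set is
#' the conducting neighborhood within `radius_mm` of the site.
#'
#' @param labels Label matrix or `tissue_labels`.
#' @param spacing_mm Node spacing (mm).
#' @param radius_mm Stimulus electrode radius (mm).
#' @return List of 7 pacing sites: `list(sector, node, nodes, angle)`.
#' @export
place_pacing_sites <- function(labels, spacing_mm = NULL, radius_mm = 1.25) {
  lab <- as_label_matrix(labels)
  if (is.null(spacing_mm)) {
    spacing_mm <- if (inherits(labels, "tissue_labels"))
      labels$spacing[[1]] else 0.5
  }
  nx <- nrow(lab); ny <- ncol(lab)
  conducting <- lab == 1L | lab == 2L
  if (!any(conducting)) stop("no conducting tissue")

  # cavity: inactive regions not connected to the image border
  inactive <- !conducting
  outside <- matrix(FALSE, nx, ny)
  frontier <- which(inactive & (row(lab) %in% c(1, nx) | col(lab) %in% c(1, ny)))
  outside[frontier] <- TRUE
  while (length(frontier)) {
    ii <- ((frontier - 1) %% nx) + 1
    jj <- ((frontier - 1) %/% nx) + 1
    nb <- c(frontier[ii > 1] - 1, frontier[ii < nx] + 1,
            frontier[jj > 1] - nx, frontier[jj < ny] + nx)
    nb <- unique(nb[inactive[nb] & !outside[nb]])
    outside[nb] <- TRUE
    frontier <- nb
  }
  cavity <- inactive & !outside

  ii <- row(lab); jj <- col(lab)
  nb_any <- function(mask) {
    m <- matrix(FALSE, nx, ny)
    m[-1, ] <- m[-1, ] | mask[-nx, ]
    m[-nx, ] <- m[-nx, ] | mask[-1, ]
    m[, -1] <- m[, -1] | mask[, -ny]
    m[, -ny] <- m[, -ny] | mask[, -1]
    m
  }
  endo <- conducting & nb_any(if (any(cavity)) cavity else outside |
                                (row(lab) %in% c(1, nx) | col(lab) %in% c(1, ny)))
  endo_idx <- which(endo)
  if (length(endo_idx) == 0) stop("no endocardial surface found")

  cx <- mean(ii[conducting]); cy <- mean(jj[conducting])
  ang <- atan2(jj[endo_idx] - cy, ii[endo_idx] - cx)
  sectors <- vh_config()$aha_sectors
  n_sec <- length(sectors)
  centers <- -pi + (seq_len(n_sec) - 0.5) * 2 * pi / n_sec
  sites <- vector("list", n_sec)
  for (s in seq_len(n_sec)) {
    dd <- abs(atan2(sin(ang - centers[s]), cos(ang - centers[s])))
    if (!length(dd)) stop("sector '", sectors[s], "' has no endocardial nodes")
    node <- endo_idx[which.min(dd)]
    if (min(dd) > pi / n_sec + 0.35)
      stop("sector '", sectors[s], "' has no endocardial nodes")
    ni <- ((node - 1) %% nx) + 1; nj <- ((node - 1) %/% nx) + 1
    d2 <- (ii - ni)^2 + (jj - nj)^2
    nodes <- which(conducting & d2 <= (radius_mm / spacing_mm)^2)
    sites[[s]] <- list(sector = sectors[s], node = node, nodes = nodes,
                       angle = centers[s])
  }
  sites
}

#' Rapid pacing protocol parameters
#'
#' An S1 drive train followed by up to `max_extrastimuli` levels of
#' progressively premature extrastimuli: the first extrastimulus starts
#' at `s2_start_frac` of the S1 cycle length and is decremented by
#' `decrement_ms` until induction or loss of capture (or
#' `min_coupling_ms`); further levels ride on the shortest capturing
#' coupling of the previous one.  After each extrastimulus the tissue is
#' observed for `observe_ms`.
#'
#' @param s1_count Number of S1 beats.
#' @param s1_cycle_ms S1 cycle length (ms).
#' @param s2_start_frac First coupling as a fraction of the S1 cycle.
#' @param decrement_ms Coupling decrement (ms).
#' @param min_coupling_ms Shortest coupling attempted (ms).
#' @param max_extrastimuli Extrastimulus levels (S2 only = 1, S2+S3 = 2).
#' @param observe_ms Post-stimulus observation window (ms).
#' @return List of class `pacing_protocol`.
#' @export
pacing_protocol <- function(s1_count = 6, s1_cycle_ms = 600,
                            s2_start_frac = 0.9, decrement_ms = 10,
                            min_coupling_ms = 200, max_extrastimuli = 2,
                            observe_ms = 2000) {
  stopifnot(s1_count >= 1, s1_cycle_ms > 0, decrement_ms > 0,
            min_coupling_ms > 0, max_extrastimuli >= 0)
  start <- s2_start_frac * s1_cycle_ms
  if (start <= min_coupling_ms) stop("empty extrastimulus schedule")
  structure(list(s1_count = s1_count, s1_cycle_ms = s1_cycle_ms,
                 s2_start_frac = s2_start_frac, decrement_ms = decrement_ms,
                 min_coupling_ms = min_coupling_ms,
                 max_extrastimuli = max_extrastimuli,
                 observe_ms = observe_ms),
            class = "pacing_protocol")
}

#' Desk-scale pacing protocol
#'
#' Compressed schedule used with the rescaled 2D substrates: a short
#' drive train (2 S1 beats at 450 ms) and a single extrastimulus level
#' scanning couplings 351, 333, 315, 297 ms, so a full 7-site study
#' runs in minutes (problem sizes are discussed in the methods
#' vignette).
#' @param observe_ms Post-stimulus observation window (ms).
#' @return A `pacing_protocol`.
#' @export
desk_pacing_protocol <- function(observe_ms = 1500) {
  pacing_protocol(s1_count = 2, s1_cycle_ms = 450, s2_start_frac = 0.78,
                  decrement_ms = 18, min_coupling_ms = 290,
                  max_extrastimuli = 1, observe_ms = observe_ms)
}

sector_angles <- function(nx, ny, lab) {
  conducting <- lab == 1L | lab == 2L
  cx <- mean(row(lab)[conducting]); cy <- mean(col(lab)[conducting])
  ij <- arrayInd(seq_len(nx * ny), c(nx, ny))
  atan2(ij[, 2] - cy, ij[, 1] - cx)
}

#' Sector index (1-7) of each grid node
#' @param record An `activation_record` (or list with `nx`, `ny`,
#'   `labels`).
#' @return Integer vector over grid nodes.
#' @export
node_sectors <- function(record) {
  ang <- sector_angles(record$nx, record$ny, record$labels)
  n_sec <- length(vh_config()$aha_sectors)
  idx <- floor((ang + pi) / (2 * pi / n_sec)) + 1
  pmin(pmax(idx, 1L), n_sec)
}

#' Detect reentrant activity after the last paced beat
#'
#' Reentry is declared when self-sustained activation continues through
#' the observation window with at least `min_cycles` complete
#' reactivation cycles of some region: a node must activate at least
#' `min_cycles + 1` times after the last stimulus (its directly paced
#' activation plus `min_cycles` reentrant returns), and the tissue must
#' not have become quiescent before the window closed.  A single ectopic
#' echo beat followed by quiescence therefore does not qualify.
#'
#' @param record An `activation_record` extending through the window
#'   (early-terminated quiescent records are accepted: they are negative
#'   by definition).
#' @param t_last_stimulus End time of the last stimulus (ms).
#' @param window_ms Observation window (ms).
#' @param min_cycles Minimum number of reactivation cycles.
#' @return List `(induced, descriptor)`; the descriptor (only present
#'   when induced) records the reentry cycle length, core sector, and
#'   core node.
#' @export
detect_reentry <- function(record, t_last_stimulus, window_ms = 2000,
                           min_cycles = 2) {
  if (!record$quiescent &&
      record$t_end < t_last_stimulus + window_ms - 1e-6)
    stop("activation record does not extend through the observation window")
  post <- record$act
  post[!(post > t_last_stimulus + 1)] <- NA
  counts <- colSums(!is.na(post))
  sustained <- !record$quiescent
  if (!sustained || max(counts) < min_cycles + 1)
    return(list(induced = FALSE, descriptor = NULL))
  re_nodes <- which(counts >= min_cycles + 1)
  second <- apply(post[, re_nodes, drop = FALSE], 2, function(a) {
    a <- a[!is.na(a)]; a[2]
  })
  core <- re_nodes[which.min(second)]
  a <- post[, core]; a <- a[!is.na(a)]
  cl <- median(diff(a))
  sec <- node_sectors(record)[core]
  list(induced = TRUE,
       descriptor = list(cycle_length_ms = cl,
                         core_sector = vh_config()$aha_sectors[sec],
                         core_sector_index = sec,
                         core_node = core))
}

# does the record show a propagated (captured) response to a stimulus
# delivered at t_on?  Capture requires most of the conducting tissue in
# a 2-4 mm annulus around the electrode to activate: a beat that only
# escapes in one direction at the absolute-refractory margin is a
# stimulation artifact, not a propagated premature beat.
stim_captured <- function(record, site, t_on, spacing_mm,
                          annulus_mm = c(2, 4), min_frac = 0.6) {
  ij <- arrayInd(seq_len(record$nx * record$ny), c(record$nx, record$ny))
  ni <- ((site$node - 1) %% record$nx) + 1
  nj <- ((site$node - 1) %/% record$nx) + 1
  d <- sqrt((ij[, 1] - ni)^2 + (ij[, 2] - nj)^2) * spacing_mm
  lab <- record$labels
  near <- d >= annulus_mm[1] & d <= annulus_mm[2] &
    (lab == 1L | lab == 2L)
  if (!any(near)) return(FALSE)
  act <- colSums(record$act[, near, drop = FALSE] > t_on + 1, na.rm = TRUE) > 0
  mean(act) >= min_frac
}

#' Run the rapid pacing protocol from one site
#'
#' Delivers the S1 drive train, then scans progressively premature
#' extrastimuli (caching tissue state between couplings so the drive
#' train is simulated once); after each extrastimulus the tissue is
#' observed and [detect_reentry()] is applied.  The scan stops at the
#' first induction, at loss of capture, or when the schedule is
#' exhausted.
#'
#' @param labels Label matrix or `tissue_labels`.
#' @param site A pacing site from [place_pacing_sites()].
#' @param protocol A [pacing_protocol()].
#' @param config A [monodomain_config()].
#' @param theta Fiber angle field (as in [simulate_monodomain()]).
#' @param verbose Print per-coupling progress.
#' @return List of class `induction_result`: `site`, `sector`,
#'   `induced`, `couplings_ms` (the extrastimulus couplings at
#'   induction), `descriptor`, `n_trials`, `lost_capture`.
#' @export
run_protocol <- function(labels, site, protocol = pacing_protocol(),
                         config = monodomain_config(), theta = 0,
                         verbose = FALSE) {
  lab <- as_label_matrix(labels)
  spacing <- config$dx_mm
  amp <- vh_config()$stim_amp
  sdur <- vh_config()$tissue_stim_dur_ms
  cl <- protocol$s1_cycle_ms
  t_last1 <- (protocol$s1_count - 1) * cl
  s1 <- lapply((seq_len(protocol$s1_count) - 1) * cl, function(on)
    list(nodes = site$nodes, onset = on, dur = sdur, amp = amp))
  base <- simulate_monodomain(lab, config, stimuli = s1,
                              duration = t_last1 + sdur + 1,
                              theta = theta, stop_quiescent = FALSE)
  if (!stim_captured(base, site, 0, spacing))
    return(structure(list(site = site$node, sector = site$sector,
                          induced = FALSE, couplings_ms = numeric(0),
                          descriptor = NULL, n_trials = 0L,
                          lost_capture = TRUE),
                     class = "induction_result"))
  n_trials <- 0L
  lost <- FALSE
  level_state <- list(state = base$state, t0 = base$t_end,
                      t_prev = t_last1, stack = numeric(0))
  couplings <- seq(round(protocol$s2_start_frac * cl),
                   protocol$min_coupling_ms, by = -protocol$decrement_ms)
  result <- NULL
  for (level in seq_len(max(protocol$max_extrastimuli, 0))) {
    shortest_capture <- NULL
    for (cc in couplings) {
      t_on <- level_state$t_prev + cc
      if (t_on <= level_state$t0) next
      n_trials <- n_trials + 1L
      rec <- simulate_monodomain(lab, config,
        stimuli = list(list(nodes = site$nodes, onset = t_on, dur = sdur,
                            amp = amp)),
        duration = t_on + sdur + protocol$observe_ms - level_state$t0,
        theta = theta, state0 = level_state$state, t0 = level_state$t0,
        stop_quiescent = TRUE)
      captured <- stim_captured(rec, site, t_on, spacing)
      det <- detect_reentry(rec, t_on + sdur, protocol$observe_ms)
      if (verbose)
        message(sprintf("level %d coupling %d: captured=%s induced=%s",
                        level, cc, captured, det$induced))
      if (det$induced) {
        result <- list(couplings = c(level_state$stack, cc),
                       descriptor = det$descriptor)
        break
      }
      if (!captured) { lost <- TRUE; break }
      shortest_capture <- cc
    }
    if (!is.null(result)) break
    if (is.null(shortest_capture)) break
    if (level == protocol$max_extrastimuli) break
    # re-run the shortest capturing extrastimulus and cache for the next level
    t_on <- level_state$t_prev + shortest_capture
    rec <- simulate_monodomain(lab, config,
      stimuli = list(list(nodes = site$nodes, onset = t_on, dur = sdur,
                          amp = amp)),
      duration = t_on + sdur + 1 - level_state$t0,
      theta = theta, state0 = level_state$state, t0 = level_state$t0,
      stop_quiescent = FALSE)
    level_state <- list(state = rec$state, t0 = rec$t_end,
                        t_prev = t_on,
                        stack = c(level_state$stack, shortest_capture))
  }
  structure(list(site = site$node, sector = site$sector,
                 induced = !is.null(result),
                 couplings_ms = if (is.null(result)) numeric(0) else result$couplings,
                 descriptor = if (is.null(result)) NULL else result$descriptor,
                 n_trials = n_trials, lost_capture = lost),
            class = "induction_result")
}

#' Probe VA inducibility of a substrate from all seven sites
#'
#' @inheritParams run_protocol
#' @param sites Pacing sites (placed automatically if `NULL`).
#' @return List of class `inducibility_study`: per-site
#'   `induction_result`s, the `at_risk` verdict (at least one inducing
#'   site), `n_inducing_sites`, and `n_morphologies`.
#' @export
assess_inducibility <- function(labels, protocol = desk_pacing_protocol(),
                                config = monodomain_config(), theta = 0,
                                sites = NULL, verbose = FALSE) {
  if (is.null(sites)) sites <- place_pacing_sites(labels, config$dx_mm)
  results <- lapply(sites, function(s)
    run_protocol(labels, s, protocol, config, theta, verbose))
  descs <- lapply(Filter(function(r) r$induced, results),
                  function(r) r$descriptor)
  structure(list(results = results,
                 at_risk = classify_patient(results),
                 n_inducing_sites = sum(vapply(results, `[[`, TRUE, "induced")),
                 n_morphologies = count_unique_morphologies(descs)),
            class = "inducibility_study")
}

#' Count unique VA morphologies
#'
#' Descriptors from one heart are clustered as the same morphology when
#' their reentry cores lie in the same sector and their cycle lengths
#' differ by less than 10%; the cluster count is returned.
#'
#' @param descriptors List of reentry descriptors (see
#'   [detect_reentry()]).
#' @return Integer count.
#' @export
count_unique_morphologies <- function(descriptors) {
  descriptors <- Filter(Negate(is.null), descriptors)
  if (!length(descriptors)) return(0L)
  clusters <- list()
  for (d in descriptors) {
    matched <- FALSE
    for (k in seq_along(clusters)) {
      cl0 <- clusters[[k]]
      if (identical(cl0$core_sector_index, d$core_sector_index) &&
          abs(cl0$cycle_length_ms - d$cycle_length_ms) <
            0.10 * cl0$cycle_length_ms) {
        matched <- TRUE; break
      }
    }
    if (!matched) clusters[[length(clusters) + 1]] <- d
  }
  length(clusters)
}
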