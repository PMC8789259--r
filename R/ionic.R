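## Single-cell electrophysiology: human ventricular myocyte (epicardial
## parameter set) with an added late sodium current, in two variants --
## nonfibrotic ("normal") and diffuse-fibrosis-remodeled ("remodeled").

#' Names of the scalable ionic parameters
#'
#' Order matches the compiled model.  Values are maximal conductances
#' (nS/pF) or maximal fluxes in the model's native units.
#' @return Character vector of parameter names.
#' @export
tt_param_names <- function() {
  c("g_Na", "g_K1", "g_to", "g_Kr", "g_Ks", "g_CaL", "g_NaL",
    "k_NaCa", "P_NaK", "Vmax_up", "g_pCa", "g_pK", "g_bNa", "g_bCa")
}

#' Names of the state variables of the myocyte model
#' @return Character vector of state names.
#' @export
tt_state_names <- function() {
  c("V", "Ki", "Nai", "Cai", "CaSS", "CaSR", "m", "h", "j", "xr1", "xr2",
    "xs", "r", "s", "d", "f", "f2", "fcass", "RR", "mL", "hL")
}

# Eight remodeling factors for diffuse-fibrosis myocytes: INaL +107%,
# ICaL +19%, IKr -34%, IKs -27%, Ito -85%, IK1 -15%, NCX +34%, SERCA -43%.
REMODELING_FACTORS <- c(
  g_NaL = 2.07, g_CaL = 1.19, g_Kr = 0.66, g_Ks = 0.73,
  g_to = 0.15, g_K1 = 0.85, k_NaCa = 1.34, Vmax_up = 0.57)

#' Ionic parameter sets for the myocyte model
#'
#' The `"normal"` (nonfibrotic) variant is the published epicardial
#' baseline with the late sodium conductance and a potassium-conductance
#' rescale calibrated so that steady-state APD90 at a 1000-ms cycle
#' length equals 280 ms (see [vh_config()]).  The `"remodeled"` variant
#' applies the eight diffuse-fibrosis scaling factors (late sodium
#' current +107%, L-type calcium +19%, rapid delayed rectifier -34%,
#' slow delayed rectifier -27%, transient outward -85%, inward rectifier
#' -15%, sodium-calcium exchanger +34%, SERCA uptake -43%).
#'
#' @param variant `"normal"` or `"remodeled"`.
#' @param scale Optional named vector of extra multiplicative factors
#'   applied on top of the variant (names from [tt_param_names()]).
#' @return Named numeric vector of class `ionic_params` with a
#'   `variant` attribute.
#' @export
make_ionic_params <- function(variant = c("normal", "remodeled"),
                              scale = NULL) {
  variant <- match.arg(variant)
  cfg <- vh_config()
  p <- c(g_Na = 14.838, g_K1 = 5.405, g_to = 0.294, g_Kr = 0.153,
         g_Ks = 0.392, g_CaL = 3.980e-5, g_NaL = 0,
         k_NaCa = 1000, P_NaK = 2.724, Vmax_up = 0.006375,
         g_pCa = 0.1238, g_pK = 0.0146, g_bNa = 0.00029, g_bCa = 0.000592)
  # baseline calibration: late sodium conductance plus a joint rescale of
  # the delayed-rectifier conductances (repolarization reserve)
  p["g_NaL"] <- cfg$g_NaL
  p[c("g_Kr", "g_Ks")] <- p[c("g_Kr", "g_Ks")] * cfg$gk_scale
  if (variant == "remodeled") {
    p[names(REMODELING_FACTORS)] <-
      p[names(REMODELING_FACTORS)] * REMODELING_FACTORS
  }
  if (!is.null(scale)) {
    if (is.null(names(scale)) || !all(names(scale) %in% tt_param_names()))
      stop("`scale` must be named with ionic parameter names")
    p[names(scale)] <- p[names(scale)] * scale
  }
  if (any(p < 0)) stop("ionic parameters must be non-negative")
  structure(p, variant = variant, class = "ionic_params")
}

#' Resting initial state of the myocyte model
#'
#' Pre-equilibrated by 100 s of quiescence from the published initial
#' conditions, so the unstimulated model is stationary.
#' @return Named numeric state vector.
#' @export
tt_initial_state <- function() {
  setNames(vh_config()$rest_state, tt_state_names())
}

#' Advance a single cell by one or more fixed time steps
#'
#' Rush-Larsen integration for the gating variables, forward Euler for
#' the membrane potential and ionic concentrations.
#'
#' @param state Named state vector (see [tt_state_names()]).
#' @param params Parameter vector from [make_ionic_params()].
#' @param dt Time step (ms), at most 0.05.
#' @param n_steps Number of steps to take.
#' @param i_stim Stimulus current (A/F); negative values depolarize.
#' @return Updated state vector.
#' @export
step_cell <- function(state, params, dt, n_steps = 1L, i_stim = 0) {
  stopifnot(length(state) == tt_n_state(), dt > 0, dt <= 0.05)
  out <- tt_cell_run(as.numeric(params), as.numeric(state), dt,
                     duration = n_steps * dt,
                     stim_onsets = if (i_stim != 0) 0 else numeric(0),
                     stim_dur = n_steps * dt, stim_amp = i_stim,
                     sample_ms = n_steps * dt)
  setNames(out$state, tt_state_names())
}

#' Pace a single cell to steady state and return the final beats
#'
#' @param params Parameter vector from [make_ionic_params()].
#' @param cycle_length_ms Pacing cycle length (ms).
#' @param n_beats Number of beats delivered.
#' @param dt Integration step (ms).
#' @param record_beats How many trailing beats to keep in the trace.
#' @param sample_ms Trace sampling interval (ms).
#' @param state Optional initial state; by default the variant's paced
#'   steady state (150 beats at a 1000-ms cycle length, precomputed and
#'   recorded in [vh_config()]), so short pacing runs measure
#'   steady-state behavior.
#' @return List with `time`, `V`, `Cai` for the recorded tail, stimulus
#'   onset times within the recorded window, and the final `state`.
#' @export
cell_pace <- function(params, cycle_length_ms = 1000, n_beats = 30,
                      dt = 0.02, record_beats = 2, sample_ms = 0.05,
                      state = NULL) {
  stopifnot(n_beats >= 1, cycle_length_ms > 0)
  cfg <- vh_config()
  if (is.null(state)) {
    state <- if (identical(attr(params, "variant"), "remodeled"))
      cfg$cell_state_remodeled else cfg$cell_state_normal
    state <- setNames(state, tt_state_names())
  }
  record_beats <- min(record_beats, n_beats)
  n_warm <- n_beats - record_beats
  onsets <- (seq_len(n_beats) - 1) * cycle_length_ms
  if (n_warm > 0) {
    warm <- tt_cell_run(as.numeric(params), as.numeric(state), dt,
                        duration = n_warm * cycle_length_ms,
                        stim_onsets = onsets[seq_len(n_warm)],
                        stim_dur = cfg$stim_dur_ms, stim_amp = cfg$stim_amp,
                        sample_ms = cycle_length_ms)
    state <- warm$state
  }
  tail_onsets <- (seq_len(record_beats) - 1) * cycle_length_ms
  out <- tt_cell_run(as.numeric(params), as.numeric(state), dt,
                     duration = record_beats * cycle_length_ms,
                     stim_onsets = tail_onsets,
                     stim_dur = cfg$stim_dur_ms, stim_amp = cfg$stim_amp,
                     sample_ms = sample_ms)
  list(time = out$time, V = out$V, Cai = out$Cai,
       stim_onsets = tail_onsets, cycle_length_ms = cycle_length_ms,
       state = setNames(out$state, tt_state_names()))
}

# APD90 of one beat given a sampled trace and the stimulus onset:
# measured from the time of maximum dV/dt to 90% repolarization toward
# the pre-stimulus diastolic potential.
apd90_from_trace <- function(time, V, stim_onset, cycle_length_ms) {
  sel <- time >= stim_onset & time < stim_onset + cycle_length_ms
  t <- time[sel]; v <- V[sel]
  if (length(t) < 10) stop("trace too short for APD measurement")
  v_rest <- v[1]
  dv <- diff(v) / diff(t)
  i_up <- which.max(dv)
  if (dv[i_up] < 10) stop("no action potential elicited (max dV/dt < 10 V/s)")
  t_up <- t[i_up]
  v_peak <- max(v[i_up:length(v)])
  v90 <- v_peak - 0.9 * (v_peak - v_rest)
  i_pk <- which.max(v)
  below <- which(v[i_pk:length(v)] <= v90)
  if (length(below) == 0) stop("beat did not repolarize to 90% within the cycle")
  j <- i_pk + below[1] - 1
  # linear interpolation of the crossing time
  t_cross <- if (j > 1 && v[j - 1] > v90) {
    t[j - 1] + (v[j - 1] - v90) / (v[j - 1] - v[j]) * (t[j] - t[j - 1])
  } else t[j]
  t_cross - t_up
}

#' Steady-state action potential duration at 90% repolarization
#'
#' Paces the cell for `n_beats` beats at the given cycle length and
#' measures APD90 of the final beat, from maximum upstroke velocity to
#' 90% return toward the diastolic potential.
#'
#' @inheritParams cell_pace
#' @return APD90 in ms.
#' @export
apd90 <- function(params, cycle_length_ms = 1000, n_beats = 30, dt = 0.02) {
  stopifnot(n_beats >= 20)
  tr <- cell_pace(params, cycle_length_ms, n_beats, dt = dt, record_beats = 1)
  apd90_from_trace(tr$time, tr$V, tr$stim_onsets[length(tr$stim_onsets)],
                   cycle_length_ms)
}

#' Phase-1 notch depth of the paced action potential
#'
#' Depth of the early repolarization notch: the drop from the upstroke
#' peak to the local minimum preceding the plateau dome, on the final
#' paced beat.  The diffuse-fibrosis-remodeled variant, with its 85%
#' reduction of the transient outward current, shows a diminished notch.
#'
#' @inheritParams cell_pace
#' @param window_ms How far past the upstroke peak to search for the
#'   notch minimum (ms).
#' @return Notch depth in mV (>= 0).
#' @export
notch_depth <- function(params, cycle_length_ms = 1000, n_beats = 30,
                        dt = 0.02, window_ms = 40) {
  tr <- cell_pace(params, cycle_length_ms, n_beats, dt = dt, record_beats = 1)
  onset <- tr$stim_onsets[length(tr$stim_onsets)]
  sel <- tr$time >= onset & tr$time < onset + cycle_length_ms
  t <- tr$time[sel]; v <- tr$V[sel]
  i_pk <- which.max(v)
  in_win <- which(t > t[i_pk] & t <= t[i_pk] + window_ms)
  if (length(in_win) == 0) stop("empty notch search window")
  v_notch <- min(v[in_win])
  max(v[i_pk] - v_notch, 0)
}
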