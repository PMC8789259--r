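## Package-level configuration: calibration constants, numerical defaults,
## and protocol parameters.  Every stochastic operation elsewhere takes an
## explicit seed; the constants here are fixed calibration results.

#' Package configuration and calibration constants
#'
#' Central record of the calibrated constants and numerical defaults used
#' throughout the pipeline:
#' \describe{
#'   \item{g_NaL, gk_scale}{Single-cell calibration: late sodium maximal
#'     conductance (nS/pF) and the joint rescale of the delayed-rectifier
#'     potassium conductances chosen so the nonfibrotic myocyte's
#'     steady-state APD90 at a 1000-ms cycle length is 280 ms while the
#'     remodeled myocyte's is 330 ms.}
#'   \item{stim_amp, stim_dur_ms}{Transmembrane stimulus: -52 A/F for
#'     1 ms (single cell); tissue pacing uses the same amplitude for
#'     2 ms.}
#'   \item{sigma_l, sigma_t}{Monodomain conductivities along/across the
#'     fiber (S/m); sigma_l is calibrated so a planar wave at 350-um grid
#'     spacing travels at 0.6 m/s along the fiber, sigma_t = sigma_l/4
#'     (2:1 conduction-velocity anisotropy).}
#'   \item{beta, Cm}{Surface-to-volume ratio (1/m) and membrane
#'     capacitance (F/m^2) used to convert conductivity to the effective
#'     monodomain diffusivity D = sigma/(beta*Cm).}
#'   \item{dt_ms, dx_mm}{Default integration step and grid spacing.}
#'   \item{apd_cycle_ms, apd_beats}{Pacing protocol under which APD90 is
#'     calibrated and reported.}
#'   \item{rest_state}{Quiescent steady state of the nonfibrotic myocyte
#'     (100 s of unpaced equilibration).}
#'   \item{aha_sectors}{The seven AHA-style sectors used for pacing-site
#'     placement.}
#' }
#' @return Named list of configuration entries.
#' @export
vh_config <- function() {
  list(
    # single-cell calibration (see the methods vignette)
    g_NaL = 0.004,
    gk_scale = 1.240655,
    stim_amp = -52,
    stim_dur_ms = 1,
    apd_cycle_ms = 1000,
    apd_beats = 30,
    # tissue-level calibration
    sigma_l = 0.159,
    sigma_t = 0.159 / 4,
    beta = 1.4e5,
    Cm = 0.01,
    dt_ms = 0.02,
    dx_mm = 0.35,
    tissue_stim_dur_ms = 2,
    # quiescent steady state of the calibrated nonfibrotic myocyte
    # (100 s unpaced equilibration from the published initial conditions)
    rest_state = c(
      -86.79713288, 142.0961296, 4.550336951, 2.737741983e-05,
      7.666311409e-05, 0.2215468932, 0.001228514692, 0.7852793463,
      0.785278036, 0.0001690244474, 0.4874727506, 0.002892761158,
      1.861087511e-08, 0.9999984221, 2.73632278e-05, 0.9999282622,
      0.9995905385, 0.9999985894, 0.9982999932, 0.001144747942,
      0.3342373231),
    # paced steady states (1000 beats at CL 1000 ms) used as the
    # starting point for single-cell pacing protocols, one per variant
    cell_state_normal = c(
      -85.40618021, 135.4269499, 9.964932031, 0.0001023250853,
      0.000209219967, 3.373453416, 0.00165242304, 0.7497062787,
      0.7493758066, 0.0002066073923, 0.4730066459, 0.003217081669,
      2.346777952e-08, 0.9999979157, 3.293910647e-05, 0.9798394479,
      0.9994300601, 0.999974711, 0.989516645, 0.001444295279,
      0.2394513318),
    cell_state_remodeled = c(
      -84.89584128, 134.4008273, 11.24313432, 0.0001002855917,
      0.0002308319503, 2.368763868, 0.001841449385, 0.7355130042,
      0.7334582065, 0.000226492508, 0.4677063311, 0.003371272039,
      2.555769053e-08, 0.9999976902, 3.525908627e-05, 0.9735945493,
      0.9993316557, 0.9999652818, 0.9879045518, 0.001572496268,
      0.2044123043),
    aha_sectors = c("basal anterior", "basal inferolateral",
                    "basal inferoseptal", "mid anteroseptal",
                    "mid inferior", "mid anterolateral", "apical septal")
  )
}
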