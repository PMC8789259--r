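## Anisotropic monodomain tissue simulation coupling the myocyte model
## to a structured 2D grid, with inexcitable dense scar.

#' Monodomain configuration
#'
#' Conductivities are converted to the effective monodomain diffusivity
#' `D = sigma / (beta * Cm)` (mm^2/ms).  Defaults are the package
#' calibration: `sigma_l` tuned so a planar wave in nonfibrotic tissue
#' at 350-um spacing conducts at 0.6 m/s along the fiber, with a 4:1
#' conductivity (2:1 velocity) anisotropy.  Conductivities are the same
#' in fibrotic and nonfibrotic myocardium; dense fibrosis is excluded
#' from the conducting domain altogether.
#'
#' `cv_scale` shrinks conduction velocity by the given factor (it scales
#' both conductivities by `cv_scale^2`), which maps the dynamics of a
#' domain `1/cv_scale` times larger onto a small grid; the substrate
#' studies use this spatial rescaling (see the methods vignette).
#'
#' @param sigma_l,sigma_t Conductivity along/across the fiber (S/m).
#' @param beta Surface-to-volume ratio (1/m).
#' @param Cm Membrane capacitance (F/m^2).
#' @param dt_ms Integration step (ms).
#' @param dx_mm Grid spacing (mm).
#' @param cv_scale Conduction-velocity rescaling factor (dimensionless).
#' @return List of class `monodomain_config` including derived
#'   diffusivities `D_l`, `D_t` (mm^2/ms).
#' @export
monodomain_config <- function(sigma_l = vh_config()$sigma_l,
                              sigma_t = vh_config()$sigma_t,
                              beta = vh_config()$beta,
                              Cm = vh_config()$Cm,
                              dt_ms = vh_config()$dt_ms,
                              dx_mm = vh_config()$dx_mm,
                              cv_scale = 1) {
  if (!(sigma_l >= sigma_t && sigma_t > 0))
    stop("require sigma_l >= sigma_t > 0")
  if (dt_ms <= 0 || dx_mm <= 0) stop("dt and dx must be positive")
  Dl <- 1000 * sigma_l / (beta * Cm) * cv_scale^2   # mm^2/ms
  Dt <- 1000 * sigma_t / (beta * Cm) * cv_scale^2
  structure(list(sigma_l = sigma_l, sigma_t = sigma_t, beta = beta, Cm = Cm,
                 dt_ms = dt_ms, dx_mm = dx_mm, cv_scale = cv_scale,
                 D_l = Dl, D_t = Dt),
            class = "monodomain_config")
}

#' Monodomain configuration for the desk-scale substrate studies
#'
#' The configuration used for the ring substrates and phantoms:
#' 0.5-mm grid, 0.045-ms step, and conduction rescaled by
#' `cv_scale = 0.37` so reentrant circuits fit the small domains (the
#' spatial rescaling is discussed in the methods vignette).  Sheet
#' phantoms, whose reentrant pathways run in both grid directions, use
#' the isotropic variant.
#'
#' @param isotropic Use equal transverse and longitudinal
#'   conductivities.
#' @return A `monodomain_config`.
#' @export
substrate_config <- function(isotropic = FALSE) {
  monodomain_config(sigma_t = if (isotropic) vh_config()$sigma_l else
                      vh_config()$sigma_t,
                    dx_mm = 0.5, dt_ms = 0.045, cv_scale = 0.37)
}

# node-level variant codes from a label matrix:
# 0 background & dense (inactive), 1 normal, 2 diffuse (remodeled)
labels_to_variant <- function(lab) {
  v <- matrix(0L, nrow(lab), ncol(lab))
  v[lab == 1L] <- 1L
  v[lab == 2L] <- 2L
  v
}

as_label_matrix <- function(labels, slice = 1L) {
  lab <- if (inherits(labels, "tissue_labels")) labels$labels else labels
  if (length(dim(lab)) == 3) lab <- lab[, , slice]
  as.matrix(lab)
}

#' Assemble the per-node conductivity (diffusivity) tensor field
#'
#' `D = D_l f f' + D_t (I - f f')` for in-plane unit fiber direction
#' `f`; inactive nodes (background, dense scar) carry a zero tensor,
#' which makes every face to them no-flux.  Diffuse-fibrosis nodes use
#' the same conductivities as normal tissue (their remodeling is
#' ionic, not conductive).
#'
#' @param labels Label matrix or `tissue_labels` (0 background,
#'   1 normal, 2 diffuse, 3 dense).
#' @param theta Fiber angle per node (radians, in-plane), a scalar, or a
#'   matrix; alternatively `fibers` may be given.
#' @param config A `monodomain_config`.
#' @param fibers Optional n x 2 or n x 3 matrix of unit fiber vectors
#'   (row per node, column-major node order).
#' @return List with matrices `Dxx`, `Dyy`, `Dxy` (mm^2/ms) and the
#'   `variant` code matrix.
#' @export
assemble_conductivity <- function(labels, theta = 0, config = monodomain_config(),
                                  fibers = NULL) {
  lab <- as_label_matrix(labels)
  v <- labels_to_variant(lab)
  if (!is.null(fibers)) {
    fpl <- fibers[, 1:2, drop = FALSE]
    nrm <- sqrt(rowSums(fibers^2))
    if (any(abs(nrm[v > 0] - 1) > 1e-9))
      stop("fiber vectors must be unit-norm")
    theta <- matrix(atan2(fpl[, 2], fpl[, 1]), nrow(lab), ncol(lab))
  }
  if (length(theta) == 1) theta <- matrix(theta, nrow(lab), ncol(lab))
  ct <- cos(theta); st <- sin(theta)
  Dxx <- config$D_l * ct^2 + config$D_t * st^2
  Dyy <- config$D_l * st^2 + config$D_t * ct^2
  Dxy <- (config$D_l - config$D_t) * ct * st
  Dxx[v == 0L] <- 0; Dyy[v == 0L] <- 0; Dxy[v == 0L] <- 0
  list(Dxx = Dxx, Dyy = Dyy, Dxy = Dxy, variant = v)
}

#' Simulate monodomain electrical activity on a labeled 2D grid
#'
#' Operator-split explicit update: a 9-point anisotropic diffusion step
#' followed by the per-node ionic step, with no-flux external and
#' dense-scar boundaries.  Normal nodes use the nonfibrotic myocyte
#' variant, diffuse-fibrosis nodes the remodeled variant.  Activation
#' times are recorded whenever the membrane potential crosses the
#' threshold upward.
#'
#' @param labels Label matrix or `tissue_labels`.
#' @param config A `monodomain_config`.
#' @param stimuli List of stimuli: each `list(nodes, onset, dur, amp)`
#'   with 1-based grid node indices (column-major).
#' @param duration Simulated time (ms) beyond `t0`.
#' @param theta,fibers Fiber orientation (as in
#'   [assemble_conductivity()]).
#' @param params_normal,params_remodeled Ionic parameter vectors.
#' @param state0 Optional full state matrix (n_state x n_nodes) from a
#'   previous run, for protocol continuation.
#' @param t0 Start time (ms).
#' @param act_thresh Activation detection threshold (mV).
#' @param stop_quiescent Stop early once all tissue has repolarized
#'   below `quiesce_v` after the last stimulus.
#' @param quiesce_v Quiescence voltage (mV).
#' @param min_run_ms Minimum simulated time before an early stop.
#' @param max_act Maximum recorded activations per node.
#' @param snapshot_ms If positive, record V snapshots at this interval.
#' @return List of class `activation_record`: activation-time matrix
#'   `act` (`max_act` rows, one column per grid node), activation counts
#'   `n_act`, final `state`, `t_end`, `quiescent`, grid geometry
#'   (`nx`, `ny`, `dx_mm`), and the active node indices.
#' @export
simulate_monodomain <- function(labels, config = monodomain_config(),
                                stimuli = list(), duration = 100,
                                theta = 0, fibers = NULL,
                                params_normal = make_ionic_params("normal"),
                                params_remodeled = make_ionic_params("remodeled"),
                                state0 = NULL, t0 = 0,
                                act_thresh = -40, stop_quiescent = TRUE,
                                quiesce_v = -65, min_run_ms = 0,
                                max_act = 40L, snapshot_ms = 0) {
  lab <- as_label_matrix(labels)
  cc <- assemble_conductivity(lab, theta = theta, config = config,
                              fibers = fibers)
  nx <- nrow(lab); ny <- ncol(lab); nn <- nx * ny
  if (is.null(state0)) {
    state0 <- matrix(vh_config()$rest_state, nrow = tt_n_state(), ncol = nn)
  }
  pm <- cbind(as.numeric(params_normal), as.numeric(params_remodeled))
  stimuli <- lapply(stimuli, function(s) {
    list(nodes = as.integer(s$nodes), onset = as.numeric(s$onset),
         dur = as.numeric(s$dur), amp = as.numeric(s$amp))
  })
  out <- md_run(as.integer(cc$variant), nx, ny, pm,
                as.numeric(cc$Dxx), as.numeric(cc$Dyy), as.numeric(cc$Dxy),
                config$dx_mm, config$dt_ms, t0, duration,
                stimuli, state0,
                as.integer(max_act), act_thresh, 60,
                stop_quiescent, quiesce_v, min_run_ms, snapshot_ms)
  out$nx <- nx; out$ny <- ny; out$dx_mm <- config$dx_mm
  out$labels <- lab
  class(out) <- "activation_record"
  out
}

#' First activation time per node
#' @param record An `activation_record`.
#' @param after Only count activations after this time (ms).
#' @return Numeric vector over grid nodes (`NA` where never activated).
#' @export
first_activation <- function(record, after = -Inf) {
  apply(record$act, 2, function(a) {
    a <- a[!is.na(a) & a > after]
    if (length(a)) a[1] else NA_real_
  })
}

#' Conduction velocity of a planar wave
#'
#' Least-squares fit of activation time against distance along the
#' propagation direction; the inverse slope is the conduction velocity.
#'
#' @param record An `activation_record` holding a planar-wave run.
#' @param direction Unit 2-vector of propagation.
#' @param margin_mm Strip at each domain end excluded from the fit.
#' @return List with `cv_m_s` and the fit's `r_squared`.
#' @export
measure_cv <- function(record, direction = c(1, 0), margin_mm = 2) {
  ft <- first_activation(record)
  ij <- arrayInd(seq_along(ft), c(record$nx, record$ny))
  x <- (ij[, 1] - 1) * record$dx_mm
  y <- (ij[, 2] - 1) * record$dx_mm
  d <- x * direction[1] + y * direction[2]
  ok <- !is.na(ft) & d > min(d) + margin_mm & d < max(d) - margin_mm
  if (sum(ok) < 3) stop("need at least 3 activated sample points")
  fit <- stats::lm(ft[ok] ~ d[ok])
  slope <- stats::coef(fit)[2]
  if (!is.finite(slope) || slope <= 0) stop("no propagating planar wave found")
  list(cv_m_s = 1 / unname(slope),
       r_squared = summary(fit)$r.squared)
}

#' Planar-wave conduction velocity in a uniform strip
#'
#' Convenience wrapper used for conductivity calibration and solver
#' verification: builds a homogeneous strip with the fiber along the
#' requested direction, paces one edge, and measures CV mid-strip.
#'
#' @param config A `monodomain_config`.
#' @param along Fiber parallel (`TRUE`) or perpendicular to propagation.
#' @param length_mm,width_mm Strip dimensions.
#' @param variant `"normal"` or `"remodeled"` tissue.
#' @return CV in m/s.
#' @export
planar_cv <- function(config = monodomain_config(), along = TRUE,
                      length_mm = 20, width_mm = 3, variant = "normal") {
  nx <- round(length_mm / config$dx_mm) + 1
  ny <- round(width_mm / config$dx_mm) + 1
  lab <- matrix(if (variant == "normal") 1L else 2L, nx, ny)
  theta <- if (along) 0 else pi / 2
  stim_nodes <- as.integer(outer(1:2, (0:(ny - 1)) * nx, `+`))
  rec <- simulate_monodomain(lab, config,
    stimuli = list(list(nodes = stim_nodes, onset = 0,
                        dur = vh_config()$tissue_stim_dur_ms,
                        amp = vh_config()$stim_amp)),
    duration = length_mm / 0.1 + 50, theta = theta,
    stop_quiescent = TRUE, min_run_ms = 10)
  measure_cv(rec, direction = c(1, 0))$cv_m_s
}
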