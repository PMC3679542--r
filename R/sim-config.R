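#' Configuration for the IFT / gliding simulator
#'
#' Bundles the kinetic, optical and camera parameters that drive
#' [simulate_ift()], [simulate_bead()], [simulate_gliding()] and
#' [render_movie()]. Defaults follow the biology of *Chlamydomonas*
#' flagella imaged by TIRF at 5 frames/s: anterograde trains at ~2 um/s,
#' retrograde trains at ~3 um/s, rare calcium-dependent pausing, and
#' gliding at ~0.9 um/s.
#'
#' @param flagellum_length Flagellum length in um (fully grown: 8-12 um).
#' @param duration Acquisition duration in s.
#' @param frame_interval Frame interval in s (default 0.2 s = 5 fps).
#' @param pixel_size Camera pixel size in um (default 0.106).
#' @param v_antero,v_retro Mean train speeds in um/s (anterograde base->tip,
#'   retrograde tip->base; both given as positive numbers).
#' @param v_antero_sd,v_retro_sd Per-train speed jitter (sd, um/s).
#' @param injection_rate_antero,injection_rate_retro Poisson train injection
#'   rates, trains/s, at the base and tip respectively.
#' @param ca_free Free calcium concentration in mol/L (TAP media: 0.34 mM).
#' @param ca_half Half-saturation constant of the calcium->pause-rate map in
#'   mol/L (Hill coefficient 1).
#' @param pause_rate_max Saturating pausing-event rate in s^-1. Interpreted as
#'   the aggregate rate per simulated cell (the paper-facing observable); see
#'   Details for the per-flagellum reading.
#' @param pause_rate_residual Residual pausing rate at zero calcium, s^-1.
#' @param pause_duration_mean Mean of the exponential pause-duration
#'   distribution, s.
#' @param bead_diffusion_coeff Free-bead diffusion coefficient on the membrane,
#'   um^2/s.
#' @param bead_attach_rate,bead_detach_rate Poisson coupling/uncoupling rates
#'   between bead and trains, s^-1. The effective attach rate is scaled by the
#'   same calcium saturation map as pausing (no coupling without calcium).
#' @param bead_speed_factor Speed of a train-coupled bead relative to the
#'   train (default 0.7: bead-carrying trains move ~30% slower).
#' @param glide_speed Cell-body gliding speed, um/s.
#' @param n_flagella Number of flagella (1 or 2). Flagellum 1 points toward
#'   +x in the lab frame, flagellum 2 toward -x.
#' @param psf_sigma Gaussian point-spread-function sigma, um.
#' @param photon_rate Expected signal photons per emitter per frame (camera
#'   units).
#' @param background_rate Expected background counts per pixel per frame.
#' @param read_noise Gaussian read noise sd, camera units.
#' @param seed Integer seed; identical config + seed reproduce bit-identical
#'   simulations.
#'
#' @details
#' The calcium dependence of pausing is a saturating Hill map with
#' coefficient 1: `H(c) = c / (c + ca_half)`, so `H(0) = 0` and
#' `H(0.34 mM) ~ 1` with the default `ca_half = 1e-6` M. The pausing rate is
#' `pause_rate_residual + (pause_rate_max - pause_rate_residual) * H(ca_free)`.
#'
#' `pause_rate_max` is the rate of pausing events per cell (all flagella
#' pooled), matching how pausing frequency is measured from kymographs
#' (events / acquisition time). To use a per-flagellum reading, multiply the
#' per-flagellum rate by `n_flagella` when building the config.
#'
#' @return A `sim_config` object (a validated named list).
#' @seealso [trap_sim_config()] for the optical-trap simulator.
#' @export
sim_config <- function(flagellum_length = 10,
                       duration = 100,
                       frame_interval = 0.2,
                       pixel_size = 0.106,
                       v_antero = 2.0,
                       v_retro = 2.96,
                       v_antero_sd = 0.2,
                       v_retro_sd = 0.14,
                       injection_rate_antero = 1.0,
                       injection_rate_retro = 1.2,
                       ca_free = 0.34e-3,
                       ca_half = 1e-6,
                       pause_rate_max = 0.125,
                       pause_rate_residual = 0.0125,
                       pause_duration_mean = 2,
                       bead_diffusion_coeff = 0.1,
                       bead_attach_rate = 0.5,
                       bead_detach_rate = 0.5,
                       bead_speed_factor = 0.7,
                       glide_speed = 0.86,
                       n_flagella = 1L,
                       psf_sigma = 0.13,
                       photon_rate = 200,
                       background_rate = 20,
                       read_noise = 2,
                       seed = 1L) {
  check_number(flagellum_length, "flagellum_length", min = 0, strict_min = TRUE)
  check_number(duration, "duration", min = 0, strict_min = TRUE)
  check_number(frame_interval, "frame_interval", min = 0, strict_min = TRUE)
  check_number(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  check_number(v_antero, "v_antero", min = 0)
  check_number(v_retro, "v_retro", min = 0)
  check_number(v_antero_sd, "v_antero_sd", min = 0)
  check_number(v_retro_sd, "v_retro_sd", min = 0)
  check_number(injection_rate_antero, "injection_rate_antero", min = 0)
  check_number(injection_rate_retro, "injection_rate_retro", min = 0)
  check_number(ca_free, "ca_free", min = 0)
  check_number(ca_half, "ca_half", min = 0, strict_min = TRUE)
  check_number(pause_rate_max, "pause_rate_max", min = 0)
  check_number(pause_rate_residual, "pause_rate_residual", min = 0)
  check_number(pause_duration_mean, "pause_duration_mean", min = 0,
               strict_min = TRUE)
  check_number(bead_diffusion_coeff, "bead_diffusion_coeff", min = 0)
  check_number(bead_attach_rate, "bead_attach_rate", min = 0)
  check_number(bead_detach_rate, "bead_detach_rate", min = 0)
  check_number(bead_speed_factor, "bead_speed_factor", min = 0, max = 1,
               strict_min = TRUE)
  check_number(glide_speed, "glide_speed", min = 0)
  if (!n_flagella %in% c(1L, 2L)) abort("`n_flagella` must be 1 or 2.")
  check_number(psf_sigma, "psf_sigma", min = 0, strict_min = TRUE)
  check_number(photon_rate, "photon_rate", min = 0)
  check_number(background_rate, "background_rate", min = 0)
  check_number(read_noise, "read_noise", min = 0)
  check_number(seed, "seed")

  cfg <- list(
    flagellum_length = flagellum_length, duration = duration,
    frame_interval = frame_interval, pixel_size = pixel_size,
    v_antero = v_antero, v_retro = v_retro,
    v_antero_sd = v_antero_sd, v_retro_sd = v_retro_sd,
    injection_rate_antero = injection_rate_antero,
    injection_rate_retro = injection_rate_retro,
    ca_free = ca_free, ca_half = ca_half,
    pause_rate_max = pause_rate_max,
    pause_rate_residual = pause_rate_residual,
    pause_duration_mean = pause_duration_mean,
    bead_diffusion_coeff = bead_diffusion_coeff,
    bead_attach_rate = bead_attach_rate,
    bead_detach_rate = bead_detach_rate,
    bead_speed_factor = bead_speed_factor,
    glide_speed = glide_speed, n_flagella = as.integer(n_flagella),
    psf_sigma = psf_sigma, photon_rate = photon_rate,
    background_rate = background_rate, read_noise = read_noise,
    seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

#' Saturating calcium -> pause-rate map
#'
#' Hill saturation with coefficient 1: `H(c) = c / (c + ca_half)`, so
#' `H(0) = 0` and `H` approaches 1 well below physiological calcium. The
#' pausing rate interpolates between the residual (calcium-deprived) and
#' maximal rates.
#'
#' @param ca_free Free calcium, mol/L.
#' @param config A [sim_config()].
#' @return Pausing rate in s^-1.
#' @export
ca_pause_rate <- function(ca_free, config) {
  check_number(ca_free, "ca_free", min = 0)
  h <- ca_free / (ca_free + config$ca_half)
  config$pause_rate_residual +
    (config$pause_rate_max - config$pause_rate_residual) * h
}

#' Configuration for the bead-in-trap simulator
#'
#' Parameters of the overdamped Langevin simulation of a bead held in a
#' stationary optical trap while IFT motors pull it through the flagellar
#' membrane: force ramps, stalls, releases, escapes and exponential recoils.
#'
#' @param stiffness Trap stiffness kappa, pN/nm (calibration target ~0.4).
#' @param drag Drag constant gamma of the bead-membrane-train complex,
#'   pN s/um (measured ~8).
#' @param sampling_rate Detector sampling rate, Hz (QPD recorded at 2 kHz).
#' @param kT Thermal energy, pN nm (4.11 at room temperature).
#' @param stall_force_mean,stall_force_sd Normal stall-force draw per run, pN.
#' @param stall_dwell_mean Mean of the exponential stall-dwell distribution, s.
#'   Runs whose drawn dwell is shorter than 0.1 s are releases by the stall
#'   definition.
#' @param escape_fraction Fraction of runs in which the motors keep producing
#'   force past the detector's linear range instead of stalling.
#' @param motor_velocity Unloaded motor velocity, um/s; sets the force ramp
#'   rate `stiffness * motor_velocity`.
#' @param run_rate Rate at which new motor runs begin when the bead is idle in
#'   the trap, s^-1.
#' @param detach_probability Probability per integration step of premature
#'   motor detachment during a force ramp (produces extra releases).
#' @param range_nm Linear detection range of the QPD, nm.
#' @param p_retrograde Probability that a run is retrograde-directed.
#' @param seed Integer seed.
#'
#' @return A `trap_sim_config` object.
#' @export
trap_sim_config <- function(stiffness = 0.4,
                            drag = 8.0,
                            sampling_rate = 2000,
                            kT = 4.11,
                            stall_force_mean = 25.2,
                            stall_force_sd = 5,
                            stall_dwell_mean = 0.5,
                            escape_fraction = 0.1,
                            motor_velocity = 2.0,
                            run_rate = 0.5,
                            detach_probability = 0,
                            range_nm = 200,
                            p_retrograde = 0.5,
                            seed = 1L) {
  check_number(stiffness, "stiffness", min = 0, strict_min = TRUE)
  check_number(drag, "drag", min = 0, strict_min = TRUE)
  check_number(sampling_rate, "sampling_rate", min = 0, strict_min = TRUE)
  check_number(kT, "kT", min = 0)
  check_number(stall_force_mean, "stall_force_mean", min = 0)
  check_number(stall_force_sd, "stall_force_sd", min = 0)
  check_number(stall_dwell_mean, "stall_dwell_mean", min = 0, strict_min = TRUE)
  check_number(escape_fraction, "escape_fraction", min = 0, max = 1)
  check_number(motor_velocity, "motor_velocity", min = 0)
  check_number(run_rate, "run_rate", min = 0)
  check_number(detach_probability, "detach_probability", min = 0, max = 1)
  check_number(range_nm, "range_nm", min = 0, strict_min = TRUE)
  check_number(p_retrograde, "p_retrograde", min = 0, max = 1)
  check_number(seed, "seed")

  # Euler-Maruyama stability: dt * kappa / gamma < 1 (gamma in pN s/nm).
  dt <- 1 / sampling_rate
  gamma_nm <- drag / 1000
  if (dt * stiffness / gamma_nm >= 1) {
    abort("Unstable integration: frame step too large for stiffness/drag (dt*kappa/gamma >= 1).")
  }

  structure(list(
    stiffness = stiffness, drag = drag, sampling_rate = sampling_rate,
    kT = kT, stall_force_mean = stall_force_mean,
    stall_force_sd = stall_force_sd, stall_dwell_mean = stall_dwell_mean,
    escape_fraction = escape_fraction, motor_velocity = motor_velocity,
    run_rate = run_rate, detach_probability = detach_probability,
    range_nm = range_nm, p_retrograde = p_retrograde,
    seed = as.integer(seed)
  ), class = "trap_sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  flagellum %g um, %g s at %g s/frame, %d flagella\n",
              x$flagellum_length, x$duration, x$frame_interval, x$n_flagella))
  cat(sprintf("  v_antero %g um/s, v_retro %g um/s; injection %g + %g /s\n",
              x$v_antero, x$v_retro, x$injection_rate_antero,
              x$injection_rate_retro))
  cat(sprintf("  pause rate %g s^-1 at [Ca2+] = %g M (residual %g)\n",
              ca_pause_rate(x$ca_free, x), x$ca_free, x$pause_rate_residual))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' @export
print.trap_sim_config <- function(x, ...) {
  cat("<trap_sim_config>\n")
  cat(sprintf("  kappa %g pN/nm, gamma %g pN s/um (tau %g ms), %g Hz\n",
              x$stiffness, x$drag, 1000 * (x$drag / 1000) / x$stiffness,
              x$sampling_rate))
  cat(sprintf("  stall %g +/- %g pN, dwell %g s, escape fraction %g, seed %d\n",
              x$stall_force_mean, x$stall_force_sd, x$stall_dwell_mean,
              x$escape_fraction, x$seed))
  invisible(x)
}
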