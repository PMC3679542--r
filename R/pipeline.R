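#' Drag constant from the recoils following classified events
#'
#' For each stall or release event, the recoil segment (from the excursion
#' peak back to baseline) is fitted with [fit_recoil()]; the per-event drag
#' constants are pooled.
#'
#' @param trace A `trap_trace`.
#' @param events Events from [classify_events()] (stalls/releases used).
#' @param kappa Trap stiffness, pN/nm (default: trace metadata).
#' @param min_r_squared Per-fit quality threshold.
#' @return A tibble of per-event fits (`t_start`, `gamma`, `tau`,
#'   `r_squared`), possibly empty.
#' @export
recoil_drag <- function(trace, events, kappa = NULL, min_r_squared = 0.8) {
  kappa <- kappa %||% attr(trace, "kappa")
  d <- trace_data(trace)
  ev <- events[events$type %in% c("stall", "release"), , drop = FALSE]
  kT <- attr(trace, "kT") %||% 4.11
  sigma <- sqrt(kT / kappa)
  out <- list()
  for (i in seq_len(nrow(ev))) {
    seg <- d[d$t >= ev$t_start[i] & d$t <= ev$t_end[i], , drop = FALSE]
    if (nrow(seg) < 12) next
    y <- abs(seg$x - median(d$x))
    # recoil starts at detachment: the last sample still at the plateau level
    # (the event peak force divided by kappa)
    level <- ev$peak_force[i] / kappa
    at_level <- which(y >= level - sigma)
    if (!length(at_level)) next
    start_idx <- max(at_level)
    rec <- seg[start_idx:nrow(seg), , drop = FALSE]
    if (nrow(rec) < 10) next
    f <- tryCatch(fit_recoil(rec, kappa, min_r_squared),
                  error = function(e) NULL)
    if (is.null(f)) next
    # tau longer than the observed decay is not identifiable
    if (f$tau > diff(range(rec$t))) next
    out[[length(out) + 1L]] <- tibble(t_start = ev$t_start[i],
                                      gamma = f$gamma, tau = f$tau,
                                      r_squared = f$r_squared)
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble(t_start = numeric(), gamma = numeric(), tau = numeric(),
           r_squared = numeric())
}

#' Run the full synthetic analysis pipeline
#'
#' Orchestrates simulate -> render -> kymograph -> FSDA -> event statistics
#' -> trap analysis under a single seed and returns a report of the summary
#' quantities. With `out_dir` set, artifacts (movie, kymograph, tracks,
#' events, report) are written with JSON sidecars echoing the config and
#' seed.
#'
#' @param config A named list (or path to a YAML file) with optional elements
#'   `sim` (arguments to [sim_config()]), `trap` (arguments to
#'   [trap_sim_config()]), `trap_duration` (s), `stages` (character subset of
#'   `c("simulate", "render", "kymo", "fsda", "events", "trap")`), and
#'   `coloc_n_null`. Unknown elements are an error.
#' @param seed Global seed (overrides `config$seed`).
#' @param out_dir Optional output directory.
#' @return A `pipeline_report` (list): `summary` (named list of headline
#'   numbers), `truth`, `kymo`, `fsda`, `pauses`, `glides`, `lag`,
#'   `independence`, `coloc`, `trap` objects as produced by each stage.
#' @export
run_pipeline <- function(config = list(), seed = NULL, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("sim", "trap", "trap_duration", "stages", "coloc_n_null", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    abort(sprintf("Unknown config keys: %s", paste(unknown, collapse = ", ")))
  }
  seed <- seed %||% config$seed %||% 1L
  stages <- config$stages %||% c("simulate", "render", "kymo", "fsda",
                                 "events", "trap")
  bad <- setdiff(stages, c("simulate", "render", "kymo", "fsda", "events",
                           "trap"))
  if (length(bad)) abort(sprintf("Unknown stages: %s", paste(bad, collapse = ", ")))

  cfg <- do.call(sim_config, c(config$sim %||% list(), list(seed = seed)))
  out <- list(config = cfg, seed = seed)
  summary <- list(seed = seed)

  if ("simulate" %in% stages) {
    truth <- simulate_ift(cfg)
    truth <- simulate_bead(cfg, truth)
    truth <- simulate_gliding(cfg, truth)
    out$truth <- truth
    summary$n_trains <- nrow(truth$trains)
    summary$n_pauses <- nrow(truth$pauses)
  }

  if ("render" %in% stages) {
    out$movie <- render_movie(out$truth, cfg)
  }

  if ("kymo" %in% stages && !is.null(out$movie)) {
    pl <- straight_path(cfg$flagellum_length, cfg$pixel_size,
                        dim(out$movie)[2] / 2, 8)
    out$kymo <- sample_kymograph(out$movie, pl)
  }

  if ("fsda" %in% stages && !is.null(out$kymo)) {
    out$fsda <- fsda_decompose(out$kymo)
    en <- out$fsda$energy
    summary$energy_anterograde <- en$fraction[en$bin == "anterograde"]
    summary$energy_retrograde <- en$fraction[en$bin == "retrograde"]
    summary$energy_paused <- en$fraction[en$bin == "paused"]
  }

  if ("events" %in% stages && !is.null(out$truth)) {
    truth <- out$truth
    out$pauses <- detect_pauses(truth$track,
                                acquisition_time = cfg$duration,
                                n_flagella = cfg$n_flagella)
    summary$pause_frequency <- out$pauses$frequency_corrected
    out$glides <- detect_gliding_onset(truth$body)
    summary$n_glides <- nrow(out$glides)
    if (nrow(out$glides)) {
      summary$gliding_speed <- mean(out$glides$speed)
      lag <- tryCatch(lag_time_analysis(truth$pauses, out$glides),
                      error = function(e) NULL)
      out$lag <- lag
      if (!is.null(lag)) {
        summary$mean_lag <- lag$mean
        mean_interpause <- cfg$duration / max(1, nrow(truth$pauses))
        out$independence <- independence_test(
          lag$mean, max(2, lag$n), mean_interpause,
          n_mc = 1e5, seed = child_seed(seed, 17L))
        summary$independence_p <- out$independence$p_value
      }
    }
    if (!is.null(truth$bead) && nrow(truth$track)) {
      out$coloc <- tryCatch(
        colocalization_test(truth$bead, truth$track,
                            n_null = config$coloc_n_null %||% 50,
                            seed = child_seed(seed, 23L),
                            duration = cfg$duration),
        error = function(e) NULL)
      if (!is.null(out$coloc)) summary$coloc_p <- out$coloc$p_value
    }
  }

  if ("trap" %in% stages) {
    tcfg <- do.call(trap_sim_config,
                    c(config$trap %||% list(), list(seed = child_seed(seed, 29L))))
    trace <- simulate_trap_trace(tcfg, duration = config$trap_duration %||% 60)
    out$trap <- list(trace = trace)
    calib_cfg <- tcfg; calib_cfg$run_rate <- 0
    calib <- calibrate_stiffness(
      simulate_trap_trace(calib_cfg, duration = 20))
    out$trap$calibration <- calib
    summary$kappa_calibrated <- calib$kappa
    ev <- classify_events(trace)
    out$trap$events <- ev
    if (nrow(ev)) {
      fs <- peak_force_stats(ev)
      out$trap$force_stats <- fs
      st <- fs$summary[fs$summary$type == "stall", ]
      if (nrow(st)) summary$stall_force_mean <- sum(st$mean * st$n) / sum(st$n)
      rd <- recoil_drag(trace, ev)
      out$trap$recoils <- rd
      if (nrow(rd)) summary$gamma_recoil <- median(rd$gamma)
    }
    osc <- simulate_trap_oscillation(gamma = tcfg$drag, seed = child_seed(seed, 31L))
    out$trap$oscillation <- oscillation_drag(osc)
    summary$gamma_oscillation <- out$trap$oscillation$gamma_mean
  }

  out$summary <- summary
  out <- structure(out, class = "pipeline_report")
  if (!is.null(out_dir)) write_pipeline_artifacts(out, out_dir, config)
  out
}

write_pipeline_artifacts <- function(report, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  extra <- list(seed = report$seed, config = config)
  if (!is.null(report$movie)) {
    write_movie(report$movie, file.path(out_dir, "movie.tif"), extra)
  }
  if (!is.null(report$kymo)) {
    write_kymograph(report$kymo, file.path(out_dir, "kymograph.tif"), extra)
  }
  if (!is.null(report$truth)) {
    write_table_csv(report$truth$track, file.path(out_dir, "tracks.csv"))
    write_table_csv(report$truth$pauses, file.path(out_dir, "pauses.csv"))
    if (!is.null(report$truth$bead)) {
      write_table_csv(report$truth$bead, file.path(out_dir, "bead.csv"))
    }
    if (!is.null(report$truth$body)) {
      write_table_csv(report$truth$body, file.path(out_dir, "body.csv"))
    }
  }
  if (!is.null(report$trap$events)) {
    write_table_csv(report$trap$events, file.path(out_dir, "trap_events.csv"))
  }
  jsonlite::write_json(report$summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  for (nm in names(x$summary)) {
    v <- x$summary[[nm]]
    cat(sprintf("  %-22s %s\n", nm,
                if (is.numeric(v)) format(signif(v, 5)) else as.character(v)))
  }
  invisible(x)
}

#' @export
glance.pipeline_report <- function(x, ...) {
  as_tibble(x$summary[vapply(x$summary, is.numeric, logical(1))])
}
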