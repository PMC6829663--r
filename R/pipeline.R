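#' Run one stage of the granule-analysis pipeline
#'
#' Ties the package's stages into the three standard analysis paths
#' (docking/density, exocytosis, enrichment) behind a single YAML-driven
#' entry point. Every stage writes its outputs together with a JSON
#' manifest echoing the full parameter set, package version and seed.
#'
#' Config layout (YAML or named list): top-level \code{outdir}, \code{seed},
#' \code{pixel_size}, \code{frame_interval}, plus one section per stage
#' (\code{simulate}, \code{detect}, \code{dock}, \code{fuse},
#' \code{enrich}, \code{trace}, \code{report}) holding that stage's
#' parameters and input paths.
#'
#' @param cmd one of "simulate", "detect", "dock", "fuse", "enrich",
#'   "trace", "report".
#' @param config named list, or path to a YAML file.
#' @return named list of artifact paths and stage counts, invisibly.
#' @export
run_pipeline <- function(cmd = c("simulate", "detect", "dock", "fuse",
                                 "enrich", "trace", "report"),
                         config) {
  cmd <- match.arg(cmd)
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  outdir <- config$outdir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  switch(cmd,
         simulate = stage_simulate(config, outdir),
         detect = stage_detect(config, outdir),
         dock = stage_dock(config, outdir),
         fuse = stage_fuse(config, outdir),
         enrich = stage_enrich(config, outdir),
         trace = stage_trace(config, outdir),
         report = stage_report(config, outdir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cfg_sim_config <- function(config) {
  s <- config$simulate %||% list()
  sim_config(image_shape = unlist(s$image_shape %||% c(128L, 128L)),
             n_frames = s$n_frames %||% 100L,
             frame_interval = config$frame_interval %||% 1,
             pixel_size = config$pixel_size %||% 100,
             psf_sigma = s$psf_sigma %||% 1.3,
             background_level = s$background_level %||% 100,
             read_noise_sd = s$read_noise_sd %||% 0,
             spot_amplitude = s$spot_amplitude %||% 500,
             snr = s$snr, shot_noise = s$shot_noise %||% TRUE,
             seed = config$seed)
}

cfg_detection <- function(config) {
  d <- config$detect %||% list()
  detection_params(prominence = d$prominence,
                   min_separation = d$min_separation %||% 3,
                   smoothing_sigma = d$smoothing_sigma %||% 1)
}

cfg_docking <- function(config) {
  d <- config$dock %||% list()
  docking_params(link_radius = d$link_radius %||% 3,
                 max_gap = d$max_gap %||% 1,
                 confine_radius = d$confine_radius %||% 1.5,
                 t_min = d$t_min %||% 2, t_dock = d$t_dock %||% 25,
                 t_survival = d$t_survival %||% 40)
}

stage_simulate <- function(config, outdir) {
  s <- config$simulate %||% list()
  cfg <- cfg_sim_config(config)
  res <- residence_model(arrival_rate = s$arrival_rate %||% 0.2,
                         p_dock = s$p_dock %||% 0.5,
                         n_arrivals = s$n_arrivals)
  sim <- simulate_movie(cfg, res)
  movie_path <- file.path(outdir, "movie.tif")
  gt_path <- file.path(outdir, "ground_truth.json")
  write_movie_tiff(sim$movie, movie_path)
  write_ground_truth(sim$ground_truth, gt_path)
  utils::write.csv(sim$ground_truth$spots,
                   file.path(outdir, "ground_truth_spots.csv"),
                   row.names = FALSE)
  write_manifest(file.path(outdir, "simulate_manifest.json"), "simulate",
                 params = c(cfg[setdiff(names(cfg), "shot_noise")],
                            list(shot_noise = cfg$shot_noise,
                                 arrival_rate = s$arrival_rate %||% 0.2,
                                 p_dock = s$p_dock %||% 0.5)),
                 outputs = c(movie_path, gt_path),
                 counts = list(granules = nrow(sim$ground_truth$spots)))
  message(sprintf("simulate: %d granules over %d frames",
                  nrow(sim$ground_truth$spots), cfg$n_frames))
  invisible(list(movie = movie_path, ground_truth = gt_path))
}

load_stage_movie <- function(config, stage) {
  path <- (config[[stage]] %||% list())$movie %||%
    file.path(config$outdir %||% ".", "movie.tif")
  if (!file.exists(path)) stop("input movie not found: ", path, call. = FALSE)
  list(movie = read_movie_tiff(path), path = path)
}

stage_detect <- function(config, outdir) {
  inp <- load_stage_movie(config, "detect")
  dp <- cfg_detection(config)
  spots <- detect_movie(inp$movie, dp)
  spots_path <- file.path(outdir, "spots.csv")
  utils::write.csv(spots, spots_path, row.names = FALSE)
  mask <- footprint_mask(inp$movie)
  dens <- granule_density(spots[spots$frame == 1, , drop = FALSE],
                          mask = mask,
                          pixel_size = config$pixel_size %||% 100)
  write_manifest(file.path(outdir, "detect_manifest.json"), "detect",
                 params = c(unclass(dp),
                            list(pixel_size = config$pixel_size %||% 100)),
                 inputs = inp$path, outputs = spots_path,
                 counts = list(spots = nrow(spots),
                               density_per_um2_frame1 = dens))
  message(sprintf("detect: %d spots, frame-1 density %.4f /um^2",
                  nrow(spots), dens))
  invisible(list(spots = spots_path, density = dens))
}

stage_dock <- function(config, outdir) {
  inp <- load_stage_movie(config, "dock")
  dp <- cfg_detection(config)
  kp <- cfg_docking(config)
  fi <- config$frame_interval %||% 1
  spots <- detect_movie(inp$movie, dp)
  tracks <- link_tracks(spots, kp, frame_interval = fi)
  events <- classify_all(tracks, kp)
  frac <- docking_fraction(events, tracks, kp)
  events$approach_time_s <- events$approach_frame * fi
  events_path <- file.path(outdir, "docking_events.csv")
  tracks_path <- file.path(outdir, "tracks.csv")
  utils::write.csv(events, events_path, row.names = FALSE)
  utils::write.csv(tracks_to_df(tracks), tracks_path, row.names = FALSE)
  write_manifest(file.path(outdir, "dock_manifest.json"), "dock",
                 params = c(unclass(dp), unclass(kp),
                            list(frame_interval = fi)),
                 inputs = inp$path, outputs = c(events_path, tracks_path),
                 counts = list(tracks = length(tracks),
                               docked = sum(events$class == "docked"),
                               visitor = sum(events$class == "visitor"),
                               transit = sum(events$class == "transit"),
                               n_approach = frac$n_approach,
                               n_stable = frac$n_stable,
                               docking_fraction = frac$fraction))
  message(sprintf("dock: %d tracks (%d docked / %d visitor / %d transit)",
                  length(tracks), sum(events$class == "docked"),
                  sum(events$class == "visitor"),
                  sum(events$class == "transit")))
  invisible(list(events = events_path, tracks = tracks_path,
                 fraction = frac))
}

stage_fuse <- function(config, outdir) {
  inp <- load_stage_movie(config, "fuse")
  dp <- cfg_detection(config)
  kp <- cfg_docking(config)
  fi <- config$frame_interval %||% 1
  f <- config$fuse %||% list()
  spots <- detect_movie(inp$movie, dp)
  tracks <- link_tracks(spots, kp, frame_interval = fi)
  events <- detect_fusion_events(tracks, inp$movie,
                                 drop_fraction = f$drop_fraction %||% 0.5,
                                 loss_max = f$loss_max %||% 2)
  events_path <- file.path(outdir, "fusion_events.csv")
  utils::write.csv(events, events_path, row.names = FALSE)
  write_manifest(file.path(outdir, "fuse_manifest.json"), "fuse",
                 params = list(drop_fraction = f$drop_fraction %||% 0.5,
                               loss_max = f$loss_max %||% 2,
                               frame_interval = fi,
                               detection = unclass(dp),
                               linking = unclass(kp)),
                 inputs = inp$path, outputs = events_path,
                 counts = list(tracks = length(tracks),
                               fusion_events = nrow(events)))
  message(sprintf("fuse: %d fusion events in %d tracks",
                  nrow(events), length(tracks)))
  invisible(list(events = events_path, n_events = nrow(events)))
}

stage_enrich <- function(config, outdir) {
  e <- config$enrich %||% list()
  if (is.null(e$marker) || is.null(e$probe))
    stop("enrich stage needs 'marker' and 'probe' TIFF paths", call. = FALSE)
  marker <- read_movie_tiff(e$marker)
  probe <- read_movie_tiff(e$probe)
  res <- enrichment_analysis(marker, probe, rule = e$rule %||% "trapezoid",
                             min_structures = e$min_structures %||% 15)
  out <- data.frame(cell_id = e$cell_id %||% 1, N_gr = res$N_gr,
                    N_All = res$N_All, min = res$min, AUC_gr = res$AUC_gr,
                    AUC_All = res$AUC_All, E = res$E, E_null = res$E_null,
                    excess = res$excess)
  out_path <- file.path(outdir, "enrichment.csv")
  utils::write.csv(out, out_path, row.names = FALSE)
  write_manifest(file.path(outdir, "enrich_manifest.json"), "enrich",
                 params = list(rule = e$rule %||% "trapezoid",
                               min_structures = e$min_structures %||% 15),
                 inputs = c(e$marker, e$probe), outputs = out_path,
                 counts = list(n_crops = dim(marker)[3], E = res$E))
  message(sprintf("enrich: E = %.3f (null %.3f) from %d crops",
                  res$E, res$E_null, dim(marker)[3]))
  invisible(list(enrichment = out_path, result = res))
}

stage_trace <- function(config, outdir) {
  tcfg <- config$trace %||% list()
  if (is.null(tcfg$csv)) stop("trace stage needs a 'csv' input path",
                              call. = FALSE)
  d <- utils::read.csv(tcfg$csv)
  tr <- granule_trace(d$time_s, d$raw,
                      background = d$background %||% 0,
                      stimulus_window = unlist(tcfg$stimulus_window))
  tr <- normalize_trace(tr)
  mr <- max_response(tr)
  ru <- tryCatch(reuptake_rate(tr, horizon = tcfg$horizon %||% 60),
                 error = function(e) NULL)
  out <- data.frame(cell_id = tcfg$cell_id %||% 1, max_response = mr,
                    tau_s = if (is.null(ru)) NA_real_ else ru$tau_s)
  out_path <- file.path(outdir, "trace_summary.csv")
  utils::write.csv(out, out_path, row.names = FALSE)
  norm_path <- file.path(outdir, "trace_normalized.csv")
  utils::write.csv(data.frame(time_s = tr$time, raw = tr$raw,
                              F_over_F0 = tr$F_over_F0),
                   norm_path, row.names = FALSE)
  write_manifest(file.path(outdir, "trace_manifest.json"), "trace",
                 params = tcfg, inputs = tcfg$csv,
                 outputs = c(out_path, norm_path),
                 counts = list(max_response = mr,
                               tau_s = out$tau_s))
  invisible(list(summary = out_path, max_response = mr))
}

stage_report <- function(config, outdir) {
  r <- config$report %||% list()
  if (is.null(r$a) || is.null(r$b))
    stop("report stage needs per-cell value CSVs 'a' and 'b'", call. = FALSE)
  va <- utils::read.csv(r$a)[[r$column %||% "value"]]
  vb <- utils::read.csv(r$b)[[r$column %||% "value"]]
  cmp <- compare_conditions(condition_summary(va, r$label_a %||% "a"),
                            condition_summary(vb, r$label_b %||% "b"),
                            design = r$design %||% "unpaired")
  out_path <- file.path(outdir, "comparison.json")
  jsonlite::write_json(cmp, out_path, auto_unbox = TRUE, digits = NA)
  write_manifest(file.path(outdir, "report_manifest.json"), "report",
                 params = r, inputs = c(r$a, r$b), outputs = out_path,
                 counts = list(p = cmp$p,
                               percent_change = cmp$percent_change))
  invisible(list(comparison = out_path, result = cmp))
}
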