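# Reproducible generate -> analyze -> report orchestration. One config
# (YAML file or equivalent list) drives everything; the config is copied
# verbatim into the output directory, every stochastic stage takes its seed
# from the config, and all numeric outputs go to CSV/JSON files (logging to
# stderr and a run log, never numbers on stdout).

pipeline_log <- function(logfile, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  message(msg)
  cat(msg, "\n", file = logfile, append = TRUE)
}

#' Run the full analysis pipeline from a config
#'
#' Stages (each optional, controlled by the config): trajectory generation
#' (or loading), curvature preference and peak-to-peak statistics,
#' clustering/contact analysis, Boltzmann inversion of pair distances,
#' thickness/area profiles, tilt/rotation kinematics, and sorting-table
#' computations. Per-stage CSV/JSON outputs and a `summary.json` are
#' written into the output directory; stage failures abort with the
#' failing stage named (outputs of completed stages are retained).
#'
#' Config keys: `seed`; `output_dir`; `generator` (either `preset` plus
#' overrides, or `coord_path`/`metadata_path` to load); `analyses`: any of
#' `curvature` (`n_slices`, `vicinity_cutoff`, `n_bins`), `undulations`,
#' `contacts` (`loose_threshold`, `close_threshold`, `debounce`),
#' `potential` (`bin_width`, `jacobian`, `second_half_only`), `profiles`
#' (`bin_width`, `correction`, `area_frames`), `kinematics`; `sorting`
#' (`records_csv`).
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#' @return Invisibly, the summary list (also written to `summary.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$output_dir)) stop("pipeline config: 'output_dir' is required")
  if (is.null(cfg$seed)) stop("pipeline config: 'seed' is required")
  if (is.null(cfg$generator))
    stop("pipeline config: 'generator' (preset or input paths) is required")
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out, "run.log")
  cat("", file = logfile)
  yaml::write_yaml(cfg, file.path(out, "config.yaml"))
  seed <- as.integer(cfg$seed)
  summary <- list(seed = seed)
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    pipeline_log(logfile, "stage %-12s done in %.1f s", name,
                 proc.time()[3] - t0)
    res
  }

  gen <- cfg$generator
  sim <- stage("generate", {
    if (!is.null(gen$coord_path)) {
      list(trajectory = load_trajectory(gen$coord_path, gen$metadata_path),
           truth = NULL)
    } else {
      preset <- if (is.null(gen$preset)) "control" else gen$preset
      overrides <- gen[setdiff(names(gen), "preset")]
      generate_membrane_trajectory(
        do.call(generator_preset,
                c(list(name = preset, seed = seed), overrides)))
    }
  })
  traj <- sim$trajectory
  an <- if (is.null(cfg$analyses)) list() else cfg$analyses

  if (isTRUE(an$undulations) || !is.null(an$curvature)) {
    und <- stage("undulations", peak_to_peak(traj))
    utils::write.csv(data.frame(frame = seq_along(und$h), h = und$h),
                     file.path(out, "peak_to_peak.csv"), row.names = FALSE)
    summary$undulations <- list(mean_h = und$mean, sd_h = und$sd)
  }

  if (!is.null(an$curvature)) {
    a <- an$curvature
    cp <- stage("curvature", curvature_preference(
      traj,
      vicinity_cutoff = if (is.null(a$vicinity_cutoff)) 3 else a$vicinity_cutoff,
      n_slices = if (is.null(a$n_slices)) 30L else a$n_slices,
      n_bins = if (is.null(a$n_bins)) 120L else a$n_bins,
      seed = seed))
    utils::write.csv(data.frame(frame = seq_along(cp$near_series),
                                near = cp$near_series,
                                away = cp$away_series),
                     file.path(out, "curvature_preference.csv"),
                     row.names = FALSE)
    summary$curvature <- list(
      mean_c_near = cp$near$estimate, ci_near = cp$near$ci,
      mean_c_away = cp$away$estimate, ci_away = cp$away$ci,
      mean_radius_near = cp$mean_radius_near)
  }

  if (!is.null(an$contacts)) {
    a <- an$contacts
    res <- stage("contacts", {
      ds <- distance_series(traj)
      loose <- if (is.null(a$loose_threshold)) 2.0 else a$loose_threshold
      close <- if (is.null(a$close_threshold)) 0.7 else a$close_threshold
      cf <- cluster_fraction(ds, loose, seed = seed)
      ev <- contact_events(ds, close,
                           debounce = if (is.null(a$debounce)) 0L else a$debounce)
      list(ds = ds, cf = cf, ev = ev)
    })
    utils::write.csv(res$ds, file.path(out, "pair_distances.csv"),
                     row.names = FALSE)
    utils::write.csv(res$ev, file.path(out, "contact_events.csv"),
                     row.names = FALSE)
    summary$contacts <- list(
      cluster_fraction = res$cf$fraction, cluster_ci = res$cf$ci,
      n_events = nrow(res$ev),
      weighted_lifetime = if (nrow(res$ev)) weighted_lifetime(res$ev)
      else NA_real_)
  }

  if (!is.null(an$potential)) {
    a <- an$potential
    pc <- stage("potential", {
      ds <- distance_series(traj)
      second <- !identical(a$second_half_only, FALSE)
      d <- if (second) ds$com[ds$frame > n_frames(traj) / 2] else ds$com
      h <- distance_histogram(d, bin_width = if (is.null(a$bin_width)) 0.25
                              else a$bin_width)
      boltzmann_invert(h, jacobian = !identical(a$jacobian, FALSE))
    })
    utils::write.csv(as.data.frame(pc), file.path(out, "potential.csv"),
                     row.names = FALSE)
    wp <- well_parameters(pc)
    summary$potential <- list(well_depth = wp$depth,
                              well_location = wp$location, flat = wp$flat)
  }

  if (!is.null(an$profiles)) {
    a <- an$profiles
    bw <- if (is.null(a$bin_width)) 0.5 else a$bin_width
    tp <- stage("thickness", thickness_profile(
      traj, bin_width = bw,
      correction = !identical(a$correction, FALSE)))
    utils::write.csv(tp, file.path(out, "thickness_profile.csv"),
                     row.names = FALSE)
    summary$thickness <- list(min_d = min(tp$value),
                              far_d = mean(tp$value[tp$r > 10]))
    if (!is.null(a$area_frames)) {
      fr <- seq(1L, n_frames(traj), length.out = min(a$area_frames,
                                                     n_frames(traj)))
      ap <- stage("area", area_per_chain_profile(traj, "upper",
                                                 bin_width = bw,
                                                 frames = unique(round(fr))))
      utils::write.csv(ap, file.path(out, "area_per_chain_upper.csv"),
                       row.names = FALSE)
      summary$area_per_chain <- list(near = ap$value[1],
                                     far = mean(ap$value[ap$r > 10]))
    }
  }

  if (isTRUE(an$kinematics)) {
    kin <- stage("kinematics", {
      ts <- tilt_series(traj)
      ids <- protein_ids(traj)
      rates <- vapply(ids, function(p)
        rotation_rate(rotor_angle_series(traj, p), traj_dt(traj)),
        numeric(1))
      list(tilt = ts, rates = rates)
    })
    utils::write.csv(as.data.frame(kin$tilt),
                     file.path(out, "tilt_series.csv"), row.names = FALSE)
    summary$kinematics <- list(mean_tilt = mean(kin$tilt),
                               rotation_rate = mean(kin$rates))
  }

  if (!is.null(cfg$sorting) && !is.null(cfg$sorting$records_csv)) {
    recs <- stage("sorting", read_sorting_records(cfg$sorting$records_csv))
    S <- vapply(recs, sorting_ratio, numeric(1))
    utils::write.csv(data.frame(S = S),
                     file.path(out, "sorting_ratios.csv"), row.names = FALSE)
    summary$sorting <- list(mean_S = mean(S), n = length(S))
  }

  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log(logfile, "pipeline complete (%d stages)", length(summary) - 1L)
  invisible(summary)
}

#' Write the small deterministic fixtures used by the test suite
#'
#' Emits a flat-membrane trajectory, a single-mode sinusoid trajectory, a
#' planted contact series, a well-sampled distance set and a synthetic
#' sorting table, together with an md5 manifest. If the manifest already
#' matches, nothing is regenerated.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return The fixture directory, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(dir, "manifest.json")
  files <- c("flat.gro", "flat.json", "sinusoid.gro", "sinusoid.json",
             "contacts.csv", "distances.csv", "sorting.csv")
  if (file.exists(manifest_path)) {
    man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    paths <- file.path(dir, files)
    if (all(file.exists(paths)) &&
        identical(unname(tools::md5sum(paths)), unname(unlist(man[files]))) &&
        identical(man$seed, as.integer(seed)))
      return(invisible(dir))
  }
  flat <- generate_membrane_trajectory(generator_config(
    box = c(20, 8), n_lipids_per_leaflet = 60, n_proteins = 0,
    lateral_jitter = 0, n_frames = 2, seed = seed))
  write_trajectory(flat$trajectory, file.path(dir, "flat.gro"),
                   metadata_path = file.path(dir, "flat.json"))
  sinus <- generate_membrane_trajectory(generator_config(
    box = c(52, 8), n_lipids_per_leaflet = 400, n_proteins = 0,
    undulation_modes = data.frame(m = 1, amplitude = 2, amplitude_sd = 0,
                                  phase = 0, phase_drift = 0),
    lateral_jitter = 0, n_frames = 2, seed = seed))
  write_trajectory(sinus$trajectory, file.path(dir, "sinusoid.gro"),
                   metadata_path = file.path(dir, "sinusoid.json"))
  ct <- generate_contact_series(list(c(2, 3), c(1, 1), c(4, 6)))
  utils::write.csv(data.frame(frame = seq_along(ct$series),
                              in_contact = ct$series),
                   file.path(dir, "contacts.csv"), row.names = FALSE)
  d <- sample_pair_distances(potential_spec(), 2000, seed = seed)
  utils::write.csv(data.frame(l = round(d, 6)),
                   file.path(dir, "distances.csv"), row.names = FALSE)
  set.seed(seed)
  n <- 24
  cc <- stats::runif(n, 0.005, 0.05)
  S <- exp(cc / 0.03) * exp(stats::rnorm(n, 0, 0.05))
  utils::write.csv(data.frame(I_tube_prot = S, I_GUV_prot = 1,
                              I_tube_lip = 1, I_GUV_lip = 1,
                              r_t = 1 / cc, condition = "synthetic"),
                   file.path(dir, "sorting.csv"), row.names = FALSE)
  paths <- file.path(dir, files)
  man <- as.list(tools::md5sum(paths))
  names(man) <- files
  man$seed <- as.integer(seed)
  jsonlite::write_json(man, manifest_path, auto_unbox = TRUE)
  invisible(dir)
}
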