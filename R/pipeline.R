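#' Default run configuration
#'
#' All tunable parameters of simulation, detection, matching, normalization
#' and classification, with documented defaults. The configuration
#' round-trips losslessly through YAML ([write_config()] /
#' [read_config()]).
#'
#' @param seed Integer seed used by every stochastic stage.
#' @return Nested list of class `"tsfitge_config"`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    simulate = list(
      n_species = 200L, n_targets = 1L, target_delta_tm = 8,
      n_ptm_substrates = 0L, treatment_minutes = 20,
      temperatures = c(37, 41, 44, 47, 50, 53, 58, 64),
      misregistration_dy = 0, background = 100, noise_add = 30,
      noise_cv = 0.03, image_shape = c(512L, 512L)
    ),
    detect = list(ball_radius = 8, min_snr = 6, min_separation = 2,
                  smooth_sigma = 0.6, fit_radius = 4),
    ratio = list(footprint_px = 25),
    match = list(max_distance = 3, mnn_max_distance = 8),
    classify = default_thresholds()
  ), class = "tsfitge_config")
}

#' Write / read a run configuration (YAML)
#'
#' @param config A `tsfitge_config`.
#' @param path File path.
#' @return `path` (write) or the configuration (read).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  cfg <- utils::modifyList(unclass(base), cfg)
  structure(cfg, class = "tsfitge_config")
}

# Design implied by a configuration (used by `simulate` stages).
.config_design <- function(config) {
  s <- config$simulate
  experiment_design(temperatures = s$temperatures,
                    treatment_minutes = s$treatment_minutes,
                    misregistration_dy = s$misregistration_dy,
                    background = s$background, noise_add = s$noise_add,
                    noise_cv = s$noise_cv, image_shape = s$image_shape,
                    seed = config$seed)
}

#' Simulate a run described by a configuration
#'
#' Generates the proteome and design from `config$simulate`, renders all
#' gels and writes images + manifest + ground truth to `dir`.
#'
#' @param config A [default_config()]-style configuration.
#' @param dir Output directory.
#' @return Path to the manifest, invisibly.
#' @export
simulate_config_run <- function(config, dir) {
  s <- config$simulate
  pro <- generate_proteome(s$n_species, s$n_targets, s$n_ptm_substrates,
                           seed = config$seed,
                           target_delta_tm = s$target_delta_tm,
                           grid_px = max(s$image_shape))
  des <- .config_design(config)
  simulate_run(pro, des, dir)
}

#' Analyze a set of quantified spot tables
#'
#' The image-free core of the pipeline, also the entry point when spot
#' tables come from external quantification software: cross-gel matching,
#' Cy2 internal-standard normalization, melting fits, shift scoring,
#' baseline pair detection and final classification.
#'
#' @param spot_tables Named list of `spot_table`s (each with `temperature`
#'   and `gel_id` attributes).
#' @param intensity_floor Scalar floor, or named vector by gel id.
#' @param config A `tsfitge_config` (matching and classification
#'   parameters are used).
#' @return List: tracks, curves, fits, shifts, ptm_pairs, artifact_pairs,
#'   calls, candidates.
#' @export
analyze_spot_tables <- function(spot_tables, intensity_floor,
                                config = default_config()) {
  tracks <- match_spots(spot_tables, max_distance = config$match$max_distance,
                        mnn_max_distance = config$match$mnn_max_distance)
  base_gid <- attr(tracks, "baseline_gel")
  base_floor <- if (length(intensity_floor) > 1)
    intensity_floor[[base_gid]] else intensity_floor
  curves <- normalize_tracks(tracks, cy2_floor = base_floor / 3)
  fits <- fit_melting_tracks(curves)
  shifts <- score_shifts(curves, fits)

  th <- utils::modifyList(default_thresholds(), config$classify)
  base_spots <- spot_tables[[base_gid]]
  ptm_pairs <- detect_ptm_pairs(base_spots, base_floor, tau = th$tau,
                                dy_tol = th$dy_tol, dx_range = th$dx_range)
  art_pairs <- detect_registration_artifacts(base_spots, base_floor,
                                             tau = th$tau,
                                             reg_x_tol = th$reg_x_tol,
                                             reg_dy_range = th$reg_dy_range,
                                             intensity_tol = th$intensity_tol)
  calls <- call_spots(shifts, tracks, base_spots, ptm_pairs, art_pairs,
                      base_floor, thresholds = th)
  thermal <- calls[calls$label %in% c("stabilized", "destabilized"), ]
  thermal <- thermal[order(-abs(thermal$z_score)), ]
  list(tracks = tracks, curves = curves, fits = fits, shifts = shifts,
       ptm_pairs = ptm_pairs, artifact_pairs = art_pairs, calls = calls,
       candidates = thermal, baseline_gel = base_gid)
}

#' Run the full TS-FITGE analysis pipeline
#'
#' Executes read -> background correction -> spot detection/quantification
#' -> per-gel ratio tables and box-plot summaries -> cross-gel matching ->
#' internal-standard normalization -> melting fits -> shift scoring ->
#' classification, writing every intermediate table to `out_dir`:
#' `spots_<gel>.tsv`, `ratios_<gel>.tsv`, `boxplot_summaries.json`,
#' `curves.tsv`, `shifts.tsv`, `calls.tsv`, `summary.json`. Deterministic
#' given (config, inputs); `summary.json` records the configuration and its
#' hash.
#'
#' @param manifest Path to a manifest TSV (`filename`, `temperature_C`,
#'   `gel_id`); filenames are resolved relative to the manifest.
#' @param out_dir Output directory (created).
#' @param config A `tsfitge_config`.
#' @return Invisibly, a list with the key tables (`spot_tables`, `ratios`,
#'   `summaries`, `tracks`, `curves`, `fits`, `shifts`, `calls`,
#'   `candidates`), gel metadata and output paths.
#' @export
run_pipeline <- function(manifest, out_dir, config = default_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  man <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  need <- c("filename", "temperature_C")
  if (!all(need %in% names(man)))
    .stopf("manifest must have columns: %s", paste(need, collapse = ", "))
  mdir <- dirname(manifest)
  paths <- file.path(mdir, man$filename)
  missing <- !file.exists(paths)
  if (any(missing))
    .stopf("stage read: manifest references missing file(s): %s",
           paste(man$filename[missing], collapse = ", "))
  if (is.null(man$gel_id)) man$gel_id <- sprintf("T%02d", round(man$temperature_C))

  dt <- config$detect
  gels <- list(); spot_tables <- list(); ratios <- list(); summaries <- list()
  floors <- numeric(0)
  for (i in seq_len(nrow(man))) {
    g <- read_gel(paths[i], man[i, , drop = FALSE])
    g <- correct_gel(g, ball_radius = dt$ball_radius)
    spots <- detect_spots(g, min_snr = dt$min_snr,
                          min_separation = dt$min_separation,
                          smooth_sigma = dt$smooth_sigma,
                          fit_radius = dt$fit_radius)
    gid <- man$gel_id[i]
    floors[gid] <- default_intensity_floor(g, config$ratio$footprint_px)
    write_spot_table(spots, file.path(out_dir, sprintf("spots_%s.tsv", gid)))
    rt <- ratio_table(spots, floors[gid])
    if (nrow(rt) >= 2) {
      sm <- summarize_ratios(rt)
      rt <- sm$entries
      summaries[[gid]] <- sm$summary
    }
    utils::write.table(rt, file.path(out_dir, sprintf("ratios_%s.tsv", gid)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gels[[gid]] <- g; spot_tables[[gid]] <- spots; ratios[[gid]] <- rt
  }
  jsonlite::write_json(summaries, file.path(out_dir, "boxplot_summaries.json"),
                       auto_unbox = TRUE, digits = NA)

  an <- analyze_spot_tables(spot_tables, floors, config)
  tracks <- an$tracks; curves <- an$curves; fits <- an$fits
  shifts <- an$shifts; calls <- an$calls
  base_gid <- an$baseline_gel

  utils::write.table(curves, file.path(out_dir, "curves.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sh_out <- merge(shifts, fits[, c("track_id", "tm_vehicle", "tm_drug",
                                   "converged_vehicle", "converged_drug")],
                  by = "track_id", sort = TRUE)
  utils::write.table(sh_out, file.path(out_dir, "shifts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(calls, file.path(out_dir, "calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  thermal <- an$candidates
  summary <- list(
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    n_gels = nrow(man),
    baseline_gel = base_gid,
    n_tracks = length(unique(tracks$track_id)),
    label_counts = as.list(table(calls$label)),
    candidates = thermal$track_id,
    intensity_floors = as.list(floors)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(manifest = man, gels = gels, spot_tables = spot_tables,
                 ratios = ratios, summaries = summaries, tracks = tracks,
                 curves = curves, fits = fits, shifts = shifts,
                 ptm_pairs = an$ptm_pairs, artifact_pairs = an$artifact_pairs,
                 calls = calls, candidates = thermal, floors = floors,
                 out_dir = out_dir))
}

# Box plot with whiskers at the 1st/99th percentiles, candidate outliers
# marked (the method's standard per-gel readout).
.plot_ratio_box <- function(summary, entries, gel_id, path) {
  grDevices::png(path, width = 480, height = 640)
  on.exit(grDevices::dev.off())
  stats_mat <- matrix(c(summary$whisker_low, summary$q1, summary$median,
                        summary$q3, summary$whisker_high), ncol = 1)
  out_idx <- entries$outlier_flag != "none"
  bx <- list(stats = stats_mat,
             n = summary$n_spots,
             conf = stats_mat[c(2, 4), , drop = FALSE],
             out = entries$log2_ratio[out_idx],
             group = rep(1, sum(out_idx)),
             names = gel_id)
  graphics::bxp(bx, ylab = "log2(Cy5 / Cy3)",
                main = sprintf("%s (whiskers: 1-99 percentiles)", gel_id),
                outpch = 17, outcol = "red")
  graphics::abline(h = 0, lty = 3, col = "grey40")
}

.plot_melting_curve <- function(curve, fits_row, track_id, path) {
  grDevices::png(path, width = 560, height = 420)
  on.exit(grDevices::dev.off())
  ylim <- range(c(curve$rel_vehicle, curve$rel_drug, 0, 1.1), na.rm = TRUE)
  graphics::plot(curve$temperature, curve$rel_vehicle, type = "b", pch = 16,
                 col = "darkgreen", ylim = ylim, xlab = "temperature (degC)",
                 ylab = "relative soluble fraction", main = track_id)
  graphics::lines(curve$temperature, curve$rel_drug, type = "b", pch = 17,
                  col = "red3")
  if (!is.null(fits_row) && nrow(fits_row) == 1 &&
      isTRUE(fits_row$converged_vehicle) && isTRUE(fits_row$converged_drug)) {
    tt <- seq(min(curve$temperature), max(curve$temperature), length.out = 100)
    t0 <- min(curve$temperature)
    graphics::lines(tt, .melt_model(tt, t0, fits_row$tm_vehicle,
                                    fits_row$slope_k_vehicle,
                                    fits_row$plateau_vehicle),
                    col = "darkgreen", lty = 2)
    graphics::lines(tt, .melt_model(tt, t0, fits_row$tm_drug,
                                    fits_row$slope_k_drug,
                                    fits_row$plateau_drug),
                    col = "red3", lty = 2)
  }
  graphics::legend("bottomleft", c("vehicle (Cy3)", "drug (Cy5)"),
                   col = c("darkgreen", "red3"), pch = c(16, 17), bty = "n")
}

#' Render a human-readable report bundle
#'
#' Writes one self-contained directory: per-gel red/green overlay PNGs,
#' per-gel box-plot PNGs with the 1-99-percentile whiskers and flagged
#' outliers, melting-curve PNGs for the top-`k` tracks by |z|, the calls
#' table, and a machine-readable `report.json` (with an explicit
#' "no candidates" note when the thermal candidate list is empty).
#'
#' @param run A [run_pipeline()] result.
#' @param out_dir Report directory (created).
#' @param top_k Number of top tracks to plot (all tracks if larger).
#' @return `out_dir`, invisibly.
#' @export
render_report <- function(run, out_dir, top_k = 6) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (gid in names(run$gels)) {
    ov <- compose_overlay(run$gels[[gid]])
    png::writePNG(ov, file.path(out_dir, sprintf("overlay_%s.png", gid)))
    if (!is.null(run$summaries[[gid]]))
      .plot_ratio_box(run$summaries[[gid]], run$ratios[[gid]], gid,
                      file.path(out_dir, sprintf("boxplot_%s.png", gid)))
  }
  sh <- run$shifts[order(-abs(run$shifts$z_score)), ]
  top <- utils::head(sh$track_id, max(top_k, 0))
  for (id in top) {
    cu <- run$curves[run$curves$track_id == id, , drop = FALSE]
    if (nrow(cu) == 0) next
    .plot_melting_curve(cu, run$fits[run$fits$track_id == id, , drop = FALSE],
                        id, file.path(out_dir, sprintf("curve_%s.png", id)))
  }
  utils::write.table(run$calls, file.path(out_dir, "calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- list(
    n_tracks = length(unique(run$tracks$track_id)),
    label_counts = as.list(table(run$calls$label)),
    candidates = if (nrow(run$candidates) > 0) run$candidates$track_id else
      character(0)
  )
  if (nrow(run$candidates) == 0)
    report$note <- "no candidates: no track passed the thermal-shift thresholds"
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
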