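# Shared fixtures, built lazily once per test run.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx_cache)) assign(name, builder(), envir = .fx_cache)
  get(name, envir = .fx_cache)
}

# Raster with analytic elliptical Gaussians at known positions (0-based).
make_gaussian_raster <- function(shape, spots, background = 0) {
  r <- matrix(background, shape[1], shape[2])
  xx <- matrix(rep(0:(shape[2] - 1), each = shape[1]), shape[1], shape[2])
  yy <- matrix(rep(0:(shape[1] - 1), times = shape[2]), shape[1], shape[2])
  for (i in seq_len(nrow(spots))) {
    s <- spots[i, ]
    r <- r + s$A * exp(-((xx - s$x0)^2 / (2 * s$sx^2) +
                           (yy - s$y0)^2 / (2 * s$sy^2)))
  }
  r
}

# Noise-free design helper.
quiet_design <- function(...) {
  args <- utils::modifyList(
    list(background = 0, noise_add = 0, noise_cv = 0, gel_gain = 1,
         warp = NULL, image_shape = c(256, 256), seed = 99),
    list(...))
  args$warp <- args$warp %||%
    rep(list(cbind(diag(2), c(0, 0))), length(args$temperatures %||%
                                                c(37, 41, 44, 47, 50, 53, 58, 64)))
  do.call(experiment_design, args)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Small end-to-end image run with one stabilized target (shared by
# pipeline and thermal tests).
fx_mtx_run <- function() fx("mtx_run", function() {
  dir <- tempfile("mtx")
  pro <- generate_proteome(50, n_targets = 1, seed = 11, target_delta_tm = 8,
                           grid_px = 320)
  des <- experiment_design(image_shape = c(320, 320), seed = 5)
  simulate_run(pro, des, dir)
  run <- suppressWarnings(
    run_pipeline(file.path(dir, "manifest.tsv"), file.path(dir, "out")))
  truth <- attr(render_gel(pro, des, 1), "truth")
  list(pro = pro, des = des, dir = dir, run = run, truth = truth)
})

# Track id of the spot nearest a ground-truth species in the baseline gel.
truth_track <- function(run, truth, species_idx) {
  base_gid <- attr(run$tracks, "baseline_gel")
  base <- run$spot_tables[[base_gid]]
  d <- sqrt((base$x - truth$x[species_idx])^2 +
              (base$y - truth$y[species_idx])^2)
  sid <- base$spot_id[which.min(d)]
  unique(run$tracks$track_id[run$tracks$spot_id == sid &
                               run$tracks$gel_id == base_gid])
}
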