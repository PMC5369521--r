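#' Construct a three-channel gel image
#'
#' Container for one temperature point: three co-registered intensity
#' rasters (Cy2 internal standard, Cy3 vehicle, Cy5 drug) plus metadata.
#'
#' @param cy2,cy3,cy5 Non-negative numeric matrices of identical shape.
#' @param temperature Denaturation temperature (degC).
#' @param gel_id Identifier.
#' @param sat_mask Optional logical matrix flagging saturated pixels.
#' @return Object of class `"gel_image"`.
#' @export
gel_image <- function(cy2, cy3, cy5, temperature, gel_id = "gel",
                      sat_mask = NULL) {
  if (!all(dim(cy2) == dim(cy3)) || !all(dim(cy2) == dim(cy5)))
    .stopf("the three channel rasters must share one shape")
  if (!is.finite(temperature))
    .stopf("temperature must be present and finite")
  structure(list(cy2 = cy2, cy3 = cy3, cy5 = cy5,
                 temperature = temperature, gel_id = gel_id,
                 sat_mask = sat_mask),
            class = "gel_image")
}

#' @export
print.gel_image <- function(x, ...) {
  cat(sprintf("gel_image '%s': %d x %d px, T = %g degC\n",
              x$gel_id, nrow(x$cy2), ncol(x$cy2), x$temperature))
  invisible(x)
}

# Add an elliptical Gaussian of integrated intensity `amount` centred at
# 0-based (x0, y0) to `raster` (modified in place by the caller). Windows
# extend to 4.5 sigma; truncation by the raster border is reported.
.deposit <- function(raster, x0, y0, sx, sy, amount) {
  nr <- nrow(raster); nc <- ncol(raster)
  wx <- ceiling(4.5 * sx); wy <- ceiling(4.5 * sy)
  c0 <- floor(x0) - wx; c1 <- ceiling(x0) + wx
  r0 <- floor(y0) - wy; r1 <- ceiling(y0) + wy
  clipped <- c0 < 0 || r0 < 0 || c1 > nc - 1 || r1 > nr - 1
  cc <- max(c0, 0):min(c1, nc - 1)
  rr <- max(r0, 0):min(r1, nr - 1)
  if (length(cc) == 0L || length(rr) == 0L || max(cc) < 0 || max(rr) < 0)
    return(list(raster = raster, clipped = TRUE))
  gy <- exp(-(rr - y0)^2 / (2 * sy^2))
  gx <- exp(-(cc - x0)^2 / (2 * sx^2))
  patch <- (amount / (2 * pi * sx * sy)) * outer(gy, gx)
  raster[rr + 1, cc + 1] <- raster[rr + 1, cc + 1] + patch
  list(raster = raster, clipped = clipped)
}

#' PTM conversion fraction at a given treatment duration
#'
#' Single-exponential approach to the maximal conversion:
#' `phi = ptm_fraction_max * (1 - exp(-t / tau))`.
#'
#' @param species Proteome rows.
#' @param treatment_minutes Drug exposure (min).
#' @return Converted fraction(s) in `[0, 1]`; 0 for non-substrates.
#' @export
ptm_fraction <- function(species, treatment_minutes) {
  species$ptm_fraction_max * (1 - exp(-treatment_minutes / species$ptm_tau_min))
}

#' Render one synthetic three-channel gel
#'
#' Forward model of a single temperature point. Each species is placed at
#' its (pI, molecular weight) position, warped by the per-gel affine
#' distortion, and deposited as an elliptical 2D Gaussian whose integrated
#' intensity is `gel_gain * channel amount`:
#' * Cy2 = abundance (unheated internal standard, heat-independent),
#' * Cy3 = abundance x soluble_fraction(vehicle, T),
#' * Cy5 = abundance x soluble_fraction(drug, T).
#'
#' PTM substrates split their Cy5 amount between the parent position
#' (fraction `1 - phi`) and a satellite at `pI + ptm_delta_pi`
#' (fraction `phi`), with `phi` given by [ptm_fraction()]; at the unheated
#' baseline this produces the horizontal red/green pair diagnostic of a
#' drug-induced modification. The Cy5 raster is additionally shifted
#' vertically by the per-gel `misregistration_dy`. A flat background plus
#' additive and signal-proportional Gaussian noise is added per channel;
#' everything is deterministic given `design$seed`.
#'
#' @param proteome A [generate_proteome()] table.
#' @param design An [experiment_design()].
#' @param temperature_index Index into `design$temperatures`.
#' @return A [gel_image()] carrying a ground-truth table in
#'   `attr(, "truth")` (positions and noiseless channel amounts, including
#'   satellite spots and clipping flags).
#' @export
render_gel <- function(proteome, design, temperature_index) {
  n_t <- length(design$temperatures)
  if (temperature_index < 1 || temperature_index > n_t)
    .stopf("temperature_index %s out of range 1..%d", temperature_index, n_t)
  idx <- as.integer(temperature_index)
  temp <- design$temperatures[idx]
  sh <- design$image_shape
  gain <- design$gel_gain[idx]
  dy5 <- design$misregistration_dy[idx]
  set.seed(.gel_seed(design$seed, idx))

  r2 <- matrix(0, sh[1], sh[2]); r3 <- r2; r5 <- r2
  n <- nrow(proteome)
  truth <- NULL
  if (n > 0) {
    pos0 <- map_coords(proteome$pI, proteome$mass_kda, design)
    pos <- apply_warp(pos0$x, pos0$y, design$warp[[idx]])
    f_v <- soluble_fraction(proteome, temp, "vehicle")
    f_d <- soluble_fraction(proteome, temp, "drug")
    phi <- ptm_fraction(proteome, design$treatment_minutes)
    # satellite position: shifted pI, same mass, then warped
    sat0 <- map_coords(proteome$pI + proteome$ptm_delta_pi,
                       proteome$mass_kda, design)
    sat <- apply_warp(sat0$x, sat0$y, design$warp[[idx]])

    amt2 <- proteome$abundance
    amt3 <- proteome$abundance * f_v
    amt5_parent <- proteome$abundance * f_d * (1 - phi)
    amt5_sat <- proteome$abundance * f_d * phi

    clipped <- logical(n)
    for (i in seq_len(n)) {
      sx <- proteome$sigma_x[i]; sy <- proteome$sigma_y[i]
      d <- .deposit(r2, pos$x[i], pos$y[i], sx, sy, gain * amt2[i])
      r2 <- d$raster; clipped[i] <- clipped[i] || d$clipped
      d <- .deposit(r3, pos$x[i], pos$y[i], sx, sy, gain * amt3[i])
      r3 <- d$raster; clipped[i] <- clipped[i] || d$clipped
      d <- .deposit(r5, pos$x[i], pos$y[i] + dy5, sx, sy, gain * amt5_parent[i])
      r5 <- d$raster; clipped[i] <- clipped[i] || d$clipped
      if (amt5_sat[i] > 0) {
        d <- .deposit(r5, sat$x[i], sat$y[i] + dy5, sx, sy, gain * amt5_sat[i])
        r5 <- d$raster; clipped[i] <- clipped[i] || d$clipped
      }
    }
    if (any(clipped))
      .warnf("%d species clipped at the raster border of gel %d (kept in ground truth)",
             sum(clipped), idx)
    truth <- data.frame(
      species_id = proteome$species_id,
      x = pos$x, y = pos$y, sat_x = sat$x, sat_y = sat$y,
      sigma_x = proteome$sigma_x, sigma_y = proteome$sigma_y,
      amount_cy2 = gain * amt2, amount_cy3 = gain * amt3,
      amount_cy5_parent = gain * amt5_parent,
      amount_cy5_satellite = gain * amt5_sat,
      is_target = proteome$is_target,
      is_ptm_substrate = proteome$is_ptm_substrate,
      clipped = clipped, stringsAsFactors = FALSE
    )
  }

  add_noise <- function(r) {
    if (design$noise_add == 0 && design$noise_cv == 0 && design$background == 0)
      return(r)
    npx <- length(r)
    out <- r + design$background +
      stats::rnorm(npx, 0, design$noise_add) +
      stats::rnorm(npx, 0, 1) * design$noise_cv * r
    matrix(pmax(out, 0), nrow(r), ncol(r))
  }
  g <- gel_image(add_noise(r2), add_noise(r3), add_noise(r5),
                 temperature = temp,
                 gel_id = sprintf("T%02d", round(temp)))
  attr(g, "truth") <- truth
  g
}

#' Write a gel image as a 16-bit multi-page TIFF
#'
#' Pages are ordered Cy2, Cy3, Cy5. Intensities are stored as
#' `round(value)` counts in 0..`scale`; values above `scale` are clipped
#' with a warning.
#'
#' @param gel A [gel_image()].
#' @param path Output file.
#' @param scale Full-scale count (default 65535, i.e. 16-bit).
#' @return `path`, invisibly.
#' @export
write_gel_tiff <- function(gel, path, scale = 65535) {
  ch <- list(gel$cy2, gel$cy3, gel$cy5)
  if (any(vapply(ch, max, 0) > scale))
    .warnf("intensities above %g clipped when writing %s", scale, path)
  pages <- lapply(ch, function(m) round(.clamp(m, 0, scale)) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a three-channel gel TIFF
#'
#' Expects at least three pages (Cy2, Cy3, Cy5 in order) of identical
#' shape; intensities are returned as floating-point counts on the
#' 0..`scale` range. Saturated pixels (>= 99.5% of full scale in any
#' channel) are recorded in the image's `sat_mask`.
#'
#' @param path TIFF file written by [write_gel_tiff()] (or equivalent).
#' @param manifest_row Optional list/row with `temperature_C` and `gel_id`.
#' @param scale Full-scale count of the stored data.
#' @return A [gel_image()].
#' @export
read_gel <- function(path, manifest_row = NULL, scale = 65535) {
  if (!file.exists(path)) .stopf("gel image file not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (length(pages) < 3L)
    .stopf("format error in %s: expected >= 3 pages (Cy2, Cy3, Cy5), found %d",
           path, length(pages))
  dims <- lapply(pages[1:3], dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    .stopf("format error in %s: page shapes differ", path)
  ch <- lapply(pages[1:3], function(p) p * scale)
  sat <- (ch[[1]] >= 0.995 * scale) | (ch[[2]] >= 0.995 * scale) |
    (ch[[3]] >= 0.995 * scale)
  temp <- if (!is.null(manifest_row)) as.numeric(manifest_row$temperature_C) else NA_real_
  gid <- if (!is.null(manifest_row)) as.character(manifest_row$gel_id) else
    sub("\\.tiff?$", "", basename(path))
  if (!is.finite(temp)) temp <- 0
  gel_image(ch[[1]], ch[[2]], ch[[3]], temperature = temp, gel_id = gid,
            sat_mask = if (any(sat)) sat else NULL)
}

#' Simulate a full TS-FITGE run to disk
#'
#' Renders one gel per design temperature, writes 16-bit multi-page TIFFs,
#' a run manifest TSV (filename, temperature_C, gel_id, page order) and a
#' ground-truth JSON (species table, design scalars, per-gel noiseless spot
#' positions and channel amounts).
#'
#' @param proteome A [generate_proteome()] table.
#' @param design An [experiment_design()].
#' @param dir Output directory (created if needed).
#' @return Path to the manifest TSV, invisibly.
#' @export
simulate_run <- function(proteome, design, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(design$temperatures)
  files <- character(n); gel_ids <- character(n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    g <- render_gel(proteome, design, i)
    files[i] <- sprintf("gel_%02d_T%g.tif", i, design$temperatures[i])
    gel_ids[i] <- g$gel_id
    write_gel_tiff(g, file.path(dir, files[i]))
    truths[[i]] <- attr(g, "truth")
  }
  manifest <- data.frame(filename = files,
                         temperature_C = design$temperatures,
                         gel_id = gel_ids,
                         pages = "cy2,cy3,cy5",
                         stringsAsFactors = FALSE)
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gt <- list(
    species = proteome,
    design = list(temperatures = design$temperatures,
                  treatment_minutes = design$treatment_minutes,
                  gel_gain = design$gel_gain,
                  warp = lapply(design$warp, as.vector),
                  misregistration_dy = design$misregistration_dy,
                  background = design$background,
                  noise_add = design$noise_add, noise_cv = design$noise_cv,
                  image_shape = design$image_shape,
                  pI_range = design$pI_range,
                  mass_range_kda = design$mass_range_kda,
                  seed = design$seed),
    gels = stats::setNames(truths, gel_ids)
  )
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

#' Simulate pre-quantified spot tables (no image rendering)
#'
#' Produces, for every design temperature, a spot table of the same form
#' that [detect_spots()] yields from a rendered image: warped positions
#' with small localization jitter and integrated intensities with
#' signal-proportional plus additive measurement noise. PTM satellites
#' appear as separate Cy5-only spots. This is the fast route for
#' many-replicate statistical experiments (null false-positive rates,
#' melting-shift recovery), bypassing the pixel-level render/detect cycle
#' while keeping the same generative statistics downstream of
#' quantification.
#'
#' @param proteome A [generate_proteome()] table.
#' @param design An [experiment_design()].
#' @param loc_jitter_px Localization noise sd (pixels).
#' @return Named list (by gel id) of `spot_table` data.frames, each with a
#'   `temperature` attribute and a `truth` attribute mapping spot ids to
#'   species.
#' @export
simulate_spot_tables <- function(proteome, design, loc_jitter_px = 0.15) {
  n_gel <- length(design$temperatures)
  # integrated additive noise ~ pixel noise aggregated over a ~25 px footprint
  int_noise <- design$noise_add * 5
  out <- vector("list", n_gel)
  ids <- character(n_gel)
  for (i in seq_len(n_gel)) {
    temp <- design$temperatures[i]
    gain <- design$gel_gain[i]
    set.seed(.gel_seed(design$seed, i))
    pos0 <- map_coords(proteome$pI, proteome$mass_kda, design)
    pos <- apply_warp(pos0$x, pos0$y, design$warp[[i]])
    f_v <- soluble_fraction(proteome, temp, "vehicle")
    f_d <- soluble_fraction(proteome, temp, "drug")
    phi <- ptm_fraction(proteome, design$treatment_minutes)
    n <- nrow(proteome)
    meas <- function(amount) {
      pmax(amount * (1 + design$noise_cv * stats::rnorm(n)) +
             stats::rnorm(n, 0, int_noise), 0)
    }
    core_f <- 1 - exp(-0.5)   # mass of a Gaussian inside its 1-sigma ellipse
    tab <- data.frame(
      x = pos$x + stats::rnorm(n, 0, loc_jitter_px),
      y = pos$y + stats::rnorm(n, 0, loc_jitter_px),
      sigma_x = proteome$sigma_x, sigma_y = proteome$sigma_y,
      theta = 0,
      intensity_cy2 = meas(gain * proteome$abundance),
      intensity_cy3 = meas(gain * proteome$abundance * f_v),
      intensity_cy5 = meas(gain * proteome$abundance * f_d * (1 - phi)),
      fit_quality = 1, flags = "",
      species_id = proteome$species_id,
      stringsAsFactors = FALSE
    )
    tab$core_cy2 <- core_f * tab$intensity_cy2
    tab$core_cy3 <- core_f * tab$intensity_cy3
    tab$core_cy5 <- core_f * tab$intensity_cy5
    sat_i <- which(phi > 0)
    if (length(sat_i)) {
      ns <- length(sat_i)
      sat0 <- map_coords(proteome$pI[sat_i] + proteome$ptm_delta_pi[sat_i],
                         proteome$mass_kda[sat_i], design)
      satp <- apply_warp(sat0$x, sat0$y, design$warp[[i]])
      sat_amt <- gain * proteome$abundance[sat_i] * f_d[sat_i] * phi[sat_i]
      sat_tab <- data.frame(
        x = satp$x + stats::rnorm(ns, 0, loc_jitter_px),
        y = satp$y + stats::rnorm(ns, 0, loc_jitter_px),
        sigma_x = proteome$sigma_x[sat_i], sigma_y = proteome$sigma_y[sat_i],
        theta = 0,
        intensity_cy2 = pmax(stats::rnorm(ns, 0, int_noise), 0),
        intensity_cy3 = pmax(stats::rnorm(ns, 0, int_noise), 0),
        intensity_cy5 = pmax(sat_amt * (1 + design$noise_cv * stats::rnorm(ns)) +
                               stats::rnorm(ns, 0, int_noise), 0),
        fit_quality = 1, flags = "ptm_satellite",
        species_id = paste0(proteome$species_id[sat_i], "_sat"),
        stringsAsFactors = FALSE
      )
      sat_tab$core_cy2 <- core_f * sat_tab$intensity_cy2
      sat_tab$core_cy3 <- core_f * sat_tab$intensity_cy3
      sat_tab$core_cy5 <- core_f * sat_tab$intensity_cy5
      tab <- rbind(tab, sat_tab)
    }
    tot <- tab$intensity_cy2 + tab$intensity_cy3 + tab$intensity_cy5
    tab <- tab[order(-tot), , drop = FALSE]
    tab$spot_id <- sprintf("S%04d", seq_len(nrow(tab)))
    truth_map <- tab$species_id
    tab$species_id <- NULL
    rownames(tab) <- NULL
    tab <- tab[, c("spot_id", "x", "y", "sigma_x", "sigma_y", "theta",
                   "intensity_cy2", "intensity_cy3", "intensity_cy5",
                   "core_cy2", "core_cy3", "core_cy5",
                   "fit_quality", "flags")]
    class(tab) <- c("spot_table", "data.frame")
    attr(tab, "temperature") <- temp
    gid <- sprintf("T%02d", round(temp))
    attr(tab, "gel_id") <- gid
    attr(tab, "truth") <- data.frame(spot_id = tab$spot_id,
                                     species_id = truth_map,
                                     stringsAsFactors = FALSE)
    out[[i]] <- tab
    ids[i] <- gid
  }
  stats::setNames(out, ids)
}
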