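#' Morphological background subtraction
#'
#' Estimates the smooth background of a gel raster by grayscale
#' morphological opening with a disc structuring element (the classic
#' rolling-ball-style correction) and subtracts it, clipping at zero. The
#' disc radius must comfortably exceed the spot width (>= 3 sigma) so spots
#' are removed from the background estimate rather than absorbed into it.
#'
#' @param raster Non-negative numeric matrix.
#' @param ball_radius Disc radius in pixels.
#' @return Background-corrected non-negative raster; flat regions map to ~0.
#' @export
subtract_background <- function(raster, ball_radius = 8) {
  if (ball_radius <= 0) .stopf("ball_radius must be positive")
  if (ball_radius < 3)
    .warnf("ball_radius %g is small; use >= 3 x spot sigma", ball_radius)
  s <- max(raster)
  if (s <= 0) return(raster * 0)
  # EBImage grayscale morphology operates on [0, 1]; rescale around it.
  brush <- EBImage::makeBrush(2L * as.integer(ceiling(ball_radius)) + 1L,
                              shape = "disc")
  bg <- EBImage::opening(raster / s, brush) * s
  pmax(raster - bg, 0)
}

# Elliptical Gaussian on a pixel grid (0-based coords).
.gauss2d <- function(xx, yy, A, x0, y0, sx, sy, th) {
  dx <- xx - x0; dy <- yy - y0
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  A * exp(-(u^2 / (2 * sx^2) + v^2 / (2 * sy^2)))
}

# Least-squares elliptical Gaussian refinement in a window around a peak.
# Pixels closer to another accepted peak than to this one are excluded
# (Voronoi partition), so neighbouring spots do not inflate the fit.
# Returns centroid, widths, orientation, amplitude, offset, fit quality.
.fit_spot <- function(raster, px, py, radius, exclude = NULL, others = NULL) {
  nr <- nrow(raster); nc <- ncol(raster)
  rr <- max(py - radius, 0):min(py + radius, nr - 1)
  cc <- max(px - radius, 0):min(px + radius, nc - 1)
  grid <- expand.grid(yy = rr, xx = cc)
  grid$I <- raster[cbind(grid$yy + 1, grid$xx + 1)]
  if (!is.null(exclude)) {
    keep <- !exclude[cbind(grid$yy + 1, grid$xx + 1)]
    grid <- grid[keep, , drop = FALSE]
  }
  if (!is.null(others) && nrow(others) > 0 && nrow(grid) > 0) {
    d_self <- (grid$xx - px)^2 + (grid$yy - py)^2
    d_oth <- outer(grid$xx, others[, 1], "-")^2 +
      outer(grid$yy, others[, 2], "-")^2
    keep <- d_self <= apply(d_oth, 1, min)
    if (sum(keep) >= 9L) grid <- grid[keep, , drop = FALSE]
  }
  moments <- function() {
    w <- pmax(grid$I - stats::median(grid$I), 0)
    if (sum(w) <= 0) w <- rep(1, nrow(grid))
    x0 <- sum(w * grid$xx) / sum(w); y0 <- sum(w * grid$yy) / sum(w)
    sx <- sqrt(max(sum(w * (grid$xx - x0)^2) / sum(w), 0.16))
    sy <- sqrt(max(sum(w * (grid$yy - y0)^2) / sum(w), 0.16))
    list(A = max(grid$I), x0 = x0, y0 = y0, sx = min(sx, radius),
         sy = min(sy, radius), th = 0, o = min(grid$I), quality = 0,
         failed = TRUE)
  }
  if (nrow(grid) < 9L) return(moments())
  start <- list(A = max(grid$I) - stats::median(grid$I), x0 = px, y0 = py,
                sx = 1, sy = 1, th = 0, o = stats::median(grid$I))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      I ~ .gauss2d(xx, yy, A, x0, y0, sx, sy, th) + o,
      data = grid, start = start,
      lower = c(A = 0, x0 = px - 2, y0 = py - 2, sx = 0.4, sy = 0.4,
                th = -pi / 2, o = -Inf),
      upper = c(A = Inf, x0 = px + 2, y0 = py + 2, sx = radius + 1,
                sy = radius + 1, th = pi / 2, o = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 60)),
    error = function(e) NULL)
  if (is.null(fit)) return(moments())
  cf <- as.list(stats::coef(fit))
  # canonical orientation: |theta| <= pi/4, sx along the nearer-x axis
  if (abs(cf$th) > pi / 4) {
    tmp <- cf$sx; cf$sx <- cf$sy; cf$sy <- tmp
    cf$th <- cf$th - sign(cf$th) * pi / 2
  }
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((grid$I - mean(grid$I))^2)
  cf$quality <- if (ss_tot > 0) .clamp(1 - ss_res / ss_tot, 0, 1) else 0
  cf$failed <- FALSE
  cf
}

# Pixel set (1-based matrix indices) inside the n-sigma ellipse of a fit.
.footprint <- function(fit, nr, nc, n_sigma = 3) {
  w <- ceiling(n_sigma * max(fit$sx, fit$sy)) + 1L
  rr <- max(floor(fit$y0) - w, 0):min(ceiling(fit$y0) + w, nr - 1)
  cc <- max(floor(fit$x0) - w, 0):min(ceiling(fit$x0) + w, nc - 1)
  g <- expand.grid(yy = rr, xx = cc)
  dx <- g$xx - fit$x0; dy <- g$yy - fit$y0
  u <- dx * cos(fit$th) + dy * sin(fit$th)
  v <- -dx * sin(fit$th) + dy * cos(fit$th)
  keep <- (u / fit$sx)^2 + (v / fit$sy)^2 <= n_sigma^2
  cbind(g$yy[keep] + 1L, g$xx[keep] + 1L)
}

#' Detect and quantify spots in a three-channel gel image
#'
#' Works on background-corrected rasters (see [subtract_background()]).
#' Each channel is Gaussian-smoothed and the detection raster is the
#' pixelwise maximum over the three smoothed channels, so spots present in
#' only one channel (PTM satellites, fully destabilized proteins, the
#' Cy2-only remnant of melted proteins) are still found. Local maxima above
#' a robust threshold (median + `min_snr` x MAD, i.e. relative to exposure)
#' are kept, greedily suppressed within `min_separation`, and refined by an
#' elliptical 2D Gaussian least-squares fit in a local window. Every
#' channel is then quantified by integrating its background-corrected
#' pixels over the SAME 3-sigma elliptical footprint, so Cy5/Cy3/Cy2 ratios
#' compare like with like.
#'
#' @param gel A [gel_image()] with background-corrected channels.
#' @param min_snr Detection threshold in robust sd units.
#' @param min_separation Minimum peak separation (pixels); closer peaks are
#'   suppressed in favour of the stronger one (ties broken row-major).
#' @param smooth_sigma Gaussian smoothing sd (pixels) before peak finding.
#' @param fit_radius Half-width of the Gaussian-fit window (pixels).
#' @return A `data.frame` of class `"spot_table"` sorted by total intensity
#'   (descending): spot_id, x, y (0-based, sub-pixel), sigma_x, sigma_y,
#'   theta, intensity_cy2/3/5 (3-sigma footprint), core_cy2/3/5 (1-sigma
#'   core, used by spatial classification rules: a channel misregistration
#'   shifts the core ratio strongly while leaving co-located color spots
#'   untouched), fit_quality, flags. Carries `gel_id` and `temperature`
#'   attributes.
#' @export
detect_spots <- function(gel, min_snr = 6, min_separation = 2,
                         smooth_sigma = 0.6, fit_radius = 4) {
  stopifnot(inherits(gel, "gel_image"))
  nr <- nrow(gel$cy2); nc <- ncol(gel$cy2)
  empty <- function() {
    out <- data.frame(spot_id = character(), x = numeric(), y = numeric(),
                      sigma_x = numeric(), sigma_y = numeric(),
                      theta = numeric(), intensity_cy2 = numeric(),
                      intensity_cy3 = numeric(), intensity_cy5 = numeric(),
                      core_cy2 = numeric(), core_cy3 = numeric(),
                      core_cy5 = numeric(),
                      fit_quality = numeric(), flags = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("spot_table", "data.frame")
    attr(out, "gel_id") <- gel$gel_id
    attr(out, "temperature") <- gel$temperature
    out
  }
  chans <- list(gel$cy2, gel$cy3, gel$cy5)
  if (all(vapply(chans, stats::sd, 0) == 0)) {
    .warnf("zero-variance rasters in gel %s: no spots", gel$gel_id)
    return(empty())
  }
  sm <- lapply(chans, function(m) EBImage::gblur(m, sigma = smooth_sigma))
  det <- pmax(sm[[1]], sm[[2]], sm[[3]])

  med <- stats::median(det)
  scale_mad <- stats::mad(det)
  # near-noiseless rasters: MAD collapses to numerical jitter; fall back to
  # the sd so the threshold stays meaningful (and scale-invariant)
  if (scale_mad <= 1e-8 * stats::sd(det)) scale_mad <- stats::sd(det)
  thr <- med + min_snr * scale_mad

  # local maxima: neighborhood max via grayscale dilation ([0,1]-scaled)
  s <- max(det)
  nmax <- EBImage::dilate(det / s, EBImage::makeBrush(3L, "box")) * s
  is_peak <- det >= nmax - 1e-9 * s & det > thr
  pk <- which(is_peak, arr.ind = TRUE)
  if (nrow(pk) == 0L) return(empty())
  vals <- det[pk]
  o <- order(-vals, pk[, 1], pk[, 2])
  pk <- pk[o, , drop = FALSE]

  # greedy non-maximum suppression within min_separation
  acc_r <- numeric(0); acc_c <- numeric(0)
  for (i in seq_len(nrow(pk))) {
    r <- pk[i, 1]; c <- pk[i, 2]
    if (length(acc_r) == 0L ||
        min(sqrt((acc_r - r)^2 + (acc_c - c)^2)) >= min_separation) {
      acc_r <- c(acc_r, r); acc_c <- c(acc_c, c)
    }
  }

  fitr <- pmax(chans[[1]], chans[[2]], chans[[3]])
  sat <- gel$sat_mask
  rows <- vector("list", length(acc_r))
  peaks_xy <- cbind(acc_c - 1L, acc_r - 1L)    # 0-based (x, y)
  for (i in seq_along(acc_r)) {
    px <- acc_c[i] - 1L; py <- acc_r[i] - 1L   # 0-based
    near <- peaks_xy[-i, , drop = FALSE]
    near <- near[abs(near[, 1] - px) <= 2 * fit_radius &
                   abs(near[, 2] - py) <= 2 * fit_radius, , drop = FALSE]
    f <- .fit_spot(fitr, px, py, fit_radius, exclude = sat, others = near)
    fp <- .footprint(f, nr, nc)
    fp1 <- .footprint(f, nr, nc, n_sigma = 1)
    i2 <- sum(gel$cy2[fp]); i3 <- sum(gel$cy3[fp]); i5 <- sum(gel$cy5[fp])
    c2 <- sum(gel$cy2[fp1]); c3 <- sum(gel$cy3[fp1]); c5 <- sum(gel$cy5[fp1])
    flags <- character(0)
    if (f$failed) flags <- c(flags, "fit_failed")
    if (!is.null(sat) && any(sat[fp])) flags <- c(flags, "saturated")
    if (any(c(i2, i3, i5) < 0)) flags <- c(flags, "negative_clipped")
    rows[[i]] <- data.frame(
      x = f$x0, y = f$y0, sigma_x = f$sx, sigma_y = f$sy, theta = f$th,
      intensity_cy2 = max(i2, 0), intensity_cy3 = max(i3, 0),
      intensity_cy5 = max(i5, 0),
      core_cy2 = max(c2, 0), core_cy3 = max(c3, 0), core_cy5 = max(c5, 0),
      fit_quality = f$quality,
      flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  tot <- out$intensity_cy2 + out$intensity_cy3 + out$intensity_cy5
  out <- out[order(-tot), , drop = FALSE]
  out$spot_id <- sprintf("S%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out <- out[, c("spot_id", "x", "y", "sigma_x", "sigma_y", "theta",
                 "intensity_cy2", "intensity_cy3", "intensity_cy5",
                 "core_cy2", "core_cy3", "core_cy5",
                 "fit_quality", "flags")]
  class(out) <- c("spot_table", "data.frame")
  attr(out, "gel_id") <- gel$gel_id
  attr(out, "temperature") <- gel$temperature
  out
}

#' Background-correct all three channels of a gel
#'
#' Convenience wrapper applying [subtract_background()] to Cy2, Cy3 and
#' Cy5, preserving metadata and the saturation mask.
#'
#' @inheritParams subtract_background
#' @param gel A [gel_image()].
#' @return A background-corrected [gel_image()].
#' @export
correct_gel <- function(gel, ball_radius = 8) {
  g <- gel_image(subtract_background(gel$cy2, ball_radius),
                 subtract_background(gel$cy3, ball_radius),
                 subtract_background(gel$cy5, ball_radius),
                 temperature = gel$temperature, gel_id = gel$gel_id,
                 sat_mask = gel$sat_mask)
  g
}

#' Default integrated-intensity floor for ratio analysis
#'
#' Integrating over an `n`-pixel footprint accumulates pixel noise with sd
#' `sigma_px * sqrt(n)`; the floor is 3 robust sds of that, taking the
#' noisiest channel. Spots below the floor in Cy3 or Cy5 are excluded from
#' ratio analysis rather than clamped, to avoid fabricated extreme ratios.
#'
#' @param gel Background-corrected [gel_image()].
#' @param footprint_px Typical footprint size in pixels.
#' @return Scalar intensity floor (arbitrary units).
#' @export
default_intensity_floor <- function(gel, footprint_px = 25) {
  sig <- max(stats::mad(gel$cy2), stats::mad(gel$cy3), stats::mad(gel$cy5))
  3 * sig * sqrt(footprint_px)
}

#' Write a spot table as TSV
#'
#' @param spots A `spot_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(spots, path) {
  df <- as.data.frame(spots)
  df <- cbind(gel_id = attr(spots, "gel_id") %||% NA,
              temperature = attr(spots, "temperature") %||% NA, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
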