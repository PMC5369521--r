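#' Define a TS-FITGE experiment design
#'
#' Collects everything the forward model needs to render one gel per
#' denaturation temperature: the temperature series (first entry is the
#' unheated baseline), drug exposure duration (controls how far
#' PTM conversion has progressed), per-gel imaging gain, per-gel affine
#' spatial distortion, per-gel vertical misregistration of the Cy5 channel
#' relative to Cy2/Cy3, noise parameters, and the raster geometry.
#'
#' When `gel_gain` or `warp` are `NULL`, realistic per-gel values are drawn
#' deterministically from `seed`: log-normal gains (sd 10%) and small affine
#' distortions (translations up to ~2 px, linear terms within 0.5%) for the
#' heated gels; the baseline gel always has the identity warp.
#'
#' @param temperatures Strictly increasing temperatures (degC); first entry
#'   is the unheated baseline.
#' @param treatment_minutes Drug exposure duration (min, >= 0).
#' @param gel_gain Per-gel multiplicative imaging gain (> 0), recycled.
#' @param warp List of 2x3 affine matrices (one per gel, pixel units) mapping
#'   reference coordinates to gel coordinates, or `NULL`.
#' @param misregistration_dy Per-gel vertical offset of the Cy5 channel
#'   (pixels, signed), recycled.
#' @param background Flat background level (counts).
#' @param noise_add Additive Gaussian noise sd (counts).
#' @param noise_cv Signal-proportional Gaussian noise coefficient of
#'   variation (default 3%).
#' @param image_shape `c(rows, cols)` of the rasters.
#' @param pI_range pH span of the horizontal axis (column 0 = low pI).
#' @param mass_range_kda Molecular-weight span of the vertical axis
#'   (row 0 = top = high mass).
#' @param seed Integer seed governing all randomness of the run.
#' @return An object of class `"experiment_design"`.
#' @export
experiment_design <- function(temperatures = c(37, 41, 44, 47, 50, 53, 58, 64),
                              treatment_minutes = 20,
                              gel_gain = NULL,
                              warp = NULL,
                              misregistration_dy = 0,
                              background = 100,
                              noise_add = 30,
                              noise_cv = 0.03,
                              image_shape = c(512, 512),
                              pI_range = c(3, 11),
                              mass_range_kda = c(10, 300),
                              seed = 1) {
  if (any(diff(temperatures) <= 0))
    .stopf("temperatures must be strictly increasing")
  if (treatment_minutes < 0) .stopf("treatment_minutes must be >= 0")
  if (any(image_shape <= 0) || length(image_shape) != 2L)
    .stopf("image_shape must be two positive integers")
  n <- length(temperatures)

  set.seed(.gel_seed(seed, 0L))
  if (is.null(gel_gain)) {
    gel_gain <- exp(stats::rnorm(n, 0, 0.1))
  } else {
    gel_gain <- rep_len(gel_gain, n)
  }
  if (any(gel_gain <= 0)) .stopf("gel_gain must be > 0")

  if (is.null(warp)) {
    warp <- lapply(seq_len(n), function(i) {
      if (i == 1L) return(cbind(diag(2), c(0, 0)))
      A <- diag(2) + matrix(stats::runif(4, -0.005, 0.005), 2, 2)
      cbind(A, stats::runif(2, -2, 2))
    })
  } else {
    if (length(warp) != n) .stopf("warp must supply one 2x3 matrix per gel")
    warp <- lapply(warp, function(w) {
      w <- as.matrix(w)
      if (!all(dim(w) == c(2, 3))) .stopf("each warp must be a 2x3 matrix")
      w
    })
  }
  misregistration_dy <- rep_len(misregistration_dy, n)

  structure(list(
    temperatures = temperatures,
    treatment_minutes = treatment_minutes,
    gel_gain = gel_gain,
    warp = warp,
    misregistration_dy = misregistration_dy,
    background = background,
    noise_add = noise_add,
    noise_cv = noise_cv,
    image_shape = as.integer(image_shape),
    pI_range = pI_range,
    mass_range_kda = mass_range_kda,
    seed = as.integer(seed)
  ), class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("TS-FITGE experiment design\n")
  cat("  temperatures (degC):", paste(x$temperatures, collapse = ", "), "\n")
  cat("  treatment:", x$treatment_minutes, "min; raster:",
      paste(x$image_shape, collapse = " x "), "px\n")
  cat("  noise: bg", x$background, "+ add sd", x$noise_add,
      "+ cv", x$noise_cv, "; seed", x$seed, "\n")
  invisible(x)
}

# Map (pI, mass) to 0-based pixel coordinates of the reference frame.
# Column 0 = left = low pI; row 0 = top = high molecular weight.
map_coords <- function(pI, mass_kda, design) {
  sh <- design$image_shape
  lr <- log10(design$mass_range_kda)
  x <- (pI - design$pI_range[1]) / diff(design$pI_range) * (sh[2] - 1)
  y <- (lr[2] - log10(mass_kda)) / diff(lr) * (sh[1] - 1)
  data.frame(x = x, y = y)
}

# Apply a 2x3 affine (reference -> gel frame) to 0-based coordinates.
apply_warp <- function(x, y, warp) {
  xy <- warp %*% rbind(x, y, 1)
  data.frame(x = xy[1, ], y = xy[2, ])
}
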