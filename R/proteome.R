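#' Default parameter ranges for the virtual proteome
#'
#' Distribution bounds used by [generate_proteome()]. Isoelectric points are
#' sampled uniformly (slightly inside the gel's pH 3--11 strip so spots do
#' not sit on the raster edge), log10 molecular weight uniformly, abundance
#' log-normally, and melting midpoints normally around 50 degC (sd 5,
#' clipped to 40--65 degC) as typical for mammalian proteomes in thermal
#' shift experiments. Spot rendering widths (`sigma_px`) are in pixels of
#' the default 512x512 raster.
#'
#' @return Named list of ranges/parameters consumed by [generate_proteome()].
#' @export
default_param_ranges <- function() {
  list(
    pI            = c(3.4, 10.6),
    log10_mass    = log10(c(12, 250)),
    abundance_meanlog = log(3e4),
    abundance_sdlog   = 0.4,
    tm_mean       = 50,
    tm_sd         = 5,
    tm_clip       = c(40, 65),
    slope_k       = c(0.7, 1.6),
    plateau_p     = c(0, 0.15),
    sigma_px      = c(0.85, 1.15),
    ptm_fraction_max = c(0.4, 0.8),
    ptm_tau_min   = 10,
    ptm_delta_pi  = -0.1
  )
}

#' Generate a virtual proteome with ground-truth melting behaviour
#'
#' Creates `n_species` virtual proteins, each with a gel position
#' (isoelectric point, molecular weight), an abundance, logistic melting
#' parameters (midpoint `tm_vehicle`, steepness `slope_k`, non-denaturable
#' floor `plateau_p`), and optional drug effects: exactly `n_targets`
#' species carry a drug-induced melting shift `delta_tm` and exactly
#' `n_ptm_substrates` species are substrates of a drug-induced
#' post-translational modification that moves a fraction of the protein to
#' a shifted isoelectric point.
#'
#' Spot positions are rejection-sampled so that pairwise distances on the
#' reference raster are at least `min_spacing_px` pixels, mimicking a
#' resolved 2D gel.
#'
#' @param n_species Number of virtual proteins.
#' @param n_targets Number of drug targets (nonzero `delta_tm`).
#' @param n_ptm_substrates Number of PTM substrates (nonzero
#'   `ptm_fraction_max`).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param param_ranges Distribution bounds, see [default_param_ranges()].
#' @param target_delta_tm Drug-induced melting shift (degC, signed) given to
#'   targets; recycled over targets.
#' @param min_spacing_px Minimum pairwise spot distance on the reference
#'   raster (pixels).
#' @param grid_px Side of the reference raster used for spacing (pixels).
#' @return A `data.frame` of class `"proteome"`, one row per species.
#' @export
generate_proteome <- function(n_species, n_targets = 0, n_ptm_substrates = 0,
                              seed = 1, param_ranges = default_param_ranges(),
                              target_delta_tm = 8, min_spacing_px = 6,
                              grid_px = 512) {
  if (n_targets + n_ptm_substrates > n_species)
    .stopf("invalid design: n_targets (%d) + n_ptm_substrates (%d) exceed n_species (%d)",
           n_targets, n_ptm_substrates, n_species)
  pr <- param_ranges
  if (n_species == 0) {
    out <- data.frame(species_id = character(), pI = numeric(),
                      mass_kda = numeric(), abundance = numeric(),
                      tm_vehicle = numeric(), slope_k = numeric(),
                      plateau_p = numeric(), delta_tm = numeric(),
                      is_target = logical(), ptm_fraction_max = numeric(),
                      ptm_tau_min = numeric(), ptm_delta_pi = numeric(),
                      is_ptm_substrate = logical(), sigma_x = numeric(),
                      sigma_y = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("proteome", "data.frame")
    return(out)
  }

  set.seed(seed)
  # Rejection-sample positions with a minimum spacing on the reference grid.
  # Each species also reserves its potential PTM-satellite site (pI shifted
  # by ptm_delta_pi) so a modified form is resolvable from its neighbours,
  # as it is on a well-resolved 2D gel.
  pI <- numeric(n_species); lm10 <- numeric(n_species)
  px <- numeric(0); py <- numeric(0)   # occupied sites (incl. satellites)
  sx_per_unit <- (grid_px - 1) / diff(pr$pI)
  sy_per_unit <- (grid_px - 1) / diff(pr$log10_mass)
  sat_dx <- pr$ptm_delta_pi * sx_per_unit
  n_acc <- 0L; tries <- 0L
  max_tries <- 2000L * n_species
  while (n_acc < n_species && tries < max_tries) {
    tries <- tries + 1L
    cand_pI <- stats::runif(1, pr$pI[1], pr$pI[2])
    cand_lm <- stats::runif(1, pr$log10_mass[1], pr$log10_mass[2])
    cx <- (cand_pI - pr$pI[1]) * sx_per_unit
    cy <- (pr$log10_mass[2] - cand_lm) * sy_per_unit
    cand_x <- c(cx, cx + sat_dx); cand_y <- c(cy, cy)
    if (length(px) > 0L &&
        min(sqrt(outer(px, cand_x, "-")^2 + outer(py, cand_y, "-")^2)) <
          min_spacing_px) next
    n_acc <- n_acc + 1L
    pI[n_acc] <- cand_pI; lm10[n_acc] <- cand_lm
    px <- c(px, cand_x); py <- c(py, cand_y)
  }
  if (n_acc < n_species)
    .stopf("could not place %d species with min_spacing_px = %g; reduce density",
           n_species, min_spacing_px)

  abundance <- stats::rlnorm(n_species, pr$abundance_meanlog, pr$abundance_sdlog)
  tm <- .clamp(stats::rnorm(n_species, pr$tm_mean, pr$tm_sd),
               pr$tm_clip[1], pr$tm_clip[2])
  k  <- stats::runif(n_species, pr$slope_k[1], pr$slope_k[2])
  p  <- stats::runif(n_species, pr$plateau_p[1], pr$plateau_p[2])
  sigx <- stats::runif(n_species, pr$sigma_px[1], pr$sigma_px[2])
  sigy <- stats::runif(n_species, pr$sigma_px[1], pr$sigma_px[2])

  idx <- sample.int(n_species, n_targets + n_ptm_substrates)
  t_idx <- idx[seq_len(n_targets)]
  m_idx <- idx[seq_len(n_ptm_substrates) + n_targets]

  delta_tm <- numeric(n_species)
  delta_tm[t_idx] <- rep_len(target_delta_tm, n_targets)
  pfm <- numeric(n_species)
  pfm[m_idx] <- stats::runif(n_ptm_substrates, pr$ptm_fraction_max[1],
                             pr$ptm_fraction_max[2])

  out <- data.frame(
    species_id = sprintf("P%04d", seq_len(n_species)),
    pI = pI, mass_kda = 10^lm10, abundance = abundance,
    tm_vehicle = tm, slope_k = k, plateau_p = p,
    delta_tm = delta_tm,
    is_target = seq_len(n_species) %in% t_idx,
    ptm_fraction_max = pfm,
    ptm_tau_min = rep(pr$ptm_tau_min, n_species),
    ptm_delta_pi = rep(pr$ptm_delta_pi, n_species),
    is_ptm_substrate = seq_len(n_species) %in% m_idx,
    sigma_x = sigx, sigma_y = sigy,
    stringsAsFactors = FALSE
  )
  class(out) <- c("proteome", "data.frame")
  out
}

#' Soluble fraction after heating
#'
#' Three-parameter logistic denaturation model: the fraction of a protein
#' remaining soluble after heating to temperature `T` is
#' `f(T) = p + (1 - p) / (1 + exp(k (T - Tm)))`, where `p` is the
#' non-denaturable floor, `k` the steepness, and `Tm` the melting midpoint.
#' Under drug treatment the midpoint of target species is shifted by
#' `delta_tm` (positive = stabilized, negative = destabilized).
#'
#' @param species One or more rows of a [generate_proteome()] table (or any
#'   data.frame with `tm_vehicle`, `slope_k`, `plateau_p`, `delta_tm`).
#' @param temperature Temperature(s) in degC. Either `species` has one row
#'   (vectorized over temperature) or `temperature` has length 1 or
#'   `nrow(species)`.
#' @param condition `"vehicle"` or `"drug"`.
#' @return Soluble fraction(s) in `[plateau_p, 1]`, monotone non-increasing
#'   in temperature.
#' @export
soluble_fraction <- function(species, temperature,
                             condition = c("vehicle", "drug")) {
  condition <- match.arg(condition)
  tm_eff <- species$tm_vehicle +
    if (condition == "drug") species$delta_tm else 0
  p <- species$plateau_p
  k <- species$slope_k
  p + (1 - p) / (1 + exp(k * (temperature - tm_eff)))
}
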