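# Signed color score of a spot: log2 ratio with the intensity floor as a
# pseudo-intensity, so single-channel spots (e.g. Cy5-only PTM satellites,
# which have no valid ratio entry) still get a finite, strongly signed
# score. Uses the 1-sigma core intensities when the table carries them:
# the core is far more sensitive to an inter-channel spatial offset (the
# registration-artifact signature) while agreeing with the integrated
# ratio for co-located channels. A 1-sigma Gaussian core holds
# 1 - exp(-1/2) ~ 39% of the integral, so the floor is scaled accordingly.
.color_score <- function(spots, intensity_floor) {
  if (!is.null(spots$core_cy5)) {
    fl <- intensity_floor * (1 - exp(-0.5))
    log2(pmax(spots$core_cy5, fl) / pmax(spots$core_cy3, fl))
  } else {
    log2(pmax(spots$intensity_cy5, intensity_floor) /
           pmax(spots$intensity_cy3, intensity_floor))
  }
}

#' Default classification thresholds
#'
#' * `tau`: color threshold on |log2(Cy5/Cy3)| beyond which a spot counts
#'   as red/green. Default 0.3, calibrated with
#'   [calibrate_color_threshold()] on inert simulations at default noise
#'   (the 99th percentile of inert |log2 ratios| is ~0.16; 0.3 adds
#'   headroom for weak spots). Configurable.
#' * `z`: z-score threshold for thermal calls (default 3).
#' * `min_y_dev`: absolute floor on the maximal curve deviation for a
#'   thermal call (default 0.3 fraction units). A standardized score alone
#'   flags inert tracks by chance: with 3% CV measurement noise the
#'   baseline-reference error propagates into every curve point, and the
#'   largest null deviation among high-z tracks reaches ~0.24; 0.3 keeps
#'   whole-run false thermal calls below ~1% of inert runs while the
#'   smallest shift of interest (2 degC at unit steepness) produces ~0.46.
#' * `min_delta_tm`: minimal fitted |Tm shift| (degC) required to call a
#'   track thermal when its baseline color is explained by a registration
#'   pair — such tracks' longitudinal deviations are contaminated by the
#'   channel offset, so transverse evidence is demanded instead.
#' * `dy_tol`, `dx_range`: PTM-pair geometry ("horizontally next to each
#'   other"): vertical tolerance 2 px, horizontal offset 2--8 px.
#' * `reg_x_tol`, `reg_dy_range`: registration-artifact geometry
#'   (vertically discrepant only): |dx| <= 1 px, 0 < |dy| <= 4 px.
#' * `intensity_tol`: relative tolerance on total intensity and widths for
#'   the artifact equal-intensity rule.
#'
#' @return Named list of thresholds.
#' @export
default_thresholds <- function() {
  list(tau = 0.3, z = 3, min_y_dev = 0.3, min_delta_tm = 2,
       dy_tol = 2, dx_range = c(2, 8),
       reg_x_tol = 1, reg_dy_range = c(1e-6, 4),
       intensity_tol = 0.35)
}

#' Calibrate the color threshold from inert simulations
#'
#' Implements the documented default rule for `tau`: simulate `n_seeds`
#' inert (no-target, no-PTM) runs at the given design's noise level, pool
#' baseline-gel log2(Cy5/Cy3) ratios, and return their 99th percentile of
#' absolute value.
#'
#' @param design An [experiment_design()] (noise and gain settings are
#'   used).
#' @param n_species Proteome size per simulation.
#' @param n_seeds Number of seeded simulations.
#' @return Scalar threshold `tau`.
#' @export
calibrate_color_threshold <- function(design, n_species = 150, n_seeds = 10) {
  ratios <- unlist(lapply(seq_len(n_seeds), function(s) {
    pro <- generate_proteome(n_species, seed = design$seed + s)
    d <- design; d$seed <- design$seed + 1000L + s
    tabs <- simulate_spot_tables(pro, d)
    base <- tabs[[1]]
    floor_i <- 3 * design$noise_add * 5
    rt <- ratio_table(base, max(floor_i, 1))
    rt$log2_ratio
  }))
  stats::quantile(abs(ratios), 0.99, names = FALSE)
}

#' Detect PTM spot pairs in the unheated gel
#'
#' A drug-induced post-translational modification shifts part of a
#' protein's population to a different isoelectric point: in the unheated
#' gel this produces a red satellite (drug-only, Cy5) horizontally next to
#' a green-shifted parent (Cy5-depleted), at the same molecular weight.
#' Pairs are opposite-sign colored spots with `|dy| <= dy_tol` and
#' horizontal offset within `dx_range`; each spot joins at most one pair
#' (greedy by combined color magnitude).
#'
#' @param spots Baseline `spot_table`.
#' @param intensity_floor Intensity floor (pseudo-intensity for the color
#'   score of single-channel spots).
#' @param tau Color threshold.
#' @param dy_tol Vertical tolerance (px).
#' @param dx_range Allowed horizontal offset `c(min, max)` (px).
#' @return `data.frame`: red_id, green_id, dx, dy, score.
#' @export
detect_ptm_pairs <- function(spots, intensity_floor,
                             tau = default_thresholds()$tau,
                             dy_tol = 2, dx_range = c(2, 8)) {
  col <- .color_score(spots, intensity_floor)
  reds <- which(col > tau); greens <- which(col < -tau)
  cand <- expand.grid(r = reds, g = greens)
  if (nrow(cand) == 0L)
    return(data.frame(red_id = character(), green_id = character(),
                      dx = numeric(), dy = numeric(), score = numeric(),
                      stringsAsFactors = FALSE))
  dx <- abs(spots$x[cand$r] - spots$x[cand$g])
  dy <- abs(spots$y[cand$r] - spots$y[cand$g])
  ok <- dy <= dy_tol & dx >= dx_range[1] & dx <= dx_range[2]
  cand <- cand[ok, , drop = FALSE]; dx <- dx[ok]; dy <- dy[ok]
  score <- abs(col[cand$r]) + abs(col[cand$g])
  o <- order(-score)
  used <- character(0)
  keep <- logical(nrow(cand))
  for (k in o) {
    ids <- c(spots$spot_id[cand$r[k]], spots$spot_id[cand$g[k]])
    if (!any(ids %in% used)) { keep[k] <- TRUE; used <- c(used, ids) }
  }
  data.frame(red_id = spots$spot_id[cand$r[keep]],
             green_id = spots$spot_id[cand$g[keep]],
             dx = dx[keep], dy = dy[keep], score = score[keep],
             stringsAsFactors = FALSE)
}

#' Detect channel misregistration artifact pairs
#'
#' A vertical offset between the Cy5 and Cy3 channels splits a single
#' protein into a red and a green spot slightly discrepant vertically,
#' with identical size and intensity. Flagged pairs are opposite-sign
#' colored spots with `|dx| <= reg_x_tol`, `0 < |dy|` within
#' `reg_dy_range`, whose total (Cy3 + Cy5) intensities and Gaussian widths
#' agree within `intensity_tol` (relative).
#'
#' @param spots A `spot_table` (typically the gel used for ranking).
#' @param intensity_floor Intensity floor for the color score.
#' @param tau Color threshold.
#' @param reg_x_tol Horizontal tolerance (px).
#' @param reg_dy_range Allowed vertical offset `c(min, max)` (px).
#' @param intensity_tol Relative tolerance for the equal-intensity and
#'   equal-width tests.
#' @return `data.frame`: red_id, green_id, dx, dy, intensity_rel_diff.
#' @export
detect_registration_artifacts <- function(spots, intensity_floor,
                                          tau = default_thresholds()$tau,
                                          reg_x_tol = 1,
                                          reg_dy_range = c(1e-6, 4),
                                          intensity_tol = 0.35) {
  col <- .color_score(spots, intensity_floor)
  tot <- spots$intensity_cy3 + spots$intensity_cy5
  reds <- which(col > tau); greens <- which(col < -tau)
  cand <- expand.grid(r = reds, g = greens)
  none <- data.frame(red_id = character(), green_id = character(),
                     dx = numeric(), dy = numeric(),
                     intensity_rel_diff = numeric(), stringsAsFactors = FALSE)
  if (nrow(cand) == 0L) return(none)
  dx <- abs(spots$x[cand$r] - spots$x[cand$g])
  dy <- abs(spots$y[cand$r] - spots$y[cand$g])
  reldiff <- function(a, b) abs(a - b) / pmax((a + b) / 2, 1e-12)
  int_ok <- reldiff(tot[cand$r], tot[cand$g]) <= intensity_tol
  wid_ok <- reldiff(spots$sigma_x[cand$r], spots$sigma_x[cand$g]) <= intensity_tol &
    reldiff(spots$sigma_y[cand$r], spots$sigma_y[cand$g]) <= intensity_tol
  ok <- dx <= reg_x_tol & dy >= reg_dy_range[1] & dy <= reg_dy_range[2] &
    int_ok & wid_ok
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0L) return(none)
  dxk <- dx[ok]; dyk <- dy[ok]
  idiff <- reldiff(tot[cand$r], tot[cand$g])
  score <- abs(col[cand$r]) + abs(col[cand$g])
  o <- order(-score)
  used <- character(0); keep <- logical(nrow(cand))
  for (k in o) {
    ids <- c(spots$spot_id[cand$r[k]], spots$spot_id[cand$g[k]])
    if (!any(ids %in% used)) { keep[k] <- TRUE; used <- c(used, ids) }
  }
  data.frame(red_id = spots$spot_id[cand$r[keep]],
             green_id = spots$spot_id[cand$g[keep]],
             dx = dxk[keep], dy = dyk[keep],
             intensity_rel_diff = idiff[keep], stringsAsFactors = FALSE)
}

#' Call every track: thermal shift, PTM pair, artifact, or unchanged
#'
#' Assembles the final per-track verdicts from the melting-shift scores and
#' the baseline-gel pair analyses. Rules, in order, per track:
#'
#' 1. `ptm_pair` — its baseline spot belongs to a PTM pair (partner
#'    recorded). PTM pairs are never called thermal.
#' 2. thermal (`stabilized` / `destabilized`) — `z_score >= z`,
#'    `y_dev_max >= min_y_dev`, and the baseline spot is NOT colored beyond
#'    `tau` (a spot already red/green in the unheated gel cannot owe its
#'    color to a thermal shift) — unless that baseline color is explained
#'    by an equal-intensity registration pair, which does not veto a
#'    thermal call. Direction from the sign of (drug - vehicle) at the
#'    maximal deviation.
#' 3. `registration_artifact` — member of a registration pair with no
#'    thermal evidence.
#' 4. `ambiguous` — colored at baseline (unexplained) with or without
#'    thermal evidence, but no partner.
#' 5. `unchanged` — everything else.
#'
#' Labels are deterministic and independent of input row order.
#'
#' @param shifts A [score_shifts()] table.
#' @param tracks The [match_spots()] tracks (to map baseline spots to
#'   tracks).
#' @param baseline_spots Baseline `spot_table`.
#' @param ptm_pairs From [detect_ptm_pairs()].
#' @param artifact_pairs From [detect_registration_artifacts()].
#' @param intensity_floor Floor used for color scores.
#' @param thresholds See [default_thresholds()].
#' @return `data.frame` of class `"spot_calls"`: track_id, label,
#'   partner_id, delta_tm, y_dev_max, z_score, baseline_color, evidence
#'   (JSON string).
#' @export
call_spots <- function(shifts, tracks, baseline_spots, ptm_pairs,
                       artifact_pairs, intensity_floor,
                       thresholds = default_thresholds()) {
  th <- utils::modifyList(default_thresholds(), thresholds)
  base_t <- attr(tracks, "baseline_temperature")
  ib <- tracks$temperature == base_t
  spot_of_track <- stats::setNames(tracks$spot_id[ib], tracks$track_id[ib])
  track_of_spot <- stats::setNames(tracks$track_id[ib], tracks$spot_id[ib])
  col <- stats::setNames(.color_score(baseline_spots, intensity_floor),
                         baseline_spots$spot_id)

  pair_partner <- function(pairs, sid) {
    if (nrow(pairs) == 0L) return(NA_character_)
    i <- match(sid, pairs$red_id)
    if (!is.na(i)) return(pairs$green_id[i])
    i <- match(sid, pairs$green_id)
    if (!is.na(i)) return(pairs$red_id[i])
    NA_character_
  }

  # every track gets exactly one call, including tracks without melting
  # scores (e.g. Cy5-only PTM satellites that cannot be Cy2-normalized)
  all_ids <- sort(unique(tracks$track_id))
  missing <- setdiff(all_ids, shifts$track_id)
  if (length(missing)) {
    pad <- shifts[rep(NA_integer_, length(missing)), , drop = FALSE]
    pad$track_id <- missing
    shifts <- rbind(shifts, pad)
  }
  shifts <- shifts[order(shifts$track_id), , drop = FALSE]
  labels <- character(nrow(shifts))
  partners <- rep(NA_character_, nrow(shifts))
  basecol <- rep(NA_real_, nrow(shifts))
  evidence <- character(nrow(shifts))
  for (i in seq_len(nrow(shifts))) {
    id <- shifts$track_id[i]
    sid <- spot_of_track[[id]]
    bc <- if (!is.null(sid) && sid %in% names(col)) col[[sid]] else NA_real_
    basecol[i] <- bc
    ptm_p <- pair_partner(ptm_pairs, sid)
    reg_p <- pair_partner(artifact_pairs, sid)
    z_ok <- is.finite(shifts$z_score[i]) && shifts$z_score[i] >= th$z
    y_ok <- is.finite(shifts$y_dev_max[i]) &&
      shifts$y_dev_max[i] >= th$min_y_dev
    colored <- is.finite(bc) && abs(bc) > th$tau
    color_vetoes <- colored && is.na(reg_p)   # artifact pairs explain color
    # registration-paired tracks need transverse (fitted Tm) evidence too,
    # and only from fits good enough to trust (both r^2 >= 0.85): the
    # channel offset contaminates their longitudinal deviations
    trans_ok <- is.na(reg_p) ||
      (is.finite(shifts$delta_tm[i]) &&
         abs(shifts$delta_tm[i]) >= th$min_delta_tm &&
         is.finite(shifts$r2_vehicle[i]) && shifts$r2_vehicle[i] >= 0.85 &&
         is.finite(shifts$r2_drug[i]) && shifts$r2_drug[i] >= 0.85)
    thermal <- z_ok && y_ok && !color_vetoes && trans_ok
    ev <- list(z = shifts$z_score[i], y_dev_max = shifts$y_dev_max[i],
               baseline_color = bc)
    if (!is.na(ptm_p)) {
      labels[i] <- "ptm_pair"
      partners[i] <- unname(track_of_spot[ptm_p] %||% ptm_p)
      ev$rule <- "baseline horizontal red/green pair"
    } else if (thermal) {
      labels[i] <- if (shifts$direction[i] >= 0) "stabilized" else "destabilized"
      ev$rule <- "melting-curve deviation"
      ev$delta_tm <- shifts$delta_tm[i]
    } else if (!is.na(reg_p)) {
      labels[i] <- "registration_artifact"
      partners[i] <- unname(track_of_spot[reg_p] %||% reg_p)
      ev$rule <- "vertical equal-intensity pair"
    } else if (colored) {
      labels[i] <- "ambiguous"
      ev$rule <- "colored at baseline, unexplained"
    } else {
      labels[i] <- "unchanged"
    }
    evidence[i] <- as.character(jsonlite::toJSON(ev, auto_unbox = TRUE,
                                                 digits = 6, na = "null"))
  }
  out <- data.frame(track_id = shifts$track_id, label = labels,
                    partner_id = partners, delta_tm = shifts$delta_tm,
                    y_dev_max = shifts$y_dev_max, z_score = shifts$z_score,
                    baseline_color = basecol, evidence = evidence,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("spot_calls", "data.frame")
  out
}
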