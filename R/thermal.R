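# Least-squares 2x3 affine from paired points (src -> dst), with one round
# of 3 x MAD outlier rejection on residual norms.
.affine_fit <- function(src, dst) {
  X <- cbind(src[, 1], src[, 2], 1)
  cf <- qr.solve(X, as.matrix(dst))          # 3 x 2
  res <- sqrt(rowSums((X %*% cf - as.matrix(dst))^2))
  thr <- stats::median(res) + 3 * stats::mad(res)
  keep <- res <= max(thr, 1e-9)
  if (sum(keep) >= 3 && sum(keep) < nrow(X)) {
    cf <- qr.solve(X[keep, , drop = FALSE], as.matrix(dst)[keep, , drop = FALSE])
  }
  t(cf)                                      # 2 x 3: [a b tx; c d ty]
}

# Mutual nearest neighbour pairs between two point sets (small n: dense).
.mnn_pairs <- function(a, b, max_dist) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(cbind(integer(0), integer(0)))
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  nb_of_a <- max.col(-d2, ties.method = "first")
  nb_of_b <- max.col(-t(d2), ties.method = "first")
  i <- seq_len(nrow(a))
  mutual <- nb_of_b[nb_of_a[i]] == i
  ok <- mutual & sqrt(d2[cbind(i, nb_of_a)]) <= max_dist
  cbind(i[ok], nb_of_a[ok])
}

#' Match spots across the temperature series into tracks
#'
#' The gel at the lowest temperature is the baseline. For every heated gel
#' an affine transform to the baseline frame is estimated from mutual
#' nearest-neighbour spot pairs (least squares with one round of 3 x MAD
#' outlier rejection; fewer than 3 pairs falls back to the identity with a
#' warning). Heated spots are then assigned to baseline spots by nearest
#' neighbour within `max_distance` (greedy by distance, one-to-one).
#' Unmatched spots in heated gels start no new tracks: a protein absent at
#' baseline has no internal-standard reference. Tracks present in every gel
#' are flagged complete.
#'
#' @param spot_tables Named list of `spot_table`s (one per gel, each with a
#'   `temperature` attribute).
#' @param max_distance Assignment radius in baseline-frame pixels.
#' @param mnn_max_distance Gating radius for registration pairs (pixels).
#' @return A long `data.frame` of class `"spot_tracks"`: track_id, gel_id,
#'   temperature, spot_id, x, y, x_reg, y_reg (baseline frame), channel
#'   intensities, flags; plus attributes `baseline_gel`, `complete`
#'   (named logical) and `registration` (per-gel transform diagnostics).
#' @export
match_spots <- function(spot_tables, max_distance = 3, mnn_max_distance = 8) {
  temps <- vapply(spot_tables, function(s) attr(s, "temperature"), 0)
  o <- order(temps)
  spot_tables <- spot_tables[o]; temps <- temps[o]
  base <- spot_tables[[1]]
  gel_ids <- vapply(spot_tables, function(s) attr(s, "gel_id") %||% NA_character_, "")

  reg <- list()
  rows <- list()
  add_rows <- function(tab, gi, track_ids, xr, yr) {
    data.frame(track_id = track_ids, gel_id = gel_ids[gi],
               temperature = temps[gi], spot_id = tab$spot_id,
               x = tab$x, y = tab$y, x_reg = xr, y_reg = yr,
               intensity_cy2 = tab$intensity_cy2,
               intensity_cy3 = tab$intensity_cy3,
               intensity_cy5 = tab$intensity_cy5,
               flags = tab$flags, stringsAsFactors = FALSE)
  }

  track_of_base <- sprintf("TR%04d", seq_len(nrow(base)))
  names(track_of_base) <- base$spot_id
  rows[[1]] <- add_rows(base, 1L, track_of_base, base$x, base$y)
  reg[[gel_ids[1]]] <- list(transform = cbind(diag(2), c(0, 0)),
                            n_pairs = nrow(base), rms = 0)

  for (gi in seq_along(spot_tables)[-1]) {
    tab <- spot_tables[[gi]]
    if (nrow(tab) == 0L) next
    pairs <- .mnn_pairs(cbind(tab$x, tab$y), cbind(base$x, base$y),
                        mnn_max_distance)
    if (nrow(pairs) < 3L) {
      .warnf("gel %s: only %d mutual pairs; registration falls back to identity",
             gel_ids[gi], nrow(pairs))
      W <- cbind(diag(2), c(0, 0)); rms <- NA_real_
    } else {
      W <- .affine_fit(cbind(tab$x, tab$y)[pairs[, 1], , drop = FALSE],
                       cbind(base$x, base$y)[pairs[, 2], , drop = FALSE])
      pr <- apply_warp(tab$x[pairs[, 1]], tab$y[pairs[, 1]], W)
      rms <- sqrt(mean((pr$x - base$x[pairs[, 2]])^2 +
                         (pr$y - base$y[pairs[, 2]])^2))
    }
    reg[[gel_ids[gi]]] <- list(transform = W, n_pairs = nrow(pairs), rms = rms)
    tr <- apply_warp(tab$x, tab$y, W)
    # greedy one-to-one nearest-neighbour assignment within max_distance
    d2 <- outer(tr$x, base$x, "-")^2 + outer(tr$y, base$y, "-")^2
    cand <- which(d2 <= max_distance^2, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(d2[cand]), , drop = FALSE]
      used_s <- logical(nrow(tab)); used_b <- logical(nrow(base))
      sel <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        si <- cand[k, 1]; bi <- cand[k, 2]
        if (!used_s[si] && !used_b[bi]) {
          used_s[si] <- TRUE; used_b[bi] <- TRUE; sel[k] <- TRUE
        }
      }
      cand <- cand[sel, , drop = FALSE]
      if (nrow(cand)) {
        tsub <- tab[cand[, 1], , drop = FALSE]
        rows[[length(rows) + 1L]] <-
          add_rows(tsub, gi, track_of_base[base$spot_id[cand[, 2]]],
                   tr$x[cand[, 1]], tr$y[cand[, 1]])
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_gels <- length(spot_tables)
  complete <- tapply(out$gel_id, out$track_id,
                     function(g) length(unique(g)) == n_gels)
  class(out) <- c("spot_tracks", "data.frame")
  attr(out, "baseline_gel") <- gel_ids[1]
  attr(out, "baseline_temperature") <- temps[1]
  attr(out, "n_gels") <- n_gels
  attr(out, "complete") <- complete
  attr(out, "registration") <- reg
  out
}

#' Normalize tracks by the Cy2 internal standard
#'
#' For each track member the channel intensities are first divided by the
#' Cy2 internal-standard intensity measured on the same footprint,
#' `R_c(T) = I_c(T) / I_cy2(T)`, which cancels per-gel gain exactly (the
#' same unheated Cy2-labelled proteome was loaded on every gel). Each
#' condition is then self-referenced to the unheated baseline,
#' `rel_c(T) = R_c(T) / R_c(T_baseline)`, so both curves start at 1.
#' Members with Cy2 at or below `cy2_floor` yield missing points; a track
#' whose baseline Cy2 fails the floor cannot be normalized and is dropped
#' (flagged in the `dropped` attribute).
#'
#' @param tracks A [match_spots()] result.
#' @param cy2_floor Intensity floor for the Cy2 reference.
#' @return A `data.frame` of class `"melting_curves"`: track_id, gel_id,
#'   temperature, rel_vehicle, rel_drug.
#' @export
normalize_tracks <- function(tracks, cy2_floor = 0) {
  base_t <- attr(tracks, "baseline_temperature")
  ok2 <- tracks$intensity_cy2 > cy2_floor
  r3 <- ifelse(ok2, tracks$intensity_cy3 / tracks$intensity_cy2, NA_real_)
  r5 <- ifelse(ok2, tracks$intensity_cy5 / tracks$intensity_cy2, NA_real_)
  is_base <- tracks$temperature == base_t
  b3 <- stats::setNames(r3[is_base], tracks$track_id[is_base])
  b5 <- stats::setNames(r5[is_base], tracks$track_id[is_base])
  base3 <- b3[tracks$track_id]; base5 <- b5[tracks$track_id]
  rel_v <- ifelse(is.finite(base3) & base3 > 0, r3 / base3, NA_real_)
  rel_d <- ifelse(is.finite(base5) & base5 > 0, r5 / base5, NA_real_)
  out <- data.frame(track_id = tracks$track_id, gel_id = tracks$gel_id,
                    temperature = tracks$temperature,
                    rel_vehicle = rel_v, rel_drug = rel_d,
                    stringsAsFactors = FALSE)
  dropped <- unique(tracks$track_id[!(tracks$track_id %in%
                                        names(b3)[is.finite(b3) & b3 > 0])])
  out <- out[!(out$track_id %in% dropped), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("melting_curves", "data.frame")
  attr(out, "baseline_temperature") <- base_t
  attr(out, "n_gels") <- attr(tracks, "n_gels")
  attr(out, "dropped") <- dropped
  out
}

# Logistic soluble-fraction model, self-referenced to the lowest observed
# temperature (matching how the measured curves are normalized). plogis is
# the overflow-safe form of 1 / (1 + exp(k (T - Tm))).
.melt_model <- function(temp, t0, tm, k, p) {
  f <- p + (1 - p) * stats::plogis(-k * (temp - tm))
  f0 <- p + (1 - p) * stats::plogis(-k * (t0 - tm))
  f / f0
}

#' Fit a logistic melting curve
#'
#' Nonlinear least squares of the 3-parameter logistic
#' `f(T) = p + (1 - p) / (1 + exp(k (T - Tm)))`, self-referenced to the
#' lowest observed temperature to match baseline-normalized data.
#' Initialization is a coarse grid over Tm (the observed temperature range)
#' and k in {0.2, 0.5, 1, 2}; bounds are `0 <= p <= 0.5`, `k > 0`. Needs at
#' least 4 non-missing points and a non-flat curve (range > 0.2) spanning
#' the apparent midpoint, else `converged = FALSE` with missing parameters.
#'
#' @param temperatures Temperatures (degC).
#' @param fractions Normalized soluble fractions (baseline = 1).
#' @return One-row `data.frame` of class `"melting_fit"`: tm, slope_k,
#'   plateau_p, r_squared, converged.
#' @export
fit_melting <- function(temperatures, fractions) {
  no_fit <- data.frame(tm = NA_real_, slope_k = NA_real_,
                       plateau_p = NA_real_, r_squared = NA_real_,
                       converged = FALSE)
  class(no_fit) <- c("melting_fit", "data.frame")
  ok <- is.finite(temperatures) & is.finite(fractions)
  temp <- temperatures[ok]; fr <- fractions[ok]
  if (length(temp) < 4L) return(no_fit)
  rng <- max(fr) - min(fr)
  mid <- (max(fr) + min(fr)) / 2
  if (rng < 0.2 || !any(fr > mid) || !any(fr < mid)) return(no_fit)
  t0 <- min(temp)

  grid <- expand.grid(tm = seq(min(temp), max(temp), length.out = 16),
                      k = c(0.2, 0.5, 1, 2))
  sse <- vapply(seq_len(nrow(grid)), function(i) {
    sum((fr - .melt_model(temp, t0, grid$tm[i], grid$k[i], 0.05))^2)
  }, 0)
  resid_fun <- function(par) fr - .melt_model(temp, t0, par[1], par[2], par[3])
  best <- NULL
  for (gi in order(sse)[1:3]) {           # fall back to next-best starts
    fit <- tryCatch(suppressWarnings(
      minpack.lm::nls.lm(
        par = c(tm = grid$tm[gi], k = grid$k[gi], p = 0.05),
        lower = c(tm = min(temp) - 15, k = 1e-3, p = 0),
        upper = c(tm = max(temp) + 15, k = 10, p = 0.5),
        fn = resid_fun,
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (!is.null(fit) && fit$info %in% 1:4 &&
        (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best)) return(no_fit)
  cf <- best$par
  ss_res <- best$deviance
  ss_tot <- sum((fr - mean(fr))^2)
  out <- data.frame(tm = unname(cf["tm"]), slope_k = unname(cf["k"]),
                    plateau_p = unname(cf["p"]),
                    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                    converged = unname(cf["k"]) > 0)
  class(out) <- c("melting_fit", "data.frame")
  out
}

#' Fit melting curves for all tracks
#'
#' Fits vehicle (Cy3-derived) and drug (Cy5-derived) curves per track.
#' Tracks missing more than half of their heated points are not fitted
#' (flagged `partial`); they can still be scored by y-deviation.
#'
#' @param curves A [normalize_tracks()] result.
#' @return `data.frame`: track_id, tm_vehicle, tm_drug, k/p/r2 per
#'   condition, converged flags, partial flag.
#' @export
fit_melting_tracks <- function(curves) {
  n_gels <- attr(curves, "n_gels") %||% length(unique(curves$temperature))
  n_heated <- n_gels - 1L
  ids <- unique(curves$track_id)
  res <- lapply(ids, function(id) {
    cu <- curves[curves$track_id == id, , drop = FALSE]
    base_t <- attr(curves, "baseline_temperature") %||% min(cu$temperature)
    n_h <- sum(cu$temperature > base_t &
                 (is.finite(cu$rel_vehicle) | is.finite(cu$rel_drug)))
    partial <- n_h < n_heated / 2
    if (partial) {
      fv <- fd <- fit_melting(numeric(0), numeric(0))
    } else {
      fv <- fit_melting(cu$temperature, cu$rel_vehicle)
      fd <- fit_melting(cu$temperature, cu$rel_drug)
    }
    data.frame(track_id = id,
               tm_vehicle = fv$tm, slope_k_vehicle = fv$slope_k,
               plateau_vehicle = fv$plateau_p, r2_vehicle = fv$r_squared,
               converged_vehicle = fv$converged,
               tm_drug = fd$tm, slope_k_drug = fd$slope_k,
               plateau_drug = fd$plateau_p, r2_drug = fd$r_squared,
               converged_drug = fd$converged,
               partial = partial, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Score drug-induced melting shifts per track
#'
#' Two complementary statistics per track:
#' * transverse: `delta_tm = tm_drug - tm_vehicle` from the two logistic
#'   fits (missing unless both converged);
#' * longitudinal: `y_dev_max`, the maximum over measured temperatures of
#'   `|rel_drug - rel_vehicle|`, and `y_dev_area`, the trapezoidal area
#'   between the two curves. Both are computed from the normalized data
#'   points, not the fits, so a steep-slope protein with a marginal Tm
#'   shift still registers.
#'
#' `z_score` standardizes `y_dev_max` across all tracks in the run
#' (robustly, by median and MAD, so a few true targets do not inflate the
#' scale).
#'
#' @param curves A [normalize_tracks()] result.
#' @param fits Optional [fit_melting_tracks()] result (computed if `NULL`).
#' @return `data.frame` of class `"shift_table"`: track_id, delta_tm,
#'   y_dev_max, y_dev_area, z_score, direction, n_points, partial.
#' @export
score_shifts <- function(curves, fits = NULL) {
  if (is.null(fits)) fits <- fit_melting_tracks(curves)
  ids <- unique(curves$track_id)
  res <- lapply(ids, function(id) {
    cu <- curves[curves$track_id == id, , drop = FALSE]
    ok <- is.finite(cu$rel_vehicle) & is.finite(cu$rel_drug)
    dv <- cu$rel_drug[ok] - cu$rel_vehicle[ok]
    tt <- cu$temperature[ok]
    ymax <- if (length(dv)) max(abs(dv)) else NA_real_
    yarea <- .abs_area(tt, dv)
    dir <- if (length(dv) && max(abs(dv)) > 0)
      sign(dv[which.max(abs(dv))]) else 0
    data.frame(track_id = id, y_dev_max = ymax, y_dev_area = yarea,
               direction = dir, n_points = sum(ok),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  fi <- fits[match(out$track_id, fits$track_id), ]
  out$delta_tm <- ifelse(fi$converged_vehicle & fi$converged_drug,
                         fi$tm_drug - fi$tm_vehicle, NA_real_)
  out$r2_vehicle <- fi$r2_vehicle
  out$r2_drug <- fi$r2_drug
  out$partial <- fi$partial

  y <- out$y_dev_max
  med <- stats::median(y, na.rm = TRUE)
  scale <- stats::mad(y, na.rm = TRUE)
  if (!is.finite(scale) || scale == 0) scale <- stats::sd(y, na.rm = TRUE)
  out$z_score <- if (is.finite(scale) && scale > 0) (y - med) / scale else 0
  rownames(out) <- NULL
  out <- out[, c("track_id", "delta_tm", "y_dev_max", "y_dev_area",
                 "z_score", "direction", "n_points", "r2_vehicle",
                 "r2_drug", "partial")]
  class(out) <- c("shift_table", "data.frame")
  out
}
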