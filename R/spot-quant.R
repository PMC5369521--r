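#' Per-spot Cy5/Cy3 ratio table
#'
#' Computes `log2(I_cy5 / I_cy3)` for every spot whose Cy3 AND Cy5
#' integrated intensities exceed `intensity_floor`; spots failing the floor
#' are excluded (and counted in the `n_excluded` attribute) rather than
#' clamped, to avoid fabricating extreme ratios from noise. A ratio of 0
#' is a "yellow" spot (equal vehicle and drug signal), positive ratios are
#' red (more soluble protein under drug, stabilization at a denaturing
#' temperature) and negative ratios green (destabilization).
#'
#' @param spots A `spot_table` from [detect_spots()].
#' @param intensity_floor Positive intensity floor; see
#'   [default_intensity_floor()].
#' @return A `data.frame` of class `"ratio_table"`: spot_id, gel_id,
#'   log2_ratio, percentile_rank (0--100), outlier_flag (filled by
#'   [summarize_ratios()]), plus x, y carried along for spatial rules.
#' @export
ratio_table <- function(spots, intensity_floor) {
  if (intensity_floor <= 0) .stopf("intensity_floor must be > 0")
  gel_id <- attr(spots, "gel_id") %||% NA_character_
  temp <- attr(spots, "temperature") %||% NA_real_
  keep <- spots$intensity_cy3 > intensity_floor &
    spots$intensity_cy5 > intensity_floor
  out <- data.frame(
    spot_id = spots$spot_id[keep],
    gel_id = gel_id,
    log2_ratio = log2(spots$intensity_cy5[keep] / spots$intensity_cy3[keep]),
    percentile_rank = NA_real_,
    outlier_flag = "none",
    x = spots$x[keep], y = spots$y[keep],
    stringsAsFactors = FALSE
  )
  n <- nrow(out)
  if (n > 0)
    out$percentile_rank <-
      100 * (rank(out$log2_ratio, ties.method = "average") - 0.5) / n
  class(out) <- c("ratio_table", "data.frame")
  attr(out, "temperature") <- temp
  attr(out, "n_excluded") <- sum(!keep)
  attr(out, "intensity_floor") <- intensity_floor
  out
}

#' Box-plot summary of a ratio distribution
#'
#' Summarizes the per-gel log2(Cy5/Cy3) distribution the way the method's
#' box plots are drawn: median, quartiles, and whiskers at the 1st and 99th
#' percentiles (linear-interpolation percentile definition). Entries beyond
#' the whiskers are flagged `high`/`low` — these are the candidate
#' stabilized/destabilized spots.
#'
#' @param entries A [ratio_table()] with at least 2 entries.
#' @return List of class `"ratio_summary"` with `$summary` (one-row
#'   data.frame: median, q1, q3, whisker_low, whisker_high, n_spots) and
#'   `$entries` (the input with `outlier_flag` filled).
#' @export
summarize_ratios <- function(entries) {
  if (nrow(entries) < 2L)
    .stopf("insufficient data: need >= 2 ratio entries, got %d", nrow(entries))
  q <- stats::quantile(entries$log2_ratio, c(0.01, 0.25, 0.5, 0.75, 0.99),
                       type = 7, names = FALSE)
  summary <- data.frame(median = q[3], q1 = q[2], q3 = q[4],
                        whisker_low = q[1], whisker_high = q[5],
                        n_spots = nrow(entries))
  entries$outlier_flag <- ifelse(entries$log2_ratio > q[5], "high",
                          ifelse(entries$log2_ratio < q[1], "low", "none"))
  structure(list(summary = summary, entries = entries),
            class = "ratio_summary")
}

#' @export
print.ratio_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "log2(Cy5/Cy3) over %d spots: median %.3f [Q1 %.3f, Q3 %.3f], 1-99%% whiskers [%.3f, %.3f]; %d high / %d low outliers\n",
    s$n_spots, s$median, s$q1, s$q3, s$whisker_low, s$whisker_high,
    sum(x$entries$outlier_flag == "high"), sum(x$entries$outlier_flag == "low")))
  invisible(x)
}

#' Rank drug-target candidate spots by ratio extremity
#'
#' Stabilized candidates are ranked by descending log2(Cy5/Cy3) (highest
#' ratio first), destabilized by ascending (lowest first), and `both` by
#' descending absolute ratio. The full ordered list is always returned —
#' any whisker-based cut is advisory.
#'
#' @param entries A [ratio_table()] (outlier flags optional).
#' @param direction `"stabilized"`, `"destabilized"`, or `"both"`.
#' @return The entries, ordered, with a `rank` column and the gel
#'   temperature carried in the `temperature` column.
#' @export
rank_candidates <- function(entries,
                            direction = c("stabilized", "destabilized", "both")) {
  direction <- match.arg(direction)
  o <- switch(direction,
              stabilized   = order(-entries$log2_ratio),
              destabilized = order(entries$log2_ratio),
              both         = order(-abs(entries$log2_ratio)))
  out <- entries[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$temperature <- attr(entries, "temperature") %||% NA_real_
  rownames(out) <- NULL
  out
}

#' Compose a red/green(/blue) overlay image
#'
#' Maps Cy5 to red and Cy3 to green (optionally Cy2 to blue), with a
#' per-channel linear contrast stretch between the given intensity
#' percentiles. Equal Cy3/Cy5 renders yellow; with Cy2 included, a spot
#' with all three channels equal renders white.
#'
#' @param gel Background-corrected [gel_image()].
#' @param stretch_percentiles Lower/upper stretch percentiles (0--100).
#' @param include_cy2 Map Cy2 to the blue channel?
#' @return An `nrow x ncol x 3` array in `[0, 1]` (R, G, B).
#' @export
compose_overlay <- function(gel, stretch_percentiles = c(1, 99.5),
                            include_cy2 = FALSE) {
  stretch <- function(m) {
    q <- stats::quantile(m, stretch_percentiles / 100, names = FALSE)
    if (q[2] <= q[1]) q[2] <- q[1] + 1
    .clamp((m - q[1]) / (q[2] - q[1]), 0, 1)
  }
  r <- stretch(gel$cy5)
  g <- stretch(gel$cy3)
  b <- if (include_cy2) stretch(gel$cy2) else matrix(0, nrow(r), ncol(r))
  out <- array(0, dim = c(nrow(r), ncol(r), 3))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out
}
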