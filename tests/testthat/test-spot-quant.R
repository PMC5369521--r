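make_spots <- function(i3, i5, x = seq_along(i3) * 10, y = 5) {
  n <- length(i3)
  df <- data.frame(spot_id = sprintf("S%03d", seq_len(n)), x = x,
                   y = rep_len(y, n), sigma_x = 1, sigma_y = 1, theta = 0,
                   intensity_cy2 = pmax(i3, i5), intensity_cy3 = i3,
                   intensity_cy5 = i5, fit_quality = 1, flags = "",
                   stringsAsFactors = FALSE)
  class(df) <- c("spot_table", "data.frame")
  attr(df, "gel_id") <- "G1"
  attr(df, "temperature") <- 53
  df
}

test_that("log2 ratios obey identity, log law and floor exclusion", {
  sp <- make_spots(i3 = c(100, 100, 400, 2), i5 = c(100, 400, 100, 100))
  rt <- ratio_table(sp, intensity_floor = 10)
  expect_equal(nrow(rt), 3)           # the I3 = 2 spot fails the floor
  expect_equal(attr(rt, "n_excluded"), 1)
  expect_equal(rt$log2_ratio, c(0, 2, -2))
  expect_error(ratio_table(sp, 0), "floor")
})

test_that("ratio antisymmetry and scale invariance hold exactly", {
  set.seed(3)
  i3 <- exp(rnorm(50, 8)); i5 <- exp(rnorm(50, 8))
  r1 <- ratio_table(make_spots(i3, i5), 1)$log2_ratio
  r2 <- ratio_table(make_spots(i5, i3), 1)$log2_ratio
  expect_equal(r1, -r2, tolerance = 1e-12)
  g <- 2.7
  r3 <- ratio_table(make_spots(g * i3, g * i5), 1)$log2_ratio
  expect_equal(r3, r1, tolerance = 1e-12)
})

test_that("box-plot summary uses 1-99 percentile whiskers and flags extremes", {
  # degenerate: all entries equal
  rt <- ratio_table(make_spots(rep(100, 5), rep(200, 5)), 1)
  s <- summarize_ratios(rt)$summary
  expect_equal(unlist(s[c("median", "q1", "q3", "whisker_low", "whisker_high")]),
               rep(1, 5), ignore_attr = TRUE)
  expect_error(summarize_ratios(rt[1, ]), "insufficient")

  # percentile oracle: independent sort-and-interpolate implementation
  set.seed(7)
  z <- rnorm(1000)
  rt <- ratio_table(make_spots(rep(1000, 1000), 1000 * 2^z), 1)
  s <- summarize_ratios(rt)$summary
  manual_pct <- function(v, p) {
    v <- sort(v); h <- (length(v) - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    v[lo] + (h - lo) * (v[hi] - v[lo])
  }
  expect_equal(s$whisker_low, manual_pct(z, 0.01), tolerance = 1e-10)
  expect_equal(s$whisker_high, manual_pct(z, 0.99), tolerance = 1e-10)
  expect_equal(s$whisker_high, 2.33, tolerance = 0.15)

  # constructed extremes are the flagged outliers (98 tight + 2 extremes:
  # the 1-99% whiskers leave exactly the injected values outside)
  base <- rnorm(98, 0, 0.05)
  rt <- ratio_table(make_spots(rep(1000, 100), 1000 * 2^c(base, 5, -5)), 1)
  sm <- summarize_ratios(rt)
  expect_equal(sm$entries$spot_id[sm$entries$outlier_flag == "high"], "S099")
  expect_equal(sm$entries$spot_id[sm$entries$outlier_flag == "low"], "S100")
})

test_that("whisker ordering invariant holds across random samples", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:300, 1)
    rt <- ratio_table(make_spots(rep(1000, n), 1000 * 2^rnorm(n, 0, 2)), 1)
    s <- summarize_ratios(rt)$summary
    expect_true(s$whisker_low <= s$q1 & s$q1 <= s$median &
                  s$median <= s$q3 & s$q3 <= s$whisker_high)
  }
})

test_that("candidate ranking honours direction semantics", {
  rt <- ratio_table(make_spots(rep(100, 4), c(800, 50, 100, 25)), 1)
  stab <- rank_candidates(rt, "stabilized")
  expect_equal(stab$spot_id[1], "S001")
  expect_true(all(diff(stab$log2_ratio) <= 0))
  dest <- rank_candidates(rt, "destabilized")
  expect_equal(dest$spot_id[1], "S004")
  both <- rank_candidates(rt, "both")
  expect_equal(both$log2_ratio, both$log2_ratio[order(-abs(both$log2_ratio))])
  expect_equal(unique(stab$temperature), 53)
})

test_that("overlay colors encode the channel semantics", {
  spot <- data.frame(A = 100, x0 = 10, y0 = 10, sx = 1, sy = 1)
  r <- make_gaussian_raster(c(24, 24), spot)
  # equal Cy3/Cy5 -> yellow (R == G), no blue
  ov <- compose_overlay(gel_image(r * 0, r, r, 37, "a"))
  expect_equal(ov[, , 1], ov[, , 2])
  expect_true(all(ov[, , 3] == 0))
  expect_gt(ov[11, 11, 1], 0.9)
  # Cy5 = 0 -> pure green at the spot
  ov <- compose_overlay(gel_image(r * 0, r, r * 0, 37, "b"))
  expect_equal(max(ov[, , 1]), 0)
  expect_gt(ov[11, 11, 2], 0.9)
  # all three equal -> white with Cy2 mapped to blue
  ov <- compose_overlay(gel_image(r, r, r, 37, "c"), include_cy2 = TRUE)
  expect_equal(ov[11, 11, ], rep(ov[11, 11, 1], 3))
  expect_gt(ov[11, 11, 1], 0.9)
})
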