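temps8 <- c(37, 41, 44, 47, 50, 53, 58, 64)

test_that("identical spot tables yield complete tracks and identity registration", {
  pro <- generate_proteome(30, seed = 31, grid_px = 256)
  des <- quiet_design(temperatures = temps8)
  tabs <- simulate_spot_tables(pro, des, loc_jitter_px = 0)
  tracks <- match_spots(tabs)
  expect_equal(length(unique(tracks$track_id)), 30)
  expect_true(all(attr(tracks, "complete")))
  reg <- attr(tracks, "registration")
  for (gid in names(reg)[-1]) {
    expect_equal(reg[[gid]]$transform, cbind(diag(2), c(0, 0)),
                 tolerance = 1e-6)
  }
})

test_that("a known affine warp is recovered to sub-pixel accuracy", {
  pro <- generate_proteome(60, seed = 32, grid_px = 256)
  warp <- lapply(seq_along(temps8), function(i) {
    if (i == 1) cbind(diag(2), c(0, 0)) else
      cbind(matrix(c(1.004, 0.003, -0.002, 0.996), 2, 2), c(1.5, -1.2))
  })
  des <- quiet_design(temperatures = temps8, warp = warp,
                      noise_add = 10, noise_cv = 0.02)
  tabs <- simulate_spot_tables(pro, des, loc_jitter_px = 0.1)
  tracks <- match_spots(tabs)
  reg <- attr(tracks, "registration")
  # recovered transform maps true warped positions back near reference
  lr <- log10(des$mass_range_kda)
  pos <- data.frame(
    x = (pro$pI - des$pI_range[1]) / diff(des$pI_range) * 255,
    y = (lr[2] - log10(pro$mass_kda)) / diff(lr) * 255)
  for (gid in names(reg)[-1]) {
    W_true <- warp[[2]]
    wx <- W_true[1, 1] * pos$x + W_true[1, 2] * pos$y + W_true[1, 3]
    wy <- W_true[2, 1] * pos$x + W_true[2, 2] * pos$y + W_true[2, 3]
    W_est <- reg[[gid]]$transform
    bx <- W_est[1, 1] * wx + W_est[1, 2] * wy + W_est[1, 3]
    by <- W_est[2, 1] * wx + W_est[2, 2] * wy + W_est[2, 3]
    rms <- sqrt(mean((bx - pos$x)^2 + (by - pos$y)^2))
    expect_lt(rms, 0.5)
  }
  expect_gt(mean(attr(tracks, "complete")), 0.9)
})

test_that("spots absent from heated gels keep incomplete tracks; no new tracks start late", {
  base <- data.frame(spot_id = c("S1", "S2"), x = c(10, 40), y = c(10, 40),
                     sigma_x = 1, sigma_y = 1, theta = 0,
                     intensity_cy2 = 1000, intensity_cy3 = 1000,
                     intensity_cy5 = 1000, fit_quality = 1, flags = "",
                     stringsAsFactors = FALSE)
  heated <- base[1, ]
  heated$spot_id <- "H1"
  late <- base
  late$spot_id <- c("L1", "L2"); late$x <- late$x + 100  # unmatched positions
  mk <- function(df, temp, gid) {
    class(df) <- c("spot_table", "data.frame")
    attr(df, "temperature") <- temp; attr(df, "gel_id") <- gid
    df
  }
  tabs <- list(T37 = mk(base, 37, "T37"), T50 = mk(heated, 50, "T50"),
               T60 = mk(late, 60, "T60"))
  tracks <- suppressWarnings(match_spots(tabs))
  comp <- attr(tracks, "complete")
  expect_equal(length(unique(tracks$track_id)), 2)  # no late-starting tracks
  expect_false(any(comp))
  # S2's track exists with only the baseline member
  t2 <- tracks[tracks$spot_id == "S2", "track_id"]
  expect_equal(sum(tracks$track_id == t2), 1)
})

test_that("Cy2 normalization cancels per-gel gain exactly and self-references baseline", {
  pro <- generate_proteome(20, n_targets = 2, seed = 33, target_delta_tm = 6,
                           grid_px = 256)
  des <- quiet_design(temperatures = temps8, noise_add = 5, noise_cv = 0.02)
  tabs <- simulate_spot_tables(pro, des)
  tracks <- match_spots(tabs)
  curves <- normalize_tracks(tracks)
  # baseline points are exactly 1
  base <- curves[curves$temperature == 37, ]
  expect_true(all(base$rel_vehicle == 1 & base$rel_drug == 1))

  # scale all three channels of one heated gel by g: curves unchanged
  tabs2 <- tabs
  for (col in c("intensity_cy2", "intensity_cy3", "intensity_cy5"))
    tabs2[[4]][[col]] <- tabs2[[4]][[col]] * 2.7
  curves2 <- normalize_tracks(match_spots(tabs2))
  o1 <- curves[order(curves$track_id, curves$temperature), ]
  o2 <- curves2[order(curves2$track_id, curves2$temperature), ]
  expect_equal(o2$rel_vehicle, o1$rel_vehicle, tolerance = 1e-12)
  expect_equal(o2$rel_drug, o1$rel_drug, tolerance = 1e-12)
})

test_that("noiseless normalized curves recover the generating soluble fraction", {
  pro <- generate_proteome(15, seed = 34, grid_px = 256)
  des <- quiet_design(temperatures = temps8)
  tabs <- simulate_spot_tables(pro, des, loc_jitter_px = 0)
  truth <- attr(tabs[[1]], "truth")
  tracks <- match_spots(tabs)
  curves <- normalize_tracks(tracks)
  base_tab <- tabs[[1]]
  for (tid in unique(curves$track_id)[1:10]) {
    sid <- tracks$spot_id[tracks$track_id == tid & tracks$temperature == 37]
    spid <- truth$species_id[truth$spot_id == sid]
    i <- match(spid, pro$species_id)
    cu <- curves[curves$track_id == tid, ]
    f <- soluble_fraction(pro[i, ], cu$temperature, "vehicle")
    f0 <- soluble_fraction(pro[i, ], 37, "vehicle")
    expect_equal(cu$rel_vehicle, f / f0, tolerance = 0.02)
  }
})

test_that("noiseless logistic samples invert to the generating parameters", {
  f <- function(T, tm, k, p) p + (1 - p) / (1 + exp(k * (T - tm)))
  fr <- f(temps8, 50, 1, 0.05) / f(37, 50, 1, 0.05)
  fit <- fit_melting(temps8, fr)
  expect_true(fit$converged)
  expect_equal(fit$tm, 50, tolerance = 0.1)
  expect_equal(fit$slope_k, 1, tolerance = 0.05)
  expect_equal(fit$plateau_p, 0.05, tolerance = 0.05 * 0.05 + 0.01)
  expect_gt(fit$r_squared, 0.999)
})

test_that("degenerate melting inputs do not fabricate fits", {
  expect_false(fit_melting(temps8, rep(1, 8))$converged)
  expect_false(fit_melting(c(37, 50), c(1, 0.2))$converged)   # too few points
  expect_true(is.na(fit_melting(temps8, rep(1, 8))$tm))
})

test_that("Tm is recovered within 0.5 degC under 3% multiplicative noise", {
  f <- function(T, tm, k, p) p + (1 - p) / (1 + exp(k * (T - tm)))
  errs <- vapply(1:25, function(s) {
    set.seed(s)
    fr <- f(temps8, 49, 1.1, 0.05) * (1 + 0.03 * rnorm(8))
    fr <- fr / fr[1]
    fit_melting(temps8, fr)$tm - 49
  }, 0)
  expect_lte(median(abs(errs)), 0.5)
})

test_that("shift scores are null for identical curves and detect a known shift", {
  pro <- generate_proteome(40, n_targets = 1, seed = 35, target_delta_tm = 8,
                           grid_px = 256)
  pro$tm_vehicle[pro$is_target] <- 50   # keep both midpoints in range
  des <- quiet_design(temperatures = temps8)
  tabs <- simulate_spot_tables(pro, des, loc_jitter_px = 0)
  tracks <- match_spots(tabs)
  curves <- normalize_tracks(tracks)
  shifts <- score_shifts(curves)
  truth <- attr(tabs[[1]], "truth")
  tgt_sid <- truth$spot_id[truth$species_id == pro$species_id[pro$is_target]]
  tgt_tid <- tracks$track_id[tracks$spot_id == tgt_sid &
                               tracks$temperature == 37]
  i <- shifts$track_id == tgt_tid
  # noiseless: inert tracks have exactly identical curves
  expect_true(all(shifts$y_dev_max[!i] < 1e-9))
  expect_true(all(abs(shifts$delta_tm[!i]) < 0.1, na.rm = TRUE))
  # the target dominates and its fitted shift matches the truth
  expect_equal(shifts$delta_tm[i], 8, tolerance = 1)
  expect_equal(which.max(shifts$y_dev_max), which(i))
  expect_gt(shifts$y_dev_area[i], 0)
})
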