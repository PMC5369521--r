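mk_spots <- function(df, temp = 37, gid = "T37") {
  defaults <- data.frame(sigma_x = 1, sigma_y = 1, theta = 0,
                         fit_quality = 1, flags = "")
  for (nm in names(defaults)) if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  if (is.null(df$intensity_cy2)) df$intensity_cy2 <- 1000
  class(df) <- c("spot_table", "data.frame")
  attr(df, "temperature") <- temp; attr(df, "gel_id") <- gid
  df
}

test_that("PTM pairs require opposite colors and horizontal adjacency", {
  sp <- mk_spots(data.frame(
    spot_id = c("R1", "G1", "R2", "R3", "N1"),
    x = c(14, 10, 30, 34, 50),
    y = c(5, 5, 20, 20, 40),
    intensity_cy3 = c(10, 1000, 500, 500, 800),
    intensity_cy5 = c(500, 400, 5000, 5000, 810)))
  pairs <- detect_ptm_pairs(sp, intensity_floor = 50)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$red_id, "R1")
  expect_equal(pairs$green_id, "G1")
  # two red spots side by side never pair (R2, R3)
  expect_false(any(c("R2", "R3") %in% c(pairs$red_id, pairs$green_id)))
})

test_that("PTM pairs respect the horizontal-offset window and vertical tolerance", {
  base <- data.frame(
    spot_id = c("R1", "G1"), x = c(10, 20), y = c(5, 5),
    intensity_cy3 = c(10, 1000), intensity_cy5 = c(500, 400))
  # dx = 10 exceeds dx_max = 8
  expect_equal(nrow(detect_ptm_pairs(mk_spots(base), 50)), 0)
  base$x <- c(10, 14)
  expect_equal(nrow(detect_ptm_pairs(mk_spots(base), 50)), 1)
  base$y <- c(5, 9)   # dy = 4 exceeds dy_tol = 2
  expect_equal(nrow(detect_ptm_pairs(mk_spots(base), 50)), 0)
})

test_that("registration artifacts demand vertical offset and equal size/intensity", {
  sp <- mk_spots(data.frame(
    spot_id = c("A", "B", "C", "D"),
    x = c(10, 10.2, 30, 30.2),
    y = c(5, 7, 20, 22),
    intensity_cy3 = c(1000, 300, 1000, 50),
    intensity_cy5 = c(300, 1000, 5000, 6000)))
  pairs <- detect_registration_artifacts(sp, intensity_floor = 50)
  expect_equal(nrow(pairs), 1)
  expect_setequal(c(pairs$red_id, pairs$green_id), c("A", "B"))
  # C/D: both red (same sign), and intensities differ wildly -> no pair
  expect_false(any(c("C", "D") %in% c(pairs$red_id, pairs$green_id)))
})

test_that("simulated PTM substrates produce parent/green + satellite/red pairs", {
  pro <- generate_proteome(30, n_ptm_substrates = 3, seed = 44, grid_px = 256)
  des <- quiet_design(noise_add = 5, noise_cv = 0.02, treatment_minutes = 20)
  tabs <- simulate_spot_tables(pro, des)
  base <- tabs[[1]]
  pairs <- detect_ptm_pairs(base, 15 * 5)
  expect_equal(nrow(pairs), 3)
  truth <- attr(base, "truth")
  sat_ids <- truth$spot_id[grepl("_sat$", truth$species_id)]
  expect_setequal(pairs$red_id, sat_ids)

  # no treatment, no modification, no pairs
  des0 <- quiet_design(noise_add = 5, noise_cv = 0.02, treatment_minutes = 0)
  tabs0 <- simulate_spot_tables(pro, des0)
  expect_equal(nrow(detect_ptm_pairs(tabs0[[1]], 15 * 5)), 0)
})

test_that("calls are deterministic, order-invariant, and respect precedence", {
  pro <- generate_proteome(40, n_targets = 1, n_ptm_substrates = 2,
                           seed = 45, target_delta_tm = -5, grid_px = 256)
  pro$tm_vehicle[pro$is_target] <- 50
  des <- quiet_design(noise_add = 5, noise_cv = 0.02)
  tabs <- simulate_spot_tables(pro, des)
  an <- analyze_spot_tables(tabs, 15 * 5)
  calls <- an$calls
  expect_equal(anyDuplicated(calls$track_id), 0)
  expect_true(all(calls$label %in% c("stabilized", "destabilized", "ptm_pair",
                                     "registration_artifact", "unchanged",
                                     "ambiguous")))
  # pair labels always carry a partner
  paired <- calls$label %in% c("ptm_pair", "registration_artifact")
  expect_true(all(!is.na(calls$partner_id[paired])))
  expect_true(all(is.na(calls$partner_id[!paired])))

  # permuting input spot rows does not change any label
  tabs_perm <- lapply(tabs, function(tb) {
    set.seed(1); o <- sample(nrow(tb))
    out <- tb[o, , drop = FALSE]
    class(out) <- class(tb)
    attr(out, "temperature") <- attr(tb, "temperature")
    attr(out, "gel_id") <- attr(tb, "gel_id")
    out
  })
  an2 <- analyze_spot_tables(tabs_perm, 15 * 5)
  label_by_spot <- function(an) {
    ib <- an$tracks$temperature == 37
    sid <- stats::setNames(an$tracks$spot_id[ib], an$tracks$track_id[ib])
    out <- stats::setNames(an$calls$label, sid[an$calls$track_id])
    out[order(names(out))]
  }
  expect_identical(label_by_spot(an), label_by_spot(an2))

  # the destabilized target is called, substrates are ptm_pair not thermal
  truth <- attr(tabs[[1]], "truth")
  tgt_sid <- truth$spot_id[truth$species_id ==
                             pro$species_id[pro$is_target]]
  tgt_tid <- an$tracks$track_id[an$tracks$spot_id == tgt_sid &
                                  an$tracks$temperature == 37]
  expect_equal(calls$label[calls$track_id == tgt_tid], "destabilized")
  for (sid in truth$spot_id[truth$species_id %in%
                              pro$species_id[pro$is_ptm_substrate]]) {
    tid <- an$tracks$track_id[an$tracks$spot_id == sid &
                                an$tracks$temperature == 37]
    expect_equal(calls$label[calls$track_id == tid], "ptm_pair")
  }
})

test_that("no thermal call is emitted for unexplained baseline-colored tracks", {
  pro <- generate_proteome(30, n_targets = 1, n_ptm_substrates = 3,
                           seed = 46, target_delta_tm = 8, grid_px = 256)
  des <- quiet_design(noise_add = 5, noise_cv = 0.02)
  tabs <- simulate_spot_tables(pro, des)
  an <- analyze_spot_tables(tabs, 15 * 5)
  base <- tabs[[attr(an$tracks, "baseline_gel")]]
  fl <- 15 * 5 * (1 - exp(-0.5))
  col <- log2(pmax(base$core_cy5, fl) / pmax(base$core_cy3, fl))
  colored <- base$spot_id[abs(col) > default_thresholds()$tau]
  in_art <- c(an$artifact_pairs$red_id, an$artifact_pairs$green_id)
  vetoed <- setdiff(colored, in_art)
  for (sid in vetoed) {
    tid <- an$tracks$track_id[an$tracks$spot_id == sid &
                                an$tracks$temperature == 37]
    expect_false(an$calls$label[an$calls$track_id == tid] %in%
                   c("stabilized", "destabilized"))
  }
})

test_that("4PL dose-response fitting recovers parameters and flags degeneracy", {
  doses <- 10^seq(-1, 2.5, length.out = 8)
  mu <- simulate_dose_response(7.6, 1, 1, 0, doses, replicates = 1)$response
  fit <- fit_dose_response(doses, mu)
  expect_true(fit$converged)
  expect_equal(fit$ec50, 7.6, tolerance = 0.01)
  expect_equal(fit$hill, 1, tolerance = 0.02)
  expect_equal(fit$ec50_position, "interpolated")

  expect_false(fit_dose_response(doses, rep(0.5, 8))$converged)
  expect_error(fit_dose_response(c(1, 2, 3, 4), 1:4), "5 distinct")
  expect_error(fit_dose_response(c(-1, doses[-1]), mu), "doses")

  # downward curve (destabilization readout)
  mu_dn <- simulate_dose_response(5, 1.2, top = 0.1, bottom = 1, doses,
                                  replicates = 1)$response
  fit_dn <- fit_dose_response(doses, mu_dn, direction = "down")
  expect_true(fit_dn$converged)
  expect_equal(fit_dn$ec50, 5, tolerance = 0.01)
  expect_lt(fit_dn$top, fit_dn$bottom)

  # noisy replicated recovery stays within 20% in the median
  errs <- vapply(1:25, function(s) {
    d <- simulate_dose_response(7.6, 1, 1, 0, doses, replicates = 3,
                                noise_sd = 0.05, seed = s)
    abs(fit_dose_response(d$dose, d$response)$ec50 - 7.6) / 7.6
  }, 0)
  expect_lte(median(errs), 0.2)
})

test_that("a genuine stabilized target survives channel misregistration", {
  pro <- generate_proteome(60, n_targets = 1, seed = 41, target_delta_tm = 8,
                           grid_px = 320)
  dir <- tempfile("target_misreg")
  des <- experiment_design(image_shape = c(320, 320), seed = 13,
                           misregistration_dy = 2)
  simulate_run(pro, des, dir)
  run <- suppressWarnings(
    run_pipeline(file.path(dir, "manifest.tsv"), file.path(dir, "out")))
  truth <- attr(render_gel(pro, des, 1), "truth")
  i <- which(pro$is_target)
  base <- run$spot_tables[[attr(run$tracks, "baseline_gel")]]
  d <- sqrt((base$x - truth$x[i])^2 + (base$y - truth$y[i])^2)
  labels <- vapply(which(d < 3.5), function(s) {
    tid <- run$tracks$track_id[run$tracks$spot_id == base$spot_id[s] &
                                 run$tracks$temperature == 37]
    run$calls$label[run$calls$track_id == tid]
  }, "")
  # the misregistration splits the target into a doublet; at least one of
  # its spots is still called stabilized, and nothing inert is
  expect_true("stabilized" %in% labels)
  n_thermal <- sum(run$calls$label %in% c("stabilized", "destabilized"))
  expect_equal(n_thermal, sum(labels %in% c("stabilized", "destabilized")))
})
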