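toy_track <- function(id, frames, area = 1, yap = 0, partner = 0,
                      nucleus = "n1") {
  tibble::tibble(
    track_id = id, frame = frames, t_min = frames * 2,
    area = area, scaffold = 1000, yap = yap, partner = partner,
    nucleus_id = nucleus, experiment_id = "e1", arm = "experiment"
  )
}

test_that("filter rules reject the hand-counted tracks and keep the survivor", {
  tr <- dplyr::bind_rows(
    toy_track("late", 1:12), # starts at frame 1
    toy_track("big", 0:12, area = 2.0), # mean area out of range
    toy_track("short", 0:8), # 9 frames < 10
    toy_track("cyto", 0:12, nucleus = NA_character_), # not nuclear
    toy_track("ok", 0:12)
  )
  res <- filter_tracks(tr)
  expect_equal(unique(res$tracks$track_id), "ok")
  expect_equal(res$n_kept, 1L)
  led <- setNames(res$rejections$n_rejected, res$rejections$rule)
  expect_equal(led[["start_frame"]], 1)
  expect_equal(led[["min_frames"]], 1)
  expect_equal(led[["area_range"]], 1)
  expect_equal(led[["nuclear"]], 1)

  all_ok <- dplyr::bind_rows(toy_track("a", 0:12), toy_track("b", 0:20))
  res2 <- filter_tracks(all_ok)
  expect_equal(nrow(res2$tracks), nrow(all_ok))
  expect_true(all(res2$rejections$n_rejected == 0))
})

test_that("mono-exponential control fit recovers exact parameters and self-corrects to 0", {
  t <- seq(0, 120, by = 2)
  ctrl <- tibble::tibble(
    track_id = "c1", t_min = t,
    partner = 200 * exp(-t / 50) + 100
  )
  m <- fit_control_correction(ctrl)
  expect_equal(m$a, 200, tolerance = 1e-6)
  expect_equal(m$tau, 50, tolerance = 1e-6)
  expect_equal(m$c, 100, tolerance = 1e-6)
  corr <- correct_partner(ctrl, m)
  expect_lt(max(abs(corr$partner_corrected)), 1e-6)

  # linearity: a step on top of the control comes out as a clean step
  exp_tr <- dplyr::mutate(ctrl,
    track_id = "e1",
    partner = partner + 50 * (t_min >= 16)
  )
  corr2 <- correct_partner(exp_tr, m)
  expect_equal(
    corr2$partner_corrected,
    50 * (t >= 16),
    tolerance = 1e-6
  )

  # flat control degenerates to a constant subtraction
  flat <- dplyr::mutate(ctrl, partner = 300)
  mf <- fit_control_correction(flat)
  corrf <- correct_partner(flat, mf)
  expect_lt(max(abs(corrf$partner_corrected)), 1e-6)
})

test_that("pipeline is invariant to a constant intensity offset", {
  t <- seq(0, 120, by = 2)
  ctrl <- tibble::tibble(track_id = "c1", t_min = t, partner = 200 * exp(-t / 50) + 100)
  exp_tr <- tibble::tibble(track_id = "e1", t_min = t, partner = 200 * exp(-t / 50) + 100 + 30 * (t >= 10))
  base <- correct_partner(exp_tr, fit_control_correction(ctrl))$partner_corrected
  shifted <- correct_partner(
    dplyr::mutate(exp_tr, partner = partner + 500),
    fit_control_correction(dplyr::mutate(ctrl, partner = partner + 500))
  )$partner_corrected
  expect_equal(base, shifted, tolerance = 1e-6)
})

test_that("recruitment gating keeps and drops tracks at the documented thresholds", {
  t <- seq(0, 40, by = 2)
  mk <- function(id, level) {
    tibble::tibble(track_id = id, t_min = t, yap = level * (t >= 4))
  }
  tr <- dplyr::bind_rows(mk("halo", 300), mk("snap", 700))
  expect_equal(unique(gate_by_recruitment(tr, threshold = 250)$track_id), c("halo", "snap"))
  expect_equal(unique(gate_by_recruitment(tr, threshold = 750)$track_id), character(0))
  expect_equal(unique(gate_by_recruitment(tr, threshold = 0)$track_id), c("halo", "snap"))

  short <- mk("s", 100)[1:3, ] # ends at 4 min, gate at 16 min
  expect_error(gate_by_recruitment(short, threshold = 0), "not covered")
})

test_that("pooling: SEM of identical tracks is 0 and differences of equal curves vanish", {
  tr <- dplyr::bind_rows(toy_track("a", 0:10, partner = 5), toy_track("b", 0:10, partner = 5))
  pooled <- pool_and_average(tr, "partner")
  expect_true(all(pooled$sem == 0))
  expect_equal(pooled$mean, rep(0, 11)) # constant channel re-zeroed at t = 0

  d <- drb_difference(pooled, pooled)
  expect_true(all(d$difference == 0))
})

test_that("sustained and adaptive scenarios separate on the corrected final/max ratio", {
  ctrl <- sim_recruitment(n_tracks = 8, arm = "control", partner = "med1", seed = 11)
  med <- sim_recruitment(n_tracks = 8, partner = "med1", seed = 12)
  pol <- sim_recruitment(n_tracks = 8, partner = "pol2", seed = 13)

  model <- fit_control_correction(ctrl)
  ratio <- function(tracks) {
    corr <- correct_partner(tracks, model)
    pooled <- pool_and_average(corr, "partner_corrected")
    pooled$mean[nrow(pooled)] / max(pooled$mean)
  }
  expect_gte(ratio(med), 0.8)
  expect_lte(ratio(pol), 0.5)

  # corrected control is flat at ~0 relative to the sustained amplitude
  ctrl_corr <- pool_and_average(correct_partner(ctrl, model), "partner_corrected", rezero = FALSE)
  med_amp <- max(pool_and_average(correct_partner(med, model), "partner_corrected")$mean)
  expect_lt(abs(mean(ctrl_corr$mean)), 0.02 * med_amp)
})

test_that("transcription-inhibitor treatment lifts the difference curve only after addition", {
  dmso <- sim_recruitment(n_tracks = 16, partner = "pol2", seed = 21)
  drb <- sim_recruitment(n_tracks = 16, partner = "pol2", drb_time = 12, seed = 22)
  ctrl <- sim_recruitment(n_tracks = 16, arm = "control", partner = "pol2", seed = 23)
  model <- fit_control_correction(ctrl)
  pool <- function(tr) pool_and_average(correct_partner(tr, model), "partner_corrected")
  d <- drb_difference(pool(drb), pool(dmso))
  before <- d$difference[d$t_min <= 12]
  after <- d$difference[d$t_min >= 40]
  scale <- max(pool(dmso)$mean)
  expect_lt(max(abs(before)), 0.15 * scale)
  expect_true(all(after > 0))
  # blocking the negative feedback keeps lifting the curve
  expect_gt(mean(d$difference[d$t_min >= 80]), mean(d$difference[d$t_min >= 40 & d$t_min < 80]))
})
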