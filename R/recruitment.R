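#' Filter rules for synthetic-condensate tracks
#'
#' The four conjunctive quality rules applied before any quantification:
#' the track must start in the first frame (t = 0), last at least
#' `min_frames` frames (default 10, i.e. 18 min at 2-min sampling), have a
#' mean condensate area inside `area_range` (default \[0.45, 1.55\] a.u.),
#' and localize to a nucleus.
#'
#' @param must_start_at_frame0 Require the first frame to be 0.
#' @param min_frames Minimum number of frames per track.
#' @param area_range Inclusive `c(low, high)` bounds on per-track mean area.
#' @param require_nuclear Require a non-missing `nucleus_id`.
#' @return List of class `filter_rules`.
#' @export
filter_rules <- function(must_start_at_frame0 = TRUE, min_frames = 10L,
                         area_range = c(0.45, 1.55), require_nuclear = TRUE) {
  stopifnot(min_frames >= 1L, area_range[1] < area_range[2])
  structure(
    list(
      must_start_at_frame0 = must_start_at_frame0,
      min_frames = as.integer(min_frames),
      area_range = area_range,
      require_nuclear = require_nuclear
    ),
    class = "filter_rules"
  )
}

#' Apply track quality filters with a rejection ledger
#'
#' Applies the four [filter_rules()] conjunctively to a long-format
#' condensate track table and reports, per rule, how many tracks violated it
#' (a track failing several rules is counted under each).
#'
#' @param tracks Long-format tibble with at least `track_id`, `frame`; `area`
#'   and `nucleus_id` are needed by the corresponding rules.
#' @param rules A [filter_rules()] object.
#' @return List: `tracks` (kept rows), `rejections` (tibble `rule`,
#'   `n_rejected`), `n_in`, `n_kept`.
#' @export
filter_tracks <- function(tracks, rules = filter_rules()) {
  stopifnot(is.data.frame(tracks), all(c("track_id", "frame") %in% names(tracks)))
  per <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      first_frame = min(.data$frame),
      n_frames = dplyr::n(),
      mean_area = if ("area" %in% names(tracks)) mean(.data$area) else NA_real_,
      nuclear = if ("nucleus_id" %in% names(tracks)) !any(is.na(.data$nucleus_id)) else NA,
      .groups = "drop"
    )
  fail_start <- rules$must_start_at_frame0 & per$first_frame != 0L
  fail_len <- per$n_frames < rules$min_frames
  fail_area <- !is.na(per$mean_area) &
    (per$mean_area < rules$area_range[1] | per$mean_area > rules$area_range[2])
  fail_nuc <- rules$require_nuclear & !is.na(per$nuclear) & !per$nuclear
  keep_ids <- per$track_id[!(fail_start | fail_len | fail_area | fail_nuc)]
  list(
    tracks = dplyr::filter(tracks, .data$track_id %in% keep_ids),
    rejections = tibble(
      rule = c("start_frame", "min_frames", "area_range", "nuclear"),
      n_rejected = c(sum(fail_start), sum(fail_len), sum(fail_area), sum(fail_nuc))
    ),
    n_in = nrow(per),
    n_kept = length(keep_ids)
  )
}

#' Fit the mono-exponential control correction
#'
#' Pools the background-subtracted partner-channel intensity of
#' control-construct tracks (fluorophore-only cargo: any apparent partner
#' signal is non-specific recruitment plus photobleaching), averages per time
#' point, and fits `I(t) = a exp(-t / tau) + c`. Subtracting this curve from
#' experimental tracks removes both nuisance components; the control
#' corrected by its own fit is ~0 by construction.
#'
#' @param control_tracks Long-format tibble with `track_id`, `t_min` and the
#'   partner channel column.
#' @param channel Partner channel column name (default `"partner"`).
#' @param background Scalar (or per-row vector) background to subtract first.
#' @return Object of class `bleach_fit`: `a`, `tau`, `c`, `rss`, `n_points`.
#' @export
fit_control_correction <- function(control_tracks, channel = "partner",
                                   background = 0) {
  stopifnot(channel %in% names(control_tracks), "t_min" %in% names(control_tracks))
  pooled <- control_tracks |>
    dplyr::mutate(.value = .data[[channel]] - background) |>
    dplyr::group_by(.data$t_min) |>
    dplyr::summarise(value = mean(.data$.value), .groups = "drop") |>
    dplyr::arrange(.data$t_min)
  if (nrow(pooled) < 5L) abort("control correction needs >= 5 pooled time points")
  t <- pooled$t_min
  v <- pooled$value
  a0 <- v[1] - v[length(v)]
  c0 <- v[length(v)]
  tau0 <- max(t) / 2
  resid_fun <- function(th) th[1] * exp(-t / exp(th[2])) + th[3] - v
  fit <- minpack.lm::nls.lm(
    par = c(a0, log(tau0), c0), fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  if (fit$info == 0) abort("mono-exponential control fit did not converge")
  structure(
    list(
      a = fit$par[1], tau = exp(fit$par[2]), c = fit$par[3],
      rss = fit$deviance, n_points = length(t)
    ),
    class = "bleach_fit"
  )
}

#' @export
print.bleach_fit <- function(x, ...) {
  cat(sprintf(
    "Control correction: I(t) = %.4g exp(-t / %.4g) + %.4g (RSS %.4g, %d points)\n",
    x$a, x$tau, x$c, x$rss, x$n_points
  ))
  invisible(x)
}

#' @method tidy bleach_fit
#' @export
tidy.bleach_fit <- function(x, ...) {
  tibble(term = c("a", "tau", "c"), estimate = c(x$a, x$tau, x$c))
}

#' @method glance bleach_fit
#' @export
glance.bleach_fit <- function(x, ...) {
  tibble(rss = x$rss, n_points = x$n_points)
}

predict_bleach <- function(model, t) model$a * exp(-t / model$tau) + model$c

#' Correct partner-channel intensities with the control model
#'
#' Subtracts the background and then the fitted mono-exponential control
#' curve, pointwise on each track's own time grid, writing the result to
#' `<channel>_corrected`. The pipeline is linear: adding a constant to all
#' raw intensities and to `background` leaves the corrected series unchanged.
#'
#' @param tracks Long-format tibble with `t_min` and the channel column.
#' @param model A `bleach_fit` from [fit_control_correction()].
#' @param channel Channel column name (default `"partner"`).
#' @param background Scalar (or per-row) background, subtracted before the
#'   control curve.
#' @return `tracks` with an added `<channel>_corrected` column.
#' @export
correct_partner <- function(tracks, model, channel = "partner", background = 0) {
  stopifnot(inherits(model, "bleach_fit"), channel %in% names(tracks))
  tracks[[paste0(channel, "_corrected")]] <-
    tracks[[channel]] - background - predict_bleach(model, tracks$t_min)
  tracks
}

#' Gate tracks by cargo recruitment at a fixed time
#'
#' Keeps tracks whose baseline-subtracted cargo (YAP) intensity at
#' `gate_time` reaches `threshold`; below-threshold condensates show no
#' significant partner response and are excluded before pooling. The value
#' at the frame nearest to `gate_time` is used, within a tolerance of one
#' frame interval.
#'
#' @param tracks Long-format tibble with `track_id`, `t_min` and the gate
#'   channel.
#' @param channel Gate channel column (default `"yap"`).
#' @param threshold Minimum baseline-subtracted intensity (a.u.), e.g. 250
#'   for a Halo cargo or 750 for a SNAP cargo.
#' @param gate_time Gate time in minutes (default 16).
#' @param frame_interval_min Frame spacing in minutes (default 2), used for
#'   the nearest-frame tolerance.
#' @return The rows of `tracks` belonging to kept tracks.
#' @export
gate_by_recruitment <- function(tracks, channel = "yap", threshold,
                                gate_time = 16, frame_interval_min = 2) {
  stopifnot(channel %in% names(tracks), "t_min" %in% names(tracks))
  per <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_map(function(g, key) {
      dt <- abs(g$t_min - gate_time)
      if (min(dt) > frame_interval_min) {
        abort(sprintf(
          "gate time %g min not covered by track %s (nearest frame %g min away)",
          gate_time, key$track_id, min(dt)
        ))
      }
      at_gate <- g[[channel]][which.min(dt)]
      at_zero <- g[[channel]][which.min(abs(g$t_min))]
      tibble(track_id = key$track_id, gated_value = at_gate - at_zero)
    }) |>
    dplyr::bind_rows()
  keep <- per$track_id[per$gated_value >= threshold]
  dplyr::filter(tracks, .data$track_id %in% keep)
}

#' Pool tracks into a mean +/- SEM time course
#'
#' Intersects the time grids of all tracks, averages the chosen channel per
#' time point across tracks, and finally re-zeroes the mean curve at t = 0
#' (the pooled mean at the first time point is subtracted from every time
#' point).
#'
#' @param tracks Long-format tibble with `track_id`, `t_min` and the channel.
#' @param channel Channel column to pool.
#' @param rezero Subtract the pooled mean at t = 0 (default TRUE).
#' @return Tibble of class `recruitment_series`: `t_min`, `mean`, `sem`, `n`.
#' @export
pool_and_average <- function(tracks, channel, rezero = TRUE) {
  stopifnot(channel %in% names(tracks))
  if (nrow(tracks) == 0L) abort("no tracks to pool")
  grids <- split(tracks$t_min, tracks$track_id)
  common <- Reduce(intersect, grids)
  if (length(common) == 0L) abort("tracks share no common time points")
  out <- tracks |>
    dplyr::filter(.data$t_min %in% common) |>
    dplyr::group_by(.data$t_min) |>
    dplyr::summarise(
      mean = mean(.data[[channel]]),
      sem = sd(.data[[channel]]) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$t_min)
  if (rezero) out$mean <- out$mean - out$mean[1]
  class(out) <- c("recruitment_series", class(out))
  out
}

#' Difference between two pooled recruitment curves
#'
#' Joins two mean time courses (e.g. transcription-inhibitor-treated vs
#' vehicle control) on their shared time grid and returns
#' `treated - control`, with SEMs combined in quadrature.
#'
#' @param treated,control `recruitment_series` tibbles from
#'   [pool_and_average()].
#' @return Tibble: `t_min`, `difference`, `sem`.
#' @export
drb_difference <- function(treated, control) {
  j <- dplyr::inner_join(treated, control, by = "t_min", suffix = c("_t", "_c"))
  if (nrow(j) == 0L) abort("curves share no common time points")
  tibble(
    t_min = j$t_min,
    difference = j$mean_t - j$mean_c,
    sem = sqrt(j$sem_t^2 + j$sem_c^2)
  )
}
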