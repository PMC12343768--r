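#' Read a single-molecule track table from a tracker CSV export
#'
#' Ingests the common tracker-export dialect (columns `TRACK_ID`, `FRAME`,
#' `POSITION_X`, `POSITION_Y`, `MEAN_INTENSITY`, frames 0-based) into a tidy
#' track table. Tracks whose frame gaps exceed `max_frame_gap` are split into
#' separate tracks at the offending gap, so downstream dwell extraction can
#' assume gap-closed tracks (a molecule blinking for at most `max_frame_gap`
#' frames is presumed continuously bound).
#'
#' @param path CSV path.
#' @param max_frame_gap Largest tolerated within-track frame gap (default 2,
#'   matching the usual gap-closing setting).
#'
#' @return Tibble with columns `track_id`, `frame`, `x`, `y`, `intensity`,
#'   `nucleus_id` (if present in the file).
#' @export
read_track_csv <- function(path, max_frame_gap = 2L) {
  df <- utils::read.csv(path, check.names = FALSE)
  # tolerate both upper-case tracker headers and tidy lower-case ones
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(df)) return(df[[nm]])
    NULL
  }
  tracks <- tibble(
    track_id = pick("TRACK_ID", "track_id"),
    frame = as.integer(pick("FRAME", "frame")),
    x = pick("POSITION_X", "x") %||% NA_real_,
    y = pick("POSITION_Y", "y") %||% NA_real_,
    intensity = pick("MEAN_INTENSITY", "intensity") %||% NA_real_,
    nucleus_id = pick("nucleus_id") %||% NA_character_
  )
  if (is.null(tracks$track_id) || anyNA(tracks$frame)) {
    abort("track CSV must contain TRACK_ID and FRAME columns")
  }
  split_tracks_at_gaps(tracks, max_frame_gap)
}

split_tracks_at_gaps <- function(tracks, max_frame_gap) {
  tracks |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(
      segment = cumsum(c(0L, diff(.data$frame) > max_frame_gap + 1L))
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      track_id = ifelse(
        .data$segment > 0L,
        paste0(.data$track_id, ".", .data$segment),
        as.character(.data$track_id)
      )
    ) |>
    dplyr::select(-"segment")
}

#' Extract dwell times from a track table
#'
#' Each track's dwell time is `(last_frame - first_frame + 1) *
#' frame_interval`; frames missed during short blinks count toward the dwell
#' (the molecule is presumed bound across a gap-closed blink). Tracks with
#' fewer than `min_frames` detections are dropped — with the default 2, bare
#' unlinked detections are excluded.
#'
#' @param tracks Track table (see [read_track_csv()]) with `track_id` and
#'   `frame` columns.
#' @param frame_interval Seconds per frame (default 0.15).
#' @param min_frames Minimum detections per track (default 2).
#' @param experiment_id Optional label carried on the result.
#'
#' @return Tibble of class `dwell_sample` with columns `track_id`, `n_frames`
#'   (detections), `dwell` (seconds) and attribute `frame_interval`.
#' @examples
#' tr <- tibble::tibble(track_id = 1, frame = 3:13)
#' extract_dwells(tr)$dwell # 1.65 s
#' @export
extract_dwells <- function(tracks, frame_interval = 0.15, min_frames = 2L,
                           experiment_id = NA_character_) {
  stopifnot(is.data.frame(tracks), all(c("track_id", "frame") %in% names(tracks)))
  dup <- duplicated(tracks[c("track_id", "frame")])
  if (any(dup)) {
    abort(sprintf(
      "duplicate (track_id, frame) row: track %s frame %d",
      tracks$track_id[dup][1], tracks$frame[dup][1]
    ))
  }
  out <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      n_frames = dplyr::n(),
      dwell = (max(.data$frame) - min(.data$frame) + 1) * frame_interval,
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_frames >= min_frames) |>
    dplyr::mutate(experiment_id = experiment_id)
  attr(out, "frame_interval") <- frame_interval
  class(out) <- c("dwell_sample", class(out))
  out
}

#' Empirical survival curve (1 - CDF) of dwell times
#'
#' Returns the right-continuous complement of the empirical CDF evaluated at
#' the sorted unique dwell times, with the point `(0, 1)` prepended:
#' `S(t) = fraction of dwells > t`. By this convention S at the smallest
#' observed dwell is already below 1 (by at least 1/n) and S at the largest
#' dwell is 0.
#'
#' @param dwells A `dwell_sample`, or a numeric vector of dwell times in
#'   seconds.
#' @return Tibble with columns `time` and `survival`, plus attribute `n`.
#' @export
survival_curve <- function(dwells) {
  d <- dwell_values(dwells)
  if (length(d) == 0L) abort("empty dwell sample")
  n <- length(d)
  r <- rle(sort(d))
  t_sorted <- r$values
  surv <- (n - cumsum(r$lengths)) / n
  out <- tibble(time = c(0, t_sorted), survival = c(1, surv))
  attr(out, "n") <- n
  class(out) <- c("survival_curve", class(out))
  out
}

dwell_values <- function(dwells) {
  if (is.data.frame(dwells)) {
    stopifnot("dwell" %in% names(dwells))
    as.numeric(dwells$dwell)
  } else {
    as.numeric(dwells)
  }
}

#' Fit a bi-exponential decay to a survival curve
#'
#' Fits `S(t) = A exp(-t / tau_ns) + (1 - A) exp(-t / tau_s)` to an empirical
#' survival curve, separating a short-lived (non-specific) and a long-lived
#' (specific) binding population. The least-squares objective is computed on
#' `log10 S` by default, which weights the rare long-dwell tail sensibly;
#' `on_log = FALSE` fits raw S. Constraints `0 < A < 1` and
#' `0 < tau_ns < tau_s` are enforced by an internal reparameterization
#' (logit A, log tau_ns, log of the tau ratio), so a label swap cannot occur.
#' Initial values: `tau_ns` = median dwell, `tau_s` = 90th percentile dwell,
#' `A` = 0.7.
#'
#' When the data are effectively single-exponential the two time constants
#' collapse; the fit is then returned with `degenerate = TRUE` (tau ratio
#' below 1.5).
#'
#' @param curve A `survival_curve` (or tibble with `time`, `survival`), or a
#'   `dwell_sample`/numeric vector, in which case the curve is computed
#'   first.
#' @param on_log Fit on log10 survival (default TRUE).
#'
#' @return Object of class `biexp_fit`: list with `A`, `tau_ns`, `tau_s`,
#'   `rss`, `n_points`, `n`, `degenerate`, `on_log`, `curve`.
#' @export
fit_biexponential <- function(curve, on_log = TRUE) {
  if (!is.data.frame(curve) || !"survival" %in% names(curve)) {
    curve <- survival_curve(curve)
  }
  keep <- curve$survival > 0 & is.finite(curve$time)
  t <- curve$time[keep]
  s <- curve$survival[keep]
  if (length(unique(t)) < 6L) abort("need at least 6 distinct time points to fit")
  tpos <- t[t > 0]
  tau_ns0 <- median(tpos)
  tau_s0 <- as.numeric(quantile(tpos, 0.9))
  if (tau_s0 <= tau_ns0) tau_s0 <- tau_ns0 * 3
  th0 <- c(qlogis(0.7), log(tau_ns0), log(tau_s0 / tau_ns0 - 1 + 1e-6))
  model <- function(th, t) {
    a <- plogis(th[1])
    tns <- exp(th[2])
    ts <- tns * (1 + exp(th[3]))
    a * exp(-t / tns) + (1 - a) * exp(-t / ts)
  }
  resid_fun <- function(th) {
    m <- model(th, t)
    if (on_log) {
      log10(pmax(m, 1e-12)) - log10(s)
    } else {
      m - s
    }
  }
  fit <- minpack.lm::nls.lm(
    par = th0, fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  if (fit$info == 0) {
    abort(sprintf(
      "bi-exponential fit did not converge (start A=0.70, tau_ns=%.3g, tau_s=%.3g; final RSS %.4g)",
      tau_ns0, tau_s0, fit$deviance
    ))
  }
  th <- fit$par
  a <- plogis(th[1])
  tau_ns <- exp(th[2])
  tau_s <- tau_ns * (1 + exp(th[3]))
  structure(
    list(
      A = a,
      tau_ns = tau_ns,
      tau_s = tau_s,
      rss = fit$deviance,
      n_points = length(t),
      n = attr(curve, "n") %||% NA_integer_,
      degenerate = (tau_s / tau_ns) < 1.5,
      on_log = on_log,
      curve = tibble(time = t, survival = s)
    ),
    class = "biexp_fit"
  )
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf(
    "Bi-exponential survival fit: A = %.3f, tau_ns = %.3f s, tau_s = %.3f s%s\n",
    x$A, x$tau_ns, x$tau_s,
    if (x$degenerate) " (degenerate: effectively single-exponential)" else ""
  ))
  cat(sprintf("  RSS %.4g on %d curve points\n", x$rss, x$n_points))
  invisible(x)
}

#' @method tidy biexp_fit
#' @export
tidy.biexp_fit <- function(x, ...) {
  tibble(
    term = c("A", "tau_ns", "tau_s"),
    estimate = c(x$A, x$tau_ns, x$tau_s)
  )
}

#' @method glance biexp_fit
#' @export
glance.biexp_fit <- function(x, ...) {
  tibble(
    rss = x$rss, n_points = x$n_points, n = x$n,
    degenerate = x$degenerate, on_log = x$on_log
  )
}

#' Dwell-time population fractions
#'
#' Splits dwell times into the population bins used to compare binding
#' classes: the fraction below the first edge (non-specific) plus the
#' overlapping upper tails at each edge (specific populations). With the
#' default edges `c(1.2, 7, 10)` seconds the bins are `< 1.2`, `>= 1.2`,
#' `>= 7`, `>= 10`; the first two partition the sample, the rest are nested
#' tails.
#'
#' @param dwells A `dwell_sample` or numeric vector.
#' @param edges Increasing bin edges in seconds.
#' @return Tibble with columns `bin` and `fraction`.
#' @export
dwell_bin_fractions <- function(dwells, edges = c(1.2, 7, 10)) {
  d <- dwell_values(dwells)
  if (length(d) == 0L) abort("empty dwell sample")
  stopifnot(all(diff(edges) > 0))
  tibble(
    bin = c(sprintf("<%g", edges[1]), sprintf(">=%g", edges)),
    fraction = c(mean(d < edges[1]), vapply(edges, function(e) mean(d >= e), numeric(1)))
  )
}

#' Per-bin fold change between two experimental arms
#'
#' Given per-experiment bin fractions for a condition and a control arm,
#' computes the per-bin fold change (mean condition fraction over mean
#' control fraction) and a two-sided equal-variance Student's t-test of the
#' fractions across experiments (Welch available via `var_equal = FALSE`).
#'
#' @param condition,control Tibbles with columns `experiment_id`, `bin`,
#'   `fraction` (one row per experiment and bin), e.g. built by binding rows
#'   of [dwell_bin_fractions()] per experiment.
#' @param var_equal Equal-variance t-test (default TRUE).
#' @return Tibble: `bin`, `fold_change`, `p_value`, `n_condition`,
#'   `n_control`, `undefined` (TRUE when the control mean is 0).
#' @export
fold_change_stats <- function(condition, control, var_equal = TRUE) {
  need <- c("experiment_id", "bin", "fraction")
  stopifnot(all(need %in% names(condition)), all(need %in% names(control)))
  bins <- unique(control$bin)
  purrr::map(bins, function(b) {
    xc <- condition$fraction[condition$bin == b]
    x0 <- control$fraction[control$bin == b]
    if (length(xc) < 2L || length(x0) < 2L) {
      abort("need >= 2 experiments per arm for fold-change statistics")
    }
    undefined <- mean(x0) == 0
    p <- tryCatch(
      t.test(xc, x0, var.equal = var_equal)$p.value,
      error = function(e) NA_real_
    )
    tibble(
      bin = b,
      fold_change = if (undefined) NA_real_ else mean(xc) / mean(x0),
      p_value = p,
      n_condition = length(xc),
      n_control = length(x0),
      undefined = undefined
    )
  }) |>
    dplyr::bind_rows()
}

#' Endogenous-expression gate from wild-type nuclear intensities
#'
#' Defines the physiological expression window as the 1st and 99th
#' percentiles of wild-type nuclear intensity, and a fixation correction
#' factor `corr_fix = mean(live) / mean(fixed)` that maps fixed-stain
#' intensities onto the live-imaging scale before gating.
#'
#' @param wt_intensities Nuclear intensities of the wild-type population
#'   (>= 100 recommended; fewer triggers a warning).
#' @param live_means,fixed_means Mean intensities of the same cells imaged
#'   live and after fixation, used for `corr_fix`. Defaults give
#'   `corr_fix = 1` (no fixation correction).
#' @param probs Percentile pair (default `c(0.01, 0.99)`).
#' @return List of class `expression_gate`: `lower`, `upper`, `corr_fix`.
#' @export
expression_gate <- function(wt_intensities, live_means = 1, fixed_means = 1,
                            probs = c(0.01, 0.99)) {
  if (length(wt_intensities) == 0L) abort("empty wild-type intensity sample")
  if (length(wt_intensities) < 100L) {
    warn(sprintf(
      "only %d wild-type nuclei; percentile gate may be unstable (>= 100 recommended)",
      length(wt_intensities)
    ))
  }
  corr_fix <- mean(live_means) / mean(fixed_means)
  if (!is.finite(corr_fix) || corr_fix <= 0) abort("corr_fix must be positive")
  bounds <- quantile(wt_intensities, probs, names = FALSE)
  if (bounds[1] >= bounds[2]) abort("degenerate gate: lower bound >= upper bound")
  structure(
    list(lower = bounds[1], upper = bounds[2], corr_fix = corr_fix),
    class = "expression_gate"
  )
}

#' @rdname expression_gate
#' @param nuclei Tibble with columns `nucleus_id` and `intensity`.
#' @param gate An `expression_gate`.
#' @param fixed Are the nucleus intensities from fixed stains (then they are
#'   multiplied by `corr_fix` before gating)? Default TRUE.
#' @return `apply_gate()`: the rows of `nuclei` whose (corrected) intensity
#'   lies strictly inside the gate.
#' @export
apply_gate <- function(nuclei, gate, fixed = TRUE) {
  stopifnot(inherits(gate, "expression_gate"), "intensity" %in% names(nuclei))
  val <- nuclei$intensity * if (fixed) gate$corr_fix else 1
  nuclei[val > gate$lower & val < gate$upper, , drop = FALSE]
}

#' @export
print.expression_gate <- function(x, ...) {
  cat(sprintf(
    "Expression gate: (%.4g, %.4g), corr_fix = %.4g\n",
    x$lower, x$upper, x$corr_fix
  ))
  invisible(x)
}
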