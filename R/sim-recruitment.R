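#' Simulate condensate recruitment time courses
#'
#' Phenomenological ODE twin of cargo-driven co-condensation with
#' transcriptional feedback. On a 2-min acquisition grid, each nucleus
#' integrates
#' \deqn{Y' = k_{on,yap} 1\{t \ge t_{rap}\} + k_{fb} M - d_y Y}
#' \deqn{M' = k_{med,on} Y - k_{med,off} M}
#' \deqn{P' = k_{pol,on} M - k_{neg} R P}
#' \deqn{R' = k_{rna} P - k_{rna,decay} R}
#' where Y is condensate-recruited cargo (YAP), M a Mediator-like partner
#' (sustained response: positive feedback through `k_fb`), P a
#' polymerase-like partner under delayed transcription-derived negative
#' feedback (adaptive response: rises, peaks, returns toward baseline), and
#' R the accumulated transcript. Setting `k_neg = 0` makes P sustained;
#' `drb_time` zeroes `k_rna` from that time on (transcription-inhibitor
#' treatment), breaking the negative feedback. Control-arm tracks have
#' `k_med_on = k_pol_on = 0`, so their partner channel carries only the
#' non-specific baseline.
#'
#' Observed channel intensities are `(truth * track_scale + baseline +
#' noise) * exp(-t / bleach_tau)` — multiplicative photobleaching on top of
#' additive detection noise, with a per-track lognormal amplitude scale.
#' The rates are not measured quantities; they are defaults chosen so that
#' the Mediator-like channel plateaus within the 2-h movie and the
#' polymerase-like channel peaks near 30 min and adapts.
#'
#' @param n_tracks Number of condensate tracks (default 20).
#' @param t_end Movie length in minutes (default 120).
#' @param dt_min Frame interval in minutes (default 2).
#' @param rapamycin_time Cargo-recruitment trigger time in minutes
#'   (default 2).
#' @param partner Which state is the partner channel: `"med1"` (M) or
#'   `"pol2"` (P).
#' @param arm `"experiment"` or `"control"` (fluorophore-only cargo).
#' @param k_on_yap,d_y,k_fb,k_med_on,k_med_off,k_pol_on,k_neg,k_rna,k_rna_decay
#'   ODE rates per minute (see Description).
#' @param drb_time Optional time (minutes) at which `k_rna` is set to 0.
#' @param bleach_tau Photobleaching time constant in minutes (default 600;
#'   `Inf` = no bleaching).
#' @param noise_sd Additive Gaussian noise SD in a.u. (default 5).
#' @param track_scale_sd SD of the per-track lognormal amplitude scale
#'   (default 0.1).
#' @param partner_baseline Non-specific partner intensity in a.u.
#'   (default 100).
#' @param seed Integer seed.
#' @param experiment_id Label stamped on all rows.
#'
#' @return Long-format tibble with columns `track_id`, `frame`, `t_min`,
#'   `area`, `scaffold`, `yap`, `partner`, `nucleus_id`, `experiment_id`,
#'   `arm`, plus attribute `truth`: tibble `t_min`, `Y`, `M`, `P`, `R`
#'   (noise-free, bleach-free state trajectories).
#' @export
sim_recruitment <- function(n_tracks = 20L, t_end = 120, dt_min = 2,
                            rapamycin_time = 2,
                            partner = c("med1", "pol2"),
                            arm = c("experiment", "control"),
                            k_on_yap = 30, d_y = 0.05, k_fb = 0.01,
                            k_med_on = 0.05, k_med_off = 0.05,
                            k_pol_on = 0.02, k_neg = 0.01,
                            k_rna = 0.05, k_rna_decay = 0.001,
                            drb_time = NULL, bleach_tau = 600,
                            noise_sd = 5, track_scale_sd = 0.1,
                            partner_baseline = 100,
                            seed = 1L, experiment_id = "sim") {
  partner <- match.arg(partner)
  arm <- match.arg(arm)
  rates <- c(k_on_yap, d_y, k_fb, k_med_on, k_med_off, k_pol_on, k_neg, k_rna, k_rna_decay)
  if (any(rates < 0)) abort("all rates must be >= 0")
  tt <- seq(0, t_end, by = dt_min)
  if (!is.null(drb_time) && (drb_time < 0 || drb_time > t_end)) {
    abort("drb_time must lie within the acquisition window")
  }
  if (arm == "control") {
    k_med_on <- 0
    k_pol_on <- 0
  }
  deriv <- function(t, state, parms) {
    rap <- as.numeric(t >= rapamycin_time)
    kr <- if (!is.null(drb_time) && t >= drb_time) 0 else k_rna
    with(as.list(state), {
      list(c(
        k_on_yap * rap + k_fb * M - d_y * Y,
        k_med_on * Y - k_med_off * M,
        k_pol_on * M - k_neg * R * P,
        kr * P - k_rna_decay * R
      ))
    })
  }
  sol <- deSolve::ode(c(Y = 0, M = 0, P = 0, R = 0), tt, deriv, NULL)
  truth <- tibble(
    t_min = sol[, "time"], Y = sol[, "Y"], M = sol[, "M"],
    P = sol[, "P"], R = sol[, "R"]
  )
  p_true <- if (partner == "med1") truth$M else truth$P
  bleach <- exp(-tt / bleach_tau)
  out <- with_seed(seed, {
    purrr::map(seq_len(n_tracks), function(i) {
      scale_i <- exp(rnorm(1, 0, track_scale_sd))
      nf <- length(tt)
      tibble(
        track_id = sprintf("%s_%s_%03d", experiment_id, arm, i),
        frame = seq_along(tt) - 1L,
        t_min = tt,
        area = runif(1, 0.8, 1.2),
        scaffold = (1000 + rnorm(nf, 0, noise_sd)) * bleach,
        yap = (truth$Y * scale_i + rnorm(nf, 0, noise_sd)) * bleach,
        partner = (p_true * scale_i + partner_baseline + rnorm(nf, 0, noise_sd)) * bleach,
        nucleus_id = sprintf("nuc_%03d", i),
        experiment_id = experiment_id,
        arm = arm
      )
    }) |>
      dplyr::bind_rows()
  })
  attr(out, "truth") <- truth
  out
}
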