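#' Simulate dwell times from a two-exponential binding mixture
#'
#' Draws dwell times from the mixture `A * Exp(tau_fast) + (1 - A) *
#' Exp(tau_slow)` — fast non-specific and slow specific chromatin binding —
#' then discretizes each dwell up to the next whole frame (a molecule present
#' for any part of a frame is detected, biasing the mean by about
#' `+frame_interval / 2`) and censors at the movie length `t_max`.
#'
#' @param n Number of dwells.
#' @param A Fast-component fraction in (0, 1) (default 0.7).
#' @param tau_fast,tau_slow Mean dwell of each component in seconds
#'   (defaults 1.2 and 7, the canonical non-specific and specific residence
#'   times).
#' @param frame_interval Seconds per frame (default 0.15).
#' @param t_max Censoring time in seconds (default 80, the longest dwell a
#'   movie can contain).
#' @param seed Integer seed; the generator is reproducible given the seed.
#' @param experiment_id Label carried on the sample.
#'
#' @return A `dwell_sample` tibble (`track_id`, `n_frames`, `dwell`,
#'   `experiment_id`) with attributes `frame_interval` and `truth`
#'   (list of the generating parameters).
#' @export
sim_dwells <- function(n, A = 0.7, tau_fast = 1.2, tau_slow = 7,
                       frame_interval = 0.15, t_max = 80, seed = 1L,
                       experiment_id = NA_character_) {
  if (A <= 0 || A >= 1) abort("A must be in (0, 1)")
  if (!(tau_fast > 0 && tau_slow > tau_fast)) abort("need 0 < tau_fast < tau_slow")
  if (t_max <= tau_slow) abort("t_max must exceed tau_slow")
  n <- as.integer(n)
  raw <- with_seed(seed, {
    fast <- runif(n) < A
    ifelse(fast, rexp(n, 1 / tau_fast), rexp(n, 1 / tau_slow))
  })
  dwell <- pmin(ceiling(raw / frame_interval) * frame_interval, t_max)
  out <- tibble(
    track_id = if (n > 0L) sprintf("sim_%06d", seq_len(n)) else character(),
    n_frames = as.integer(round(dwell / frame_interval)),
    dwell = dwell,
    experiment_id = experiment_id
  )
  attr(out, "frame_interval") <- frame_interval
  attr(out, "truth") <- list(
    A = A, tau_fast = tau_fast, tau_slow = tau_slow,
    frame_interval = frame_interval, t_max = t_max, seed = seed
  )
  class(out) <- c("dwell_sample", class(out))
  out
}

#' Simulate a tracker-style detection table
#'
#' Converts simulated dwells into per-frame detections: each bound molecule
#' becomes a run of consecutive frames at a fixed (jittered) position, with
#' optional 1-2-frame blinks (detections missed while the molecule stays
#' bound; never longer than the usual gap-closing limit) and optional
#' single-frame spurious detections.
#'
#' @inheritParams sim_dwells
#' @param blink_rate Per-interior-frame probability of starting a 1-2-frame
#'   blink (default 0).
#' @param n_noise_tracks Number of single-frame noise detections (default 0).
#' @param fov_px Field of view in pixels for random positions (default 256).
#'
#' @return Tibble with columns `track_id`, `frame`, `x`, `y`, `intensity`,
#'   `nucleus_id`, plus attribute `truth` (tibble `track_id`, `true_dwell`).
#' @export
sim_track_table <- function(n, A = 0.7, tau_fast = 1.2, tau_slow = 7,
                            frame_interval = 0.15, t_max = 80, seed = 1L,
                            blink_rate = 0, n_noise_tracks = 0L, fov_px = 256) {
  dwells <- sim_dwells(n, A, tau_fast, tau_slow, frame_interval, t_max, seed)
  rows <- with_seed(seed + 1L, {
    recs <- purrr::map(seq_len(nrow(dwells)), function(i) {
      k <- dwells$n_frames[i]
      start <- sample.int(500L, 1L)
      frames <- start:(start + k - 1L)
      if (blink_rate > 0 && k > 2L) {
        drop <- logical(k)
        j <- 2L
        while (j <= k - 1L) {
          if (runif(1) < blink_rate) {
            len <- sample(1:2, 1L)
            stop_at <- min(j + len - 1L, k - 1L)
            drop[j:stop_at] <- TRUE
            j <- stop_at + 2L # keep a detected frame between blinks
          } else {
            j <- j + 1L
          }
        }
        frames <- frames[!drop]
      }
      tibble(
        track_id = dwells$track_id[i],
        frame = frames,
        x = runif(1, 1, fov_px) + rnorm(length(frames), 0, 0.2),
        y = runif(1, 1, fov_px) + rnorm(length(frames), 0, 0.2),
        intensity = rnorm(length(frames), 1000, 50),
        nucleus_id = "n1"
      )
    })
    if (n_noise_tracks > 0L) {
      recs <- c(recs, list(tibble(
        track_id = sprintf("noise_%04d", seq_len(n_noise_tracks)),
        frame = sample.int(500L, n_noise_tracks, replace = TRUE),
        x = runif(n_noise_tracks, 1, fov_px),
        y = runif(n_noise_tracks, 1, fov_px),
        intensity = rnorm(n_noise_tracks, 400, 50),
        nucleus_id = "n1"
      )))
    }
    dplyr::bind_rows(recs)
  })
  attr(rows, "truth") <- tibble(track_id = dwells$track_id, true_dwell = dwells$dwell)
  rows
}

#' Simulate an IDR sequence with controlled composition and patterning
#'
#' Generates a random sequence at the given composition; optionally runs
#' seeded Monte-Carlo position swaps until the neg-vs-pos patterning delta is
#' within `tol` of `target_delta` (or `max_iter` swaps), allowing blocky and
#' well-mixed arrangements of identical composition to be produced at will.
#' If the target is unreachable the best-effort arrangement is returned with
#' `target_reached = FALSE`.
#'
#' @param length Sequence length (>= 12).
#' @param composition Named numeric fractions. Names may be residue-group
#'   names (residues drawn uniformly within the group) or one-letter residue
#'   codes; fractions must sum to <= 1, any remainder is filled with G.
#' @param target_delta Optional target for `patterning_delta(seq, "neg",
#'   "pos")`.
#' @param tol Absolute tolerance on the target (default 0.002).
#' @param max_iter Swap budget (default 20000).
#' @param groups Residue groups.
#' @param seed Integer seed.
#'
#' @return List: `sequence`, `delta` (achieved, NA when the sequence has no
#'   charged residues), `target_reached`.
#' @export
sim_idr <- function(length, composition = c(neg = 0.2, pos = 0.2, pol = 0.3),
                    target_delta = NULL, tol = 0.002, max_iter = 20000L,
                    groups = residue_groups(), seed = 1L) {
  length <- as.integer(length)
  if (length < 12L) abort("length must be >= 12")
  if (sum(composition) > 1 + 1e-9) abort("composition fractions must sum to <= 1")
  counts <- round(composition * length)
  with_seed(seed, {
    pool <- unlist(purrr::imap(counts, function(k, nm) {
      res <- if (nm %in% names(groups)) groups[[nm]] else toupper(nm)
      if (!all(res %in% AA20)) abort(sprintf("unknown composition component '%s'", nm))
      sample(res, k, replace = TRUE)
    }), use.names = FALSE)
    if (length(pool) > length) pool <- pool[seq_len(length)]
    pool <- c(pool, rep("G", length - base::length(pool)))
    ch <- sample(pool)
    delta_of <- function(ch) {
      tryCatch(
        patterning_delta(paste(ch, collapse = ""), "neg", "pos", groups),
        error = function(e) NA_real_
      )
    }
    d <- delta_of(ch)
    reached <- TRUE
    if (!is.null(target_delta)) {
      if (is.na(d)) abort("patterning target is undefined: composition has no charged residues")
      it <- 0L
      while (abs(d - target_delta) > tol && it < max_iter) {
        ij <- sample.int(length, 2L)
        cand <- ch
        cand[ij] <- cand[rev(ij)]
        d2 <- delta_of(cand)
        if (abs(d2 - target_delta) < abs(d - target_delta)) {
          ch <- cand
          d <- d2
        }
        it <- it + 1L
      }
      reached <- abs(d - target_delta) <= tol
    }
    list(
      sequence = paste(ch, collapse = ""),
      delta = d,
      target_reached = reached
    )
  })
}

#' Simulate an IDRome background set
#'
#' Generates `n` independent random IDR sequences for use as a composition
#' background ([build_background()]). The default composition sampler draws
#' per-sequence residue-group fractions around values typical of
#' disorder-promoting sequences (polar- and proline-rich, moderately
#' charged).
#'
#' @param n Number of background IDRs.
#' @param length_range Integer range of sequence lengths (default 40-200).
#' @param sampler Function `(i) -> named composition vector` understood by
#'   [sim_idr()]; NULL uses the default sampler.
#' @param seed Integer seed.
#' @return Tibble with `idr_id` and `sequence`.
#' @export
sim_idrome <- function(n, length_range = c(40L, 200L), sampler = NULL, seed = 1L) {
  if (is.null(sampler)) {
    sampler <- function(i) {
      base <- c(neg = 0.12, pos = 0.10, pol = 0.30, pro = 0.08, hyd = 0.15, aro = 0.04)
      f <- pmax(base + rnorm(length(base), 0, 0.02), 0)
      f / max(1, sum(f) / 0.95) # keep a G remainder
    }
  }
  with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
    seqs <- vapply(seq_len(n), function(i) {
      sim_idr(lens[i], sampler(i), seed = sample.int(1e6, 1L))$sequence
    }, character(1))
    tibble(idr_id = sprintf("bg_%04d", seq_len(n)), sequence = seqs)
  })
}

#' Simulate a nuclear image with Gaussian clusters of known molecule number
#'
#' Builds a flat-background nucleus containing 2D Gaussian spots whose full
#' integrated mass is `molecules * unitary` counts, plus i.i.d. Gaussian
#' noise — a minimal stand-in for a fluorescence image of labelled clusters
#' with a known single-molecule intensity.
#'
#' @param dims Image `c(height, width)` in pixels (default 128 x 128).
#' @param background Flat background level (default 100).
#' @param clusters Tibble/data frame with columns `x`, `y`, `molecules`.
#' @param unitary Integrated intensity of one molecule (default 100).
#' @param psf_sigma Gaussian sigma of the point-spread function in pixels
#'   (default 1.5).
#' @param noise_sd SD of additive Gaussian noise (default 0).
#' @param nucleus_mask Logical matrix, TRUE = nuclear; NULL = whole image.
#' @param seed Integer seed.
#'
#' @return List: `image` (matrix `[y, x]`), `mask`, `truth` (the cluster
#'   table with the generating `amplitude` added), `unitary`, `psf_sigma`.
#'   Spots closer than 3 sigma trigger an overlap warning.
#' @export
sim_cluster_scene <- function(dims = c(128L, 128L), background = 100,
                              clusters = tibble(x = numeric(), y = numeric(), molecules = numeric()),
                              unitary = 100, psf_sigma = 1.5, noise_sd = 0,
                              nucleus_mask = NULL, seed = 1L) {
  h <- dims[1]
  w <- dims[2]
  if (is.null(nucleus_mask)) nucleus_mask <- matrix(TRUE, h, w)
  stopifnot(all(dim(nucleus_mask) == c(h, w)))
  clusters <- as_tibble(clusters)
  if (nrow(clusters) > 0L) {
    if (any(clusters$x < 1 | clusters$x > w | clusters$y < 1 | clusters$y > h)) {
      abort("cluster centres must lie inside the image")
    }
    if (nrow(clusters) > 1L) {
      d <- as.matrix(stats::dist(clusters[, c("x", "y")]))
      diag(d) <- Inf
      if (min(d) < 3 * psf_sigma) {
        warn("some cluster centres are closer than 3 sigma; fits may interfere")
      }
    }
  }
  img <- matrix(background, h, w)
  gx <- matrix(rep(seq_len(w), each = h), h, w)
  gy <- matrix(rep(seq_len(h), times = w), h, w)
  amp <- clusters$molecules * unitary / (2 * pi * psf_sigma^2)
  for (i in seq_len(nrow(clusters))) {
    img <- img + amp[i] * exp(
      -(((gx - clusters$x[i])^2 + (gy - clusters$y[i])^2) / (2 * psf_sigma^2))
    )
  }
  if (noise_sd > 0) {
    img <- img + with_seed(seed, matrix(rnorm(h * w, 0, noise_sd), h, w))
  }
  list(
    image = img,
    mask = nucleus_mask,
    truth = dplyr::mutate(clusters, amplitude = amp),
    unitary = unitary,
    psf_sigma = psf_sigma
  )
}
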