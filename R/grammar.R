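#' Sliding-window charge profile of a protein sequence
#'
#' For every full window of length `window`, the window value is the fraction
#' of positively charged residues minus the fraction of negatively charged
#' residues (net charge per residue of the window). Each residue is then
#' assigned the mean of the window values over all full windows that contain
#' it, so residues near the termini average fewer windows. With
#' `window = nchar(seq)` every residue's value equals the sequence NCPR.
#'
#' @param seq Amino-acid sequence string.
#' @param window Window length (>= 1, <= sequence length). Length 5 resolves
#'   individual charge blocks; length 31 gives a smoothed profile matching the
#'   interaction-map window.
#' @param groups Residue groups; only `pos` and `neg` are used.
#'
#' @return Tibble with columns `position`, `residue`, `value` (in \[-1, 1\]).
#' @examples
#' charge_profile("KKGEE", window = 3)
#' @export
charge_profile <- function(seq, window = 5L, groups = residue_groups()) {
  ch <- aa_chars(seq)
  n <- length(ch)
  window <- as.integer(window)
  if (window < 1L || window > n) {
    abort(sprintf("window must be in [1, %d], got %d", n, window))
  }
  w <- window_fractions(ch %in% groups$pos, window) -
    window_fractions(ch %in% groups$neg, window)
  # residue r is covered by windows max(1, r-L+1) .. min(r, n-L+1)
  cw <- c(0, cumsum(w))
  lo <- pmax(1L, seq_len(n) - window + 1L)
  hi <- pmin(seq_len(n), n - window + 1L)
  vals <- (cw[hi + 1L] - cw[lo]) / (hi - lo + 1L)
  tibble(position = seq_len(n), residue = ch, value = vals)
}

# Fraction of TRUE entries in each full window of length g (vector of
# length n - g + 1).
window_fractions <- function(ind, g) {
  window_counts(ind, g) / g
}

window_counts <- function(ind, g) {
  cs <- c(0, cumsum(as.integer(ind)))
  n <- length(ind)
  cs[(g + 1L):(n + 1L)] - cs[1:(n - g + 1L)]
}

#' Compositional features of a sequence
#'
#' Computes the 20 amino-acid fractions, the fraction in each residue group,
#' the fraction of charged residues (FCR, pos or neg), and the net charge per
#' residue (NCPR, fraction pos minus fraction neg). All are permutation
#' invariant.
#'
#' @param seq Amino-acid sequence string.
#' @param groups Residue groups, see [residue_groups()].
#'
#' @return Tibble with columns `feature` and `value`. Amino-acid fractions sum
#'   to 1; NCPR lies in \[-1, 1\].
#' @examples
#' composition_features("DEKRST")
#' @export
composition_features <- function(seq, groups = residue_groups()) {
  ch <- aa_chars(seq)
  n <- length(ch)
  aa_frac <- vapply(AA20, function(a) sum(ch == a), numeric(1)) / n
  grp_frac <- vapply(groups, function(g) mean(ch %in% g), numeric(1))
  fpos <- mean(ch %in% groups$pos)
  fneg <- mean(ch %in% groups$neg)
  tibble(
    feature = c(
      paste0("frac_", AA20),
      paste0("frac_", names(groups)),
      "fcr", "ncpr"
    ),
    value = unname(c(aa_frac, grp_frac, mean(ch %in% c(groups$pos, groups$neg)), fpos - fneg))
  )
}

#' Kappa-style patterning statistic delta
#'
#' Quantifies how segregated ("blocky") two residue types are along a
#' sequence. For each window size `g`, every full window i gets the local
#' asymmetry `sigma_i = (fX_i - fY_i)^2 / (fX_i + fY_i)` (0 when the window
#' holds no X or Y residue); the whole-sequence asymmetry `sigma_bar` is
#' computed the same way from global fractions; and
#' `delta_g = mean_i (sigma_i - sigma_bar)^2`. The returned delta is the mean
#' of `delta_g` over the window sizes (default \{5, 6\}, the usual blob
#' sizes). High delta = segregated/blocky; low = well-mixed.
#'
#' To measure segregation of a single group "with respect to everything
#' else", pass `y = NULL`: Y is then the complement of X.
#'
#' @param seq Amino-acid sequence string.
#' @param x,y Group names (in `groups`) or character vectors of residues.
#'   X and Y must be disjoint. `y = NULL` uses the complement of X.
#' @param groups Residue groups used to resolve group names.
#' @param windows Integer window sizes (default `c(5, 6)`).
#'
#' @return Single non-negative number.
#' @examples
#' patterning_delta("EEEEKKKK", "neg", "pos", windows = 5) # blocky: 0.0656
#' patterning_delta("EKEKEKEK", "neg", "pos")              # mixed:  0.0008
#' @export
patterning_delta <- function(seq, x, y = NULL, groups = residue_groups(),
                             windows = c(5L, 6L)) {
  ch <- aa_chars(seq)
  sets <- resolve_xy(x, y, groups)
  delta_from_codes(code_xy(ch, sets$x, sets$y), windows)
}

resolve_xy <- function(x, y, groups) {
  resolve_one <- function(g) {
    if (is.character(g) && length(g) == 1L && g %in% names(groups)) {
      groups[[g]]
    } else {
      toupper(g)
    }
  }
  xs <- resolve_one(x)
  ys <- if (is.null(y)) setdiff(AA20, xs) else resolve_one(y)
  if (!groups_disjoint(xs, ys)) {
    abort("patterning groups X and Y must be disjoint")
  }
  list(x = xs, y = ys)
}

# Integer codes: 1 = X, 2 = Y, 0 = other.
code_xy <- function(ch, xs, ys) {
  code <- integer(length(ch))
  code[ch %in% xs] <- 1L
  code[ch %in% ys] <- 2L
  code
}

delta_from_codes <- function(code, windows) {
  n <- length(code)
  if (max(windows) > n) {
    abort(sprintf("sequence length %d shorter than window %d", n, max(windows)))
  }
  cx_tot <- sum(code == 1L)
  cy_tot <- sum(code == 2L)
  if (cx_tot + cy_tot == 0L) {
    abort("patterning statistic undefined: sequence has no X or Y residues")
  }
  fx <- cx_tot / n
  fy <- cy_tot / n
  sigma_bar <- (fx - fy)^2 / (fx + fy)
  mean(vapply(windows, function(g) {
    cx <- window_counts(code == 1L, g)
    cy <- window_counts(code == 2L, g)
    tot <- cx + cy
    sigma <- numeric(length(tot))
    nz <- tot > 0L
    sigma[nz] <- ((cx[nz] - cy[nz])^2) / (g * tot[nz])
    mean((sigma - sigma_bar)^2)
  }, numeric(1)))
}

#' Patterning z-score against a shuffle null
#'
#' Compares the observed patterning delta ([patterning_delta()]) with the
#' distribution of delta over uniform random permutations of the sequence
#' (compositionally identical random sequences):
#' `z = (delta_obs - mean(delta_shuffled)) / sd(delta_shuffled)`.
#' Positive z means more segregated/blocky than random; negative z means more
#' well-mixed. If every shuffle gives the same delta (e.g. a homopolymer) the
#' null is degenerate and z is reported as 0 with `degenerate = TRUE`.
#'
#' @inheritParams patterning_delta
#' @param n_shuffles Number of permutations (>= 100; default 10000).
#' @param seed Integer seed; results are deterministic given the seed.
#'
#' @return One-row tibble: `group_x`, `group_y`, `delta`, `null_mean`,
#'   `null_sd`, `z`, `n_shuffles`, `seed`, `degenerate`.
#' @export
patterning_zscore <- function(seq, x, y = NULL, groups = residue_groups(),
                              windows = c(5L, 6L), n_shuffles = 10000L,
                              seed = 1L) {
  if (n_shuffles < 100L) abort("n_shuffles must be >= 100")
  ch <- aa_chars(seq)
  sets <- resolve_xy(x, y, groups)
  code <- code_xy(ch, sets$x, sets$y)
  d_obs <- delta_from_codes(code, windows)
  d_null <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      delta_from_codes(sample(code), windows)
    }, numeric(1))
  })
  mu <- mean(d_null)
  s <- sd(d_null)
  degenerate <- !is.finite(s) || s == 0
  tibble(
    group_x = if (is.character(x) && length(x) == 1L) x else paste(sets$x, collapse = ""),
    group_y = if (is.null(y)) "rest" else if (is.character(y) && length(y) == 1L) y else paste(sets$y, collapse = ""),
    delta = d_obs,
    null_mean = mu,
    null_sd = s,
    z = if (degenerate) 0 else (d_obs - mu) / s,
    n_shuffles = as.integer(n_shuffles),
    seed = as.integer(seed),
    degenerate = degenerate
  )
}

#' Build an IDRome background of compositional features
#'
#' Computes [composition_features()] for each background IDR and returns the
#' per-feature mean and standard deviation, used to z-score query IDRs
#' against the proteome-wide IDR population.
#'
#' @param idrs Tibble of IDRs with a `sequence` column (see [extract_idrs()]
#'   or [sim_idrome()]).
#' @param groups Residue groups.
#'
#' @return Tibble with columns `feature`, `mean`, `sd`, `n_background`, of
#'   class `idrome_background`.
#' @export
build_background <- function(idrs, groups = residue_groups()) {
  stopifnot(is.data.frame(idrs), "sequence" %in% names(idrs))
  if (nrow(idrs) < 2L) abort("background needs at least 2 IDRs")
  feats <- purrr::map(idrs$sequence, composition_features, groups = groups)
  mat <- vapply(feats, function(f) f$value, numeric(nrow(feats[[1]])))
  out <- tibble(
    feature = feats[[1]]$feature,
    mean = rowMeans(mat),
    sd = apply(mat, 1, sd),
    n_background = nrow(idrs)
  )
  class(out) <- c("idrome_background", class(out))
  out
}

#' Composition z-scores of a sequence against an IDRome background
#'
#' `z = (x_f - mean_f) / sd_f` per feature; features whose background SD is 0
#' are flagged degenerate and given z = 0.
#'
#' @param seq Amino-acid sequence string.
#' @param background An `idrome_background` from [build_background()].
#' @param groups Residue groups (must match those used for the background).
#'
#' @return Tibble: `feature`, `value`, `z`, `degenerate`.
#' @export
composition_zscores <- function(seq, background, groups = residue_groups()) {
  stopifnot(inherits(background, "idrome_background"))
  f <- composition_features(seq, groups)
  b <- dplyr::left_join(f, background, by = "feature")
  if (any(is.na(b$mean))) abort("background is missing features present in the query")
  degenerate <- !is.finite(b$sd) | b$sd == 0
  z <- ifelse(degenerate, 0, (b$value - b$mean) / b$sd)
  tibble(feature = b$feature, value = b$value, z = z, degenerate = degenerate)
}

#' Full grammar report for a set of IDRs
#'
#' Assembles, per IDR, the composition z-scores against an IDRome background
#' and the patterning z-scores against shuffle nulls for every residue group
#' on its own (vs the complement of the group) and for every disjoint pair of
#' groups. Features with `|z| >= 1` for at least one IDR are conventionally
#' the ones displayed; the `display` column records `|z| >= 1` per feature
#' and IDR.
#'
#' Pairs of groups that are not disjoint (e.g. `ala` within `hyd` under the
#' defaults) cannot carry a patterning statistic and are skipped.
#'
#' @param idrs Tibble of IDRs with `idr_id` and `sequence` columns.
#' @param background An `idrome_background` from [build_background()].
#' @param groups Residue groups.
#' @param windows Patterning window sizes.
#' @param n_shuffles Shuffle-null size per patterning feature.
#' @param seed Integer seed for the shuffle nulls.
#'
#' @return Tibble of class `grammar_report` with columns `idr_id`, `feature`,
#'   `type` ("composition" or "patterning"), `value`, `z`, `degenerate`,
#'   `display`.
#' @export
grammar_report <- function(idrs, background, groups = residue_groups(),
                           windows = c(5L, 6L), n_shuffles = 10000L, seed = 1L) {
  stopifnot(is.data.frame(idrs), all(c("idr_id", "sequence") %in% names(idrs)))
  gnames <- names(groups)
  pairs <- c(
    purrr::map(gnames, function(g) c(g, NA_character_)),
    utils::combn(gnames, 2L, simplify = FALSE)
  )
  per_idr <- purrr::map2(idrs$idr_id, idrs$sequence, function(id, seq) {
    comp <- composition_zscores(seq, background, groups)
    comp <- dplyr::mutate(comp, idr_id = id, type = "composition")
    pat <- purrr::map(pairs, function(p) {
      x <- p[1]
      y <- if (is.na(p[2])) NULL else p[2]
      ys <- if (is.null(y)) setdiff(AA20, groups[[x]]) else groups[[y]]
      label <- if (is.null(y)) paste0("pat_", x) else paste0("pat_", x, "_", y)
      if (!groups_disjoint(groups[[x]], ys)) {
        return(tibble(
          feature = label, value = NA_real_, z = NA_real_, degenerate = TRUE
        ))
      }
      res <- tryCatch(
        patterning_zscore(seq, x, y, groups, windows, n_shuffles, seed),
        error = function(e) NULL
      )
      if (is.null(res)) {
        tibble(feature = label, value = NA_real_, z = NA_real_, degenerate = TRUE)
      } else {
        tibble(feature = label, value = res$delta, z = res$z, degenerate = res$degenerate)
      }
    })
    pat <- dplyr::mutate(dplyr::bind_rows(pat), idr_id = id, type = "patterning")
    dplyr::bind_rows(comp, pat)
  })
  out <- dplyr::bind_rows(per_idr)
  out <- dplyr::mutate(
    out,
    display = !is.na(.data$z) & abs(.data$z) >= 1
  )
  out <- dplyr::select(
    out, "idr_id", "feature", "type", "value", "z", "degenerate", "display"
  )
  class(out) <- c("grammar_report", class(out))
  out
}
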