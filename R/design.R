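#' Design a well-mixed-charge sequence variant
#'
#' Disperses blocks of charged residues within the IDRs of a protein while
#' conserving composition and net charge exactly. Within each IDR region
#' separately, negative (D, E) and positive (K, R, H) residues — excluding
#' any position listed in `fixed_negative_positions` — are extracted in
#' N-to-C order into separate queues (per-region processing keeps each IDR's
#' net charge exactly conserved, not just the total). The same charged positions are then refilled
#' in N-to-C order by alternating draws: the next unused negative residue,
#' then the next unused positive residue, and so on, making charged positions
#' mostly every-other-charge. When one queue runs dry, the remaining residues
#' of the other queue are placed in extraction order. Residues outside the
#' IDR regions (structured domains), non-charged residues, and fixed
#' positions are untouched, so the variant is a pure permutation of charged
#' residues among charged positions.
#'
#' Histidine counts as positive for extraction and alternation but carries
#' zero charge in the net-charge conservation check (see
#' [validate_variant()]); both conventions are standard and used side by
#' side.
#'
#' @param wt_sequence Wild-type amino-acid sequence string.
#' @param idr_regions List (or 2-column matrix) of 1-based inclusive
#'   `(start, end)` IDR ranges; must not overlap.
#' @param fixed_negative_positions Integer positions (1-based) that hold a
#'   negative residue in the WT and must keep it.
#' @param neg_set,pos_set Residue sets used for extraction (defaults
#'   `{D, E}` and `{K, R, H}`).
#' @param first Which queue the alternation starts with, `"neg"` (default)
#'   or `"pos"`.
#'
#' @return List of class `design_result` with elements `wt_sequence`,
#'   `variant_sequence`, `swapped_positions` (positions whose residue
#'   changed), `charged_positions`, and per-IDR net charge before/after
#'   (charge scheme K/R = +1, D/E = -1, H = 0).
#' @examples
#' design_well_mixed("GEEGGKKG", idr_regions = list(c(1, 8)))$variant_sequence
#' @export
design_well_mixed <- function(wt_sequence, idr_regions,
                              fixed_negative_positions = integer(),
                              neg_set = c("D", "E"),
                              pos_set = c("K", "R", "H"),
                              first = c("neg", "pos")) {
  first <- match.arg(first)
  ch <- aa_chars(wt_sequence)
  n <- length(ch)
  regions <- normalize_regions(idr_regions, n)
  fixed <- as.integer(fixed_negative_positions)
  in_region <- logical(n)
  for (r in regions) in_region[r[1]:r[2]] <- TRUE
  if (length(fixed) > 0L) {
    if (any(!in_region[fixed])) abort("fixed positions must lie inside the IDR regions")
    if (any(!ch[fixed] %in% neg_set)) {
      bad <- fixed[!ch[fixed] %in% neg_set][1]
      abort(sprintf("fixed position %d does not hold a negative residue in the WT", bad))
    }
  }
  variant <- ch
  charged_all <- integer()
  # each IDR is rebuilt from its own residues, so per-IDR composition and net
  # charge are conserved exactly
  for (r in regions) {
    span <- r[1]:r[2]
    charged <- span[ch[span] %in% c(neg_set, pos_set)]
    charged <- setdiff(charged, fixed)
    charged_all <- c(charged_all, charged)
    neg_q <- ch[charged][ch[charged] %in% neg_set]
    pos_q <- ch[charged][ch[charged] %in% pos_set]
    want_neg <- first == "neg"
    ni <- 1L
    pi <- 1L
    for (p in charged) {
      take_neg <- if (want_neg) ni <= length(neg_q) else ni <= length(neg_q) && pi > length(pos_q)
      if (take_neg) {
        variant[p] <- neg_q[ni]
        ni <- ni + 1L
      } else {
        variant[p] <- pos_q[pi]
        pi <- pi + 1L
      }
      want_neg <- !want_neg
    }
  }
  charged <- charged_all
  net <- function(s, r) {
    seg <- s[r[1]:r[2]]
    sum(seg %in% c("K", "R")) - sum(seg %in% c("D", "E"))
  }
  per_idr <- tibble(
    region = vapply(regions, function(r) sprintf("%d-%d", r[1], r[2]), character(1)),
    net_charge_wt = vapply(regions, net, numeric(1), s = ch),
    net_charge_variant = vapply(regions, net, numeric(1), s = variant)
  )
  structure(
    list(
      wt_sequence = wt_sequence,
      variant_sequence = paste(variant, collapse = ""),
      swapped_positions = which(variant != ch),
      charged_positions = charged,
      fixed_positions = fixed,
      idr_regions = regions,
      per_idr_net_charge = per_idr
    ),
    class = "design_result"
  )
}

normalize_regions <- function(idr_regions, n) {
  if (is.matrix(idr_regions) || is.data.frame(idr_regions)) {
    idr_regions <- lapply(
      seq_len(nrow(idr_regions)),
      function(i) as.numeric(idr_regions[i, 1:2])
    )
  }
  regions <- lapply(idr_regions, function(r) as.integer(r[1:2]))
  for (r in regions) {
    if (r[1] < 1L || r[2] > n || r[2] < r[1]) {
      abort(sprintf("IDR region %d-%d out of bounds for length-%d sequence", r[1], r[2], n))
    }
  }
  if (length(regions) > 1L) {
    o <- order(vapply(regions, `[`, integer(1), 1L))
    regions <- regions[o]
    starts <- vapply(regions, `[`, integer(1), 1L)
    ends <- vapply(regions, `[`, integer(1), 2L)
    if (any(starts[-1] <= ends[-length(ends)])) abort("IDR regions must not overlap")
  }
  regions
}

#' Validate a designed sequence variant against its wild type
#'
#' Checks the contract of [design_well_mixed()]: identical length and residue
#' composition (pure permutation), identical per-IDR net charge (K/R = +1,
#' D/E = -1, H = 0), unchanged fixed positions, and unchanged sequence
#' outside the IDR regions. Also reports the neg-vs-pos patterning delta of
#' both sequences and their shuffle-null z-scores, which is how "well-mixed"
#' is quantified.
#'
#' @param wt,variant Amino-acid sequence strings of equal length.
#' @param idr_regions,fixed_negative_positions As in [design_well_mixed()].
#' @param n_shuffles,seed Shuffle-null settings for the patterning z-scores.
#'
#' @return List of class `design_validation`: `checks` (tibble of named
#'   check/pass rows), `delta` (tibble with WT and variant delta and z), and
#'   `pass` (all checks passed).
#' @export
validate_variant <- function(wt, variant, idr_regions,
                             fixed_negative_positions = integer(),
                             n_shuffles = 1000L, seed = 1L) {
  wt_ch <- aa_chars(wt, "wt")
  va_ch <- aa_chars(variant, "variant")
  if (length(wt_ch) != length(va_ch)) abort("wt and variant must have equal length")
  n <- length(wt_ch)
  regions <- normalize_regions(idr_regions, n)
  fixed <- as.integer(fixed_negative_positions)
  in_region <- logical(n)
  for (r in regions) in_region[r[1]:r[2]] <- TRUE

  net <- function(s, r) {
    seg <- s[r[1]:r[2]]
    sum(seg %in% c("K", "R")) - sum(seg %in% c("D", "E"))
  }
  checks <- tibble(
    check = c(
      "equal_length", "composition_identity", "net_charge_per_idr",
      "fixed_positions_unchanged", "non_idr_unchanged"
    ),
    pass = c(
      TRUE,
      identical(sort(wt_ch), sort(va_ch)),
      all(vapply(regions, net, numeric(1), s = wt_ch) ==
        vapply(regions, net, numeric(1), s = va_ch)),
      length(fixed) == 0L || all(wt_ch[fixed] == va_ch[fixed]),
      all(wt_ch[!in_region] == va_ch[!in_region])
    )
  )
  groups <- residue_groups()
  delta_row <- function(label, s) {
    zs <- tryCatch(
      patterning_zscore(s, "neg", "pos", groups, n_shuffles = n_shuffles, seed = seed),
      error = function(e) NULL
    )
    tibble(
      sequence = label,
      delta = if (is.null(zs)) NA_real_ else zs$delta,
      z = if (is.null(zs)) NA_real_ else zs$z
    )
  }
  structure(
    list(
      checks = checks,
      delta = dplyr::bind_rows(delta_row("wt", wt), delta_row("variant", variant)),
      pass = all(checks$pass)
    ),
    class = "design_validation"
  )
}

#' @export
print.design_result <- function(x, ...) {
  cat("Well-mixed-charge design\n")
  cat(sprintf(
    "  length %d, %d charged positions refilled, %d residues moved\n",
    nchar(x$wt_sequence), length(x$charged_positions), length(x$swapped_positions)
  ))
  print(x$per_idr_net_charge)
  invisible(x)
}

#' @export
print.design_validation <- function(x, ...) {
  cat(sprintf("Design validation: %s\n", if (x$pass) "PASS" else "FAIL"))
  print(x$checks)
  print(x$delta)
  invisible(x)
}
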