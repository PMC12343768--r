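#' Residue-pair interaction weight matrices
#'
#' `default_pair_matrix()` returns a documented simplified mean-field
#' potential: opposite charges attract (`w(pos, neg) = -1`), like charges
#' repel (`+1`), aromatic pairs attract (`-0.7`, pi-pi), aromatic-positive
#' pairs attract (`-0.5`, cation-pi), and all other pairs are neutral.
#' Negative values are attractive throughout. Any 20x20 symmetric matrix —
#' for example one derived from a coarse-grained force field — can be used
#' instead; `read_pair_matrix()` loads one from a TSV with a header row and
#' 20 labelled rows.
#'
#' @param name Name recorded on the matrix attribute.
#' @return 20x20 symmetric numeric matrix with dimnames = amino acids and
#'   attribute `name`.
#' @examples
#' w <- default_pair_matrix()
#' w["E", "K"]
#' @export
default_pair_matrix <- function(name = "simplified-electrostatic") {
  groups <- residue_groups()
  w <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  pos <- groups$pos
  neg <- groups$neg
  aro <- groups$aro
  w[pos, neg] <- -1
  w[neg, pos] <- -1
  w[pos, pos] <- 1
  w[neg, neg] <- 1
  w[aro, aro] <- -0.7
  w[aro, pos] <- -0.5
  w[pos, aro] <- -0.5
  attr(w, "name") <- name
  w
}

#' @rdname default_pair_matrix
#' @param path TSV file: header of 20 residue letters, then 20 rows with a
#'   leading residue label and 20 numeric entries.
#' @export
read_pair_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (!all(dim(m) == c(20L, 20L))) abort("pair matrix must be 20x20")
  rn <- toupper(rownames(m))
  cn <- toupper(colnames(m))
  if (!setequal(rn, AA20) || !setequal(cn, AA20)) {
    abort("pair matrix rows/columns must be the 20 canonical residues")
  }
  m <- m[AA20, AA20]
  if (any(!is.finite(m))) abort("pair matrix entries must be finite")
  if (max(abs(m - t(m))) > 1e-8) abort("pair matrix must be symmetric")
  attr(m, "name") <- basename(path)
  m
}

#' Mean-field interaction strength between two residue windows
#'
#' `epsilon = mean over all residue pairs (i in A, j in B) of w(a_i, b_j)`.
#' Order within each window does not matter (mean-field). Negative values
#' are attractive.
#'
#' @param win_a,win_b Amino-acid strings (the two windows).
#' @param matrix 20x20 pair weight matrix (default
#'   [default_pair_matrix()]).
#' @return Single number.
#' @examples
#' window_epsilon("EEE", "KKK") # -1
#' @export
window_epsilon <- function(win_a, win_b, matrix = default_pair_matrix()) {
  a <- aa_chars(win_a, "window A")
  b <- aa_chars(win_b, "window B")
  mean(matrix[a, b, drop = FALSE])
}

#' Window-by-window intermolecular interaction map of two IDRs
#'
#' Slides a window of length `window` (default 31) over both sequences
#' (stride 1, full windows only) and computes the mean-field interaction
#' strength [window_epsilon()] for every window pair, giving an
#' `(n_a - window + 1) x (n_b - window + 1)` matrix `epsilon` whose axes are
#' 1-based window start positions. Negative entries are attractive.
#'
#' Each sequence additionally gets a per-residue attractive vector: for every
#' residue, the mean of `min(epsilon, 0)` over all map cells whose window
#' (on that sequence's axis) contains the residue. Entries are always <= 0;
#' a value of 0 means the residue participates in no attractive window pair.
#'
#' @param seq_a,seq_b Amino-acid sequence strings (each >= `window` long).
#' @param window Window length (default 31).
#' @param matrix 20x20 pair weight matrix.
#' @param id_a,id_b Identifiers recorded in the result.
#'
#' @return List of class `intermap`: `epsilon` (matrix), `window`, `id_a`,
#'   `id_b`, `attractive_a`, `attractive_b` (numeric vectors, one entry per
#'   residue), `matrix_name`.
#' @export
intermap <- function(seq_a, seq_b, window = 31L, matrix = default_pair_matrix(),
                     id_a = "A", id_b = "B") {
  a <- aa_chars(seq_a, "sequence A")
  b <- aa_chars(seq_b, "sequence B")
  window <- as.integer(window)
  if (length(a) < window || length(b) < window) {
    abort(sprintf("both sequences must be at least window = %d residues long", window))
  }
  ca <- window_composition(a, window) # n_win_a x 20 counts
  cb <- window_composition(b, window)
  eps <- (ca %*% matrix %*% t(cb)) / (window * window)
  dimnames(eps) <- list(seq_len(nrow(eps)), seq_len(ncol(eps)))
  structure(
    list(
      epsilon = eps,
      window = window,
      id_a = id_a,
      id_b = id_b,
      attractive_a = attractive_vector(eps, length(a), window, margin = 1L),
      attractive_b = attractive_vector(eps, length(b), window, margin = 2L),
      matrix_name = attr(matrix, "name") %||% "custom"
    ),
    class = "intermap"
  )
}

# n_win x 20 matrix of residue counts per full window.
window_composition <- function(ch, g) {
  n <- length(ch)
  m <- vapply(AA20, function(a) window_counts(ch == a, g), numeric(n - g + 1L))
  matrix(m, nrow = n - g + 1L, ncol = 20L, dimnames = list(NULL, AA20))
}

# Mean of min(eps, 0) over map cells whose window on `margin` contains each
# residue.
attractive_vector <- function(eps, n, window, margin) {
  neg <- pmin(eps, 0)
  row_means <- if (margin == 1L) rowMeans(neg) else colMeans(neg)
  n_win <- length(row_means)
  cw <- c(0, cumsum(row_means))
  lo <- pmax(1L, seq_len(n) - window + 1L)
  hi <- pmin(seq_len(n), n_win)
  unname((cw[hi + 1L] - cw[lo]) / (hi - lo + 1L))
}

#' Compare two interaction maps against the same partner
#'
#' Summarizes an interaction map — minimum epsilon (strongest attraction),
#' mean attractive epsilon (mean over cells with epsilon < 0; 0 when none),
#' and fraction of attractive cells — for two maps sharing the same partner
#' sequence and window, and reports their differences (variant minus
#' reference). A typical use is the blocky wild type versus its
#' well-mixed-charge permutation.
#'
#' @param map_ref,map_var `intermap` objects with identical `id_b`/partner
#'   and window.
#' @return Tibble with one row per map plus a `difference` row.
#' @export
summarize_interaction <- function(map_ref, map_var) {
  stopifnot(inherits(map_ref, "intermap"), inherits(map_var, "intermap"))
  if (map_ref$window != map_var$window) abort("maps use different windows")
  if (ncol(map_ref$epsilon) != ncol(map_var$epsilon)) {
    abort("maps have different partner dimensions; were they computed against the same partner?")
  }
  one <- function(m, label) {
    e <- m$epsilon
    att <- e[e < 0]
    tibble(
      map = label,
      min_epsilon = min(e),
      mean_attractive = if (length(att)) mean(att) else 0,
      frac_attractive = mean(e < 0)
    )
  }
  s1 <- one(map_ref, "reference")
  s2 <- one(map_var, "variant")
  diff <- tibble(
    map = "difference",
    min_epsilon = s2$min_epsilon - s1$min_epsilon,
    mean_attractive = s2$mean_attractive - s1$mean_attractive,
    frac_attractive = s2$frac_attractive - s1$frac_attractive
  )
  dplyr::bind_rows(s1, s2, diff)
}

#' @export
print.intermap <- function(x, ...) {
  cat(sprintf(
    "Intermap %s x %s: %d x %d windows (L = %d), matrix '%s'\n",
    x$id_a, x$id_b, nrow(x$epsilon), ncol(x$epsilon), x$window, x$matrix_name
  ))
  cat(sprintf(
    "  epsilon range [%.3f, %.3f], %.1f%% attractive cells\n",
    min(x$epsilon), max(x$epsilon), 100 * mean(x$epsilon < 0)
  ))
  invisible(x)
}

#' Tidy an interaction map into long format
#'
#' @param x An `intermap` object.
#' @param ... Unused.
#' @return Tibble with columns `window_a`, `window_b`, `epsilon`.
#' @method tidy intermap
#' @export
tidy.intermap <- function(x, ...) {
  e <- x$epsilon
  tibble(
    window_a = rep(seq_len(nrow(e)), times = ncol(e)),
    window_b = rep(seq_len(ncol(e)), each = nrow(e)),
    epsilon = as.vector(e)
  )
}
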