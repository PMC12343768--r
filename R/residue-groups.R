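#' Residue-group definitions for sequence-grammar features
#'
#' Returns the named list of residue groups used throughout the grammar
#' machinery. The defaults follow the common condensate-grammar conventions:
#' positively charged (K, R), negatively charged (D, E), polar
#' (S, T, N, Q, C, H), aliphatic/hydrophobic (A, I, L, M, V), aromatic
#' (F, W, Y), and the single-residue groups proline, alanine and glycine.
#'
#' Histidine sits in the polar group here; the well-mixed-charge design
#' algorithm ([design_well_mixed()]) separately counts H as positive during
#' residue extraction, mirroring the two conventions used in practice.
#'
#' @param ... Named character vectors overriding or adding groups, e.g.
#'   `pos = c("K", "R", "H")`.
#'
#' @return Named list of character vectors of one-letter residue codes.
#' @examples
#' residue_groups()$pos
#' residue_groups(pos = c("K", "R", "H"))$pos
#' @export
residue_groups <- function(...) {
  groups <- list(
    pos = c("K", "R"),
    neg = c("D", "E"),
    pol = c("S", "T", "N", "Q", "C", "H"),
    hyd = c("A", "I", "L", "M", "V"),
    aro = c("F", "W", "Y"),
    pro = "P",
    ala = "A",
    gly = "G"
  )
  override <- list(...)
  if (length(override) > 0L) {
    if (is.null(names(override)) || any(names(override) == "")) {
      abort("group overrides must be named")
    }
    for (nm in names(override)) {
      g <- toupper(override[[nm]])
      if (length(g) == 0L || !all(g %in% AA20)) {
        abort(sprintf("group '%s' must be a non-empty set of canonical residues", nm))
      }
      groups[[nm]] <- g
    }
  }
  groups
}

# TRUE when two residue sets share no residue (required for patterning pairs).
groups_disjoint <- function(x, y) length(intersect(x, y)) == 0L
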