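#' Read protein records from a FASTA file
#'
#' Parses a (multi-record, wrapped or unwrapped) FASTA file into a tibble of
#' protein records. Sequences are validated against the 20-letter canonical
#' amino-acid alphabet; ambiguity codes (X, B, Z, ...) are rejected with an
#' error naming the record and position.
#'
#' @param path Path to a FASTA file.
#'
#' @return A tibble with columns `id`, `description` and `sequence`, one row
#'   per record, in file order. An empty file yields a zero-row tibble.
#' @seealso [write_fasta()], [extract_idrs()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: %s", path))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(sprintf("malformed FASTA in %s: %s", path, conditionMessage(e)))
    }
  )
  if (length(set) == 0L) {
    return(tibble(id = character(), description = character(), sequence = character()))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- unname(gsub("[[:space:]]", "", as.character(set)))
  for (i in seq_along(seqs)) {
    ch <- strsplit(toupper(seqs[i]), "", fixed = TRUE)[[1]]
    if (length(ch) == 0L) {
      abort(sprintf("record '%s' has an empty sequence", ids[i]))
    }
    bad <- which(!ch %in% AA20)
    if (length(bad) > 0L) {
      abort(sprintf(
        "record '%s' contains non-canonical residue '%s' at position %d",
        ids[i], ch[bad[1]], bad[1]
      ))
    }
  }
  tibble(id = ids, description = descs, sequence = toupper(seqs))
}

#' Write protein records to a FASTA file
#'
#' Inverse of [read_fasta()]: writes one unwrapped record per row so that a
#' read/write round trip reproduces sequences byte-identically.
#'
#' @param records Tibble with columns `id`, `sequence`, and optionally
#'   `description`.
#' @param path Output path.
#'
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  headers <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 20000L)
  invisible(path)
}

#' Extract intrinsically disordered regions from a protein record
#'
#' IDRs can be supplied either as explicit residue ranges (the usual case when
#' boundaries come from domain annotations or published tables) or as a
#' per-residue disorder mask, in which case maximal runs of disordered
#' residues longer than `min_len` are extracted. All coordinates are 1-based
#' and inclusive.
#'
#' In mask mode the length filter is strict (`length > min_len`), so with the
#' default `min_len = 30` a 30-residue run is dropped. Region mode returns the
#' regions as given, without a length filter, because explicit boundaries are
#' trusted input.
#'
#' @param record A one-row data frame (or list) with `id` and `sequence`, as
#'   returned by [read_fasta()].
#' @param regions List (or 2-column matrix/data frame) of `(start, end)`
#'   residue ranges. Mutually exclusive with `mask`.
#' @param mask Logical vector, one element per residue; `TRUE` = disordered.
#' @param min_len Strict lower bound on run length in mask mode (default 30).
#'
#' @return Tibble with columns `parent_id`, `start`, `end`, `idr_id` and
#'   `sequence`, one row per IDR.
#' @examples
#' rec <- tibble::tibble(id = "toy", sequence = strrep("QSPG", 25))
#' extract_idrs(rec, regions = list(c(1, 40), c(61, 100)))
#' @export
extract_idrs <- function(record, regions = NULL, mask = NULL, min_len = 30L) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- as.list(record)
  }
  seq <- record$sequence
  n <- nchar(seq)
  aa_chars(seq, sprintf("sequence of '%s'", record$id))
  if (is.null(regions) == is.null(mask)) {
    abort("supply exactly one of `regions` or `mask`")
  }
  if (!is.null(mask)) {
    if (!is.logical(mask) && !all(mask %in% c(0, 1))) {
      abort("`mask` must be logical or 0/1")
    }
    mask <- as.logical(mask)
    if (length(mask) != n) {
      abort(sprintf("mask length %d != sequence length %d", length(mask), n))
    }
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths > min_len
    starts <- starts[keep]
    ends <- ends[keep]
  } else {
    if (is.matrix(regions) || is.data.frame(regions)) {
      regions <- lapply(seq_len(nrow(regions)), function(i) as.numeric(regions[i, 1:2]))
    }
    starts <- vapply(regions, function(r) as.integer(r[1]), integer(1))
    ends <- vapply(regions, function(r) as.integer(r[2]), integer(1))
    if (any(starts < 1L) || any(ends > n) || any(ends < starts)) {
      abort(sprintf("region out of bounds for sequence of length %d", n))
    }
  }
  tibble(
    parent_id = rep(record$id %||% "seq", length(starts)),
    start = as.integer(starts),
    end = as.integer(ends),
    idr_id = if (length(starts)) {
      sprintf("%s_%d-%d", record$id %||% "seq", starts, ends)
    } else {
      character()
    },
    sequence = if (length(starts)) substring(seq, starts, ends) else character()
  )
}

#' Read a per-residue disorder mask from a two-column TSV
#'
#' Expects columns `residue_index` (1-based) and a 0/1 disorder call; returns
#' a logical vector ordered by residue index.
#'
#' @param path Path to the TSV file.
#' @param n_residues Optional expected length for validation.
#' @return Logical vector.
#' @export
read_disorder_mask <- function(path, n_residues = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (ncol(df) < 2L) abort("disorder mask TSV needs two columns (residue_index, call)")
  idx <- as.integer(df[[1]])
  call <- as.numeric(df[[2]])
  if (any(is.na(idx)) || any(!call %in% c(0, 1))) {
    abort("disorder mask calls must be 0/1 with integer residue indices")
  }
  mask <- logical(max(idx))
  mask[idx] <- call == 1
  if (!is.null(n_residues) && length(mask) != n_residues) {
    if (length(mask) > n_residues) abort("mask index exceeds sequence length")
    mask <- c(mask, logical(n_residues - length(mask)))
  }
  mask
}
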