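#' Read and write single-plane TIFF images as numeric matrices
#'
#' Thin wrappers around the tiff package. Images are numeric matrices
#' indexed `[y, x]` (row = y), in arbitrary intensity units; 16-bit TIFFs
#' are rescaled by the reader to \[0, 1\] and multiplied back to the stated
#' bit depth.
#'
#' @param path TIFF path.
#' @param bits Bit depth used to undo the tiff package's \[0, 1\] scaling on
#'   read and apply it on write (default 16).
#' @return `read_image_tiff()`: numeric matrix.
#' @export
read_image_tiff <- function(path, bits = 16L) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img * (2^bits - 1)
}

#' @rdname read_image_tiff
#' @param image Numeric matrix.
#' @export
write_image_tiff <- function(image, path, bits = 16L) {
  tiff::writeTIFF(pmin(pmax(image / (2^bits - 1), 0), 1), path, bits.per.sample = 16L)
  invisible(path)
}

#' Fit a 2D Gaussian with offset to a spot
#'
#' Least-squares fit of
#' `amplitude * exp(-((x - x0)^2 / (2 sx^2) + (y - y0)^2 / (2 sy^2))) + offset`
#' on the `(2 r + 1)^2` pixel patch centred on `seed_xy` (sub-pixel centre
#' free within the patch). The cluster integral is the sum, over pixels
#' inside the 2-sigma ellipse of the fit, of `model - offset` — i.e. about
#' 86.5% of the full Gaussian mass, which cancels when molecule counts are
#' calibrated against single molecules measured the same way
#' ([calibrate_unitary()]).
#'
#' Sigma is constrained to `[0.5, sigma_max]` pixels inside the
#' optimizer. The fit is rejected (`ok = FALSE`, with a `reason`) when the
#' amplitude is not positive (e.g. a flat patch) or a sigma pins at the
#' upper bound (no localized spot).
#'
#' @param image Numeric matrix indexed `[y, x]`.
#' @param seed_xy Numeric `c(x, y)` seed position in pixels (1-based).
#' @param patch_radius Half-width of the square fit patch (default 5 px).
#' @param sigma_max Upper optimizer bound on sigma in pixels (default 3, the
#'   optical PSF scale; must be <= `patch_radius`).
#' @param raw_integral Sum raw pixel values minus offset instead of model
#'   values (default FALSE: model values).
#'
#' @return One-row tibble: `x`, `y`, `sigma_x`, `sigma_y`, `amplitude`,
#'   `offset`, `integral`, `ok`, `reason`.
#' @export
fit_gaussian2d <- function(image, seed_xy, patch_radius = 5L, sigma_max = 3,
                           raw_integral = FALSE) {
  r <- as.integer(patch_radius)
  cx <- round(seed_xy[1])
  cy <- round(seed_xy[2])
  if (cx - r < 1 || cx + r > ncol(image) || cy - r < 1 || cy + r > nrow(image)) {
    abort(sprintf("fit patch around (%g, %g) extends outside the image", seed_xy[1], seed_xy[2]))
  }
  xs <- (cx - r):(cx + r)
  ys <- (cy - r):(cy + r)
  patch <- image[ys, xs]
  px <- matrix(rep(xs, each = length(ys)), nrow = length(ys))
  py <- matrix(rep(ys, times = length(xs)), nrow = length(ys))
  off0 <- min(patch)
  amp0 <- max(patch) - off0
  if (amp0 <= 0) {
    return(tibble(
      x = NA_real_, y = NA_real_, sigma_x = NA_real_, sigma_y = NA_real_,
      amplitude = NA_real_, offset = NA_real_, integral = NA_real_,
      ok = FALSE, reason = "non-positive amplitude"
    ))
  }
  # sigma constrained to [0.5, sigma_max] px inside the optimizer
  smax <- min(sigma_max, r)
  sig <- function(u) 0.5 + (smax - 0.5) * plogis(u)
  sig_inv <- function(s) qlogis((s - 0.5) / (smax - 0.5))
  model <- function(th) {
    th[1] * exp(-(((px - th[2])^2) / (2 * sig(th[4])^2) +
      ((py - th[3])^2) / (2 * sig(th[5])^2))) + th[6]
  }
  th0 <- c(amp0, seed_xy[1], seed_xy[2], sig_inv(min(1.5, smax * 0.9)), sig_inv(min(1.5, smax * 0.9)), off0)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = th0,
      fn = function(th) as.vector(model(th) - patch),
      control = minpack.lm::nls.lm.control(maxiter = 300)
    ),
    error = function(e) NULL
  )
  reject <- function(reason) {
    tibble(
      x = NA_real_, y = NA_real_, sigma_x = NA_real_, sigma_y = NA_real_,
      amplitude = NA_real_, offset = NA_real_, integral = NA_real_,
      ok = FALSE, reason = reason
    )
  }
  if (is.null(fit)) return(reject("singular fit"))
  th <- fit$par
  amp <- th[1]
  x0 <- th[2]
  y0 <- th[3]
  sx <- sig(th[4])
  sy <- sig(th[5])
  off <- th[6]
  if (amp <= 0) return(reject("non-positive amplitude"))
  if (sx >= smax * 0.999 || sy >= smax * 0.999) {
    return(reject(sprintf("sigma (%.2f, %.2f) at the %g px bound", sx, sy, smax)))
  }
  if (x0 < cx - r || x0 > cx + r || y0 < cy - r || y0 > cy + r) {
    return(reject("centre drifted outside the patch"))
  }
  ell <- ellipse_pixels(dim(image), x0, y0, sx, sy, k = 2)
  vals <- if (raw_integral) {
    image[ell] - off
  } else {
    amp * exp(-(((ell[, 2] - x0)^2) / (2 * sx^2) + ((ell[, 1] - y0)^2) / (2 * sy^2)))
  }
  tibble(
    x = x0, y = y0, sigma_x = sx, sigma_y = sy, amplitude = amp,
    offset = off, integral = sum(vals), ok = TRUE, reason = NA_character_
  )
}

# Pixel coordinates (matrix of [y, x] index pairs) inside the k-sigma ellipse.
ellipse_pixels <- function(dims, x0, y0, sx, sy, k = 2) {
  ylo <- max(1L, floor(y0 - k * sy))
  yhi <- min(dims[1], ceiling(y0 + k * sy))
  xlo <- max(1L, floor(x0 - k * sx))
  xhi <- min(dims[2], ceiling(x0 + k * sx))
  ys <- ylo:yhi
  xs <- xlo:xhi
  gy <- rep(ys, times = length(xs))
  gx <- rep(xs, each = length(ys))
  inside <- ((gx - x0) / (k * sx))^2 + ((gy - y0) / (k * sy))^2 <= 1
  cbind(gy[inside], gx[inside])
}

#' Molecule counting against a single-molecule unitary intensity
#'
#' `molecules_per_cluster()` converts an integrated cluster intensity into a
#' molecule count by dividing by the unitary (single-molecule) integrated
#' intensity. `calibrate_unitary()` estimates that unitary intensity as the
#' median of integrated intensities of isolated single molecules — measured
#' through the same Gaussian-fit path as the clusters, so any partial-mass
#' factor of the integration region cancels.
#'
#' @param integral Integrated cluster intensity (or vector).
#' @param unitary_intensity Integrated intensity of one molecule (> 0).
#' @return Numeric molecule count(s).
#' @examples
#' molecules_per_cluster(3000, 100) # 30
#' calibrate_unitary(c(90, 100, 110)) # 100
#' @export
molecules_per_cluster <- function(integral, unitary_intensity) {
  if (!is.numeric(unitary_intensity) || unitary_intensity <= 0) {
    abort("unitary intensity must be positive")
  }
  if (any(integral < 0, na.rm = TRUE)) abort("integrals must be non-negative")
  integral / unitary_intensity
}

#' @rdname molecules_per_cluster
#' @param single_molecule_integrals Integrated intensities of isolated single
#'   molecules.
#' @export
calibrate_unitary <- function(single_molecule_integrals) {
  v <- single_molecule_integrals[is.finite(single_molecule_integrals)]
  if (length(v) == 0L) abort("empty calibration sample")
  if (any(v <= 0)) abort("single-molecule integrals must be positive")
  median(v)
}

#' Survival curve of cluster sizes
#'
#' 1 - CDF of molecule counts per cluster: fraction of clusters with more
#' than `k` molecules, evaluated at the sorted unique counts (with `(0, 1)`
#' prepended), mirroring [survival_curve()].
#'
#' @param records Tibble with a `molecules` column.
#' @return Tibble with columns `molecules` and `survival`.
#' @export
cluster_size_cdf <- function(records) {
  stopifnot("molecules" %in% names(records))
  m <- records$molecules[is.finite(records$molecules)]
  if (length(m) == 0L) abort("no finite molecule counts")
  ks <- sort(unique(m))
  surv <- vapply(ks, function(k) mean(m > k), numeric(1))
  tibble(molecules = c(0, ks), survival = c(1, surv))
}

#' Dense/dilute phase decomposition of a nucleus
#'
#' Splits nuclear intensity into a dense phase — the summed integrals of
#' clusters with at least `min_molecules` molecules, normalized to the
#' nuclear pixel count — and a dilute (soluble) phase, the mean intensity of
#' nuclear pixels outside the 2-sigma ellipse of every fitted cluster
#' (regardless of its size). `total` is the mean over all nuclear pixels.
#'
#' @param image Numeric matrix indexed `[y, x]`.
#' @param nucleus_mask Logical matrix of the same dimensions; TRUE = nuclear
#'   pixel.
#' @param records Cluster records with columns `x`, `y`, `sigma_x`,
#'   `sigma_y`, `integral`, `molecules` (see [fit_gaussian2d()] and
#'   [molecules_per_cluster()]).
#' @param min_molecules Dense-phase qualification threshold (default 10).
#'
#' @return One-row tibble: `dense`, `dilute`, `total`, `n_clusters`,
#'   `n_dense_clusters`, `nuclear_area` (pixels).
#' @export
phase_decomposition <- function(image, nucleus_mask, records, min_molecules = 10) {
  stopifnot(all(dim(image) == dim(nucleus_mask)))
  if (!any(nucleus_mask)) abort("empty nucleus mask")
  area <- sum(nucleus_mask)
  ok <- records[!is.na(records$integral), , drop = FALSE]
  dense_rec <- ok[ok$molecules >= min_molecules, , drop = FALSE]
  cluster_px <- matrix(FALSE, nrow(image), ncol(image))
  if (nrow(ok) > 0L) {
    for (i in seq_len(nrow(ok))) {
      ell <- ellipse_pixels(dim(image), ok$x[i], ok$y[i], ok$sigma_x[i], ok$sigma_y[i], k = 2)
      cluster_px[ell] <- TRUE
    }
  }
  dilute_px <- nucleus_mask & !cluster_px
  tibble(
    dense = sum(dense_rec$integral) / area,
    dilute = if (any(dilute_px)) mean(image[dilute_px]) else NA_real_,
    total = mean(image[nucleus_mask]),
    n_clusters = nrow(ok),
    n_dense_clusters = nrow(dense_rec),
    nuclear_area = area
  )
}
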