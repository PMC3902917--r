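# Fluorescence line profiles along the cell, polar-fraction statistics and a
# minimal spot localizer for synthetic images.
#
# Coordinate convention, package-wide: relative long-axis position in [0, 1],
# pole at 0, septum/midcell at 0.5. Distance to the nearest pole is obtained
# by folding, min(p, 1 - p).

#' Normalize a fluorescence line profile
#'
#' Rescales the position coordinate to `[0, 1]` and divides the intensity by
#' its integral (trapezoidal rule) so the profile integrates to 1 over the
#' cell; for a uniformly sampled trace this equals division by the mean
#' intensity. Normalization is idempotent and preserves peak positions.
#'
#' @param raw data frame with columns `rel_pos` and `intensity`
#'   (non-negative, not all zero), optionally `cell_id` and `channel`,
#'   ordered or not.
#' @return Data frame with the same columns, `rel_pos` in `[0, 1]`
#'   ascending, unit integral.
#' @examples
#' p <- data.frame(rel_pos = 0:4, intensity = c(2, 2, 2, 2, 2))
#' normalize_profile(p)$intensity # constant 1
#' @export
normalize_profile <- function(raw) {
  if (!all(c("rel_pos", "intensity") %in% names(raw)))
    stop("profile needs 'rel_pos' and 'intensity' columns", call. = FALSE)
  if (nrow(raw) < 2L) stop("profile needs at least 2 samples", call. = FALSE)
  if (any(raw$intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  if (all(raw$intensity == 0)) stop("all-zero profile cannot be normalized",
                                    call. = FALSE)
  out <- raw[order(raw$rel_pos), , drop = FALSE]
  p <- out$rel_pos
  rng <- range(p)
  if (diff(rng) == 0) stop("positions are degenerate", call. = FALSE)
  p <- (p - rng[1]) / diff(rng)
  i <- out$intensity
  integral <- sum(diff(p) * (utils::head(i, -1) + utils::tail(i, -1)) / 2)
  out$rel_pos <- p
  out$intensity <- i / integral
  rownames(out) <- NULL
  out
}

#' Average normalized line profiles across cells
#'
#' Each profile is normalized, resampled by linear interpolation onto a
#' common grid of `n_bins` points spanning `[0, 1]`, and averaged per bin.
#' By default cells keep the orientation they were measured in (random with
#' respect to old/new pole); `align = "brightest_pole"` flips each profile
#' so its brighter half lies at position 0 before averaging.
#'
#' @param profiles list of profile data frames (see [normalize_profile()]).
#' @param n_bins number of grid points.
#' @param align `"none"` or `"brightest_pole"`.
#' @return Data frame `rel_pos`, `intensity` (the mean normalized profile)
#'   and `n` (number of cells averaged).
#' @export
average_profiles <- function(profiles, n_bins = 50,
                             align = c("none", "brightest_pole")) {
  align <- match.arg(align)
  if (!length(profiles)) stop("need at least one profile", call. = FALSE)
  n_bins <- check_count(n_bins, "n_bins", lower = 2L)
  grid <- seq(0, 1, length.out = n_bins)
  acc <- numeric(n_bins)
  for (p in profiles) {
    np <- normalize_profile(p)
    y <- stats::approx(np$rel_pos, np$intensity, xout = grid, rule = 2)$y
    if (align == "brightest_pole" &&
        sum(y[grid > 0.5]) > sum(y[grid < 0.5])) y <- rev(y)
    acc <- acc + y
  }
  data.frame(rel_pos = grid, intensity = acc / length(profiles),
             n = length(profiles))
}

#' Fraction of positions in the polar zones
#'
#' Fraction of relative long-axis positions lying within `cutoff` of either
#' pole, i.e. with `min(p, 1 - p) <= cutoff`. Under a uniform distribution
#' this is `2 * cutoff`; nucleoid-excluded plasmids and polar replication
#' events exceed it.
#'
#' @param positions numeric vector in `[0, 1]`.
#' @param cutoff polar zone half-width as a fraction of cell length, in
#'   `(0, 0.5]`; default 0.2 (the pole-to-20%-of-length zone).
#' @return Scalar fraction.
#' @examples
#' polar_fraction(c(0.05, 0.5, 0.95)) # 2/3
#' @export
polar_fraction <- function(positions, cutoff = 0.2) {
  check_num(cutoff, "cutoff", lower = 0, upper = 0.5, strict_lower = TRUE)
  positions <- as.numeric(positions)
  if (any(positions < 0 | positions > 1))
    stop("positions must lie in [0, 1]", call. = FALSE)
  if (!length(positions)) return(NA_real_)
  mean(pmin(positions, 1 - positions) <= cutoff)
}

#' Fraction of positions inside a midcell band
#'
#' Fraction of relative positions falling inside `band` (default the
#' one-fourth to three-fourths region where chromosomal replisomes are
#' found). With `fold = TRUE` positions are first folded onto `[0, 0.5]`
#' (distance from the nearest pole, the "only half of the cell" plotting
#' convention) and the band is interpreted on that half-cell axis.
#'
#' @param positions numeric vector in `[0, 1]`.
#' @param band length-2 numeric, `0 <= band[1] < band[2] <= 1`.
#' @param fold fold positions to distance-from-pole before classifying?
#' @return Scalar fraction.
#' @examples
#' classify_midcell_band(c(0.1, 0.5, 0.6)) # 2/3
#' @export
classify_midcell_band <- function(positions, band = c(0.25, 0.75),
                                  fold = FALSE) {
  positions <- as.numeric(positions)
  if (any(positions < 0 | positions > 1))
    stop("positions must lie in [0, 1]", call. = FALSE)
  if (length(band) != 2L || band[1] >= band[2])
    stop("'band' must be an increasing pair", call. = FALSE)
  if (fold) positions <- pmin(positions, 1 - positions)
  if (!length(positions)) return(NA_real_)
  mean(positions >= band[1] & positions <= band[2])
}

#' Localize fluorescent spots in a 2D image
#'
#' Minimal spot finder for synthetic images: candidate pixels must exceed a
#' threshold of background mean + 3 background SD and be strict local
#' maxima over their 8-neighbourhood, and are then refined by a
#' background-subtracted intensity centroid in a square window on the raw
#' image. Background statistics are estimated robustly (median and MAD, so
#' bright spots do not inflate them), and candidate detection runs on a
#' 3x3 mean-filtered copy of the image: smoothing suppresses single-pixel
#' noise excursions (which would otherwise cross a 3-SD threshold about
#' once per thousand pixels) while leaving diffraction-sized spots nearly
#' untouched. This is analysis plumbing, not a tracking method.
#'
#' @param image numeric matrix.
#' @param threshold absolute intensity threshold on the smoothed image;
#'   default `median(image) + 3 * mad(image)` of the raw image.
#' @param window centroid half-width in pixels.
#' @return Data frame with columns `x` (column coordinate), `y` (row
#'   coordinate) and `amplitude` (background-subtracted peak height); zero
#'   rows when nothing is detected.
#' @examples
#' img <- gen_spot_image(cbind(20, 12), amplitude = 80, psf_sd = 1.5,
#'                       noise_sd = 1, shape = c(32, 32), seed = 1)
#' localize_spots(img)
#' @export
localize_spots <- function(image, threshold = NULL, window = 3) {
  if (!is.matrix(image)) stop("'image' must be a matrix", call. = FALSE)
  bg <- stats::median(image)
  bg_sd <- stats::mad(image)
  if (is.null(threshold)) threshold <- bg + 3 * bg_sd
  nr <- nrow(image); nc <- ncol(image)
  sm <- mean_filter3(image)
  hits <- which(sm > threshold, arr.ind = TRUE)
  out <- data.frame(x = numeric(0), y = numeric(0), amplitude = numeric(0))
  if (!nrow(hits)) return(out)
  for (k in seq_len(nrow(hits))) {
    r <- hits[k, 1]; c <- hits[k, 2]
    rr <- max(1, r - 1):min(nr, r + 1)
    cc <- max(1, c - 1):min(nc, c + 1)
    neigh <- sm[rr, cc]
    if (sm[r, c] < max(neigh)) next
    if (sum(neigh == max(neigh)) > 1L && !(which.max(neigh) ==
        which(rr == r) + (which(cc == c) - 1L) * length(rr))) next
    rr <- max(1, r - window):min(nr, r + window)
    cc <- max(1, c - window):min(nc, c + window)
    patch <- pmax(image[rr, cc] - bg, 0)
    tot <- sum(patch)
    if (tot <= 0) next
    y <- sum(rr * rowSums(patch)) / tot
    x <- sum(cc * colSums(patch)) / tot
    out <- rbind(out, data.frame(x = x, y = y,
                                 amplitude = image[r, c] - bg))
  }
  # merge detections closer than one window (plateau duplicates)
  if (nrow(out) > 1L) {
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out) - 1L)) {
      if (!keep[i]) next
      for (j in (i + 1L):nrow(out)) {
        if (keep[j] && (out$x[i] - out$x[j])^2 + (out$y[i] - out$y[j])^2 <
            window^2) keep[j] <- FALSE
      }
    }
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
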