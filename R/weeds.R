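#' Sobel edge-magnitude filter
#'
#' Gradient magnitude from 3x3 Sobel kernels with reflect padding,
#' normalised to \[0, 1\] by the image's maximum response (an all-flat
#' image returns all zeros). Invariant to additive intensity offsets.
#'
#' @param image single-channel intensity matrix.
#' @return edge-magnitude raster in \[0, 1\].
#' @export
edge_filter <- function(image) {
  .assert(.is_raster(image), "image must be a single-channel numeric matrix")
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)        # d/dx (cols)
  ky <- t(kx)                                                 # d/dy (rows)
  mag <- sqrt(.conv2_reflect(image, kx)^2 + .conv2_reflect(image, ky)^2)
  mx <- max(mag)
  if (mx > 0) mag <- mag / mx
  mag
}

#' Green-excess channel
#'
#' Reduces an RGB image to 2G - R - B (rescaled to \[0, 1\]), which
#' emphasises green vegetation against soil; used ahead of the entropy
#' filter when colour input is available. Grey matrices pass through.
#'
#' @param im RGB array or matrix.
#' @return intensity matrix in \[0, 1\].
#' @export
green_excess <- function(im) {
  if (is.matrix(im)) return(im)
  g <- 2 * im[, , 2] - im[, , 1] - im[, , 3]   # range [-2, 2]
  (g + 2) / 4
}

#' Local Shannon entropy of grey texture
#'
#' Per pixel, the base-2 Shannon entropy of the `n_levels`-bin grey
#' histogram over a centred square window (reflect padding at the
#' borders; for even window sizes the window spans `floor((w-1)/2)`
#' pixels above/left and `w - 1 - floor((w-1)/2)` below/right of the
#' centre). Grass presents high-frequency, multi-directional texture and
#' scores high; smooth dock leaves score low — the discriminator this
#' module's segmentation relies on.
#'
#' Implemented as one box filter per grey level via integral images, so
#' cost is linear in pixels times `n_levels`.
#'
#' @param image intensity matrix in \[0, 1\] (use [green_excess()] or
#'   [as_luminance()] first for colour input).
#' @param window_px window side in pixels (>= 2; classic choice 32).
#' @param n_levels grey quantisation levels (>= 2).
#' @return an `entropy_map`: list with `entropy` raster (bits, in
#'   \[0, log2(n_levels)\]), `window_px`, `n_levels`.
#' @export
local_entropy <- function(image, window_px = 32, n_levels = 64) {
  .assert(.is_raster(image), "image must be a numeric matrix")
  .assert(window_px >= 2, "window_px must be >= 2")
  .assert(n_levels >= 2, "n_levels must be >= 2")
  nr <- nrow(image); nc <- ncol(image)
  lw <- (window_px - 1L) %/% 2L
  rw <- window_px - 1L - lw
  qi <- pmin(floor(pmin(pmax(image, 0), 1) * n_levels), n_levels - 1L)
  pad <- .pad_reflect(qi, lw, rw, lw, rw)
  npix <- window_px^2
  ent <- matrix(0, nr, nc)
  for (lev in 0:(n_levels - 1L)) {
    ind <- (pad == lev) * 1
    if (!any(ind > 0)) next
    # integral image -> per-window counts
    S <- apply(apply(ind, 2, cumsum), 1, cumsum)  # transposed integral
    S <- rbind(0, cbind(0, t(S)))
    cnt <- S[(window_px + 1):(nr + window_px), (window_px + 1):(nc + window_px)] -
      S[1:nr, (window_px + 1):(nc + window_px)] -
      S[(window_px + 1):(nr + window_px), 1:nc] + S[1:nr, 1:nc]
    pr <- cnt / npix
    nz <- pr > 0
    ent[nz] <- ent[nz] - pr[nz] * log2(pr[nz])
  }
  structure(list(entropy = ent, window_px = window_px, n_levels = n_levels),
            class = "entropy_map")
}

#' @export
print.entropy_map <- function(x, ...) {
  cat(sprintf("entropy_map: %d x %d px, window %d px, %d levels, range [%.2f, %.2f] bits\n",
              nrow(x$entropy), ncol(x$entropy), x$window_px, x$n_levels,
              min(x$entropy), max(x$entropy)))
  invisible(x)
}

# Otsu threshold on a numeric vector (256-bin histogram)
.otsu <- function(v, nbin = 256) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(floor((v - rng[1]) / diff(rng) * nbin) + 1L, nbin), nbin)
  w <- h / sum(h)
  omega <- cumsum(w)
  centers <- rng[1] + (seq_len(nbin) - 0.5) / nbin * diff(rng)
  mu <- cumsum(w * centers)
  mu_t <- mu[nbin]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  centers[which.max(sigma_b)]
}

# region table for a binary mask
.mask_regions <- function(mask) {
  if (!any(mask))
    return(data.frame(label = integer(0), area = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0)))
  cc <- EBImage::bwlabel(mask)
  ri <- row(mask); ci <- col(mask)
  labs <- seq_len(max(cc))
  data.frame(
    label = labs,
    area = as.integer(tabulate(cc[cc > 0], max(cc))),
    centroid_row = vapply(labs, function(l) mean(ri[cc == l]), 0),
    centroid_col = vapply(labs, function(l) mean(ci[cc == l]), 0))
}

.weed_mask <- function(mask) {
  structure(list(mask = mask, regions = .mask_regions(mask),
                 coverage_fraction = mean(mask)),
            class = "weed_mask")
}

#' @export
print.weed_mask <- function(x, ...) {
  cat(sprintf("weed_mask: %d x %d px, %d region(s), coverage %.1f%%\n",
              nrow(x$mask), ncol(x$mask), nrow(x$regions),
              100 * x$coverage_fraction))
  invisible(x)
}

# odd-sized disc brush (EBImage brushes must be odd)
.disc <- function(px) EBImage::makeBrush(max(3L, 2L * (px %/% 2L) + 1L), "disc")

#' Segment dock leaves by low texture entropy
#'
#' Thresholds the local-entropy map (dock leaves are smooth, hence
#' low-entropy, against high-entropy grass), cleans the binary mask by
#' morphological opening then closing with disc elements, and removes
#' components smaller than `min_area_px`.
#'
#' When `threshold_bits` is `NULL` the threshold is chosen
#' automatically: Otsu's method on the entropy map, accepted only when
#' the resulting low class is genuinely low-entropy (class-mean ratio
#' below `auto_ratio`). Dock and grass entropies differ multiplicatively
#' (smooth leaf vs fine texture), so the ratio test keeps the automatic
#' threshold from hallucinating dock in a pure-grass scene, where Otsu
#' would otherwise split the unimodal entropy distribution in half.
#'
#' @param entropy an [local_entropy()] result.
#' @param threshold_bits manual threshold in bits, or `NULL` for
#'   automatic selection.
#' @param open_px,close_px disc diameters (px) for opening and closing.
#' @param min_area_px minimum connected-component area kept.
#' @param auto_ratio acceptance bound on (mean entropy below threshold)
#'   / (mean entropy above threshold) for the automatic threshold.
#' @return a `weed_mask`: binary `mask`, `regions` table (label, area,
#'   centroid), and `coverage_fraction`.
#' @export
segment_dock <- function(entropy, threshold_bits = NULL, open_px = 5,
                         close_px = 9, min_area_px = 200, auto_ratio = 0.75) {
  .assert(inherits(entropy, "entropy_map"),
          "entropy must come from local_entropy()")
  E <- entropy$entropy
  emax <- log2(entropy$n_levels)
  if (is.null(threshold_bits)) {
    thr <- .otsu(as.vector(E))
    lo <- E < thr
    if (!any(lo) || !any(!lo) ||
        mean(E[lo]) >= auto_ratio * mean(E[!lo]))
      return(.weed_mask(matrix(FALSE, nrow(E), ncol(E))))
    threshold_bits <- thr
  }
  .assert(threshold_bits >= 0 && threshold_bits <= emax,
          "threshold_bits must lie in [0, log2(n_levels)] = [0, %.2f]", emax)
  mask <- E < threshold_bits
  if (any(mask) && open_px > 1)
    mask <- EBImage::opening(mask, .disc(open_px)) > 0
  if (any(mask) && close_px > 1)
    mask <- EBImage::closing(mask, .disc(close_px)) > 0
  if (any(mask) && min_area_px > 0) {
    cc <- EBImage::bwlabel(mask)
    if (max(cc) > 0) {
      areas <- tabulate(cc[cc > 0], max(cc))
      keep <- which(areas >= min_area_px)
      mask <- matrix(cc %in% keep, nrow(mask), ncol(mask)) & mask
    }
  }
  .weed_mask(mask)
}

#' Fuse a weed mask with a depth range threshold
#'
#' Combining 3D range thresholding with the 2D entropy segmentation
#' improves reliability: mask pixels are retained only where the
#' co-registered depth lies in `[z_min, z_max]`; regions and coverage
#' are recomputed on the fused mask.
#'
#' @param mask a `weed_mask` from [segment_dock()].
#' @param depth co-registered depth raster or [depth_map()].
#' @param z_min,z_max retained depth band (inclusive).
#' @return a new `weed_mask`.
#' @export
range_threshold_fuse <- function(mask, depth, z_min, z_max) {
  z <- if (inherits(depth, "depth_map")) depth$z else depth
  .assert(identical(dim(z), dim(mask$mask)),
          "depth (%d x %d) is not co-registered with the mask (%d x %d)",
          nrow(z), ncol(z), nrow(mask$mask), ncol(mask$mask))
  .weed_mask(mask$mask & !is.na(z) & z >= z_min & z <= z_max)
}
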