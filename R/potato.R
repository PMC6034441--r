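#' Conveyor depth frame
#'
#' One depth capture from the harvester's downward-looking RGB-D camera:
#' per-pixel distance from the camera in mm, a half-open region of
#' interest `(row0, col0, row1, col1)` (0-based, end-exclusive) covering
#' the conveyor belt, and a capture timestamp in seconds.
#'
#' @param depth depth raster, mm from camera (> 0 where valid).
#' @param roi integer vector (row0, col0, row1, col1), half-open,
#'   0-based; default: the whole frame.
#' @param timestamp capture time, seconds.
#' @param pixel_pitch mm per pixel on the belt plane.
#' @return a `depth_frame` object.
#' @export
depth_frame <- function(depth, roi = NULL, timestamp = 0, pixel_pitch = 1) {
  .assert(.is_raster(depth), "depth must be a numeric matrix")
  if (is.null(roi)) roi <- c(0L, 0L, nrow(depth), ncol(depth))
  .assert(length(roi) == 4 && roi[1] >= 0 && roi[2] >= 0 &&
            roi[3] <= nrow(depth) && roi[4] <= ncol(depth) &&
            roi[3] > roi[1] && roi[4] > roi[2],
          "roi must be (row0, col0, row1, col1), half-open, inside the frame")
  .assert(all(depth[!is.na(depth)] > 0), "depth must be > 0 mm where valid")
  structure(list(depth = depth, roi = as.integer(roi),
                 timestamp = timestamp, pixel_pitch = pixel_pitch),
            class = "depth_frame")
}

#' @export
print.depth_frame <- function(x, ...) {
  cat(sprintf("depth_frame: %d x %d px, roi [%d:%d, %d:%d), t = %.2f s\n",
              nrow(x$depth), ncol(x$depth), x$roi[1], x$roi[3], x$roi[2],
              x$roi[4], x$timestamp))
  invisible(x)
}

#' Normalise a depth frame to height above the belt
#'
#' Estimates the conveyor-belt plane by a robust least-squares plane fit
#' to the deepest `belt_percentile` percent of ROI pixels (tubers are
#' nearer the camera than the belt, so the deep fraction is belt), with
#' two trimming reweight passes against outliers, then returns
#' `plane - depth`: mm above the belt, clamped at zero. Pixels outside
#' the ROI are set to `NA`.
#'
#' @param frame a [depth_frame()].
#' @param belt_percentile percent of deepest ROI pixels assumed to be
#'   belt (50-100).
#' @return height raster (mm above belt) with attributes `pixel_pitch`,
#'   `timestamp`, `roi` and class `height_map`.
#' @export
normalize_depth <- function(frame, belt_percentile = 60) {
  .assert(inherits(frame, "depth_frame"), "frame must be a depth_frame")
  .assert(belt_percentile >= 50 && belt_percentile <= 100,
          "belt_percentile must be in [50, 100]")
  roi <- frame$roi
  rr <- (roi[1] + 1L):roi[3]; cc <- (roi[2] + 1L):roi[4]
  d <- frame$depth[rr, cc]
  ri <- row(d); ci <- col(d)
  ok <- is.finite(d)
  thr <- quantile(d[ok], 1 - belt_percentile / 100, names = FALSE)
  sel <- ok & d >= thr
  .assert(sum(sel) >= 100,
          "too few belt pixels (%d) to fit the belt plane", sum(sel))
  X <- cbind(1, ci[sel], ri[sel])
  y <- d[sel]
  beta <- qr.solve(X, y)
  for (it in 1:2) {                      # trim gross outliers, refit
    res <- y - X %*% beta
    keep <- abs(res) <= 3 * max(mad(res), 1e-6)
    if (sum(keep) >= 100) beta <- qr.solve(X[keep, , drop = FALSE], y[keep])
  }
  plane <- beta[1] + beta[2] * ci + beta[3] * ri
  h <- pmax(plane - d, 0)
  out <- matrix(NA_real_, nrow(frame$depth), ncol(frame$depth))
  out[rr, cc] <- h
  structure(out, class = c("height_map", "matrix", "array"),
            pixel_pitch = frame$pixel_pitch, timestamp = frame$timestamp,
            roi = roi)
}

#' Detect tuber candidate regions on the belt
#'
#' Connected components of pixels at least `min_height_mm` above the
#' belt with area at least `min_area_px`. Touching tubers may appear
#' merged as a single region at this stage; [fit_and_split()] separates
#' them using the 3D surface.
#'
#' @param heights height raster from [normalize_depth()].
#' @param min_height_mm detection height threshold (> 0).
#' @param min_area_px minimum component area in pixels.
#' @return list of regions, each a list with `pixels` (linear indices
#'   into the raster), `area`, `bbox` (row0, col0, row1, col1,
#'   half-open, 0-based).
#' @export
detect_tubers <- function(heights, min_height_mm = 8, min_area_px = 150) {
  .assert(min_height_mm > 0, "min_height_mm must be > 0")
  mask <- !is.na(heights) & heights >= min_height_mm
  if (!any(mask)) return(list())
  cc <- EBImage::bwlabel(mask)
  out <- list()
  for (l in seq_len(max(cc))) {
    idx <- which(cc == l)
    if (length(idx) < min_area_px) next
    rws <- ((idx - 1L) %% nrow(mask)) + 1L
    cls <- ((idx - 1L) %/% nrow(mask)) + 1L
    out[[length(out) + 1L]] <- list(
      pixels = idx, area = length(idx),
      bbox = c(min(rws) - 1L, min(cls) - 1L, max(rws), max(cls)))
  }
  out
}

# --- ellipsoid fitting ------------------------------------------------------

# rotation matrix from a rotation vector (Rodrigues)
.rotvec <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# signed Sampson (gradient-normalised algebraic) distances from points to
# an ellipsoid surface, in mm: F / |grad F| with F = sum((y_i/a_i)^2) - 1.
# First-order approximation to true geometric distance, well behaved at
# the equator where ray-based distances degenerate.
.ellipsoid_residuals <- function(center, axes, R, pts) {
  y <- sweep(pts, 2, center) %*% R            # body coordinates
  u <- sweep(y, 2, axes, "/")
  F <- rowSums(u^2) - 1
  g <- 2 * sweep(u, 2, axes, "/")
  F / pmax(sqrt(rowSums(g^2)), 1e-9)
}

#' Fit an ellipsoid to 3D surface points
#'
#' Least-squares ellipsoid through the visible top-surface point cloud
#' of a tuber. The algebraic stage uses an ellipsoid-specific
#' constrained quadric fit (the `4J - I^2 > 0` constraint solved as a
#' generalized eigenproblem), which cannot return hyperboloid or
#' paraboloid solutions — important here because only the upper half of
#' each tuber is visible to the camera. The geometric stage optionally
#' refines centre, semi-axes and orientation by quasi-Newton
#' minimisation of gradient-normalised (Sampson) point-to-surface
#' distances, which removes most of the noise-induced axis inflation of
#' the algebraic stage.
#'
#' @param points N x 3 matrix of (x, y, z) coordinates in mm, N >= 30,
#'   non-coplanar.
#' @param refine run the geometric refinement stage (default TRUE).
#' @param max_refine_points subsample size for the refinement stage.
#' @return an `ellipsoid`: list with `center` (mm), `semi_axes`
#'   (a >= b >= c, mm), `orientation` (3x3, columns = body axes in
#'   camera frame), `rms_residual` (mm), `fit_ok` (FALSE for degenerate
#'   or non-ellipsoidal solutions).
#' @export
fit_ellipsoid <- function(points, refine = TRUE, max_refine_points = 500) {
  points <- as.matrix(points)
  .assert(ncol(points) == 3, "points must be N x 3")
  .assert(nrow(points) >= 30, "need at least 30 points (got %d)", nrow(points))
  sv <- svd(scale(points, scale = FALSE))$d
  .assert(sv[3] > 1e-9 * sv[1], "points are coplanar; cannot fit an ellipsoid")
  fail <- structure(list(center = rep(NA_real_, 3), semi_axes = rep(NA_real_, 3),
                         orientation = diag(3), rms_residual = NA_real_,
                         fit_ok = FALSE), class = "ellipsoid")
  mu <- colMeans(points)
  sc <- sqrt(mean(rowSums(sweep(points, 2, mu)^2)))
  P <- sweep(points, 2, mu) / sc
  x <- P[, 1]; y <- P[, 2]; z <- P[, 3]
  D1 <- cbind(x^2, y^2, z^2, 2 * y * z, 2 * x * z, 2 * x * y)
  D2 <- cbind(2 * x, 2 * y, 2 * z, 1)
  S11 <- crossprod(D1); S12 <- crossprod(D1, D2); S22 <- crossprod(D2)
  S22i <- tryCatch(solve(S22), error = function(e) NULL)
  if (is.null(S22i)) return(fail)
  C1i <- rbind(c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
  Ci <- rbind(cbind(C1i, matrix(0, 3, 3)),
              cbind(matrix(0, 3, 3), diag(-0.25, 3)))
  M <- Ci %*% (S11 - S12 %*% S22i %*% t(S12))
  ev <- tryCatch(eigen(M), error = function(e) NULL)
  if (is.null(ev)) return(fail)
  vals <- Re(ev$values); vecs <- Re(ev$vectors)
  # the ellipsoid solution has the unique positive eigenvalue; with exact
  # (residual-free) data that eigenvalue degenerates to ~0, so accept
  # near-zero candidates and keep the first that extracts a real ellipsoid
  cand <- order(vals, decreasing = TRUE)
  cand <- cand[vals[cand] > -1e-6 * max(abs(vals))]
  extracted <- NULL
  for (ci in cand) {
    u1 <- vecs[, ci]
    u2 <- -S22i %*% t(S12) %*% u1
    Q <- matrix(c(u1[1], u1[6], u1[5],
                  u1[6], u1[2], u1[4],
                  u1[5], u1[4], u1[3]), 3, 3)
    bv <- u2[1:3]; d <- u2[4]
    Qi <- tryCatch(solve(Q), error = function(e) NULL)
    if (is.null(Qi)) next
    center_n <- as.numeric(-Qi %*% bv)
    dc <- as.numeric(bv %*% Qi %*% bv) - d
    eq <- eigen(Q, symmetric = TRUE)
    lam <- eq$values
    if (dc < 0) { lam <- -lam; dc <- -dc }
    if (any(lam <= 0) || dc <= 0) next
    extracted <- list(center_n = center_n, axes_n = sqrt(dc / lam),
                      Rm = eq$vectors)
    break
  }
  if (is.null(extracted)) return(fail)
  center_n <- extracted$center_n
  axes_n <- extracted$axes_n
  Rm <- extracted$Rm
  center <- mu + sc * center_n
  axes <- sc * axes_n
  if (refine) {
    idx <- if (nrow(points) > max_refine_points)
      round(seq(1, nrow(points), length.out = max_refine_points)) else
        seq_len(nrow(points))
    pts <- points[idx, , drop = FALSE]
    par0 <- c(center, log(axes), 0, 0, 0)
    scale0 <- sqrt(mean(axes^2))
    objfn <- function(par) {
      # trust region: keep the refinement near the algebraic solution,
      # out-of-band axes or centres mark a degenerate search direction
      if (any(!is.finite(par)) || any(abs(par[4:6] - par0[4:6]) > log(3)) ||
          sqrt(sum((par[1:3] - par0[1:3])^2)) > 2 * scale0)
        return(1e12)
      ax <- exp(par[4:6])
      R <- Rm %*% .rotvec(par[7:9])
      v <- sum(.ellipsoid_residuals(par[1:3], ax, R, pts)^2)
      if (!is.finite(v)) 1e12 else v
    }
    fit <- tryCatch(
      optim(par0, objfn, method = "BFGS", control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$value <= objfn(par0)) {
      center <- fit$par[1:3]
      axes <- exp(fit$par[4:6])
      Rm <- Rm %*% .rotvec(fit$par[7:9])
    }
  }
  ord <- order(axes, decreasing = TRUE)
  axes <- axes[ord]
  Rm <- Rm[, ord, drop = FALSE]
  if (det(Rm) < 0) Rm[, 3] <- -Rm[, 3]
  rms <- sqrt(mean(.ellipsoid_residuals(center, axes, Rm, points)^2))
  structure(list(center = center, semi_axes = axes, orientation = Rm,
                 rms_residual = rms, fit_ok = TRUE),
            class = "ellipsoid")
}

#' @export
print.ellipsoid <- function(x, ...) {
  if (!x$fit_ok) { cat("ellipsoid: fit failed\n"); return(invisible(x)) }
  cat(sprintf("ellipsoid: semi-axes (%.1f, %.1f, %.1f) mm, centre (%.1f, %.1f, %.1f) mm, rms %.2f mm\n",
              x$semi_axes[1], x$semi_axes[2], x$semi_axes[3],
              x$center[1], x$center[2], x$center[3], x$rms_residual))
  invisible(x)
}

# 3D points (x, y, z) mm for a region of a height map
.region_points <- function(region, heights, pixel_pitch, min_h = 0.5) {
  idx <- region$pixels
  h <- heights[idx]
  keep <- is.finite(h) & h > min_h
  idx <- idx[keep]; h <- h[keep]
  rws <- ((idx - 1L) %% nrow(heights))
  cls <- ((idx - 1L) %/% nrow(heights))
  cbind(x = cls * pixel_pitch, y = rws * pixel_pitch, z = h)
}

#' Fit ellipsoids to a candidate region, splitting touching tubers
#'
#' Fits one ellipsoid to the region's 3D surface points. If the RMS
#' point-to-surface residual is within `max_residual_mm` the region is
#' accepted as a single tuber; otherwise the region is split at the
#' watershed of its height map between local maxima and each part is
#' fitted separately, recursing at most `max_depth` times. Regions that
#' cannot be split further but still fit poorly (flat debris, clods) are
#' returned flagged `low_confidence` rather than raising an error.
#'
#' @param region one region from [detect_tubers()].
#' @param heights height raster from [normalize_depth()].
#' @param pixel_pitch mm per pixel.
#' @param max_residual_mm acceptance bound on RMS surface residual.
#' @param watershed_tol_mm minimum peak-to-saddle height difference for
#'   the watershed to treat two maxima as distinct tubers.
#' @param max_depth maximum split recursion depth.
#' @param boundary_trim_px split-part pixels within this distance of the
#'   watershed boundary are excluded from the fit (contact-zone heights
#'   belong to whichever tuber is taller, and bias the fit upward).
#' @return list of `ellipsoid` objects, each with extra fields `pixels`
#'   (the supporting pixel indices) and `low_confidence`.
#' @export
fit_and_split <- function(region, heights, pixel_pitch,
                          max_residual_mm = 3, watershed_tol_mm = 3,
                          max_depth = 2, boundary_trim_px = 5) {
  pts <- .region_points(region, heights, pixel_pitch)
  flagged <- function(e, low) { e$pixels <- region$pixels; e$low_confidence <- low; list(e) }
  failed <- structure(list(center = rep(NA_real_, 3),
                           semi_axes = rep(NA_real_, 3),
                           orientation = diag(3), rms_residual = NA_real_,
                           fit_ok = FALSE), class = "ellipsoid")
  if (nrow(pts) < 30) return(flagged(failed, TRUE))
  # degenerate (e.g. coplanar debris) point sets flag rather than abort
  e <- tryCatch(fit_ellipsoid(pts), error = function(err) failed)
  if (e$fit_ok && e$rms_residual <= max_residual_mm)
    return(flagged(e, FALSE))
  if (max_depth <= 0) return(flagged(e, TRUE))
  # watershed split between the region's height maxima
  hm <- matrix(0, nrow(heights), ncol(heights))
  hm[region$pixels] <- pmax(heights[region$pixels], 0)
  hs <- .gauss_smooth(hm, 1.5)
  hs[hm <= 0] <- 0
  ws <- EBImage::watershed(hs, tolerance = watershed_tol_mm, ext = 2)
  ws <- as.integer(ws)                      # flatten Image -> labels
  labs <- unique(ws[region$pixels])
  labs <- labs[labs > 0]
  if (length(labs) < 2) return(flagged(e, TRUE))
  out <- list()
  for (l in labs) {
    idx <- region$pixels[ws[region$pixels] == l]
    if (length(idx) < 30) next
    # in the contact zone the height map is the max of both tuber
    # surfaces, which sits above either one; points near the watershed
    # boundary are therefore excluded from the fit (but kept in the
    # record's pixel support)
    other <- matrix(FALSE, nrow(heights), ncol(heights))
    other[region$pixels[ws[region$pixels] > 0 &
                          ws[region$pixels] != l]] <- TRUE
    near <- EBImage::dilate(other,
                            EBImage::makeBrush(2 * boundary_trim_px + 1,
                                               "disc")) > 0
    fit_idx <- idx[!near[idx]]
    if (length(fit_idx) < 30) fit_idx <- idx
    sub <- list(pixels = fit_idx, area = length(fit_idx))
    part <- fit_and_split(sub, heights, pixel_pitch, max_residual_mm,
                          watershed_tol_mm, max_depth - 1,
                          boundary_trim_px)
    for (pe in part) { pe$pixels <- idx; out <- c(out, list(pe)) }
  }
  if (length(out) == 0) flagged(e, TRUE) else out
}

#' Tuber dimensions from a fitted ellipsoid
#'
#' Length, width and height are the sorted ellipsoid diameters
#' (2a, 2b, 2c), invariant to the ellipsoid's orientation.
#'
#' @param e an [fit_ellipsoid()] result.
#' @return named numeric vector (length, width, height) in mm.
#' @export
tuber_dimensions <- function(e) {
  .assert(inherits(e, "ellipsoid") && isTRUE(e$fit_ok), "need a valid ellipsoid")
  setNames(2 * e$semi_axes, c("length", "width", "height"))
}

#' Measurement accuracy relative to the vision estimate
#'
#' Percentage agreement between a caliper ground-truth measurement and
#' the vision system's estimate, with the error taken relative to the
#' estimate: `100 * (1 - |true - est| / est)`. Exact estimates score
#' 100; gross errors can score below zero. Vectorised.
#'
#' @param true_mm caliper measurement, mm (> 0).
#' @param est_mm vision estimate, mm (> 0).
#' @return accuracy percent.
#' @export
accuracy_percent <- function(true_mm, est_mm) {
  .assert(all(true_mm > 0) && all(est_mm > 0),
          "measurements must be positive")
  100 * (1 - abs(true_mm - est_mm) / est_mm)
}

#' Measure all tubers in a depth frame
#'
#' End-to-end metrology for one conveyor frame: belt normalisation
#' ([normalize_depth()]), candidate detection ([detect_tubers()]),
#' ellipsoid fitting with touching-tuber splitting ([fit_and_split()]),
#' then sizing ([tuber_dimensions()], [sieve_size()], [size_band()]).
#'
#' @param frame a [depth_frame()].
#' @param band_edges sieve-size band edges, mm (see [size_band()]).
#' @param min_height_mm,min_area_px detection thresholds.
#' @param max_residual_mm ellipsoid acceptance residual.
#' @param belt_percentile belt-plane estimation fraction.
#' @return data.frame of tuber records: `length`, `width`, `height`,
#'   `sieve_size` (mm), `band`, `centroid_row`, `centroid_col` (px),
#'   `timestamp` (s), `confidence` ("high"/"low"), `rms_mm`.
#' @export
measure_tubers <- function(frame, band_edges = c(45, 65, 80),
                           min_height_mm = 8, min_area_px = 150,
                           max_residual_mm = 3, belt_percentile = 60) {
  heights <- normalize_depth(frame, belt_percentile)
  regions <- detect_tubers(heights, min_height_mm, min_area_px)
  rec <- list()
  for (reg in regions) {
    for (e in fit_and_split(reg, heights, frame$pixel_pitch,
                            max_residual_mm)) {
      rws <- ((e$pixels - 1L) %% nrow(heights)) + 1L
      cls <- ((e$pixels - 1L) %/% nrow(heights)) + 1L
      if (isTRUE(e$fit_ok)) {
        dims <- setNames(2 * e$semi_axes, NULL)
      } else {
        # bounding-box fallback sizing for failed fits
        ext <- sort(c(diff(range(rws)) + 1, diff(range(cls)) + 1),
                    decreasing = TRUE) * frame$pixel_pitch
        dims <- c(ext, max(heights[e$pixels], na.rm = TRUE))
      }
      sv <- sieve_size(dims[2], min(dims[2], dims[3]))
      rec[[length(rec) + 1L]] <- data.frame(
        length = dims[1], width = dims[2], height = dims[3],
        sieve_size = sv, band = size_band(sv, band_edges),
        centroid_row = mean(rws), centroid_col = mean(cls),
        timestamp = frame$timestamp,
        confidence = if (isTRUE(e$low_confidence)) "low" else "high",
        rms_mm = if (is.null(e$rms_residual)) NA_real_ else e$rms_residual)
    }
  }
  if (length(rec) == 0)
    return(data.frame(length = numeric(0), width = numeric(0),
                      height = numeric(0), sieve_size = numeric(0),
                      band = character(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), timestamp = numeric(0),
                      confidence = character(0), rms_mm = numeric(0)))
  do.call(rbind, rec)
}
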