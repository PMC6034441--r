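#' Lambertian reflectance map
#'
#' Predicted radiance of a Lambertian surface element with gradient
#' (p, q) and albedo `albedo`, lit from gradient-space direction
#' (ps, qs):
#' \deqn{R(p,q) = \varrho \frac{1 + p\,p_s + q\,q_s}
#'   {\sqrt{1+p^2+q^2}\,\sqrt{1+p_s^2+q_s^2}}}
#' which equals albedo times the cosine between the unit surface normal
#' \[-p,-q,1\]/|.| and the unit light vector \[-ps,-qs,1\]/|.|. Negative
#' values (surface facing away from the light, i.e. attached shadow) are
#' clamped to zero, matching physical capture.
#'
#' All arguments are vectorised.
#'
#' @param p,q surface gradients.
#' @param ps,qs light direction in gradient space.
#' @param albedo diffuse albedo, >= 0.
#' @return radiance value(s).
#' @export
#' @examples
#' reflectance_map(0, 0, 0, 0, 0.8)  # normal aligned with light: 0.8
#' reflectance_map(1, 0, 0, 0, 1)    # 1/sqrt(2)
reflectance_map <- function(p, q, ps, qs, albedo) {
  .assert(all(is.finite(p)) && all(is.finite(q)) && all(is.finite(ps)) &&
            all(is.finite(qs)) && all(is.finite(albedo)),
          "reflectance_map: all inputs must be finite")
  .assert(all(albedo >= 0), "albedo must be non-negative")
  r <- albedo * (1 + p * ps + q * qs) /
    (sqrt(1 + p^2 + q^2) * sqrt(1 + ps^2 + qs^2))
  pmax(r, 0)
}

#' Shadow / saturation validity mask
#'
#' A pixel is valid only if, in *every* image of the stack, its
#' intensity lies strictly inside `(low, high)`. This enforces, where it
#' can be checked, the Lambertian-PS assumption that surfaces are free
#' of cast and self shadows, and guards against sensor saturation.
#'
#' @param stack an [image_stack()].
#' @param low,high open-interval bounds on \[0, 1\] intensities.
#' @return logical matrix, `TRUE` where valid.
#' @export
shadow_mask <- function(stack, low = 0.02, high = 0.98) {
  .assert(low >= 0 && low < high && high <= 1, "need 0 <= low < high <= 1")
  Reduce(`&`, lapply(stack$images, function(im) im > low & im < high))
}

# shared pixel solver: I (k x N) intensities, M (k x 3) unit light rows,
# per-pixel image validity V (k x N logical). Returns scaled-normal G (3 x N)
# and logical solvable vector.
.ps_lstsq_pixels <- function(I, M, V) {
  k <- nrow(I); N <- ncol(I)
  G <- matrix(NA_real_, 3, N)
  nvalid <- colSums(V)
  solvable <- nvalid >= 3
  if (!any(solvable)) return(list(G = G, solvable = solvable))
  # group pixels by validity pattern so each distinct pattern is one
  # (pseudo)inverse and one matrix multiply
  pat <- colSums(V * 2^(seq_len(k) - 1))
  for (pv in unique(pat[solvable])) {
    idx <- which(pat == pv & solvable)
    rows <- which(bitwAnd(pv, 2^(seq_len(k) - 1)) > 0)
    Ms <- M[rows, , drop = FALSE]
    sv <- svd(Ms)
    if (sv$d[3] < 1e-10 * sv$d[1]) { solvable[idx] <- FALSE; next }
    pinv <- sv$v %*% (t(sv$u) / sv$d)
    G[, idx] <- pinv %*% I[rows, idx, drop = FALSE]
  }
  list(G = G, solvable = solvable)
}

.ps_fields_from_G <- function(G, solvable, d, pixel_pitch) {
  albedo <- sqrt(colSums(G^2))
  nz <- G[3, ] / albedo
  ok <- solvable & is.finite(albedo) & albedo > 0 & nz > 1e-12
  p <- q <- alb <- rep(NA_real_, length(albedo))
  p[ok] <- -G[1, ok] / G[3, ok]
  q[ok] <- -G[2, ok] / G[3, ok]
  alb[ok] <- albedo[ok]
  surface_fields(matrix(p, d[1], d[2]), matrix(q, d[1], d[2]),
                 matrix(alb, d[1], d[2]), matrix(ok, d[1], d[2]),
                 pixel_pitch = pixel_pitch)
}

#' Exact three-light photometric-stereo solve
#'
#' Per pixel, solves the 3x3 linear system I = M (albedo n) where the
#' rows of M are the unit light vectors, recovering the scaled normal;
#' the albedo is its Euclidean length and the unit normal its direction.
#' Three images suffice to determine normals and albedo uniquely
#' provided the light directions are not collinear in azimuth. Pixels
#' failing the shadow/saturation test in any image are flagged invalid.
#'
#' @param stack an [image_stack()] of exactly 3 images.
#' @param lights a [light_set()] of exactly 3 lights.
#' @param low,high shadow/saturation thresholds (see [shadow_mask()]).
#' @return a [surface_fields()] object.
#' @export
solve_ps_exact <- function(stack, lights, low = 0.02, high = 0.98) {
  .assert(length(stack$images) == 3, "solve_ps_exact needs exactly 3 images")
  .assert(length(lights$ps) == 3, "solve_ps_exact needs exactly 3 lights")
  .check_light_rank(lights)
  d <- dim(stack$images[[1]])
  I <- do.call(rbind, lapply(stack$images, as.vector))
  valid <- as.vector(shadow_mask(stack, low, high))
  V <- matrix(rep(valid, each = 3), 3)
  res <- .ps_lstsq_pixels(I, lights$L, V)
  .ps_fields_from_G(res$G, res$solvable, d, stack$pixel_pitch)
}

#' Least-squares multi-light photometric-stereo solve
#'
#' Per-pixel linear least squares for the scaled normal using all images
#' whose intensity at the pixel is inside the shadow/saturation band.
#' With four or more lights this improves on the three-light solve under
#' noise; with exactly three valid images it reduces to
#' [solve_ps_exact()]. Pixels with fewer than three usable intensities
#' are marked invalid rather than raising an error.
#'
#' @param stack an [image_stack()] of >= 3 images.
#' @param lights a [light_set()] with rank-3 unit light matrix.
#' @param low,high shadow/saturation thresholds.
#' @return a [surface_fields()] object.
#' @export
solve_ps_lsq <- function(stack, lights, low = 0.02, high = 0.98) {
  k <- length(stack$images)
  .assert(k >= 3, "least-squares PS needs at least 3 images (got %d)", k)
  .assert(length(lights$ps) == k,
          "lights (%d) must match stack images (%d)", length(lights$ps), k)
  .check_light_rank(lights)
  d <- dim(stack$images[[1]])
  I <- do.call(rbind, lapply(stack$images, as.vector))
  .assert(low >= 0 && low < high && high <= 1, "need 0 <= low < high <= 1")
  V <- do.call(rbind, lapply(stack$images,
                             function(im) as.vector(im > low & im < high)))
  res <- .ps_lstsq_pixels(I, lights$L, V)
  .ps_fields_from_G(res$G, res$solvable, d, stack$pixel_pitch)
}

#' Two-source x-gradient recovery for moving platforms
#'
#' A full multi-light solve cannot be used from a moving rig, because
#' the scene shifts between exposures. With just two lights placed
#' symmetrically along the camera's x axis (the travel direction),
#' the x-gradient is still recoverable per pixel from a single
#' simultaneous-capture pair: under the Lambertian reflectance map with
#' lights (ps, 0) and (-ps, 0),
#' \deqn{\frac{I_1 - I_2}{I_1 + I_2} = p\,p_s}
#' so `p = ((i1 - i2)/(i1 + i2)) / ps`. Albedo and the y-gradient cancel
#' exactly. Pixels whose summed intensity falls below `floor` are
#' flagged invalid.
#'
#' @param i1,i2 intensity rasters under the +ps and -ps lights.
#' @param lights a [light_set()] of exactly 2 lights with qs = 0 and
#'   opposite ps.
#' @param floor minimum `i1 + i2` for a valid pixel.
#' @return list with `p` (x-gradient raster) and `valid_mask`.
#' @export
two_source_gradient <- function(i1, i2, lights, floor = 1e-3) {
  .assert(.is_raster(i1) && .is_raster(i2) && identical(dim(i1), dim(i2)),
          "i1 and i2 must be numeric matrices of equal size")
  .assert(length(lights$ps) == 2, "two_source_gradient needs exactly 2 lights")
  tol <- 1e-9
  if (abs(lights$qs[1]) > tol || abs(lights$qs[2]) > tol ||
      abs(lights$ps[1] + lights$ps[2]) > tol || abs(lights$ps[1]) < tol)
    stop(paste("two-source lights must be symmetric about the camera x axis:",
               "qs = 0 for both and ps2 = -ps1 != 0"), call. = FALSE)
  s <- i1 + i2
  valid <- is.finite(s) & s > floor
  p <- matrix(NA_real_, nrow(i1), ncol(i1))
  p[valid] <- ((i1[valid] - i2[valid]) / s[valid]) / lights$ps[1]
  list(p = p, valid_mask = valid)
}
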