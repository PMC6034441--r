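#' Mean, Gaussian and principal curvatures of a depth map
#'
#' Treats the depth raster as a Monge patch z = f(x, y) and computes,
#' from Gaussian-smoothed central-difference derivatives, the full
#' (not small-slope) curvature expressions:
#' \deqn{K = \frac{f_{xx} f_{yy} - f_{xy}^2}{(1 + f_x^2 + f_y^2)^2}}
#' \deqn{H = \frac{(1+f_x^2) f_{yy} - 2 f_x f_y f_{xy} + (1+f_y^2) f_{xx}}
#'   {2 (1 + f_x^2 + f_y^2)^{3/2}}}
#' principal curvatures k1 >= k2 = H +- sqrt(max(H^2 - K, 0)), and the
#' scale-free shape index
#' \deqn{S = \frac{2}{\pi} \arctan\frac{k_2 + k_1}{k_2 - k_1} \in [-1, 1]}
#' undefined (NA) at umbilic flat points where k1 = k2.
#'
#' Leaf surfaces are not small-slope, hence the full first-derivative
#' terms are retained.
#'
#' @param depth a [depth_map()] or plain height matrix.
#' @param sigma Gaussian pre-smoothing scale in pixels (>= 0; 0 = none).
#' @return a `curvature_field`: list with rasters `H`, `K`, `k1`, `k2`,
#'   `S`, first derivatives `fx`, `fy`, and `sigma`.
#' @export
curvature_fields <- function(depth, sigma = 1) {
  z <- if (inherits(depth, "depth_map")) depth$z else depth
  .assert(.is_raster(z), "depth must be a numeric matrix or depth_map")
  .assert(sigma >= 0, "sigma must be >= 0")
  .assert(nrow(z) >= 5 && ncol(z) >= 5,
          "depth raster smaller than the differentiation stencil (need >= 5 px)")
  z <- .gauss_smooth(z, sigma)
  d1 <- .deriv_xy(z)
  fx <- d1$fx; fy <- d1$fy
  fxx <- .deriv_xy(fx)$fx
  fxy <- .deriv_xy(fx)$fy
  fyy <- .deriv_xy(fy)$fy
  g <- 1 + fx^2 + fy^2
  K <- (fxx * fyy - fxy^2) / g^2
  H <- ((1 + fx^2) * fyy - 2 * fx * fy * fxy + (1 + fy^2) * fxx) /
    (2 * g^(3 / 2))
  disc <- sqrt(pmax(H^2 - K, 0))
  k1 <- H + disc
  k2 <- H - disc
  S <- matrix(NA_real_, nrow(z), ncol(z))
  def <- k1 != k2
  S[def] <- (2 / pi) * atan((k2[def] + k1[def]) / (k2[def] - k1[def]))
  structure(list(H = H, K = K, k1 = k1, k2 = k2, S = S,
                 fx = fx, fy = fy, sigma = sigma),
            class = "curvature_field")
}

#' @export
print.curvature_field <- function(x, ...) {
  cat(sprintf("curvature_field: %d x %d px (sigma = %.2g)\n  H in [%.3g, %.3g], K in [%.3g, %.3g]\n",
              nrow(x$H), ncol(x$H), x$sigma, min(x$H), max(x$H), min(x$K), max(x$K)))
  invisible(x)
}

# HK surface-type label levels (fixed order; integer codes index this)
.hk_levels <- c("peak", "pit", "ridge", "valley", "saddle_ridge",
                "saddle_valley", "flat", "minimal")

#' HK segmentation of a curvature field
#'
#' Labels every pixel by the signs of mean curvature H and Gaussian
#' curvature K against thresholds `eps_H`, `eps_K`, using the standard
#' eight-class surface-type taxonomy (depth increasing toward the
#' camera, so a dome bulging at the viewer has H < 0, K > 0 and is
#' labelled `peak`):
#'
#' | H vs eps_H | K vs eps_K | label |
#' |---|---|---|
#' | ~0 | ~0 | flat |
#' | ~0 | < -eps | minimal |
#' | < -eps | > +eps | peak |
#' | > +eps | > +eps | pit |
#' | < -eps | ~0 | ridge |
#' | > +eps | ~0 | valley |
#' | < -eps | < -eps | saddle_ridge |
#' | > +eps | < -eps | saddle_valley |
#'
#' The combination |H| <= eps_H with K > eps_K cannot occur when
#' eps_K >= eps_H^2 (since K <= H^2); with other thresholds it is mapped
#' to `flat`.
#'
#' @param curv a [curvature_fields()] result.
#' @param eps_H mean-curvature zero band, 1/px (default 0.002).
#' @param eps_K Gaussian-curvature zero band, 1/px^2 (default 1e-5).
#' @return an `hk_labels` object: factor-coded integer `labels` matrix,
#'   the level set, per-label `counts`, and the thresholds used.
#' @export
hk_segment <- function(curv, eps_H = 0.002, eps_K = 1e-5) {
  .assert(eps_H > 0 && eps_K > 0, "eps_H and eps_K must be > 0")
  H <- curv$H; K <- curv$K
  sH <- (H > eps_H) - (H < -eps_H)
  sK <- (K > eps_K) - (K < -eps_K)
  lab <- matrix(7L, nrow(H), ncol(H))       # flat
  lab[sH == 0 & sK == -1] <- 8L             # minimal
  lab[sH == -1 & sK == 1] <- 1L             # peak
  lab[sH == 1 & sK == 1] <- 2L              # pit
  lab[sH == -1 & sK == 0] <- 3L             # ridge
  lab[sH == 1 & sK == 0] <- 4L              # valley
  lab[sH == -1 & sK == -1] <- 5L            # saddle_ridge
  lab[sH == 1 & sK == -1] <- 6L             # saddle_valley
  counts <- setNames(tabulate(lab, 8L), .hk_levels)
  structure(list(labels = lab, levels = .hk_levels, counts = counts,
                 eps_H = eps_H, eps_K = eps_K),
            class = "hk_labels")
}

#' @export
print.hk_labels <- function(x, ...) {
  cat(sprintf("hk_labels: %d x %d px (eps_H = %.3g, eps_K = %.3g)\n",
              nrow(x$labels), ncol(x$labels), x$eps_H, x$eps_K))
  print(x$counts)
  invisible(x)
}

#' Locate meristem candidates from HK labels
#'
#' The growing point of a rosette-habit plant sits in a central
#' depression, which under the HK taxonomy appears as a blob of `pit`
#' pixels (elliptic, curving away from the camera); for other habits the
#' polarity can be flipped to `peak`. Connected components of the chosen
#' label with at least `min_blob_px` pixels each yield one candidate at
#' the component's |K|-weighted centroid, scored by the component's mean
#' |K| (sharper depressions score higher).
#'
#' @param labels an [hk_segment()] result.
#' @param curv the matching [curvature_fields()] result.
#' @param min_blob_px minimum component area in pixels.
#' @param polarity `"pit"` (default, rosette depression) or `"peak"`.
#' @return data.frame with columns `row`, `col` (centroid, 1-based
#'   fractional pixels), `score`, `area`, `method`, sorted by
#'   descending score. Zero rows if nothing qualifies.
#' @export
detect_meristem_hk <- function(labels, curv, min_blob_px = 5,
                               polarity = c("pit", "peak")) {
  polarity <- match.arg(polarity)
  .assert(min_blob_px >= 1, "min_blob_px must be >= 1")
  want <- match(polarity, .hk_levels)
  mask <- labels$labels == want
  empty <- data.frame(row = numeric(0), col = numeric(0),
                      score = numeric(0), area = integer(0),
                      method = character(0))
  if (!any(mask)) return(empty)
  cc <- EBImage::bwlabel(mask)
  ncomp <- max(cc)
  out <- empty
  absK <- abs(curv$K)
  ri <- row(mask); ci <- col(mask)
  for (i in seq_len(ncomp)) {
    sel <- cc == i
    area <- sum(sel)
    if (area < min_blob_px) next
    w <- absK[sel]
    if (sum(w) == 0) w <- rep(1, area)
    out <- rbind(out, data.frame(
      row = sum(ri[sel] * w) / sum(w),
      col = sum(ci[sel] * w) / sum(w),
      score = mean(absK[sel]), area = area, method = "hk"))
  }
  out[order(-out$score), , drop = FALSE]
}

#' 3D leaf area from recovered gradients
#'
#' Projected leaf area underestimates true area wherever the leaf is
#' tilted; with per-pixel surface orientation the foreshortening can be
#' undone exactly: each pixel contributes
#' `pixel_pitch^2 * sqrt(1 + p^2 + q^2)` (projected area divided by the
#' cosine of the local surface tilt).
#'
#' @param fields a [surface_fields()] object.
#' @param mask logical raster selecting the leaf.
#' @param pixel_pitch mm per pixel (> 0).
#' @return area in mm^2, with attribute `excluded_px` counting mask
#'   pixels skipped because the solve marked them invalid.
#' @export
leaf_area_3d <- function(fields, mask, pixel_pitch) {
  .assert(pixel_pitch > 0, "pixel_pitch must be > 0")
  .assert(is.logical(mask) && identical(dim(mask), dim(fields$p)),
          "mask must be a logical raster matching the fields")
  .assert(any(mask), "mask is empty")
  use <- mask & fields$valid_mask
  excluded <- sum(mask) - sum(use)
  area <- sum(pixel_pitch^2 * sqrt(1 + fields$p[use]^2 + fields$q[use]^2))
  structure(area, excluded_px = excluded)
}
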