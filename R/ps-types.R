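#' Co-registered multi-light image stack
#'
#' Bundles the images captured under each light of a photometric-stereo
#' rig. All images must share dimensions and hold normalised intensities
#' in \[0, 1\]. Colour arrays (rows x cols x 3) are reduced to luminance
#' unless `keep_colour = TRUE`.
#'
#' @param images list of 2D intensity matrices (or rows x cols x 3 arrays).
#' @param pixel_pitch optional mm per pixel, used for metric areas.
#' @param keep_colour keep RGB planes (for per-channel albedo recovery).
#' @return an `image_stack` object.
#' @export
image_stack <- function(images, pixel_pitch = NULL, keep_colour = FALSE) {
  .assert(is.list(images) && length(images) >= 2,
          "an image stack needs at least 2 images (got %d)", length(images))
  colour <- NULL
  images <- lapply(images, function(im) {
    if (is.array(im) && length(dim(im)) == 3) {
      if (keep_colour) colour <<- TRUE
      im <- as_luminance(im)
    }
    .assert(.is_raster(im), "stack images must be numeric matrices")
    im
  })
  d <- dim(images[[1]])
  for (im in images) {
    .assert(identical(dim(im), d), "all stack images must share dimensions")
    .assert(all(is.finite(im)) && all(im >= 0) && all(im <= 1),
            "stack intensities must be finite and in [0, 1]")
  }
  structure(list(images = images, pixel_pitch = pixel_pitch),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("image_stack: %d images, %d x %d px%s\n", length(x$images),
              d[1], d[2],
              if (is.null(x$pixel_pitch)) "" else
                sprintf(", %.3g mm/px", x$pixel_pitch)))
  invisible(x)
}

#' Convert an RGB array to luminance
#'
#' Rec. 709 weights; grey-scale matrices pass through unchanged.
#'
#' @param im matrix or rows x cols x 3 array.
#' @return intensity matrix.
#' @export
as_luminance <- function(im) {
  if (is.matrix(im)) return(im)
  .assert(length(dim(im)) == 3 && dim(im)[3] >= 3, "expected an RGB array")
  0.2126 * im[, , 1] + 0.7152 * im[, , 2] + 0.0722 * im[, , 3]
}

#' Calibrated illumination directions in gradient space
#'
#' Each light is parameterised by gradient-space coordinates (ps, qs),
#' inducing the direction vector L = \[-ps, -qs, 1\] (unit-normalised
#' internally). For a full photometric-stereo solve at least three
#' directions are required and they must not be collinear in azimuth
#' (equivalently, the matrix of unit light vectors must have rank 3).
#'
#' @param ps,qs numeric vectors of gradient-space light coordinates.
#' @return a `light_set` object.
#' @export
light_set <- function(ps, qs) {
  .assert(length(ps) == length(qs) && length(ps) >= 1,
          "ps and qs must be equal-length, non-empty")
  .assert(all(is.finite(ps)) && all(is.finite(qs)), "light coordinates must be finite")
  L <- cbind(-ps, -qs, 1)
  L <- L / sqrt(rowSums(L^2))
  structure(list(ps = ps, qs = qs, L = L), class = "light_set")
}

#' @export
print.light_set <- function(x, ...) {
  cat(sprintf("light_set: %d lights\n", length(x$ps)))
  for (i in seq_along(x$ps))
    cat(sprintf("  [%d] ps=%+.3f qs=%+.3f\n", i, x$ps[i], x$qs[i]))
  invisible(x)
}

# rank-3 check for a full PS solve; names the offending configuration
.check_light_rank <- function(lights, n_required = 3) {
  .assert(length(lights$ps) >= n_required,
          "full photometric stereo needs at least %d lights (got %d)",
          n_required, length(lights$ps))
  s <- svd(lights$L)$d
  if (s[3] < 1e-8 * s[1])
    stop(sprintf(paste0(
      "light directions are collinear in azimuth (light matrix is rank-",
      "deficient); azimuths: %s"),
      paste(sprintf("%.1f°", atan2(-lights$qs, -lights$ps) * 180 / pi),
            collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' Per-pixel recovered surface orientation and albedo
#'
#' Container returned by the photometric-stereo solvers. `p` and `q` are
#' the gradient-space slopes (p = -df/dx, q = -df/dy for surface
#' z = f(x, y)), `normal` the unit normal field \[-p,-q,1\]/|.| as a
#' rows x cols x 3 array, `albedo` the non-negative diffuse reflectance,
#' and `valid_mask` flags pixels where the Lambertian assumptions held
#' (no shadow or saturation in any input image).
#'
#' @param p,q gradient rasters.
#' @param albedo albedo raster (>= 0 where valid).
#' @param valid_mask logical raster.
#' @param pixel_pitch optional mm per pixel.
#' @return a `surface_fields` object.
#' @export
surface_fields <- function(p, q, albedo, valid_mask, pixel_pitch = NULL) {
  .assert(identical(dim(p), dim(q)) && identical(dim(p), dim(albedo)) &&
            identical(dim(p), dim(valid_mask)), "field dimensions must agree")
  nr <- nrow(p); nc <- ncol(p)
  nrm <- sqrt(1 + p^2 + q^2)
  normal <- array(NA_real_, c(nr, nc, 3))
  normal[, , 1] <- -p / nrm
  normal[, , 2] <- -q / nrm
  normal[, , 3] <- 1 / nrm
  structure(list(p = p, q = q, normal = normal, albedo = albedo,
                 valid_mask = valid_mask, pixel_pitch = pixel_pitch),
            class = "surface_fields")
}

#' @export
print.surface_fields <- function(x, ...) {
  cat(sprintf("surface_fields: %d x %d px, %.1f%% valid, albedo range [%.3g, %.3g]\n",
              nrow(x$p), ncol(x$p), 100 * mean(x$valid_mask),
              suppressWarnings(min(x$albedo[x$valid_mask])),
              suppressWarnings(max(x$albedo[x$valid_mask]))))
  invisible(x)
}

#' @export
plot.surface_fields <- function(x, what = c("albedo", "p", "q"), ...) {
  what <- match.arg(what)
  m <- x[[what]]
  m[!x$valid_mask] <- NA
  image(t(m)[, nrow(m):1], asp = nrow(m) / ncol(m), axes = FALSE,
        col = grDevices::gray.colors(256), ...)
  title(main = what)
  invisible(x)
}

#' Integrated depth map
#'
#' Heights z = f(x, y) toward the camera, defined only up to an additive
#' constant when produced by gradient integration (the integrators
#' return mean-centred depth).
#'
#' @param z height raster.
#' @param pixel_pitch optional mm per pixel.
#' @param units unit label carried in metadata.
#' @return a `depth_map` object.
#' @export
depth_map <- function(z, pixel_pitch = NULL, units = "px") {
  .assert(.is_raster(z), "z must be a numeric matrix")
  structure(list(z = z, pixel_pitch = pixel_pitch, units = units),
            class = "depth_map")
}

#' @export
print.depth_map <- function(x, ...) {
  cat(sprintf("depth_map: %d x %d px, range [%.3g, %.3g] %s\n",
              nrow(x$z), ncol(x$z), min(x$z, na.rm = TRUE),
              max(x$z, na.rm = TRUE), x$units))
  invisible(x)
}

#' @export
plot.depth_map <- function(x, ...) {
  image(t(x$z)[, nrow(x$z):1], asp = nrow(x$z) / ncol(x$z), axes = FALSE,
        col = grDevices::hcl.colors(256, "viridis"), ...)
  invisible(x)
}
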