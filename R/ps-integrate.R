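# DFT frequency vector (radians per sample)
.fft_freq <- function(n) {
  k <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2):1))
  2 * pi * k / n
}

# Frankot-Chellappa spectral least-squares integration of a target
# gradient field (gx = dz/dx, gy = dz/dy) on a periodic domain.
.fc_solve <- function(gx, gy) {
  nr <- nrow(gx); nc <- ncol(gx)
  wx <- .fft_freq(nc)  # x = columns
  wy <- .fft_freq(nr)  # y = rows
  WX <- matrix(rep(wx, each = nr), nr, nc)
  WY <- matrix(rep(wy, nc), nr, nc)
  denom <- WX^2 + WY^2
  denom[1, 1] <- 1
  Z <- (-1i * (WX * fft(gx) + WY * fft(gy))) / denom
  Z[1, 1] <- 0
  Re(fft(Z, inverse = TRUE)) / (nr * nc)
}

#' Integrate a gradient field to a depth map
#'
#' Recovers depth z = f(x, y) whose gradients best match the recovered
#' field in the least-squares sense, under the sign convention
#' p = -dz/dx, q = -dz/dy. Photometric-stereo gradient fields are never
#' perfectly integrable (noise, shadows, the Lambertian approximation),
#' so a least-squares spectral solve is used: the mean gradient is
#' integrated exactly as a plane ramp, and the residual is integrated by
#' Frankot-Chellappa projection on an even/odd mirror-extended domain
#' (equivalent to a cosine-basis Poisson solve), which avoids the
#' wrap-around artefacts a plain periodic solve would introduce on
#' non-periodic surfaces. The returned depth is mean-centred: integrated
#' depth is only defined up to an additive constant.
#'
#' Invalid pixels contribute a zero residual gradient (i.e. they are
#' interpolated smoothly).
#'
#' @param fields a [surface_fields()] object, or any list with `p`, `q`
#'   and optionally `valid_mask` rasters.
#' @return a [depth_map()] (units: pixels of height per pixel of travel,
#'   or mm if `pixel_pitch` was set and gradients are dimensionless).
#' @export
integrate_gradients <- function(fields) {
  p <- fields$p; q <- fields$q
  .assert(.is_raster(p) && .is_raster(q) && identical(dim(p), dim(q)),
          "p and q must be numeric matrices of equal size")
  valid <- fields$valid_mask
  if (is.null(valid)) valid <- is.finite(p) & is.finite(q)
  .assert(any(valid), "cannot integrate an all-invalid gradient field")
  nr <- nrow(p); nc <- ncol(p)
  pbar <- mean(p[valid]); qbar <- mean(q[valid])
  # residual target gradients (dz/dx = -p), zero where invalid
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  gx[valid] <- -(p[valid] - pbar)
  gy[valid] <- -(q[valid] - qbar)
  # mirror extension: z even in both axes => dz/dx odd in x / even in y,
  # dz/dy even in x / odd in y
  gxe <- rbind(cbind(gx, -gx[, nc:1]), cbind(gx[nr:1, ], -gx[nr:1, nc:1]))
  gye <- rbind(cbind(gy, gy[, nc:1]), cbind(-gy[nr:1, ], -gy[nr:1, nc:1]))
  z <- .fc_solve(gxe, gye)[1:nr, 1:nc]
  co <- .centered_coords(nr, nc)
  z <- z - pbar * co$x - qbar * co$y
  z <- z - mean(z)
  depth_map(z, pixel_pitch = fields$pixel_pitch)
}
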