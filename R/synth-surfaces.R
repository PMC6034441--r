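#' Generate an analytic test surface
#'
#' Produces a depth raster together with its *exact* analytic gradient
#' fields (p = -dz/dx, q = -dz/dy), unit normals and validity mask, for
#' use as ground truth when exercising the photometric-stereo and
#' curvature pipelines. Supported kinds:
#'
#' * `plane`: `p0`, `q0` slopes (defaults 0.3, 0).
#' * `sphere`: upper cap of radius `radius` px (default 100); pixels
#'   beyond 0.98 radius are masked invalid.
#' * `cylinder`: axis along y, radius `radius`.
#' * `saddle`: z = (x^2 - y^2) / (2 `rscale`).
#' * `ellipsoid`: upper half with semi-axes `a`, `b`, `c` px.
#' * `leaf`: smooth lobed dome of height `height` with an optional
#'   raised midrib vein (`vein_amp`).
#' * `rosette`: radial sinusoidal leaves sloping up toward the plant
#'   centre, with a small sharp central depression (the meristem pit);
#'   the true centre is recorded in `truth$center`. Leaf count,
#'   amplitudes and the centre location are drawn from `seed`.
#'
#' Coordinates: x = column, y = row, both centred on the raster; z
#' toward the camera, in pixels.
#'
#' @param kind surface kind (see above).
#' @param size raster size in px (scalar or c(rows, cols)).
#' @param seed RNG seed for stochastic kinds; the output is a pure
#'   function of (parameters, seed).
#' @param ... kind-specific parameters.
#' @return a `synthetic_surface`: list with `z`, `p`, `q`, `normal`
#'   (rows x cols x 3), `mask`, `truth` (kind-specific ground truth)
#'   and `kind`.
#' @export
make_surface <- function(kind = c("plane", "sphere", "cylinder", "saddle",
                                  "ellipsoid", "leaf", "rosette"),
                         size = 65, seed = NULL, ...) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  if (length(size) == 1) size <- c(size, size)
  nr <- size[1]; nc <- size[2]
  co <- .centered_coords(nr, nc)
  x <- co$x; y <- co$y
  prm <- list(...)
  mask <- matrix(TRUE, nr, nc)
  truth <- list()
  get <- function(name, default) if (is.null(prm[[name]])) default else prm[[name]]
  if (kind == "plane") {
    p0 <- get("p0", 0.3); q0 <- get("q0", 0); z0 <- get("z0", 0)
    z <- z0 - p0 * x - q0 * y
    p <- matrix(p0, nr, nc); q <- matrix(q0, nr, nc)
    truth <- list(p0 = p0, q0 = q0)
  } else if (kind == "sphere") {
    R <- get("radius", 100)
    .assert(R > 0, "radius must be > 0")
    r2 <- x^2 + y^2
    mask <- r2 < (0.98 * R)^2
    s <- sqrt(pmax(R^2 - r2, (0.05 * R)^2))
    z <- s
    p <- x / s; q <- y / s
    truth <- list(radius = R)
  } else if (kind == "cylinder") {
    R <- get("radius", 100)
    .assert(R > 0, "radius must be > 0")
    mask <- abs(x) < 0.98 * R
    s <- sqrt(pmax(R^2 - x^2, (0.05 * R)^2))
    z <- s
    p <- x / s; q <- matrix(0, nr, nc)
    truth <- list(radius = R)
  } else if (kind == "saddle") {
    R <- get("rscale", 100)
    .assert(R > 0, "rscale must be > 0")
    z <- (x^2 - y^2) / (2 * R)
    p <- -x / R; q <- y / R
    truth <- list(rscale = R)
  } else if (kind == "ellipsoid") {
    a <- get("a", 40); b <- get("b", 30); ch <- get("c", 20)
    .assert(a > 0 && b > 0 && ch > 0, "semi-axes must be > 0")
    w2 <- (x / a)^2 + (y / b)^2
    mask <- w2 < 0.98^2
    s <- sqrt(pmax(1 - w2, 0.05^2))
    z <- ch * s
    p <- ch * x / (a^2 * s); q <- ch * y / (b^2 * s)
    truth <- list(a = a, b = b, c = ch)
  } else if (kind == "leaf") {
    h <- get("height", 10); a <- get("a", 0.35 * nc); b <- get("b", 0.28 * nr)
    v <- get("vein_amp", 0.8); wv <- get("vein_width", 2.5)
    base <- exp(-(x / a)^2 - (y / b)^2)
    venv <- exp(-(x / wv)^2) * exp(-(y / (0.9 * b))^2)
    z <- h * base + v * venv
    dzdx <- h * base * (-2 * x / a^2) +
      v * venv * (-2 * x / wv^2)
    dzdy <- h * base * (-2 * y / b^2) +
      v * venv * (-2 * y / (0.9 * b)^2)
    p <- -dzdx; q <- -dzdy
    mask <- base > 0.05
    truth <- list(height = h, a = a, b = b)
  } else if (kind == "rosette") {
    # radial leaves sloping up to the centre, sharp central depression
    H <- get("height", runif(1, 9, 14))
    sp <- get("mound_sigma", 0.18 * min(nr, nc) * runif(1, 0.9, 1.1))
    nl <- get("n_leaves", sample(5:8, 1))
    amp <- get("leaf_amp", runif(1, 0.25, 0.45))
    phi <- get("phase", runif(1, 0, 2 * pi))
    sd_ <- get("dip_sigma", runif(1, 2.5, 4))
    # dip curvature must dominate the inter-leaf troughs, as the meristem
    # whorl centre does on a live rosette
    D <- get("dip_depth", 6 * H * sd_^2 / sp^2 * runif(1, 1, 1.3))
    cjit <- get("center_jitter", 0.12 * min(nr, nc))
    ctr <- get("center_offset", runif(2, -cjit, cjit))  # (x, y) offset
    csm <- 0.35 * sp                                     # angular gating radius
    xt <- x - ctr[1]; yt <- y - ctr[2]
    r2 <- xt^2 + yt^2
    th <- atan2(yt, xt)
    u <- nl * th + phi
    g <- exp(-r2 / (2 * sp^2))
    e <- exp(-r2 / (2 * sd_^2))
    # squared gate: suppresses the angular modulation hard near the
    # centre, where n-fold sinusoids would otherwise alias across pixels
    s1 <- r2 / (r2 + csm^2)
    s <- s1^2
    A <- amp * cos(u)
    z <- H * g * (1 + s * A) - D * e
    gx <- -xt / sp^2 * g; gy <- -yt / sp^2 * g
    ex <- -xt / sd_^2 * e; ey <- -yt / sd_^2 * e
    sx <- 4 * csm^2 * s1 * xt / (r2 + csm^2)^2
    sy <- 4 * csm^2 * s1 * yt / (r2 + csm^2)^2
    sAx <- amp * nl * sin(u) * yt * r2 / (r2 + csm^2)^2   # s * dA/dx
    sAy <- -amp * nl * sin(u) * xt * r2 / (r2 + csm^2)^2  # s * dA/dy
    dzdx <- H * (gx * (1 + s * A) + g * (sx * A + sAx)) - D * ex
    dzdy <- H * (gy * (1 + s * A) + g * (sy * A + sAy)) - D * ey
    p <- -dzdx; q <- -dzdy
    truth <- list(center = c(row = ctr[2] + (nr + 1) / 2,
                             col = ctr[1] + (nc + 1) / 2),
                  height = H, n_leaves = nl, dip_depth = D,
                  dip_sigma = sd_)
  }
  nrm <- sqrt(1 + p^2 + q^2)
  normal <- array(NA_real_, c(nr, nc, 3))
  normal[, , 1] <- -p / nrm
  normal[, , 2] <- -q / nrm
  normal[, , 3] <- 1 / nrm
  structure(list(z = z, p = p, q = q, normal = normal, mask = mask,
                 truth = truth, kind = kind),
            class = "synthetic_surface")
}

#' Render a Lambertian image stack from a surface
#'
#' Forward model of the photometric-stereo capture: for each light,
#' intensity = `clamp(albedo * max(0, n . L) + N(0, noise_sigma), 0, 1)`
#' where n is the unit surface normal and L the unit light vector. The
#' attached-shadow truth (any light with n . L <= 0) and the surface
#' mask are recorded as attributes.
#'
#' @param surface a [make_surface()] result (or any list with `p`, `q`,
#'   `mask`).
#' @param lights a [light_set()].
#' @param albedo scalar or raster in \[0, 1\] scale (values > 1 allowed;
#'   clamping applies to the rendered intensity).
#' @param noise_sigma additive Gaussian intensity noise sd.
#' @param seed RNG seed for the noise.
#' @param pixel_pitch carried through to the stack.
#' @return an [image_stack()] with attributes `shadow_truth` (logical
#'   raster) and `surface_mask`.
#' @export
render_lambertian <- function(surface, lights, albedo = 1, noise_sigma = 0,
                              seed = NULL, pixel_pitch = NULL) {
  .assert(length(lights$ps) >= 1, "need at least one light")
  if (!is.null(seed)) set.seed(seed)
  p <- surface$p; q <- surface$q
  nr <- nrow(p); nc <- ncol(p)
  if (length(albedo) == 1) albedo <- matrix(albedo, nr, nc)
  nrm <- sqrt(1 + p^2 + q^2)
  shadow <- matrix(FALSE, nr, nc)
  imgs <- vector("list", length(lights$ps))
  for (i in seq_along(lights$ps)) {
    L <- lights$L[i, ]
    ndl <- (-p * L[1] - q * L[2] + L[3]) / nrm
    shadow <- shadow | (ndl <= 0)
    im <- albedo * pmax(ndl, 0)
    if (noise_sigma > 0) im <- im + matrix(rnorm(nr * nc, 0, noise_sigma), nr, nc)
    im[!surface$mask] <- 0
    imgs[[i]] <- pmin(pmax(im, 0), 1)
  }
  st <- image_stack(imgs, pixel_pitch = pixel_pitch)
  attr(st, "shadow_truth") <- shadow & surface$mask
  attr(st, "surface_mask") <- surface$mask
  st
}
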