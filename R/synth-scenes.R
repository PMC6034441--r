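# dense-rotation-grid sieve evaluation used for generator ground truth
.sieve_grid <- function(width, height, n = 4097) {
  th <- seq(0, pi / 2, length.out = n)
  A <- width / 2; B <- height / 2
  e1 <- 2 * sqrt(A^2 * cos(th)^2 + B^2 * sin(th)^2)
  e2 <- 2 * sqrt(A^2 * sin(th)^2 + B^2 * cos(th)^2)
  min(pmax(e1, e2))
}

# footprint support radius of an ellipse (semi-axes a, b, rotated by yaw)
# in direction dir (radians)
.ellipse_support <- function(a, b, yaw, dir) {
  d <- dir - yaw
  sqrt((a * cos(d))^2 + (b * sin(d))^2)
}

#' Generate a synthetic conveyor depth frame with known tubers
#'
#' Emulates the harvester's depth camera looking down at the belt:
#' a belt plane (optionally tilted) at `belt_depth_mm` from the camera,
#' carrying upper-half ellipsoidal tubers at random yaw. With
#' probability `touching_prob` a tuber is placed in contact with the
#' previous one, so the pair merges into a single detection region and
#' must be split from the 3D surface. Gaussian depth noise and an
#' optional 1 mm quantisation emulate the sensor.
#'
#' @param n_tubers number of tubers (>= 0).
#' @param axis_ranges_mm list with `a`, `b`, `c` ranges (mm) for the
#'   semi-axes; draws are sorted so a >= b >= c.
#' @param touching_prob probability that tuber i is placed touching
#'   tuber i - 1.
#' @param noise_sigma_mm depth noise sd, mm.
#' @param seed RNG seed (the frame is a pure function of it).
#' @param frame_size c(rows, cols) px.
#' @param pixel_pitch_mm mm per pixel on the belt.
#' @param belt_depth_mm camera-to-belt distance, mm.
#' @param belt_tilt_deg belt tilt about the x axis, degrees.
#' @param quantize_mm round depths to 1 mm (sensor resolution emulation).
#' @param timestamp capture time, s.
#' @return list with `frame` (a [depth_frame()]) and `truth`
#'   (data.frame: length, width, height, sieve_size, band,
#'   centroid_row, centroid_col, touching_pair).
#' @export
make_conveyor_frame <- function(n_tubers = 6,
                                axis_ranges_mm = list(a = c(35, 60),
                                                      b = c(25, 45),
                                                      c = c(16, 30)),
                                touching_prob = 0.2, noise_sigma_mm = 1,
                                seed = NULL, frame_size = c(256, 352),
                                pixel_pitch_mm = 1.5, belt_depth_mm = 800,
                                belt_tilt_deg = 0, quantize_mm = FALSE,
                                timestamp = 0) {
  .assert(n_tubers >= 0, "n_tubers must be >= 0")
  for (nm in c("a", "b", "c"))
    .assert(length(axis_ranges_mm[[nm]]) == 2 &&
              all(axis_ranges_mm[[nm]] > 0) &&
              diff(axis_ranges_mm[[nm]]) >= 0,
            "axis range %s must be positive and ordered", nm)
  if (!is.null(seed)) set.seed(seed)
  nr <- frame_size[1]; nc <- frame_size[2]
  xm <- matrix(rep((seq_len(nc) - 1) * pixel_pitch_mm, each = nr), nr, nc)
  ym <- matrix(rep((seq_len(nr) - 1) * pixel_pitch_mm, nc), nr, nc)
  plane <- belt_depth_mm + tan(belt_tilt_deg * pi / 180) * ym
  heights <- matrix(0, nr, nc)
  margin <- 15 * pixel_pitch_mm
  xmax <- (nc - 1) * pixel_pitch_mm; ymax <- (nr - 1) * pixel_pitch_mm
  placed <- list()
  truth <- list()
  for (i in seq_len(n_tubers)) {
    a <- runif(1, axis_ranges_mm$a[1], axis_ranges_mm$a[2])
    b <- runif(1, axis_ranges_mm$b[1], axis_ranges_mm$b[2])
    ch <- runif(1, axis_ranges_mm$c[1], axis_ranges_mm$c[2])
    ax <- sort(c(a, b, ch), decreasing = TRUE)
    a <- ax[1]; b <- ax[2]; ch <- ax[3]
    yaw <- runif(1, 0, pi)
    touch <- i > 1 && runif(1) < touching_prob
    ok <- FALSE
    for (try in 1:400) {
      if (try > 150) touch <- FALSE   # fall back to free placement
      if (touch) {
        prev <- placed[[i - 1]]
        dir <- runif(1, 0, 2 * pi)
        dist <- 0.92 * (.ellipse_support(prev$a, prev$b, prev$yaw, dir) +
                          .ellipse_support(a, b, yaw, dir))
        cx <- prev$cx + dist * cos(dir)
        cy <- prev$cy + dist * sin(dir)
      } else {
        cx <- runif(1, margin + a, xmax - margin - a)
        cy <- runif(1, margin + a, ymax - margin - a)
      }
      if (cx < margin / 2 || cx > xmax - margin / 2 ||
          cy < margin / 2 || cy > ymax - margin / 2) next
      clear <- TRUE
      for (j in seq_along(placed)) {
        if (touch && j == i - 1) next
        pj <- placed[[j]]
        dir <- atan2(cy - pj$cy, cx - pj$cx)
        mind <- 1.08 * (.ellipse_support(pj$a, pj$b, pj$yaw, dir) +
                          .ellipse_support(a, b, yaw, dir))
        if (sqrt((cx - pj$cx)^2 + (cy - pj$cy)^2) < mind) { clear <- FALSE; break }
      }
      if (clear) { ok <- TRUE; break }
    }
    if (!ok) stop("overcrowded placement: cannot fit tubers without excessive overlap",
                  call. = FALSE)
    placed[[i]] <- list(cx = cx, cy = cy, a = a, b = b, c = ch, yaw = yaw)
    # render the upper-half ellipsoid into the height map
    u <- (xm - cx) * cos(yaw) + (ym - cy) * sin(yaw)
    v <- -(xm - cx) * sin(yaw) + (ym - cy) * cos(yaw)
    w2 <- (u / a)^2 + (v / b)^2
    h <- ifelse(w2 < 1, ch * (1 + sqrt(pmax(1 - w2, 0))), 0)
    heights <- pmax(heights, h)
    sv <- .sieve_grid(2 * b, 2 * ch)
    truth[[i]] <- data.frame(
      length = 2 * a, width = 2 * b, height = 2 * ch, sieve_size = sv,
      band = size_band(sv), centroid_row = cy / pixel_pitch_mm + 1,
      centroid_col = cx / pixel_pitch_mm + 1,
      touching_pair = if (touch) i - 1L else NA_integer_)
  }
  depth <- plane - heights
  if (noise_sigma_mm > 0) depth <- depth + matrix(rnorm(nr * nc, 0, noise_sigma_mm), nr, nc)
  if (quantize_mm) depth <- round(depth)
  m <- 10L
  frame <- depth_frame(depth, roi = c(m, m, nr - m, nc - m),
                       timestamp = timestamp, pixel_pitch = pixel_pitch_mm)
  truth <- if (n_tubers > 0) do.call(rbind, truth) else
    data.frame(length = numeric(0), width = numeric(0), height = numeric(0),
               sieve_size = numeric(0), band = character(0),
               centroid_row = numeric(0), centroid_col = numeric(0),
               touching_pair = integer(0))
  list(frame = frame, truth = truth)
}

#' Generate a grass scene with smooth dock blobs
#'
#' Background: rank-normalised multi-orientation high-frequency texture
#' (grass has fine, multi-directional blade structure, hence a rich grey
#' histogram and high local entropy). Docks: smooth lobed elliptical
#' blobs of nearly constant grey (broad smooth leaves, low entropy).
#' The generator is procedural, not photorealistic: the segmentation
#' pipeline discriminates on entropy, not appearance.
#'
#' @param image_size scalar or c(rows, cols) px.
#' @param n_docks number of dock blobs (0 for a dock-free scene).
#' @param dock_area_fraction target truth-mask coverage in \[0, 0.5\];
#'   achieved coverage is within 10% of the request.
#' @param seed RNG seed.
#' @return list with `image` (matrix in \[0, 1\]) and `truth_mask`
#'   (logical).
#' @export
make_grass_dock <- function(image_size = 256, n_docks = 3,
                            dock_area_fraction = 0.08, seed = NULL) {
  .assert(dock_area_fraction >= 0 && dock_area_fraction <= 0.5,
          "dock_area_fraction must be in [0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  if (length(image_size) == 1) image_size <- c(image_size, image_size)
  nr <- image_size[1]; nc <- image_size[2]
  co <- .centered_coords(nr, nc)
  g <- matrix(0, nr, nc)
  for (k in 1:6) {
    ang <- runif(1, 0, pi)
    lam <- runif(1, 2.5, 6)
    ph <- runif(1, 0, 2 * pi)
    g <- g + sin(2 * pi * (co$x * cos(ang) + co$y * sin(ang)) / lam + ph)
  }
  g <- g + matrix(rnorm(nr * nc, 0, 0.6), nr, nc)
  img <- matrix(rank(g, ties.method = "first") / (nr * nc), nr, nc)
  truth <- matrix(FALSE, nr, nc)
  if (n_docks > 0 && dock_area_fraction > 0) {
    target <- dock_area_fraction * nr * nc
    shares <- runif(n_docks, 0.7, 1.3)
    shares <- shares / sum(shares)
    centers <- list()
    for (d in seq_len(n_docks)) {
      area <- target * shares[d]
      ar <- runif(1, 0.6, 0.9)                   # aspect ratio b/a
      ra <- sqrt(area / (pi * ar * 1.02))        # 1.02: mean lobe factor
      rb <- ra * ar
      phl <- runif(1, 0, 2 * pi)
      for (try in 1:300) {
        cx <- runif(1, -nc / 2 + ra + 10, nc / 2 - ra - 10)
        cy <- runif(1, -nr / 2 + ra + 10, nr / 2 - ra - 10)
        if (all(vapply(centers, function(cn)
          sqrt((cx - cn[1])^2 + (cy - cn[2])^2) > ra + cn[3] + 6, TRUE)))
          break
      }
      centers[[d]] <- c(cx, cy, ra)
      xt <- co$x - cx; yt <- co$y - cy
      th <- atan2(yt, xt)
      rr <- sqrt((xt / ra)^2 + (yt / rb)^2)
      inside <- rr < 1 + 0.2 * cos(3 * th + phl)
      lvl <- runif(1, 0.35, 0.6)
      img[inside] <- lvl + 0.015 * (co$x[inside] / nc)
      truth <- truth | inside
    }
  }
  list(image = pmin(pmax(img, 0), 1), truth_mask = truth)
}

#' Generate a serpentine harvester GPS scene
#'
#' A harvester track covering a rectangular field in parallel passes
#' (serpentine), fixes at 1 Hz, with Poisson-timed tuber records whose
#' size bands are drawn from a configurable distribution. Used to
#' exercise geo-tagging, grid binning and heat-map rendering with known
#' conservation properties.
#'
#' @param field_size_m c(east-west, north-south) extent, metres.
#' @param pass_spacing_m distance between passes, metres.
#' @param speed_mps harvester speed, m/s.
#' @param tuber_rate_hz mean tuber detections per second (Poisson).
#' @param bands band labels.
#' @param band_probs sampling probabilities, one per band.
#' @param seed RNG seed.
#' @param origin c(lat, lon) of the field's south-west corner, degrees.
#' @return list with `track` (a [gps_track()]), `records` (data.frame:
#'   timestamp, band), and `duration_s`.
#' @export
make_gps_scene <- function(field_size_m = c(160, 100), pass_spacing_m = 10,
                           speed_mps = 1.5, tuber_rate_hz = 0.8,
                           bands = band_labels(),
                           band_probs = c(0.15, 0.45, 0.30, 0.10),
                           seed = NULL,
                           origin = c(lat = 52.2, lon = 0.1)) {
  .assert(all(field_size_m > 0) && pass_spacing_m > 0 && speed_mps > 0 &&
            tuber_rate_hz >= 0, "scene parameters must be positive")
  .assert(length(band_probs) == length(bands),
          "band_probs must match bands")
  if (!is.null(seed)) set.seed(seed)
  Lx <- field_size_m[1]; Ly <- field_size_m[2]
  ys <- seq(0, Ly, by = pass_spacing_m)
  # serpentine waypoints: alternate pass direction, side-step between
  wp <- matrix(0, 0, 2)
  for (i in seq_along(ys)) {
    xs <- if (i %% 2 == 1) c(0, Lx) else c(Lx, 0)
    wp <- rbind(wp, cbind(xs, ys[i]))
  }
  seg <- diff(wp)
  seglen <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seglen))
  duration <- cum[length(cum)] / speed_mps
  tfix <- seq(0, floor(duration), by = 1)
  pos_at <- function(t) {
    s <- pmin(t * speed_mps, cum[length(cum)])
    i <- pmin(findInterval(s, cum, rightmost.closed = TRUE), nrow(seg))
    f <- (s - cum[i]) / seglen[i]
    cbind(wp[i, 1] + f * seg[i, 1], wp[i, 2] + f * seg[i, 2])
  }
  pf <- pos_at(tfix)
  lat0 <- origin[["lat"]]; lon0 <- origin[["lon"]]
  lat <- lat0 + pf[, 2] / .EARTH_R * 180 / pi
  lon <- lon0 + pf[, 1] / (.EARTH_R * cos(lat0 * pi / 180)) * 180 / pi
  track <- gps_track(tfix, lat, lon)
  tr <- numeric(0)
  if (tuber_rate_hz > 0) {
    t <- 0
    repeat {
      t <- t + rexp(1, tuber_rate_hz)
      if (t > duration) break
      tr <- c(tr, t)
    }
  }
  records <- data.frame(
    timestamp = tr,
    band = if (length(tr) > 0)
      sample(bands, length(tr), replace = TRUE, prob = band_probs)
    else character(0))
  list(track = track, records = records, duration_s = duration)
}
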