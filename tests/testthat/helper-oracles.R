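# shared fixtures and independent oracles for the test suite

# mean angular error (radians) between recovered and true normal fields
angular_error <- function(fields, surf, extra_mask = TRUE) {
  v <- fields$valid_mask & surf$mask & extra_mask
  nv <- cbind(fields$normal[, , 1][v], fields$normal[, , 2][v],
              fields$normal[, , 3][v])
  tv <- cbind(surf$normal[, , 1][v], surf$normal[, , 2][v],
              surf$normal[, , 3][v])
  acos(pmin(1, rowSums(nv * tv)))
}

# brute-force sieve oracle, independent of the package's optimiser and of
# its support-function extents: sample the ellipse boundary densely, rotate
# the point set, and read the axis-aligned extents directly.
sieve_brute <- function(width, height, n_theta = 721, n_pts = 4001) {
  t <- seq(0, 2 * pi, length.out = n_pts)
  ex <- width / 2 * cos(t)
  ey <- height / 2 * sin(t)
  best <- Inf
  for (th in seq(0, pi / 2, length.out = n_theta)) {
    rx <- ex * cos(th) - ey * sin(th)
    ry <- ex * sin(th) + ey * cos(th)
    side <- max(2 * max(abs(rx)), 2 * max(abs(ry)))
    if (side < best) best <- side
  }
  best
}

iou <- function(a, b) sum(a & b) / max(sum(a | b), 1)

# standard three- and four-light rigs used across tests
lights3 <- function() light_set(c(0.5, -0.5, 0), c(0, 0, 0.5))
lights4 <- function() light_set(c(0.4, -0.4, 0, 0), c(0, 0, 0.4, -0.4))

# interior selector: centred square excluding a border (in px)
interior <- function(nr, nc, border) {
  m <- matrix(FALSE, nr, nc)
  m[(border + 1):(nr - border), (border + 1):(nc - border)] <- TRUE
  m
}

# meristem scorer fixture: localised gradient histograms from a set of
# training rosettes (20 meristem windows vs 200 background windows; the
# background pool includes near-misses >= 8 px off-centre, which teaches
# the margin to reject the dip's shoulder ring)
train_rosette_scorer <- function(train_seeds = 101:120, window = 32,
                                 n_bins = 16, p_range = 0.8) {
  pos <- NULL; neg <- NULL
  set.seed(99)
  for (s in train_seeds) {
    surf <- make_surface("rosette", size = 96, seed = s)
    gh <- gradient_histogram_features(surf$p, window, n_bins, stride = 2,
                                      p_range = p_range)
    tc <- surf$truth$center
    i <- which.min(abs(gh$centers_row - tc["row"]))
    j <- which.min(abs(gh$centers_col - tc["col"]))
    pos <- rbind(pos, gh$features[i, j, ])
    nwr <- length(gh$centers_row); nwc <- length(gh$centers_col)
    cnt <- 0
    while (cnt < 10) {
      ii <- sample(nwr, 1); jj <- sample(nwc, 1)
      d <- sqrt((gh$centers_row[ii] - tc["row"])^2 +
                  (gh$centers_col[jj] - tc["col"])^2)
      if (d > 8) { neg <- rbind(neg, gh$features[ii, jj, ]); cnt <- cnt + 1 }
    }
  }
  train_window_scorer(pos, neg)
}
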