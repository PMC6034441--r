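test_that("a plane yields no meristem candidates", {
  surf <- make_surface("plane", size = 48, p0 = 0.05)
  cv <- curvature_fields(surf$z, sigma = 1)
  cand <- detect_meristem_hk(hk_segment(cv), cv, min_blob_px = 5)
  expect_equal(nrow(cand), 0)
})

test_that("the rosette depression is localised to within 3 px", {
  for (s in c(3, 7, 11)) {
    surf <- make_surface("rosette", size = 96, seed = s)
    cv <- curvature_fields(surf$z, sigma = 1)
    cand <- detect_meristem_hk(hk_segment(cv), cv, min_blob_px = 5)
    expect_gt(nrow(cand), 0)
    d <- sqrt((cand$row[1] - surf$truth$center["row"])^2 +
                (cand$col[1] - surf$truth$center["col"])^2)
    expect_lt(d, 3)
    expect_true(all(diff(cand$score) <= 0))   # sorted by descending score
  }
})

test_that("two disjoint rosettes give exactly two candidates, one each", {
  mk <- function(off) make_surface("rosette", size = 128, height = 11,
                                   mound_sigma = 16, n_leaves = 6,
                                   leaf_amp = 0.3, phase = 0.5,
                                   dip_sigma = 3, dip_depth = 2.4,
                                   center_offset = off)
  s1 <- mk(c(-30, -30)); s2 <- mk(c(30, 30))
  z <- s1$z + s2$z
  cv <- curvature_fields(z, sigma = 1)
  # eps_K raised above the inter-leaf trough curvature so only the two
  # meristem depressions qualify as pit components
  cand <- detect_meristem_hk(hk_segment(cv, eps_K = 5e-3), cv,
                             min_blob_px = 5)
  expect_equal(nrow(cand), 2)
  truths <- rbind(s1$truth$center, s2$truth$center)
  for (k in 1:2) {
    d <- sqrt((cand$row - truths[k, "row"])^2 + (cand$col - truths[k, "col"])^2)
    expect_lt(min(d), 3)
  }
})

test_that("meristem detection is equivariant under translation", {
  base <- list(height = 12, mound_sigma = 17, n_leaves = 7, leaf_amp = 0.35,
               phase = 1.1, dip_sigma = 3.2, dip_depth = 2.6)
  mk <- function(off) do.call(make_surface,
                              c(list(kind = "rosette", size = 128,
                                     center_offset = off), base))
  c0 <- detect_meristem_hk(hk_segment(curvature_fields(mk(c(0, 0))$z, 1)),
                           curvature_fields(mk(c(0, 0))$z, 1))
  c1 <- detect_meristem_hk(hk_segment(curvature_fields(mk(c(9, -13))$z, 1)),
                           curvature_fields(mk(c(9, -13))$z, 1))
  # center_offset is (x, y): columns shift by +9, rows by -13
  expect_equal(c1$row[1] - c0$row[1], -13, tolerance = 0.3)
  expect_equal(c1$col[1] - c0$col[1], 9, tolerance = 0.3)
})

test_that("gradient histograms are normalised with fixed symmetric bins", {
  # constant zero gradient: all mass in the central bin of an odd binning
  gh <- gradient_histogram_features(matrix(0, 32, 32), 8, 9, p_range = 1)
  expect_true(all(gh$features[, , 5] == 1))
  expect_true(all(gh$features[, , -5] == 0))
  # histograms always sum to exactly 1
  gh2 <- gradient_histogram_features(matrix(rnorm(48 * 48, 0, 2), 48, 48),
                                     12, 7)
  expect_equal(as.vector(apply(gh2$features, c(1, 2), sum)),
               rep(1, length(gh2$centers_row) * length(gh2$centers_col)))
  # uniform draws fill bins to within the finite-sample bound 3/window_px
  set.seed(3)
  p <- matrix(runif(64 * 64, -1, 1), 64, 64)
  gh3 <- gradient_histogram_features(p, 16, 8, stride = 16, p_range = 1)
  expect_lt(max(abs(gh3$features - 1 / 8)), 3 / 16)
  expect_error(gradient_histogram_features(matrix(0, 8, 8), 16, 8), "larger")
})

test_that("a constant scorer yields a flat heat map with scan-order tie-break", {
  p <- matrix(rnorm(40 * 40, 0, 0.1), 40, 40)
  res <- scan_meristem_classifier(p, function(v) 1, window_px = 8,
                                  stride = 4)
  expect_true(all(res$heat == 1))
  expect_equal(res$candidate$row, res$centers_row[1])
  expect_equal(res$candidate$col, res$centers_col[1])
  # arg-max consistency: reported score equals the heat maximum
  expect_equal(res$candidate$score, max(res$heat))
})

test_that("a trained linear scorer locates held-out rosette meristems", {
  scorer <- train_rosette_scorer()
  hits <- 0
  for (s in 1:10) {
    surf <- make_surface("rosette", size = 96, seed = s)
    res <- scan_meristem_classifier(surf$p, scorer, window_px = 32,
                                    n_bins = 16, stride = 2, p_range = 0.8)
    d <- sqrt((res$candidate$row - surf$truth$center["row"])^2 +
                (res$candidate$col - surf$truth$center["col"])^2)
    if (d <= 5) hits <- hits + 1
    expect_equal(res$candidate$score, max(res$scores))
  }
  expect_gte(hits, 8)
})

test_that("3D leaf area undoes foreshortening", {
  nr <- 20; nc <- 20
  mask <- matrix(FALSE, nr, nc); mask[1:10, 1:10] <- TRUE
  flat <- surface_fields(matrix(0, nr, nc), matrix(0, nr, nc),
                         matrix(1, nr, nc), matrix(TRUE, nr, nc))
  expect_equal(as.numeric(leaf_area_3d(flat, mask, 1)), 100)
  tilted <- surface_fields(matrix(1, nr, nc), matrix(0, nr, nc),
                           matrix(1, nr, nc), matrix(TRUE, nr, nc))
  expect_equal(as.numeric(leaf_area_3d(tilted, mask, 1)), 100 * sqrt(2))
  # equality with projected area only for p = q = 0
  expect_gte(as.numeric(leaf_area_3d(tilted, mask, 1)), 100)
  # invalid pixels inside the mask are excluded and reported
  vm <- matrix(TRUE, nr, nc); vm[1, 1] <- FALSE
  part <- surface_fields(matrix(0, nr, nc), matrix(0, nr, nc),
                         matrix(1, nr, nc), vm)
  a <- leaf_area_3d(part, mask, 1)
  expect_equal(as.numeric(a), 99)
  expect_equal(attr(a, "excluded_px"), 1)
})

test_that("hemisphere-cap area matches the analytic 2*pi*R*h", {
  R <- 60
  surf <- make_surface("sphere", size = 129, radius = R)
  co <- fieldvision:::.centered_coords(129, 129)
  rmask <- 0.8 * R
  mask <- (co$x^2 + co$y^2) < rmask^2
  fields <- surface_fields(surf$p, surf$q, matrix(1, 129, 129),
                           surf$mask)
  est <- as.numeric(leaf_area_3d(fields, mask, 1))
  h <- R - sqrt(R^2 - rmask^2)
  expect_equal(est, 2 * pi * R * h, tolerance = 0.02)
})
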