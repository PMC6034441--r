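test_that("belt normalisation recovers heights above tilted planes", {
  # pure plane: heights all ~ 0
  sc <- make_conveyor_frame(n_tubers = 0, noise_sigma_mm = 0, seed = 1)
  h <- normalize_depth(sc$frame)
  expect_lt(max(h, na.rm = TRUE), 0.1)
  # plane + one hemisphere of radius 30 mm
  sc2 <- make_conveyor_frame(n_tubers = 1, noise_sigma_mm = 0, seed = 2,
                             axis_ranges_mm = list(a = c(30, 30),
                                                   b = c(30, 30),
                                                   c = c(30, 30)))
  h2 <- normalize_depth(sc2$frame)
  expect_equal(max(h2, na.rm = TRUE), 60, tolerance = 1 / 60)
  # 2-degree belt tilt is removed by the plane fit
  sc3 <- make_conveyor_frame(n_tubers = 0, noise_sigma_mm = 0,
                             belt_tilt_deg = 2, seed = 3)
  h3 <- normalize_depth(sc3$frame)
  expect_lt(max(h3, na.rm = TRUE), 0.5)
})

test_that("tuber detection counts regions and merges touching pairs", {
  sc0 <- make_conveyor_frame(n_tubers = 0, seed = 1)
  expect_equal(length(detect_tubers(normalize_depth(sc0$frame))), 0)
  sc5 <- make_conveyor_frame(n_tubers = 5, touching_prob = 0,
                             noise_sigma_mm = 0, seed = 5)
  expect_equal(length(detect_tubers(normalize_depth(sc5$frame))), 5)
  sc2 <- make_conveyor_frame(n_tubers = 2, touching_prob = 1,
                             noise_sigma_mm = 0, seed = 8)
  expect_equal(sum(!is.na(sc2$truth$touching_pair)), 1)
  expect_equal(length(detect_tubers(normalize_depth(sc2$frame))), 1)
})

test_that("ellipsoid fitting recovers exact and noisy half-surfaces", {
  set.seed(1)
  a <- 50; b <- 40; ch <- 28
  th <- runif(2000, 0, 2 * pi); phi <- acos(runif(2000))
  P <- cbind(a * sin(phi) * cos(th), b * sin(phi) * sin(th), ch * cos(phi))
  ang <- 0.7
  R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
  P2 <- P %*% t(R) + matrix(rep(c(100, 200, 30), each = 2000), ncol = 3)
  e <- fit_ellipsoid(P2)
  expect_true(e$fit_ok)
  expect_equal(e$semi_axes, c(a, b, ch), tolerance = 0.02)
  expect_equal(e$center, c(100, 200, 30), tolerance = 1e-6)
  expect_lt(e$rms_residual, 1e-6)
  # sphere: three equal axes within 1%
  S <- 30 * cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
  es <- fit_ellipsoid(S)
  expect_equal(es$semi_axes, c(30, 30, 30), tolerance = 0.01)
  # depth-camera grid sampling with 1 mm noise: within 5% over 20 trials
  gx <- seq(-a, a, by = 1.5); gy <- seq(-b, b, by = 1.5)
  G <- expand.grid(x = gx, y = gy)
  w2 <- (G$x / a)^2 + (G$y / b)^2
  G <- G[w2 < 1, ]; z <- ch * sqrt(1 - w2[w2 < 1])
  set.seed(42)
  errs <- vapply(1:20, function(i) {
    en <- fit_ellipsoid(cbind(G$x, G$y, z + rnorm(length(z), 0, 1)))
    max(abs(en$semi_axes / c(a, b, ch) - 1))
  }, 0)
  expect_lt(max(errs), 0.05)
})

test_that("ellipsoid fitting is equivariant under rigid motion", {
  set.seed(6)
  th <- runif(800, 0, 2 * pi); phi <- acos(runif(800))
  P <- cbind(45 * sin(phi) * cos(th), 35 * sin(phi) * sin(th),
             22 * cos(phi))
  e0 <- fit_ellipsoid(P)
  aa <- 0.9; Rz <- matrix(c(cos(aa), sin(aa), 0, -sin(aa), cos(aa), 0,
                            0, 0, 1), 3, 3)
  tr <- c(12, -7, 55)
  e1 <- fit_ellipsoid(P %*% t(Rz) + matrix(rep(tr, each = 800), ncol = 3))
  expect_equal(e1$semi_axes, e0$semi_axes, tolerance = 1e-6)
  expect_equal(e1$center, as.numeric(Rz %*% e0$center + tr),
               tolerance = 1e-6)
})

test_that("degenerate point sets are rejected or flagged", {
  flat <- cbind(runif(100), runif(100), 0)
  expect_error(fit_ellipsoid(flat), "coplanar")
  expect_error(fit_ellipsoid(matrix(rnorm(60), 20, 3)), "at least 30")
})

test_that("fit_and_split accepts singles, splits pairs, flags debris", {
  sc <- make_conveyor_frame(n_tubers = 1, touching_prob = 0, seed = 21)
  h <- normalize_depth(sc$frame)
  reg <- detect_tubers(h)
  expect_equal(length(reg), 1)
  fits <- fit_and_split(reg[[1]], h, sc$frame$pixel_pitch)
  expect_equal(length(fits), 1)
  expect_false(fits[[1]]$low_confidence)
  expect_lte(fits[[1]]$rms_residual, 3)

  sc2 <- make_conveyor_frame(n_tubers = 2, touching_prob = 1,
                             seed = 51)
  h2 <- normalize_depth(sc2$frame)
  reg2 <- detect_tubers(h2)
  expect_equal(length(reg2), 1)
  fits2 <- fit_and_split(reg2[[1]], h2, sc2$frame$pixel_pitch)
  expect_equal(length(fits2), 2)
  tru <- sc2$truth[order(sc2$truth$centroid_col), ]
  est <- fits2[order(vapply(fits2, function(e)
    mean(((e$pixels - 1) %/% nrow(h2)) + 1), 0))]
  for (k in 1:2)
    expect_equal(unname(2 * est[[k]]$semi_axes),
                 as.numeric(tru[k, c("length", "width", "height")]),
                 tolerance = 0.10)

  # a flat-topped debris patch is no ellipsoid: flagged low-confidence
  sc3 <- make_conveyor_frame(n_tubers = 0, noise_sigma_mm = 0, seed = 3)
  h3 <- normalize_depth(sc3$frame)
  h3[60:120, 60:150] <- 15       # flat plateau, 15 mm
  reg3 <- detect_tubers(h3)
  fits3 <- fit_and_split(reg3[[1]], h3, sc3$frame$pixel_pitch)
  expect_true(all(vapply(fits3, function(e)
    isTRUE(e$low_confidence) || e$rms_residual > 3, TRUE)))
})

test_that("tuber dimensions are the sorted ellipsoid diameters", {
  e <- structure(list(center = c(0, 0, 0), semi_axes = c(54.5, 30, 19.5),
                      orientation = diag(3), rms_residual = 0,
                      fit_ok = TRUE), class = "ellipsoid")
  expect_equal(as.numeric(tuber_dimensions(e)), c(109, 60, 39))
  e$semi_axes <- c(25, 25, 25)
  expect_equal(as.numeric(tuber_dimensions(e)), c(50, 50, 50))
})

test_that("accuracy percentages reproduce the reference trial table", {
  tab <- read.csv(system.file("extdata", "harvester_trial_measurements.csv",
                              package = "fieldvision"))
  expect_equal(nrow(tab), 18)
  got <- accuracy_percent(tab$true_mm, tab$est_mm)
  expect_true(all(abs(got - tab$accuracy_pct) <= 0.05 + 1e-9))
  expect_equal(accuracy_percent(92, 109), 84.4, tolerance = 1e-3)
  expect_equal(accuracy_percent(58, 33), 24.2, tolerance = 2e-3)
  expect_equal(accuracy_percent(70, 70), 100)
  expect_error(accuracy_percent(-1, 10), "positive")
})

test_that("sieve size agrees with its geometry", {
  # a circle passes a square of its own diameter
  expect_equal(sieve_size(60, 60), 60, tolerance = 1e-6)
  # a nearly flat ellipse slots through the diagonal: side -> width/sqrt(2)
  expect_equal(sieve_size(60, 0.01), 60 / sqrt(2), tolerance = 1e-3)
  # brute-force boundary-sampling oracle
  expect_equal(sieve_size(60, 40), sieve_brute(60, 40), tolerance = 0.05)
  # monotone in both arguments; bounded by height and width
  s1 <- sieve_size(60, 40); s2 <- sieve_size(62, 40); s3 <- sieve_size(60, 42)
  expect_lte(s1, s2); expect_lte(s1, s3)
  expect_gte(s1, 40); expect_lte(s1, 60)
  expect_error(sieve_size(30, 40), "width >= height")
})

test_that("size bands use half-open intervals on the printed ranges", {
  expect_equal(size_band(c(44.9, 45, 64.9, 65, 79.9, 80, 92)),
               c("<45", "45-65", "45-65", "65-80", "65-80", "80+", "80+"))
  expect_error(size_band(-3), "positive")
  expect_error(size_band(50, edges = c(65, 45)), "increasing")
  # custom five-band grading
  expect_equal(size_band(50, edges = c(30, 45, 65, 80)), "45-65")
})

test_that("frame measurement bands every accepted record exactly once", {
  sc <- make_conveyor_frame(n_tubers = 4, seed = 13)
  rec <- measure_tubers(sc$frame)
  expect_equal(nrow(rec), 4)
  expect_true(all(rec$band %in% band_labels()))
  tallied <- table(factor(rec$band, levels = band_labels()))
  expect_equal(sum(tallied), nrow(rec))
  expect_true(all(rec$length >= rec$width & rec$width >= rec$height))
})
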