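test_that("generators are pure functions of their seed", {
  expect_identical(make_surface("rosette", size = 48, seed = 7),
                   make_surface("rosette", size = 48, seed = 7))
  expect_identical(make_conveyor_frame(n_tubers = 3, seed = 5),
                   make_conveyor_frame(n_tubers = 3, seed = 5))
  expect_identical(make_grass_dock(96, 2, 0.1, seed = 2),
                   make_grass_dock(96, 2, 0.1, seed = 2))
  s1 <- make_gps_scene(seed = 9); s2 <- make_gps_scene(seed = 9)
  expect_identical(s1$records, s2$records)
  expect_identical(as.data.frame(s1$track), as.data.frame(s2$track))
})

test_that("analytic gradients agree with numerical derivatives of the depth", {
  for (kind in c("leaf", "sphere", "saddle")) {
    surf <- make_surface(kind, size = 96, seed = 3,
                         radius = if (kind == "sphere") 200 else NULL)
    d <- fieldvision:::.deriv_xy(surf$z)
    keep <- interior(96, 96, 3) & surf$mask
    expect_lt(max(abs(-d$fx[keep] - surf$p[keep])), 0.05)
    expect_lt(mean(abs(-d$fx[keep] - surf$p[keep])), 0.005)
    expect_lt(mean(abs(-d$fy[keep] - surf$q[keep])), 0.005)
  }
  # rosette: sub-pixel check by sliding the whole pattern with
  # center_offset, which samples z at continuously shifted positions
  prm <- list(height = 12, mound_sigma = 17, n_leaves = 7, leaf_amp = 0.35,
              phase = 0.8, dip_sigma = 3, dip_depth = 2.5)
  mk <- function(off) do.call(make_surface,
                              c(list(kind = "rosette", size = 96,
                                     center_offset = off), prm))
  delta <- 0.02
  z0 <- mk(c(0, 0))
  num_p <- -(mk(c(-delta / 2, 0))$z - mk(c(delta / 2, 0))$z) / delta
  num_q <- -(mk(c(0, -delta / 2))$z - mk(c(0, delta / 2))$z) / delta
  expect_lt(max(abs(num_p - z0$p)), 1e-3)
  expect_lt(max(abs(num_q - z0$q)), 1e-3)
})

test_that("generated normals are unit length and consistent with p, q", {
  surf <- make_surface("rosette", size = 48, seed = 1)
  nrm2 <- surf$normal[, , 1]^2 + surf$normal[, , 2]^2 + surf$normal[, , 3]^2
  expect_lt(max(abs(nrm2 - 1)), 1e-12)
  expect_equal(-surf$normal[, , 1] / surf$normal[, , 3], surf$p,
               tolerance = 1e-12)
  # apex of a sphere looks straight at the camera
  sp <- make_surface("sphere", size = 65, radius = 100)
  expect_equal(sp$normal[33, 33, ], c(0, 0, 1), tolerance = 1e-12)
  # plane surfaces carry their stated constant gradients
  pl <- make_surface("plane", size = 16, p0 = 0.3, q0 = 0)
  expect_true(all(pl$p == 0.3) && all(pl$q == 0))
})

test_that("rendering honours albedo extremes", {
  surf <- make_surface("plane", size = 16, p0 = 0, q0 = 0)
  st <- render_lambertian(surf, light_set(c(0, 0), c(0, 0)), albedo = 1)
  expect_true(all(st$images[[1]] == 1))
  st0 <- render_lambertian(surf, lights3(), albedo = 0)
  for (im in st0$images) expect_true(all(im == 0))
})

test_that("conveyor truth satisfies the tuber-record invariants", {
  sc <- make_conveyor_frame(n_tubers = 6, seed = 17)
  tr <- sc$truth
  expect_true(all(tr$length >= tr$width & tr$width >= tr$height &
                    tr$height > 0))
  expect_true(all(tr$sieve_size >= tr$height & tr$sieve_size <= tr$width))
  expect_true(all(tr$band == size_band(tr$sieve_size)))
  # an empty belt really is empty
  sc0 <- make_conveyor_frame(n_tubers = 0, noise_sigma_mm = 0, seed = 1)
  expect_lt(diff(range(sc0$frame$depth)), 1e-9)
})

test_that("grass/dock scenes hit their coverage target with entropy contrast", {
  sc <- make_grass_dock(256, n_docks = 3, dock_area_fraction = 0.05,
                        seed = 12)
  expect_gte(mean(sc$truth_mask), 0.045)
  expect_lte(mean(sc$truth_mask), 0.055)
  em <- local_entropy(sc$image, 32, 64)
  expect_gt(mean(em$entropy[!sc$truth_mask]), mean(em$entropy[sc$truth_mask]))
  # dock-free scene has an empty truth mask
  expect_equal(sum(make_grass_dock(64, 0, 0, seed = 1)$truth_mask), 0)
})

test_that("GPS scenes produce Poisson-consistent record counts", {
  scene <- make_gps_scene(tuber_rate_hz = 0.8, seed = 3)
  lambda <- 0.8 * scene$duration_s
  expect_lt(abs(nrow(scene$records) - lambda), 4 * sqrt(lambda))
  expect_true(all(diff(scene$track$timestamp) > 0))
  # zero rate: a track with no records
  expect_equal(nrow(make_gps_scene(tuber_rate_hz = 0, seed = 1)$records), 0)
})

test_that("generated fixtures flow through the public file formats", {
  td <- file.path(tempdir(), "synth-io")
  dir.create(td, showWarnings = FALSE)
  # conveyor frame: float TIFF + sidecar -> measure_tubers
  sc <- make_conveyor_frame(n_tubers = 2, touching_prob = 0, seed = 4)
  fp <- file.path(td, "frame.tif")
  write_depth_frame(fp, sc$frame)
  rec <- measure_tubers(read_depth_frame(fp))
  expect_equal(nrow(rec), 2)
  # PS stack: 16-bit PNGs + YAML config -> solver
  surf <- make_surface("sphere", size = 48, radius = 150)
  st <- render_lambertian(surf, lights3(), albedo = 0.7)
  cfg <- write_ps_stack(file.path(td, "ps"), st, lights3())
  pc <- read_ps_config(cfg)
  f <- solve_ps_exact(pc$stack, pc$lights)
  v <- f$valid_mask & surf$mask
  # 16-bit quantisation bounds the recovered gradient error
  expect_lt(max(abs(f$p[v] - surf$p[v])), 2e-3)
})
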