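test_that("reflectance map matches the Lambertian model", {
  # normal aligned with light: R = albedo
  expect_equal(reflectance_map(0, 0, 0, 0, 0.8), 0.8)
  # surface normal parallel to light direction: R = albedo for any gradient
  for (g in list(c(0.3, -0.2), c(1, 1), c(0, 0.7)))
    expect_equal(reflectance_map(g[1], g[2], g[1], g[2], 0.55), 0.55)
  # hand evaluation: p=1 tilts the normal 45 degrees from a vertical light
  expect_equal(reflectance_map(1, 0, 0, 0, 1), 1 / sqrt(2), tolerance = 1e-5)
  # attached shadow clamps to zero
  expect_equal(reflectance_map(-2, 0, 2, 0, 1), 0)
  expect_error(reflectance_map(NA, 0, 0, 0, 1), "finite")
  expect_error(reflectance_map(0, 0, 0, 0, -0.1), "non-negative")
})

test_that("exact three-light solve inverts the forward render", {
  lights <- lights3()
  flat <- make_surface("plane", size = 24, p0 = 0, q0 = 0)
  st <- render_lambertian(flat, lights, albedo = 0.9)
  f <- solve_ps_exact(st, lights)
  expect_true(all(f$valid_mask))
  expect_lt(max(abs(f$p)), 1e-12)
  expect_lt(max(abs(f$q)), 1e-12)
  expect_lt(max(abs(f$albedo - 0.9)), 1e-12)
  expect_lt(max(abs(f$normal[, , 3] - 1)), 1e-12)

  tilted <- make_surface("plane", size = 24, p0 = 0.3, q0 = -0.2)
  st2 <- render_lambertian(tilted, lights, albedo = 0.6)
  f2 <- solve_ps_exact(st2, lights)
  expect_lt(max(abs(f2$p[f2$valid_mask] - 0.3)), 1e-9)
  expect_lt(max(abs(f2$q[f2$valid_mask] + 0.2)), 1e-9)
  expect_lt(max(abs(f2$albedo[f2$valid_mask] - 0.6)), 1e-9)
})

test_that("a cast-shadow (zeroed) pixel is flagged invalid, not solved", {
  lights <- lights3()
  st <- render_lambertian(make_surface("plane", size = 16), lights,
                          albedo = 0.7)
  imgs <- st$images
  imgs[[2]][5, 7] <- 0
  f <- solve_ps_exact(image_stack(imgs), lights)
  expect_false(f$valid_mask[5, 7])
  expect_true(is.na(f$albedo[5, 7]))
  expect_true(all(f$valid_mask[-5, ]))
})

test_that("collinear-azimuth light sets are rejected by name", {
  bad <- light_set(c(0.5, -0.5, 0.25), c(0, 0, 0))
  st <- render_lambertian(make_surface("plane", size = 8), lights3(),
                          albedo = 0.5)
  expect_error(solve_ps_exact(st, bad), "collinear in azimuth")
})

test_that("least-squares solve recovers a sphere and reduces to exact for 3 lights", {
  surf <- make_surface("sphere", size = 65, radius = 200)
  st4 <- render_lambertian(surf, lights4(), albedo = 0.8)
  f4 <- solve_ps_lsq(st4, lights4())
  expect_lt(mean(angular_error(f4, surf)), 1e-6)
  expect_lt(max(abs(f4$albedo[f4$valid_mask & surf$mask] - 0.8)), 1e-8)

  st3 <- render_lambertian(surf, lights3(), albedo = 0.8)
  fe <- solve_ps_exact(st3, lights3())
  fl <- solve_ps_lsq(st3, lights3())
  expect_equal(fl$p, fe$p, tolerance = 1e-12)
  expect_equal(fl$albedo, fe$albedo, tolerance = 1e-12)
  expect_identical(fl$valid_mask, fe$valid_mask)
})

test_that("under noise the four-light solve beats every three-light subset", {
  surf <- make_surface("sphere", size = 65, radius = 200)
  st <- render_lambertian(surf, lights4(), albedo = 0.7, noise_sigma = 0.01,
                          seed = 11)
  e4 <- mean(angular_error(solve_ps_lsq(st, lights4()), surf))
  e3 <- vapply(utils::combn(4, 3, simplify = FALSE), function(ix) {
    mean(angular_error(
      solve_ps_exact(image_stack(st$images[ix]),
                     light_set(lights4()$ps[ix], lights4()$qs[ix])), surf))
  }, 0)
  expect_lt(e4, min(e3))
})

test_that("scaling light intensity scales albedo and leaves normals unchanged", {
  surf <- make_surface("sphere", size = 33, radius = 120)
  st1 <- render_lambertian(surf, lights3(), albedo = 0.4)
  st2 <- render_lambertian(surf, lights3(), albedo = 0.8)
  f1 <- solve_ps_exact(st1, lights3())
  f2 <- solve_ps_exact(st2, lights3())
  v <- f1$valid_mask & f2$valid_mask
  expect_equal(f2$albedo[v] / f1$albedo[v], rep(2, sum(v)), tolerance = 1e-9)
  expect_equal(f1$p[v], f2$p[v], tolerance = 1e-9)
  expect_equal(f1$q[v], f2$q[v], tolerance = 1e-9)
})

test_that("noiseless renders round-trip to machine precision across seeds", {
  for (s in 1:5) {
    surf <- make_surface("rosette", size = 64, seed = s)
    st <- render_lambertian(surf, lights4(), albedo = 0.7)
    f <- solve_ps_lsq(st, lights4())
    shadow <- attr(st, "shadow_truth")
    v <- f$valid_mask & surf$mask & !shadow
    expect_gt(mean(v), 0.5)
    expect_lt(max(abs(f$p[v] - surf$p[v])), 1e-8)
    expect_lt(max(abs(f$q[v] - surf$q[v])), 1e-8)
    expect_lt(max(abs(f$albedo[v] - 0.7)), 1e-8)
  }
})

test_that("two-source gradient recovery is exact and q-independent", {
  l2 <- light_set(c(0.5, -0.5), c(0, 0))
  # i1 = i2 forces p = 0
  g0 <- two_source_gradient(matrix(0.4, 8, 8), matrix(0.4, 8, 8), l2)
  expect_true(all(g0$p[g0$valid_mask] == 0))
  # q drops out of the ratio: sweep q over a grid at fixed p
  for (qv in c(-0.8, -0.3, 0, 0.4, 1.1)) {
    surf <- make_surface("plane", size = 16, p0 = 0.2, q0 = qv)
    st <- render_lambertian(surf, l2, albedo = 0.5)
    g <- two_source_gradient(st$images[[1]], st$images[[2]], l2)
    expect_lt(max(abs(g$p[g$valid_mask] - 0.2)), 1e-12)
  }
  # asymmetric lights are a configuration error
  expect_error(two_source_gradient(matrix(0.4, 4, 4), matrix(0.4, 4, 4),
                                   light_set(c(0.5, -0.4), c(0, 0))),
               "symmetric")
  expect_error(two_source_gradient(matrix(0.4, 4, 4), matrix(0.4, 4, 4),
                                   light_set(c(0.5, -0.5), c(0.1, 0))),
               "symmetric")
})

test_that("two-source gradient agrees with the full solve on the x-axis pair", {
  surf <- make_surface("sphere", size = 49, radius = 150)
  l4 <- lights4()
  st <- render_lambertian(surf, l4, albedo = 0.7)
  full <- solve_ps_lsq(st, l4)
  two <- two_source_gradient(st$images[[1]], st$images[[2]],
                             light_set(l4$ps[1:2], l4$qs[1:2]))
  v <- full$valid_mask & two$valid_mask & surf$mask
  expect_lt(max(abs(full$p[v] - two$p[v])), 1e-6)
})

test_that("shadow mask applies the open intensity interval per image", {
  st <- image_stack(list(matrix(0.5, 8, 8), matrix(0.5, 8, 8)))
  expect_true(all(shadow_mask(st, 0.02, 0.98)))
  im <- matrix(0.5, 8, 8); im[3, 3] <- 1
  st2 <- image_stack(list(im, matrix(0.5, 8, 8)))
  m <- shadow_mask(st2, 0.02, 0.98)
  expect_false(m[3, 3]); expect_equal(sum(!m), 1)
  expect_error(shadow_mask(st, 0.5, 0.5), "low < high")
})

test_that("shadow-mask exclusions match the analytic attached-shadow set", {
  surf <- make_surface("sphere", size = 65, radius = 60)
  grazing <- light_set(c(1.2, 1.2), c(0, 0))   # duplicated grazing light
  st <- render_lambertian(surf, grazing, albedo = 1)
  low <- 0.02
  m <- shadow_mask(st, low, 0.999)
  # analytic n . L from the generator's exact normals
  L <- grazing$L[1, ]
  ndl <- surf$normal[, , 1] * L[1] + surf$normal[, , 2] * L[2] +
    surf$normal[, , 3] * L[3]
  expected <- ndl > low & ndl < 0.999 & surf$mask
  expect_identical(m[surf$mask], expected[surf$mask])
})
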