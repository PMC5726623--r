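test_that("light placement maps spread to arc angle", {
  L0 <- place_lights(0)
  for (l in L0) expect_equal(l$position, c(0, -5, 0))
  L1 <- place_lights(1)
  expect_equal(L1$left$position, c(-5, 0, 0))
  expect_equal(L1$right$position, c(5, 0, 0))
  Lh <- place_lights(0.5)
  expect_equal(Lh$left$position, c(-5 * sin(pi / 4), -5 * cos(pi / 4), 0))
  expect_equal(Lh$right$position, c(5 * sin(pi / 4), -5 * cos(pi / 4), 0))
  for (a in c(0, 0.17, 0.5, 0.93, 1))
    for (l in place_lights(a))
      expect_equal(sqrt(sum(l$position^2)), 5, tolerance = 1e-9)
  expect_error(place_lights(-0.1), "alpha")
  expect_error(place_lights(1.2), "alpha")
})

test_that("smoothness-roughness mapping and Fresnel follow their closed forms", {
  expect_equal(smoothness_to_roughness(1), 0)
  expect_equal(smoothness_to_roughness(0), 1)
  expect_equal(smoothness_to_roughness(0.2), 0.64)
  expect_error(smoothness_to_roughness(1.5), "smoothness")
  expect_equal(fresnel_schlick(1, 0.04), 0.04)
  expect_equal(fresnel_schlick(0, 0.04), 1)
  expect_equal(fresnel_schlick(0.5, 0.04), 0.04 + 0.96 * 0.5^5)
})

test_that("GGX NDF is normalized, peaked at the normal, widens with roughness", {
  for (a in c(0.04, 0.16, 0.36, 0.64)) {
    # maximal at n.h = 1, monotone in n.h (the lobe is a decreasing
    # function of the angle from the normal)
    x <- seq(0, 1, length.out = 500)
    d <- ggx_ndf(x, a)
    expect_true(all(diff(d) > 0))
    expect_equal(which.max(d), length(x))
    # projected hemispherical integral = 1 by quadrature
    th <- seq(0, pi / 2, length.out = 20001)
    f <- ggx_ndf(cos(th), a) * cos(th) * sin(th)
    integral <- 2 * pi * sum((f[-1] + f[-length(f)]) / 2) * diff(th)[1]
    expect_equal(integral, 1, tolerance = 1e-3)
  }
  # angular half-width at half max grows strictly with a (by bisection)
  hwhm <- function(a) {
    f <- function(th) ggx_ndf(cos(th), a) - ggx_ndf(1, a) / 2
    stats::uniroot(f, c(1e-6, pi / 2 - 1e-6), tol = 1e-10)$root
  }
  w <- vapply(c(0.04, 0.16, 0.36, 0.64), hwhm, 0)
  expect_true(all(diff(w) > 0))
  # roughness 0 is floored, not infinite
  expect_true(is.finite(ggx_ndf(1, 0)))
})

test_that("attenuation reaches zero at range and is monotone", {
  expect_equal(attenuation(10, 10), 0)
  expect_equal(attenuation(0, 10), 1)
  d <- seq(0, 10, length.out = 2000)
  expect_true(all(diff(attenuation(d, 10)) <= 1e-15))
  expect_error(attenuation(1, -1), "range")
})

test_that("shade obeys ambient, linearity and mirror maximization", {
  p <- c(0, -0.04, 0); n <- c(0, -1, 0); v <- c(0, -1, 0)
  off <- list(point_light(c(0, -5, 0), intensity = 0))
  expect_equal(as.numeric(shade(p, n, v, off, material(0.4))),
               rep(0.6 * 0.5, 3))
  # doubling all intensities doubles radiance when ambient is off
  l1 <- place_lights(0.3, intensity = 0.7)
  l2 <- place_lights(0.3, intensity = 1.4)
  s1 <- shade(p, n, v, l1, material(0.5), ambient_intensity = 0)
  s2 <- shade(p, n, v, l2, material(0.5), ambient_intensity = 0)
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
  # back-facing points get ambient only
  s <- shade(p, -n, v, l1, material(0.5))
  expect_equal(as.numeric(s), rep(0.3, 3))
  # specular-only response is maximal when the normal equals the half vector
  Lpos <- c(3, -4, 0) / 5 * 5
  light <- list(point_light(Lpos, intensity = 1))
  vdir <- c(0, -1, 0)
  ldir <- (Lpos - p) / sqrt(sum((Lpos - p)^2))
  h <- (ldir + vdir) / sqrt(sum((ldir + vdir)^2))
  mat <- material(0.6, albedo = c(0, 0, 0))
  lum_at <- function(nrm) shade(p, nrm, vdir, light, mat,
                                ambient_intensity = 0)[1]
  base <- lum_at(h)
  for (dth in c(-0.05, -0.02, 0.02, 0.05)) {
    R <- rbind(c(cos(dth), -sin(dth), 0), c(sin(dth), cos(dth), 0),
               c(0, 0, 1))
    expect_lt(lum_at(as.numeric(R %*% h)), base)
  }
})

test_that("render masks the background and handles degenerate scenes", {
  img <- single_light_render(0.6, size = 64)
  # foreground of a sphere render is a filled disc: area close to pi r^2
  # of the projected radius, and the mask is a single connected region
  expect_true(any(img$foreground_mask))
  expect_equal(img$n_views, 1L)
  expect_true(all(img$luminance >= 0))
  expect_true(all(img$luminance[!img$foreground_mask] == 0))
  # lights off + ambient: constant luminance over the foreground
  sc <- scene(test_sphere_mesh(), material(0.4),
              list(point_light(c(0, -5, 0), intensity = 0)))
  flat <- render(sc, default_camera(size = c(64, 64)))
  vals <- flat$luminance[flat$foreground_mask]
  expect_equal(stats::sd(vals), 0)
  expect_equal(vals[1], 0.3, tolerance = 1e-12)
  expect_error(render(scene(triangle_mesh(matrix(0, 1, 3),
                                          matrix(integer(0), 0, 3)),
                            material(0.5), list()),
                      default_camera()),
               "empty mesh")
})

test_that("clipping only affects pixels at or above the ceiling", {
  sc <- scene(test_sphere_mesh(), material(0.6),
              place_lights(0.1, intensity = 60))
  cam <- default_camera(size = c(64, 64))
  raw <- render(sc, cam, clip = FALSE)
  cl <- render(sc, cam, clip = TRUE)
  expect_gt(cl$clipped_count, 0)
  over <- raw$rgb >= 1
  expect_true(all(cl$rgb[!over] == raw$rgb[!over]))
  expect_true(all(cl$rgb <= 1))
  expect_equal(raw$clipped_count, 0L)
})

test_that("stereo rendering concatenates two half images", {
  sc <- scene(test_sphere_mesh(), material(0.5), place_lights(0.2, 1.5))
  cl <- default_camera("left", size = c(48, 48))
  cr <- default_camera("right", size = c(48, 48))
  st <- render_stereo(sc, cl, cr)
  expect_equal(dim(st$luminance), c(48, 96))
  expect_equal(st$n_views, 2L)
  # identical cameras give two identical halves
  same <- render_stereo(sc, cl, cl)
  expect_equal(same$luminance[, 1:48], same$luminance[, 49:96])
  # swapping cameras mirrors the half order
  sw <- render_stereo(sc, cr, cl)
  expect_equal(sw$luminance[, 1:48], st$luminance[, 49:96])
  expect_error(render_stereo(sc, cl, default_camera("right",
                                                    size = c(32, 32))),
               "size")
})

test_that("total foreground luminance is monotone in light intensity", {
  sc_at <- function(i) scene(test_sphere_mesh(), material(0.45),
                             place_lights(0.3, intensity = i))
  cam <- default_camera(size = c(64, 64))
  tot <- vapply(c(0.25, 0.5, 1, 1.5, 2.5),
                function(i) sum(render(sc_at(i), cam,
                                       clip = FALSE)$luminance), 0)
  expect_true(all(diff(tot) > 0))
})

test_that("highlight peak luminance increases with smoothness", {
  peaks <- vapply(c(0.2, 0.3, 0.4, 0.5, 0.6),
                  function(s) max(single_light_render(s)$luminance), 0)
  expect_true(all(diff(peaks) > 0))
})

test_that("the image is invariant under rigid rotation of the whole scene", {
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  mesh <- test_blob_mesh(1, resolution = 3)
  lights <- place_lights(0.32, 1.5)
  cam <- default_camera(size = c(64, 64))
  img1 <- render(scene(mesh, material(0.5), lights), cam, clip = FALSE)
  mesh_r <- triangle_mesh(mesh$vertices %*% t(R), mesh$faces,
                          normals = mesh$normals %*% t(R))
  lights_r <- lapply(lights, function(l) {
    l$position <- as.numeric(R %*% l$position); l
  })
  cam_r <- camera(as.numeric(R %*% cam$position),
                  as.numeric(R %*% cam$target), fov = cam$fov,
                  size = cam$size)
  img2 <- render(scene(mesh_r, material(0.5), lights_r), cam_r, clip = FALSE)
  expect_equal(img2$foreground_mask, img1$foreground_mask)
  expect_lt(max(abs(img2$luminance - img1$luminance)), 1e-6)
})
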