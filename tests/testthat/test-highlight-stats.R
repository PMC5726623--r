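test_that("gloss-layer threshold is mean + 2 population SD, strictly greater", {
  lum <- matrix(c(1, 1, 1, 1, 1, 1, 1, 1, 5), 3, 3)
  img <- toy_image(lum)
  gl <- segment_gloss_layer(img)
  v <- as.numeric(lum)
  expect_equal(gl$threshold, mean(v) + 2 * sqrt(mean((v - mean(v))^2)))
  # constant foreground: threshold equals the mean, no pixel strictly above
  flat <- segment_gloss_layer(toy_image(matrix(0.3, 4, 4)))
  expect_equal(flat$n_components, 0)
  expect_false(any(flat$binary_mask))
  # empty foreground errors
  expect_error(segment_gloss_layer(toy_image(matrix(0, 2, 2),
                                             matrix(FALSE, 2, 2))),
               "foreground")
})

test_that("threshold is equivariant under a constant luminance shift", {
  set.seed(21)
  lum <- matrix(runif(400), 20, 20)
  fg <- matrix(runif(400) > 0.2, 20, 20)
  g1 <- segment_gloss_layer(toy_image(lum, fg))
  g2 <- segment_gloss_layer(toy_image(lum + 0.37, fg))
  expect_equal(g2$threshold, g1$threshold + 0.37, tolerance = 1e-12)
  expect_identical(g2$binary_mask, g1$binary_mask)
})

test_that("diagonally touching pixels form one 8-connected component", {
  lum <- matrix(0.1, 5, 5)
  lum[2, 2] <- 0.9
  lum[3, 3] <- 0.8
  gl <- segment_gloss_layer(toy_image(lum))
  expect_equal(gl$n_components, 1)
  # the same mask under 4-connectivity gives two components (oracle)
  expect_equal(max(flood_fill_label(gl$binary_mask, 4)), 2)
  expect_equal(max(flood_fill_label(gl$binary_mask, 8)), 1)
})

test_that("component labelling matches a brute-force flood fill", {
  set.seed(33)
  for (rep in 1:200) {
    mask <- matrix(runif(32 * 32) < runif(1, 0.1, 0.6), 32, 32)
    lab <- label_components(mask)
    oracle <- flood_fill_label(mask, 8)
    expect_equal(max(lab), max(oracle))
    expect_identical(canonical_labels(lab), canonical_labels(oracle))
  }
  # the same labelling drives segmentation end to end: sparse bright pixels
  # survive the mean + 2 SD threshold and come back labelled
  set.seed(34)
  for (rep in 1:20) {
    mask <- matrix(runif(32 * 32) < 0.05, 32, 32)
    lum <- matrix(0.1, 32, 32)
    lum[mask] <- 1
    gl <- segment_gloss_layer(toy_image(lum))
    expect_identical(gl$binary_mask, mask)
    expect_equal(gl$n_components, max(flood_fill_label(mask, 8)))
  }
})

test_that("highlight statistics follow their definitions", {
  lum <- matrix(0.1, 6, 6)
  lum[2, 2] <- 0.8; lum[2, 3] <- 0.9; lum[3, 2] <- 1.0; lum[3, 3] <- 0.9
  img <- toy_image(lum)
  gl <- segment_gloss_layer(img)
  st <- compute_statistics(gl, img)
  expect_equal(gl$n_components, 1)
  expect_equal(st$mean_size, 4)
  expect_equal(st$strength, 0.9)
  expect_equal(st$pct_area, 4 / 36)
  expect_true(st$valid)
  # stereo convention: components divided by the number of views
  img2 <- toy_image(cbind(lum, lum), n_views = 2)
  st2 <- compute_statistics(segment_gloss_layer(img2), img2)
  expect_equal(st2$number, 1)        # 2 components over 2 half-images
  expect_equal(st2$mean_size, 4)
  # empty layer: statistics are missing and flagged
  st0 <- compute_statistics(segment_gloss_layer(toy_image(matrix(1, 3, 3))),
                            toy_image(matrix(1, 3, 3)))
  expect_false(st0$valid)
  expect_true(is.na(st0$pct_area))
  # a layer covering the whole foreground has pct_area 1
  full_layer <- list(binary_mask = matrix(TRUE, 3, 3),
                     labels = matrix(1L, 3, 3), n_components = 1,
                     threshold = 0)
  stf <- compute_statistics(full_layer, toy_image(matrix(0.5, 3, 3)))
  expect_equal(stf$pct_area, 1)
})

test_that("contrast measures follow their closed forms", {
  flat <- toy_image(matrix(0.4, 8, 8))
  ct <- contrasts(flat)
  expect_equal(ct$michelson, 0)
  expect_equal(ct$space_avg_michelson, 0)
  expect_equal(ct$space_avg_whittle, 0)
  two <- matrix(0.2, 10, 10); two[, 6:10] <- 0.6
  ct2 <- contrasts(toy_image(two))
  expect_equal(ct2$michelson, 0.5)
  # multiplicative luminance scaling leaves Michelson measures unchanged
  set.seed(5)
  lum <- matrix(runif(900, 0.1, 1), 30, 30)
  a <- contrasts(toy_image(lum))
  b <- contrasts(toy_image(3 * lum))
  expect_equal(b$michelson, a$michelson, tolerance = 1e-12)
  expect_equal(b$space_avg_michelson, a$space_avg_michelson,
               tolerance = 1e-12)
  expect_equal(b$space_avg_whittle, a$space_avg_whittle, tolerance = 1e-9)
  expect_error(contrasts(toy_image(matrix(1, 2, 2), matrix(FALSE, 2, 2))),
               "foreground")
})

test_that("contrasts ignore the background", {
  set.seed(6)
  lum <- matrix(runif(400, 0.2, 0.8), 20, 20)
  fg <- matrix(TRUE, 20, 20); fg[1:5, ] <- FALSE
  a <- contrasts(toy_image(lum, fg))
  lum2 <- lum; lum2[!fg] <- 99  # arbitrary background values
  b <- contrasts(toy_image(lum2, fg))
  expect_equal(b, a)
})

test_that("validity flags reproduce the two exclusion rules", {
  # clipped foreground pixel
  lum <- matrix(0.2, 6, 6); lum[3, 3] <- 1
  img <- toy_image(lum, clip = TRUE, clip_ceiling = 1)
  vf <- validity(img)
  expect_true(vf$clipped)
  expect_true(vf$invalid)
  # constant image: empty gloss layer
  vf2 <- validity(toy_image(matrix(0.4, 5, 5)))
  expect_true(vf2$empty_gloss_layer)
  expect_true(vf2$invalid)
  # a mid-smoothness low-intensity stimulus is valid end to end
  img3 <- stimulus_render("sphere", 0.5, 0.16, 0.5)
  vf3 <- validity(img3)
  expect_false(vf3$invalid)
})

test_that("pct_area grows and strength rises with smoothness where defined", {
  # in this shading world the mean + 2 SD rule detects highlights from
  # smoothness ~0.4 upward on a smooth single-light sphere; across that
  # range the layer strengthens monotonically
  st <- lapply(c(0.4, 0.5, 0.6), function(s) {
    img <- single_light_render(s)
    compute_statistics(segment_gloss_layer(img), img)
  })
  strength <- vapply(st, `[[`, 0, "strength")
  expect_true(all(diff(strength) > 0))
  expect_true(all(vapply(st, `[[`, TRUE, "valid")))
  # at low smoothness the broad weak lobe stays within 2 SD of the mean:
  # empty layer, flagged invalid (the regime the exclusion rules exist for)
  img02 <- single_light_render(0.2)
  expect_equal(segment_gloss_layer(img02)$n_components, 0)
})

test_that("stimulus_record assembles one CSV-ready row", {
  img <- stimulus_render("sphere", 0.5, 0.32, 1.5)
  rec <- stimulus_record(img, meta = list(shape = "sphere", smoothness = 0.5,
                                          alpha = 0.32, intensity = 1.5))
  expect_equal(nrow(rec), 1)
  expect_true(all(c("shape", "smoothness", "alpha", "intensity", "number",
                    "mean_size", "pct_area", "strength", "michelson",
                    "sa_michelson", "sa_whittle", "invalid",
                    "clipped_count") %in% names(rec)))
  expect_false(rec$invalid)
  expect_gt(rec$strength, rec$michelson)
})
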