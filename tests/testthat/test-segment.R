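test_that("region means match direct evaluation on small cases", {
  img <- matrix(c(1, 1, 1,
                  1, 5, 5,
                  1, 5, 5), 3, 3, byrow = TRUE)
  phi <- matrix(-1, 3, 3); phi[2:3, 2:3] <- 1
  expect_equal(region_means(img, phi), c(c1 = 5, c2 = 1))
  # constant image: both means equal the constant
  expect_equal(region_means(matrix(0.3, 4, 4), phi = matrix(c(1, -1), 4, 4)),
               c(c1 = 0.3, c2 = 0.3))
  # checkerboard exact partition
  cb <- matrix(rep(c(0, 1), 8), 4, 4)
  expect_equal(region_means(cb, ifelse(cb == 1, 1, -1)), c(c1 = 1, c2 = 0))
  # phi == 0 counts as outside (exact Heaviside)
  phi0 <- matrix(0, 3, 3); phi0[1, 1] <- 1
  expect_equal(unname(region_means(img, phi0)[1]), img[1, 1])
  expect_error(region_means(img, matrix(1, 3, 3)),
               class = "octedema_collapse_error")
})

test_that("spf evaluates the midpoint-normalized force and keeps its range", {
  img <- matrix(c(1, 5, 5, 1, 1, 5), 2, 3)
  out <- spf(img, c1 = 5, c2 = 1)
  expect_equal(out[img == 5], rep(1, 3))
  expect_equal(out[img == 1], rep(-1, 3))
  expect_error(spf(matrix(2, 3, 3), 2, 2), class = "octedema_degenerate_error")
  for (i in 1:20) {
    set.seed(i)
    r <- matrix(runif(36), 6, 6)
    cm <- region_means(r, matrix(c(1, -1), 6, 6))
    v <- spf(r, cm["c1"], cm["c2"])
    expect_true(all(v >= -1 & v <= 1))
  }
})

test_that("evolve_step has zero-force and fixed-point behaviour", {
  img <- rbind(matrix(0.1, 8, 16), matrix(0.9, 8, 16))
  phi_match <- ifelse(img > 0.5, 1, -1)
  cfg <- sbgfrls_config()
  st <- octedema:::new_level_set_state(phi_match)
  # alpha = 0: no force, mask unchanged
  s0 <- evolve_step(st, img, sbgfrls_config(alpha = 0))
  expect_identical(s0$phi > 0, phi_match > 0)
  # correct binary partition is a fixed point
  s1 <- evolve_step(st, img, cfg)
  expect_identical(s1$phi > 0, phi_match > 0)
  expect_equal(attr(s1, "changed"), 0)
  expect_equal(s1$iteration, 1L)
})

test_that("an inverted initialization still converges onto the bright object", {
  # bright block on dark background; phi > 0 on the *background*: the
  # contour shrinks where it lies outside the object and expands where it
  # lies inside, so the positive region migrates onto the object
  img <- matrix(0.1, 32, 32); img[10:22, 10:22] <- 0.9
  phi <- ifelse(img > 0.5, -1, 1)
  st <- octedema:::new_level_set_state(phi)
  cfg <- sbgfrls_config()
  gap <- numeric(8)
  for (k in 1:8) {
    st <- evolve_step(st, img, cfg)
    gap[k] <- abs(st$c1 - 0.9)   # distance of the inside mean from the object
  }
  expect_lt(gap[8], gap[1])
  expect_gte(dice_of(st$phi > 0, img > 0.5), 0.95)
})

test_that("segment recovers the clean phantom almost exactly", {
  p <- generate_phantom(small_spec(seed = 1, speckle_shape = 1e9,
                                   background_noise_sd = 0))
  seg <- segment(p$clean)
  expect_gte(dice_of(seg$retina_mask, p$retina_mask), 0.99)
  expect_gte(dice_of(seg$edema_mask, p$edema_mask), 0.95)
  expect_true(seg$converged)
  expect_lte(seg$iterations, seg$history$iteration[nrow(seg$history)])
  expect_false(any(seg$edema_mask & !seg$retina_mask))
  expect_named(seg$history, c("iteration", "c1", "c2", "changed_fraction"))
})

test_that("segment converges well before the iteration cap on phantoms", {
  p <- generate_phantom(small_spec(seed = 6))
  seg <- segment(enhance(p$image))
  expect_true(seg$converged)
  expect_lt(seg$iterations, 100)
})

test_that("extract_edema isolates interior dark components only", {
  p <- generate_phantom(small_spec(seed = 2, speckle_shape = 1e9,
                                   background_noise_sd = 0))
  # no cavities: empty mask
  flat <- render_clean(phantom_spec(height = 64L, width = 96L, band_top = 18L,
                                    band_bottom = 50L, band_offset = 0,
                                    edema = list()))
  e0 <- extract_edema(flat$retina_mask, flat$clean)
  expect_false(any(e0))
  # one cavity: one component, centroid within 2 px of the spec center
  e1 <- extract_edema(p$retina_mask, p$clean)
  lab <- EBImage::bwlabel(e1 * 1L)
  expect_equal(max(lab), 1L)
  ctr <- c(mean(row(e1)[e1]), mean(col(e1)[e1]))
  expect_lt(max(abs(ctr - c(34, 48))), 2)
  # two cavities: two components
  sp2 <- phantom_spec(height = 64L, width = 96L, band_top = 18L,
                      band_bottom = 50L, band_offset = 0,
                      edema = list(c(34, 28, 6, 10), c(34, 70, 6, 10)),
                      speckle_shape = 1e9, background_noise_sd = 0)
  p2 <- generate_phantom(sp2)
  e2 <- extract_edema(p2$retina_mask, p2$clean)
  expect_equal(max(EBImage::bwlabel(e2 * 1L)), 2L)
  expect_false(any(e2 & !p2$retina_mask))
  expect_error(extract_edema(matrix(FALSE, 4, 4), matrix(0.5, 4, 4)),
               class = "octedema_collapse_error")
})

test_that("sbgfrls_config validates its invariants", {
  expect_error(sbgfrls_config(dt = 0), class = "octedema_spec_error")
  expect_error(sbgfrls_config(reg_sigma = -1), class = "octedema_spec_error")
  expect_error(sbgfrls_config(max_iter = 0), class = "octedema_spec_error")
  expect_error(sbgfrls_config(tol = 1), class = "octedema_spec_error")
})
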