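test_that("contrast enhancement is a clipped affine rescale onto [0, 1]", {
  sl <- matrix(c(0, 100, 50, 25), 2, 2)
  out <- enhance_contrast(sl, 0, 100)
  expect_equal(out, (sl - 0) / 100) # closed-form (v - min)/(max - min)
  expect_identical(sort(unique(as.numeric(
    enhance_contrast(matrix(c(0, 100), 10, 10), 0, 100)))), c(0, 1))
  # monotone: rank order preserved
  set.seed(2)
  sl2 <- matrix(stats::runif(100, -5, 40), 10)
  out2 <- enhance_contrast(sl2, 1, 99)
  expect_true(all(diff(out2[order(sl2)]) >= 0))
  expect_true(all(out2 >= 0 & out2 <= 1))
})

test_that("a constant slice enhances to all zeros with a warning", {
  expect_warning(out <- enhance_contrast(matrix(7, 5, 5)), "zero")
  expect_equal(out, matrix(0, 5, 5))
})

test_that("region growing covers a uniform slice and respects bounds", {
  sl <- matrix(3, 8, 11)
  expect_true(all(grow_region(sl, c(4, 6), 0)))
  expect_error(grow_region(sl, c(0, 6), 1), "outside")
  expect_error(grow_region(sl, c(4, 12), 1), "outside")
})

test_that("region growing segments a disc exactly and stays off it from outside", {
  sl <- matrix(0, 30, 30)
  disc <- outer(1:30, 1:30, function(r, c) (r - 15)^2 + (c - 15)^2 <= 64)
  sl[disc] <- 100
  expect_identical(grow_region(sl, c(15, 15), 50), disc)
  expect_false(any(grow_region(sl, c(2, 2), 50) & disc))
})

test_that("region growing equals the brute-force flood fill on random slices", {
  set.seed(77)
  kinds <- rep(c("disc", "annulus_adjacent", "uniform"), length.out = 50)
  for (i in seq_len(50)) {
    sc <- random_disc_slice(kinds[i])
    tol <- stats::runif(1, 20, 60)
    expect_identical(grow_region(sc$slice, sc$seed, tol),
                     oracle_flood_fill(sc$slice, sc$seed, tol))
  }
})

test_that("contour tracing handles degenerate and full-frame masks", {
  single <- matrix(FALSE, 5, 5); single[3, 4] <- TRUE
  ct <- trace_contour(single, 2L)
  expect_equal(unname(ct$points_px), matrix(c(3, 4), 1))
  full <- matrix(TRUE, 4, 6)
  ctf <- trace_contour(full, 1L)
  pts <- unique(ctf$points_px)
  border <- which(outer(1:4, 1:6, function(r, c)
    r %in% c(1, 4) | c %in% c(1, 6)), arr.ind = TRUE)
  expect_setequal(paste(pts[, 1], pts[, 2]),
                  paste(border[, 1], border[, 2]))
  expect_error(trace_contour(matrix(FALSE, 3, 3)), "empty")
  two <- matrix(FALSE, 5, 5); two[1, 1] <- TRUE; two[5, 5] <- TRUE
  expect_error(trace_contour(two), "2")
})

test_that("disc contour is a closed boundary loop of the right length", {
  mask <- outer(1:40, 1:40, function(r, c) (r - 20)^2 + (c - 20)^2 <= 100)
  ct <- trace_contour(mask, 3L)
  p <- ct$points_px
  expect_lt(abs(nrow(p) - 2 * pi * 10) / (2 * pi * 10), 0.15)
  expect_lte(max(abs(p[1, ] - p[nrow(p), ])), 1) # loop closed
  expect_true(all(mask[p])) # all on foreground
  # every contour pixel touches background or the border
  on_boundary <- apply(p, 1, function(q) {
    any(sapply(-1:1, function(dr) sapply(-1:1, function(dc) {
      r <- q[1] + dr; c_ <- q[2] + dc
      r < 1 || r > 40 || c_ < 1 || c_ > 40 || !mask[r, c_]
    })))
  })
  expect_true(all(on_boundary))
})

test_that("contour tracing is invariant to background padding", {
  mask <- outer(1:20, 1:20, function(r, c) (r - 10)^2 + (c - 11)^2 <= 30)
  padded <- matrix(FALSE, 26, 27)
  padded[4 + (1:20), 5 + (1:20)] <- mask
  ct0 <- trace_contour(mask, 1L)$points_px
  ct1 <- trace_contour(padded, 1L)$points_px
  expect_equal(unname(ct1), unname(sweep(ct0, 2, c(4, 5), "+")))
})

test_that("stack_contours maps pixels through spacing and origin", {
  vol <- voxel_volume(array(0, c(4, 6, 5)), spacing = c(1, 1, 1))
  ct <- structure(list(slice_index = 2L,
                       points_px = rbind(c(1, 1), c(2, 3), c(4, 5))),
                  class = "slice_contour")
  cloud <- stack_contours(list(ct), vol)
  expect_equal(unname(cloud),
               unname(cbind(1, rbind(c(0, 0), c(1, 2), c(3, 4)))))
  vol2 <- voxel_volume(array(0, c(4, 6, 5)), spacing = c(2.0, 0.5, 0.5),
                       origin = c(10, -1, 3))
  cloud2 <- stack_contours(list(ct), vol2)
  # manual affine map of each index triple
  manual <- t(apply(rbind(c(2, 1, 1), c(2, 2, 3), c(2, 4, 5)), 1,
                    function(ix) c(10, -1, 3) + (ix - 1) * c(2, 0.5, 0.5)))
  expect_equal(unname(cloud2), manual)
  expect_error(stack_contours(list(structure(list(slice_index = 9L,
                                                  points_px = rbind(c(1, 1))),
                                             class = "slice_contour")),
                              vol), "range")
  expect_equal(nrow(stack_contours(list(), vol)), 0)
})

test_that("segmenting a voxelized bone recovers the true surface", {
  s <- fixture_sample("cuboid", seed = 55, side = "right")
  vol <- voxelize(s$mesh, spacing_mm = 1, inside_level = 1000,
                  outside_level = 0, noise_sd = 10, seed = 2)
  seg <- segment_volume(vol, seed_mm = colMeans(s$mesh$vertices),
                        tolerance = 0.3)
  expect_gt(nrow(seg$cloud), 200)
  # distance from cloud points to the true star surface, measured radially
  ctr <- colMeans(s$mesh$vertices)
  d <- sweep(seg$cloud, 2, ctr)
  r <- sqrt(rowSums(d^2))
  u <- d / r
  th <- acos(pmin(1, pmax(-1, u[, 3])))
  ph <- atan2(u[, 2], u[, 1]) %% (2 * pi)
  truth <- fit_spharm(parameterize(s$mesh), 4)
  r_true <- reconstruct_radii(truth, th, ph)
  expect_gt(mean(abs(r - r_true) <= 1.5 * 1), 0.95)
})
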