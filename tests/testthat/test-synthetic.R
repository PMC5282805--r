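zero_var_spec <- function() {
  spec <- default_bone_classes()$cuboid
  bone_class_spec(spec$name, spec$mean_coeffs,
                  rep(0, length(spec$mean_coeffs)),
                  spec$landmark_patch_dirs)
}

test_that("zero-variance populations reproduce the class mean exactly", {
  pop <- sample_population(zero_var_spec(), 3, seed = 5)
  right <- Filter(function(s) s$side == "right", pop)
  expect_length(pop, 6)
  for (s in right) {
    expect_identical(s$coeffs_true, default_bone_classes()$cuboid$mean_coeffs)
  }
})

test_that("the same seed reproduces a population bit-for-bit", {
  spec <- default_bone_classes()$talus
  a <- sample_population(spec, 4, seed = 99)
  b <- sample_population(spec, 4, seed = 99)
  expect_identical(a, b)
  c_ <- sample_population(spec, 4, seed = 100)
  expect_false(identical(a, c_))
})

test_that("sample means converge to class means (law of large numbers)", {
  spec0 <- default_bone_classes()$navicular
  spec <- bone_class_spec(spec0$name, spec0$mean_coeffs,
                          rep(0.05, length(spec0$mean_coeffs)),
                          spec0$landmark_patch_dirs)
  pop <- sample_population(spec, 200, seed = 31)
  right <- Filter(function(s) s$side == "right", pop)
  draws <- vapply(right, function(s) s$coeffs_true,
                  numeric(length(spec$mean_coeffs)))
  dev <- abs(rowMeans(draws) - spec$mean_coeffs)
  expect_true(all(dev <= 3 * 0.05 / sqrt(200)))
})

test_that("every sample carries its true landmarks on labelled vertices", {
  pop <- sample_population(default_bone_classes()$calcaneus, 3, seed = 8)
  for (s in pop) {
    lm <- s$landmarks_true
    for (p in c("a", "b", "c")) {
      idx <- lm[[paste0(p, "_idx")]]
      expect_identical(s$mesh$labels[idx], p)
      expect_equal(unname(lm[[paste0(p, "_mm")]]),
                   unname(s$mesh$vertices[idx, ]))
    }
  }
})

test_that("mirroring is an involution preserving radii and orientation", {
  s <- fixture_sample("talus", seed = 17, side = "right")
  m1 <- mirror_shape(s$mesh, s$landmarks_true)
  expect_true(mesh_is_closed(m1$mesh))
  expect_gt(mesh_signed_volume(m1$mesh), 0)
  m2 <- mirror_shape(m1$mesh, m1$landmarks)
  expect_identical(m2$mesh$vertices, s$mesh$vertices)
  expect_identical(m2$mesh$faces[, 1], s$mesh$faces[, 1])
  expect_equal(mesh_signed_volume(m2$mesh), mesh_signed_volume(s$mesh))
  # reflection is an isometry: centroid radii multiset unchanged
  rad <- function(m) sort(sqrt(rowSums(sweep(m$vertices, 2,
                                             colMeans(m$vertices))^2)))
  expect_equal(rad(m1$mesh), rad(s$mesh), tolerance = 1e-12)
  # 20-bin radius histograms equal
  b <- seq(min(rad(s$mesh)) - 1e-9, max(rad(s$mesh)) + 1e-9,
           length.out = 21)
  expect_identical(hist(rad(m1$mesh), breaks = b, plot = FALSE)$counts,
                   hist(rad(s$mesh), breaks = b, plot = FALSE)$counts)
})

test_that("mirroring a centered sphere permutes its vertex set", {
  sph <- icosphere(2)
  mir <- mirror_shape(sph)$mesh
  key <- function(v) do.call(order, as.data.frame(round(v, 10)))
  expect_equal(sph$vertices[key(sph$vertices), ],
               mir$vertices[key(mir$vertices), ], tolerance = 1e-12)
})

test_that("mirror_shape rejects open meshes", {
  m <- icosphere(1)
  expect_error(mirror_shape(tri_mesh(m$vertices, m$faces[-3, ])),
               "closed")
})

test_that("mirrored meshes carry exactly the mirrored coefficients", {
  pop <- sample_population(default_bone_classes()$cuboid, 2, seed = 121)
  for (s in pop) {
    fit <- fit_spharm(parameterize(s$mesh), 4)
    expect_equal(fit$coeffs, s$coeffs_true, tolerance = 1e-9)
  }
  # explicit reflection rule check on a right-side fit
  right <- Filter(function(s) s$side == "right", pop)[[1]]
  mir <- mirror_shape(right$mesh)$mesh
  fit_m <- fit_spharm(parameterize(mir), 4)
  expect_equal(fit_m$coeffs,
               mirror_spharm_coeffs(right$coeffs_true), tolerance = 1e-9)
})

test_that("voxelized sphere matches the analytic and brute-force volumes", {
  # generic position: a bone never sits exactly on the scanner lattice
  sph <- radial_mesh(rep(5, 642), icosphere(3),
                     origin = c(sqrt(2) / 2, sqrt(3) / 3, sqrt(5) / 5))
  vol <- voxelize(sph, spacing_mm = 1, inside_level = 1000,
                  outside_level = 0, noise_sd = 0)
  n_in <- sum(vol$values == 1000)
  expect_lt(abs(n_in - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.05)
  expect_identical(sort(unique(as.numeric(vol$values))), c(0, 1000))
  # brute-force oracle: point-in-sphere over the same grid
  d <- dim(vol$values)
  ax <- lapply(1:3, function(i) vol$origin[i] + (seq_len(d[i]) - 1) *
                 vol$spacing[i])
  g <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  ctr <- c(sqrt(2) / 2, sqrt(3) / 3, sqrt(5) / 5)
  n_oracle <- sum(rowSums(sweep(g, 2, ctr)^2) < 25)
  expect_lt(abs(n_in - n_oracle), 0.02 * n_oracle + 5)
})

test_that("halving the spacing scales the inside count by about 8", {
  sph <- radial_mesh(rep(5, 162), icosphere(2),
                     origin = c(0.31, 0.67, 0.49))
  n1 <- sum(voxelize(sph, 1, 1, 0)$values == 1)
  n05 <- sum(voxelize(sph, 0.5, 1, 0)$values == 1)
  expect_lt(abs(n05 / n1 - 8) / 8, 0.10)
})

test_that("voxelize is seed-deterministic and adds the requested noise", {
  sph <- radial_mesh(rep(4, 42), icosphere(1))
  v1 <- voxelize(sph, 1, 100, 0, noise_sd = 5, seed = 3)
  v2 <- voxelize(sph, 1, 100, 0, noise_sd = 5, seed = 3)
  expect_identical(v1$values, v2$values)
  expect_gt(length(unique(as.numeric(v1$values))), 2)
})

test_that("generated meshes pass the star-shape check in a stress run", {
  specs <- default_bone_classes()
  n_checked <- 0
  for (nm in names(specs)) {
    pop <- sample_population(specs[[nm]], 13, seed = 400 + n_checked)
    for (s in pop) {
      expect_silent(parameterize(s$mesh))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 100)
})

test_that("invalid class specs are rejected", {
  spec <- default_bone_classes()$cuboid
  expect_error(bone_class_spec("bad", spec$mean_coeffs * 0,
                               spec$coeff_sd, spec$landmark_patch_dirs),
               "non-positive")
  expect_error(bone_class_spec("bad", spec$mean_coeffs, spec$coeff_sd,
                               rbind(c(0, 0, 1), c(0, 0, 1),
                                     c(1, 0, 0))),
               "parallel")
})
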