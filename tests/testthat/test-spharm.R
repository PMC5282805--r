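test_that("parameterize recovers exact spherical coordinates", {
  m <- radial_mesh(rep(5, 642), icosphere(3))
  s <- parameterize(m)
  expect_equal(s$r, rep(5, 642), tolerance = 1e-12)
  expect_equal(unname(s$origin), c(0, 0, 0), tolerance = 1e-12)
  # axis points: theta = 0 at +z, theta = pi/2 / phi = 0 at +x
  top <- which.max(m$vertices[, 3])
  expect_equal(s$theta[top], 0, tolerance = 1e-7)
  px <- which.max(m$vertices[, 1])
  expect_equal(s$theta[px], pi / 2, tolerance = 1e-7)
  expect_equal(s$phi[px] %% (2 * pi), 0, tolerance = 1e-7)
})

test_that("spherical coordinates round-trip back to the vertices", {
  s0 <- fixture_sample("talus", seed = 71, side = "right")
  sp <- parameterize(s0$mesh)
  rebuilt <- cbind(sp$r * sin(sp$theta) * cos(sp$phi),
                   sp$r * sin(sp$theta) * sin(sp$phi),
                   sp$r * cos(sp$theta))
  rebuilt <- sweep(rebuilt, 2, sp$origin, "+")
  expect_equal(rebuilt, unname(s0$mesh$vertices), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("a non-star-shaped mesh is rejected at parameterization", {
  m <- icosphere(2)
  v <- m$vertices * 5
  # put vertex 1 on vertex 2's ray at a different radius, compensating
  # via the antipodal vertex so the centroid stays at the origin and the
  # two directions stay exactly parallel
  anti <- which.min(rowSums(sweep(v, 2, -v[1, ])^2))
  v_new1 <- v[2, ] / 5 * 9
  v[anti, ] <- v[anti, ] + (v[1, ] - v_new1)
  v[1, ] <- v_new1
  expect_error(parameterize(tri_mesh(v, m$faces)), "star-shaped")
})

test_that("unit sphere fits give c0 = 2*sqrt(pi) and nothing else", {
  s <- parameterize(radial_mesh(rep(1, 642), icosphere(3)))
  for (L in c(0, 3, 6)) {
    fit <- fit_spharm(s, L)
    expect_equal(fit$coeffs[1], 2 * sqrt(pi), tolerance = 1e-9)
    if (L > 0) expect_lt(max(abs(fit$coeffs[-1])), 1e-9)
    expect_lt(fit$rms_residual, 1e-12)
  }
})

test_that("a pure Y20 perturbation is recovered against quadrature", {
  ang <- icosphere_angles(3)
  r <- 1 + 0.3 * sh_basis(ang$theta, ang$phi, 2)[, 7]
  s <- spherical_samples(ang$theta, ang$phi, r)
  fit <- fit_spharm(s, 2)
  expect_equal(fit$coeffs[7], 0.3, tolerance = 1e-6)
  expect_equal(fit$coeffs[1], 2 * sqrt(pi), tolerance = 1e-6)
  # independent quadrature oracle for the same coefficients
  f <- function(theta, phi) 1 + 0.3 * sh_basis(theta, phi, 2)[, 7]
  expect_equal(oracle_sh_coefficient(f, 2, 0), 0.3, tolerance = 1e-9)
  expect_equal(oracle_sh_coefficient(f, 0, 0), 2 * sqrt(pi),
               tolerance = 1e-9)
  expect_equal(oracle_sh_coefficient(f, 2, 1), 0, tolerance = 1e-9)
})

test_that("the L = 0 fit is the closed-form mean-radius solution", {
  set.seed(14)
  n <- 200
  s <- spherical_samples(acos(stats::runif(n, -1, 1)),
                         stats::runif(n, 0, 2 * pi),
                         stats::runif(n, 2, 6))
  fit <- fit_spharm(s, 0)
  expect_equal(fit$coeffs[1], mean(s$r) * 2 * sqrt(pi),
               tolerance = 1e-12)
})

test_that("fits are independent of sample ordering", {
  s0 <- fixture_sample("cuboid", seed = 73, side = "right")
  sp <- parameterize(s0$mesh)
  fit1 <- fit_spharm(sp, 4)
  set.seed(5)
  perm <- sample(length(sp$r))
  sp2 <- spherical_samples(sp$theta[perm], sp$phi[perm], sp$r[perm],
                           sp$origin)
  fit2 <- fit_spharm(sp2, 4)
  expect_equal(fit1$coeffs, fit2$coeffs, tolerance = 1e-10)
})

test_that("ill-distributed samples raise a conditioning error", {
  # all samples on one ring: azimuthal orders are confounded
  n <- 300
  s <- spherical_samples(rep(pi / 2, n),
                         2 * pi * (seq_len(n) - 1) / n, rep(3, n))
  expect_error(fit_spharm(s, 6), "rank|conditioning|ill-distributed")
  expect_error(fit_spharm(spherical_samples(1, 1, 1), 3), "at least")
})

test_that("rotating a shape preserves per-degree energies", {
  s0 <- fixture_sample("calcaneus", seed = 79, side = "right")
  fit0 <- fit_spharm(parameterize(s0$mesh), 4)
  set.seed(21)
  R <- random_rotation()
  m2 <- tri_mesh(s0$mesh$vertices %*% t(R), s0$mesh$faces)
  fit2 <- fit_spharm(parameterize(m2), 4)
  idx <- sh_index_table(4)
  e0 <- tapply(fit0$coeffs^2, idx$l, sum)
  e2 <- tapply(fit2$coeffs^2, idx$l, sum)
  expect_false(isTRUE(all.equal(fit0$coeffs, fit2$coeffs))) # coeffs move
  expect_equal(as.numeric(e2[-2]), as.numeric(e0[-2]),
               tolerance = 1e-6) # l = 1 energy is re-centering noise
  expect_lt(max(e0[2], e2[2]), 1e-6)
})

test_that("MDL short-circuits on exact fits and reports the full curve", {
  s <- parameterize(radial_mesh(rep(4, 162), icosphere(2)))
  sel <- select_order_mdl(s, 6)
  expect_equal(sel$L_opt, 0)
  expect_true(sel$exact_fit)
  ang <- icosphere_angles(3)
  r <- as.numeric(sh_basis(ang$theta, ang$phi, 2) %*%
                    c(10, 0, 0, 0, 0.5, 0, 0.8, 0, 0)) # L = 2 content
  set.seed(33)
  s2 <- spherical_samples(ang$theta, ang$phi, r + stats::rnorm(642, 0, 0.02))
  sel2 <- select_order_mdl(s2, 5)
  expect_length(sel2$mdl, 6)
  expect_equal(sel2$L_opt, 2)
  expect_equal(sel2$L_opt, oracle_mdl_order(s2, 5))
})

test_that("reconstruction inverts fitting on the fitted directions", {
  model <- spharm_model(2, c(2 * sqrt(pi), rep(0, 8)))
  ang <- icosphere_angles(2)
  expect_equal(reconstruct_radii(model, ang$theta, ang$phi),
               rep(1, 162), tolerance = 1e-12)
  s0 <- fixture_sample("navicular", seed = 83, side = "right")
  sp <- parameterize(s0$mesh)
  fit <- fit_spharm(sp, 3)
  r_hat <- reconstruct_radii(fit, sp$theta, sp$phi)
  expect_equal(sqrt(mean((sp$r - r_hat)^2)), fit$rms_residual,
               tolerance = 1e-12)
  m <- reconstruct_mesh(fit, 2)
  expect_silent(mesh_validate(m))
  neg <- spharm_model(3, -fit$coeffs)
  expect_error(reconstruct_mesh(neg, 2), "non-positive")
})
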