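#' Bone class specification for the synthetic population generator
#'
#' Describes one synthetic bone class by its mean SPHARM coefficient
#' vector, per-coefficient Gaussian inter-subject standard deviations, the
#' three surface patch directions where landmark regions are painted, and
#' the extremal-projection rules that define landmarks a, b, c inside
#' those patches.
#'
#' @param name class label, one of the four tarsal bones by default.
#' @param mean_coeffs real SPHARM coefficient vector of length (L+1)^2;
#'   must yield a strictly positive radius function.
#' @param coeff_sd nonnegative per-coefficient SD vector, same length.
#' @param landmark_patch_dirs 3 x 3 matrix, rows = unit directions of
#'   patches "a", "b", "c"; pairwise non-parallel.
#' @param patch_radius_deg angular radius of the painted geodesic caps.
#' @return object of class \code{bone_class_spec}.
#' @export
bone_class_spec <- function(name, mean_coeffs, coeff_sd,
                            landmark_patch_dirs, patch_radius_deg = 10) {
  stopifnot(length(mean_coeffs) == length(coeff_sd),
            all(coeff_sd >= 0),
            is.matrix(landmark_patch_dirs),
            dim(landmark_patch_dirs) == c(3, 3))
  L <- sh_degree_of(mean_coeffs)
  dirs <- landmark_patch_dirs / sqrt(rowSums(landmark_patch_dirs^2))
  for (i in 1:2) for (j in (i + 1):3) {
    if (abs(sum(dirs[i, ] * dirs[j, ])) > cos(5 * pi / 180)) {
      stop("landmark patch directions ", i, " and ", j,
           " are (anti)parallel within 5 degrees")
    }
  }
  # strict positivity of the mean radius on a dense sphere sampling
  u <- icosphere(4)$vertices
  r <- as.numeric(sh_basis(acos(pmin(1, pmax(-1, u[, 3]))),
                           atan2(u[, 2], u[, 1]) %% (2 * pi), L) %*%
                    mean_coeffs)
  if (any(r <= 0)) {
    stop("mean_coeffs of class '", name,
         "' yield non-positive radii (min ", format(min(r), digits = 3),
         " mm)")
  }
  rownames(dirs) <- c("a", "b", "c")
  structure(list(name = name, mean_coeffs = as.numeric(mean_coeffs),
                 coeff_sd = as.numeric(coeff_sd), L = L,
                 landmark_patch_dirs = dirs,
                 patch_radius_deg = patch_radius_deg),
            class = "bone_class_spec")
}

#' Default synthetic tarsal bone classes
#'
#' Four bone-like classes (calcaneus-, talus-, cuboid- and navicular-like)
#' defined at degree L = 4 (25 coefficients). Mean sizes follow the
#' relative sizes of the real bones (calcaneus largest, navicular
#' smallest; mean radii 14, 12, 10 and 9 mm). Classes differ in 5--7
#' degree-2..4 coefficients by at least 3 inter-subject SDs, emulating the
#' near-perfect separability of real tarsal bones. Degree-1 coefficients
#' are identically zero (mean and SD): a degree-1 radius perturbation is,
#' to first order, a translation of the expansion origin, not a change of
#' shape, and is absorbed when surfaces are re-centred at their centroid
#' during parameterization -- so it is not an identifiable shape
#' parameter. Inter-subject variation is Gaussian per coefficient: SD
#' 1.0 mm on the size term (l = 0) and 0.2 on all degree >= 2
#' coefficients.
#'
#' @return named list of four \code{bone_class_spec} objects.
#' @export
default_bone_classes <- function() {
  L <- 4
  K <- sh_n_coeffs(L)
  sd0 <- c(1.0, rep(0, 3), rep(0.2, K - 4))
  mk <- function(name, mean_radius, shape, dirs) {
    mc <- numeric(K)
    mc[1] <- 2 * sqrt(pi) * mean_radius
    mc[as.integer(names(shape))] <- shape
    bone_class_spec(name, mc, sd0, dirs)
  }
  # flat index k = l^2 + l + m + 1: degree 2 -> 5..9, 3 -> 10..16, 4 -> 17..25
  list(
    calcaneus = mk("calcaneus", 14,
                   c("5" = 1.2, "7" = 2.0, "9" = -1.0, "13" = 1.0,
                     "17" = 0.8, "21" = 0.9),
                   rbind(c(0.2, 0.1, 1), c(1, 0.25, 0.3), c(0.1, -1, -0.2))),
    talus = mk("talus", 12,
               c("7" = 1.0, "8" = 1.1, "14" = 0.9, "18" = -0.8,
                 "22" = 0.8, "25" = 0.7),
               rbind(c(0, 0.15, 1), c(1, 0.1, 0.35), c(-0.2, -1, -0.1))),
    cuboid = mk("cuboid", 10,
                c("6" = 1.2, "7" = -1.5, "11" = -0.9, "19" = 1.0,
                  "21" = 1.0, "25" = 0.8),
                rbind(c(0.1, -0.1, 1), c(1, 0.3, 0.2), c(0, -1, -0.3))),
    navicular = mk("navicular", 9,
                   c("7" = -2.0, "9" = 1.0, "15" = 0.8, "16" = -0.7,
                     "23" = 0.9, "25" = -0.8),
                   rbind(c(-0.1, 0.2, 1), c(1, -0.2, 0.25), c(0.15, -1, 0)))
  )
}

#' Default landmark rules for a bone class
#'
#' Landmark a/b/c of a synthetic bone is the labelled-patch vertex with
#' maximal projection onto the patch direction. For left (mirrored)
#' samples the rule directions are mirrored across x = 0.
#'
#' @param spec a \code{bone_class_spec}.
#' @param side "right" or "left".
#' @return list of three \code{landmark_rule} objects named a, b, c.
#' @export
class_landmark_rules <- function(spec, side = "right") {
  dirs <- spec$landmark_patch_dirs
  if (side == "left") dirs[, 1] <- -dirs[, 1]
  lapply(stats::setNames(c("a", "b", "c"), c("a", "b", "c")),
         function(lab) landmark_rule(lab, dirs[lab, ], "max"))
}

# paint geodesic-cap labels "a","b","c" on icosphere directions
paint_patches <- function(unit_dirs, patch_dirs, patch_radius_deg) {
  labels <- rep.int("", nrow(unit_dirs))
  thr <- cos(patch_radius_deg * pi / 180)
  for (lab in rownames(patch_dirs)) {
    labels[unit_dirs %*% patch_dirs[lab, ] >= thr] <- lab
  }
  labels
}

#' Sample a synthetic bone population for one class
#'
#' Draws \code{n_per_side} right-side and \code{n_per_side} left-side
#' bones from a class. Each sample's true coefficients are the class mean
#' plus independent Gaussian perturbations (\code{coeff_sd}); left samples
#' are mirrored copies of their own independent draws, never of a right
#' sample, emulating a population of 2n distinct subjects. A left
#' sample's \code{coeffs_true} is the exact expansion of its mirrored
#' surface (see \code{\link{mirror_spharm_coeffs}}), so truth always
#' describes the mesh as delivered. Draws whose
#' radius function is not strictly positive on the mesh sampling are
#' redrawn up to 100 times, then the generation fails loudly.
#'
#' @param spec a \code{bone_class_spec}.
#' @param n_per_side samples per side (>= 1).
#' @param seed integer RNG seed; same seed reproduces the population
#'   bit-for-bit.
#' @param subdiv_level icosphere level of the generated meshes.
#' @return list of \code{synthetic_sample} objects (length 2n): each has
#'   \code{class_name}, \code{side}, \code{coeffs_true}, \code{mesh}
#'   (labelled \code{tri_mesh}), \code{landmarks_true}, \code{subject_id},
#'   \code{seed}.
#' @export
sample_population <- function(spec, n_per_side, seed, subdiv_level = 3) {
  stopifnot(inherits(spec, "bone_class_spec"), n_per_side >= 1)
  set.seed(seed)
  sphere <- icosphere(subdiv_level)
  u <- sphere$vertices
  theta <- acos(pmin(1, pmax(-1, u[, 3])))
  phi <- atan2(u[, 2], u[, 1]) %% (2 * pi)
  B <- sh_basis(theta, phi, spec$L)
  labels <- paint_patches(u, spec$landmark_patch_dirs,
                          spec$patch_radius_deg)
  K <- length(spec$mean_coeffs)

  draw_coeffs <- function() {
    for (try in 1:100) {
      coeffs <- spec$mean_coeffs + stats::rnorm(K) * spec$coeff_sd
      radii <- as.numeric(B %*% coeffs)
      if (all(radii > 0)) return(list(coeffs = coeffs, radii = radii))
    }
    stop("could not draw a positive radius function for class '",
         spec$name, "' after 100 retries; largest coefficient magnitudes: ",
         paste(format(sort(abs(coeffs), decreasing = TRUE)[1:3],
                      digits = 3), collapse = ", "))
  }

  true_landmarks <- function(mesh, side) {
    dirs <- spec$landmark_patch_dirs
    if (side == "left") dirs[, 1] <- -dirs[, 1]
    idx <- vapply(c("a", "b", "c"), function(lab) {
      cand <- which(mesh$labels == lab)
      cand[which.max(mesh$vertices[cand, , drop = FALSE] %*% dirs[lab, ])]
    }, integer(1))
    landmark_triple(mesh, spec$name, idx[1], idx[2], idx[3])
  }

  samples <- vector("list", 2 * n_per_side)
  for (i in seq_len(2 * n_per_side)) {
    side <- if (i <= n_per_side) "right" else "left"
    d <- draw_coeffs()
    mesh <- radial_mesh(d$radii, sphere, labels = labels)
    lm <- NULL
    coeffs_true <- d$coeffs
    if (side == "left") {
      mirrored <- mirror_shape(mesh, true_landmarks(mesh, "right"))
      mesh <- mirrored$mesh
      lm <- true_landmarks(mesh, "left")
      coeffs_true <- mirror_spharm_coeffs(d$coeffs)
    } else {
      lm <- true_landmarks(mesh, "right")
    }
    samples[[i]] <- structure(
      list(class_name = spec$name, side = side, coeffs_true = coeffs_true,
           mesh = mesh, landmarks_true = lm, subject_id = i, seed = seed),
      class = "synthetic_sample")
  }
  samples
}

#' Mirror a bone surface across the x = 0 plane
#'
#' Reflects vertex coordinates (x negated), flips face winding so outward
#' orientation is preserved, and reflects the landmark coordinates.
#'
#' @param mesh a closed \code{tri_mesh}.
#' @param landmarks optional \code{landmark_triple} to reflect along.
#' @return list with reflected \code{mesh} and \code{landmarks}.
#' @export
mirror_shape <- function(mesh, landmarks = NULL) {
  if (!mesh_is_closed(mesh)) stop("mirror_shape requires a closed mesh")
  v <- mesh$vertices
  v[, 1] <- -v[, 1]
  out <- tri_mesh(v, mesh$faces[, c(1, 3, 2)], mesh$labels)
  lm <- NULL
  if (!is.null(landmarks)) {
    lm <- landmark_triple(out, landmarks$bone, landmarks$a_idx,
                          landmarks$b_idx, landmarks$c_idx)
  }
  list(mesh = out, landmarks = lm)
}

#' Voxelize a closed mesh into a CT-like volume phantom
#'
#' Builds a regular grid covering the mesh bounding box padded by at
#' least two voxels, assigns \code{inside_level} to voxel centres inside
#' the closed surface and \code{outside_level} outside (even-odd ray
#' parity test), and adds Gaussian noise. The grid is aligned to the
#' world lattice (voxel centres at integer multiples of the spacing),
#' like a scanner field of view: the sampling grid does not move with
#' the object, so discretization artefacts depend on where the object
#' sits, exactly as in a real acquisition. Emulates the bone/soft-tissue
#' contrast of a CT volume.
#'
#' @param mesh a closed \code{tri_mesh} with positive volume.
#' @param spacing_mm isotropic voxel spacing (mm).
#' @param inside_level,outside_level intensity levels.
#' @param noise_sd Gaussian noise SD (0 = clean binary phantom).
#' @param seed RNG seed for the noise.
#' @return \code{voxel_volume} object.
#' @export
voxelize <- function(mesh, spacing_mm, inside_level = 1000,
                     outside_level = 0, noise_sd = 0, seed = 1) {
  mesh_validate(mesh)
  if (mesh_signed_volume(mesh) <= 0) stop("degenerate mesh volume")
  v <- mesh$vertices
  lo_i <- floor((apply(v, 2, min) - 2 * spacing_mm) / spacing_mm)
  hi_i <- ceiling((apply(v, 2, max) + 2 * spacing_mm) / spacing_mm)
  lo <- lo_i * spacing_mm
  n <- pmax(2L, as.integer(hi_i - lo_i) + 1L)
  ax <- lapply(1:3, function(i) lo[i] + spacing_mm * (seq_len(n[i]) - 1))
  centers <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  inside <- points_in_mesh(centers, mesh)
  vals <- ifelse(inside, inside_level, outside_level)
  if (noise_sd > 0) {
    set.seed(seed)
    vals <- vals + stats::rnorm(length(vals), 0, noise_sd)
  }
  voxel_volume(array(vals, dim = n), spacing = rep(spacing_mm, 3),
               origin = lo)
}

#' Reflect real SPHARM coefficients across the x = 0 plane
#'
#' Under the mirror x -> -x the azimuth maps phi -> pi - phi, so the
#' cosine harmonics of order m pick up a factor (-1)^m and the sine
#' harmonics a factor (-1)^(m+1); zonal terms are unchanged. The
#' returned vector is the exact expansion of the mirrored radius
#' function.
#'
#' @param coeffs real coefficient vector of length (L+1)^2.
#' @return coefficient vector of the mirrored shape.
#' @export
mirror_spharm_coeffs <- function(coeffs) {
  idx <- sh_index_table(sh_degree_of(coeffs))
  fac <- ifelse(idx$m >= 0, (-1)^idx$m, (-1)^(idx$m + 1))
  coeffs * fac
}

#' Even-odd point-in-mesh test
#'
#' Casts a ray from each query point along a fixed direction chosen to
#' avoid edge-grazing on axis-aligned grids and counts triangle
#' crossings (Moller-Trumbore, vectorized over points per triangle).
#'
#' @param points n x 3 matrix of query points (mm).
#' @param mesh closed \code{tri_mesh}.
#' @return logical vector, TRUE for points inside.
#' @export
points_in_mesh <- function(points, mesh) {
  d <- c(0.577350269189626, 0.514495755427527, 0.633724312548194)
  d <- d / sqrt(sum(d^2))
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(points)
  crossings <- integer(n)
  for (fi in seq_len(nrow(f))) {
    v0 <- v[f[fi, 1], ]; v1 <- v[f[fi, 2], ]; v2 <- v[f[fi, 3], ]
    e1 <- v1 - v0
    e2 <- v2 - v0
    h <- c(d[2] * e2[3] - d[3] * e2[2],
           d[3] * e2[1] - d[1] * e2[3],
           d[1] * e2[2] - d[2] * e2[1])
    a <- sum(e1 * h)
    if (abs(a) < 1e-12) next
    s <- sweep(points, 2, v0)
    uu <- (s %*% h) / a
    q <- cbind(s[, 2] * e1[3] - s[, 3] * e1[2],
               s[, 3] * e1[1] - s[, 1] * e1[3],
               s[, 1] * e1[2] - s[, 2] * e1[1])
    vv <- (q %*% d) / a
    tt <- (q %*% e2) / a
    hit <- uu >= 0 & vv >= 0 & (uu + vv) <= 1 & tt > 0
    crossings <- crossings + as.integer(hit)
  }
  crossings %% 2L == 1L
}
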