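#' Estimate oriented surface normals of a point cloud
#'
#' Fits a local plane through each point and its k nearest neighbours and
#' takes the smallest-variance direction of the neighbourhood covariance
#' as the normal. Neighbour ties at equal distance are broken by point
#' index. Normal signs are flipped so that each normal points away from
#' the cloud centroid (outward for star-shaped clouds).
#'
#' @param cloud n x 3 matrix of points (mm), n >= k + 1.
#' @param k neighbour count (>= 3).
#' @return object of class \code{oriented_cloud}: list with
#'   \code{points} and unit \code{normals} (both n x 3).
#' @export
estimate_normals <- function(cloud, k = 12) {
  cloud <- as.matrix(cloud)
  n <- nrow(cloud)
  stopifnot(k >= 3)
  if (n < k + 1) {
    stop("need at least k + 1 = ", k + 1, " points, got ", n)
  }
  ctr <- colMeans(cloud)
  normals <- matrix(0, n, 3)
  block <- 512L
  for (b0 in seq(1L, n, by = block)) {
    b1 <- min(n, b0 + block - 1L)
    idx <- b0:b1
    # squared distances from block points to all points
    d2 <- outer(rowSums(cloud[idx, , drop = FALSE]^2), rowSums(cloud^2),
                "+") - 2 * cloud[idx, , drop = FALSE] %*% t(cloud)
    for (i in seq_along(idx)) {
      o <- order(d2[i, ], seq_len(n))[seq_len(k + 1)] # self + k nearest
      nbh <- cloud[o, , drop = FALSE]
      cv <- stats::cov(nbh)
      if (!all(is.finite(cv)) || sum(diag(cv)) < 1e-24) {
        stop("degenerate neighbourhood at point ", idx[i],
             " (coincident points)")
      }
      ev <- eigen(cv, symmetric = TRUE)
      nrm <- ev$vectors[, 3]
      if (sum(nrm * (cloud[idx[i], ] - ctr)) < 0) nrm <- -nrm
      normals[idx[i], ] <- nrm
    }
  }
  structure(list(points = cloud, normals = normals),
            class = "oriented_cloud")
}

#' @export
print.oriented_cloud <- function(x, ...) {
  cat("oriented_cloud:", nrow(x$points), "points with unit normals\n")
  invisible(x)
}

#' Radial remeshing of a star-shaped point cloud
#'
#' Resamples a star-shaped cloud onto the vertices of a subdivided
#' icosahedron: each unit direction gets the inverse-squared-angular-
#' distance weighted average of the radii of the \code{k_interp}
#' angularly nearest cloud points (about the cloud centroid). This
#' replaces a volumetric surface reconstruction for the star-shaped
#' geometries this pipeline targets and feeds directly into the radial
#' SPHARM representation. Errors when some direction has no cloud point
#' within 30 degrees (the cloud does not cover the sphere).
#'
#' @param cloud an \code{oriented_cloud} or plain n x 3 point matrix.
#' @param subdiv_level icosphere subdivision level (level s gives
#'   \code{10 * 4^s + 2} vertices).
#' @param k_interp number of angular neighbours to interpolate from.
#' @return closed, outward-oriented \code{tri_mesh}.
#' @export
radial_remesh <- function(cloud, subdiv_level = 3, k_interp = 6) {
  pts <- if (inherits(cloud, "oriented_cloud")) cloud$points else
    as.matrix(cloud)
  stopifnot(nrow(pts) >= k_interp)
  ctr <- colMeans(pts)
  d <- sweep(pts, 2, ctr)
  r <- sqrt(rowSums(d^2))
  if (any(r == 0)) stop("cloud point coincides with the centroid")
  u <- d / r
  sphere <- icosphere(subdiv_level)
  dots <- sphere$vertices %*% t(u) # cosine of angular distance
  radii <- numeric(nrow(dots))
  max_gap <- 0
  gap_dir <- NULL
  for (i in seq_len(nrow(dots))) {
    o <- order(dots[i, ], decreasing = TRUE)[seq_len(k_interp)]
    ang <- acos(pmin(1, pmax(-1, dots[i, o])))
    if (ang[1] > max_gap) {
      max_gap <- ang[1]
      gap_dir <- sphere$vertices[i, ]
    }
    if (ang[1] < 1e-9) {
      radii[i] <- r[o[1]]
    } else {
      w <- 1 / ang^2
      radii[i] <- sum(w * r[o]) / sum(w)
    }
  }
  if (max_gap > 30 * pi / 180) {
    stop("cloud is not star-shaped / does not cover the sphere: ",
         "angular gap of ", format(max_gap * 180 / pi, digits = 3),
         " degrees toward direction (",
         paste(format(gap_dir, digits = 3), collapse = ", "), ")")
  }
  radial_mesh(radii, sphere, origin = ctr)
}
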