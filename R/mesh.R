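#' Triangle mesh constructor
#'
#' Lightweight S3 container for a closed triangle surface mesh in
#' physical (mm) coordinates, the common currency of the pipeline.
#' Faces index vertices 1-based and are wound counter-clockwise seen from
#' outside (outward normals, positive signed volume).
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces integer m x 3 matrix of vertex indices.
#' @param labels optional character vector of per-vertex region labels
#'   ("" for unlabelled); used by the landmarking stage.
#' @return object of class \code{tri_mesh}.
#' @export
tri_mesh <- function(vertices, faces, labels = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3,
            min(faces) >= 1, max(faces) <= nrow(vertices))
  if (!is.null(labels)) stopifnot(length(labels) == nrow(vertices))
  structure(list(vertices = vertices, faces = faces, labels = labels),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat("tri_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces")
  if (!is.null(x$labels)) {
    labs <- unique(x$labels[nzchar(x$labels)])
    if (length(labs)) cat(", labelled patches:", paste(labs, collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Closed-manifold check
#'
#' A mesh is closed and consistently wound when every undirected edge is
#' shared by exactly two faces and appears once in each direction.
#'
#' @param mesh a \code{tri_mesh}.
#' @return logical scalar.
#' @export
mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)]) # directed half-edges
  key <- paste(he[, 1], he[, 2])
  if (anyDuplicated(key)) return(FALSE) # same directed edge twice
  rev_key <- paste(he[, 2], he[, 1])
  all(key %in% rev_key)
}

#' Signed volume of a closed mesh
#'
#' Sum of signed tetrahedron volumes against the origin; positive for
#' outward-wound closed surfaces.
#'
#' @param mesh a \code{tri_mesh}.
#' @return numeric scalar (mm^3).
#' @export
mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Validate tri_mesh invariants
#'
#' Checks closedness, consistent winding and positive signed volume;
#' errors with a message naming the violated invariant.
#'
#' @param mesh a \code{tri_mesh}.
#' @return the mesh, invisibly.
#' @export
mesh_validate <- function(mesh) {
  if (!inherits(mesh, "tri_mesh")) stop("not a tri_mesh")
  if (!mesh_is_closed(mesh)) {
    stop("mesh is not a closed, consistently wound manifold")
  }
  if (mesh_signed_volume(mesh) <= 0) {
    stop("mesh signed volume is not positive (inward-facing normals?)")
  }
  invisible(mesh)
}

#' Subdivided icosahedron sphere mesh
#'
#' Unit sphere triangulation with \code{10 * 4^level + 2} vertices obtained
#' by repeated 1-to-4 edge-midpoint subdivision of the regular icosahedron,
#' re-projecting midpoints to the unit sphere. Vertices are deduplicated
#' via an edge-midpoint cache so the result is a closed manifold.
#'
#' @param level subdivision level (0 = plain icosahedron).
#' @return \code{tri_mesh} with unit-norm vertices and outward winding.
#' @export
icosphere <- function(level = 3) {
  stopifnot(level >= 0, level == round(level))
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (iter in seq_len(level)) {
    nv <- nrow(v)
    midpoint_cache <- new.env(hash = TRUE, parent = emptyenv())
    extra <- list()
    midpoint <- function(i, j) {
      key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
      idx <- midpoint_cache[[key]]
      if (is.null(idx)) {
        p <- v[i, ] + v[j, ]
        p <- p / sqrt(sum(p^2))
        extra[[length(extra) + 1L]] <<- p
        idx <- nv + length(extra)
        midpoint_cache[[key]] <- idx
      }
      idx
    }
    newf <- matrix(0L, 4 * nrow(f), 3)
    for (fi in seq_len(nrow(f))) {
      a <- f[fi, 1]; b <- f[fi, 2]; c_ <- f[fi, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newf[4 * fi - 3, ] <- c(a, ab, ca)
      newf[4 * fi - 2, ] <- c(b, bc, ab)
      newf[4 * fi - 1, ] <- c(c_, ca, bc)
      newf[4 * fi, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, extra))
    f <- newf
  }
  tri_mesh(v, f)
}

#' Mesh built from per-direction radii on an icosphere
#'
#' Scales each unit-sphere vertex by the supplied radius and translates to
#' \code{origin}; the faces are inherited from the icosphere so closedness
#' and winding carry over.
#'
#' @param radii positive radii, one per icosphere vertex.
#' @param sphere an \code{icosphere()} mesh (unit vertices).
#' @param origin length-3 translation (mm).
#' @param labels optional per-vertex labels.
#' @return \code{tri_mesh}.
#' @export
radial_mesh <- function(radii, sphere = icosphere(3), origin = c(0, 0, 0),
                        labels = NULL) {
  stopifnot(length(radii) == nrow(sphere$vertices))
  if (any(radii <= 0)) stop("non-positive radius in radial_mesh")
  v <- sphere$vertices * radii
  v <- sweep(v, 2, origin, "+")
  tri_mesh(v, sphere$faces, labels)
}
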