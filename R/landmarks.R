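#' Landmark triple on a bone surface
#'
#' Holds the three anatomical points a, b, c that anchor the rigid pose
#' normalization (for the cuboid, e.g., the lowest and highest points of
#' the fourth-metatarsal articular surface and the most posterior point of
#' the tuberosity). The points must be distinct mesh vertices and
#' non-collinear so that they span a plane.
#'
#' @param mesh the \code{tri_mesh} the landmarks live on.
#' @param bone bone label.
#' @param a_idx,b_idx,c_idx vertex indices of points a, b, c.
#' @return object of class \code{landmark_triple} with fields
#'   \code{a_mm}, \code{b_mm}, \code{c_mm}, \code{bone}, \code{a_idx},
#'   \code{b_idx}, \code{c_idx}.
#' @export
landmark_triple <- function(mesh, bone, a_idx, b_idx, c_idx) {
  idx <- c(a_idx, b_idx, c_idx)
  stopifnot(all(idx >= 1), all(idx <= nrow(mesh$vertices)))
  if (anyDuplicated(idx)) stop("landmark vertices must be distinct")
  p <- mesh$vertices[idx, , drop = FALSE]
  cr <- crossprod3(p[2, ] - p[1, ], p[3, ] - p[1, ])
  scale <- max(1, max(abs(p)))
  if (sqrt(sum(cr^2)) <= 1e-8 * scale^2) {
    stop("landmarks are collinear (degenerate triangle); supply an ",
         "override for at least one point")
  }
  structure(list(a_mm = p[1, ], b_mm = p[2, ], c_mm = p[3, ],
                 bone = bone, a_idx = as.integer(a_idx),
                 b_idx = as.integer(b_idx), c_idx = as.integer(c_idx)),
            class = "landmark_triple")
}

#' @export
print.landmark_triple <- function(x, ...) {
  cat("landmark_triple (", x$bone, "):\n", sep = "")
  for (p in c("a", "b", "c")) {
    cat(" ", p, "= vertex", x[[paste0(p, "_idx")]], "at (",
        paste(format(x[[paste0(p, "_mm")]], digits = 4), collapse = ", "),
        ") mm\n")
  }
  invisible(x)
}

#' Extremal-projection landmark rule
#'
#' Operationalizes a description like "the highest point of the trochlea"
#' as: among the vertices carrying \code{region_label}, the one with
#' maximal (or minimal) projection onto \code{direction}.
#'
#' @param region_label label of the vertex patch to search.
#' @param direction length-3 direction; normalized internally.
#' @param sense "max" or "min".
#' @return object of class \code{landmark_rule}.
#' @export
landmark_rule <- function(region_label, direction, sense = c("max", "min")) {
  sense <- match.arg(sense)
  nd <- sqrt(sum(direction^2))
  if (nd == 0) stop("zero direction vector")
  structure(list(region_label = region_label,
                 direction = as.numeric(direction) / nd, sense = sense),
            class = "landmark_rule")
}

#' Find the extremal labelled vertex along a direction
#'
#' Returns the vertex carrying the rule's region label whose projection on
#' the rule direction is extremal. Ties (within 1e-12 of the extremum,
#' relative to the coordinate scale) are broken by lexicographic vertex
#' coordinates, then by lowest index, so the result is deterministic and
#' invariant to vertex reordering.
#'
#' @param mesh a \code{tri_mesh} with vertex labels.
#' @param rule a \code{landmark_rule}.
#' @return vertex index (integer).
#' @export
find_extremal_vertex <- function(mesh, rule) {
  if (is.null(mesh$labels)) stop("mesh carries no vertex labels")
  cand <- which(mesh$labels == rule$region_label)
  if (!length(cand)) {
    stop("no vertex carries region label '", rule$region_label, "'")
  }
  p <- mesh$vertices[cand, , drop = FALSE]
  proj <- as.numeric(p %*% rule$direction)
  if (rule$sense == "min") proj <- -proj
  tol <- 1e-12 * max(1, max(abs(p)))
  tied <- which(proj >= max(proj) - tol)
  o <- order(p[tied, 1], p[tied, 2], p[tied, 3], cand[tied])
  cand[tied[o[1]]]
}

#' Detect the landmark triple of a bone mesh
#'
#' Applies three extremal-projection rules with distinct region labels,
#' supports an expert-override map (fixed vertex indices standing in for
#' manual intervention), and validates non-collinearity.
#'
#' @param mesh labelled \code{tri_mesh}.
#' @param bone bone label for the resulting triple.
#' @param rules named list of three \code{landmark_rule}s (names a, b, c).
#' @param override optional named list/vector mapping any of "a","b","c"
#'   to a vertex index that replaces the rule result.
#' @return \code{landmark_triple}.
#' @export
detect_landmarks <- function(mesh, bone, rules, override = NULL) {
  stopifnot(length(rules) == 3)
  if (is.null(names(rules)) || !setequal(names(rules), c("a", "b", "c"))) {
    names(rules) <- c("a", "b", "c")
  }
  labs <- vapply(rules, function(r) r$region_label, character(1))
  if (anyDuplicated(labs)) {
    stop("landmark rules must use three distinct region labels")
  }
  idx <- vapply(c("a", "b", "c"), function(nm) {
    ov <- override[[nm]]
    if (!is.null(ov)) return(as.integer(ov))
    find_extremal_vertex(mesh, rules[[nm]])
  }, integer(1))
  landmark_triple(mesh, bone, idx["a"], idx["b"], idx["c"])
}

# cross product of two length-3 vectors
crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
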