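#' Angle between the landmark plane and the z = 0 plane
#'
#' Computes the unit normal n of the plane through a, b, c (sign chosen so
#' n_z >= 0), the tilt angle alpha = arccos(n_z) in \[0, pi/2\], and the
#' rotation axis (normalized n x z-hat) about which a rotation by alpha
#' maps n onto +z-hat. When the landmarks already lie in a z = const
#' plane, alpha = 0 and the axis is undefined (returned as NA with a
#' flag).
#'
#' @param a,b,c length-3 landmark coordinates, non-collinear.
#' @return list with \code{alpha_rad}, \code{axis1} (unit 3-vector or
#'   NAs), \code{degenerate} (TRUE when alpha = 0).
#' @export
plane_angle <- function(a, b, c) {
  n <- crossprod3(b - a, c - a)
  nn <- sqrt(sum(n^2))
  scale <- max(1, max(abs(c(a, b, c))))
  if (nn <= 1e-12 * scale^2) stop("landmark points are collinear")
  n <- n / nn
  if (n[3] < 0) n <- -n
  alpha <- acos(pmin(1, pmax(-1, n[3])))
  axis <- crossprod3(n, c(0, 0, 1))
  an <- sqrt(sum(axis^2))
  if (an < 1e-12) {
    return(list(alpha_rad = 0, axis1 = rep(NA_real_, 3),
                degenerate = TRUE))
  }
  list(alpha_rad = alpha, axis1 = axis / an, degenerate = FALSE)
}

#' Axis-angle rotation matrix (Rodrigues)
#'
#' Right-handed rotation by \code{angle} about the unit vector
#' \code{axis}.
#'
#' @param axis length-3 unit axis.
#' @param angle rotation angle (radians).
#' @return 3 x 3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Landmark-based rigid pose normalization
#'
#' Places a bone in its canonical landmark frame by three rigid steps:
#' (1) rotate the oriented landmark-plane normal
#' n = (b - a) x (c - a) onto +z-hat, about the line where the landmark
#' plane meets z = 0, so the landmark plane becomes parallel to z = 0
#' with a fixed facing; (2) translate by -c so landmark c sits at the
#' origin (the landmark plane is then exactly z = 0); (3) fix the
#' direction of landmark a: in mode \code{"in_plane"} (default) rotate
#' about z-hat so a lands on the +x half-axis, which preserves the
#' landmark plane and makes the normalization idempotent; in mode
#' \code{"literal_x"} rotate about x-hat by the angle beta between
#' x-hat and the position vector of a, with the sign that minimizes
#' |a_z| afterwards. No scaling is ever applied: bone size is
#' deliberately carried into the shape coefficients.
#'
#' Step 1 uses the \emph{oriented} normal (rotation angle in \[0, pi\])
#' rather than the unsigned plane angle of \code{\link{plane_angle}}:
#' aligning whichever normal sign has positive z would flip the model
#' upside-down for half of all starting orientations and destroy the
#' rigid-invariance contract that two copies of a bone differing only by
#' a rigid motion must normalize identically.
#'
#' @param mesh a \code{tri_mesh}.
#' @param lm a valid \code{landmark_triple} on that mesh.
#' @param mode "in_plane" or "literal_x".
#' @return list with \code{mesh} (transformed), \code{landmarks}
#'   (transformed triple), \code{transform} (a \code{pose_transform}:
#'   \code{alpha_rad}, \code{axis1}, \code{C_mm}, \code{beta_rad},
#'   \code{mode}).
#' @export
normalize_pose <- function(mesh, lm, mode = c("in_plane", "literal_x")) {
  mode <- match.arg(mode)
  n0 <- crossprod3(lm$b_mm - lm$a_mm, lm$c_mm - lm$a_mm)
  nn <- sqrt(sum(n0^2))
  scale <- max(1, max(abs(c(lm$a_mm, lm$b_mm, lm$c_mm))))
  if (nn <= 1e-12 * scale^2) stop("landmark points are collinear")
  n0 <- n0 / nn
  alpha <- acos(pmin(1, pmax(-1, n0[3])))
  axis1 <- crossprod3(n0, c(0, 0, 1))
  an <- sqrt(sum(axis1^2))
  if (an < 1e-12) {
    # normal already along z: identity, or a half-turn about x for -z
    axis1 <- c(1, 0, 0)
    R1 <- if (n0[3] > 0) diag(3) else rotation_matrix(axis1, pi)
    if (n0[3] > 0) axis1 <- rep(NA_real_, 3)
  } else {
    axis1 <- axis1 / an
    R1 <- rotation_matrix(axis1, alpha)
  }
  v <- mesh$vertices %*% t(R1)
  p <- rbind(lm$a_mm, lm$b_mm, lm$c_mm) %*% t(R1)

  C_mm <- p[3, ]
  v <- sweep(v, 2, C_mm)
  p <- sweep(p, 2, C_mm)

  A <- p[1, ]
  beta <- acos(pmin(1, pmax(-1, A[1] / sqrt(sum(A^2)))))
  if (mode == "in_plane") {
    gamma <- atan2(A[2], A[1])
    R3 <- rotation_matrix(c(0, 0, 1), -gamma)
  } else {
    Rp <- rotation_matrix(c(1, 0, 0), beta)
    Rm <- rotation_matrix(c(1, 0, 0), -beta)
    R3 <- if (abs((Rp %*% A)[3]) <= abs((Rm %*% A)[3])) Rp else Rm
  }
  v <- v %*% t(R3)
  out <- tri_mesh(v, mesh$faces, mesh$labels)
  lm_out <- landmark_triple(out, lm$bone, lm$a_idx, lm$b_idx, lm$c_idx)
  transform <- structure(
    list(alpha_rad = alpha, axis1 = axis1, C_mm = C_mm,
         beta_rad = beta, mode = mode),
    class = "pose_transform")
  list(mesh = out, landmarks = lm_out, transform = transform)
}

#' @export
print.pose_transform <- function(x, ...) {
  cat("pose_transform (mode ", x$mode, "): alpha = ",
      format(x$alpha_rad, digits = 4), " rad, beta = ",
      format(x$beta_rad, digits = 4), " rad, C = (",
      paste(format(x$C_mm, digits = 4), collapse = ", "), ") mm\n",
      sep = "")
  invisible(x)
}
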