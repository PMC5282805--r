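#' Spherical parameterization of a star-shaped mesh
#'
#' Maps every vertex of a closed, star-shaped mesh to spherical samples
#' \eqn{(\theta_i, \phi_i, r_i)} about the vertex centroid: the expansion
#' origin of the radial SPHARM representation. The mesh must be star-shaped
#' about that centroid for the radius function to be single-valued; the
#' check rejects meshes where two vertices share a direction (within 0.1
#' degree) but disagree in radius by more than 1 percent.
#'
#' @param mesh a closed \code{tri_mesh}.
#' @return object of class \code{spherical_samples}: list with
#'   \code{theta}, \code{phi}, \code{r} (mm) and \code{origin} (mm).
#' @export
parameterize <- function(mesh) {
  mesh_validate(mesh)
  v <- mesh$vertices
  origin <- colMeans(v)
  d <- sweep(v, 2, origin)
  r <- sqrt(rowSums(d^2))
  if (any(r == 0)) stop("vertex coincides with the expansion origin")
  u <- d / r
  theta <- acos(pmin(1, pmax(-1, u[, 3])))
  phi <- atan2(u[, 2], u[, 1]) %% (2 * pi)
  # star-shape check: near-identical directions must agree in radius
  ang_tol <- cos(0.1 * pi / 180)
  if (nrow(u) <= 4000) {
    G <- u %*% t(u)
    diag(G) <- -1
    cand <- which(G > ang_tol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  } else {
    o <- order(theta, phi)
    cand <- cbind(o[-length(o)], o[-1])
    keep <- rowSums(u[cand[, 1], , drop = FALSE] *
                    u[cand[, 2], , drop = FALSE]) > ang_tol
    cand <- cand[keep, , drop = FALSE]
  }
  if (nrow(cand)) {
    ra <- r[cand[, 1]]; rb <- r[cand[, 2]]
    bad <- abs(ra - rb) > 0.01 * pmax(ra, rb)
    if (any(bad)) {
      i <- which(bad)[1]
      stop("mesh is not star-shaped about its centroid: vertices ",
           cand[i, 1], " and ", cand[i, 2],
           " share a direction but differ in radius")
    }
  }
  structure(list(theta = theta, phi = phi, r = r, origin = origin),
            class = "spherical_samples")
}

#' Spherical samples constructor
#'
#' Builds the \code{spherical_samples} container directly from angles and
#' radii, e.g. for fitting an analytic radius field without a mesh.
#'
#' @param theta polar angles in \[0, pi\].
#' @param phi azimuths.
#' @param r positive radii (mm).
#' @param origin expansion origin (mm).
#' @return object of class \code{spherical_samples}.
#' @export
spherical_samples <- function(theta, phi, r, origin = c(0, 0, 0)) {
  stopifnot(length(theta) == length(phi), length(theta) == length(r),
            all(r > 0), length(origin) == 3)
  structure(list(theta = as.numeric(theta), phi = as.numeric(phi),
                 r = as.numeric(r), origin = as.numeric(origin)),
            class = "spherical_samples")
}

#' @export
print.spherical_samples <- function(x, ...) {
  cat("spherical_samples:", length(x$r), "directions, radius range [",
      format(min(x$r), digits = 4), ",", format(max(x$r), digits = 4),
      "] mm\n")
  invisible(x)
}

#' Least-squares SPHARM fit of a radius function
#'
#' Fits the real orthonormal spherical-harmonic expansion
#' \eqn{r(\theta,\phi) = \sum_k c_k Y_k(\theta,\phi)} up to degree \code{L}
#' by linear least squares through a QR factorization, so the solution is
#' independent of sample ordering to numerical precision.
#'
#' @param samples a \code{spherical_samples} object.
#' @param L maximum degree; needs at least \code{2*(L+1)^2} samples.
#' @return object of class \code{spharm_model}: list with \code{L},
#'   \code{coeffs} (length \code{(L+1)^2}, flat index k = l^2+l+m+1),
#'   \code{origin}, \code{rms_residual}.
#' @export
fit_spharm <- function(samples, L) {
  stopifnot(inherits(samples, "spherical_samples"), L >= 0)
  n <- length(samples$r)
  K <- sh_n_coeffs(L)
  if (n < 2 * K) {
    stop("need at least ", 2 * K, " samples to fit degree ", L,
         ", got ", n)
  }
  B <- sh_basis(samples$theta, samples$phi, L)
  qrB <- qr(B)
  if (qrB$rank < K) {
    stop("rank-deficient SPHARM design (rank ", qrB$rank, " < ", K,
         "); condition estimate ", format(kappa(B), digits = 3),
         " - samples are ill-distributed on the sphere")
  }
  coeffs <- as.numeric(qr.coef(qrB, samples$r))
  resid <- samples$r - as.numeric(B %*% coeffs)
  spharm_model(L = L, coeffs = coeffs, origin = samples$origin,
               rms_residual = sqrt(mean(resid^2)))
}

#' SPHARM model constructor
#'
#' @param L maximum degree.
#' @param coeffs real coefficient vector of length \code{(L+1)^2}.
#' @param origin expansion origin (mm).
#' @param rms_residual root-mean-square fit residual (mm), if known.
#' @return object of class \code{spharm_model}.
#' @export
spharm_model <- function(L, coeffs, origin = c(0, 0, 0), rms_residual = NA_real_) {
  stopifnot(length(coeffs) == sh_n_coeffs(L), length(origin) == 3)
  structure(list(L = as.integer(L), coeffs = as.numeric(coeffs),
                 origin = as.numeric(origin),
                 rms_residual = as.numeric(rms_residual)),
            class = "spharm_model")
}

#' @export
print.spharm_model <- function(x, ...) {
  cat("spharm_model: L =", x$L, "(", length(x$coeffs), "coefficients ),",
      "mean radius", format(x$coeffs[1] / (2 * sqrt(pi)), digits = 4),
      "mm, rms residual", format(x$rms_residual, digits = 3), "mm\n")
  invisible(x)
}

#' Model-order selection by minimum description length
#'
#' Fits every degree \code{0..L_max} and scores each with the regression
#' MDL criterion
#' \deqn{MDL(L) = (N/2)\,\ln(RSS_L/N) + ((L+1)^2/2)\,\ln N,}
#' returning the minimizing degree (smallest on ties). An exact fit
#' (RSS numerically zero) short-circuits to the smallest exact degree,
#' since the log-likelihood term is unbounded below there.
#'
#' @param samples a \code{spherical_samples} object.
#' @param L_max largest degree to consider.
#' @return list with \code{L_opt}, \code{mdl} (numeric vector, one value
#'   per degree 0..L_max, \code{-Inf} marking an exact fit), and
#'   \code{rss} per degree.
#' @export
select_order_mdl <- function(samples, L_max) {
  stopifnot(L_max >= 0)
  n <- length(samples$r)
  mdl <- rss <- numeric(L_max + 1)
  scale2 <- mean(samples$r^2)
  for (L in 0:L_max) {
    fit <- fit_spharm(samples, L)
    rssL <- fit$rms_residual^2 * n
    rss[L + 1] <- rssL
    if (rssL <= 1e-20 * scale2 * n) {
      mdl[L + 1] <- -Inf
      mdl <- mdl[seq_len(L + 1)]
      rss <- rss[seq_len(L + 1)]
      return(list(L_opt = L, mdl = mdl, rss = rss, exact_fit = TRUE))
    }
    mdl[L + 1] <- n / 2 * log(rssL / n) + sh_n_coeffs(L) / 2 * log(n)
  }
  list(L_opt = which.min(mdl) - 1L, mdl = mdl, rss = rss,
       exact_fit = FALSE)
}

#' Reconstruct radii from a SPHARM model
#'
#' @param model a \code{spharm_model}.
#' @param theta,phi directions at which to evaluate the expansion.
#' @return numeric vector of radii (mm).
#' @export
reconstruct_radii <- function(model, theta, phi) {
  B <- sh_basis(theta, phi, model$L)
  as.numeric(B %*% model$coeffs)
}

#' Reconstruct a surface mesh from a SPHARM model
#'
#' Evaluates the expansion on the vertices of a subdivided icosahedron and
#' builds the radial mesh at the model origin. Errors if the model implies
#' a non-positive radius anywhere on that sampling.
#'
#' @param model a \code{spharm_model}.
#' @param subdiv_level icosphere subdivision level for the output mesh.
#' @return \code{tri_mesh}.
#' @export
reconstruct_mesh <- function(model, subdiv_level = 3) {
  sphere <- icosphere(subdiv_level)
  u <- sphere$vertices
  theta <- acos(pmin(1, pmax(-1, u[, 3])))
  phi <- atan2(u[, 2], u[, 1]) %% (2 * pi)
  radii <- reconstruct_radii(model, theta, phi)
  if (any(radii <= 0)) {
    bad <- which(radii <= 0)
    stop("model reconstructs non-positive radii in ", length(bad),
         " directions (first at theta=", format(theta[bad[1]], digits = 3),
         ", phi=", format(phi[bad[1]], digits = 3), ")")
  }
  radial_mesh(radii, sphere, origin = model$origin)
}
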