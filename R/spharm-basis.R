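#' Real orthonormal spherical-harmonic basis
#'
#' Evaluates the real orthonormal spherical harmonics \eqn{Y_{lm}} (no
#' Condon--Shortley phase) at the given directions. Coefficient vectors in
#' this package are flat-indexed by \code{k = l^2 + l + m + 1} (1-based),
#' with \code{m < 0} the sine harmonics, \code{m = 0} zonal and
#' \code{m > 0} the cosine harmonics:
#' \deqn{Y_{l0} = \bar P_{l0}(\cos\theta),\quad
#'       Y_{lm} = \sqrt{2}\,\bar P_{lm}(\cos\theta)\cos(m\phi)\ (m>0),\quad
#'       Y_{l,-m} = \sqrt{2}\,\bar P_{lm}(\cos\theta)\sin(m\phi)}
#' where \eqn{\bar P_{lm}} are the fully normalized associated Legendre
#' functions, so that \eqn{\int Y_k Y_{k'}\,d\Omega = \delta_{kk'}}.
#'
#' The normalized Legendre functions are computed by the standard stable
#' three-term recurrence in degree, seeded diagonally; this avoids the
#' catastrophic overflow of unnormalized \eqn{P_l^m} at moderate degree.
#'
#' @param theta polar angles in \[0, pi\].
#' @param phi azimuth angles (any reals; wrapped mod 2pi).
#' @param L maximum degree (>= 0).
#' @return numeric matrix, \code{length(theta)} rows, \code{(L+1)^2} columns.
#' @examples
#' B <- sh_basis(pi / 3, pi / 4, 2)
#' stopifnot(abs(B[1, 1] - 1 / (2 * sqrt(pi))) < 1e-12)
#' @export
sh_basis <- function(theta, phi, L) {
  stopifnot(length(theta) == length(phi), L >= 0, L == round(L))
  n <- length(theta)
  K <- (L + 1L)^2
  B <- matrix(0, n, K)
  x <- cos(theta)
  s <- sin(theta)
  sqrt2 <- sqrt(2)

  # diagonal seed: Pbar_00 = 1/sqrt(4*pi)
  pmm <- rep.int(1 / sqrt(4 * pi), n)
  for (m in 0:L) {
    if (m > 0) pmm <- pmm * s * sqrt((2 * m + 1) / (2 * m))
    plm2 <- pmm # l = m
    plm1 <- NULL
    for (l in m:L) {
      if (l == m) {
        plm <- plm2
      } else if (l == m + 1) {
        plm <- sqrt(2 * m + 3) * x * plm2
        plm1 <- plm
      } else {
        a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
        b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
        plm <- a * (x * plm1 - b * plm2)
        plm2 <- plm1
        plm1 <- plm
      }
      kz <- l^2 + l + 1L # 1-based flat index of (l, 0)
      if (m == 0) {
        B[, kz] <- plm
      } else {
        B[, kz + m] <- sqrt2 * plm * cos(m * phi)
        B[, kz - m] <- sqrt2 * plm * sin(m * phi)
      }
    }
  }
  B
}

#' Degree/order bookkeeping for flat SPHARM coefficient indices
#'
#' @param L maximum degree.
#' @return data.frame with columns \code{k} (1-based flat index), \code{l},
#'   \code{m}; row \code{k} corresponds to \code{k = l^2 + l + m + 1}.
#' @export
sh_index_table <- function(L) {
  l <- rep.int(0:L, times = 2 * (0:L) + 1)
  m <- unlist(lapply(0:L, function(li) -li:li), use.names = FALSE)
  data.frame(k = seq_len((L + 1L)^2), l = l, m = m)
}

#' Number of real SPHARM coefficients up to degree L
#' @param L maximum degree.
#' @return integer \code{(L+1)^2}.
#' @export
sh_n_coeffs <- function(L) (L + 1L)^2

# degree of a coefficient vector of length (L+1)^2, error if not square
sh_degree_of <- function(coeffs) {
  L <- sqrt(length(coeffs)) - 1
  if (abs(L - round(L)) > 1e-9) {
    stop("coefficient vector length ", length(coeffs),
         " is not a perfect square (L+1)^2")
  }
  as.integer(round(L))
}
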