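# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the flood fill is depth-first and recursive in
# style, the quadrature projections use Gauss-Legendre nodes, and the
# ANOVA sums of squares come straight from the textbook formulas.

# brute-force flood fill: fixed-band criterion, 4-connectivity, stack-based
oracle_flood_fill <- function(slice, seed_px, tolerance) {
  nr <- nrow(slice); nc <- ncol(slice)
  v0 <- slice[seed_px[1], seed_px[2]]
  mask <- matrix(FALSE, nr, nc)
  stack <- list(seed_px)
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (p[1] < 1 || p[1] > nr || p[2] < 1 || p[2] > nc) next
    if (mask[p[1], p[2]]) next
    if (abs(slice[p[1], p[2]] - v0) > tolerance) next
    mask[p[1], p[2]] <- TRUE
    stack <- c(stack, list(p + c(0, 1), p + c(0, -1),
                           p + c(1, 0), p + c(-1, 0)))
  }
  mask
}

# quadrature projection of a radius field onto one spherical harmonic,
# using Gauss-Legendre nodes in cos(theta) and a uniform azimuth grid
oracle_sh_coefficient <- function(radius_fun, l, m, n_theta = 64,
                                  n_phi = 128) {
  gl <- pracma::gaussLegendre(n_theta, -1, 1)
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  grid <- expand.grid(x = gl$x, phi = phi)
  w <- rep(gl$w, times = n_phi) * (2 * pi / n_phi)
  theta <- acos(grid$x)
  k <- l^2 + l + m + 1
  Y <- sh_basis(theta, grid$phi, l)[, k]
  sum(w * radius_fun(theta, grid$phi) * Y)
}

# textbook balanced two-way ANOVA with interaction, direct SS formulas
oracle_two_way_ss <- function(A, B, y) {
  A <- as.character(A); B <- as.character(B)
  N <- length(y)
  gm <- mean(y)
  a_means <- tapply(y, A, mean)
  b_means <- tapply(y, B, mean)
  cell_means <- tapply(y, list(A, B), mean)
  n_cell <- table(A, B)[1, 1]
  a_lv <- names(a_means); b_lv <- names(b_means)
  ss_a <- n_cell * length(b_lv) * sum((a_means - gm)^2)
  ss_b <- n_cell * length(a_lv) * sum((b_means - gm)^2)
  ss_ab <- n_cell * sum((sweep(sweep(cell_means, 1, a_means),
                               2, b_means) + gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_res <- ss_tot - ss_a - ss_b - ss_ab
  df_a <- length(a_lv) - 1
  df_b <- length(b_lv) - 1
  df_ab <- df_a * df_b
  df_res <- N - length(a_lv) * length(b_lv)
  list(ss = c(A = ss_a, B = ss_b, AB = ss_ab, res = ss_res),
       F = c(A = (ss_a / df_a) / (ss_res / df_res),
             B = (ss_b / df_b) / (ss_res / df_res),
             AB = (ss_ab / df_ab) / (ss_res / df_res)))
}

# brute-force MDL order selection from independent least-squares refits
oracle_mdl_order <- function(samples, L_max) {
  n <- length(samples$r)
  mdl <- vapply(0:L_max, function(L) {
    B <- sh_basis(samples$theta, samples$phi, L)
    rss <- sum(stats::lsfit(B, samples$r, intercept = FALSE)$residuals^2)
    n / 2 * log(rss / n) + (L + 1)^2 / 2 * log(n)
  }, numeric(1))
  which.min(mdl) - 1L
}

# uniform random rotation (QR of a Gaussian matrix, det forced to +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply a rigid motion to a mesh and its landmark triple
apply_rigid <- function(mesh, lm, R, t) {
  v <- mesh$vertices %*% t(R)
  v <- sweep(v, 2, t, "+")
  m2 <- tri_mesh(v, mesh$faces, mesh$labels)
  list(mesh = m2,
       landmarks = landmark_triple(m2, lm$bone, lm$a_idx, lm$b_idx,
                                   lm$c_idx))
}

# random synthetic slice for segmentation tests: a bright disc on a dark
# background, optionally with a second adjacent disc and uniform noise
random_disc_slice <- function(kind = c("disc", "annulus_adjacent",
                                       "uniform")) {
  kind <- match.arg(kind)
  nr <- sample(25:45, 1); nc <- sample(25:45, 1)
  sl <- matrix(stats::runif(nr * nc, 0, 10), nr, nc)
  if (kind == "uniform") {
    return(list(slice = sl, seed = c(sample(nr, 1), sample(nc, 1))))
  }
  ctr <- c(sample(8:(nr - 8), 1), sample(8:(nc - 8), 1))
  rad <- sample(4:7, 1)
  for (r in 1:nr) for (c in 1:nc) {
    if ((r - ctr[1])^2 + (c - ctr[2])^2 <= rad^2) {
      sl[r, c] <- 100 + stats::runif(1, 0, 10)
    }
  }
  if (kind == "annulus_adjacent") {
    ctr2 <- ctr + c(0, min(nc - ctr[2] - 2, rad * 2 + 2))
    for (r in 1:nr) for (c in 1:nc) {
      if ((r - ctr2[1])^2 + (c - ctr2[2])^2 <= 9 &&
          (r - ctr[1])^2 + (c - ctr[2])^2 > rad^2) {
        sl[r, c] <- 200 + stats::runif(1, 0, 10)
      }
    }
  }
  list(slice = sl, seed = ctr)
}

# one deterministic synthetic bone sample (the suite's workhorse fixture)
fixture_sample <- function(class = "calcaneus", seed = 101, n = 1,
                           side = NULL) {
  spec <- default_bone_classes()[[class]]
  pop <- sample_population(spec, n, seed = seed)
  if (!is.null(side)) pop <- Filter(function(s) s$side == side, pop)
  if (n == 1 && !is.null(side)) pop[[1]] else pop
}

# icosphere directions as (theta, phi)
icosphere_angles <- function(level = 3) {
  u <- icosphere(level)$vertices
  list(theta = acos(pmin(1, pmax(-1, u[, 3]))),
       phi = atan2(u[, 2], u[, 1]) %% (2 * pi), u = u)
}
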