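#' Voxel volume container
#'
#' 3D scalar intensity grid with physical spacing and origin, the input
#' of the slice-wise segmentation stage. Axis 1 is the sagittal axis by
#' default: fixing an index along it yields one sagittal slice.
#'
#' @param values 3D numeric array.
#' @param spacing three positive voxel spacings (mm).
#' @param origin physical coordinate (mm) of voxel (1,1,1)'s centre.
#' @param sagittal_axis which array axis indexes sagittal slices (1-3).
#' @return object of class \code{voxel_volume}.
#' @export
voxel_volume <- function(values, spacing, origin = c(0, 0, 0),
                         sagittal_axis = 1L) {
  stopifnot(length(dim(values)) == 3, length(spacing) == 3,
            all(spacing > 0), length(origin) == 3,
            sagittal_axis %in% 1:3)
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 sagittal_axis = as.integer(sagittal_axis)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("voxel_volume:", paste(dim(x$values), collapse = " x "),
      "voxels, spacing (", paste(format(x$spacing, digits = 4),
                                 collapse = ", "),
      ") mm, sagittal axis", x$sagittal_axis, "\n")
  invisible(x)
}

#' Extract one sagittal slice as a 2D matrix
#'
#' @param volume a \code{voxel_volume}.
#' @param index slice index along the sagittal axis.
#' @return 2D numeric matrix (remaining two axes in order).
#' @export
volume_slice <- function(volume, index) {
  d <- dim(volume$values)
  ax <- volume$sagittal_axis
  if (index < 1 || index > d[ax]) {
    stop("slice index ", index, " out of range 1..", d[ax])
  }
  sl <- switch(ax,
               volume$values[index, , ],
               volume$values[, index, ],
               volume$values[, , index])
  matrix(sl, nrow = d[setdiff(1:3, ax)[1]])
}

#' Percentile-clipped linear contrast enhancement
#'
#' Rescales a slice linearly onto \[0, 1\], clipping at the given
#' intensity percentiles. The mapping is monotone non-decreasing, so
#' region-growing tolerances keep their meaning. A constant slice maps to
#' all zeros with a warning rather than an error.
#'
#' @param slice 2D numeric matrix.
#' @param low_pct,high_pct clip percentiles, 0 <= low < high <= 100.
#' @return matrix of the same shape with values in \[0, 1\].
#' @export
enhance_contrast <- function(slice, low_pct = 1, high_pct = 99) {
  stopifnot(low_pct >= 0, high_pct <= 100, low_pct < high_pct)
  qs <- stats::quantile(slice, c(low_pct, high_pct) / 100, names = FALSE)
  if (qs[2] <= qs[1]) {
    warning("slice has no intensity spread between the clip percentiles; ",
            "returning all zeros")
    return(array(0, dim(slice)))
  }
  out <- (slice - qs[1]) / (qs[2] - qs[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Seeded region growing on a slice
#'
#' Returns the maximal 4-connected set of pixels containing the seed in
#' which every pixel value v satisfies |v - v_seed| <= tolerance. The
#' criterion is fixed relative to the seed value (not a running mean), so
#' the result is independent of traversal order.
#'
#' @param slice 2D numeric matrix.
#' @param seed_px length-2 (row, col) 1-based seed pixel.
#' @param tolerance nonnegative intensity band half-width.
#' @return logical matrix mask, same shape as \code{slice}.
#' @export
grow_region <- function(slice, seed_px, tolerance) {
  nr <- nrow(slice); nc <- ncol(slice)
  r0 <- seed_px[1]; c0 <- seed_px[2]
  if (r0 < 1 || r0 > nr || c0 < 1 || c0 > nc) {
    stop("seed pixel (", r0, ", ", c0, ") outside the ", nr, " x ", nc,
         " slice")
  }
  stopifnot(tolerance >= 0)
  allowed <- abs(slice - slice[r0, c0]) <= tolerance
  mask <- matrix(FALSE, nr, nc)
  seed_lin <- (c0 - 1L) * nr + r0
  mask[seed_lin] <- TRUE
  frontier <- seed_lin
  while (length(frontier)) {
    rows <- (frontier - 1L) %% nr + 1L
    cols <- (frontier - 1L) %/% nr + 1L
    nb <- c(frontier[rows > 1L] - 1L,
            frontier[rows < nr] + 1L,
            frontier[cols > 1L] - nr,
            frontier[cols < nc] + nr)
    nb <- unique(nb[allowed[nb] & !mask[nb]])
    mask[nb] <- TRUE
    frontier <- nb
  }
  mask
}

#' Trace the outer boundary contour of a single-component mask
#'
#' Moore-neighbour boundary tracing, clockwise in pixel axes (rows grow
#' downward), with Jacob's stopping criterion. Every returned pixel is
#' foreground and touches background or the image border within its
#' 8-neighbourhood.
#'
#' @param mask logical matrix with exactly one 4-connected foreground
#'   component.
#' @param slice_index slice index to record in the result.
#' @return object of class \code{slice_contour}: list with
#'   \code{slice_index} and \code{points_px} (n x 2 matrix of (row, col)
#'   pixels forming a closed loop).
#' @export
trace_contour <- function(mask, slice_index = 1L) {
  if (!any(mask)) stop("empty mask: no region to trace")
  ncomp <- count_components4(mask)
  if (ncomp > 1) {
    stop("mask has ", ncomp, " 4-connected components; expected exactly 1")
  }
  nr <- nrow(mask); nc <- ncol(mask)
  start_lin <- which(t(mask))[1] # row-major scan: top row first
  start <- c((start_lin - 1L) %/% nc + 1L, (start_lin - 1L) %% nc + 1L)
  if (sum(mask) == 1L) {
    return(structure(list(slice_index = as.integer(slice_index),
                          points_px = matrix(start, 1, 2,
                                             dimnames = list(NULL, c("row", "col")))),
                     class = "slice_contour"))
  }
  # clockwise Moore neighbourhood starting west (rows grow downward)
  moves <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                 c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  fg <- function(p) p[1] >= 1 && p[1] <= nr && p[2] >= 1 && p[2] <= nc &&
    mask[p[1], p[2]]
  pts <- list()
  cur <- start
  backtrack_dir <- 1L # entered scanning from the west
  first_dir <- NA_integer_
  guard <- 4L * sum(mask) + 8L
  repeat {
    pts[[length(pts) + 1L]] <- cur
    found <- FALSE
    dir <- backtrack_dir
    for (step in 1:8) {
      dir <- dir %% 8L + 1L # next clockwise neighbour
      cand <- cur + moves[dir, ]
      if (fg(cand)) {
        # new backtrack: the neighbour just before cand, relative to cand
        prev <- cur + moves[(dir - 2L) %% 8L + 1L, ]
        off <- prev - cand
        backtrack_dir <- which(moves[, 1] == off[1] & moves[, 2] == off[2])
        if (is.na(first_dir)) first_dir <- dir
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) break # isolated pixel cluster fallback (unreachable here)
    if (all(cur == start) && length(pts) > 1L) {
      # Jacob's criterion: stop when re-entering start the way we first left
      nxt_dir <- backtrack_dir
      stop_now <- FALSE
      for (step in 1:8) {
        nxt_dir <- nxt_dir %% 8L + 1L
        if (fg(start + moves[nxt_dir, ])) {
          stop_now <- nxt_dir == first_dir
          break
        }
      }
      if (stop_now) break
    }
    if (length(pts) > guard) break # safety net
  }
  structure(list(slice_index = as.integer(slice_index),
                 points_px = do.call(rbind, pts)),
            class = "slice_contour")
}

# number of 4-connected foreground components (BFS labelling)
count_components4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  ncomp <- 0L
  todo <- which(mask & !seen)
  while (length(todo)) {
    ncomp <- ncomp + 1L
    frontier <- todo[1]
    seen[frontier] <- TRUE
    while (length(frontier)) {
      rows <- (frontier - 1L) %% nr + 1L
      cols <- (frontier - 1L) %/% nr + 1L
      nb <- c(frontier[rows > 1L] - 1L,
              frontier[rows < nr] + 1L,
              frontier[cols > 1L] - nr,
              frontier[cols < nc] + nr)
      nb <- unique(nb[mask[nb] & !seen[nb]])
      seen[nb] <- TRUE
      frontier <- nb
    }
    todo <- which(mask & !seen)
  }
  ncomp
}

#' Assemble slice contours into a 3D point cloud in millimetres
#'
#' Maps every contour pixel (row, col) of slice s to physical coordinates
#' origin + (index - 1) * spacing along the matching axes (voxel-centre
#' convention, 1-based indices).
#'
#' @param contours list of \code{slice_contour} objects.
#' @param volume the \code{voxel_volume} the contours came from.
#' @return numeric n x 3 matrix of points (mm).
#' @export
stack_contours <- function(contours, volume) {
  d <- dim(volume$values)
  ax <- volume$sagittal_axis
  inplane <- setdiff(1:3, ax)
  pts <- lapply(contours, function(ct) {
    if (ct$slice_index < 1 || ct$slice_index > d[ax]) {
      stop("contour slice index ", ct$slice_index, " out of range 1..",
           d[ax])
    }
    n <- nrow(ct$points_px)
    idx <- matrix(0, n, 3)
    idx[, ax] <- ct$slice_index
    idx[, inplane[1]] <- ct$points_px[, 1]
    idx[, inplane[2]] <- ct$points_px[, 2]
    sweep(sweep(idx - 1, 2, volume$spacing, "*"), 2, volume$origin, "+")
  })
  out <- do.call(rbind, pts)
  if (is.null(out)) out <- matrix(numeric(0), 0, 3)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Slice-wise segmentation of one bone from a volume
#'
#' Drives the per-slice stages across the volume: starting at the slice
#' containing the seed point, each sagittal slice is contrast-enhanced,
#' region-grown from the seed, and contour-traced; the seed is propagated
#' to neighbouring slices as the previous mask's centroid (falling back
#' to any previous-mask pixel that still looks like bone) until the bone
#' disappears. Propagation is gated on \emph{raw} intensity continuity --
#' the candidate seed's raw value must stay within the starting slice's
#' equivalent raw band -- because per-slice enhancement rescales even a
#' bone-free slice onto \[0, 1\] and would otherwise let the region walk
#' into noise beyond the bone ends. Contours are stacked into a point
#' cloud in mm.
#'
#' @param volume a \code{voxel_volume}.
#' @param seed_mm physical seed point inside the bone (mm).
#' @param tolerance region-growing tolerance on the enhanced (\[0,1\])
#'   intensity scale.
#' @param low_pct,high_pct contrast-enhancement clip percentiles.
#' @return list with \code{contours} (list of \code{slice_contour}) and
#'   \code{cloud} (n x 3 matrix, mm).
#' @export
segment_volume <- function(volume, seed_mm, tolerance = 0.25,
                           low_pct = 1, high_pct = 99) {
  d <- dim(volume$values)
  ax <- volume$sagittal_axis
  inplane <- setdiff(1:3, ax)
  idx0 <- round((seed_mm - volume$origin) / volume$spacing) + 1
  if (any(idx0 < 1) || any(idx0 > d)) {
    stop("seed point lies outside the volume")
  }
  s0 <- idx0[ax]
  seed_px0 <- c(idx0[inplane[1]], idx0[inplane[2]])

  raw0_slice <- volume_slice(volume, s0)
  raw0 <- raw0_slice[seed_px0[1], seed_px0[2]]
  q0 <- stats::quantile(raw0_slice, c(low_pct, high_pct) / 100,
                        names = FALSE)
  raw_band <- tolerance * max(q0[2] - q0[1], .Machine$double.eps)

  next_seed <- function(prev_mask, raw) {
    # centroid of the previous mask if still bone-like, else any
    # previous-mask pixel whose raw value stays in the bone band
    w <- which(prev_mask, arr.ind = TRUE)
    ctr <- round(colMeans(w))
    ok <- function(px) px[1] >= 1 && px[1] <= nrow(raw) &&
      px[2] >= 1 && px[2] <= ncol(raw) &&
      abs(raw[px[1], px[2]] - raw0) <= raw_band
    if (ok(ctr)) return(ctr)
    cand <- which(abs(raw[w] - raw0) <= raw_band)
    if (!length(cand)) return(NULL)
    w[cand[1], ]
  }

  first_enh <- enhance_contrast(raw0_slice, low_pct, high_pct)
  masks <- list()
  masks[[as.character(s0)]] <- grow_region(first_enh, seed_px0, tolerance)
  for (dir in c(1L, -1L)) {
    prev <- masks[[as.character(s0)]]
    s <- s0 + dir
    while (s >= 1 && s <= d[ax]) {
      raw <- volume_slice(volume, s)
      px <- next_seed(prev, raw)
      if (is.null(px)) break
      sl <- enhance_contrast(raw, low_pct, high_pct)
      mask <- grow_region(sl, px, tolerance)
      if (!any(mask)) break
      masks[[as.character(s)]] <- mask
      prev <- mask
      s <- s + dir
    }
  }
  slices <- sort(as.integer(names(masks)))
  contours <- lapply(slices, function(s) {
    trace_contour(largest_component4(masks[[as.character(s)]]), s)
  })
  list(contours = contours, cloud = stack_contours(contours, volume))
}

# keep only the largest 4-connected component of a mask
largest_component4 <- function(mask) {
  nr <- nrow(mask)
  best <- NULL
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  todo <- which(mask & !seen)
  while (length(todo)) {
    comp <- logical(length(mask))
    frontier <- todo[1]
    seen[frontier] <- TRUE
    comp[frontier] <- TRUE
    while (length(frontier)) {
      rows <- (frontier - 1L) %% nr + 1L
      cols <- (frontier - 1L) %/% nr + 1L
      nb <- c(frontier[rows > 1L] - 1L,
              frontier[rows < nr] + 1L,
              frontier[cols > 1L] - nr,
              frontier[cols < ncol(mask)] + nr)
      nb <- unique(nb[mask[nb] & !seen[nb]])
      seen[nb] <- TRUE
      comp[nb] <- TRUE
      frontier <- nb
    }
    if (is.null(best) || sum(comp) > sum(best)) best <- comp
    todo <- which(mask & !seen)
  }
  matrix(best, nrow(mask), ncol(mask))
}
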