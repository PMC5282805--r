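#' Write a mesh as ASCII PLY
#'
#' Vertex coordinates (optionally with normals and a landmark-patch
#' label property) and triangular faces, 0-based face indices per the
#' PLY convention. Numbers are printed with 17 significant digits so
#' round-trips are lossless.
#'
#' @param mesh a \code{tri_mesh}.
#' @param path output file path.
#' @param normals optional n x 3 matrix of vertex normals.
#' @return the path, invisibly.
#' @export
write_ply <- function(mesh, path, normals = NULL) {
  v <- mesh$vertices
  f <- mesh$faces
  has_lab <- !is.null(mesh$labels)
  header <- c("ply", "format ascii 1.0",
              "comment tarsalSSM surface mesh",
              paste("element vertex", nrow(v)),
              "property double x", "property double y", "property double z")
  if (!is.null(normals)) {
    header <- c(header, "property double nx", "property double ny",
                "property double nz")
  }
  if (has_lab) header <- c(header, "property uchar patch")
  header <- c(header, paste("element face", nrow(f)),
              "property list uchar int vertex_indices", "end_header")
  vm <- v
  if (!is.null(normals)) vm <- cbind(vm, normals)
  vl <- apply(vm, 1, function(row) {
    paste(sprintf("%.17g", row), collapse = " ")
  })
  if (has_lab) {
    # encode patch labels as bytes: 0 = unlabelled, 97.. = letter codes
    codes <- vapply(mesh$labels, function(s) {
      if (nzchar(s)) utf8ToInt(substr(s, 1, 1)) else 0
    }, numeric(1))
    vl <- paste(vl, codes)
  }
  fl <- apply(f - 1L, 1, function(row) paste(c(3L, row), collapse = " "))
  writeLines(c(header, vl, fl), path)
  invisible(path)
}

#' Read an ASCII PLY mesh written by \code{write_ply}
#'
#' @param path PLY file path.
#' @return \code{tri_mesh}, with labels when a patch property is present
#'   and normals (if stored) as attribute \code{"normals"}.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply") stop("not a PLY file: ", path)
  endh <- which(lines == "end_header")[1]
  header <- lines[seq_len(endh)]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", header, value = TRUE)))
  vprops <- sub("^property \\S+ ", "",
                grep("^property (double|float|uchar) ", header,
                     value = TRUE))
  vlines <- lines[endh + seq_len(nv)]
  vm <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), as.numeric))
  colnames(vm) <- vprops
  flines <- lines[endh + nv + seq_len(nf)]
  fm <- do.call(rbind, lapply(strsplit(flines, " "), function(x) {
    as.integer(x[2:4]) + 1L
  }))
  labels <- NULL
  if ("patch" %in% vprops) {
    labels <- ifelse(vm[, "patch"] > 0,
                     vapply(vm[, "patch"], function(ci) {
                       if (ci > 0) intToUtf8(ci) else ""
                     }, character(1)), "")
  }
  mesh <- tri_mesh(vm[, c("x", "y", "z")], fm, labels)
  if (all(c("nx", "ny", "nz") %in% vprops)) {
    attr(mesh, "normals") <- vm[, c("nx", "ny", "nz")]
  }
  mesh
}

#' Write a mesh as Wavefront OBJ
#'
#' @param mesh a \code{tri_mesh}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_obj <- function(mesh, path) {
  v <- apply(mesh$vertices, 1, function(row) {
    paste("v", paste(sprintf("%.17g", row), collapse = " "))
  })
  f <- apply(mesh$faces, 1, function(row) {
    paste("f", paste(row, collapse = " "))
  })
  writeLines(c("# tarsalSSM surface mesh", v, f), path)
  invisible(path)
}

#' Write a voxel volume as NIfTI
#'
#' @param volume a \code{voxel_volume}.
#' @param path output path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
write_volume_nifti <- function(volume, path) {
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume into a \code{voxel_volume}
#'
#' @param path NIfTI file path.
#' @param origin physical coordinate of voxel (1,1,1); the physical
#'   origin is pipeline metadata not preserved in the simple qform
#'   written by \code{write_volume_nifti}.
#' @param sagittal_axis grid axis indexing sagittal slices.
#' @return \code{voxel_volume}.
#' @export
read_volume_nifti <- function(path, origin = c(0, 0, 0),
                              sagittal_axis = 1L) {
  img <- RNifti::readNifti(path)
  voxel_volume(array(as.numeric(img), dim = dim(img)),
               spacing = RNifti::pixdim(img)[1:3], origin = origin,
               sagittal_axis = sagittal_axis)
}

#' Write SPHARM coefficients as CSV
#'
#' Long format with degree/order bookkeeping: columns l, m, k, value.
#'
#' @param model a \code{spharm_model}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_coefficients_csv <- function(model, path) {
  idx <- sh_index_table(model$L)
  idx$value <- model$coeffs
  utils::write.csv(idx[, c("l", "m", "k", "value")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write landmarks as JSON
#'
#' @param lm a \code{landmark_triple}.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_landmarks_json <- function(lm, path) {
  jsonlite::write_json(
    list(bone = lm$bone,
         a = list(index = lm$a_idx, mm = lm$a_mm),
         b = list(index = lm$b_idx, mm = lm$b_mm),
         c = list(index = lm$c_idx, mm = lm$c_mm)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
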