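# ---- readers / writers ----
# NIfTI-1 through RNifti; FSL bvec/bval text; TrackVis TRK and MRtrix TCK
# tractogram formats (binary, little-endian). The package's canonical
# coordinate space is mm with a diagonal voxel-to-mm affine, which makes
# TRK's voxel-mm convention and world mm coincide.

#' Write a 3D/4D volume as NIfTI-1
#' @param data numeric or logical array
#' @param voxel_size isotropic voxel size, mm
#' @param path output path (.nii or .nii.gz)
#' @export
write_nifti_vol <- function(data, voxel_size, path) {
  if (is.logical(data)) data <- array(as.integer(data), dim(data))
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- c(rep(voxel_size, 3),
                           rep(1, max(length(dim(data)) - 3, 0)))
  aff <- diag(c(rep(voxel_size, 3), 1))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#' @param path file path
#' @return list `data` (array), `voxel_size`, `affine`
#' @export
read_nifti_vol <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  list(data = array(as.numeric(img), dim(img)),
       voxel_size = RNifti::pixdim(img)[1], affine = unclass(aff))
}

#' Write FSL-style bvec/bval files
#'
#' bvec: 3 x N (zero columns for b = 0 volumes); bval: 1 x N.
#'
#' @param scheme a [gradient_scheme()]
#' @param bvec_path,bval_path output paths
#' @export
write_bvec_bval <- function(scheme, bvec_path, bval_path) {
  n <- length(scheme$bvals)
  B <- matrix(0, 3, n)
  B[, scheme$bvals > 0] <- t(scheme$directions)
  write(t(format(B, digits = 17)), bvec_path, ncolumns = n)
  write(format(scheme$bvals, digits = 17), bval_path, ncolumns = n)
  invisible(bvec_path)
}

#' Read FSL-style bvec/bval files
#'
#' Non-unit direction vectors are normalized with a warning.
#'
#' @param bvec_path,bval_path input paths
#' @return a [gradient_scheme()]
#' @export
read_bvec_bval <- function(bvec_path, bval_path) {
  B <- as.matrix(utils::read.table(bvec_path))
  bval <- as.numeric(utils::read.table(bval_path))
  if (nrow(B) != 3) stop("bvec must have 3 rows")
  if (ncol(B) != length(bval)) stop("bvec/bval length mismatch")
  dw <- bval > 0
  dirs <- unname(t(B[, dw, drop = FALSE]))
  nrm <- sqrt(rowSums(dirs^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    warning("non-unit bvec directions normalized")
    dirs <- dirs / nrm
  }
  bnz <- unique(bval[dw])
  if (length(bnz) != 1) stop("expected a single shell")
  # b = 0 entries are reordered first (the scheme's canonical layout)
  gradient_scheme(dirs, b = bnz, n_b0 = sum(!dw))
}

write_padded <- function(con, s, width) {
  raw_s <- charToRaw(s)
  writeBin(c(raw_s, raw(width - length(raw_s))), con)
}

#' Write a tractogram as TrackVis TRK
#'
#' Version-2 header with the voxel-to-RAS affine embedded; coordinates are
#' written in the package's mm space (identical to TRK voxel-mm under the
#' diagonal affine).
#'
#' @param t a [tractogram()]
#' @param path output path
#' @param dims grid dimensions (voxels)
#' @export
write_trk <- function(t, path, dims) {
  con <- file(path, "wb")
  on.exit(close(con))
  vs <- t$voxel_size
  write_padded(con, "TRACK", 6)
  writeBin(as.integer(dims), con, size = 2)
  writeBin(rep(vs, 3), con, size = 4)
  writeBin(rep(0, 3), con, size = 4)              # origin
  writeBin(0L, con, size = 2)                     # n_scalars
  writeBin(raw(200), con)
  writeBin(0L, con, size = 2)                     # n_properties
  writeBin(raw(200), con)
  aff <- diag(c(rep(vs, 3), 1))
  writeBin(as.numeric(t(aff)), con, size = 4)     # vox_to_ras, row-major
  writeBin(raw(444), con)                         # reserved
  write_padded(con, "RAS", 4)                     # voxel_order
  writeBin(raw(4), con)                           # pad2
  writeBin(rep(0, 6), con, size = 4)              # image_orientation_patient
  writeBin(raw(2), con)                           # pad1
  writeBin(raw(6), con)                           # invert/swap flags
  writeBin(length(t$streamlines), con, size = 4)  # n_count
  writeBin(2L, con, size = 4)                     # version
  writeBin(1000L, con, size = 4)                  # hdr_size
  for (sl in t$streamlines) {
    writeBin(nrow(sl), con, size = 4)
    writeBin(as.numeric(t(sl)), con, size = 4)
  }
  invisible(path)
}

#' Read a TrackVis TRK file
#' @param path input path
#' @return a [tractogram()]; grid dims in attribute `dims`
#' @export
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 6)[1:5])
  if (magic != "TRACK") stop("malformed TRK header: id_string")
  dims <- readBin(con, "integer", 3, size = 2)
  vs <- readBin(con, "numeric", 3, size = 4)
  invisible(readBin(con, "numeric", 3, size = 4))
  n_scalars <- readBin(con, "integer", 1, size = 2)
  invisible(readBin(con, "raw", 200))
  n_props <- readBin(con, "integer", 1, size = 2)
  invisible(readBin(con, "raw", 200))
  invisible(readBin(con, "numeric", 16, size = 4))
  invisible(readBin(con, "raw", 444 + 4 + 4))
  invisible(readBin(con, "numeric", 6, size = 4))
  invisible(readBin(con, "raw", 2 + 6))
  n_count <- readBin(con, "integer", 1, size = 4)
  version <- readBin(con, "integer", 1, size = 4)
  hdr_size <- readBin(con, "integer", 1, size = 4)
  if (hdr_size != 1000L) stop("malformed TRK header: hdr_size")
  sl <- vector("list", n_count)
  for (i in seq_len(n_count)) {
    np <- readBin(con, "integer", 1, size = 4)
    pts <- readBin(con, "numeric", np * (3 + n_scalars), size = 4)
    if (n_scalars == 0) {
      sl[[i]] <- matrix(pts, np, 3, byrow = TRUE)
    } else {
      m <- matrix(pts, np, 3 + n_scalars, byrow = TRUE)
      sl[[i]] <- m[, 1:3, drop = FALSE]
    }
    if (n_props > 0) invisible(readBin(con, "numeric", n_props, size = 4))
  }
  tg <- tractogram(sl, voxel_size = vs[1])
  attr(tg, "dims") <- dims
  tg
}

#' Write a tractogram as MRtrix TCK
#' @param t a [tractogram()]
#' @param path output path
#' @export
write_tck <- function(t, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ",
                length(t$streamlines), "\n")
  offset_line_len <- nchar("file: . ") + 6 + 1 + nchar("END\n")
  offset <- nchar(hdr) + offset_line_len
  hdr <- paste0(hdr, "file: . ", formatC(offset, width = 6), "\nEND\n")
  writeBin(charToRaw(hdr), con)
  for (sl in t$streamlines) {
    writeBin(as.numeric(t(sl)), con, size = 4)
    writeBin(rep(NaN, 3), con, size = 4)
  }
  writeBin(rep(Inf, 3), con, size = 4)
  invisible(path)
}

#' Read an MRtrix TCK file
#' @param path input path
#' @param voxel_size mm (TCK carries none; needed for the container)
#' @return a [tractogram()]
#' @export
read_tck <- function(path, voxel_size = NA_real_) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  hdr_end <- grepRaw("END\n", raw_all, fixed = TRUE)
  if (length(hdr_end) == 0) stop("malformed TCK header: no END")
  hdr <- strsplit(rawToChar(raw_all[1:(hdr_end + 3)]), "\n")[[1]]
  if (hdr[1] != "mrtrix tracks") stop("malformed TCK header: magic")
  off_line <- grep("^file: ", hdr, value = TRUE)
  offset <- as.integer(sub("^file: \\. *", "", off_line))
  vals <- readBin(raw_all[(offset + 1):length(raw_all)], "numeric",
                  (length(raw_all) - offset) / 4, size = 4)
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  breaks <- which(is.nan(m[, 1]) | is.infinite(m[, 1]))
  sl <- list(); start <- 1L
  for (b in breaks) {
    if (b > start) sl[[length(sl) + 1L]] <- m[start:(b - 1L), , drop = FALSE]
    start <- b + 1L
    if (is.infinite(m[b, 1])) break
  }
  tractogram(sl, voxel_size = voxel_size)
}

#' Write a JSON cluster/atlas manifest
#' @param x list or data.frame
#' @param path output path
#' @export
write_manifest <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
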