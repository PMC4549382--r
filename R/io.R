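#' Write a tractogram in MRtrix TCK format
#'
#' Binary TCK: a text header followed by little-endian float32 point
#' triplets in world mm, with NaN triplets separating streamlines and an
#' Inf triplet terminating the file.
#'
#' @param t A \code{tractogram} (or list of point matrices).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_tck <- function(t, path) {
  sl <- if (inherits(t, "tractogram")) t$streamlines else t
  header <- paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ",
                   length(sl), "\n")
  # offset field must include its own length; pad to a fixed width
  off_line <- function(off) sprintf("file: . %d\nEND\n", off)
  off <- nchar(header, type = "bytes") + nchar(off_line(1e8), type = "bytes")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(header, sprintf("file: . %09d\nEND\n", off)), con,
            eos = NULL)
  for (m in sl) {
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRtrix TCK file
#'
#' @param path Path to a TCK file written by \code{\link{write_tck}} or a
#'   compatible tool (Float32LE datatype).
#' @return List of n x 3 point matrices.
#' @export
read_tck <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  end_tok <- grepRaw("END\n", raw, fixed = TRUE)
  if (length(end_tok) == 0) stop("not a TCK file (no END token)")
  header <- rawToChar(raw[1:(end_tok[1] + 3)])
  if (!grepl("^mrtrix tracks", header)) stop("not a TCK file")
  off <- as.integer(sub(".*file: \\. ([0-9]+).*", "\\1", header))
  vals <- readBin(raw[(off + 1):length(raw)], "numeric",
                  n = (length(raw) - off) / 4, size = 4, endian = "little")
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  breaks <- which(is.nan(pts[, 1]) | is.infinite(pts[, 1]))
  out <- list()
  start <- 1
  for (b in breaks) {
    if (b > start) out[[length(out) + 1]] <- pts[start:(b - 1), , drop = FALSE]
    if (is.infinite(pts[b, 1])) break
    start <- b + 1
  }
  out
}

#' Write a 3D mask or scalar volume as NIfTI
#'
#' @param x 3D array, logical array, or \code{scalar_map}.
#' @param path Output path (.nii or .nii.gz).
#' @param voxel_mm Isotropic voxel size recorded in the header.
#' @return The path, invisibly.
#' @export
write_volume_nifti <- function(x, path, voxel_mm = 1) {
  if (inherits(x, "scalar_map")) {
    voxel_mm <- x$voxel_mm
    x <- x$values
  }
  img <- RNifti::asNifti(x * 1)
  RNifti::pixdim(img) <- rep(voxel_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write per-streamline segmentation assignments as a delimited table
#'
#' @param label_sets List of termination label sets.
#' @param codes Rejection codes.
#' @param vf,hier Segment assignments from the two schemes.
#' @param path Output TSV path.
#' @return The data frame written, invisibly.
#' @export
write_assignment_table <- function(label_sets, codes, vf, hier, path) {
  df <- data.frame(id = seq_along(codes),
                   labels = vapply(label_sets, paste, character(1),
                                   collapse = "+"),
                   rejection = codes,
                   visual_field = as.character(vf),
                   hierarchy = as.character(hier))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
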