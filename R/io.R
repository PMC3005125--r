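# Volume and field I/O: NIfTI via RNifti, plus a minimal MetaImage
# (.mhd/.mha) reader/writer. Landmarks are whitespace-delimited text,
# one point per line, 0-based voxel indices.

.is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)
.is_mhd_path <- function(path) grepl("\\.(mhd|mha)$", path, ignore.case = TRUE)

.mhd_types <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
                MET_SHORT = "integer", MET_USHORT = "integer",
                MET_INT = "integer", MET_UINT = "integer",
                MET_FLOAT = "double", MET_DOUBLE = "double")
.mhd_sizes <- c(MET_UCHAR = 1L, MET_CHAR = 1L, MET_SHORT = 2L, MET_USHORT = 2L,
                MET_INT = 4L, MET_UINT = 4L, MET_FLOAT = 4L, MET_DOUBLE = 8L)
.mhd_signed <- c(MET_UCHAR = FALSE, MET_CHAR = TRUE, MET_SHORT = TRUE,
                 MET_USHORT = FALSE, MET_INT = TRUE, MET_UINT = FALSE,
                 MET_FLOAT = TRUE, MET_DOUBLE = TRUE)

.read_mhd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  offset <- 0L
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    offset <- offset + nchar(line, type = "bytes") + 1L
    if (length(line) == 0L) stop("unterminated MetaImage header", call. = FALSE)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) stop("malformed MetaImage header line: ", line, call. = FALSE)
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else rep(1, length(dims))
  type <- hdr$ElementType
  if (!(type %in% names(.mhd_types)))
    stop("unsupported MetaImage element type: ", type, call. = FALSE)
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    vals <- readBin(con, what = .mhd_types[[type]], n = n,
                    size = .mhd_sizes[[type]], signed = .mhd_signed[[type]],
                    endian = "little")
  } else {
    raw_path <- file.path(dirname(path), hdr$ElementDataFile)
    rcon <- file(raw_path, "rb")
    on.exit(close(rcon), add = TRUE)
    vals <- readBin(rcon, what = .mhd_types[[type]], n = n,
                    size = .mhd_sizes[[type]], signed = .mhd_signed[[type]],
                    endian = "little")
  }
  if (length(vals) != n) stop("truncated MetaImage data", call. = FALSE)
  out <- array(as.numeric(vals), dims)
  attr(out, "spacing") <- spacing
  out
}

.write_mhd <- function(x, path, spacing) {
  dims <- dim(x)
  local_ <- grepl("\\.mha$", path, ignore.case = TRUE)
  data_file <- if (local_) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path),
                                                   ignore.case = TRUE), ".raw")
  hdr <- c(
    "ObjectType = Image",
    sprintf("NDims = %d", length(dims)),
    sprintf("DimSize = %s", paste(dims, collapse = " ")),
    "ElementType = MET_DOUBLE",
    sprintf("ElementSpacing = %s", paste(spacing, collapse = " ")),
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("ElementDataFile = %s", data_file))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (local_) {
    writeBin(as.numeric(x), con, size = 8L, endian = "little")
  } else {
    rcon <- file(file.path(dirname(path), data_file), "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(as.numeric(x), rcon, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Read a scalar volume from NIfTI or MetaImage
#'
#' Supports `.nii`/`.nii.gz` (via RNifti) and `.mhd`/`.mha` (local or
#' separate-raw MetaImage). The voxel spacing is attached as attribute
#' `"spacing"`.
#'
#' @param path File path.
#' @return Numeric array with attribute `"spacing"` (mm per voxel per axis).
#' @export
read_volume <- function(path) {
  if (.is_nifti_path(path)) {
    img <- RNifti::readNifti(path)
    out <- array(as.numeric(img), dim(img))
    pd <- RNifti::pixdim(img)
    attr(out, "spacing") <- pd[seq_along(dim(out))]
    out
  } else if (.is_mhd_path(path)) {
    .read_mhd(path)
  } else {
    stop("unsupported volume format: ", path, call. = FALSE)
  }
}

#' Write a scalar volume to NIfTI or MetaImage
#'
#' @param x Numeric array (2D or 3D).
#' @param path Output path ending in `.nii`, `.nii.gz`, `.mhd` or `.mha`.
#' @param spacing Voxel size per axis in mm (defaults to the array's
#'   `"spacing"` attribute, else 1).
#' @return The path, invisibly.
#' @export
write_volume <- function(x, path, spacing = NULL) {
  if (is.null(spacing)) spacing <- attr(x, "spacing")
  if (is.null(spacing)) spacing <- rep(1, length(dim(x)))
  if (.is_nifti_path(path)) {
    img <- RNifti::asNifti(array(as.numeric(x), dim(x)))
    RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, path)
  } else if (.is_mhd_path(path)) {
    .write_mhd(x, path, spacing)
  } else {
    stop("unsupported volume format: ", path, call. = FALSE)
  }
  invisible(path)
}

#' Read a displacement field
#'
#' Reads a multi-component volume whose last dimension holds the vector
#' components (the layout written by [write_field()]).
#'
#' @param path File path (NIfTI or MetaImage).
#' @return Displacement field array (trailing component dimension).
#' @export
read_field <- function(path) {
  x <- read_volume(path)
  d <- dim(x)
  if (d[length(d)] != length(d) - 1L)
    stop("file does not contain a displacement field ",
         "(last dimension must hold the vector components)", call. = FALSE)
  attr(x, "spacing") <- attr(x, "spacing")[seq_len(length(d) - 1L)]
  x
}

#' Write a displacement field
#'
#' Stores the field as a multi-component volume with the vector dimension
#' last (a `c(nx, ny, 2)` array for 2D, `c(nx, ny, nz, 3)` for 3D).
#'
#' @param D Displacement field.
#' @param path Output path (NIfTI or MetaImage).
#' @param spacing Voxel size of the underlying grid (mm).
#' @return The path, invisibly.
#' @export
write_field <- function(D, path, spacing = NULL) {
  .check_field(D, "D")
  if (is.null(spacing)) spacing <- rep(1, .field_ndim(D))
  write_volume(D, path, spacing = c(spacing, 1))
}

#' Read landmarks from a text file
#'
#' Whitespace-delimited, one point per line, 0-based voxel indices (the
#' common point-list convention); converted to this package's 1-based voxel
#' coordinates.
#'
#' @param path File path.
#' @param ndim Expected dimensionality (2 or 3; default from the file).
#' @return Numeric matrix, one landmark per row, 1-based coordinates.
#' @export
read_landmarks <- function(path, ndim = NULL) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (!is.null(ndim) && ncol(m) != ndim)
    stop("expected ", ndim, " coordinates per landmark", call. = FALSE)
  unname(m) + 1
}
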