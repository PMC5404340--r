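#' Binary label volumes
#'
#' Container for a binary (0/1) segmentation volume on a regular grid.
#' Voxel `(i, j, k)` (0-based) has its centre at world position
#' `origin + c(i, j, k) * spacing` (mm); world coordinates are used by all
#' downstream mesh operations.
#'
#' @param data 3-D array with values in `{0, 1}`.
#' @param spacing positive length-3 voxel spacing (mm/voxel).
#' @param origin length-3 world position of voxel `(0, 0, 0)` (mm).
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("'data' must be a 3-D array")
  spacing <- as_point3(spacing, "spacing")
  origin <- as_point3(origin, "origin")
  if (any(spacing <= 0)) stop("'spacing' must be strictly positive")
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1))) {
    stop("'data' must be binary (values in {0, 1})")
  }
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("label_volume: %s voxels, spacing (%s) mm, %d foreground\n",
              paste(dim(x$data), collapse = " x "),
              paste(format(x$spacing), collapse = ", "),
              sum(x$data)))
  invisible(x)
}

# World coordinates of voxel centres along each axis.
grid_axes <- function(vol) {
  d <- dim(vol$data)
  lapply(1:3, function(k) vol$origin[k] + (seq_len(d[k]) - 1) * vol$spacing[k])
}

#' Read a volume from NIfTI or MetaImage
#'
#' NIfTI (`.nii`, `.nii.gz`) is read through RNifti; MetaImage (`.mhd`,
#' `.mha`, uncompressed) through a minimal built-in reader. Values are
#' binarized with `value > 0.5`.
#'
#' @param path file path.
#' @return A `label_volume` with spacing/origin taken from the header.
#' @export
read_label_volume <- function(path) {
  if (grepl("\\.(nii|nii\\.gz)$", path)) {
    img <- RNifti::readNifti(path)
    spacing <- RNifti::pixdim(img)[1:3]
    arr <- as.array(img)
    if (length(dim(arr)) > 3L) arr <- array(arr, dim(arr)[1:3])
    orig <- tryCatch(-RNifti::xform(img)[1:3, 4], error = function(e) c(0, 0, 0))
    label_volume((arr > 0.5) * 1, spacing = spacing, origin = as.numeric(orig))
  } else if (grepl("\\.(mhd|mha)$", path)) {
    read_metaimage(path)
  } else {
    stop("unsupported volume format: ", path)
  }
}

#' Write a volume or scalar grid to NIfTI
#'
#' @param data a `label_volume`, or a list with `data`/`energy`, `spacing`,
#'   `origin` fields, or a bare 3-D array.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param spacing,origin used when `data` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(data, path, spacing = c(1, 1, 1),
                               origin = c(0, 0, 0)) {
  if (is.list(data)) {
    arr <- data$data %||% data$energy
    spacing <- data$spacing %||% spacing
    origin <- data$origin %||% origin
  } else {
    arr <- data
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Minimal uncompressed MetaImage reader (local raw, MET_* scalar types).
read_metaimage <- function(path) {
  if (grepl("\\.mha$", path)) {
    con <- file(path, "rb")
    on.exit(close(con))
    header <- character(0)
    repeat {
      ln <- readLines(con, n = 1L)
      header <- c(header, ln)
      if (grepl("^ElementDataFile", ln)) break
    }
    hdr <- parse_mhd_header(header)
    arr <- read_mhd_raw(con, hdr)
  } else {
    header <- readLines(path, warn = FALSE)
    hdr <- parse_mhd_header(header)
    raw_path <- file.path(dirname(path), hdr$datafile)
    con <- file(raw_path, "rb")
    on.exit(close(con))
    arr <- read_mhd_raw(con, hdr)
  }
  label_volume((arr > 0.5) * 1, spacing = hdr$spacing, origin = hdr$origin)
}

parse_mhd_header <- function(lines) {
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  get <- function(k, default = NULL) {
    i <- match(k, keys)
    if (is.na(i)) default else vals[i]
  }
  if (!is.null(get("CompressedData")) &&
      toupper(get("CompressedData")) == "TRUE") {
    stop("compressed MetaImage files are not supported")
  }
  dims <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  list(
    dims = dims,
    spacing = as.numeric(strsplit(get("ElementSpacing", "1 1 1"), "\\s+")[[1]]),
    origin = as.numeric(strsplit(get("Offset", "0 0 0"), "\\s+")[[1]]),
    type = get("ElementType", "MET_UCHAR"),
    datafile = get("ElementDataFile", "LOCAL"))
}

read_mhd_raw <- function(con, hdr) {
  n <- prod(hdr$dims)
  vals <- switch(hdr$type,
    MET_UCHAR = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    MET_CHAR = as.numeric(readBin(con, "integer", n, size = 1, signed = TRUE)),
    MET_SHORT = as.numeric(readBin(con, "integer", n, size = 2)),
    MET_USHORT = as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE)),
    MET_INT = as.numeric(readBin(con, "integer", n, size = 4)),
    MET_FLOAT = readBin(con, "double", n, size = 4),
    MET_DOUBLE = readBin(con, "double", n, size = 8),
    stop("unsupported MetaImage element type: ", hdr$type))
  array(vals, dim = hdr$dims)
}

#' Write a label volume as an uncompressed MetaImage (.mha)
#'
#' @param vol a `label_volume`.
#' @param path output path ending in `.mha`.
#' @return `path`, invisibly.
#' @export
write_metaimage <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"), grepl("\\.mha$", path))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    sprintf("DimSize = %s", paste(dim(vol$data), collapse = " ")),
    sprintf("ElementSpacing = %s", paste(format(vol$spacing, trim = TRUE), collapse = " ")),
    sprintf("Offset = %s", paste(format(vol$origin, trim = TRUE), collapse = " ")),
    "ElementType = MET_UCHAR",
    "ElementDataFile = LOCAL")
  writeLines(hdr, con)
  writeBin(as.integer(vol$data), con, size = 1)
  invisible(path)
}
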