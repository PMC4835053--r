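#' Read a 3D volume from NIfTI or MetaImage
#'
#' Supports NIfTI-1 (`.nii`, `.nii.gz`) via RNifti and uncompressed local
#' MetaImage (`.mha`). Spacing is taken from the header; the origin is the
#' translation part of the stored transform. Direction cosines are assumed to
#' be the identity (see [vol3d()]); files with oblique orientations should be
#' resampled before use.
#'
#' @param path path to an existing `.nii`, `.nii.gz`, `.mha` or `.mhd` file.
#' @return A [vol3d()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.mha$|\\.mhd$", path, ignore.case = TRUE)) return(read_mha(path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) > 3L) {
    if (prod(d[-(1:3)]) != 1L)
      stop("expected a scalar 3D image but dimension ", which(d[-(1:3)] > 1)[1] + 3,
           " has size ", d[-(1:3)][d[-(1:3)] > 1][1])
    img <- array(as.array(img), dim = d[1:3])
  } else if (length(d) < 3L) {
    stop("expected a 3D image, got ", length(d), "D")
  }
  xf <- RNifti::xform(RNifti::asNifti(img))
  vol3d(array(as.numeric(img), dim = dim(img)[1:3]),
        spacing = RNifti::pixdim(img)[1:3],
        origin = as.numeric(xf[1:3, 4]))
}

#' Write a 3D volume to NIfTI or MetaImage
#'
#' Integer-valued data round-trips bitwise; floating point within 1e-6.
#' NaN or infinite intensities are rejected before writing.
#'
#' @param img a [vol3d()] (or [labelmap()]).
#' @param path output path ending in `.nii`, `.nii.gz` or `.mha`.
#' @export
write_volume <- function(img, path) {
  stopifnot(inherits(img, "vol3d"))
  if (any(!is.finite(img$data))) stop("volume contains non-finite intensities")
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  if (grepl("\\.mha$", path, ignore.case = TRUE)) return(write_mha(img, path))
  arr <- img$data
  if (inherits(img, "labelmap")) storage.mode(arr) <- "integer"
  n <- RNifti::asNifti(arr)
  RNifti::pixdim(n) <- img$spacing
  sf <- rbind(cbind(diag(img$spacing), img$origin), c(0, 0, 0, 1))
  RNifti::sform(n) <- structure(sf, code = 2L)
  RNifti::writeNifti(n, path)
  invisible(path)
}

#' Read a label map and validate it against a dictionary
#'
#' @param path file path as in [read_volume()].
#' @param dictionary named integer vector of organ labels.
#' @return A [labelmap()]. Fractional voxel values beyond 1e-6 are a format
#'   error; unknown nonzero labels are reported by value.
#' @export
read_labelmap <- function(path, dictionary = default_label_dictionary()) {
  v <- read_volume(path)
  r <- round(v$data)
  if (max(abs(v$data - r)) > 1e-6)
    stop("label file contains fractional voxel values: ", path)
  labelmap(array(as.integer(r), dim = dim(r)), v$spacing, v$origin, dictionary)
}

#' Write / read a dense displacement field
#'
#' Stored as a 5D NIfTI vector image (`nx, ny, nz, 1, 3`) with intent code
#' 1007 (displacement vector), components in world mm. Round trip is lossless
#' to 1e-6 mm.
#'
#' @param field a [dispfield()].
#' @param path `.nii` or `.nii.gz` path.
#' @export
write_displacement_field <- function(field, path) {
  stopifnot(inherits(field, "dispfield"))
  d <- dim(field$data)
  arr <- array(field$data, dim = c(d[1:3], 1L, 3L))
  n <- RNifti::asNifti(arr, reference = list(intent_code = 1007L))
  RNifti::pixdim(n) <- field$spacing
  sf <- rbind(cbind(diag(field$spacing), field$origin), c(0, 0, 0, 1))
  RNifti::sform(n) <- structure(sf, code = 2L)
  RNifti::writeNifti(n, path)
  invisible(path)
}

#' @rdname write_displacement_field
#' @export
read_displacement_field <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 5L && d[4] == 1L) {
    arr <- array(as.numeric(img), dim = c(d[1:3], d[5]))
  } else if (length(d) == 4L) {
    arr <- array(as.numeric(img), dim = d)
  } else {
    stop("not a vector displacement image: ", length(d), "D array")
  }
  if (dim(arr)[4] != 3L)
    stop("displacement image has ", dim(arr)[4], " components, expected 3")
  xf <- RNifti::xform(RNifti::asNifti(img))
  dispfield(arr, spacing = RNifti::pixdim(img)[1:3],
            origin = as.numeric(xf[1:3, 4]))
}

# ---- MetaImage (.mha, local uncompressed payload) --------------------------

mha_types <- c(MET_UCHAR = "integer", MET_CHAR = "integer", MET_SHORT = "integer",
               MET_USHORT = "integer", MET_INT = "integer", MET_UINT = "integer",
               MET_FLOAT = "double", MET_DOUBLE = "double")
mha_sizes <- c(MET_UCHAR = 1L, MET_CHAR = 1L, MET_SHORT = 2L, MET_USHORT = 2L,
               MET_INT = 4L, MET_UINT = 4L, MET_FLOAT = 4L, MET_DOUBLE = 8L)

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("unexpected end of MetaImage header: ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementDataFile"]], "LOCAL"))
    stop("only LOCAL MetaImage payloads are supported")
  nd <- as.integer(hdr[["NDims"]])
  if (!identical(nd, 3L)) stop("expected a 3D MetaImage, got NDims=", nd)
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr[["ElementSpacing"]] %||% "1 1 1", "\\s+")[[1]])
  origin <- as.numeric(strsplit((hdr[["Offset"]] %||% hdr[["Origin"]]) %||% "0 0 0",
                                "\\s+")[[1]])
  etype <- hdr[["ElementType"]]
  if (!etype %in% names(mha_types)) stop("unsupported MetaImage ElementType: ", etype)
  n <- prod(dims)
  raw <- readBin(con, what = mha_types[[etype]], n = n, size = mha_sizes[[etype]],
                 signed = !etype %in% c("MET_UCHAR", "MET_USHORT"),
                 endian = "little")
  vol3d(array(as.numeric(raw), dim = dims), spacing = spacing, origin = origin)
}

write_mha <- function(img, path) {
  is_int <- inherits(img, "labelmap") ||
    max(abs(img$data - round(img$data))) < 1e-12
  etype <- if (is_int) "MET_INT" else "MET_DOUBLE"
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False", "CompressedData = False",
           paste("DimSize =", paste(dim(img$data), collapse = " ")),
           paste("ElementSpacing =", paste(img$spacing, collapse = " ")),
           paste("Offset =", paste(img$origin, collapse = " ")),
           paste("ElementType =", etype),
           "ElementDataFile = LOCAL")
  writeLines(hdr, con)
  if (is_int) {
    writeBin(as.integer(round(img$data)), con, size = 4L, endian = "little")
  } else {
    writeBin(as.numeric(img$data), con, size = 8L, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resample a volume to isotropic spacing
#'
#' All pipeline computation happens on a common resampled grid (default 1 mm
#' isotropic, matching the finite-element scale). Intensities are linearly
#' interpolated; label maps use nearest-neighbour.
#'
#' @param img a [vol3d()] or [labelmap()].
#' @param spacing target isotropic spacing in mm.
#' @return The resampled object of the same class.
#' @export
resample_iso <- function(img, spacing = 1) {
  if (all(abs(img$spacing - spacing) < 1e-9)) return(img)
  extent <- (grid_dims(img) - 1) * img$spacing
  nd <- pmax(2L, as.integer(floor(extent / spacing)) + 1L)
  out_geom <- list(spacing = rep(spacing, 3), origin = img$origin)
  out_geom$data <- array(0, dim = nd)  # geometry stub for voxel_centers
  p <- voxel_centers(out_geom)
  interp <- if (inherits(img, "labelmap")) "nearest" else "linear"
  vals <- sample_volume(img, p, interp = interp, fill = 0)
  if (inherits(img, "labelmap")) {
    labelmap(array(as.integer(vals), dim = nd), rep(spacing, 3), img$origin,
             img$dictionary)
  } else {
    vol3d(array(vals, dim = nd), rep(spacing, 3), img$origin)
  }
}
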