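#' 3D volume with voxel spacing
#'
#' A thin container for image-like grids: a numeric or logical 3D array plus
#' the physical voxel spacing in mm per axis. All grids in avtopo use R's
#' native array order `[x, y, z]` with 1-based voxel indices; physical
#' coordinates are `(index - 1) * spacing`.
#'
#' @param data 3D array (numeric or logical).
#' @param spacing numeric length-3, mm per voxel along x, y, z.
#' @return An `av_volume`: the array with a `spacing` attribute.
#' @export
#' @examples
#' v <- av_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 1))
#' av_spacing(v)
av_volume <- function(data, spacing = c(1, 1, 1)) {
  if (length(dim(data)) != 3L) abort("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    abort("`spacing` must be 3 positive numbers (mm)")
  structure(data, spacing = spacing, class = "av_volume")
}

#' @export
print.av_volume <- function(x, ...) {
  cat(sprintf("<av_volume> %s voxels, spacing %s mm, range [%g, %g]\n",
              paste(dim(x), collapse = "x"),
              paste(signif(av_spacing(x), 4), collapse = "x"),
              suppressWarnings(min(x, na.rm = TRUE)),
              suppressWarnings(max(x, na.rm = TRUE))))
  invisible(x)
}

#' @rdname av_volume
#' @param x an `av_volume` (or plain array, for which unit spacing is assumed).
#' @export
av_spacing <- function(x) {
  sp <- attr(x, "spacing")
  if (is.null(sp)) c(1, 1, 1) else sp
}

as_array3 <- function(x) {
  a <- unclass(x)
  attr(a, "spacing") <- NULL
  a
}

#' Read and write 3D volumes
#'
#' NIfTI (`.nii`, `.nii.gz`) is handled by RNifti; uncompressed local-raw
#' MetaImage (`.mha`) is read and written directly. Round-trips preserve
#' values bit-exactly (float64 for numeric data) and spacing to well below
#' 1e-6 mm.
#'
#' @param path file path ending in `.nii`, `.nii.gz` or `.mha`.
#' @return `read_volume`: an [av_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) abort(paste0("cannot read NIfTI file ", path, ": ",
                                                     conditionMessage(e))))
    arr <- as.array(img)
    if (length(dim(arr)) != 3L) abort(paste0(path, " is not a 3D volume"))
    av_volume(arr, spacing = RNifti::pixdim(img)[1:3])
  } else if (grepl("\\.mha$", path)) {
    read_mha(path)
  } else {
    abort(paste0("unknown volume format (expected .nii/.nii.gz/.mha): ", path))
  }
}

#' @rdname read_volume
#' @param vol an [av_volume()] or 3D array.
#' @param spacing spacing override (mm); defaults to the volume's own.
#' @export
write_volume <- function(vol, path, spacing = NULL) {
  spacing <- spacing %||% av_spacing(vol)
  arr <- as_array3(vol)
  if (is.logical(arr)) arr <- array(as.integer(arr), dim(arr))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(arr, reference = NULL)
    img <- RNifti::`pixdim<-`(img, spacing)
    RNifti::writeNifti(img, path, datatype = if (is.integer(arr)) "int32" else "double")
  } else if (grepl("\\.mha$", path)) {
    write_mha(arr, spacing, path)
  } else {
    abort(paste0("unknown volume format (expected .nii/.nii.gz/.mha): ", path))
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mha_types <- c(MET_UCHAR = "integer", MET_SHORT = "integer", MET_INT = "integer",
               MET_FLOAT = "double", MET_DOUBLE = "double")
mha_sizes <- c(MET_UCHAR = 1L, MET_SHORT = 2L, MET_INT = 4L,
               MET_FLOAT = 4L, MET_DOUBLE = 8L)

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) abort(paste0("corrupt MetaImage header in ", path))
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) abort(paste0("corrupt MetaImage header in ", path))
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementDataFile"]], "LOCAL"))
    abort("only LOCAL-raw MetaImage files are supported")
  dm <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  sp <- as.numeric(strsplit(hdr[["ElementSpacing"]] %||% "1 1 1", "\\s+")[[1]])
  et <- hdr[["ElementType"]]
  if (is.null(et) || !et %in% names(mha_types))
    abort(paste0("unsupported MetaImage ElementType in ", path))
  n <- prod(dm)
  what <- mha_types[[et]]
  raw <- readBin(con, what = what, n = n, size = mha_sizes[[et]],
                 endian = "little", signed = !identical(et, "MET_UCHAR"))
  if (length(raw) != n) abort(paste0("truncated MetaImage data in ", path))
  av_volume(array(raw, dm), spacing = sp)
}

write_mha <- function(arr, spacing, path) {
  et <- if (is.integer(arr)) "MET_INT" else "MET_DOUBLE"
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(dim(arr), collapse = " ")),
           paste("ElementSpacing =", paste(format(spacing, digits = 17), collapse = " ")),
           paste("ElementType =", et),
           "ElementDataFile = LOCAL")
  writeLines(hdr, con)
  writeBin(as.vector(arr), con, size = mha_sizes[[et]], endian = "little")
  invisible(path)
}

# voxel (1-based index, possibly fractional) <-> physical mm
vox_to_mm <- function(v, spacing) sweep(v - 1, 2, spacing, `*`)
mm_to_vox <- function(p, spacing) sweep(p, 2, spacing, `/`) + 1
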