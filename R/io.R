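# File I/O: MetaImage (.mha single-file, .mhd + .raw), NIfTI-1 (.nii,
# .nii.gz), plain-text point lists, and a JSON transform
# container. No R reader for these volume formats is available in the
# supported dependency set, so the two formats are implemented here
# directly: identity direction matrices only, little-endian data.
#
# MetaImage stores geometry as decimal text (printed with 17 significant
# digits), so spacing and origin round-trip bit-exactly. NIfTI-1 stores
# geometry in single-precision floats, a limitation of the format itself.

.MET_TYPES <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_UINT   = list(what = "integer", size = 4L, signed = TRUE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "double",  size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "double",  size = 8L, signed = TRUE))

.fmt17 <- function(x) sprintf("%.17g", x)

# ---------------------------------------------------------------- MetaImage

#' Write a volume or mask as MetaImage
#'
#' `.mha` stores header and raw data in one file; `.mhd` writes a sidecar
#' `.raw` next to it. Masks are stored as `MET_UCHAR`, volumes as
#' `MET_DOUBLE` (bit-exact round-trip).
#'
#' @param v an `mmdir_volume` or `mmdir_mask`.
#' @param path output path ending in `.mha` or `.mhd`.
#' @return `path`, invisibly.
#' @export
write_metaimage <- function(v, path) {
  is_mask <- inherits(v, "mmdir_mask")
  d <- dim(v$data)
  etype <- if (is_mask) "MET_UCHAR" else "MET_DOUBLE"
  local <- grepl("\\.mha$", path, ignore.case = TRUE)
  if (!local && !grepl("\\.mhd$", path, ignore.case = TRUE))
    stop("MetaImage path must end in .mha or .mhd")
  datafile <- if (local) "LOCAL" else
    paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(.fmt17(v$origin), collapse = " ")),
    "CenterOfRotation = 0 0 0",
    "AnatomicalOrientation = RAI",
    paste("ElementSpacing =", paste(.fmt17(v$spacing), collapse = " ")),
    paste("DimSize =", paste(d, collapse = " ")),
    paste("ElementType =", etype),
    paste("ElementDataFile =", datafile))
  payload <- if (is_mask) as.integer(v$data) else as.double(v$data)
  wsize <- .MET_TYPES[[etype]]$size
  if (local) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
    writeBin(payload, con, size = wsize, endian = "little")
  } else {
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(con))
    writeBin(payload, con, size = wsize, endian = "little")
  }
  invisible(path)
}

#' Read a MetaImage volume
#'
#' @param path `.mha` or `.mhd` file.
#' @param as_mask return an `mmdir_mask` (values must be 0/1).
#' @return An `mmdir_volume` or `mmdir_mask`.
#' @export
read_metaimage <- function(path, as_mask = FALSE) {
  raw <- readBin(path, "raw", n = file.size(path))
  # header = lines up to and including the ElementDataFile line
  nl <- which(raw == as.raw(10L))
  hdr_end <- NA_integer_
  last <- 0L
  fields <- list()
  for (pos in nl) {
    line <- rawToChar(raw[(last + 1L):(pos - 1L)])
    last <- pos
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*?)\\s*$",
                                   line))[[1]]
    if (length(kv) == 3L) fields[[kv[2]]] <- kv[3]
    if (length(kv) == 3L && kv[2] == "ElementDataFile") {
      hdr_end <- pos
      break
    }
  }
  if (is.na(hdr_end)) stop("not a MetaImage file: ", path)
  need <- function(k) {
    if (is.null(fields[[k]])) stop("MetaImage header missing ", k)
    fields[[k]]
  }
  if (!is.null(fields$CompressedData) &&
      tolower(fields$CompressedData) == "true")
    stop("compressed MetaImage not supported")
  if (!is.null(fields$BinaryDataByteOrderMSB) &&
      tolower(fields$BinaryDataByteOrderMSB) == "true")
    stop("big-endian MetaImage not supported")
  tm <- fields$TransformMatrix
  if (!is.null(tm)) {
    m <- as.double(strsplit(trimws(tm), "\\s+")[[1]])
    if (!isTRUE(all.equal(m, c(1, 0, 0, 0, 1, 0, 0, 0, 1))))
      stop("oblique MetaImage direction matrices not supported")
  }
  d <- as.integer(strsplit(need("DimSize"), "\\s+")[[1]])
  if (length(d) != 3L) stop("only 3D MetaImage supported")
  spacing <- as.double(strsplit(need("ElementSpacing"), "\\s+")[[1]])
  origin <- if (is.null(fields$Offset)) c(0, 0, 0) else
    as.double(strsplit(fields$Offset, "\\s+")[[1]])
  etype <- need("ElementType")
  ti <- .MET_TYPES[[etype]]
  if (is.null(ti)) stop("unsupported MetaImage ElementType ", etype)
  datafile <- need("ElementDataFile")
  n <- prod(d)
  if (identical(datafile, "LOCAL")) {
    data_raw <- raw[(hdr_end + 1L):length(raw)]
    vals <- readBin(data_raw, ti$what, n = n, size = ti$size,
                    signed = ti$signed, endian = "little")
  } else {
    rp <- file.path(dirname(path), datafile)
    vals <- readBin(rp, ti$what, n = n, size = ti$size,
                    signed = ti$signed, endian = "little")
  }
  if (length(vals) < n) stop("MetaImage data truncated")
  arr <- array(as.double(vals), d)
  if (as_mask) label_mask(arr != 0, spacing = spacing, origin = origin)
  else volume(arr, spacing = spacing, origin = origin)
}

# ------------------------------------------------------------------- NIfTI

.nifti_dtypes <- list(`2`  = list(what = "integer", size = 1L, signed = FALSE),
                      `4`  = list(what = "integer", size = 2L, signed = TRUE),
                      `8`  = list(what = "integer", size = 4L, signed = TRUE),
                      `16` = list(what = "double",  size = 4L, signed = TRUE),
                      `64` = list(what = "double",  size = 8L, signed = TRUE))

#' Write a volume or mask as NIfTI-1
#'
#' Identity direction; geometry goes into the sform (code 1) and `pixdim`.
#' Masks are written as `uint8`, volumes as `float64`. Note NIfTI-1 stores
#' spacing/origin as single-precision floats.
#'
#' @param v an `mmdir_volume` or `mmdir_mask`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(v, path) {
  is_mask <- inherits(v, "mmdir_mask")
  d <- dim(v$data)
  datatype <- if (is_mask) 2L else 64L
  bitpix <- if (is_mask) 8L else 64L
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wpad <- function(n) writeBin(raw(n), con)
  wi(348L, 4L)                       # sizeof_hdr
  wpad(10L + 18L)                    # data_type, db_name
  wi(0L, 4L); wi(0L, 2L)             # extents, session_error
  writeBin(charToRaw("r"), con); wpad(1L)  # regular, dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2L)   # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2L)         # intent_p1-3, intent_code
  wi(datatype, 2L); wi(bitpix, 2L); wi(0L, 2L)  # datatype,bitpix,slice_start
  wf(c(1, v$spacing, 0, 0, 0, 0))    # pixdim[8], qfac = 1
  wf(352); wf(1); wf(0)              # vox_offset, scl_slope, scl_inter
  wi(0L, 2L); wpad(1L)               # slice_end, slice_code
  writeBin(as.raw(2L), con)          # xyzt_units = mm
  wf(c(0, 0, 0, 0))                  # cal_max, cal_min, slice_dur, toffset
  wi(c(0L, 0L), 4L)                  # glmax, glmin
  wpad(80L + 24L)                    # descrip, aux_file
  wi(0L, 2L); wi(1L, 2L)             # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0)); wf(v$origin)       # quatern_b/c/d, qoffset
  wf(c(v$spacing[1], 0, 0, v$origin[1]))
  wf(c(0, v$spacing[2], 0, v$origin[2]))
  wf(c(0, 0, v$spacing[3], v$origin[3]))
  wpad(16L)                          # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  wpad(4L)                           # extension flag
  payload <- if (is_mask) as.integer(v$data) else as.double(v$data)
  writeBin(payload, con, size = bitpix %/% 8L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Supports uncompressed `.nii` and gzipped `.nii.gz`, little-endian,
#' axis-aligned geometry (diagonal sform / unit quaternion only).
#'
#' @param path input file.
#' @param as_mask return an `mmdir_mask` (values must be 0/1).
#' @return An `mmdir_volume` or `mmdir_mask`.
#' @export
read_nifti <- function(path, as_mask = FALSE) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header")
  ri <- function(off, size, n = 1L, signed = TRUE)
    readBin(hdr[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            signed = signed, endian = "little")
  rf <- function(off, n = 1L)
    readBin(hdr[(off + 1L):(off + 4L * n)], "double", n = n, size = 4L,
            endian = "little")
  if (ri(0L, 4L) != 348L) stop("unsupported NIfTI (not little-endian?)")
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file")
  dims <- ri(40L, 2L, n = 8L)
  if (dims[1] != 3L && !(dims[1] > 3L && all(dims[5:(dims[1] + 1)] == 1L)))
    stop("only 3D NIfTI volumes supported")
  d <- dims[2:4]
  datatype <- ri(70L, 2L)
  ti <- .nifti_dtypes[[as.character(datatype)]]
  if (is.null(ti)) stop("unsupported NIfTI datatype ", datatype)
  pixdim <- rf(76L, n = 8L)
  vox_offset <- rf(108L)
  scl_slope <- rf(112L); scl_inter <- rf(116L)
  sform_code <- ri(254L, 2L)
  spacing <- abs(pixdim[2:4])
  origin <- c(0, 0, 0)
  if (sform_code > 0L) {
    srow <- rbind(rf(280L, 4L), rf(296L, 4L), rf(312L, 4L))
    offdiag <- srow[1:3, 1:3]; diag(offdiag) <- 0
    if (any(abs(offdiag) > 1e-6 * max(abs(srow[1:3, 1:3]))))
      stop("oblique NIfTI orientation not supported")
    if (any(diag(srow[1:3, 1:3]) <= 0))
      stop("axis-flipping NIfTI orientation not supported")
    spacing <- diag(srow[1:3, 1:3])
    origin <- srow[, 4]
  } else {
    qform_code <- ri(252L, 2L)
    if (qform_code > 0L) {
      q <- rf(256L, 3L)
      if (any(abs(q) > 1e-6))
        stop("rotated NIfTI qform not supported")
      origin <- rf(268L, 3L)
    }
  }
  if (magic == "ni1") stop("detached .hdr/.img NIfTI pairs not supported")
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n <- prod(d)
  vals <- readBin(con, ti$what, n = n, size = ti$size, signed = ti$signed,
                  endian = "little")
  if (length(vals) < n) stop("NIfTI data truncated")
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  if (any(!is.finite(vals))) stop("NIfTI volume contains non-finite values")
  arr <- array(vals, d)
  if (as_mask) label_mask(arr != 0, spacing = spacing, origin = origin)
  else volume(arr, spacing = spacing, origin = origin)
}

#' Read a volume by extension
#' @param path `.mha`, `.mhd`, `.nii` or `.nii.gz` file.
#' @param as_mask return an `mmdir_mask`.
#' @return An `mmdir_volume` or `mmdir_mask`.
#' @export
read_volume <- function(path, as_mask = FALSE) {
  if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE))
    read_metaimage(path, as_mask = as_mask)
  else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
    read_nifti(path, as_mask = as_mask)
  else stop("unrecognized volume extension: ", basename(path))
}

#' Write a volume by extension
#' @param v an `mmdir_volume` or `mmdir_mask`.
#' @param path output path (`.mha`, `.mhd`, `.nii`, `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE))
    write_metaimage(v, path)
  else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
    write_nifti(v, path)
  else stop("unrecognized volume extension: ", basename(path))
}

# -------------------------------------------------------------- point sets

#' Write a plain-text point list
#'
#' Format: line 1 `point`, line 2 the integer count, then one `x y z` world
#' coordinate (mm) per line. One file per image side; pairing is by line
#' order.
#'
#' @param pts N x 3 matrix of world points (mm).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_point_set <- function(pts, path) {
  pts <- .as_points(pts)
  lines <- c("point", nrow(pts),
             apply(pts, 1, function(r) paste(.fmt17(r), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text point list
#' @param path file written by [write_point_set()].
#' @return N x 3 matrix of world points (mm).
#' @export
read_point_set <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L || tolower(lines[1]) != "point")
    stop("not a point-set file: ", path)
  n <- as.integer(lines[2])
  if (is.na(n) || n < 1L || length(lines) < 2L + n)
    stop("corrupt point-set file: ", path)
  vals <- lapply(lines[3:(2L + n)],
                 function(l) as.double(strsplit(l, "[ ,\t]+")[[1]]))
  if (any(vapply(vals, length, 1L) != 3L) || anyNA(unlist(vals)))
    stop("corrupt point-set file: ", path)
  do.call(rbind, vals)
}

# -------------------------------------------------------------- transforms

# Numeric fields are serialized as 17-significant-digit strings so the JSON
# round-trip is bit-exact (jsonlite prints at most 15 digits for numbers).
.transform_to_list <- function(t) {
  if (inherits(t, "mmdir_affine"))
    list(kind = "affine", matrix = .fmt17(as.double(t$matrix)),
         translation = .fmt17(t$translation))
  else if (inherits(t, "mmdir_bspline"))
    list(kind = "bspline", grid_origin = .fmt17(t$grid_origin),
         grid_spacing = .fmt17(t$grid_spacing), grid_dim = t$grid_dim,
         coefficients = .fmt17(as.double(t$coefficients)))
  else if (inherits(t, "mmdir_composite"))
    list(kind = "composite",
         affine = if (is.null(t$affine)) NULL else
           .transform_to_list(t$affine),
         bspline = if (is.null(t$bspline)) NULL else
           .transform_to_list(t$bspline))
  else stop("not a transform")
}

.transform_from_list <- function(x) {
  switch(x$kind,
    affine = affine_transform(matrix(as.double(x$matrix), 3, 3),
                              as.double(x$translation)),
    bspline = bspline_transform(as.double(x$grid_origin),
                                as.double(x$grid_spacing),
                                as.integer(x$grid_dim),
                                array(as.double(x$coefficients),
                                      c(as.integer(x$grid_dim), 3L))),
    composite = composite_transform(
      affine = if (is.null(x$affine)) NULL else
        .transform_from_list(x$affine),
      bspline = if (is.null(x$bspline)) NULL else
        .transform_from_list(x$bspline)),
    stop("unknown transform kind: ", x$kind))
}

#' Serialize a transform to a self-describing JSON file
#'
#' Full-precision (bit-exact) round-trip.
#'
#' @param t a transform.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(t, path) {
  jsonlite::write_json(.transform_to_list(t), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a transform written by [write_transform()]
#' @param path `.json` file.
#' @return The transform object.
#' @export
read_transform <- function(path) {
  .transform_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}
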