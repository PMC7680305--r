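#' Read a 3D volume from NIfTI or NRRD
#'
#' Format is chosen by extension: `.nii` / `.nii.gz` are read with RNifti,
#' `.nrrd` with the package's own minimal NRRD reader (NRRD0004, `raw` or
#' `gzip` encoding, little-endian). Spacing is taken from the stored affine
#' (column norms) for NIfTI and from `space directions` for NRRD; the origin
#' is the affine translation / `space origin`.
#'
#' @param path file path.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "lnrad_io_error")
  }
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    read_nrrd(path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    read_nifti_volume(path)
  } else {
    rlang::abort(paste0("unknown volume format: ", path), class = "lnrad_io_error")
  }
}

#' Write a 3D volume to NIfTI or NRRD
#'
#' @param volume a [ct_volume()] or [ct_mask()] (masks are written as 0/1).
#' @param path output path ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  vox <- if (inherits(volume, "ct_mask")) {
    array(as.numeric(volume$voxels), dim(volume$voxels))
  } else {
    volume$voxels
  }
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    write_nrrd(vox, volume$spacing, volume$origin, path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    aff <- diag(c(volume$spacing, 1))
    aff[1:3, 4] <- volume$origin
    img <- RNifti::asNifti(vox, datatype = "double")
    img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
    RNifti::writeNifti(img, path)
  } else {
    rlang::abort(paste0("unknown volume format: ", path), class = "lnrad_io_error")
  }
  invisible(path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  ct_mask(v$voxels != 0, v$spacing, v$origin)
}

#' @rdname write_volume
#' @param mask a [ct_mask()].
#' @export
write_mask <- function(mask, path) write_volume(mask, path)

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path, internal = FALSE)
  aff <- RNifti::xform(img)
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  origin <- aff[1:3, 4]
  if (any(spacing <= 0)) {
    rlang::abort("non-positive voxel spacing in NIfTI header.",
                 class = "lnrad_io_error")
  }
  vox <- array(as.numeric(img), dim(img)[1:3])
  ct_volume(vox, spacing, origin)
}

# --- minimal NRRD0004 support ------------------------------------------------

nrrd_types <- list(
  "double" = list(what = "double", size = 8),
  "float"  = list(what = "double", size = 4),
  "int"    = list(what = "integer", size = 4),
  "short"  = list(what = "integer", size = 2),
  "uchar"  = list(what = "integer", size = 1)
)

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic)) {
    rlang::abort("not an NRRD file.", class = "lnrad_io_error")
  }
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0 || line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):\\s*(.*)$", line))[[1]]
    if (length(kv) == 3) fields[[trimws(kv[2])]] <- trimws(kv[3])
  }
  type <- fields[["type"]]
  if (is.null(type) || is.null(nrrd_types[[type]])) {
    rlang::abort(paste0("unsupported NRRD type: ", type %||% "<missing>"),
                 class = "lnrad_io_error")
  }
  if (!identical(fields[["dimension"]], "3")) {
    rlang::abort("only 3-dimensional NRRD volumes are supported.",
                 class = "lnrad_io_error")
  }
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  spacing <- nrrd_parse_directions(fields)
  origin <- if (!is.null(fields[["space origin"]])) {
    nrrd_parse_vector(fields[["space origin"]])
  } else c(0, 0, 0)
  if (any(spacing <= 0)) {
    rlang::abort("non-positive voxel spacing in NRRD header.",
                 class = "lnrad_io_error")
  }
  enc <- fields[["encoding"]] %||% "raw"
  spec <- nrrd_types[[type]]
  n <- prod(sizes)
  if (enc == "raw") {
    data <- readBin(con, spec$what, n = n, size = spec$size, endian = "little")
  } else if (enc %in% c("gzip", "gz")) {
    payload <- readBin(con, "raw", n = file.size(path))
    data <- readBin(memDecompress(payload, type = "gzip"), spec$what,
                    n = n, size = spec$size, endian = "little")
  } else {
    rlang::abort(paste0("unsupported NRRD encoding: ", enc),
                 class = "lnrad_io_error")
  }
  # NRRD stores the fastest-varying axis first, matching R's column-major order
  ct_volume(array(as.numeric(data), sizes), spacing, origin)
}

nrrd_parse_vector <- function(s) {
  as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
}

nrrd_parse_directions <- function(fields) {
  sd <- fields[["space directions"]]
  if (!is.null(sd)) {
    vecs <- regmatches(sd, gregexpr("\\(([^)]*)\\)", sd))[[1]]
    m <- vapply(vecs, function(v) nrrd_parse_vector(v), numeric(3))
    return(sqrt(colSums(m^2)))
  }
  sp <- fields[["spacings"]]
  if (!is.null(sp)) return(as.numeric(strsplit(sp, "\\s+")[[1]]))
  rlang::abort("NRRD header lacks spacing information.", class = "lnrad_io_error")
}

write_nrrd <- function(vox, spacing, origin, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    "# generated by lnrad",
    "type: double",
    "dimension: 3",
    paste("sizes:", paste(dim(vox), collapse = " ")),
    "space: left-posterior-superior",
    sprintf("space directions: (%g,0,0) (0,%g,0) (0,0,%g)",
            spacing[1], spacing[2], spacing[3]),
    sprintf("space origin: (%g,%g,%g)", origin[1], origin[2], origin[3]),
    "encoding: raw",
    "endian: little",
    ""
  )
  writeLines(hdr, con, sep = "\n")
  writeBin(as.numeric(vox), con, size = 8, endian = "little")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
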