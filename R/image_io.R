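#' Read a volumetric image
#'
#' Reads a 3D grayscale volume from one of the supported on-disk formats into
#' a [volume3d()]. Slices are stacked along the first (z) axis; a directory of
#' slices is ordered by lexicographic file name.
#'
#' @param path file path (or directory for `png_dir`).
#' @param format one of `"tiff_stack"`, `"nifti"`, `"png_dir"`, `"raw"`.
#'   Default `"auto"` guesses from the file extension (directory implies
#'   `png_dir`).
#' @param spacing voxel spacing override; if `NULL`, metadata is used when the
#'   format carries it (NIfTI), otherwise 1 mm isotropic.
#' @param shape,dtype for `format = "raw"` only: grid shape `(nz, ny, nx)` and
#'   element type (`"uint8"`, `"uint16"`, `"float32"`, `"float64"`).
#' @return A [volume3d()].
#' @export
read_volume <- function(path, format = c("auto", "tiff_stack", "nifti",
                                         "png_dir", "raw"),
                        spacing = NULL, shape = NULL, dtype = "float32") {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("file not found: ", path)
  out <- switch(format,
    tiff_stack = read_tiff_stack(path),
    nifti      = read_nifti_volume(path),
    png_dir    = read_png_dir(path),
    raw        = read_raw_volume(path, shape, dtype),
    stop("unsupported format: ", format))
  if (!is.null(spacing)) out$spacing <- as.numeric(spacing)
  out
}

guess_format <- function(path) {
  if (dir.exists(path)) return("png_dir")
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  switch(ext,
    tif = , tiff = "tiff_stack",
    nii = "nifti",
    raw = "raw",
    stop("cannot guess format from extension: ", path))
}

read_tiff_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  pages <- lapply(pages, collapse_channels)
  shp <- vapply(pages, dim, integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
    stop("inconsistent slice shapes in TIFF stack")
  volume3d(stack_slices(pages))
}

read_png_dir <- function(path) {
  files <- sort(list.files(path, pattern = "\\.(png|bmp)$", ignore.case = TRUE,
                           full.names = TRUE))
  if (!length(files)) stop("no PNG/BMP slices found in ", path)
  pages <- lapply(files, function(f) collapse_channels(png::readPNG(f)))
  shp <- vapply(pages, dim, integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
    stop("inconsistent slice shapes in slice directory")
  volume3d(stack_slices(pages))
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 3L) stop("NIfTI image is not 3D")
  pd <- RNifti::pixdim(img)
  # NIfTI stores (x, y, z); reorder to the package's (z, y, x) convention
  volume3d(aperm(a, c(3, 2, 1)), spacing = rev(pd[1:3]))
}

read_raw_volume <- function(path, shape, dtype) {
  if (is.null(shape) || length(shape) != 3L)
    stop("`shape` (nz, ny, nx) is required for raw volumes")
  shape <- as.integer(shape)
  n <- prod(shape)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- switch(dtype,
    uint8   = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    uint16  = as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
                                 endian = "little")),
    float32 = readBin(con, "numeric", n, size = 4, endian = "little"),
    float64 = readBin(con, "numeric", n, size = 8, endian = "little"),
    stop("unsupported dtype: ", dtype))
  if (length(vals) != n) stop("raw file shorter than `shape` implies")
  # file is slice-major: x fastest, then y, then z
  volume3d(aperm(array(vals, dim = rev(shape)), c(3, 2, 1)))
}

collapse_channels <- function(m) {
  if (length(dim(m)) == 3L) m <- apply(m[, , 1:min(3, dim(m)[3]), drop = FALSE],
                                       c(1, 2), mean)
  m
}

stack_slices <- function(pages) {
  a <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) a[i, , ] <- pages[[i]]
  a
}

#' Write a volumetric image
#'
#' Writes a [volume3d()] to disk. TIFF stacks are written as 32-bit float
#' pages, PNG directories as 8/16-bit gray (values must lie in `[0, 1]`),
#' NIfTI as float with the volume's spacing, raw as little-endian float32.
#'
#' @param vol a [volume3d()].
#' @param path output file (or directory for `png_dir`, created if needed).
#' @param format as in [read_volume()] (no `"auto"`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path,
                         format = c("tiff_stack", "nifti", "png_dir", "raw")) {
  format <- match.arg(format)
  vol <- as_volume3d(vol)
  d <- dim(vol$data)
  switch(format,
    tiff_stack = {
      pages <- lapply(seq_len(d[1]), function(z) vol$data[z, , ])
      tiff::writeTIFF(pages, path, bits.per.sample = 32)
    },
    png_dir = {
      if (any(vol$data < 0 | vol$data > 1))
        stop("PNG export requires intensities in [0, 1]")
      if (!dir.exists(path)) dir.create(path, recursive = TRUE)
      for (z in seq_len(d[1]))
        png::writePNG(vol$data[z, , ],
                      file.path(path, sprintf("slice_%04d.png", z - 1L)))
    },
    nifti = {
      img <- RNifti::asNifti(aperm(vol$data, c(3, 2, 1)))
      RNifti::pixdim(img) <- rev(vol$spacing)
      RNifti::writeNifti(img, path)
    },
    raw = {
      con <- file(path, "wb")
      on.exit(close(con))
      writeBin(as.numeric(aperm(vol$data, c(3, 2, 1))), con, size = 4,
               endian = "little")
    })
  invisible(path)
}

#' Rescale intensities linearly to [0, 1]
#'
#' Linear min-max normalization: the smallest intensity maps to 0 and the
#' largest to 1. A constant volume maps to all zeros. The operation is
#' idempotent.
#'
#' @param vol a [volume3d()] (or 3D array).
#' @return A [volume3d()] with intensities in `[0, 1]`.
#' @export
normalize_intensity <- function(vol) {
  vol <- as_volume3d(vol)
  rng <- range(vol$data)
  vol$data <- if (rng[2] > rng[1]) (vol$data - rng[1]) / (rng[2] - rng[1])
              else array(0, dim = dim(vol$data))
  vol
}

#' Write a label volume as an 8-bit gray image stack
#'
#' Each label is exported at its `display_gray` value. The written stack
#' round-trips: [read_labels()] with the same label map recovers the integer
#' grid exactly.
#'
#' @param lab a [label_volume()].
#' @param path output path (file for `tiff_stack`, directory for `png_dir`).
#' @param format `"tiff_stack"` or `"png_dir"`.
#' @return `path`, invisibly.
#' @export
write_labels <- function(lab, path, format = c("tiff_stack", "png_dir")) {
  format <- match.arg(format)
  if (!inherits(lab, "label_volume")) stop("`lab` must be a label_volume")
  gray <- lab$display_gray[match(lab$data, lab$label_map)]
  if (anyNA(gray)) stop("label volume contains unmapped values")
  vol <- volume3d(array(gray / 255, dim = dim(lab$data)),
                  spacing = lab$spacing, origin = lab$origin)
  if (format == "tiff_stack") {
    pages <- lapply(seq_len(dim(vol$data)[1]), function(z) vol$data[z, , ])
    tiff::writeTIFF(pages, path, bits.per.sample = 8)
  } else {
    write_volume(vol, path, "png_dir")
  }
  invisible(path)
}

#' Read an 8-bit label stack back into a label volume
#'
#' Inverse of [write_labels()]: gray values are matched (to the nearest 1/255)
#' against `display_gray` and mapped back to integer classes.
#'
#' @param path file or directory written by [write_labels()].
#' @param format as in [write_labels()].
#' @inheritParams label_volume
#' @return A [label_volume()].
#' @export
read_labels <- function(path, format = c("tiff_stack", "png_dir"),
                        label_map = c(background = 0L, pulp = 1L,
                                      dentine = 2L, enamel = 3L),
                        display_gray = c(0L, 96L, 160L, 255L)) {
  format <- match.arg(format)
  vol <- read_volume(path, if (format == "tiff_stack") "tiff_stack" else "png_dir")
  gray <- as.integer(round(vol$data * 255))
  idx <- match(gray, as.integer(display_gray))
  if (anyNA(idx))
    stop("stack contains gray values not present in `display_gray`")
  label_volume(array(unname(label_map)[idx], dim = dim(vol$data)),
               label_map = label_map, display_gray = display_gray,
               spacing = vol$spacing, origin = vol$origin)
}

#' Load or save a run configuration
#'
#' Configurations are plain named lists serialized as YAML (or JSON). Unknown
#' top-level keys are rejected so that typos fail loudly.
#'
#' @param path YAML or JSON file.
#' @param allowed character vector of permitted top-level keys; `NULL` skips
#'   validation.
#' @return Named list.
#' @export
read_config <- function(path, allowed = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (tolower(tools::file_ext(path)) == "json")
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.null(allowed)) {
    bad <- setdiff(names(cfg), allowed)
    if (length(bad))
      stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  cfg
}

#' @rdname read_config
#' @param cfg named list to save.
#' @export
write_config <- function(cfg, path) {
  if (tolower(tools::file_ext(path)) == "json")
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  else yaml::write_yaml(cfg, path)
  invisible(path)
}
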