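#' 3D scalar volume with voxel geometry
#'
#' A `volume3d` is the basic container of the package: a 3D numeric array in
#' `(z, y, x)` order (slice index first) together with the voxel spacing in mm
#' and the voxel offset of the array within its parent volume (used when a
#' region of interest is cropped out and later pasted back).
#'
#' @param data 3D numeric array, indexed `[z, y, x]`. A matrix is promoted to a
#'   single-slice volume of shape `(1, nrow, ncol)`.
#' @param spacing numeric length-3, voxel size `(dz, dy, dx)` in mm; all
#'   components must be positive. Default `c(1, 1, 1)` mm, the acquisition
#'   geometry assumed when file metadata is absent.
#' @param origin integer length-3, 0-based voxel offset `(z0, y0, x0)` of this
#'   array within its parent volume. Default `c(0, 0, 0)`.
#' @return An object of class `volume3d`.
#' @examples
#' v <- volume3d(array(runif(8 * 8 * 8), dim = c(8, 8, 8)))
#' dim(v)
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.matrix(data)) data <- array(data, dim = c(1L, nrow(data), ncol(data)))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (z, y, x)")
  if (!all(is.finite(data))) stop("volume contains non-finite values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive values (dz, dy, dx) in mm")
  origin <- as.integer(origin)
  if (length(origin) != 3L) stop("`origin` must have length 3")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume3d")
}

#' Coerce to a volume3d
#'
#' @param x a `volume3d` (returned unchanged) or a 3D array.
#' @param ... passed to [volume3d()] when `x` is an array.
#' @return A `volume3d`.
#' @export
as_volume3d <- function(x, ...) {
  if (inherits(x, "volume3d")) return(x)
  volume3d(x, ...)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels (z, y, x)\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing: %.3g x %.3g x %.3g mm, origin: (%d, %d, %d)\n",
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Integer label volume for tooth tissue classes
#'
#' Stores one integer class per voxel. The default label map follows the
#' anatomical convention used throughout the package: 0 background, 1 pulp,
#' 2 dentine, 3 enamel. `display_gray` gives the 8-bit gray value used when a
#' label map is exported as an image stack (background black, pulp dark grey,
#' dentine grey, enamel white).
#'
#' @param data 3D integer array `[z, y, x]`; every value must be a key of
#'   `label_map`.
#' @param label_map named integer vector mapping class names to codes.
#' @param display_gray integer vector of 8-bit gray values, one per label, in
#'   the order of `label_map`.
#' @param spacing,origin voxel geometry, as in [volume3d()].
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data,
                         label_map = c(background = 0L, pulp = 1L,
                                       dentine = 2L, enamel = 3L),
                         display_gray = c(0L, 96L, 160L, 255L),
                         spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (z, y, x)")
  storage.mode(data) <- "integer"
  label_map <- as.integer(label_map) |> stats::setNames(names(label_map))
  if (is.null(names(label_map)) || any(!nzchar(names(label_map))))
    stop("`label_map` must be a named integer vector")
  bad <- setdiff(unique(as.vector(data)), unname(label_map))
  if (length(bad))
    stop("unmapped label value(s) present: ", paste(bad, collapse = ", "))
  if (length(display_gray) != length(label_map))
    stop("`display_gray` must have one entry per label")
  display_gray <- as.integer(display_gray)
  if (any(display_gray < 0L | display_gray > 255L))
    stop("`display_gray` values must be 8-bit (0..255)")
  if (anyDuplicated(display_gray))
    stop("`display_gray` values must be distinct")
  structure(list(data = data, label_map = label_map,
                 display_gray = display_gray,
                 spacing = as.numeric(spacing), origin = as.integer(origin)),
            class = "label_volume")
}

#' @export
dim.label_volume <- function(x) dim(x$data)

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<label_volume> %d x %d x %d voxels (z, y, x)\n",
              d[1], d[2], d[3]))
  tab <- table(factor(x$data, levels = unname(x$label_map),
                      labels = names(x$label_map)))
  for (nm in names(tab))
    cat(sprintf("  %-10s %d voxels\n", nm, tab[[nm]]))
  invisible(x)
}

# internal: fetch the integer code of a label given by name or code
label_code <- function(lab, label) {
  if (is.character(label)) {
    if (!label %in% names(lab$label_map))
      stop("unknown label name: ", label)
    return(unname(lab$label_map[[label]]))
  }
  label <- as.integer(label)
  if (!label %in% lab$label_map) stop("unknown label code: ", label)
  label
}
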