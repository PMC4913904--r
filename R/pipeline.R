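#' Pipeline configuration
#'
#' Bundles all stage parameters of the end-to-end framework: ROI crop around a
#' seed point, 3D GFRLS tooth segmentation, morphological cleanup, grayscale
#' masking, enamel thresholding, and PCNN classification of the tooth
#' interior.
#'
#' @param seed_point `(z, y, x)` voxel (0-based) inside the tooth.
#' @param block_radius half-extent of the cubic ROI, voxels per axis.
#' @param gfrls a [gfrls_params()].
#' @param erosion_iters binary-erosion iterations used for mask cleanup (0
#'   disables cleanup).
#' @param erosion_se structuring element, `"cross"` (6-neighborhood) or
#'   `"box"` (26-neighborhood).
#' @param reconstruct if `TRUE` (default), the eroded mask is used as a marker
#'   for morphological reconstruction inside the original mask, so cleanup
#'   removes small noise components without thinning the tooth surface (an
#'   opening by reconstruction). `FALSE` keeps the plain eroded mask.
#' @param largest_component keep only the largest 26-connected component of
#'   the cleaned mask (bracket/noise safeguard).
#' @param enamel_threshold intensity threshold in `(0, 1)`, or `"auto"` for a
#'   maximal between-class-variance (Otsu) split of the nonzero tooth
#'   intensities.
#' @param pcnn a [pcnn_params()]; the default uses `k = 2` (dentine vs pulp
#'   inside the non-enamel tooth).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed_point, block_radius = 48L,
                            gfrls = gfrls_params(),
                            erosion_iters = 1L,
                            erosion_se = c("cross", "box"),
                            reconstruct = TRUE,
                            largest_component = TRUE,
                            enamel_threshold = "auto",
                            pcnn = pcnn_params(k = 2L)) {
  erosion_se <- match.arg(erosion_se)
  stopifnot(length(seed_point) == 3L, block_radius >= 1, erosion_iters >= 0)
  if (!identical(enamel_threshold, "auto")) {
    stopifnot(is.numeric(enamel_threshold), enamel_threshold > 0,
              enamel_threshold < 1)
  }
  structure(list(seed_point = as.integer(seed_point),
                 block_radius = as.integer(block_radius), gfrls = gfrls,
                 erosion_iters = as.integer(erosion_iters),
                 erosion_se = erosion_se, reconstruct = reconstruct,
                 largest_component = largest_component,
                 enamel_threshold = enamel_threshold, pcnn = pcnn),
            class = "pipeline_config")
}

#' Extract a cubic region of interest around a seed point
#'
#' Crops a block of half-extent `block_radius` centered on the seed, clipped
#' to the volume bounds; the crop's origin is recorded so results can be
#' pasted back into full-volume coordinates.
#'
#' @param vol a [volume3d()].
#' @param seed_point `(z, y, x)` voxel, 0-based, inside the volume.
#' @param block_radius voxels per axis.
#' @return A [volume3d()] crop.
#' @export
extract_roi <- function(vol, seed_point, block_radius) {
  vol <- as_volume3d(vol)
  d <- dim(vol$data)
  seed <- as.integer(seed_point)
  if (any(seed < 0L) || any(seed >= d)) stop("seed point outside the volume")
  lo <- pmax(seed - block_radius, 0L)
  hi <- pmin(seed + block_radius, d - 1L)
  volume3d(vol$data[(lo[1] + 1L):(hi[1] + 1L),
                    (lo[2] + 1L):(hi[2] + 1L),
                    (lo[3] + 1L):(hi[3] + 1L), drop = FALSE],
           spacing = vol$spacing, origin = vol$origin + lo)
}

#' Binary mask erosion
#'
#' Standard iterated binary erosion with a 3x3x3 cross or box structuring
#' element (voxels outside the grid count as background); the result is always
#' a subset of the input. Isolated voxels vanish after one iteration, which is
#' the noise-removal purpose of the step.
#'
#' @param mask binary 3D array or [volume3d()] of 0/1.
#' @param se `"cross"` or `"box"`.
#' @param iterations number of erosion passes (0 returns the input).
#' @return Logical 3D array.
#' @export
erode_mask <- function(mask, se = c("cross", "box"), iterations = 1L) {
  se <- match.arg(se)
  if (inherits(mask, "volume3d")) mask <- mask$data
  m <- mask != 0
  for (i in seq_len(iterations)) m <- erode3d_once(m, se)
  m
}

#' Apply a binary mask to a grayscale volume
#'
#' Tooth voxels keep their original intensity; background voxels are set to 0.
#' This realizes the framework's conversion of the binary segmentation back to
#' a grayscale tooth image.
#'
#' @param vol a [volume3d()].
#' @param mask binary array of the same shape.
#' @return A [volume3d()].
#' @export
mask_to_gray <- function(vol, mask) {
  vol <- as_volume3d(vol)
  if (inherits(mask, "volume3d")) mask <- mask$data
  if (!identical(dim(vol$data), dim(mask))) stop("shape mismatch")
  vol$data <- vol$data * (mask != 0)
  vol
}

#' Extract the enamel from the masked tooth volume
#'
#' Enamel is the bright tissue: tooth voxels (nonzero after masking) with
#' intensity at or above the threshold. With `threshold = "auto"`, the
#' threshold is the maximal between-class-variance split ([otsu_threshold()])
#' of the nonzero intensities.
#'
#' @param tooth_gray masked grayscale [volume3d()] (background exactly 0).
#' @param threshold numeric in `(0, 1]` or `"auto"`.
#' @return Logical 3D array (`TRUE` = enamel). Empty (with a warning) if no
#'   voxel qualifies.
#' @export
extract_enamel <- function(tooth_gray, threshold = "auto") {
  tooth_gray <- as_volume3d(tooth_gray)
  vals <- tooth_gray$data[tooth_gray$data > 0]
  if (!length(vals)) {
    warning("no nonzero tooth voxels; enamel mask is empty")
    return(array(FALSE, dim = dim(tooth_gray$data)))
  }
  thr <- if (identical(threshold, "auto")) otsu_threshold(vals)
         else as.numeric(threshold)
  out <- tooth_gray$data > 0 & tooth_gray$data >= thr
  if (!any(out)) warning("enamel mask is empty at threshold ", signif(thr, 4))
  out
}

#' Run the full segmentation and classification framework
#'
#' Executes the end-to-end pipeline on a grayscale volume:
#' \enumerate{
#'   \item normalize intensities and crop an ROI around the seed point;
#'   \item segment the tooth with 3D GFRLS ([gfrls_segment()]);
#'   \item clean the binary mask (erosion, optional reconstruction, optional
#'     largest-component filter);
#'   \item convert back to grayscale inside the mask;
#'   \item threshold the enamel;
#'   \item classify the remaining tooth interior slice-by-slice with the
#'     improved PCNN, then split the PCNN classes into dentine (bright) and
#'     pulp (dark) against a global Otsu threshold of the interior
#'     intensities;
#'   \item compose the labels (enamel wins over interior classes, background
#'     where the mask is 0) and paste back into full-volume coordinates.
#' }
#'
#' @param vol a [volume3d()] (or 3D array).
#' @param config a [pipeline_config()].
#' @return List of class `pipeline_result`: `labels` (a full-size
#'   [label_volume()]), and `report` (effective parameters, convergence flag,
#'   per-structure voxel and Halton volumes).
#' @export
run_pipeline <- function(vol, config) {
  stopifnot(inherits(config, "pipeline_config"))
  vol <- as_volume3d(vol)
  full_shape <- dim(vol$data)
  empty <- function(warn) {
    warning(warn)
    lab <- label_volume(array(0L, dim = full_shape), spacing = vol$spacing,
                        origin = vol$origin)
    structure(list(labels = lab,
                   report = list(warning = warn, converged = NA)),
              class = "pipeline_result")
  }
  if (max(vol$data) == min(vol$data))
    return(empty("constant volume: nothing to segment"))

  norm <- normalize_intensity(vol)
  roi <- extract_roi(norm, config$seed_point, config$block_radius)

  seg <- gfrls_segment(roi, params = config$gfrls)
  mask <- seg$mask$data != 0
  if (!any(mask))
    return(empty("segmentation produced an empty mask"))

  # cleanup: opening by reconstruction removes speckle without thinning the
  # surviving object; optionally keep only the largest 26-connected component
  if (config$erosion_iters > 0) {
    marker <- erode_mask(mask, config$erosion_se, config$erosion_iters)
    mask <- if (config$reconstruct) {
      if (any(marker)) reconstruct3d(marker, mask) else marker
    } else marker
    if (!any(mask))
      return(empty("mask vanished during morphological cleanup"))
  }
  if (config$largest_component) mask <- largest_component3d(mask)

  tooth_gray <- mask_to_gray(roi, mask)
  enamel <- extract_enamel(tooth_gray, config$enamel_threshold)
  interior <- mask & !enamel

  lab_roi <- array(0L, dim = dim(mask))
  lab_roi[enamel] <- 3L
  if (any(interior)) {
    lab_roi[interior] <- classify_interior(tooth_gray$data, interior,
                                           config$pcnn)
  }

  lab_full <- array(0L, dim = full_shape)
  off <- roi$origin - vol$origin
  d <- dim(mask)
  lab_full[(off[1] + 1L):(off[1] + d[1]),
           (off[2] + 1L):(off[2] + d[2]),
           (off[3] + 1L):(off[3] + d[3])] <- lab_roi
  labels <- label_volume(lab_full, spacing = vol$spacing, origin = vol$origin)

  report <- list(
    seed_point = config$seed_point, block_radius = config$block_radius,
    roi_origin = roi$origin, roi_shape = d,
    gfrls = unclass(config$gfrls),
    gfrls_iterations = seg$iterations, converged = seg$converged,
    erosion_iters = config$erosion_iters, erosion_se = config$erosion_se,
    reconstruct = config$reconstruct,
    largest_component = config$largest_component,
    enamel_threshold = config$enamel_threshold,
    pcnn = unclass(config$pcnn)[c("beta", "vF", "vL", "vTheta", "aF", "aL",
                                  "aTheta", "dt", "k", "n_iter")],
    volumes_mm3 = structure_volumes(labels))
  structure(list(labels = labels, report = report),
            class = "pipeline_result")
}

# classify the masked tooth interior (dentine vs pulp) slice-by-slice with
# the improved PCNN, mapping PCNN classes to tissues by a global intensity
# threshold (so slices containing a single tissue are labelled consistently)
classify_interior <- function(gray, interior, params) {
  global_thr <- {
    vals <- gray[interior]
    if (length(unique(vals)) < 2L) -Inf else otsu_threshold(vals)
  }
  out <- integer(sum(interior))
  pos <- array(cumsum(interior), dim = dim(interior)) # index into `out`
  for (z in seq_len(dim(interior)[1])) {
    sel <- interior[z, , ]
    if (!any(sel)) next
    S <- gray[z, , ] * sel
    res <- pcnn_run(S, params)
    cls <- labels_from_output(res$Y, params$k)
    tissue <- map_classes_to_tissue(cls[sel], S[sel], global_thr)
    out[pos[z, , ][sel]] <- tissue
  }
  out
}

# per-slice PCNN classes -> tissue codes (1 pulp, 2 dentine): a class whose
# mean original intensity reaches the global dentine/pulp threshold is dentine
map_classes_to_tissue <- function(cls, intens, global_thr) {
  tissue <- integer(length(cls))
  for (c0 in unique(cls)) {
    sel <- cls == c0
    tissue[sel] <- if (mean(intens[sel]) >= global_thr) 2L else 1L
  }
  tissue
}

structure_volumes <- function(labels) {
  structs <- setdiff(names(labels$label_map), "background")
  vv <- vapply(structs, function(s) voxel_volume(labels, s), numeric(1))
  as.list(vv)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$labels)
  if (!is.null(x$report$converged))
    cat(sprintf("  GFRLS: %s after %s iterations\n",
                if (isTRUE(x$report$converged)) "converged" else "not converged",
                x$report$gfrls_iterations %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
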