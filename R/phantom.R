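#' Specification of the synthetic tooth phantom
#'
#' Describes a deterministic single-tooth MicroCT phantom with exact ground
#' truth: a crown ellipsoid whose outer shell above the equator is enamel, a
#' nested pulp-chamber ellipsoid continued downward by a root-canal cylinder,
#' dentine filling the remainder, and (optionally) a bracket rod of tooth-like
#' intensity touching the tooth base — the foreign object that makes the real
#' scans hard to segment. Intensity tiers are ordered background < pulp <
#' dentine < enamel, with the bracket between dentine and enamel; Gaussian
#' noise is added and intensities clipped to `[0, 1]`. Labels are the exact
#' pre-noise geometry.
#'
#' @param shape grid shape `(nz, ny, nx)`; default 128^3 (256^3 supported).
#' @param spacing voxel size in mm.
#' @param means named intensities of `background`, `pulp`, `dentine`,
#'   `enamel`, `bracket`, each in `[0, 1]`.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param bracket logical: include the bracket rod.
#' @param tooth_center voxel center (z, y, x) of the crown ellipsoid (0-based,
#'   may be fractional).
#' @param tooth_axes semi-axes (z, y, x) of the crown ellipsoid, voxels.
#' @param enamel_shell fraction of the normalized ellipsoid radius beyond
#'   which upper-crown voxels are enamel (the enamel cap thickness is
#'   `(1 - enamel_shell)` times the local semi-axis).
#' @param pulp_center,pulp_axes center and semi-axes of the pulp chamber.
#' @param canal_radius radius (voxels) of the root-canal cylinder; 0 disables
#'   it.
#' @param canal_z_range z extent (0-based, inclusive) of the canal below the
#'   pulp chamber center.
#' @param bracket_radius,bracket_z_range geometry of the bracket rod (circular
#'   cross-section in-plane, centered under the tooth).
#' @param rng_seed integer seed making the noise reproducible.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L, 128L),
                         spacing = c(1, 1, 1),
                         means = c(background = 0.05, pulp = 0.35,
                                   dentine = 0.65, enamel = 0.95,
                                   bracket = 0.70),
                         noise_sd = 0.02,
                         bracket = TRUE,
                         tooth_center = NULL,
                         tooth_axes = NULL,
                         enamel_shell = 0.8,
                         pulp_center = NULL,
                         pulp_axes = NULL,
                         canal_radius = NULL,
                         canal_z_range = NULL,
                         bracket_radius = NULL,
                         bracket_z_range = NULL,
                         rng_seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 16L), noise_sd >= 0,
            enamel_shell > 0, enamel_shell < 1)
  req <- c("background", "pulp", "dentine", "enamel", "bracket")
  if (!all(req %in% names(means))) stop("`means` must name all five tiers")
  if (!(means["background"] < means["pulp"] &&
        means["pulp"] < means["dentine"] &&
        means["dentine"] < means["enamel"]))
    stop("tier means must satisfy background < pulp < dentine < enamel")
  # default geometry scales with the grid so small test phantoms stay nested
  s <- shape / 128
  if (is.null(tooth_center)) tooth_center <- (shape - 1) / 2
  if (is.null(tooth_axes))   tooth_axes <- c(45, 30, 30) * s
  if (is.null(pulp_center))  pulp_center <- tooth_center + c(-4, 0, 0) * s
  if (is.null(pulp_axes))    pulp_axes <- c(18, 10, 10) * s
  if (is.null(canal_radius)) canal_radius <- 3 * s[2]
  if (is.null(canal_z_range))
    canal_z_range <- c(tooth_center[1] - 34 * s[1], pulp_center[1])
  if (is.null(bracket_radius)) bracket_radius <- 8 * s[2]
  if (is.null(bracket_z_range))
    bracket_z_range <- c(0, tooth_center[1] - tooth_axes[1] + 2 * s[1])
  # nesting checks: pulp chamber strictly inside the dentine core
  core <- tooth_axes * enamel_shell
  off <- abs(pulp_center - tooth_center)
  if (any(off + pulp_axes >= core))
    stop("pulp geometry is not nested inside the dentine core")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 means = means, noise_sd = noise_sd, bracket = bracket,
                 tooth_center = tooth_center, tooth_axes = tooth_axes,
                 enamel_shell = enamel_shell, pulp_center = pulp_center,
                 pulp_axes = pulp_axes, canal_radius = canal_radius,
                 canal_z_range = canal_z_range,
                 bracket_radius = bracket_radius,
                 bracket_z_range = bracket_z_range,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# normalized squared ellipsoid coordinate on the (z, y, x) grid
ellipsoid_d2 <- function(shape, center, axes) {
  z <- (seq_len(shape[1]) - 1 - center[1]) / axes[1]
  y <- (seq_len(shape[2]) - 1 - center[2]) / axes[2]
  x <- (seq_len(shape[3]) - 1 - center[3]) / axes[3]
  outer(outer(z^2, y^2, `+`), x^2, `+`)
}

#' Generate the synthetic tooth phantom
#'
#' Builds the intensity volume and its exact ground-truth label volume from a
#' [phantom_spec()]. The same spec and seed always produce identical output.
#' The bracket is a foreign object: bright in the image but labelled
#' background in the truth.
#'
#' @param spec a [phantom_spec()].
#' @return List with `volume` (a [volume3d()], intensities in `[0, 1]`) and
#'   `labels` (a [label_volume()]).
#' @export
phantom_generate <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  shape <- spec$shape
  d2_tooth <- ellipsoid_d2(shape, spec$tooth_center, spec$tooth_axes)
  tooth <- d2_tooth <= 1
  enamel <- tooth & (d2_tooth >= spec$enamel_shell^2) &
    slices_at_or_above(shape, spec$tooth_center[1])
  pulp <- ellipsoid_d2(shape, spec$pulp_center, spec$pulp_axes) <= 1
  if (spec$canal_radius > 0) {
    r2 <- in_plane_r2(shape, spec$pulp_center[2:3])
    zr <- sort(spec$canal_z_range)
    zmask <- z_range_mask(shape, zr[1], zr[2])
    pulp <- pulp | (zmask & (r2 <= spec$canal_radius^2))
  }
  pulp <- pulp & tooth & !enamel
  dentine <- tooth & !enamel & !pulp

  lab <- array(0L, dim = shape)
  lab[pulp] <- 1L
  lab[dentine] <- 2L
  lab[enamel] <- 3L

  img <- array(spec$means[["background"]], dim = shape)
  img[pulp] <- spec$means[["pulp"]]
  img[dentine] <- spec$means[["dentine"]]
  img[enamel] <- spec$means[["enamel"]]
  if (spec$bracket) {
    r2 <- in_plane_r2(shape, spec$tooth_center[2:3])
    zr <- sort(spec$bracket_z_range)
    br <- z_range_mask(shape, zr[1], zr[2]) &
      (r2 <= spec$bracket_radius^2) & !tooth
    img[br] <- spec$means[["bracket"]]
  }
  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    set.seed(spec$rng_seed)
    img <- img + stats::rnorm(length(img), sd = spec$noise_sd)
    img <- pmin(pmax(img, 0), 1)
    dim(img) <- shape
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  list(volume = volume3d(img, spacing = spec$spacing),
       labels = label_volume(lab, spacing = spec$spacing))
}

slices_at_or_above <- function(shape, z0) {
  zmask <- (seq_len(shape[1]) - 1) >= z0
  array(rep(zmask, times = shape[2] * shape[3]), dim = shape)
}

z_range_mask <- function(shape, zlo, zhi) {
  zmask <- (seq_len(shape[1]) - 1) >= zlo & (seq_len(shape[1]) - 1) <= zhi
  array(rep(zmask, times = shape[2] * shape[3]), dim = shape)
}

# squared in-plane distance from an (y, x) axis, broadcast over z
in_plane_r2 <- function(shape, center_yx) {
  y2 <- ((seq_len(shape[2]) - 1) - center_yx[1])^2
  x2 <- ((seq_len(shape[3]) - 1) - center_yx[2])^2
  r2 <- outer(y2, x2, `+`)
  aperm(array(r2, dim = c(shape[2], shape[3], shape[1])), c(3, 1, 2))
}

#' Ground-truth volumes of a phantom
#'
#' Per-structure true volumes in mm^3 (voxel count times voxel volume) of a
#' generated phantom's label volume, written to CSV if `path` is given.
#'
#' @param labels the phantom's [label_volume()].
#' @param path optional CSV output path.
#' @return Data frame with columns `structure`, `voxels`, `volume_mm3`.
#' @export
save_truth_report <- function(labels, path = NULL) {
  vv <- prod(labels$spacing)
  structs <- setdiff(names(labels$label_map), "background")
  out <- data.frame(
    structure = structs,
    voxels = vapply(structs, function(s)
      sum(labels$data == labels$label_map[[s]]), numeric(1)),
    row.names = NULL)
  out$volume_mm3 <- out$voxels * vv
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
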