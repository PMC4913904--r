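#' Halton low-discrepancy sequence
#'
#' Radical-inverse (van der Corput) value of an index in a prime base: the
#' base-`b` digits of `index` are mirrored about the radix point. Pairs of
#' coprime bases (2, 3) give the 2D Halton sequence used for quasi-Monte Carlo
#' area estimation.
#'
#' @param index positive integer index (vectorized).
#' @param base prime base.
#' @return Numeric vector in (0, 1).
#' @examples
#' halton(1:4, 2) # 1/2, 1/4, 3/4, 1/8
#' @export
halton <- function(index, base = 2L) {
  index <- as.numeric(index)
  if (any(index < 1)) stop("`index` must be >= 1")
  out <- numeric(length(index))
  f <- 1 / base
  i <- index
  while (any(i > 0)) {
    out <- out + f * (i %% base)
    i <- i %/% base
    f <- f / base
  }
  out
}

#' Configuration of the Halton volume estimator
#'
#' @param n_points number of quasi-random points scattered per slice.
#' @param bases two coprime prime bases for the in-plane axes.
#' @return A list of class `halton_config`.
#' @export
halton_config <- function(n_points = 1e5, bases = c(2L, 3L)) {
  stopifnot(n_points >= 1, length(bases) == 2L, bases[1] != bases[2])
  structure(list(n_points = as.integer(n_points), bases = as.integer(bases)),
            class = "halton_config")
}

#' Quasi-Monte Carlo area of a 2D region
#'
#' Scatters `n_points` 2D Halton points over the bounding box of the region
#' and estimates the area as `(m / N) * S_box`, where `m` is the number of
#' points landing on region pixels and `S_box` the bounding-box area. The
#' estimate is deterministic (the Halton sequence has no seed). An empty
#' region has area 0; a region filling its bounding box is exact for any `N`.
#'
#' @param region 2D logical/0-1 matrix.
#' @param cfg a [halton_config()].
#' @param pixel_area in-plane pixel area in mm^2.
#' @return Area in mm^2.
#' @export
slice_area <- function(region, cfg = halton_config(), pixel_area = 1) {
  region <- region != 0
  if (!any(region)) return(0)
  rows <- range(which(rowSums(region) > 0))
  cols <- range(which(colSums(region) > 0))
  nr <- rows[2] - rows[1] + 1L
  nc <- cols[2] - cols[1] + 1L
  idx <- seq_len(cfg$n_points)
  u <- halton(idx, cfg$bases[1])
  v <- halton(idx, cfg$bases[2])
  ri <- rows[1] + pmin(floor(u * nr), nr - 1L)
  ci <- cols[1] + pmin(floor(v * nc), nc - 1L)
  m <- sum(region[cbind(ri, ci)])
  (m / cfg$n_points) * nr * nc * pixel_area
}

#' Halton-sequence volume of a labelled structure
#'
#' Per-slice quasi-Monte Carlo areas summed over the stack:
#' \eqn{V = \sum_i S_i \, dz}, with each slice's area estimated by
#' [slice_area()] over that slice's own bounding box of the structure.
#'
#' @param labels a [label_volume()] (or binary 3D array).
#' @param label label name or code to measure (ignored when `labels` is
#'   already binary).
#' @param cfg a [halton_config()].
#' @param spacing voxel spacing override (`(dz, dy, dx)` mm); default: the
#'   label volume's own spacing.
#' @return Volume in mm^3.
#' @export
estimate_volume <- function(labels, label = "enamel", cfg = halton_config(),
                            spacing = NULL) {
  b <- binary_structure(labels, label)
  if (is.null(spacing)) spacing <- b$spacing
  mask <- b$mask
  pixel_area <- spacing[2] * spacing[3]
  areas <- vapply(seq_len(dim(mask)[1]), function(z)
    slice_area(mask[z, , ], cfg, pixel_area), numeric(1))
  sum(areas) * spacing[1]
}

#' Voxel-count volume of a labelled structure
#'
#' Exact discrete volume: number of voxels carrying the label times the voxel
#' volume. Serves as the reference the Halton estimator converges to.
#'
#' @inheritParams estimate_volume
#' @return Volume in mm^3.
#' @export
voxel_volume <- function(labels, label = "enamel", spacing = NULL) {
  b <- binary_structure(labels, label)
  if (is.null(spacing)) spacing <- b$spacing
  sum(b$mask) * prod(spacing)
}

binary_structure <- function(labels, label) {
  if (inherits(labels, "label_volume")) {
    code <- label_code(labels, label)
    list(mask = labels$data == code, spacing = labels$spacing)
  } else if (inherits(labels, "volume3d")) {
    list(mask = labels$data != 0, spacing = labels$spacing)
  } else {
    list(mask = labels != 0, spacing = c(1, 1, 1))
  }
}

#' Signed relative volume error
#'
#' \eqn{E = (V_{computed} - V_{true}) / V_{true}}, signed: positive means
#' over-estimation.
#'
#' @param computed,true_ volumes in mm^3; `true_` must be positive.
#' @return Signed fraction.
#' @export
relative_error <- function(computed, true_) {
  if (any(true_ <= 0)) stop("true volume must be positive")
  (computed - true_) / true_
}

#' Mean absolute deviation of volumes
#'
#' Mean of `|computed - true|` over a set of (structure, case) volume pairs,
#' in mm^3.
#'
#' @param computed,true_ numeric vectors of paired volumes.
#' @return MAD in mm^3.
#' @export
volume_mad <- function(computed, true_) {
  stopifnot(length(computed) == length(true_), length(computed) >= 1)
  mean(abs(computed - true_))
}

#' Correlation coefficient with absolute numerator
#'
#' \deqn{CorrCo = \frac{\left|\sum_i (x_i - \bar x)(y_i - \bar y)\right|}
#'   {\sqrt{\sum_i (x_i-\bar x)^2 \sum_i (y_i - \bar y)^2}},}
#' the magnitude of the Pearson correlation, in `[0, 1]` (1 is a perfect
#' linear fit of either sign). Both vectors must be non-constant.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return Value in `[0, 1]`.
#' @export
corrco <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("corrco undefined for a constant vector")
  abs(sum((x - mean(x)) * (y - mean(y)))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

#' Overlap validity indexes
#'
#' Compares an automatic classification `A` against a reference `D`:
#' similarity index \eqn{S = 2|A \cap D| / (|A| + |D|)} (the Dice
#' coefficient; S > 0.7 conventionally indicates strong agreement),
#' sensitivity \eqn{SENS = |A \cap D| / |D|} and specificity
#' \eqn{SPEC = |A \cap D| / |A|}. High sensitivity with low specificity flags
#' an over-large automatic classification. Total overlap gives all three
#' equal to 1.
#'
#' @param A,D binary masks (logical or 0/1 arrays) of identical shape.
#' @return Named numeric vector `c(S =, SENS =, SPEC =)`.
#' @export
overlap_indexes <- function(A, D) {
  A <- A != 0; D <- D != 0
  if (!identical(dim(A), dim(D))) stop("shape mismatch between A and D")
  nA <- sum(A); nD <- sum(D)
  if (nD == 0) stop("sensitivity undefined: reference mask is empty")
  if (nA == 0) stop("specificity undefined: automatic mask is empty")
  inter <- sum(A & D)
  c(S = 2 * inter / (nA + nD), SENS = inter / nD, SPEC = inter / nA)
}

#' Full evaluation report of a classification against a reference
#'
#' Computes, per structure, the Halton volumes of prediction and reference,
#' the signed relative error, and the overlap indexes; plus the pooled MAD
#' and CorrCo over all structures.
#'
#' @param pred,truth [label_volume()]s with identical geometry and label maps.
#' @param cfg a [halton_config()].
#' @param structures label names to evaluate (default: all non-background).
#' @return A list of class `metrics_report`: `per_structure` data frame and
#'   scalars `mad`, `corrco`.
#' @export
metrics_report <- function(pred, truth, cfg = halton_config(),
                           structures = NULL) {
  stopifnot(inherits(pred, "label_volume"), inherits(truth, "label_volume"))
  if (!identical(dim(pred$data), dim(truth$data)))
    stop("prediction and truth have different shapes")
  if (is.null(structures))
    structures <- setdiff(names(truth$label_map), "background")
  rows <- lapply(structures, function(s) {
    code <- label_code(truth, s)
    vp <- estimate_volume(pred, s, cfg)
    vt <- estimate_volume(truth, s, cfg)
    ov <- overlap_indexes(pred$data == code, truth$data == code)
    data.frame(structure = s, computed_mm3 = vp, true_mm3 = vt,
               relative_error = relative_error(vp, vt),
               S = ov[["S"]], SENS = ov[["SENS"]], SPEC = ov[["SPEC"]])
  })
  per <- do.call(rbind, rows)
  structure(list(per_structure = per,
                 mad = volume_mad(per$computed_mm3, per$true_mm3),
                 corrco = if (nrow(per) >= 2) corrco(per$computed_mm3,
                                                     per$true_mm3) else NA_real_),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  print(x$per_structure, row.names = FALSE, digits = 4)
  cat(sprintf("MAD: %.4f mm^3", x$mad))
  if (is.finite(x$corrco)) cat(sprintf("   CorrCo: %.4f", x$corrco))
  cat("\n")
  invisible(x)
}
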