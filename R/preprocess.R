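#' Z-score normalize a channel volume
#'
#' Subtracts the mean and divides by the standard deviation of the
#' intensities, with the statistics computed either over a supplied region
#' mask, over the foreground (nonzero voxels; the default, so background air
#' does not dominate), or over the whole volume. The returned statistics
#' allow exact inversion.
#'
#' @param volume 3-D numeric array.
#' @param region_mask optional logical/binary array selecting the statistics
#'   region; overrides `region`.
#' @param region `"foreground"` (nonzero voxels) or `"volume"`.
#' @param channel channel name used in error messages.
#' @return list with `volume` (normalized array) and `stats` (mean, sd,
#'   region descriptor).
#' @export
zscore_normalize <- function(volume, region_mask = NULL,
                             region = c("foreground", "volume"),
                             channel = "volume") {
  region <- match.arg(region)
  if (!all(is.finite(volume))) stop("non-finite values in channel '", channel, "'")
  if (is.null(region_mask)) {
    sel <- if (region == "foreground") volume != 0 else rep(TRUE, length(volume))
    if (!any(sel)) sel <- rep(TRUE, length(volume))
  } else {
    if (!any(region_mask)) stop("empty region mask for channel '", channel, "'")
    sel <- as.logical(region_mask)
    region <- "region-mask"
  }
  vals <- volume[sel]
  m <- mean(vals)
  s <- sqrt(sum((vals - m)^2) / length(vals))  # population SD: exact unit variance
  if (s <= 0) stop("zero variance in channel '", channel, "': cannot normalize")
  list(volume = (volume - m) / s,
       stats = list(mean = m, sd = s, region = region))
}

#' Invert a z-score normalization
#'
#' @param volume normalized array.
#' @param stats the `stats` element returned by [zscore_normalize()].
#' @return The reconstructed array.
#' @export
denormalize <- function(volume, stats) volume * stats$sd + stats$mean

#' Resample a volume to a target voxel size
#'
#' The output grid spans the same world extent (voxel-center convention);
#' intensities use trilinear interpolation, masks should use nearest
#' neighbour. Resampling a volume to its own voxel size is the identity.
#'
#' @param volume 3-D array.
#' @param affine 4 x 4 voxel-to-world matrix (must be invertible; only the
#'   voxel scale is consulted for axis-aligned grids).
#' @param target_voxel_size mm triple.
#' @param interpolation `"linear"` or `"nearest"`.
#' @return list with the resampled `volume` and its updated `affine`.
#' @export
resample_to_grid <- function(volume, affine, target_voxel_size,
                             interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (abs(det(affine)) < 1e-12) stop("non-invertible affine")
  d <- dim(volume)
  src_vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  tgt <- rep(target_voxel_size, length.out = 3)
  nd <- pmax(1L, as.integer(round(d * src_vox / tgt)))

  # source (0-based) coordinates of the target voxel centers per axis
  coord <- lapply(1:3, function(a) {
    ((seq_len(nd[a]) - 0.5) * tgt[a] / src_vox[a]) - 0.5
  })
  if (interpolation == "nearest") {
    ix <- lapply(1:3, function(a) pmin(pmax(round(coord[[a]]) + 1, 1), d[a]))
    out <- volume[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  } else {
    lo <- lapply(1:3, function(a) pmin(pmax(floor(coord[[a]]), 0), d[a] - 1))
    fr <- lapply(1:3, function(a) pmin(pmax(coord[[a]] - lo[[a]], 0), 1))
    hi <- lapply(1:3, function(a) pmin(lo[[a]] + 1, d[a] - 1))
    g <- function(i, j, k) volume[cbind(rep(i + 1, times = nd[2] * nd[3]),
                                        rep(rep(j + 1, each = nd[1]), times = nd[3]),
                                        rep(k + 1, each = nd[1] * nd[2]))]
    fx <- rep(fr[[1]], times = nd[2] * nd[3])
    fy <- rep(rep(fr[[2]], each = nd[1]), times = nd[3])
    fz <- rep(fr[[3]], each = nd[1] * nd[2])
    v <- (1 - fx) * (1 - fy) * (1 - fz) * g(lo[[1]], lo[[2]], lo[[3]]) +
      fx * (1 - fy) * (1 - fz) * g(hi[[1]], lo[[2]], lo[[3]]) +
      (1 - fx) * fy * (1 - fz) * g(lo[[1]], hi[[2]], lo[[3]]) +
      fx * fy * (1 - fz) * g(hi[[1]], hi[[2]], lo[[3]]) +
      (1 - fx) * (1 - fy) * fz * g(lo[[1]], lo[[2]], hi[[3]]) +
      fx * (1 - fy) * fz * g(hi[[1]], lo[[2]], hi[[3]]) +
      (1 - fx) * fy * fz * g(lo[[1]], hi[[2]], hi[[3]]) +
      fx * fy * fz * g(hi[[1]], hi[[2]], hi[[3]])
    out <- array(v, nd)
  }
  new_affine <- affine
  new_affine[1:3, 1:3] <- affine[1:3, 1:3] %*% diag(tgt / src_vox)
  list(volume = out, affine = new_affine)
}

# Voxel axis most aligned with the world left-right (x) direction.
midsagittal_axis <- function(affine) which.max(abs(affine[1, 1:3]))

# Flip a 3-D array along one axis.
flip_axis <- function(v, axis) {
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- rev(seq_len(dim(v)[axis]))
  do.call(`[`, c(list(v), idx, list(drop = FALSE)))
}

#' Reflect a study and its masks about the mid-sagittal plane
#'
#' Flips every channel and every mask along the voxel axis most aligned with
#' the world left-right direction (per the affine). Applying the reflection
#' twice returns the input bit-exactly.
#'
#' @param study a [multi_sequence_study()].
#' @param masks a [mask_set()] on the same grid (optional).
#' @return list with reflected `study` and `masks`.
#' @export
reflect_midsagittal <- function(study, masks = NULL) {
  stopifnot(inherits(study, "multi_sequence_study"))
  ax <- midsagittal_axis(study$affine)
  study$channels <- lapply(study$channels, flip_axis, axis = ax)
  if (!is.null(masks)) {
    masks$masks <- lapply(masks$masks, flip_axis, axis = ax)
    if (!is.null(masks$observers)) {
      masks$observers <- lapply(masks$observers, function(o)
        lapply(o, flip_axis, axis = ax))
    }
  }
  list(study = study, masks = masks)
}
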