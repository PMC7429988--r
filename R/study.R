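#' Multi-sequence study container
#'
#' A named set of co-registered 3-D channel volumes on a shared grid. Channel
#' names are restricted to the ten sequences handled by the pipeline:
#' p, q, FLAIR, T1c, T2, FA, MD, ADC, S0, rCBV.
#'
#' @param channels named list of 3-D arrays sharing one shape.
#' @param affine 4 x 4 voxel-to-world matrix.
#' @param voxel_size mm triple.
#' @param study_id identifier string.
#' @return A `multi_sequence_study`.
#' @export
multi_sequence_study <- function(channels, affine = diag(c(voxel_size, 1)),
                                 voxel_size = c(2, 2, 2),
                                 study_id = "study") {
  stopifnot(is.list(channels), length(channels) >= 1L)
  bad <- setdiff(names(channels), CHANNEL_NAMES)
  if (length(bad)) {
    stop("unknown channel name(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(CHANNEL_NAMES, collapse = ", "))
  }
  d <- dim(channels[[1]])
  ok <- vapply(channels, function(v) identical(dim(v), d), logical(1))
  if (!all(ok)) stop("all channel volumes must share one shape")
  structure(
    list(channels = channels, affine = affine, voxel_size = voxel_size,
         study_id = study_id),
    class = "multi_sequence_study"
  )
}

#' @export
print.multi_sequence_study <- function(x, ...) {
  cat("<multi_sequence_study> '", x$study_id, "': ",
      paste(dim(x$channels[[1]]), collapse = " x "), " grid, channels ",
      paste(names(x$channels), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-compartment ground-truth masks
#'
#' @param masks named list of binary 3-D arrays; names from
#'   p-mask, q-mask, FLAIR-mask, T1c-mask.
#' @param observers optional named list (observer id -> named list of masks)
#'   of per-observer variants.
#' @return A `mask_set`.
#' @export
mask_set <- function(masks, observers = NULL) {
  bad <- setdiff(names(masks), MASK_NAMES)
  if (length(bad)) {
    stop("unknown mask name(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(MASK_NAMES, collapse = ", "))
  }
  for (nm in names(masks)) {
    v <- masks[[nm]]
    if (!all(v %in% c(0, 1))) stop("mask '", nm, "' is not binary")
    masks[[nm]] <- array(as.integer(v), dim(v))
  }
  d <- dim(masks[[1]])
  ok <- vapply(masks, function(v) identical(dim(v), d), logical(1))
  if (!all(ok)) stop("all masks must share one shape")
  structure(list(masks = masks, observers = observers), class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  sizes <- vapply(x$masks, sum, numeric(1))
  cat("<mask_set> ", paste(sprintf("%s (%d vox)", names(sizes), as.integer(sizes)),
                           collapse = ", "), "\n", sep = "")
  invisible(x)
}
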