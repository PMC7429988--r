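#' Fit the diffusion tensor voxelwise
#'
#' Ordinary least squares on the log-linearised single-tensor model
#' `log S = log S0 - b g' D g`, solved per voxel over the 7-column design
#' (six unique tensor components plus intercept). Voxels whose mean b = 0
#' signal does not exceed `background_threshold` times the global mean b = 0
#' signal are treated as background and excluded. Nonpositive samples are
#' dropped from a voxel's regression when at least 7 samples remain,
#' otherwise the voxel is invalidated; both events are counted in the
#' returned object.
#'
#' @param dwi a [dwi_volume()].
#' @param background_threshold fraction of the global mean b = 0 signal below
#'   which a voxel is considered background (default 0.05).
#' @return A `tensor_field`: `components` array (x, y, z, 6) holding
#'   (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) in mm^2/s, `log_s0`, logical
#'   `valid_mask`, and counts `n_dropped_samples`, `n_invalidated`.
#' @export
fit_tensor <- function(dwi, background_threshold = 0.05) {
  stopifnot(inherits(dwi, "dwi_volume"))
  proto <- dwi$protocol
  X <- design_matrix(proto)
  d <- dim(dwi$signal)[1:3]
  nvox <- prod(d)
  sig <- matrix(dwi$signal, nrow = nvox)  # voxels x acquisitions

  b0 <- proto$bvals == 0
  mean_b0 <- rowMeans(sig[, b0, drop = FALSE])
  valid <- mean_b0 > background_threshold * mean(mean_b0)

  comps <- matrix(0, nvox, 6)
  logs0 <- numeric(nvox)
  n_dropped <- 0L
  n_invalidated <- 0L

  idx <- which(valid)
  if (length(idx)) {
    sv <- sig[idx, , drop = FALSE]
    pos_ok <- rowSums(sv <= 0) == 0L
    # Fast path: shared design, one QR for all clean voxels.
    clean <- idx[pos_ok]
    if (length(clean)) {
      beta <- qr.coef(qr(X), t(log(sig[clean, , drop = FALSE])))
      logs0[clean] <- beta[1, ]
      comps[clean, ] <- t(beta[2:7, , drop = FALSE])
    }
    # Slow path: voxels with nonpositive samples get a per-voxel subset fit.
    dirty <- idx[!pos_ok]
    for (v in dirty) {
      keep <- sig[v, ] > 0
      if (sum(keep) >= 7L && qr(X[keep, , drop = FALSE])$rank == 7L) {
        n_dropped <- n_dropped + sum(!keep)
        beta <- qr.coef(qr(X[keep, , drop = FALSE]), log(sig[v, keep]))
        logs0[v] <- beta[1]
        comps[v, ] <- beta[2:7]
      } else {
        valid[v] <- FALSE
        n_invalidated <- n_invalidated + 1L
      }
    }
  }
  comps[!valid, ] <- 0
  logs0[!valid] <- 0

  structure(
    list(
      components = array(comps, dim = c(d, 6)),
      log_s0 = array(logs0, dim = d),
      valid_mask = array(valid, dim = d),
      affine = dwi$affine,
      voxel_size = dwi$voxel_size,
      n_dropped_samples = n_dropped,
      n_invalidated = n_invalidated
    ),
    class = "tensor_field"
  )
}

#' Construct a tensor field directly
#'
#' Used by the phantom generator and in tests; `components` holds the six
#' unique entries (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) of the symmetric tensor.
#'
#' @param components array (x, y, z, 6), mm^2/s.
#' @param valid_mask logical array (x, y, z); defaults to all valid.
#' @param log_s0 per-voxel log baseline signal; defaults to 0.
#' @param affine,voxel_size grid geometry.
#' @return A `tensor_field`.
#' @export
tensor_field <- function(components, valid_mask = NULL, log_s0 = NULL,
                         affine = diag(c(voxel_size, 1)),
                         voxel_size = c(2, 2, 2)) {
  d <- dim(components)
  stopifnot(length(d) == 4L, d[4] == 6L)
  if (is.null(valid_mask)) valid_mask <- array(TRUE, d[1:3])
  if (is.null(log_s0)) log_s0 <- array(0, d[1:3])
  structure(
    list(components = components, log_s0 = log_s0,
         valid_mask = array(as.logical(valid_mask), d[1:3]),
         affine = affine, voxel_size = voxel_size,
         n_dropped_samples = 0L, n_invalidated = 0L),
    class = "tensor_field"
  )
}

#' @export
print.tensor_field <- function(x, ...) {
  cat("<tensor_field> ", paste(dim(x$valid_mask), collapse = " x "),
      " grid, ", sum(x$valid_mask), " valid voxels\n", sep = "")
  invisible(x)
}

#' Eigendecompose a tensor field
#'
#' Per-voxel symmetric eigendecomposition; eigenvalues are sorted descending
#' and negative eigenvalues (a noise artefact of the unconstrained linear
#' fit) are clamped to zero after sorting, with the clamp count recorded.
#'
#' @param field a `tensor_field`.
#' @return An `eigen_system` with `eigenvalues` (x, y, z, 3) sorted
#'   descending, `eigenvectors` (x, y, z, 9; column-major 3x3 frames),
#'   `valid_mask`, and `n_clamped`.
#' @export
eigendecompose <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  d <- dim(field$valid_mask)
  nvox <- prod(d)
  comps <- matrix(field$components, nrow = nvox)
  valid <- as.vector(field$valid_mask)

  evals <- matrix(0, nvox, 3)
  evecs <- matrix(0, nvox, 9)
  evecs[, c(1, 5, 9)] <- 1
  n_clamped <- 0L
  if (any(valid)) {
    sub <- comps[valid, , drop = FALSE]
    if (any(!is.finite(sub))) {
      bad <- which(valid)[which(rowSums(!is.finite(sub)) > 0)[1]]
      stop("non-finite tensor component on valid voxel at linear index ", bad)
    }
    res <- eig3_batch(sub)
    evals[valid, ] <- res$eigenvalues
    evecs[valid, ] <- res$eigenvectors
    n_clamped <- res$n_clamped
  }
  structure(
    list(eigenvalues = array(evals, c(d, 3)),
         eigenvectors = array(evecs, c(d, 9)),
         valid_mask = field$valid_mask,
         affine = field$affine, voxel_size = field$voxel_size,
         n_clamped = n_clamped),
    class = "eigen_system"
  )
}

#' Compute the five scalar decomposition maps
#'
#' From the sorted eigenvalues: mean diffusivity `MD = (l1 + l2 + l3)/3`,
#' fractional anisotropy
#' `FA = sqrt(3/2) * sqrt(sum((li - MD)^2)) / sqrt(sum(li^2))`,
#' the isotropic magnitude `p = sqrt(3) * MD`, the anisotropic magnitude
#' `q = sqrt(sum((li - MD)^2))`, and `ADC = 3 * MD`. Note the ADC convention
#' here equals the tensor trace (three times the common ADC = MD
#' convention), matching the decomposition this package implements.
#'
#' @param eig an `eigen_system`.
#' @param p_scale `"sqrt3"` (default) for `p = sqrt(3) * MD`, or
#'   `"literal3"` for `p = 3 * MD`; the latter breaks the
#'   `FA * sqrt(p^2 + q^2) = sqrt(3/2) * q` identity.
#' @return A `scalar_map_set` with 3-D maps `fa`, `md`, `adc`, `p`, `q`
#'   (zero outside `valid_mask`).
#' @export
compute_maps <- function(eig, p_scale = c("sqrt3", "literal3")) {
  stopifnot(inherits(eig, "eigen_system"))
  p_scale <- match.arg(p_scale)
  d <- dim(eig$valid_mask)
  ev <- matrix(eig$eigenvalues, ncol = 3)
  md <- rowMeans(ev)
  dev2 <- (ev[, 1] - md)^2 + (ev[, 2] - md)^2 + (ev[, 3] - md)^2
  ss <- ev[, 1]^2 + ev[, 2]^2 + ev[, 3]^2
  fa <- ifelse(ss > 0, sqrt(1.5) * sqrt(dev2) / sqrt(ss), 0)
  q <- sqrt(dev2)
  p <- if (p_scale == "sqrt3") sqrt(3) * md else 3 * md
  adc <- 3 * md

  valid <- as.vector(eig$valid_mask)
  z <- function(v) { v[!valid] <- 0; array(v, d) }
  structure(
    list(fa = z(fa), md = z(md), adc = z(adc), p = z(p), q = z(q),
         valid_mask = eig$valid_mask, p_scale = p_scale,
         affine = eig$affine, voxel_size = eig$voxel_size),
    class = "scalar_map_set"
  )
}

#' @export
print.scalar_map_set <- function(x, ...) {
  cat("<scalar_map_set> maps fa/md/adc/p/q on a ",
      paste(dim(x$fa), collapse = " x "), " grid (p_scale = ",
      x$p_scale, ")\n", sep = "")
  invisible(x)
}

#' Check the algebraic identities linking the scalar maps
#'
#' Over valid voxels, reports the maximum absolute violation of
#' `FA * sqrt(p^2 + q^2) - sqrt(3/2) * q`, of `p - sqrt(3) * MD`, and of
#' `ADC - 3 * MD`; the set passes when all are below `tol`. Voxels exceeding
#' `tol` are returned for inspection.
#'
#' @param maps a `scalar_map_set` produced with the default `p_scale`.
#' @param tol violation tolerance (default 1e-8).
#' @return A list with the three maxima, `pass`, and `flagged_voxels`
#'   (matrix of array indices).
#' @export
validate_identity <- function(maps, tol = 1e-8) {
  stopifnot(inherits(maps, "scalar_map_set"))
  valid <- maps$valid_mask
  fa <- maps$fa[valid]; p <- maps$p[valid]; q <- maps$q[valid]
  md <- maps$md[valid]; adc <- maps$adc[valid]
  v_fapq <- abs(fa * sqrt(p^2 + q^2) - sqrt(1.5) * q)
  v_p <- abs(p - sqrt(3) * md)
  v_adc <- abs(adc - 3 * md)
  worst <- pmax(v_fapq, v_p, v_adc)
  flagged <- which(valid, arr.ind = TRUE)[worst > tol, , drop = FALSE]
  list(
    max_identity_violation = if (length(v_fapq)) max(v_fapq) else 0,
    max_p_violation = if (length(v_p)) max(v_p) else 0,
    max_adc_violation = if (length(v_adc)) max(v_adc) else 0,
    pass = !nrow(flagged),
    flagged_voxels = flagged
  )
}
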