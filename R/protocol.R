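#' Diffusion acquisition protocol
#'
#' Bundles the acquisition table of b-values (s/mm^2) and unit gradient
#' directions describing a DWI series. Directions of diffusion-weighted
#' acquisitions (b > 0) must be unit vectors; at least one b = 0 baseline is
#' required, and the log-linear tensor design built from the table must have
#' full column rank 7 (6 tensor components plus the log-baseline intercept).
#'
#' @param bvals numeric vector of b-values, one per acquisition (s/mm^2).
#' @param bvecs gradient directions, a 3 x M or M x 3 numeric matrix.
#' @return An object of class `diffusion_protocol` with elements `bvals`,
#'   `bvecs` (M x 3), and `n_acq`.
#' @export
diffusion_protocol <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) == 3L && ncol(bvecs) != 3L) bvecs <- t(bvecs)
  if (ncol(bvecs) != 3L) stop("bvecs must be 3 x M or M x 3")
  if (length(bvals) != nrow(bvecs)) {
    stop("bvals (", length(bvals), ") and bvecs (", nrow(bvecs),
         ") disagree on the number of acquisitions")
  }
  if (any(bvals < 0)) stop("b-values must be nonnegative")
  if (!any(bvals == 0)) stop("protocol must contain at least one b = 0 acquisition")
  dw <- bvals > 0
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(abs(nrm[dw] - 1) > 1e-6)) {
    stop("diffusion-weighted gradient directions must be unit vectors (norm within 1e-6)")
  }
  if (length(bvals) < 7L) stop("at least 7 acquisitions are required to fit the tensor")
  proto <- structure(
    list(bvals = bvals, bvecs = bvecs, n_acq = length(bvals)),
    class = "diffusion_protocol"
  )
  X <- design_matrix(proto)
  qx <- qr(X)
  if (qx$rank < 7L) {
    bad <- colnames(X)[sort(qx$pivot[seq(qx$rank + 1L, 7L)])]
    stop("rank-deficient diffusion design (rank ", qx$rank,
         "): deficient columns ", paste(bad, collapse = ", "))
  }
  proto
}

#' @export
print.diffusion_protocol <- function(x, ...) {
  cat("<diffusion_protocol> ", x$n_acq, " acquisitions; b = ",
      paste(sort(unique(x$bvals)), collapse = ", "), " s/mm^2\n", sep = "")
  invisible(x)
}

#' Default multi-b-value protocol
#'
#' Six b-shells (0, 350, 650, 1000, 1300, 1600 s/mm^2) with each nonzero
#' shell scanned along 13 directions, emulating a clinical single-shot EPI
#' DTI acquisition. Directions are a deterministic spherical Fibonacci set.
#'
#' @param bvals b-shells to include (s/mm^2); must contain 0.
#' @param n_directions number of gradient directions per nonzero shell.
#' @return A [diffusion_protocol()].
#' @export
default_protocol <- function(bvals = c(0, 350, 650, 1000, 1300, 1600),
                             n_directions = 13) {
  dirs <- fibonacci_sphere(n_directions)
  bnz <- bvals[bvals > 0]
  all_b <- c(0, rep(bnz, each = n_directions))
  all_g <- rbind(c(0, 0, 0), dirs[rep(seq_len(n_directions), times = length(bnz)), ])
  diffusion_protocol(all_b, all_g)
}

# Deterministic quasi-uniform unit vectors on the sphere.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Rows: [1, -b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz, -2b gy gz]
# so that X %*% c(log S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) = log S.
design_matrix <- function(protocol) {
  b <- protocol$bvals
  g <- protocol$bvecs
  X <- cbind(
    1,
    -b * g[, 1]^2,
    -b * g[, 2]^2,
    -b * g[, 3]^2,
    -2 * b * g[, 1] * g[, 2],
    -2 * b * g[, 1] * g[, 3],
    -2 * b * g[, 2] * g[, 3]
  )
  colnames(X) <- c("logS0", "Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz")
  X
}

#' 4-D diffusion-weighted volume
#'
#' @param signal nonnegative 4-D array (x, y, z, acquisition).
#' @param protocol a [diffusion_protocol()]; its acquisition count must match
#'   the fourth dimension of `signal`.
#' @param affine 4 x 4 voxel-to-world matrix.
#' @param voxel_size voxel edge lengths in mm.
#' @return An object of class `dwi_volume`.
#' @export
dwi_volume <- function(signal, protocol,
                       affine = diag(c(voxel_size, 1)),
                       voxel_size = c(2, 2, 2)) {
  stopifnot(inherits(protocol, "diffusion_protocol"))
  d <- dim(signal)
  if (length(d) != 4L) stop("signal must be a 4-D array")
  if (d[4] != protocol$n_acq) {
    stop("signal has ", d[4], " acquisitions but the protocol has ", protocol$n_acq)
  }
  if (any(signal < 0)) stop("signal values must be nonnegative")
  structure(
    list(signal = signal, protocol = protocol, affine = affine,
         voxel_size = voxel_size),
    class = "dwi_volume"
  )
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$signal)
  cat("<dwi_volume> ", paste(d[1:3], collapse = " x "), " grid, ",
      d[4], " acquisitions\n", sep = "")
  invisible(x)
}
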