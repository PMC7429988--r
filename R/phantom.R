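#' Synthetic GBM phantom specification
#'
#' Describes a desk-scale multi-sequence glioblastoma phantom: five nested
#' spherical tumor compartments (necrotic core, enhancing rim, tumor bulk,
#' invasion zone, edema) with smooth sigmoid boundaries embedded in
#' anisotropic white-matter background inside an ellipsoidal head, plus the
#' acquisition-level noise and the per-channel contrast table used to emit
#' surrogate anatomical/perfusion channels.
#'
#' Diffusivity triples are sorted principal diffusivities in mm^2/s. The
#' default tumor profile elevates mean diffusivity and suppresses anisotropy
#' relative to background white matter, and places the invasion-zone
#' contrast primarily in the isotropic (p) channel with only weak FLAIR
#' support, so channel-ablation experiments have a genuine multi-channel
#' advantage to detect.
#'
#' @param grid_shape voxel grid triple (default 64 x 64 x 32).
#' @param voxel_size mm triple (default 2 mm isotropic).
#' @param center tumor center in mm, or NULL for the grid center.
#' @param radii named mm radii, nondecreasing: core, enhancing, bulk,
#'   invasion, edema. A nonpositive radius disables that compartment.
#' @param edge_width sigmoid boundary width (mm).
#' @param diffusivities named list of sorted diffusivity triples (mm^2/s)
#'   for background and the five compartments.
#' @param fiber_tilt amplitude (radians) of the slow in-plane rotation of
#'   the background fiber direction across the volume.
#' @param head_fraction ellipsoidal head semi-axes as a fraction of the
#'   half field of view; outside the head all signal is (near) zero.
#' @param s0_mean baseline (b = 0) signal level inside the head.
#' @param noise_sigma Rician noise standard deviation on the DWI signal.
#' @param contrast compartment-by-channel mean-intensity table for the
#'   surrogate anatomical/perfusion channels (T1c, FLAIR, T2, S0, rCBV).
#' @param channel_noise_sd Gaussian noise SD on the surrogate channels.
#' @param seed integer seed controlling every stochastic element.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 32),
                         voxel_size = c(2, 2, 2),
                         center = NULL,
                         radii = c(core = 6, enhancing = 10, bulk = 14,
                                   invasion = 19, edema = 24),
                         edge_width = 1,
                         diffusivities = list(
                           background = c(1.7, 0.4, 0.3) * 1e-3,
                           core       = c(3.0, 3.0, 3.0) * 1e-3,
                           enhancing  = c(1.2, 1.0, 0.9) * 1e-3,
                           bulk       = c(1.6, 1.4, 1.3) * 1e-3,
                           invasion   = c(1.5, 1.1, 1.0) * 1e-3,
                           edema      = c(2.0, 1.3, 1.2) * 1e-3
                         ),
                         fiber_tilt = pi / 8,
                         head_fraction = 0.92,
                         s0_mean = 1000,
                         noise_sigma = 10,
                         contrast = default_contrast_table(),
                         channel_noise_sd = 5,
                         seed = 1L) {
  comp_names <- c("core", "enhancing", "bulk", "invasion", "edema")
  radii <- radii[comp_names]
  if (anyNA(radii)) stop("radii must name all of: ", paste(comp_names, collapse = ", "))
  pos <- radii[radii > 0]
  if (is.unsorted(pos)) stop("compartment radii must be nondecreasing (nested spheres)")
  stopifnot(length(grid_shape) == 3L, length(voxel_size) == 3L)
  if (noise_sigma < 0) stop("noise_sigma must be nonnegative")
  if (channel_noise_sd < 0) stop("channel_noise_sd must be nonnegative")
  dnames <- c("background", comp_names)
  if (!all(dnames %in% names(diffusivities))) {
    stop("diffusivities must name: ", paste(dnames, collapse = ", "))
  }
  if (any(unlist(diffusivities) < 0)) stop("diffusivities must be nonnegative")
  fov <- grid_shape * voxel_size
  if (is.null(center)) center <- fov / 2
  semi <- head_fraction * fov / 2
  reach <- abs(center - fov / 2) + max(radii)
  if (any(reach > semi)) {
    stop("compartment radii exceed the grid: tumor of radius ", max(radii),
         " mm at the given center does not fit inside the head ",
         "(semi-axes ", paste(round(semi, 1), collapse = " x "), " mm)")
  }
  structure(
    list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
         center = center, radii = radii, edge_width = edge_width,
         diffusivities = diffusivities[dnames], fiber_tilt = fiber_tilt,
         head_fraction = head_fraction, s0_mean = s0_mean,
         noise_sigma = noise_sigma, contrast = contrast,
         channel_noise_sd = channel_noise_sd, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Default compartment-to-channel contrast table
#'
#' Mean intensities (arbitrary units, background 100) of the surrogate
#' anatomical and perfusion channels per compartment: bright enhancing rim
#' on T1c, bright edema on FLAIR/T2, dark necrosis on T1c/rCBV, and a
#' deliberately faint invasion zone on FLAIR.
#'
#' @return A 6 x 5 numeric matrix (compartments x channels).
#' @export
default_contrast_table <- function() {
  m <- rbind(
    background = c(T1c = 100, FLAIR = 100, T2 = 100, S0 = 100, rCBV = 100),
    core       = c(60,  80, 190, 120,  30),
    enhancing  = c(200, 150, 130, 110, 220),
    bulk       = c(110, 160, 150, 115, 180),
    invasion   = c(100, 112, 110, 105, 120),
    edema      = c(95, 180, 170, 108,  90)
  )
  colnames(m) <- c("T1c", "FLAIR", "T2", "S0", "rCBV")
  m
}

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic substream seeds below 2^31.
seed_stream <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 1103515245 * k) %% 2147483647)
}

# Geometry shared by the tensor field and the surrogate channels: sigmoid
# membership weights (voxels x [background, core..edema]), hard labels
# (0 = background, 1..5 = innermost compartment), head mask.
phantom_geometry <- function(spec) {
  gs <- spec$grid_shape; vs <- spec$voxel_size
  cx <- (seq_len(gs[1]) - 0.5) * vs[1]
  cy <- (seq_len(gs[2]) - 0.5) * vs[2]
  cz <- (seq_len(gs[3]) - 0.5) * vs[3]
  X <- array(rep(cx, times = gs[2] * gs[3]), gs)
  Y <- array(rep(rep(cy, each = gs[1]), times = gs[3]), gs)
  Z <- array(rep(cz, each = gs[1] * gs[2]), gs)
  d <- sqrt((X - spec$center[1])^2 + (Y - spec$center[2])^2 + (Z - spec$center[3])^2)

  fov <- gs * vs
  semi <- spec$head_fraction * fov / 2
  head <- ((X - fov[1] / 2) / semi[1])^2 + ((Y - fov[2] / 2) / semi[2])^2 +
    ((Z - fov[3] / 2) / semi[3])^2 <= 1

  sig <- vapply(spec$radii, function(r) {
    if (r <= 0) rep(0, length(d)) else as.vector(1 / (1 + exp(-(r - d) / spec$edge_width)))
  }, numeric(length(d)))
  # inclusion is cumulative outward; per-compartment weights are successive
  # differences, background takes the remainder
  w <- cbind(
    background = 1 - sig[, 5],
    core = sig[, 1],
    enhancing = sig[, 2] - sig[, 1],
    bulk = sig[, 3] - sig[, 2],
    invasion = sig[, 4] - sig[, 3],
    edema = sig[, 5] - sig[, 4]
  )
  labels <- array(0L, gs)
  for (k in 5:1) {
    r <- spec$radii[k]
    if (r > 0) labels[d <= r] <- k
  }
  labels[!head] <- 0L
  list(weights = w, labels = labels, head = head, X = X, Y = Y, Z = Z)
}

#' Build the phantom tensor field
#'
#' Constructs a voxelwise diffusion tensor field from the compartment
#' geometry: background voxels carry anisotropic tensors aligned to a slowly
#' rotating in-plane fiber orientation field; tumor compartments carry their
#' diffusivity profiles in the same local frame; sigmoid membership weights
#' blend the profiles across compartment boundaries (partial volume).
#'
#' @param spec a [phantom_spec()].
#' @return A list: `field` (a `tensor_field` valid inside the head),
#'   `labels` (integer array, 0 background / 1 core .. 5 edema), `head`
#'   (logical array), and `weights` (membership matrix, used internally for
#'   the surrogate channels).
#' @export
build_tensor_field <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- phantom_geometry(spec)
  gs <- spec$grid_shape
  nvox <- prod(gs)

  # effective principal diffusivities: membership-weighted blend of profiles
  prof <- do.call(rbind, spec$diffusivities)  # 6 x 3, rows match weights cols
  lam <- geo$weights %*% prof                 # voxels x 3

  # local fiber frame: e1 in-plane at angle a(x), e2 orthogonal in-plane, e3 = z
  fovx <- gs[1] * spec$voxel_size[1]
  a <- spec$fiber_tilt * sin(2 * pi * as.vector(geo$X) / fovx)
  ca <- cos(a); sa <- sin(a)
  # D = lam1 e1 e1' + lam2 e2 e2' + lam3 e3 e3', e1 = (sa, ca, 0), e2 = (ca, -sa, 0)
  comps <- cbind(
    Dxx = lam[, 1] * sa^2 + lam[, 2] * ca^2,
    Dyy = lam[, 1] * ca^2 + lam[, 2] * sa^2,
    Dzz = lam[, 3],
    Dxy = lam[, 1] * sa * ca - lam[, 2] * ca * sa,
    Dxz = 0,
    Dyz = 0
  )
  comps[!geo$head, ] <- 0
  field <- tensor_field(array(comps, c(gs, 6)), valid_mask = geo$head,
                        log_s0 = array(log(spec$s0_mean) * geo$head, gs),
                        voxel_size = spec$voxel_size)
  list(field = field, labels = geo$labels, head = geo$head, weights = geo$weights)
}

#' Simulate diffusion-weighted MRI from a tensor field
#'
#' Forward model `S = S0 exp(-b g' D g)` per acquisition, with Rician noise
#' realised as the magnitude of the noise-free signal plus two independent
#' zero-mean Gaussian channels of standard deviation `noise_sigma`. With
#' `noise_sigma = 0` the simulation is the exact inverse of [fit_tensor()]'s
#' log-linear model.
#'
#' @param field a `tensor_field`; `exp(log_s0)` provides the per-voxel
#'   baseline where valid (overridden by `s0_mean` if given).
#' @param protocol a [diffusion_protocol()].
#' @param s0_mean baseline signal inside the valid mask; NULL uses the
#'   field's `log_s0`.
#' @param noise_sigma Rician noise SD (signal units), >= 0.
#' @param seed integer seed for the noise.
#' @return A [dwi_volume()].
#' @export
simulate_dwi <- function(field, protocol, s0_mean = NULL, noise_sigma = 0,
                         seed = 1L) {
  stopifnot(inherits(field, "tensor_field"),
            inherits(protocol, "diffusion_protocol"))
  if (noise_sigma < 0) stop("noise_sigma must be nonnegative")
  gs <- dim(field$valid_mask)
  nvox <- prod(gs)
  comps <- matrix(field$components, nrow = nvox)
  s0 <- if (is.null(s0_mean)) exp(field$log_s0) * field$valid_mask else
    s0_mean * field$valid_mask
  s0 <- as.vector(s0)

  g <- protocol$bvecs
  gco <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
               2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  quad <- comps %*% t(gco)                      # voxels x M, g' D g
  S <- s0 * exp(-sweep(quad, 2, protocol$bvals, `*`))
  if (noise_sigma > 0) {
    with_seed(seed, {
      n1 <- matrix(rnorm(length(S), 0, noise_sigma), nrow(S))
      n2 <- matrix(rnorm(length(S), 0, noise_sigma), nrow(S))
      S <- sqrt((S + n1)^2 + n2^2)
    })
  }
  dwi_volume(array(S, c(gs, protocol$n_acq)), protocol,
             affine = field$affine, voxel_size = field$voxel_size)
}

#' Generate one synthetic multi-sequence study
#'
#' Builds the compartmentalised tensor field, simulates DWI with Rician
#' noise, and derives the five DTI channels (p, q, FA, MD, ADC) by running
#' the full tensor-fitting pipeline on the simulated signal — not by copying
#' the ground-truth field. Surrogate anatomical/perfusion channels (T1c,
#' FLAIR, T2, S0, rCBV) are blended from the contrast table with Gaussian
#' noise. Ground-truth masks come from the compartment labels: T1c-mask is
#' the enhancing region, q-mask the tumor bulk, p-mask the invasion zone,
#' FLAIR-mask the full edema extent; by construction q-mask is nested inside
#' p-mask.
#'
#' @param spec a [phantom_spec()].
#' @param protocol a [diffusion_protocol()] (default [default_protocol()]).
#' @param study_id identifier; default derived from the spec seed.
#' @return A list with `study` ([multi_sequence_study()]), `masks`
#'   ([mask_set()]), and `labels`.
#' @export
generate_study <- function(spec, protocol = default_protocol(),
                           study_id = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(study_id)) study_id <- sprintf("phantom-seed%d", spec$seed)
  bt <- build_tensor_field(spec)
  gs <- spec$grid_shape

  dwi <- simulate_dwi(bt$field, protocol, s0_mean = spec$s0_mean,
                      noise_sigma = spec$noise_sigma,
                      seed = seed_stream(spec$seed, 1L))
  tf <- fit_tensor(dwi)
  maps <- compute_maps(eigendecompose(tf))

  channels <- list(p = maps$p, q = maps$q, FA = maps$fa, MD = maps$md,
                   ADC = maps$adc)
  anat <- with_seed(seed_stream(spec$seed, 2L), {
    lapply(colnames(spec$contrast), function(ch) {
      v <- as.vector(bt$weights %*% spec$contrast[, ch]) +
        rnorm(prod(gs), 0, spec$channel_noise_sd)
      v[!bt$head] <- 0
      array(v, gs)
    })
  })
  names(anat) <- colnames(spec$contrast)
  channels <- c(channels, anat)[CHANNEL_NAMES]

  lab <- bt$labels
  masks <- mask_set(list(
    "T1c-mask" = array(as.integer(lab %in% 1:2), gs),
    "q-mask" = array(as.integer(lab %in% 1:3), gs),
    "p-mask" = array(as.integer(lab %in% 1:4), gs),
    "FLAIR-mask" = array(as.integer(lab %in% 1:5), gs)
  ))
  study <- multi_sequence_study(channels, affine = bt$field$affine,
                                voxel_size = spec$voxel_size,
                                study_id = study_id)
  list(study = study, masks = masks, labels = lab)
}

#' Generate a phantom cohort
#'
#' Replicates [generate_study()] with randomised tumor centers (up to 8 mm
#' in-plane, 4 mm axial) and sizes (global radius scale 0.85-1.15), each
#' study fully determined by the cohort seed.
#'
#' @param n number of studies (>= 1).
#' @param base_spec template [phantom_spec()].
#' @param protocol a [diffusion_protocol()].
#' @param seed cohort seed.
#' @return A list of `n` elements, each as returned by [generate_study()].
#' @export
generate_cohort <- function(n, base_spec = phantom_spec(),
                            protocol = default_protocol(), seed = 1L) {
  stopifnot(n >= 1)
  draws <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      list(jitter = c(runif(2, -8, 8), runif(1, -4, 4)),
           scale = runif(1, 0.85, 1.15))
    })
  })
  lapply(seq_len(n), function(i) {
    sp <- base_spec
    sp$radii <- base_spec$radii * draws[[i]]$scale
    sp$center <- base_spec$center + draws[[i]]$jitter
    sp$seed <- seed_stream(seed, 100L + i)
    # keep the scaled tumor inside the head: pull the center back if needed
    fov <- sp$grid_shape * sp$voxel_size
    semi <- sp$head_fraction * fov / 2
    room <- semi - max(sp$radii)
    if (any(room < 0)) stop("jittered tumor does not fit the grid")
    off <- sp$center - fov / 2
    sp$center <- fov / 2 + pmin(pmax(off, -room), room)
    out <- generate_study(sp, protocol, study_id = sprintf("phantom-%03d", i))
    out$spec <- sp
    out
  })
}
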