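#' Dual-pathway multi-scale network configuration
#'
#' Describes the segmentation network: two parallel convolutional pathways —
#' one on the native-resolution patch, one on a downsampled wider-context
#' patch of the same location — each with `n_feature_layers` 3-D
#' convolutional layers, followed by fully connected (1x1x1 convolution)
#' layers and a softmax classification layer. Residual connections are added
#' between the outputs of every two layers, skipping the first two layers of
#' each pathway. The geometry is validated so both pathway outputs align on
#' one output lattice: the normal-pathway output size must be divisible by
#' `downsample_factor`, and the context patch is sized accordingly.
#'
#' @param input_channels ordered character vector of channel names.
#' @param n_classes number of output classes (default 2: target/background).
#' @param kernel_size cubic convolution kernel edge (default 5).
#' @param n_feature_layers convolution layers per pathway (default 4; with
#'   the two fully connected layers and the classification layer this is the
#'   11-layer configuration).
#' @param features feature maps per convolution layer (default 30,30,40,40).
#' @param fc_features width of the fully connected layers (default 40).
#' @param n_fc_layers number of fully connected layers (default 2).
#' @param downsample_factor context-pathway downsampling factor (default 3).
#' @param normal_patch_size native-resolution training patch edge
#'   (default 25).
#' @return A `network_config` with derived geometry: `output_size`,
#'   `margin`, `context_patch_size` (full-resolution extent) and
#'   `low_patch_size` (after downsampling).
#' @export
network_config <- function(input_channels,
                           n_classes = 2L,
                           kernel_size = 5L,
                           n_feature_layers = 4L,
                           features = c(30L, 30L, 40L, 40L),
                           fc_features = 40L,
                           n_fc_layers = 2L,
                           downsample_factor = 3L,
                           normal_patch_size = 25L) {
  stopifnot(length(input_channels) >= 1L, n_classes >= 2L,
            kernel_size %% 2 == 1, n_feature_layers >= 2L,
            length(features) == n_feature_layers,
            n_fc_layers %in% 1:2)
  if (downsample_factor < 2L) {
    stop("downsample_factor must be >= 2 so the context pathway's receptive ",
         "field strictly exceeds the normal pathway's")
  }
  shrink <- n_feature_layers * (kernel_size - 1L)
  out <- normal_patch_size - shrink
  if (out < 1L) {
    stop("normal_patch_size ", normal_patch_size, " is consumed by ",
         n_feature_layers, " layers of kernel ", kernel_size,
         "; need at least ", shrink + 1L)
  }
  if (out %% downsample_factor != 0L) {
    stop("pathway outputs misaligned: the output lattice (",
         "normal_patch_size - n_feature_layers*(kernel_size-1) = ", out,
         ") must be divisible by downsample_factor = ", downsample_factor,
         " so the upsampled context output matches the normal output")
  }
  low_patch <- out %/% downsample_factor + shrink
  structure(
    list(input_channels = input_channels, n_classes = as.integer(n_classes),
         kernel_size = as.integer(kernel_size),
         n_feature_layers = as.integer(n_feature_layers),
         features = as.integer(features), fc_features = as.integer(fc_features),
         n_fc_layers = as.integer(n_fc_layers),
         downsample_factor = as.integer(downsample_factor),
         normal_patch_size = as.integer(normal_patch_size),
         output_size = as.integer(out), margin = as.integer(shrink %/% 2L),
         shrink = as.integer(shrink),
         low_patch_size = as.integer(low_patch),
         context_patch_size = as.integer(out + downsample_factor * shrink),
         residual_layers = seq(4L, n_feature_layers, by = 2L)),
    class = "network_config"
  )
}

#' A compact configuration for desk-scale experiments
#'
#' Kernel 3, features (8, 8, 12, 12), fully connected width 16, normal patch
#' 14 (output lattice 6^3) — small enough to train on one CPU in minutes
#' while keeping the dual-pathway residual architecture intact.
#'
#' @param input_channels channel names.
#' @param ... overrides passed to [network_config()].
#' @return A `network_config`.
#' @export
small_network_config <- function(input_channels, ...) {
  args <- list(input_channels = input_channels, kernel_size = 3L,
               features = c(8L, 8L, 12L, 12L), fc_features = 16L,
               normal_patch_size = 14L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(network_config, args)
}

#' One experiment row: input channels plus target mask
#'
#' With `model_id` in 1..16 the combination must match the built-in
#' experiment table (see [model_table()]); `model_id = 0` allows free
#' combinations.
#'
#' @param model_id integer 0..16.
#' @param input_channels subset of the ten channel names; defaults to the
#'   table row when `model_id >= 1`.
#' @param target_mask one of p-mask, q-mask, FLAIR-mask, T1c-mask.
#' @return A `model_spec`.
#' @export
model_spec <- function(model_id = 0L, input_channels = NULL, target_mask = NULL) {
  tab <- model_table()
  if (model_id >= 1L) {
    if (model_id > 16L) stop("model_id must be in 0..16")
    row <- tab[tab$model_id == model_id, ]
    if (is.null(input_channels)) input_channels <- row$channels[[1]]
    if (is.null(target_mask)) target_mask <- row$target
    if (!setequal(input_channels, row$channels[[1]]) ||
        !identical(target_mask, row$target)) {
      stop("model_id ", model_id, " requires channels {",
           paste(row$channels[[1]], collapse = ", "), "} and target ",
           row$target)
    }
  }
  if (is.null(input_channels) || is.null(target_mask)) {
    stop("input_channels and target_mask are required when model_id = 0")
  }
  bad <- setdiff(input_channels, CHANNEL_NAMES)
  if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "))
  if (!target_mask %in% MASK_NAMES) {
    stop("target_mask must be one of: ", paste(MASK_NAMES, collapse = ", "))
  }
  structure(list(model_id = as.integer(model_id),
                 input_channels = input_channels, target_mask = target_mask),
            class = "model_spec")
}

#' The sixteen-model experiment table
#'
#' Channel combinations and targets of the per-compartment experiment grid:
#' models 1-4 use all ten sequences, 5-8 the p/q/FLAIR/T1c quartet, 9-12
#' the DTI pair or the anatomical pair, and 13-16 single sequences; targets
#' cycle through p-mask, q-mask, FLAIR-mask, T1c-mask.
#'
#' @return A tibble with columns model_id, channels (list), target.
#' @export
model_table <- function() {
  all10 <- CHANNEL_NAMES
  quad <- c("p", "q", "FLAIR", "T1c")
  tibble::tibble(
    model_id = 1:16,
    channels = list(all10, all10, all10, all10,
                    quad, quad, quad, quad,
                    c("p", "q"), c("p", "q"), c("FLAIR", "T1c"), c("FLAIR", "T1c"),
                    "p", "q", "FLAIR", "T1c"),
    target = c("p-mask", "q-mask", "FLAIR-mask", "T1c-mask",
               "p-mask", "q-mask", "FLAIR-mask", "T1c-mask",
               "p-mask", "q-mask", "FLAIR-mask", "T1c-mask",
               "p-mask", "q-mask", "FLAIR-mask", "T1c-mask")
  )
}

#' Training configuration
#'
#' @param epochs number of epochs.
#' @param segments_per_epoch training patches sampled per epoch (freshly
#'   drawn and shuffled each epoch from the run seed).
#' @param batch_size patches per parameter update.
#' @param learning_rate RMSprop step size.
#' @param foreground_fraction fraction of patch centers drawn inside the
#'   target mask (class balancing; default 0.5).
#' @param augment apply random mid-sagittal reflection to patches.
#' @param seed run seed; every stochastic component (sampler, weight
#'   initialisation, augmentation) draws from a named substream of it.
#' @return A `train_config`.
#' @export
train_config <- function(epochs = 5L, segments_per_epoch = 100L,
                         batch_size = 10L, learning_rate = 1e-4,
                         foreground_fraction = 0.5, augment = TRUE,
                         seed = 1L) {
  stopifnot(epochs >= 1L, segments_per_epoch >= 1L, batch_size >= 1L,
            learning_rate > 0)
  if (foreground_fraction < 0 || foreground_fraction > 1) {
    stop("foreground_fraction must be in [0, 1]")
  }
  structure(list(epochs = as.integer(epochs),
                 segments_per_epoch = as.integer(segments_per_epoch),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 foreground_fraction = foreground_fraction,
                 augment = isTRUE(augment), seed = as.integer(seed)),
            class = "train_config")
}

#' Build (initialise) a network
#'
#' He-normal weight initialisation, zero biases; deterministic given
#' (config, seed).
#'
#' @param config a [network_config()].
#' @param seed initialisation seed.
#' @return A `pqseg_model` holding the configuration, a flat named parameter
#'   list, and the normalization procedure identifier used at inference.
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  k <- config$kernel_size
  nc <- length(config$input_channels)
  params <- list()
  with_seed(seed, {
    for (pw in c("N", "C")) {
      cin <- nc
      for (i in seq_len(config$n_feature_layers)) {
        cout <- config$features[i]
        fan_in <- k^3 * cin
        params[[sprintf("%s%d.W", pw, i)]] <-
          array(rnorm(k^3 * cin * cout, 0, sqrt(2 / fan_in)),
                c(k, k, k, cin, cout))
        params[[sprintf("%s%d.b", pw, i)]] <- numeric(cout)
        cin <- cout
      }
    }
    cat_c <- 2L * config$features[config$n_feature_layers]
    widths <- c(cat_c, rep(config$fc_features, config$n_fc_layers))
    for (j in seq_len(config$n_fc_layers)) {
      params[[sprintf("fc%d.W", j)]] <-
        array(rnorm(widths[j] * widths[j + 1], 0, sqrt(2 / widths[j])),
              c(1, 1, 1, widths[j], widths[j + 1]))
      params[[sprintf("fc%d.b", j)]] <- numeric(widths[j + 1])
    }
    wlast <- widths[length(widths)]
    params[["cls.W"]] <- array(rnorm(wlast * config$n_classes, 0,
                                     sqrt(2 / wlast)),
                               c(1, 1, 1, wlast, config$n_classes))
    params[["cls.b"]] <- numeric(config$n_classes)
  })
  structure(list(config = config, params = params, opt_state = NULL,
                 norm_procedure = "zscore-foreground", seed = as.integer(seed)),
            class = "pqseg_model")
}

#' @export
print.pqseg_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat("<pqseg_model> ", length(x$config$input_channels), " input channel(s), ",
      np, " parameters, output lattice ", x$config$output_size, "^3\n", sep = "")
  invisible(x)
}

# ---- array helpers -------------------------------------------------------

relu <- function(x) pmax(x, 0)

crop_center4 <- function(a, m) {
  d <- dim(a)
  a[(m + 1):(d[1] - m), (m + 1):(d[2] - m), (m + 1):(d[3] - m), , drop = FALSE]
}

upsample_rep <- function(a, f) {
  d <- dim(a)
  a[rep(seq_len(d[1]), each = f), rep(seq_len(d[2]), each = f),
    rep(seq_len(d[3]), each = f), , drop = FALSE]
}

downsample_grad <- function(g, f) {
  d <- dim(g)
  X <- d[1] %/% f; Y <- d[2] %/% f; Z <- d[3] %/% f
  out <- array(0, c(X, Y, Z, d[4]))
  for (i in seq_len(f)) for (j in seq_len(f)) for (k in seq_len(f)) {
    out <- out + g[seq(i, by = f, length.out = X),
                   seq(j, by = f, length.out = Y),
                   seq(k, by = f, length.out = Z), , drop = FALSE]
  }
  out
}

downsample_mean <- function(a, f) downsample_grad(a, f) / f^3

# Extract a block of `size` starting at (1-based) `start`, zero-padding
# where the block extends beyond the volume.
extract_padded <- function(vol, start, size) {
  d <- dim(vol)
  out <- array(0, size)
  lo <- pmax(start, 1L)
  hi <- pmin(start + size - 1L, d)
  if (all(lo <= hi)) {
    out[(lo[1] - start[1] + 1):(hi[1] - start[1] + 1),
        (lo[2] - start[2] + 1):(hi[2] - start[2] + 1),
        (lo[3] - start[3] + 1):(hi[3] - start[3] + 1)] <-
      vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  }
  out
}

stack_channels <- function(vols, start, size) {
  arr <- array(0, c(size, length(vols)))
  for (ci in seq_along(vols)) {
    arr[, , , ci] <- extract_padded(vols[[ci]], start, size)
  }
  arr
}

# ---- forward / backward --------------------------------------------------

fwd_pathway <- function(x, params, prefix, config) {
  k <- config$kernel_size
  acts <- vector("list", config$n_feature_layers + 1L)
  zs <- vector("list", config$n_feature_layers)
  acts[[1]] <- x
  for (i in seq_len(config$n_feature_layers)) {
    z <- conv3d_fw(acts[[i]], params[[sprintf("%s%d.W", prefix, i)]],
                   params[[sprintf("%s%d.b", prefix, i)]])
    a <- relu(z)
    if (i %in% config$residual_layers) {
      src <- crop_center4(acts[[i - 1]], k - 1L)
      cmin <- min(dim(src)[4], dim(a)[4])
      a[, , , seq_len(cmin)] <- a[, , , seq_len(cmin), drop = FALSE] +
        src[, , , seq_len(cmin), drop = FALSE]
    }
    zs[[i]] <- z
    acts[[i + 1]] <- a
  }
  list(acts = acts, zs = zs)
}

bwd_pathway <- function(g_top, cache, params, prefix, config, grads) {
  k <- config$kernel_size
  L <- config$n_feature_layers
  gacc <- vector("list", L + 1L)
  gacc[[L + 1L]] <- g_top
  for (i in L:1) {
    g <- gacc[[i + 1L]]
    if (i %in% config$residual_layers) {
      src_dim <- dim(cache$acts[[i - 1L]])
      cmin <- min(src_dim[4], dim(g)[4])
      pad <- array(0, src_dim)
      m <- k - 1L
      pad[(m + 1):(src_dim[1] - m), (m + 1):(src_dim[2] - m),
          (m + 1):(src_dim[3] - m), seq_len(cmin)] <-
        g[, , , seq_len(cmin), drop = FALSE]
      gacc[[i - 1L]] <- if (is.null(gacc[[i - 1L]])) pad else gacc[[i - 1L]] + pad
    }
    grelu <- g * (cache$zs[[i]] > 0)
    bw <- conv3d_bw(cache$acts[[i]], params[[sprintf("%s%d.W", prefix, i)]],
                    grelu, need_gx = i > 1L)
    wk <- sprintf("%s%d.W", prefix, i); bk <- sprintf("%s%d.b", prefix, i)
    grads[[wk]] <- if (is.null(grads[[wk]])) bw$gw else grads[[wk]] + bw$gw
    grads[[bk]] <- if (is.null(grads[[bk]])) bw$gb else grads[[bk]] + bw$gb
    if (i > 1L) {
      gacc[[i]] <- if (is.null(gacc[[i]])) bw$gx else gacc[[i]] + bw$gx
    }
  }
  grads
}

# Full forward pass on one (normal, context-downsampled) patch pair.
# Returns per-voxel class scores and, optionally, the cache for backward.
forward_net <- function(model, xn, xc, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  f <- cfg$downsample_factor
  pn <- fwd_pathway(xn, p, "N", cfg)
  pc <- fwd_pathway(xc, p, "C", cfg)
  an <- pn$acts[[cfg$n_feature_layers + 1L]]
  ac <- pc$acts[[cfg$n_feature_layers + 1L]]
  up <- upsample_rep(ac, f)
  dn <- dim(an)
  xf <- array(c(an, up), c(dn[1:3], dn[4] * 2L))
  fz <- list(); fa <- list(xf)
  for (j in seq_len(cfg$n_fc_layers)) {
    z <- conv3d_fw(fa[[j]], p[[sprintf("fc%d.W", j)]], p[[sprintf("fc%d.b", j)]])
    a <- relu(z)
    if (j == 2L && dim(a)[4] == dim(fa[[j]])[4]) a <- a + fa[[j]]  # fc residual
    fz[[j]] <- z
    fa[[j + 1L]] <- a
  }
  scores <- conv3d_fw(fa[[cfg$n_fc_layers + 1L]], p[["cls.W"]], p[["cls.b"]])
  out <- list(scores = scores)
  if (keep_cache) {
    out$cache <- list(pn = pn, pc = pc, xf = xf, fz = fz, fa = fa)
  }
  out
}

backward_net <- function(model, cache, gscores) {
  cfg <- model$config
  p <- model$params
  grads <- list()
  nfc <- cfg$n_fc_layers
  bw <- conv3d_bw(cache$fa[[nfc + 1L]], p[["cls.W"]], gscores, need_gx = TRUE)
  grads[["cls.W"]] <- bw$gw; grads[["cls.b"]] <- bw$gb
  g <- bw$gx
  for (j in nfc:1) {
    gdirect <- NULL
    if (j == 2L && dim(cache$fa[[j + 1L]])[4] == dim(cache$fa[[j]])[4]) {
      gdirect <- g  # fc residual skip
    }
    grelu <- g * (cache$fz[[j]] > 0)
    bw <- conv3d_bw(cache$fa[[j]], p[[sprintf("fc%d.W", j)]], grelu,
                    need_gx = TRUE)
    grads[[sprintf("fc%d.W", j)]] <- bw$gw
    grads[[sprintf("fc%d.b", j)]] <- bw$gb
    g <- if (is.null(gdirect)) bw$gx else bw$gx + gdirect
  }
  cl <- cfg$features[cfg$n_feature_layers]
  gan <- g[, , , seq_len(cl), drop = FALSE]
  gup <- g[, , , cl + seq_len(cl), drop = FALSE]
  gac <- downsample_grad(gup, cfg$downsample_factor)
  grads <- bwd_pathway(gan, cache$pn, p, "N", cfg, grads)
  grads <- bwd_pathway(gac, cache$pc, p, "C", cfg, grads)
  grads
}

# Softmax over the class (4th) dimension.
softmax4 <- function(scores) {
  d <- dim(scores)
  m <- matrix(scores, ncol = d[4])
  m <- exp(m - apply(m, 1, max))
  array(m / rowSums(m), d)
}

# Cross-entropy loss and score gradient for integer labels (1..n_classes).
softmax_ce <- function(scores, labels) {
  d <- dim(scores)
  n <- prod(d[1:3])
  pm <- matrix(softmax4(scores), ncol = d[4])
  li <- cbind(seq_len(n), as.vector(labels))
  loss <- -mean(log(pmax(pm[li], 1e-12)))
  gm <- pm
  gm[li] <- gm[li] - 1
  list(loss = loss, grad = array(gm / n, d))
}

# ---- patch sampling ------------------------------------------------------

# Normalized channel volumes + target mask + cached foreground indices for
# one study, in the channel order of the model spec.
prep_study <- function(entry, spec) {
  ch <- entry$study$channels
  missing <- setdiff(spec$input_channels, names(ch))
  if (length(missing)) {
    stop("study '", entry$study$study_id, "' is missing channel(s): ",
         paste(missing, collapse = ", "))
  }
  vols <- lapply(spec$input_channels, function(nm) {
    v <- ch[[nm]]
    if (stats::sd(v) == 0) return(v - mean(v))  # constant channel: center only
    zscore_normalize(v, channel = nm)$volume
  })
  names(vols) <- spec$input_channels
  mask <- entry$masks$masks[[spec$target_mask]]
  if (is.null(mask)) {
    stop("study '", entry$study$study_id, "' has no mask '", spec$target_mask, "'")
  }
  list(vols = vols, mask = mask, fg = which(mask == 1L),
       dim = dim(mask), study_id = entry$study$study_id)
}

# Sample one training patch (normal + downsampled context + label lattice).
# Boundary centers are shifted inward so the normal patch fits the volume.
sample_patch <- function(ps, cfg, foreground, augment) {
  d <- ps$dim
  P <- cfg$normal_patch_size
  if (any(d < P)) stop("volume ", paste(d, collapse = "x"),
                       " smaller than the normal patch ", P)
  if (foreground && length(ps$fg)) {
    v <- ps$fg[sample.int(length(ps$fg), 1L)]
    ctr <- as.integer(arrayInd(v, d))
  } else {
    ctr <- c(sample.int(d[1], 1L), sample.int(d[2], 1L), sample.int(d[3], 1L))
  }
  O <- cfg$output_size; mg <- cfg$margin; f <- cfg$downsample_factor
  o0 <- ctr - (O - 1L) %/% 2L
  s <- pmin(pmax(o0 - mg, 1L), d - P + 1L)   # normal patch start, clamped
  o0 <- s + mg
  xn <- stack_channels(ps$vols, s, rep(P, 3L))
  cs <- o0 - f * mg
  xc_full <- stack_channels(ps$vols, cs, rep(cfg$context_patch_size, 3L))
  xc <- downsample_mean(xc_full, f)
  lab <- extract_padded(ps$mask, o0, rep(O, 3L)) + 1L  # 1 = background, 2 = target
  if (augment && stats::runif(1) < 0.5) {
    xn <- xn[P:1, , , , drop = FALSE]
    xc <- xc[dim(xc)[1]:1, , , , drop = FALSE]
    lab <- lab[O:1, , , drop = FALSE]
  }
  list(xn = xn, xc = xc, labels = array(as.integer(lab), rep(O, 3L)),
       center = ctr, study_id = ps$study_id)
}

#' Extract a batch of training segments
#'
#' DeepMedic-style class-balanced segment sampling: approximately
#' `foreground_fraction` of patch centers lie inside the target mask, patch
#' extraction never indexes outside the volume (normal-patch centers are
#' shifted inward; the wider context is zero-padded), channels follow the
#' model spec's order, and reflection augmentation is applied per patch with
#' probability 0.5 when enabled.
#'
#' @param cohort list of study entries (each with `study` and `masks`).
#' @param spec a [model_spec()].
#' @param config a [network_config()] (its input channels must match).
#' @param tc a [train_config()].
#' @param n_patches number of segments to draw.
#' @param seed sampling seed (default from `tc`).
#' @return A `patch_batch`: `normal_patches` (batch, x, y, z, channel),
#'   `context_patches` (batch at downsampled resolution), `labels`
#'   (batch, x, y, z; 1 background / 2 target), and a `provenance` tibble.
#' @export
extract_segments <- function(cohort, spec, config, tc, n_patches = 100L,
                             seed = tc$seed) {
  prepped <- lapply(cohort, prep_study, spec = spec)
  if (!any(vapply(prepped, function(p) length(p$fg) > 0L, logical(1)))) {
    stop("target mask '", spec$target_mask, "' is empty across the cohort")
  }
  P <- config$normal_patch_size
  Lo <- config$low_patch_size
  O <- config$output_size
  nc <- length(spec$input_channels)
  xn <- array(0, c(n_patches, P, P, P, nc))
  xc <- array(0, c(n_patches, Lo, Lo, Lo, nc))
  lab <- array(1L, c(n_patches, O, O, O))
  prov <- vector("list", n_patches)
  with_seed(seed, {
    for (b in seq_len(n_patches)) {
      si <- sample.int(length(prepped), 1L)
      fg <- stats::runif(1) < tc$foreground_fraction
      pt <- sample_patch(prepped[[si]], config, fg, tc$augment)
      xn[b, , , , ] <- pt$xn
      xc[b, , , , ] <- pt$xc
      lab[b, , , ] <- pt$labels
      prov[[b]] <- tibble::tibble(study_id = pt$study_id,
                                  center_x = pt$center[1],
                                  center_y = pt$center[2],
                                  center_z = pt$center[3])
    }
  })
  structure(list(normal_patches = xn, context_patches = xc, labels = lab,
                 provenance = dplyr::bind_rows(prov)),
            class = "patch_batch")
}

# ---- training ------------------------------------------------------------

rmsprop_step <- function(model, grads, lr, rho = 0.9, eps = 1e-6) {
  if (is.null(model$opt_state)) {
    model$opt_state <- lapply(model$params, function(p) p * 0)
  }
  for (nm in names(grads)) {
    g <- grads[[nm]]
    v <- rho * model$opt_state[[nm]] + (1 - rho) * g^2
    model$opt_state[[nm]] <- v
    model$params[[nm]] <- model$params[[nm]] - lr * g / (sqrt(v) + eps)
  }
  model
}

#' Train a segmentation model
#'
#' Class-balanced segments are freshly drawn and shuffled each epoch from
#' the run seed; parameters are updated by RMSprop on the voxelwise
#' cross-entropy. The history records per-epoch mean training loss and, when
#' a validation cohort is given, the mean validation Dice from dense
#' inference.
#'
#' @param model a [build_network()] model.
#' @param cohort_train,cohort_val lists of study entries (`cohort_val` may
#'   be empty).
#' @param spec a [model_spec()]; its channels must match the model config.
#' @param tc a [train_config()].
#' @return list with the trained `model` and a `history` tibble
#'   (epoch, train_loss, val_dice).
#' @export
train_model <- function(model, cohort_train, cohort_val, spec, tc) {
  stopifnot(inherits(model, "pqseg_model"), inherits(tc, "train_config"))
  if (!identical(model$config$input_channels, spec$input_channels)) {
    stop("model config channels do not match the model spec")
  }
  if (!length(cohort_train)) stop("empty training cohort")
  cfg <- model$config
  prepped <- lapply(cohort_train, prep_study, spec = spec)
  if (!any(vapply(prepped, function(p) length(p$fg) > 0L, logical(1)))) {
    stop("target mask '", spec$target_mask, "' is empty across the cohort")
  }
  history <- vector("list", tc$epochs)
  for (ep in seq_len(tc$epochs)) {
    losses <- numeric(tc$segments_per_epoch)
    with_seed(seed_stream(tc$seed, ep), {
      done <- 0L
      while (done < tc$segments_per_epoch) {
        nb <- min(tc$batch_size, tc$segments_per_epoch - done)
        grads <- NULL
        for (b in seq_len(nb)) {
          si <- sample.int(length(prepped), 1L)
          fg <- stats::runif(1) < tc$foreground_fraction
          pt <- sample_patch(prepped[[si]], cfg, fg, tc$augment)
          fw <- forward_net(model, pt$xn, pt$xc, keep_cache = TRUE)
          ce <- softmax_ce(fw$scores, pt$labels)
          if (!is.finite(ce$loss)) {
            stop("training diverged (non-finite loss) at epoch ", ep)
          }
          losses[done + b] <- ce$loss
          g <- backward_net(model, fw$cache, ce$grad)
          grads <- if (is.null(grads)) g else {
            for (nm in names(g)) grads[[nm]] <- grads[[nm]] + g[[nm]]
            grads
          }
        }
        for (nm in names(grads)) grads[[nm]] <- grads[[nm]] / nb
        model <- rmsprop_step(model, grads, tc$learning_rate)
        done <- done + nb
      }
    })
    vd <- NA_real_
    if (length(cohort_val)) {
      vd <- mean(vapply(cohort_val, function(e) {
        pr <- predict_study(model, e$study, spec)
        dice(pr$binary_mask, e$masks$masks[[spec$target_mask]])
      }, numeric(1)))
    }
    history[[ep]] <- tibble::tibble(epoch = ep, train_loss = mean(losses),
                                    val_dice = vd)
  }
  list(model = model, history = dplyr::bind_rows(history))
}

# ---- inference -----------------------------------------------------------

#' Dense whole-volume prediction
#'
#' Assembles a full-volume class-probability map by tiling the output
#' lattice. Tile starts lie on a grid whose stride is divisible by the
#' downsample factor, so the context pathway's pooling blocks align across
#' tiles and tiled inference equals untiled inference away from the volume
#' border (where zero padding enters). Channels are normalized with the
#' training-time procedure (per-channel foreground z-scores).
#'
#' @param model a trained `pqseg_model`.
#' @param study a [multi_sequence_study()].
#' @param spec the [model_spec()] used in training.
#' @param tile_output output-tile edge; must be a multiple of the downsample
#'   factor. `NULL` picks a default; `Inf` runs a single untiled pass.
#' @return A `segmentation_result`: `probability` (x, y, z, class),
#'   `binary_mask` (target probability >= 0.5), and `model_spec`.
#' @export
predict_study <- function(model, study, spec, tile_output = NULL) {
  stopifnot(inherits(model, "pqseg_model"),
            inherits(study, "multi_sequence_study"))
  cfg <- model$config
  f <- cfg$downsample_factor
  d <- dim(study$channels[[1]])
  entry <- list(study = study,
                masks = list(masks = stats::setNames(
                  list(array(0L, d)), spec$target_mask)))
  ps <- prep_study(entry, spec)

  if (is.null(tile_output)) tile_output <- 12L * f
  if (is.infinite(tile_output)) {
    tile_output <- as.integer(f * ceiling(max(d) / f))
  }
  Ot <- as.integer(tile_output)
  if (Ot %% f != 0L) {
    stop("tile_output must be divisible by downsample_factor = ", f)
  }
  mg <- cfg$margin
  Pn <- Ot + cfg$shrink
  ctx <- Ot + f * cfg$shrink

  prob <- array(0, c(d, cfg$n_classes))
  starts <- lapply(1:3, function(a) seq(1L, d[a], by = Ot))
  for (z0 in starts[[3]]) for (y0 in starts[[2]]) for (x0 in starts[[1]]) {
    o0 <- c(x0, y0, z0)
    xn <- stack_channels(ps$vols, o0 - mg, rep(Pn, 3L))
    xc <- downsample_mean(stack_channels(ps$vols, o0 - f * mg, rep(ctx, 3L)), f)
    sc <- forward_net(model, xn, xc)$scores
    pr <- softmax4(sc)
    keep <- pmin(rep(Ot, 3L), d - o0 + 1L)
    prob[o0[1]:(o0[1] + keep[1] - 1L), o0[2]:(o0[2] + keep[2] - 1L),
         o0[3]:(o0[3] + keep[3] - 1L), ] <-
      pr[seq_len(keep[1]), seq_len(keep[2]), seq_len(keep[3]), , drop = FALSE]
  }
  structure(list(probability = prob,
                 binary_mask = array(as.integer(prob[, , , 2L] >= 0.5), d),
                 model_spec = spec),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("<segmentation_result> target ", x$model_spec$target_mask, ", ",
      sum(x$binary_mask), " voxels segmented\n", sep = "")
  invisible(x)
}

#' Merge per-compartment segmentations into one label volume
#'
#' Each voxel receives the highest-priority target whose binary mask is set,
#' else background (0). The default priority orders the compartments from
#' innermost to outermost tumor biology: enhancing core, tumor bulk,
#' edema/non-enhancing, invasion.
#'
#' @param results list of `segmentation_result`s on one grid.
#' @param priority ordered target names, highest priority first; must cover
#'   all supplied targets.
#' @param grid grid dimensions, required when `results` is empty.
#' @return Integer label array; 0 is background, label i is `priority[i]`
#'   (stored in the `"targets"` attribute).
#' @export
merge_predictions <- function(results,
                              priority = c("T1c-mask", "q-mask",
                                           "FLAIR-mask", "p-mask"),
                              grid = NULL) {
  if (!length(results)) {
    if (is.null(grid)) stop("grid dimensions required for an empty result list")
    out <- array(0L, grid)
    attr(out, "targets") <- priority
    return(out)
  }
  d <- dim(results[[1]]$binary_mask)
  targets <- vapply(results, function(r) r$model_spec$target_mask, character(1))
  if (!all(targets %in% priority)) {
    stop("priority must cover all supplied targets; missing: ",
         paste(setdiff(targets, priority), collapse = ", "))
  }
  out <- array(0L, d)
  for (t in rev(priority)) {                 # low priority first, overwritten
    i <- which(targets == t)
    if (!length(i)) next
    m <- results[[i[1]]]$binary_mask
    if (!identical(dim(m), d)) stop("grid mismatch across results")
    out[m == 1L] <- match(t, priority)
  }
  attr(out, "targets") <- priority
  out
}
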