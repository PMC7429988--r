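#' Read a NIfTI volume
#'
#' @param path a NIfTI-1/2 file (.nii or .nii.gz).
#' @param expect_dims required dimensionality (3 or 4), or NULL for any.
#' @return list with `data` (numeric array in native orientation), `affine`
#'   (4 x 4 voxel-to-world), and `voxel_size` (mm).
#' @export
read_volume <- function(path, expect_dims = NULL) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  d <- dim(img)
  if (!is.null(expect_dims) && length(d) != expect_dims) {
    stop("'", path, "' is ", length(d), "-D where ", expect_dims,
         "-D was expected")
  }
  affine <- structure(RNifti::xform(img), class = "matrix")
  attr(affine, "code") <- NULL
  list(data = array(as.numeric(img), d),
       affine = unclass(affine)[1:4, 1:4],
       voxel_size = RNifti::pixdim(img)[seq_len(min(3L, length(d)))])
}

#' Write a NIfTI volume
#'
#' Intensities are stored as float32; masks (binary content or
#' `datatype = "mask"`) as uint8.
#'
#' @param lattice finite numeric array (3-D or 4-D).
#' @param affine 4 x 4 voxel-to-world matrix.
#' @param path output path (.nii or .nii.gz).
#' @param datatype `"auto"`, `"float"`, or `"mask"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(lattice, affine, path,
                         datatype = c("auto", "float", "mask")) {
  datatype <- match.arg(datatype)
  if (!all(is.finite(lattice))) {
    stop("refusing to write non-finite values to '", path, "'")
  }
  if (datatype == "auto") {
    datatype <- if (all(lattice %in% c(0, 1))) "mask" else "float"
  }
  img <- RNifti::asNifti(array(as.numeric(lattice), dim(lattice)))
  RNifti::pixdim(img) <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path,
                     datatype = if (datatype == "mask") "uint8" else "float")
  invisible(path)
}

#' Read FSL-style bvals/bvecs sidecars
#'
#' `bvals` is one space-separated row of M values; `bvecs` three rows of M
#' direction components.
#'
#' @param bvals_path,bvecs_path sidecar file paths.
#' @return A [diffusion_protocol()].
#' @export
read_bvals_bvecs <- function(bvals_path, bvecs_path) {
  bvals <- scan(bvals_path, quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvecs_path))
  if (nrow(bv) != 3L) stop("bvecs must have 3 rows (", bvecs_path, ")")
  diffusion_protocol(bvals, t(unname(bv)))
}

#' Write bvals/bvecs sidecars
#'
#' @param protocol a [diffusion_protocol()].
#' @param bvals_path,bvecs_path output paths.
#' @return invisibly, the two paths.
#' @export
write_bvals_bvecs <- function(protocol, bvals_path, bvecs_path) {
  writeLines(paste(protocol$bvals, collapse = " "), bvals_path)
  writeLines(apply(t(protocol$bvecs), 1, paste, collapse = " "), bvecs_path)
  invisible(c(bvals_path, bvecs_path))
}

#' Write a study (and masks) to disk with a JSON manifest
#'
#' Each channel and mask is stored as one NIfTI file; the manifest records
#' study id, relative paths, and a provenance block.
#'
#' @param study a [multi_sequence_study()].
#' @param masks optional [mask_set()].
#' @param dir output directory (created if missing).
#' @param provenance named list recorded verbatim in the manifest.
#' @return Path of the manifest JSON.
#' @export
write_manifest <- function(study, masks = NULL, dir, provenance = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ch_paths <- list()
  for (nm in names(study$channels)) {
    fn <- paste0(gsub("[^A-Za-z0-9]", "_", nm), ".nii.gz")
    write_volume(study$channels[[nm]], study$affine, file.path(dir, fn),
                 datatype = "float")
    ch_paths[[nm]] <- fn
  }
  mk_paths <- list()
  if (!is.null(masks)) {
    for (nm in names(masks$masks)) {
      fn <- paste0(gsub("[^A-Za-z0-9]", "_", nm), ".nii.gz")
      write_volume(masks$masks[[nm]], study$affine, file.path(dir, fn),
                   datatype = "mask")
      mk_paths[[nm]] <- fn
    }
  }
  manifest <- list(study_id = study$study_id,
                   voxel_size = study$voxel_size,
                   affine = study$affine,
                   channels = ch_paths, masks = mk_paths,
                   provenance = provenance)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Load a study (and masks) from a JSON manifest
#'
#' @param path manifest path written by [write_manifest()].
#' @return list with `study`, `masks` (NULL when none), and `provenance`.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  dir <- dirname(path)
  for (fn in c(unlist(m$channels), unlist(m$masks))) {
    if (!file.exists(file.path(dir, fn))) {
      stop("manifest references missing file: ", fn)
    }
  }
  channels <- lapply(m$channels, function(fn) {
    read_volume(file.path(dir, fn), expect_dims = 3L)$data
  })
  affine <- matrix(unlist(m$affine), 4, 4)
  study <- multi_sequence_study(channels, affine = affine,
                                voxel_size = as.numeric(m$voxel_size),
                                study_id = m$study_id)
  masks <- NULL
  if (length(m$masks)) {
    mk <- lapply(m$masks, function(fn) {
      read_volume(file.path(dir, fn), expect_dims = 3L)$data
    })
    masks <- mask_set(mk)
  }
  list(study = study, masks = masks, provenance = m$provenance)
}

# ---- configuration -------------------------------------------------------

config_defaults <- function() {
  list(
    phantom = list(grid_shape = c(64, 64, 32), voxel_size = c(2, 2, 2),
                   noise_sigma = 20, s0_mean = 1000, seed = 1),
    network = list(kernel_size = 5, n_feature_layers = 4,
                   features = c(30, 30, 40, 40), fc_features = 40,
                   n_fc_layers = 2, downsample_factor = 3,
                   normal_patch_size = 25, n_classes = 2),
    train = list(epochs = 5, segments_per_epoch = 100, batch_size = 10,
                 learning_rate = 1e-4, foreground_fraction = 0.5,
                 augment = TRUE, seed = 1),
    split = list(fractions = c(40, 10, 30), seed = 1),
    p_scale = "sqrt3",
    background_threshold = 0.05
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML (or JSON) configuration with sections `phantom`, `network`,
#' `train`, `split` and top-level options `p_scale`,
#' `background_threshold`; fills defaults, rejects unknown keys, and
#' validates each section against its constructor's invariants. An empty
#' file yields the full default configuration.
#'
#' @param path YAML/JSON file path, or NULL for pure defaults.
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL) {
  defaults <- config_defaults()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  bad <- setdiff(names(user), names(defaults))
  if (length(bad)) stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  cfg <- defaults
  for (sec in names(user)) {
    if (is.list(defaults[[sec]])) {
      badk <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
      if (length(badk)) {
        stop("unknown key(s) in '", sec, "': ", paste(badk, collapse = ", "))
      }
      cfg[[sec]][names(user[[sec]])] <- user[[sec]]
    } else {
      cfg[[sec]] <- user[[sec]]
    }
  }
  # validate through the constructors so invariant violations name their key
  tryCatch({
    do.call(phantom_spec, cfg$phantom[intersect(names(cfg$phantom),
                                                names(formals(phantom_spec)))])
  }, error = function(e) stop("phantom: ", conditionMessage(e)))
  tryCatch({
    nc <- cfg$network
    do.call(network_config, c(list(input_channels = "FLAIR"), nc))
  }, error = function(e) stop("network: ", conditionMessage(e)))
  tryCatch({
    do.call(train_config, cfg$train)
  }, error = function(e) stop("train: ", conditionMessage(e)))
  if (!cfg$p_scale %in% c("sqrt3", "literal3")) {
    stop("p_scale: must be 'sqrt3' or 'literal3'")
  }
  if (cfg$background_threshold < 0 || cfg$background_threshold >= 1) {
    stop("background_threshold: must be in [0, 1)")
  }
  cfg
}

#' Dump a configuration to YAML
#'
#' @param cfg configuration list from [load_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# Minimal structured run logging: version, config hash, seeds, inputs.
pq_log <- function(..., level = "INFO") {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", ...)
  message(msg)
  invisible(msg)
}

#' Log the reproducibility context of a run
#'
#' Emits package version, a hash of the resolved configuration, all seeds
#' and input paths to stderr — sufficient to reproduce the run.
#'
#' @param command command name.
#' @param cfg resolved configuration list.
#' @param seeds named seed vector.
#' @param inputs character vector of input paths.
#' @return invisibly, the log line.
#' @export
log_run_context <- function(command, cfg = NULL, seeds = NULL, inputs = NULL) {
  h <- if (is.null(cfg)) "none" else {
    s <- utf8ToInt(as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                                 digits = NA)))
    sprintf("%08x", sum(s * seq_along(s)) %% 4294967291)
  }
  pq_log(command, ": pqseg ",
         as.character(utils::packageVersion("pqseg")),
         ", config ", h,
         if (!is.null(seeds)) paste0(", seeds [",
                                     paste(names(seeds), seeds, sep = "=",
                                           collapse = ", "), "]") else "",
         if (length(inputs)) paste0(", inputs: ",
                                    paste(inputs, collapse = ", ")) else "")
}
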