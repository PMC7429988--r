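# Shared fixtures, generated in code and cached for the session.

.pqseg_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .pqseg_cache)) {
    assign(key, force(expr), envir = .pqseg_cache)
  }
  get(key, envir = .pqseg_cache)
}

# random symmetric positive-definite tensors at diffusivity scale (mm^2/s)
random_spd_components <- function(n, seed = 1) {
  pqseg:::with_seed(seed, t(sapply(seq_len(n), function(i) {
    A <- matrix(rnorm(9), 3)
    S <- crossprod(A) * 1e-3 / 3
    c(S[1, 1], S[2, 2], S[3, 3], S[1, 2], S[1, 3], S[2, 3])
  })))
}

components_to_matrix <- function(cmp) {
  matrix(c(cmp[1], cmp[4], cmp[5],
           cmp[4], cmp[2], cmp[6],
           cmp[5], cmp[6], cmp[3]), 3, 3)
}

random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3)))
}

# small phantom (fits the compact network geometry, fast to simulate)
tiny_phantom_spec <- function(seed = 1) {
  phantom_spec(grid_shape = c(32, 32, 24), voxel_size = c(2, 2, 2),
               radii = c(core = 3, enhancing = 5.5, bulk = 8,
                         invasion = 11, edema = 14),
               seed = seed)
}

tiny_cohort <- function(n = 4, seed = 11) {
  cached(sprintf("tiny_cohort_%d_%d", n, seed),
         generate_cohort(n, tiny_phantom_spec(), seed = seed))
}

# the desk-scale cohort used by the end-to-end experiments (shared across
# test files to avoid regenerating ~1 min of simulation)
study_cohort <- function() {
  cached("study_cohort_12", generate_cohort(12, phantom_spec(), seed = 2026))
}

tiny_net_config <- function(channels) {
  small_network_config(channels, features = c(4L, 4L, 6L, 6L), fc_features = 8L)
}
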