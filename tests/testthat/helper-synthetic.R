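# Small, fast simulation configuration for unit tests; acceptance tests use
# the package defaults.
test_config <- function(...) {
  args <- utils::modifyList(
    list(canvas = c(96L, 96L), n_roots = 10L, step_len = 4,
         branch_prob = 0.08, root_radius = 1.8),
    list(...))
  do.call(simulation_config, args)
}

test_roi <- function(config = test_config()) {
  h <- config$canvas[1]; w <- config$canvas[2]
  disk_mask(h, w, radius = config$limbus_radius_frac * (min(h, w) - 1) / 2)
}

# A flat-background frame with a bright horizontal band, handy for
# preprocessing tests.
flat_frame <- function(value = 0.4, n = 64L, modality = "OCTA") {
  image_frame(matrix(value, n, n), modality = modality)
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

clamp_test <- function(x) pmin(pmax(x, 0), 1)
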