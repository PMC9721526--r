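# Fixtures are generated in code; no files are shipped.

# random field with all-distinct values and a guaranteed minimum gap, so
# finite-difference probes and tie-breaking never cross a value boundary
rand_distinct_field <- function(shape, seed) {
  n <- prod(shape)
  withr::with_seed(seed, {
    vals <- (sample.int(n) - stats::runif(n, 0, 0.3)) / (n + 1)
    array(vals, shape)
  })
}

# 0.9-ring on 0.1 background enclosing a single interior pixel
ring_field_5x5 <- function() {
  f <- matrix(0.1, 5, 5)
  f[2:4, 2:4] <- 0.9
  f[3, 3] <- 0.1
  f
}

# annulus (0.9 on 0.1 background) with a radial slit lowered to `gap`,
# so the loop is broken at threshold 0.5 but restorable from below
ring_with_gap <- function(n = 16L, gap = 0.4) {
  s <- make_phantom("ring", c(n, n))$target
  f <- 0.1 + 0.8 * s
  cx <- (n + 1) / 2
  slit <- which(s > 0 & abs(row(s) - cx) <= 0.51 & col(s) > cx)
  f[slit] <- gap
  f
}

bar_multiset <- function(b) {
  sort(sprintf("%d|%.10f|%.10f", b$dim, b$birth, b$death))
}

# tiny training world shared by the training tests
tiny_world <- function(seed = 7L, n_lab = 2L, n_val = 2L, epochs = 6L) {
  ds <- make_dataset(n_labelled = n_lab, n_unlabelled = 2L, n_val = n_val,
                     n_test = 2L, kinds = "ring", shape = c(16L, 16L), m = 4L,
                     preserve_centre = 2L, seed = seed)
  net <- build_unet(2, depth = 1L, base_channels = 2L, seed = seed)
  cfg <- train_config(epochs = epochs, lr = 1e-3, val_interval = 2L,
                      patience = 3L, seed = seed)
  list(ds = ds, net = net, cfg = cfg)
}
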