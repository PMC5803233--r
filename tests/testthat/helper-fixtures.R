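# shared fixtures, built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# small voxelised phantom with a few particles
fix_phantom <- function() {
  fixture("phantom48", function() {
    generate_phantom(48, 3, d_min = 8, d_max = 14, seed = 11)
  })
}

# clean projections of the small phantom on a modest angle grid
fix_projections <- function() {
  fixture("proj48", function() {
    forward_project(fix_phantom(), seq(0, 180, length.out = 61),
                    method = "discrete")
  })
}

# a quick low-capacity trained model on a tiny denoising problem
fix_trained_tiny <- function() {
  fixture("tiny_model", function() {
    po <- fix_projections()
    pn <- add_noise(po, 0.2, seed = 3)
    pairs <- training_pairs(pn, po, c(0, 45))
    m <- build_network(network_spec(patch_edge = 16), seed = 5)
    m <- train_cnn(m, pairs, epochs = 8, batch_size = 16, lr = 1e-3,
                   patch_stride = 8, seed = 7)
    list(model = m, clean = po, noisy = pn)
  })
}
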