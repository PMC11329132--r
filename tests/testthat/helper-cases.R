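# Small shared fixtures, all generated in code.

# fast, fully deterministic little phantom suite
tiny_config <- function(seed = 1, n_slices = 9, size = 16, ...) {
  args <- utils::modifyList(
    list(n_slices = n_slices, n_rows = size, n_cols = size,
         shells = 1, texture_amplitude = 0, noise_sd = 0,
         texture_corr_length = 1, seed = seed),
    list(...))
  do.call(phantom_config, args)
}

tiny_case <- function(seed = 1, n_slices = 9, size = 16, k = 3, ...) {
  make_paired_case(tiny_config(seed, n_slices, size, ...), k,
                   id = sprintf("tiny%d", seed))
}

# training config small enough for unit tests (not the study profile)
tiny_train_config <- function(epochs = 1, seed = 5, ...) {
  args <- utils::modifyList(
    list(epochs = epochs, lr = 1e-3, l1_smooth = 0.05,
         generator = generator_spec(depth = 2, base_width = 4),
         discriminator = discriminator_spec(n_blocks = 2, base_width = 4),
         input_size = 16, seed = seed),
    list(...))
  do.call(training_config, args)
}

# a stub enhancer whose five position models return fixed matrices or maps
stub_enhancer <- function(fns, method = 1, k = 3) {
  enh <- copy_baseline_enhancer(k = k, method = method)
  for (pos in names(fns)) enh$models[[pos]] <- stub_generator(fns[[pos]])
  enh
}

rand_slice <- function(n = 16, m = n) {
  matrix(sample.int(4096, n * m, replace = TRUE) - 1L, n, m)
}
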