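# Random all-standard protein sequences (relies on caller's RNG state).
random_protein <- function(len) {
  paste(sample(aa_alphabet, len, replace = TRUE), collapse = "")
}

random_records <- function(n, len_range = c(40, 120)) {
  tibble::tibble(
    id = sprintf("r%03d", seq_len(n)),
    sequence = vapply(sample(len_range[1]:len_range[2], n, replace = TRUE),
                      random_protein, character(1))
  )
}

write_temp_fasta <- function(lines) {
  f <- withr::local_tempfile(fileext = ".fasta",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# Small, quickly trainable network for structural / pipeline tests.
tiny_sp_config <- function() {
  sp_model_config(n_motif_kernels = 8, motif_kernel_length = 9,
                  dense_units = 8, epochs = 4, patience = 4, restarts = 1)
}

# Lazily trained small models, shared across test files.
.fixture_env <- new.env(parent = emptyenv())

get_tiny_sp_fit <- function() {
  if (is.null(.fixture_env$sp)) {
    d <- generate_sp_dataset(16, generator_config(seed = 101))
    .fixture_env$sp <- train_sp(d, tiny_sp_config(), outer_folds = 2,
                                inner_folds = 2, seed = 3)
  }
  .fixture_env$sp
}

get_tiny_ups_fit <- function() {
  if (is.null(.fixture_env$ups)) {
    d <- generate_ups_dataset(40, 60, generator_config(seed = 102))
    feats <- dplyr::bind_cols(ups_feature_subset(generate_features(d)),
                              label = d$label)
    .fixture_env$ups <- train_ups(
      feats, grid = tibble::tibble(max_depth = 2, nrounds = 30, eta = 0.1),
      outer_folds = 3, inner_folds = 2, seed = 4
    )
  }
  .fixture_env$ups
}
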