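# Shared fixtures: small configurations that keep unit tests fast while
# exercising every code path.

tiny_sim_config <- function(...) {
  args <- utils::modifyList(
    list(frame_size = 32, n_frames = 4, background_noise_sd = 0,
         motion_artifact_prob = 0),
    list(...)
  )
  do.call(simulator_config, args)
}

tiny_model_config <- function(...) {
  args <- utils::modifyList(
    list(n_encoder_layers = 2, n_heads = 2, model_dim = 8,
         feedforward_dim = 12, conv_kernel = 3, conv_channels = 5,
         dropout = 0, max_len = 32),
    list(...)
  )
  do.call(temporal_model_config, args)
}

tiny_backbone <- function(seed = 42) {
  backbone_spec("tiny_test_cnn", input_size = 32, seed = seed)
}

# An empty scene layout for direct render_frame() calls.
empty_layout <- function() {
  list(cells = tibble::tibble(x = numeric(0), y = numeric(0),
                              radius = numeric(0), rx = numeric(0),
                              ry = numeric(0), theta = numeric(0)),
       rbc = tibble::tibble(x = numeric(0), y = numeric(0),
                            radius = numeric(0)))
}

cell_layout <- function(x, y, r, e = 0, theta = 0) {
  list(cells = tibble::tibble(x = x, y = y, radius = r,
                              rx = r * (1 + e), ry = r / (1 + e),
                              theta = theta),
       rbc = tibble::tibble(x = numeric(0), y = numeric(0),
                            radius = numeric(0)))
}

# Random feature matrix with reproducible content.
random_features <- function(tt, d, seed = 1) {
  set.seed(seed)
  matrix(rnorm(tt * d), tt, d)
}

# Small in-memory dataset for training tests.
tiny_dataset <- function(n_cases = 4, spc = 2, preset = "separated",
                         seed = 7, n_frames = 4) {
  generate_dataset(n_cases, spc,
                   config = simulator_config(frame_size = 32,
                                             n_frames = n_frames,
                                             motion_artifact_prob = 0,
                                             background_noise_sd = 0.01),
                   profiles = cle_profiles(preset), seed = seed)
}
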