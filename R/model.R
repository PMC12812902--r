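#' Configuration of the sequence-based temporal classifier
#'
#' The temporal model consumes a `T x D` sequence of per-frame visual
#' embeddings and produces one binary grade prediction per examination:
#' input projection to `model_dim`, additive positional encoding, a stack of
#' transformer encoder blocks (multihead self-attention + position-wise
#' feedforward, residual connections, layer normalization), a 1-D
#' convolution along the temporal axis, masked global average pooling into a
#' single global temporal embedding, and a fully connected softmax head.
#'
#' @param n_encoder_layers Number of transformer encoder blocks (default 2,
#'   i.e. two multihead self-attention layers).
#' @param n_heads Attention heads; must divide `model_dim`.
#' @param model_dim Width of the encoder representation.
#' @param feedforward_dim Hidden width of the position-wise feedforward.
#' @param conv_kernel Temporal convolution kernel size (odd).
#' @param conv_channels Temporal convolution output channels = length of the
#'   global embedding.
#' @param conv_activation `"relu"` (default) or `"identity"` applied to the
#'   convolution output before pooling. With `conv_kernel = 1`, an identity
#'   filter and identity activation, the whole temporal stage reduces to
#'   mean pooling over frames (the bag-of-frames ablation reference).
#' @param dropout Dropout fraction applied during training.
#' @param positional_encoding `"sinusoidal"` (parameter-free, default) or
#'   `"learned"`.
#' @param max_len Maximum supported sequence length.
#' @param n_classes Fixed at 2 (high/low grade).
#' @return An object of class `temporal_model_config`.
#' @export
temporal_model_config <- function(n_encoder_layers = 2L,
                                  n_heads = 4L,
                                  model_dim = 32L,
                                  feedforward_dim = 64L,
                                  conv_kernel = 3L,
                                  conv_channels = 32L,
                                  conv_activation = c("relu", "identity"),
                                  dropout = 0.1,
                                  positional_encoding = c("sinusoidal", "learned"),
                                  max_len = 512L,
                                  n_classes = 2L) {
  cfg <- list(
    n_encoder_layers = as.integer(n_encoder_layers),
    n_heads = as.integer(n_heads),
    model_dim = as.integer(model_dim),
    feedforward_dim = as.integer(feedforward_dim),
    conv_kernel = as.integer(conv_kernel),
    conv_channels = as.integer(conv_channels),
    conv_activation = match.arg(conv_activation),
    dropout = dropout,
    positional_encoding = match.arg(positional_encoding),
    max_len = as.integer(max_len),
    n_classes = as.integer(n_classes)
  )
  assert_that(cfg$n_classes == 2L, "only binary grading is supported")
  assert_that(cfg$model_dim %% cfg$n_heads == 0,
              "model_dim must be divisible by n_heads")
  assert_that(cfg$conv_kernel %% 2 == 1, "conv_kernel must be odd")
  assert_that(is_prob(cfg$dropout), "dropout must lie in [0, 1]")
  assert_that(cfg$n_encoder_layers >= 1 && cfg$feedforward_dim >= 1 &&
                cfg$conv_channels >= 1 && cfg$max_len >= 1,
              "layer sizes must be positive")
  class(cfg) <- "temporal_model_config"
  cfg
}

# Xavier/He-initialized flat parameter list for the temporal classifier.
init_temporal_params <- function(config, input_dim, seed = 1L) {
  d <- config$model_dim
  with_seed(seed, {
    gl <- function(fan_in, fan_out) {
      matrix(stats::rnorm(fan_in * fan_out, 0, sqrt(2 / (fan_in + fan_out))),
             fan_in, fan_out)
    }
    p <- list(proj_W = gl(input_dim, d), proj_b = rep(0, d))
    if (config$positional_encoding == "learned") {
      p$pos_P <- matrix(stats::rnorm(config$max_len * d, 0, 0.02),
                        config$max_len, d)
    }
    for (l in seq_len(config$n_encoder_layers)) {
      pre <- paste0("l", l, "_")
      for (nm in c("Wq", "Wk", "Wv", "Wo")) p[[paste0(pre, nm)]] <- gl(d, d)
      for (nm in c("bq", "bk", "bv", "bo")) p[[paste0(pre, nm)]] <- rep(0, d)
      p[[paste0(pre, "ln1_g")]] <- rep(1, d)
      p[[paste0(pre, "ln1_b")]] <- rep(0, d)
      p[[paste0(pre, "W1")]] <- gl(d, config$feedforward_dim)
      p[[paste0(pre, "b1")]] <- rep(0, config$feedforward_dim)
      p[[paste0(pre, "W2")]] <- gl(config$feedforward_dim, d)
      p[[paste0(pre, "b2")]] <- rep(0, d)
      p[[paste0(pre, "ln2_g")]] <- rep(1, d)
      p[[paste0(pre, "ln2_b")]] <- rep(0, d)
    }
    p$conv_W <- array(stats::rnorm(config$conv_kernel * d * config$conv_channels,
                                   0, sqrt(2 / (config$conv_kernel * d))),
                      dim = c(config$conv_kernel, d, config$conv_channels))
    p$conv_b <- rep(0, config$conv_channels)
    p$head_W <- gl(config$conv_channels, 2)
    p$head_b <- rep(0, 2)
    p
  })
}

#' Initialize a sequence-based temporal classification model
#'
#' @param config A [temporal_model_config()].
#' @param backbone A [backbone_spec()] supplying per-frame embeddings (its
#'   `embedding_dim` fixes the model's input width).
#' @param seed Seed for weight initialization.
#' @return An object of class `cle_temporal_model`.
#' @export
init_temporal_model <- function(config = temporal_model_config(),
                                backbone = backbone_spec(),
                                seed = 1L) {
  stopifnot(inherits(config, "temporal_model_config"),
            inherits(backbone, "backbone_spec"))
  structure(
    list(config = config, backbone = backbone,
         input_dim = backbone$embedding_dim,
         params = init_temporal_params(config, backbone$embedding_dim, seed),
         scaling = NULL),
    class = "cle_temporal_model"
  )
}

# Per-dimension z-scoring fitted on the training frames. Raw backbone
# embeddings are orders of magnitude smaller than the positional encoding;
# without standardization the temporal signal would be drowned out.
fit_feature_scaling <- function(feature_list) {
  X <- do.call(rbind, lapply(feature_list, unclass_features))
  mu <- colMeans(X)
  sdv <- pmax(apply(X, 2, stats::sd), 1e-8)
  list(mean = mu, sd = sdv)
}

apply_feature_scaling <- function(x, scaling) {
  if (is.null(scaling)) return(x)
  sweep(sweep(x, 2, scaling$mean, "-"), 2, scaling$sd, "/")
}

#' @export
print.cle_temporal_model <- function(x, ...) {
  cat(sprintf(paste0("<cle_temporal_model> %d encoder layer(s), %d heads, ",
                     "model_dim %d, conv k=%d -> %d channels; backbone %s (D=%d)\n"),
              x$config$n_encoder_layers, x$config$n_heads, x$config$model_dim,
              x$config$conv_kernel, x$config$conv_channels,
              x$backbone$family, x$input_dim))
  invisible(x)
}

label_levels <- c("high", "low")

label_to_index <- function(label) {
  assert_that(all(label %in% label_levels),
              "labels must be 'high' or 'low'")
  match(label, label_levels)
}

new_grade_prediction <- function(logits, frame_detail = NULL) {
  assert_that(all(is.finite(logits)), "non-finite logits")
  probs <- softmax_vec(logits)
  structure(
    list(prob_high = probs[1], prob_low = probs[2],
         label = label_levels[which.max(probs)],
         logits = logits, frame_detail = frame_detail),
    class = "grade_prediction"
  )
}

#' @export
print.grade_prediction <- function(x, ...) {
  cat(sprintf("<grade_prediction> %s (p_high = %.3f, p_low = %.3f)\n",
              x$label, x$prob_high, x$prob_low))
  invisible(x)
}

#' Add positional encoding to a feature sequence
#'
#' Adds position-dependent offsets so the (otherwise permutation-equivariant)
#' attention layers can distinguish temporal order. Sinusoidal mode uses the
#' closed form `sin(p / 10000^(2i/D))` / `cos(p / 10000^(2i/D))` with
#' zero-based position `p` and dimension pair index `i`; learned mode adds a
#' trained per-position table taken from `model`.
#'
#' @param features `T x D` numeric matrix (already projected to the model
#'   width for learned mode).
#' @param mode `"sinusoidal"` or `"learned"`.
#' @param model A `cle_temporal_model`; required for `"learned"`.
#' @return `T x D` matrix, `features` plus the positional table.
#' @export
add_positional_encoding <- function(features,
                                    mode = c("sinusoidal", "learned"),
                                    model = NULL) {
  mode <- match.arg(mode)
  features <- as.matrix(features)
  tt <- nrow(features); d <- ncol(features)
  if (mode == "sinusoidal") {
    return(features + sinusoidal_encoding(tt, d))
  }
  assert_that(!is.null(model) && !is.null(model$params$pos_P),
              "learned positional encoding requires a model carrying pos_P")
  assert_that(tt <= nrow(model$params$pos_P), "sequence exceeds max_len")
  features + model$params$pos_P[seq_len(tt), , drop = FALSE]
}

# Run only the encoder stack (projection and positional encoding are assumed
# already applied when called standalone on model_dim-wide input).
encoder_stack <- function(params, config, h, mask) {
  for (l in seq_len(config$n_encoder_layers)) {
    pre <- paste0("l", l, "_")
    att <- mha_fwd(h, params, pre, config$n_heads, mask)
    h <- layernorm_fwd(h + att$out, params[[paste0(pre, "ln1_g")]],
                       params[[paste0(pre, "ln1_b")]])$y
    z <- sweep(h %*% params[[paste0(pre, "W1")]], 2,
               params[[paste0(pre, "b1")]], "+")
    f <- sweep(pmax(z, 0) %*% params[[paste0(pre, "W2")]], 2,
               params[[paste0(pre, "b2")]], "+")
    h <- layernorm_fwd(h + f, params[[paste0(pre, "ln2_g")]],
                       params[[paste0(pre, "ln2_b")]])$y
  }
  h
}

#' Contextualize a feature sequence with the transformer encoder
#'
#' Applies the model's encoder blocks to a `T x model_dim` sequence (to which
#' positional encoding has already been added), modeling dependencies across
#' frames. Padded positions, marked `FALSE` in `mask`, are excluded from the
#' attention of real positions and cannot influence their outputs.
#'
#' @param features `T x model_dim` matrix.
#' @param model A `cle_temporal_model`.
#' @param mask Logical vector, `TRUE` for real frames; default all real.
#' @return `T x model_dim` matrix of contextualized embeddings.
#' @export
encode_temporal <- function(features, model, mask = NULL) {
  stopifnot(inherits(model, "cle_temporal_model"))
  features <- as.matrix(features)
  assert_that(ncol(features) == model$config$model_dim,
              "features must be model_dim wide (use add_positional_encoding after projection)")
  mask <- mask %||% rep(TRUE, nrow(features))
  assert_that(length(mask) == nrow(features), "mask/feature length mismatch")
  encoder_stack(model$params, model$config, features, mask)
}

#' Aggregate an encoded sequence into the global temporal embedding
#'
#' 1-D convolution along the temporal axis (same-padded, odd kernel) captures
#' local temporal patterns; the activation output is then average-pooled over
#' the unpadded positions, compressing the sequence into one
#' `conv_channels`-long global embedding. Padded rows are zeroed before the
#' convolution so they cannot leak through the kernel support.
#'
#' @param encoded `T x model_dim` matrix from [encode_temporal()].
#' @param model A `cle_temporal_model`.
#' @param mask Logical vector, `TRUE` for real frames.
#' @return Numeric vector of length `conv_channels`.
#' @export
aggregate_temporal <- function(encoded, model, mask = NULL) {
  stopifnot(inherits(model, "cle_temporal_model"))
  encoded <- as.matrix(encoded)
  mask <- mask %||% rep(TRUE, nrow(encoded))
  assert_that(sum(mask) > 0, "all-padded sequence")
  hm <- encoded * mask
  cv <- conv1d_fwd(hm, model$params$conv_W, model$params$conv_b)
  act <- if (model$config$conv_activation == "relu") pmax(cv$y, 0) else cv$y
  colSums(act * mask) / sum(mask)
}

#' Classify a global temporal embedding
#'
#' Fully connected layer followed by a softmax over the two grades.
#'
#' @param embedding Numeric vector of length `conv_channels`.
#' @param model A `cle_temporal_model`.
#' @return A `grade_prediction` with probabilities summing to 1.
#' @export
classify <- function(embedding, model) {
  stopifnot(inherits(model, "cle_temporal_model"))
  assert_that(length(embedding) == nrow(model$params$head_W),
              "embedding length does not match head input")
  logits <- as.numeric(embedding %*% model$params$head_W + model$params$head_b)
  new_grade_prediction(logits)
}

#' Predict the grade of one CLE examination sequence
#'
#' Full composition: per-frame backbone features, input projection and
#' positional encoding, transformer encoder, temporal convolution with
#' global pooling, softmax head. One prediction per examination. Also
#' accepts a precomputed `T x D` feature matrix (class `cle_features` or
#' plain matrix), skipping the backbone.
#'
#' @param sequence A `cle_sequence`, or a `T x D` feature matrix.
#' @param model A `cle_temporal_model`.
#' @return A `grade_prediction`.
#' @export
predict_sequence <- function(sequence, model) {
  stopifnot(inherits(model, "cle_temporal_model"))
  feats <- if (is.matrix(sequence)) {
    sequence
  } else {
    extract_features(sequence, model$backbone)
  }
  assert_that(nrow(feats) >= 1, "empty sequence")
  x <- apply_feature_scaling(unclass_features(feats), model$scaling)
  out <- temporal_forward(model$params, model$config, x)
  new_grade_prediction(out$logits)
}

unclass_features <- function(x) {
  x <- unclass(x)
  attributes(x) <- list(dim = dim(x))
  x
}

# ---- frame-based baseline ---------------------------------------------------

new_frame_model <- function(W, b, backbone, scaling = NULL) {
  structure(list(W = W, b = b, backbone = backbone, scaling = scaling),
            class = "cle_frame_model")
}

#' @export
print.cle_frame_model <- function(x, ...) {
  cat(sprintf("<cle_frame_model> softmax head on %s features (D=%d)\n",
              x$backbone$family, nrow(x$W)))
  invisible(x)
}

#' Frame-based baseline prediction for an examination
#'
#' The conventional baseline: the backbone plus a softmax head applied to
#' every frame independently (no temporal modeling), with the per-frame
#' predictions combined into one per-examination label. `"majority"` takes
#' the majority vote of per-frame argmax labels, breaking ties toward
#' high-grade (privileging sensitivity); `"mean_prob"` averages per-frame
#' class probabilities and takes the argmax. Both rules are symmetric in the
#' frame order, so the baseline is frame-permutation-invariant — in contrast
#' to the sequence model.
#'
#' @param sequence A `cle_sequence`, or a precomputed `T x D` feature matrix.
#' @param frame_model A `cle_frame_model` from [train_frame_baseline()].
#' @param aggregation `"majority"` or `"mean_prob"`.
#' @return A `grade_prediction`; per-frame probabilities are attached as
#'   `frame_detail`.
#' @export
predict_frame_baseline <- function(sequence, frame_model,
                                   aggregation = c("majority", "mean_prob")) {
  stopifnot(inherits(frame_model, "cle_frame_model"))
  aggregation <- match.arg(aggregation)
  feats <- if (is.matrix(sequence)) {
    sequence
  } else {
    extract_features(sequence, frame_model$backbone)
  }
  assert_that(nrow(feats) >= 1, "empty sequence")
  x <- apply_feature_scaling(unclass_features(feats), frame_model$scaling)
  logits <- sweep(x %*% frame_model$W, 2, frame_model$b, "+")
  probs <- softmax_rows(logits)
  frame_labels <- label_levels[max.col(probs, ties.method = "first")]
  detail <- tibble::tibble(frame = seq_len(nrow(probs)),
                           prob_high = probs[, 1], prob_low = probs[, 2],
                           label = frame_labels)
  if (aggregation == "majority") {
    n_high <- sum(frame_labels == "high")
    n_low <- sum(frame_labels == "low")
    agg_logits <- if (n_high >= n_low) c(1, 0) else c(0, 1) # tie -> high
  } else {
    mp <- colMeans(probs)
    agg_logits <- log(pmax(mp, 1e-12))
  }
  new_grade_prediction(agg_logits, frame_detail = detail)
}
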