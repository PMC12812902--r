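backbone_registry <- list(
  tiny_test_cnn       = list(input_size = 32L,  embedding_dim = 32L),
  inception_resnet_v2 = list(input_size = 299L, embedding_dim = 1536L),
  resnet50            = list(input_size = 224L, embedding_dim = 2048L),
  vgg16               = list(input_size = 224L, embedding_dim = 4096L),
  vision_transformer  = list(input_size = 224L, embedding_dim = 768L)
)

#' Specify a visual feature backbone
#'
#' A backbone encodes each frame independently into a fixed-length embedding;
#' all temporal reasoning happens downstream. Four ImageNet-pretrained
#' families are registered with their conventional input sizes and embedding
#' dimensions, plus `tiny_test_cnn`: a small randomly initialized CNN
#' (3 strided conv blocks, 8 channels, coarse 2x2 spatial pooling, D = 32)
#' that needs no download and is the backbone used throughout the package's
#' experiments and tests. Its pooling keeps a coarse 2x2 spatial layout
#' rather than a strict global average so that silhouette *positions* remain
#' visible to the temporal model — a strictly translation-invariant embedding
#' would erase the motion cue that separates flowing red blood cells from
#' static tumor cells.
#'
#' @param family Backbone family name.
#' @param weights `"random"` or `"pretrained"`. Pretrained weights are only
#'   meaningful for the ImageNet families and require an external runtime and
#'   weight files; `tiny_test_cnn` is always randomly initialized from
#'   `seed`.
#' @param frozen Keep backbone weights fixed during training (default; the
#'   temporal model is trained on top of frozen per-frame features).
#' @param input_size Input side length; defaults to the family convention.
#' @param seed Seed for random weight initialization (He-scaled normals).
#' @return An object of class `backbone_spec`, carrying initialized
#'   parameters for `tiny_test_cnn`.
#' @examples
#' spec <- backbone_spec("tiny_test_cnn", seed = 1)
#' spec$embedding_dim
#' @export
backbone_spec <- function(family = c("tiny_test_cnn", "inception_resnet_v2",
                                     "resnet50", "vgg16",
                                     "vision_transformer"),
                          weights = c("random", "pretrained"),
                          frozen = TRUE,
                          input_size = NULL,
                          seed = 42L) {
  family <- match.arg(family)
  weights <- match.arg(weights)
  reg <- backbone_registry[[family]]
  input_size <- as.integer(input_size %||% reg$input_size)
  spec <- list(family = family, weights = weights, frozen = isTRUE(frozen),
               input_size = input_size, embedding_dim = reg$embedding_dim,
               seed = as.integer(seed), params = NULL)
  if (family == "tiny_test_cnn") {
    assert_that(input_size %% 8 == 0 && input_size >= 16,
                "tiny_test_cnn input_size must be a multiple of 8, >= 16")
    spec$params <- init_tiny_cnn(seed)
  }
  class(spec) <- "backbone_spec"
  spec
}

# He-initialized 3-block CNN: 1 -> 8 -> 8 -> 8 channels, 3x3 kernels,
# stride 2, zero-padding 1. Followed by 2x2 quadrant average pooling.
init_tiny_cnn <- function(seed, channels = 8L, n_blocks = 3L) {
  with_seed(seed, {
    cin <- 1L
    layers <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      sd <- sqrt(2 / (3 * 3 * cin))
      layers[[b]] <- list(
        W = array(stats::rnorm(3 * 3 * cin * channels, 0, sd),
                  dim = c(3, 3, cin, channels)),
        b = rep(0, channels)
      )
      cin <- channels
    }
    list(layers = layers, channels = channels)
  })
}

# ---- minimal conv2d via im2col ---------------------------------------------

im2col <- function(xpad, k, stride, out_h, out_w) {
  cin <- dim(xpad)[3]
  P <- matrix(NA_real_, out_h * out_w, k * k * cin)
  idx <- 0L
  rows0 <- seq(1L, by = stride, length.out = out_h)
  cols0 <- seq(1L, by = stride, length.out = out_w)
  for (ci in seq_len(cin)) {
    for (kj in seq_len(k)) {
      for (ki in seq_len(k)) {
        idx <- idx + 1L
        P[, idx] <- as.vector(xpad[rows0 + ki - 1L, cols0 + kj - 1L, ci])
      }
    }
  }
  P
}

flatten_kernel <- function(W) {
  k <- dim(W)[1]; cin <- dim(W)[3]; cout <- dim(W)[4]
  Wm <- matrix(NA_real_, k * k * cin, cout)
  for (co in seq_len(cout)) {
    idx <- 0L
    for (ci in seq_len(cin)) {
      for (kj in seq_len(k)) {
        for (ki in seq_len(k)) {
          idx <- idx + 1L
          Wm[idx, co] <- W[ki, kj, ci, co]
        }
      }
    }
  }
  Wm
}

conv2d_relu <- function(x, W, b, stride = 2L, pad = 1L) {
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]
  k <- dim(W)[1]; cout <- dim(W)[4]
  xpad <- array(0, dim = c(h + 2 * pad, w + 2 * pad, cin))
  xpad[pad + seq_len(h), pad + seq_len(w), ] <- x
  out_h <- (h + 2 * pad - k) %/% stride + 1L
  out_w <- (w + 2 * pad - k) %/% stride + 1L
  P <- im2col(xpad, k, stride, out_h, out_w)
  Y <- P %*% flatten_kernel(W)
  Y <- sweep(Y, 2, b, "+")
  Y[Y < 0] <- 0
  array(Y, dim = c(out_h, out_w, cout))
}

# Forward pass of the tiny CNN on one grayscale frame (matrix in [0,1]).
# Returns the 32-dim embedding; with keep_activations = TRUE also the
# post-ReLU activation stack of the last conv block (for Grad-CAM).
tiny_cnn_forward <- function(frame, params, keep_activations = FALSE) {
  x <- array(frame, dim = c(nrow(frame), ncol(frame), 1L))
  for (b in seq_along(params$layers)) {
    x <- conv2d_relu(x, params$layers[[b]]$W, params$layers[[b]]$b)
  }
  pooled <- quadrant_pool(x)
  if (keep_activations) list(embedding = pooled, activations = x) else pooled
}

# Average-pool each channel over a 2x2 grid of spatial quadrants and
# concatenate: embedding index = (quadrant - 1) * channels + channel.
quadrant_pool <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]; cc <- dim(x)[3]
  assert_that(h >= 2 && w >= 2, "activation map too small for quadrant pooling")
  hs <- list(seq_len(h %/% 2), (h %/% 2 + 1):h)
  ws <- list(seq_len(w %/% 2), (w %/% 2 + 1):w)
  out <- numeric(4 * cc)
  q <- 0L
  for (wi in 1:2) {
    for (hi in 1:2) {
      q <- q + 1L
      sub <- x[hs[[hi]], ws[[wi]], , drop = FALSE]
      out[(q - 1L) * cc + seq_len(cc)] <- apply(sub, 3, mean)
    }
  }
  out
}

# Gradient of the embedding wrt the last-block activations: scatter the
# embedding gradient back through the quadrant average.
quadrant_pool_backward <- function(g, dims) {
  h <- dims[1]; w <- dims[2]; cc <- dims[3]
  dx <- array(0, dim = dims)
  hs <- list(seq_len(h %/% 2), (h %/% 2 + 1):h)
  ws <- list(seq_len(w %/% 2), (w %/% 2 + 1):w)
  q <- 0L
  for (wi in 1:2) {
    for (hi in 1:2) {
      q <- q + 1L
      npix <- length(hs[[hi]]) * length(ws[[wi]])
      for (c in seq_len(cc)) {
        dx[hs[[hi]], ws[[wi]], c] <- dx[hs[[hi]], ws[[wi]], c] +
          g[(q - 1L) * cc + c] / npix
      }
    }
  }
  dx
}

#' Extract per-frame visual embeddings from a sequence
#'
#' Applies the backbone independently to every frame of a model-input batch
#' (or a `cle_sequence`, which is preprocessed first), yielding a `T x D`
#' feature matrix. Frames never mix at this stage: permuting input frames
#' permutes the embedding rows identically, and repeated identical frames
#' yield identical rows. With fixed weights the mapping is deterministic.
#'
#' @param x A `T x C x H x W` array from [to_model_input()], or a
#'   `cle_sequence`.
#' @param spec A [backbone_spec()]. Only `tiny_test_cnn` can run without
#'   user-supplied pretrained weights.
#' @return A `T x D` numeric matrix of class `cle_features`; sequence
#'   metadata (id, label) is carried in attributes when available.
#' @export
extract_features <- function(x, spec = backbone_spec()) {
  stopifnot(inherits(spec, "backbone_spec"))
  if (spec$family != "tiny_test_cnn") {
    stop(sprintf(paste(
      "backbone family '%s' requires ImageNet-pretrained weights and a",
      "deep-learning runtime that this package does not bundle;",
      "use family = 'tiny_test_cnn' for self-contained experiments"),
      spec$family), call. = FALSE)
  }
  meta <- list()
  if (inherits(x, "cle_sequence")) {
    meta <- list(sequence_id = x$sequence_id, case_id = x$case_id,
                 label = x$label)
    x <- preprocess_sequence(x, input_size = spec$input_size)
  }
  assert_that(length(dim(x)) == 4, "input must be a T x C x H x W array")
  assert_that(dim(x)[3] == spec$input_size && dim(x)[4] == spec$input_size,
              sprintf("spatial size %dx%d does not match backbone input %d",
                      dim(x)[3], dim(x)[4], spec$input_size))
  tt <- dim(x)[1]
  feats <- matrix(NA_real_, tt, spec$embedding_dim)
  for (t in seq_len(tt)) {
    # channel replication is inverted by averaging; tiny CNN is single-channel
    frame <- apply(x[t, , , , drop = FALSE], c(3, 4), mean)
    feats[t, ] <- tiny_cnn_forward(frame, spec$params)
  }
  assert_that(all(is.finite(feats)), "non-finite activations in backbone")
  structure(feats, class = c("cle_features", "matrix"),
            sequence_id = meta$sequence_id %||% NA_character_,
            case_id = meta$case_id %||% NA_character_,
            label = meta$label %||% NA_character_)
}
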