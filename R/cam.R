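#' Class activation map for one frame
#'
#' Gradient-weighted class activation mapping on the tiny CNN backbone: the
#' gradient of the target-class logit is propagated back to the last
#' convolutional block's (post-ReLU) activation maps; each channel is
#' weighted by its spatially averaged gradient, the weighted sum is
#' rectified, min-max normalized to `[0, 1]` (a constant relevance map
#' normalizes to all zeros), and bilinearly upsampled to the input frame
#' resolution. For the sequence model the frame is scored as a single-frame
#' sequence, so the gradient path runs through the full temporal head; for
#' the frame-based baseline it runs through the per-frame softmax head.
#'
#' @param model A `cle_temporal_model` or `cle_frame_model` with a
#'   `tiny_test_cnn` backbone (the registered activation layer).
#' @param frame Numeric matrix in `[0, 1]` (any size; resized to the
#'   backbone input internally).
#' @param target_class `"high"` or `"low"`.
#' @return An object of class `cam_map`: list with `map` (relevance matrix
#'   at frame resolution, values in `[0, 1]`, max = 1 unless identically 0),
#'   `target_class` and `frame_dim`.
#' @export
compute_cam <- function(model, frame, target_class = c("high", "low")) {
  target_class <- match.arg(target_class)
  backbone <- model$backbone
  assert_that(!is.null(backbone) && backbone$family == "tiny_test_cnn",
              "compute_cam requires a model with a registered tiny_test_cnn activation layer")
  assert_that(is.matrix(frame) && is.numeric(frame), "frame must be a matrix")
  small <- resize_frame(frame, backbone$input_size)
  fwd_bb <- tiny_cnn_forward(small, backbone$params, keep_activations = TRUE)
  A <- fwd_bb$activations # post-ReLU maps of the last conv block
  emb <- fwd_bb$embedding
  g_emb <- embedding_gradient(model, emb, label_to_index(target_class))
  dA <- quadrant_pool_backward(g_emb, dim(A))
  # channel weights: spatial mean of the gradient, then rectified weighted sum
  alpha <- apply(dA, 3, mean)
  M <- matrix(0, dim(A)[1], dim(A)[2])
  for (c in seq_len(dim(A)[3])) M <- M + alpha[c] * A[, , c]
  M[M < 0] <- 0
  rng <- range(M)
  M <- if (diff(rng) < 1e-12) M * 0 else (M - rng[1]) / diff(rng)
  up <- bilinear_resize(M, nrow(frame), ncol(frame))
  up <- clamp01(up)
  if (max(up) > 0) up <- up / max(up)
  structure(list(map = up, target_class = target_class,
                 frame_dim = dim(frame)),
            class = "cam_map")
}

# Gradient of the target-class logit with respect to the frame embedding.
embedding_gradient <- function(model, emb, class_idx) {
  onehot <- c(0, 0); onehot[class_idx] <- 1
  if (inherits(model, "cle_frame_model")) {
    return(as.numeric(model$W[, class_idx]))
  }
  stopifnot(inherits(model, "cle_temporal_model"))
  x <- matrix(emb, nrow = 1)
  fwd <- temporal_forward(model$params, model$config, x, need_cache = TRUE)
  bwd <- temporal_backward(model$params, model$config, fwd$cache, onehot)
  as.numeric(bwd$dx)
}

#' @export
print.cam_map <- function(x, ...) {
  cat(sprintf("<cam_map> %dx%d, class %s, peak %.2f\n",
              nrow(x$map), ncol(x$map), x$target_class, max(x$map)))
  invisible(x)
}

# Blue -> cyan -> yellow -> red colormap (warm = high relevance).
cam_colormap <- function(v) {
  ramp <- grDevices::colorRamp(c("#0000AA", "#00FFFF", "#FFFF00", "#FF0000"))
  ramp(clamp01(v)) / 255
}

#' Overlay a class activation map on its frame
#'
#' Alpha-blends the relevance heatmap, mapped through a blue-to-red
#' colormap (warm colors = high relevance), onto the grayscale frame. The
#' output is deterministic: identical inputs produce identical RGB values.
#'
#' @param frame Numeric matrix in `[0, 1]`.
#' @param cam A `cam_map` with dimensions matching `frame`.
#' @param alpha Blend weight of the heatmap in `[0, 1]`.
#' @return `H x W x 3` numeric array in `[0, 1]`.
#' @export
overlay_cam <- function(frame, cam, alpha = 0.45) {
  stopifnot(inherits(cam, "cam_map"))
  assert_that(all(dim(frame) == dim(cam$map)),
              "frame and CAM dimensions differ")
  assert_that(is_prob(alpha), "alpha must lie in [0, 1]")
  cols <- cam_colormap(as.vector(cam$map))
  out <- array(NA_real_, dim = c(nrow(frame), ncol(frame), 3))
  for (ch in 1:3) {
    out[, , ch] <- (1 - alpha) * frame +
      alpha * matrix(cols[, ch], nrow(frame), ncol(frame))
  }
  clamp01(out)
}

#' Center of mass of a CAM relevance map
#'
#' Intensity-weighted centroid in (row, column) pixel coordinates; used to
#' check that the model's evidence localizes on hypercellular regions.
#'
#' @param cam A `cam_map`.
#' @return Numeric `c(row, col)`, or `c(NA, NA)` for an all-zero map.
#' @export
cam_center_of_mass <- function(cam) {
  stopifnot(inherits(cam, "cam_map"))
  m <- cam$map
  tot <- sum(m)
  if (tot == 0) return(c(NA_real_, NA_real_))
  rows <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
  cols <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE)
  c(sum(rows * m), sum(cols * m)) / tot
}
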